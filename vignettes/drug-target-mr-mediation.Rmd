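---
title: "Drug-target Mendelian randomization with two-step mediation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target MR with two-step mediation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The design

`mrmediate` implements a four-stage drug-target Mendelian randomization
(MR) analysis on GWAS summary statistics:

1. **Cis-instrument selection.** Variants are admitted as proxies for
   pharmacological target inhibition only if they (i) are expression QTLs
   for the target gene, (ii) lie in the cis region around the gene, and
   (iii) associate with the target's downstream biomarker at
   P < 1×10⁻⁴. Survivors are clumped at r² < 0.8 — deliberately
   permissive, because a cis region rarely contains many independent
   signals and correlated instruments still add information.
2. **Colocalization gate.** Before trusting the locus, a Bayesian
   colocalization test asks whether target expression and the biomarker
   share a single causal variant; the locus is carried forward only when
   the shared-variant posterior PP4 strictly exceeds 0.70.
3. **Outcome MR.** Five estimators relate instrument-outcome to
   instrument-exposure effects, with heterogeneity (Cochran's Q) and
   directional-pleiotropy (Egger intercept) diagnostics.
4. **Mediator screen and mediation.** Each of M candidate metabolites is
   screened (exposure→metabolite, Bonferroni α/M; metabolite→outcome on
   the metabolite's own instruments, Bonferroni α/K with K the observed
   step-1 survivors), and double-survivors get a two-step MR
   decomposition of the total effect.

The standard MR assumptions apply throughout: instruments are associated
with the exposure (checked via F-statistics, with F > 10 the conventional
bar), independent of confounders, and affect the outcome only through the
exposure (probed, not guaranteed, by the Egger intercept and Q).

## Estimators

With harmonized per-SNP effects (β̂ₓⱼ, β̂ᵧⱼ) and outcome standard errors
σᵧⱼ, weights wⱼ = 1/σᵧⱼ²:

- **IVW (primary).** Zero-intercept weighted regression,
  β̂ = Σwⱼβ̂ₓⱼβ̂ᵧⱼ / Σwⱼβ̂ₓⱼ². The random-effects treatment is
  *multiplicative*: the fixed-effect standard error is inflated by
  √max(1, Q/(k−1)). The additive (DerSimonian–Laird) alternative was
  rejected because the multiplicative model is the dominant two-sample MR
  convention and leaves the point estimate untouched.
- **MR-Egger.** The same regression with an intercept, after orienting
  every SNP to a positive exposure effect (exposure-decreasing alleles
  are recoded, not dropped). The intercept estimates average directional
  pleiotropy; residual heterogeneity (df = k−2) uses the same
  multiplicative inflation, applied to slope and intercept alike.
- **Weighted median.** Ratio estimates θⱼ = β̂ᵧⱼ/β̂ₓⱼ with weights
  (β̂ₓⱼ/σᵧⱼ)², interpolated at the half-shifted cumulative weight
  pⱼ = cumⱼ − wⱼ/2 crossing 0.5. Consistent while valid instruments hold
  ≥ 50% of the weight.
- **Simple/weighted mode.** Argmax of a gaussian-kernel density over θ.
  Bandwidth is the median-absolute-deviation normal-reference rule
  0.9·mad(θ)·k^(−1/5) times a user factor (default 1); the density is
  evaluated on a 512-point grid spanning the θ range ± 3 bandwidths and
  the maximum refined by golden-section search. If mad(θ) = 0 the sd is
  used; if all θ coincide the common value is returned.
- **Wald ratio.** Single-SNP fallback; first-order standard error
  σᵧ/|β̂ₓ| by default, with the second-order exposure-uncertainty term
  available by flag.

P-values are two-sided normal for every method (not t) — a documented,
configurable convention. Median and mode standard errors come from a
parametric bootstrap (default 1000 draws) with an explicit seed argument,
so pipelines are reproducible.

Exposure orientation: when the exposure is an *inhibition* proxy (effects
per SD of biomarker lowering), `invert_exposure = TRUE` negates the
instrument-exposure effects so protective outcome effects keep their
conventional sign.

## Colocalization

Per-SNP evidence is the Wakefield approximate Bayes factor: with
z = β̂/se and r = w²/(w² + se²),
log ABF = ½log(1−r) + ½z²r. The prior effect scale w defaults to 0.15
for quantitative traits (0.2 is the usual choice for log-odds). The five
hypotheses are accumulated entirely in log space with log-sum-exp, so
|z| > 30 cannot overflow; the distinct-variant sum uses
L3 = L1·L2 − L4 via `log1p`, which is exact for a single-SNP region
(PP3 ≡ 0). Priors default to p1 = p2 = 1e-4, p12 = 1e-5, the cited
method's conventional values; only the 70% rule is fixed by the design,
so priors are arguments. "Colocalization probability" is read as PP4
alone, not PP3+PP4 — the stricter and more common reading; the gate
threshold is an argument for users who prefer the other.

## Mediation

Two-step MR estimates β1 (exposure→mediator, on the exposure's
instruments), β2 (mediator→outcome, on the *mediator's own* genome-wide
instruments, univariable rather than multivariable — matching the
described procedure; the exposure-adjusted alternative is a known
variant) and the total effect α. Indirect effect β1·β2 with first-order
product-delta standard error √(β1²se2² + β2²se1²); proportion mediated
β1·β2/α with first-order ratio-delta variance
se²ᵢₙd/α² + (β1β2)²se²_α/α⁴. Independence of the three estimates is
assumed (distinct instrument sets, non-overlapping samples) and
covariance terms are omitted — standard two-sample practice and a
documented limitation. The second-order product term se1²se2² is off by
default, available by flag. A proportion outside [−1, 1] flags
inconsistent mediation (warning, never an error); α = 0 makes the
proportion undefined (error).

## Harmonization and selection conventions

- Palindromic SNPs (A/T, C/G) are dropped when the effect-allele
  frequency is missing or within w = 0.08 of 0.5 on either side
  (configurable); otherwise frequency concordance decides orientation.
  The conservative two-sample MR convention — allele labels alone cannot
  resolve strand for a palindrome.
- Non-palindromic strand flips are resolved by complementing alleles.
- Duplicate SNP ids keep the smallest p-value; positions are 1-based;
  alleles upper-cased on read.
- A p-value disagreeing with the Wald p by more than a factor of 10
  (compared on the log₁₀ scale, so underflowing z-scores are still
  caught) warns but never drops: meta-analysis p-values legitimately
  differ from β/se.
- Clumping is greedy and plink-style: rank by p (ties by chromosome,
  position — fully deterministic and order-invariant), accept the best,
  remove correlated neighbours within the window, repeat. The cis
  clumping window defaults to 1000 kb (the region is small; the window
  only needs to span it) and the cis region to gene ± 100 kb — neither is
  dictated by the design, both are arguments. Downstream IVW treats the
  r² < 0.8 cis instruments as independent; no correlation-aware estimator
  is provided, so cis standard errors are somewhat optimistic — a
  documented property of the permissive cis threshold.
- Per-SNP variance explained uses
  R²ⱼ = 2fⱼ(1−fⱼ)βⱼ² / (2fⱼ(1−fⱼ)βⱼ² + 2fⱼ(1−fⱼ)nⱼseⱼ²) with the
  (β/se)² fallback F when frequency or sample size is missing.

## The synthetic-data generator

Every validation runs on simulated summary statistics with known truth;
no genotype-level data is touched, which is adequate because every
downstream method consumes only summary data.

`simulate_mediation_study()` draws, for exposure instrument j with true
effect γⱼ: exposure β ~ N(γⱼ, se²ₑₓₚ), mediator
β ~ N(γⱼβ1 + πⱼ, se²ₘₑd), outcome β ~ N(γⱼα + πⱼ, se²ₒᵤₜ) with
α = θ_direct + β1β2 always derived, and pleiotropic effects πⱼ zero,
N(0, sd²) or N(mean, sd²). The mediator's own instruments follow the
same pattern with effects γ_med and outcome means γ_med·β2.

**Calibration of the default conditions.** The defaults encode a
six-instrument inhibition proxy with β1 = 0.65, β2 = 0.01,
θ_direct = 0.0435 (α = 0.05, proportion mediated 13%). Path-level
standard errors were back-computed from published 95% interval widths via
(hi − lo)/3.92 — se(β1) = 0.145, se(β2) = 0.0033, se(α) = 0.0128 — and
the per-SNP scales chosen once to reproduce them under IVW:
γ ∈ [0.024, 0.040] (Σγ² = 0.0062), se_out = 0.001 (consistent with a
kidney-function GWAS of n ≈ 5.7×10⁵), se_med = 0.0114 (a metabolite GWAS
of n ≈ 1.2×10⁵ at modest allele frequency), se_exp = 0.0026 (a biobank
biomarker GWAS of n ≈ 3.4×10⁵), and 20 mediator instruments with
γ_med ∈ [0.055, 0.080]. Per-SNP F ranges ≈ 85–240, comfortably above the
F > 10 bar. The screen presets (`panel-one-mediator`, `panel-null`) use a
strengthened variant (se_med = 0.006, γ_med ∈ [0.12, 0.16]) so that the
planted mediator's two gates are essentially deterministic while null
metabolites keep standard-normal z-scores — the regime the screen's
identification checks are meant to probe.

`simulate_coloc_region()` uses the standard single-causal-variant model
for marginal z-scores, z = R·z_causal + e with e ~ N(0, R) and R an
AR(1) correlation matrix (one parameter, always positive definite); the
shipped presets use causal |z| = 12 with ρ = 0.5 (shared) and ρ = 0.1
(distinct).

What the generator does **not** emulate: real LD beyond AR(1), allele
frequency–effect size coupling, sample overlap between studies, the
correlation structure of real metabolite panels, winner's-curse selection
of instruments, or population stratification. Passing tests therefore
demonstrate the correctness and calibration of the estimators under
their stated assumptions, not robustness to every failure mode of real
data.

## Problem sizes and numerics

The test and acceptance workloads use 200 replicates for mean recovery,
1000 for interval coverage, 500 for Egger test size (50 SNPs), 100 seeds
per colocalization preset, and 50/200 seeds for the screen's
identification/family-wise-error checks — sizes at which Monte-Carlo
standard errors are a few tenths of the quantities examined while the
whole suite runs in about a minute. All simulation entry points are pure
functions of their seed; bootstrap seeds are explicit arguments.

Numerical care points: colocalization in log space (above); IVW/Egger
closed-form weighted regressions (no matrix inversion needed at these
sizes); the mode search bounded to the observed θ range ± 3 bandwidths;
standard errors floored only in the simulator's noiseless limit so the
exact-recovery identity tests remain finite.

## Known limitations

- **Delta-interval coverage.** Under the calibrated default conditions
  the first-order delta 95% interval for the proportion mediated covers
  the true 13% in about 92–94% of replicates (the acceptance script
  recomputes this). The shortfall is a property of the first-order ratio
  delta with plug-in standard errors when the denominator is estimated
  with CV ≈ 0.25: the plug-in interval narrows exactly when the estimate
  strays, and the ratio distribution is right-skewed. Fieller or
  bootstrap intervals would be the remedy; they are out of scope here
  because the delta interval is the method under study.
- Correlated cis instruments are treated as independent by IVW (se
  optimism at the r² < 0.8 threshold).
- No MR-PRESSO outlier removal, multivariable MR, correlated-instrument
  IVW, SuSiE-style multi-causal colocalization, proxy-SNP lookup or
  genome-build liftover.
- The published cohort-scale estimates that motivate the default effect
  sizes require the full source datasets; here they serve as generative
  truths for calibration, not as quantities the package claims to
  reproduce from data.
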