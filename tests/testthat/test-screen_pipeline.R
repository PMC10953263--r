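test_that("bonferroni_threshold is exact and matches the printed gates", {
  expect_equal(bonferroni_threshold(0.05, 249), 0.05 / 249)
  expect_equal(signif(bonferroni_threshold(0.05, 249), 2), 2.0e-4)
  expect_equal(signif(bonferroni_threshold(0.05, 9), 2), 0.0056)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("the screen gates on alpha/M then alpha/K and audits every row", {
  panel <- simulate_preset("panel-one-mediator", seed = 2)
  sc <- run_screen(panel$exposure_instruments, panel$metabolite_stats,
                   panel$metabolite_instruments, panel$outcome_stats)
  expect_equal(nrow(sc), 20)
  expect_equal(attr(sc, "M"), 20)
  expect_equal(attr(sc, "step1_threshold"), 0.05 / 20)
  K <- attr(sc, "K")
  expect_equal(attr(sc, "step2_threshold"), 0.05 / K)
  expect_equal(sum(sc$step1_pass), K)
  # step-1/step-2 bookkeeping invariants
  expect_equal(sc$step1_pass, sc$step1_p < attr(sc, "step1_threshold"))
  expect_true(all(is.na(sc$step2_p[!sc$step1_pass])))
  expect_true(all(!is.na(sc$step2_p[sc$step1_pass])))
  expect_setequal(screen_mediators(sc),
                  sc$metabolite_id[sc$step1_pass & sc$step2_pass %in% TRUE])
  # the planted mediator is found, with a mediation decomposition attached
  expect_true("met_007" %in% screen_mediators(sc))
  med <- attr(sc, "mediation")[["met_007"]]
  expect_s3_class(med, "mediation_result")
  expect_true(sc$direction_consistent[sc$metabolite_id == "met_007"])
})

test_that("a survivor without step-2 instruments is flagged, not fatal", {
  panel <- simulate_preset("panel-one-mediator", seed = 3)
  inst <- panel$metabolite_instruments
  inst[["met_007"]] <- NULL
  sc <- run_screen(panel$exposure_instruments, panel$metabolite_stats,
                   inst, panel$outcome_stats)
  row <- sc[sc$metabolite_id == "met_007", ]
  expect_true(row$step1_pass)
  expect_match(row$note, "no instruments")
  expect_true(is.na(row$step2_p))
})

test_that("a single-metabolite screen reduces both gates to alpha", {
  panel <- simulate_metabolite_panel(1, true_mediator_index = 1,
                                     base_cfg = truth_config(), seed = 4)
  sc <- run_screen(panel$exposure_instruments, panel$metabolite_stats,
                   panel$metabolite_instruments, panel$outcome_stats)
  expect_equal(attr(sc, "step1_threshold"), 0.05)
  expect_equal(attr(sc, "step2_threshold"), 0.05)
})

test_that("screen results are reproducible from the seed", {
  p1 <- simulate_preset("panel-one-mediator", seed = 9)
  p2 <- simulate_preset("panel-one-mediator", seed = 9)
  s1 <- run_screen(p1$exposure_instruments, p1$metabolite_stats,
                   p1$metabolite_instruments, p1$outcome_stats)
  s2 <- run_screen(p2$exposure_instruments, p2$metabolite_stats,
                   p2$metabolite_instruments, p2$outcome_stats)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("the four-stage pipeline runs end to end on the shipped preset", {
  r <- full_pipeline(list(seed = 6))
  s <- r$stage_outputs
  expect_equal(s$instruments$n_instruments, 6)
  expect_gt(s$instruments$min_f, 10)
  expect_gt(s$coloc$PP4, 0.70)
  expect_gt(s$mr$ivw_beta, 0)                  # protective eGFR direction
  expect_equal(s$screen$mediators, "met_007")
  expect_true(is.finite(s$mediation$proportion))
})

test_that("the pipeline halts at the colocalization gate on a distinct locus", {
  expect_error(full_pipeline(list(seed = 6, coloc_preset = "coloc-distinct")),
               "colocalization gate")
})

test_that("a rerun with the same config reproduces the report", {
  r1 <- full_pipeline(list(seed = 8))
  r2 <- full_pipeline(list(seed = 8))
  expect_identical(r1$stage_outputs, r2$stage_outputs)
})

test_that("the pipeline writes its tables and a machine-readable report", {
  out <- file.path(tempfile("run"), "out")
  r <- full_pipeline(list(seed = 6, out_dir = out))
  for (f in c("instruments.tsv", "coloc.tsv", "mr_results.tsv", "screen.tsv",
              "mediation.tsv", "report.json"))
    expect_true(file.exists(file.path(out, f)))
  rep <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(rep$stage_outputs$instruments$n_instruments, 6)
  tab <- utils::read.table(file.path(out, "mr_results.tsv"), header = TRUE)
  expect_true("ivw_re" %in% tab$method)
})
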