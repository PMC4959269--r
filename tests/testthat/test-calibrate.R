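# cheap, fully deterministic statistic for calibration tests: basal-state
# levels of the receptor and C/EBPa as functions of two free parameters
basal_stat <- function(p) {
  b <- basal_state(p)
  c(ir_basal = b[["ir"]], cebpa_basal = b[["cebpa"]])
}

test_that("calibration is a fixed point when targets come from the start", {
  p0 <- adipo_params()
  s0 <- basal_stat(p0)
  targets <- calibration_targets(names(s0), unname(s0), tol = 0.05)
  res <- calibrate_params(basal_stat, targets,
                          bounds = list(syn_ir = c(0.01, 1), alpha6 = c(0.5, 10)),
                          base = p0, budget = 120, seed = 1)
  expect_true(res$ok)
  expect_lt(res$loss, 1e-10)
  expect_true(all(res$report$within_tol))
})

test_that("synthetic targets are recovered from a random start", {
  p_true <- adipo_params(syn_ir = 0.031, alpha6 = 4.2)
  s_true <- basal_stat(p_true)
  targets <- calibration_targets(names(s_true), unname(s_true), tol = 0.05)
  res <- calibrate_params(basal_stat, targets,
                          bounds = list(syn_ir = c(0.005, 0.5), alpha6 = c(0.5, 20)),
                          base = adipo_params(), budget = 400, seed = 2)
  expect_true(res$ok)
  expect_true(all(res$report$within_tol))
  # loss trace is non-increasing across accepted refinement steps
  expect_true(all(diff(res$trace) <= 1e-12))
})

test_that("unreachable mandatory targets yield a failure report, not an error", {
  targets <- calibration_targets("ir_basal", 1e6, tol = 0.01)
  res <- calibrate_params(basal_stat, targets,
                          bounds = list(syn_ir = c(0.01, 0.05)),
                          budget = 100, seed = 3)
  expect_false(res$ok)
  expect_false(any(res$report$within_3tol))
})

test_that("run_experiment writes a reproducible bundle", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cfg <- list(experiment = "simulate", seed = 5, total_h = 48, dt_out = 8,
              out_dir = out1)
  s1 <- run_experiment(cfg)
  expect_true(file.exists(file.path(out1, "trajectory.csv")))
  expect_true(file.exists(file.path(out1, "summary.json")))
  tr <- read_trajectory(file.path(out1, "trajectory.csv"))
  expect_identical(names(tr), c("time_h", adipo_species))
  expect_identical(nrow(tr), 7L)

  cfg$out_dir <- out2
  s2 <- run_experiment(cfg)
  j1 <- jsonlite::read_json(file.path(out1, "summary.json"))
  j2 <- jsonlite::read_json(file.path(out2, "summary.json"))
  expect_identical(j1, j2)

  expect_error(run_experiment(list(experiment = "made-up")), "unknown experiment")
  expect_error(run_experiment(list(seed = 1)), "experiment")
})

test_that("ensemble experiment reports bimodality of the end state", {
  out <- withr::local_tempdir()
  s <- run_experiment(list(experiment = "ensemble", seed = 11, n_cells = 250,
                           total_h = 96, out_dir = out))
  expect_true(file.exists(file.path(out, "cells.csv")))
  expect_true(is.logical(s$bimodal))
})
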