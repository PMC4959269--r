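test_that("the feedback-free model has exactly one fixed point at the linear balance", {
  p <- linear_params()
  v <- no_feedback_variant()
  fps <- find_fixed_points(p, list(insulin = 1), v)
  expect_identical(nrow(fps), 1L)
  expect_true(fps$stable[1])
  expect_equal(fps$pparg[1], p$syn_pparg * p$base_pparg / p$deg_pparg,
               tolerance = 1e-6)
  expect_equal(fps$cebpb[1], basal_state(p, v)[["cebpb"]], tolerance = 1e-4)
})

test_that("the calibrated switch has two stable states and one saddle", {
  fps <- find_fixed_points(inputs = list(insulin = 1))
  expect_identical(nrow(fps), 3L)
  expect_equal(fps$stable, c(TRUE, FALSE, TRUE))
  expect_lt(max(fps$residual), 1e-8)
  expect_gt(fps$pparg[3] / fps$pparg[1], 4)
  # the saddle sits between the stable states
  expect_true(fps$pparg[1] < fps$pparg[2] && fps$pparg[2] < fps$pparg[3])
})

test_that("brute-force basin mapping finds no attractor missing from the list", {
  p <- adipo_params()
  fps <- find_fixed_points(p, list(insulin = 1))
  stable <- fps[fps$stable, ]
  set.seed(17)
  starts <- matrix(runif(6 * 12, 0, 12), ncol = 6)
  for (i in seq_len(nrow(starts))) {
    y <- adiposwitch:::relax_to_steady(p, list(insulin = 1), feedback_variant(),
                                       starts[i, ], 800)
    d_rel <- apply(stable[, adipo_species], 1, function(s) {
      max(rel_err(y, unlist(s))[unlist(s) > 1e-3])
    })
    expect_lt(min(d_rel), 0.05)
  }
})

test_that("stable fixed points survive perturb-and-relax (Lyapunov check)", {
  p <- adipo_params()
  fps <- find_fixed_points(p, list(insulin = 1))
  for (i in which(fps$stable)) {
    y0 <- unlist(fps[i, adipo_species])
    y <- adiposwitch:::relax_to_steady(p, list(insulin = 1), feedback_variant(),
                                       y0 * 1.01, 1200)
    expect_lt(max(rel_err(y, y0)[y0 > 1e-6]), 1e-4)
  }
})

test_that("one-loop nullclines are explicit curves matching the fixed points", {
  p <- linear_params()
  nc <- nullclines_one_loop(p, cebpb_levels = 1,
                            cebpa_grid = seq(0, 4, length.out = 50),
                            pakt_clamp = 1)
  # in the feedback-free limit the PPARg nullcline is flat at the basal balance
  pn <- nc$curves[nc$curves$which == "pparg_nullcline", ]
  expect_lt(diff(range(pn$pparg)), 1e-6)
  expect_identical(nrow(nc$intersections), 1L)

  # calibrated model: a Hill-3 C/EBPa nullcline is sigmoidal in PPARg --
  # its maximum slope is much larger than its slope near zero
  p2 <- adipo_params()
  a_null <- function(P) p2$syn_cebpa / p2$deg_cebpa *
    (p2$base_cebpa + P^3 / (p2$alpha4^3 + P^3))
  P <- seq(0.05, 10, length.out = 400)
  sl <- diff(a_null(P)) / diff(P)
  expect_gt(max(sl), 5 * sl[1])
})

test_that("one-loop steady-state curves intersect once in most regimes", {
  # with loop 2 absent, C/EBPb is clamped; most clamp values give a single
  # intersection (no bistability), the paper's argument for the second loop
  nc <- nullclines_one_loop(cebpb_levels = c(0.3, 0.8, 1.5, 3, 6))
  counts <- table(nc$intersections$cebpb_level)
  expect_gte(mean(counts == 1), 0.6)
})

test_that("hysteresis: empty window without feedback, open window when intact", {
  lv <- 2^seq(-7, 4, length.out = 12)
  hb0 <- stimulus_sweep_hysteresis(linear_params(), no_feedback_variant(),
                                   "rosi", lv, relax_h = 300)
  expect_null(attr(hb0, "window"))
  expect_equal(hb0$forward, hb0$backward, tolerance = 1e-6)

  hb <- stimulus_sweep_hysteresis(channel = "rosi", levels = lv, relax_h = 500)
  expect_false(is.null(attr(hb, "window")))
  # forward branch is monotone non-decreasing in stimulus
  expect_true(all(diff(hb$forward) > -1e-6))
  # backward branch stays high at zero-side doses (memory)
  expect_gt(hb$backward[1], 0.5 * max(hb$forward))
})

test_that("irreversibility: intact model commits, loop2-less model reverts", {
  pr <- protocol_dim(48, 96)
  r1 <- irreversibility_test(protocol = pr, relax_h = 200)
  expect_true(r1$committed)
  r2 <- irreversibility_test(variant = feedback_variant(loop2_on = FALSE),
                             protocol = pr, relax_h = 200)
  expect_false(r2$committed)
  # no stimulus at all: no commitment
  r3 <- irreversibility_test(protocol = stimulus_protocol(
    tibble::tibble(channel = "insulin", start_h = 0, end_h = 96, level = 1), 96))
  expect_false(r3$committed)
})
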