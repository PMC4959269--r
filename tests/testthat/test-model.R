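test_that("pparg_activity follows the saturable ligand-boost law", {
  p <- adipo_params()
  expect_equal(pparg_activity(1, 0, p), 1)
  expect_equal(pparg_activity(0, 10, p), 0)
  p2 <- adipo_params(rosi_gain = 2)
  expect_equal(pparg_activity(1, p2$rosi_k, p2), 2)   # half-saturating dose
  # strictly increasing in dose when protein present
  doses <- c(0, 0.1, 1, 10, 100)
  act <- pparg_activity(1, doses, p)
  expect_true(all(diff(act) > 0))
  expect_error(pparg_activity(1, -1, p), "rosi_level")
})

test_that("derivatives match hand evaluation of the rate equations", {
  p <- unit_params()
  zero <- setNames(rep(0, 6), adipo_species)
  d0 <- adipo_derivatives(zero, p, list(gr = 0, camp = 0, insulin = 1, rosi = 0))
  # zero state kills every Hill term and all degradation; only syn*base remains
  # (the pAKT gate multiplies the PPARg feedback term, not its basal drive)
  expect_equal(unname(d0), c(1, 1, 1, 1, 1, 0), tolerance = 1e-12)

  ones <- setNames(c(1, 1, 1, 1, 1, 0), adipo_species)
  d1 <- adipo_derivatives(ones, p, list(gr = 1, camp = 1, insulin = 1, rosi = 0))
  # dB = (1 + 1*1 + 1/2) - 1; dP = (1 + (2^3/(1+2^3))*(1/2)) - 1
  # dA = (1 + 1/2) - 1; dK = (1+1)*1/(1+1) - 1; dR = (1 + 1/2) - 1
  # dFat = (1/2)*(1/2) - 0
  expect_equal(unname(d1), c(1.5, 8 / 18, 0.5, 0, 0.5, 0.25), tolerance = 1e-12)

  # removing loop 2 deletes only the activity term of the C/EBPb equation
  d1b <- adipo_derivatives(ones, p, list(gr = 1, camp = 1, insulin = 1, rosi = 0),
                           feedback_variant(loop2_on = FALSE))
  expect_equal(unname(d1b)[1], 1.0, tolerance = 1e-12)
  expect_equal(unname(d1b)[-1], unname(d1)[-1], tolerance = 1e-12)

  expect_error(adipo_derivatives(setNames(c(-1, 1, 1, 1, 1, 0), adipo_species), p),
               "finite and >= 0")
})

test_that("loop switches decouple the corresponding equations", {
  p <- adipo_params()
  s <- setNames(c(2, 3, 1.5, 1, 1, 0.2), adipo_species)
  # loop2 off: C/EBPb rate independent of PPARg
  v2 <- feedback_variant(loop2_on = FALSE)
  for (dP in c(0.5, 2, 7)) {
    s2 <- s; s2["pparg"] <- dP
    expect_equal(adipo_derivatives(s2, p, variant = v2)[["cebpb"]],
                 adipo_derivatives(s, p, variant = v2)[["cebpb"]])
  }
  # loop3 off: receptor rate independent of C/EBPa
  v3 <- feedback_variant(loop3_on = FALSE)
  for (dA in c(0.2, 1, 5)) {
    s3 <- s; s3["cebpa"] <- dA
    expect_equal(adipo_derivatives(s3, p, variant = v3)[["ir"]],
                 adipo_derivatives(s, p, variant = v3)[["ir"]])
  }
})

test_that("the alpha4 denominator switch reproduces the squared variant", {
  p <- adipo_params()
  s <- setNames(c(1, 2, 1, 1, 1, 0), adipo_species)
  d_cubed <- adipo_derivatives(s, p)[["cebpa"]]
  d_sq <- adipo_derivatives(s, p, alpha4_printed = TRUE)[["cebpa"]]
  act <- 2
  expect_equal(d_sq - d_cubed,
               p$syn_cebpa * (act^3 / (p$alpha4^2 + act^3) -
                                act^3 / (p$alpha4^3 + act^3)),
               tolerance = 1e-12)
})

test_that("basal fixed point: closed forms, annihilation and integration oracle", {
  # with all feedback silenced each species settles at syn*base/deg
  p <- linear_params()
  v <- no_feedback_variant()
  b <- basal_state(p, v)
  expect_equal(b[["pparg"]], p$syn_pparg * p$base_pparg / p$deg_pparg)
  expect_equal(b[["cebpa"]], p$syn_cebpa * p$base_cebpa / p$deg_cebpa,
               tolerance = 1e-6)
  expect_equal(b[["fat"]], 0)

  # reference parameters: residual is zero and a long zero-input run stays put
  p <- adipo_params()
  b <- basal_state(p)
  expect_lt(max(abs(adipo_derivatives(b, p))), 1e-8)
  prot0 <- stimulus_protocol(total_h = 500)
  tr <- simulate_adipo(prot0, p, initial = b, dt_out = NULL, times = 500)
  expect_lt(max(rel_err(unlist(tr[1, adipo_species]), b)[b > 0]), 1e-6)

  # transcription-factor basal levels are normalized to 1
  expect_equal(unname(b[c("cebpb", "pparg", "cebpa")]), c(1, 1, 1),
               tolerance = 1e-3)

  # total knockdown empties the cell
  v0 <- feedback_variant(knockdown = setNames(rep(0, 6), adipo_species))
  expect_equal(unname(basal_state(p, v0)), rep(0, 6))
})

test_that("zero-input protocol from the basal point is a constant trajectory", {
  p <- adipo_params()
  prot <- stimulus_protocol(total_h = 200)
  tr <- simulate_adipo(prot, p, dt_out = 20)
  b <- basal_state(p)
  drift <- apply(tr[, adipo_species], 1, function(r) max(rel_err(r, b)[b > 0]))
  expect_lt(max(drift), 1e-6)
})

test_that("adaptive integration agrees with the fixed-step RK4 oracle", {
  p <- adipo_params()
  prot <- protocol_dim(stim_h = 10, total_h = 24)
  times <- c(5, 10, 24)
  tr <- simulate_adipo(prot, p, dt_out = NULL, times = times)
  oracle <- rk4_protocol(prot, p, feedback_variant(), times)
  for (tt in times) {
    got <- unlist(tr[tr$time_h == tt, adipo_species])
    want <- oracle[[as.character(tt)]]
    expect_lt(max(rel_err(got, want)[want > 1e-8]), 1e-4)
  }
})

test_that("oracle equivalence holds across random parameter perturbations", {
  set.seed(101)
  base <- unlist(adipo_params())
  prot <- protocol_rosi_pulse(1, 4, 12)
  for (k in 1:10) {
    vals <- base * exp(rnorm(length(base), 0, 0.15))
    p <- adipo_params(values = as.list(vals))
    tr <- simulate_adipo(prot, p, dt_out = NULL, times = 12)
    want <- rk4_protocol(prot, p, feedback_variant(), 12)[["12"]]
    got <- unlist(tr[1, adipo_species])
    expect_lt(max(rel_err(got, want)[want > 1e-8]), 1e-4)
  }
})

test_that("trajectories are non-negative for random non-negative starts", {
  set.seed(77)
  p <- adipo_params()
  prot <- protocol_dim(total_h = 96)
  for (k in 1:5) {
    y0 <- setNames(runif(6, 0, 10), adipo_species)
    tr <- simulate_adipo(prot, p, initial = y0, dt_out = 8)
    expect_true(all(as.matrix(tr[, adipo_species]) >= 0))
  }
})

test_that("commitment persists after stimulus withdrawal in the standard run", {
  tr <- simulate_adipo(protocol_dim(total_h = 96), dt_out = NULL,
                       times = c(48, 96))
  expect_gte(tr$pparg[tr$time_h == 96], 0.5 * tr$pparg[tr$time_h == 48])
})

test_that("trajectory CSV round-trips", {
  tr <- simulate_adipo(protocol_rosi_pulse(1, 3, 6), dt_out = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(as.data.frame(back), as.data.frame(tr[, c("time_h", adipo_species)]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
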