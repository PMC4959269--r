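#' Fit a four-parameter Hill curve
#'
#' Least-squares fit of `r(d) = floor + (ceiling - floor) * d^n / (ec50^n + d^n)`
#' by Levenberg--Marquardt ([minpack.lm::nlsLM()]), multi-started over
#' initial Hill exponents 0.5, 1, 2 and 4; the best converged fit is
#' returned. The fit is scale-equivariant: rescaling doses rescales `ec50`
#' and rescaling responses rescales `floor`/`ceiling`, leaving `hill_n`
#' untouched.
#'
#' @param doses Positive doses; at least 6 points spanning at least two
#'   decades.
#' @param responses Responses, same length.
#' @return A `hill_fit`: list with `floor`, `ceiling`, `ec50`, `hill_n`,
#'   `rss`, `converged`, `n_obs` plus the data.
#' @examples
#' d <- 2^(0:11) / 16
#' r <- 0.2 + 0.8 * d^3 / (2^3 + d^3)
#' fit_hill(d, r)
#' @export
fit_hill <- function(doses, responses) {
  if (length(doses) != length(responses)) abort("doses and responses differ in length")
  if (length(doses) < 6) abort("need at least 6 dose points")
  if (any(doses <= 0)) abort("doses must be > 0")
  if (log10(max(doses) / min(doses)) < 2) abort("doses must span at least 2 decades")
  rng <- max(responses) - min(responses)
  if (rng < 0.05 * max(abs(responses))) {
    abort("flat curve: dynamic range below 5% of the maximal response")
  }
  dat <- data.frame(d = doses, r = responses)
  best <- NULL
  for (n0 in c(0.5, 1, 2, 4)) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        r ~ fl + (ce - fl) * d^n / (ec^n + d^n), data = dat,
        start = list(fl = min(responses), ce = max(responses),
                     ec = exp(mean(log(doses))), n = n0),
        lower = c(-Inf, -Inf, min(doses) * 1e-6, 0.05),
        upper = c(Inf, Inf, max(doses) * 1e6, 50),
        control = minpack.lm::nls.lm.control(maxiter = 300)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || deviance(fit) < deviance(best)) best <- fit
  }
  if (is.null(best)) abort("Hill fit failed from every start")
  cf <- coef(best)
  structure(list(floor = unname(cf["fl"]), ceiling = unname(cf["ce"]),
                 ec50 = unname(cf["ec"]), hill_n = unname(cf["n"]),
                 rss = deviance(best), converged = best$convInfo$isConv %||% TRUE,
                 n_obs = length(doses), doses = doses, responses = responses),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> floor %.4g ceiling %.4g ec50 %.4g n %.3g (rss %.3g)\n",
              x$floor, x$ceiling, x$ec50, x$hill_n, x$rss))
  invisible(x)
}

#' @exportS3Method
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("floor", "ceiling", "ec50", "hill_n"),
         estimate = c(x$floor, x$ceiling, x$ec50, x$hill_n))
}

#' @exportS3Method
glance.hill_fit <- function(x, ...) {
  tibble(floor = x$floor, ceiling = x$ceiling, ec50 = x$ec50,
         hill_n = x$hill_n, rss = x$rss, converged = x$converged,
         n_obs = x$n_obs)
}

#' @exportS3Method
augment.hill_fit <- function(x, ...) {
  pred <- x$floor + (x$ceiling - x$floor) *
    x$doses^x$hill_n / (x$ec50^x$hill_n + x$doses^x$hill_n)
  tibble(dose = x$doses, response = x$responses, .fitted = pred,
         .resid = x$responses - pred)
}

#' @exportS3Method
autoplot.hill_fit <- function(object, ...) {
  dd <- exp(seq(log(min(object$doses)), log(max(object$doses)), length.out = 200))
  pred <- object$floor + (object$ceiling - object$floor) *
    dd^object$hill_n / (object$ec50^object$hill_n + dd^object$hill_n)
  ggplot(tibble(dose = object$doses, response = object$responses),
         aes(.data$dose, .data$response)) +
    geom_point() +
    geom_line(data = tibble(dose = dd, response = pred)) +
    scale_x_log10() +
    labs(x = "dose", y = "response") +
    theme_minimal()
}

#' Deterministic dose-response of the model
#'
#' Runs the model at each dose of one input channel from the basal state and
#' records the chosen readouts, then attaches a Hill fit per readout. Two
#' readout modes are available. `"steady_state"` relaxes each dose at least
#' `t_settle` hours and reports the settled value of the forward
#' (basal-start) branch; in a bistable regime this branch jumps at the fold,
#' which the fit metadata flags. `"timed"` reports the value after
#' `readout_h` hours of sustained stimulation, matching endpoint-fixed
#' titration experiments; it is the default for reproducing 48-h
#' immunostaining dose curves.
#'
#' @param params An `adipo_params`.
#' @param variant A `feedback_variant`.
#' @param channel Stimulated channel, default `"rosi"`.
#' @param doses Dose vector; default a 12-point 2-fold dilution series.
#' @param readouts Species to record, default the three transcription
#'   factors.
#' @param mode `"timed"` (default) or `"steady_state"`.
#' @param readout_h Readout time for `"timed"` mode (h), default 48.
#' @param t_settle Relaxation time for `"steady_state"` mode (h, >= 240).
#' @param base_inputs Constant levels of the other channels
#'   (default `list(insulin = 1)`).
#' @return A `dose_response_curve`: tibble `dose` x readouts, with attribute
#'   `fits` (named list of `hill_fit`) and `settled` flags in steady-state
#'   mode.
#' @export
dose_response <- function(params = reference_params(),
                          variant = feedback_variant(), channel = "rosi",
                          doses = 2^seq(-7, 4, length.out = 12),
                          readouts = c("cebpb", "pparg", "cebpa"),
                          mode = c("timed", "steady_state"),
                          readout_h = 48, t_settle = 400,
                          base_inputs = list(insulin = 1)) {
  mode <- match.arg(mode)
  p <- validate_params(params)
  if (mode == "steady_state" && t_settle < 240) abort("t_settle must be >= 240 h")
  y0 <- basal_state(p, variant)
  rows <- vector("list", length(doses))
  settled <- rep(TRUE, length(doses))
  for (i in seq_along(doses)) {
    u <- base_inputs; u[[channel]] <- doses[i]
    if (mode == "steady_state") {
      y <- relax_to_steady(p, u, variant, y0, t_settle)
      f <- rhs_at(p, u, variant)
      if (max(abs(f(y))) > 1e-8) {
        y <- relax_to_steady(p, u, variant, y, t_settle)
        settled[i] <- max(abs(f(y))) <= 1e-8
      }
    } else {
      ctx <- .segment_ctx(p, lapply(c(gr = "gr", camp = "camp",
                                      insulin = "insulin", rosi = "rosi"),
                                    function(ch) u[[ch]] %||% 0), variant, FALSE)
      sol <- deSolve::lsoda(y0, c(0, readout_h), .rhs_desolve, ctx,
                            rtol = 1e-8, atol = 1e-10)
      y <- pmax(sol[nrow(sol), -1], 0)
    }
    rows[[i]] <- c(dose = doses[i], setNames(y, adipo_species))
  }
  curve <- as_tibble(as.data.frame(do.call(rbind, rows)))[, c("dose", readouts)]
  fits <- lapply(readouts, function(rd) {
    tryCatch(fit_hill(curve$dose, curve[[rd]]), error = function(e) NULL)
  })
  names(fits) <- readouts
  structure(curve, fits = fits, mode = mode, settled = settled,
            channel = channel,
            branch = "forward (basal-start); in a hysteretic regime the fit describes this branch only",
            class = c("dose_response_curve", class(curve)))
}

#' @rdname dose_response
#' @export
steady_state_dose_response <- function(params = reference_params(),
                                       variant = feedback_variant(),
                                       channel = "rosi",
                                       doses = 2^seq(-7, 4, length.out = 12),
                                       readouts = c("cebpb", "pparg", "cebpa"),
                                       t_settle = 400,
                                       base_inputs = list(insulin = 1)) {
  dose_response(params, variant, channel, doses, readouts,
                mode = "steady_state", t_settle = t_settle,
                base_inputs = base_inputs)
}

#' @exportS3Method
glance.dose_response_curve <- function(x, ...) {
  fits <- attr(x, "fits")
  bind_rows(imap(fits, function(f, rd) {
    if (is.null(f)) return(tibble(readout = rd))
    mutate(glance(f), readout = rd, .before = 1)
  }))
}

#' @exportS3Method
autoplot.dose_response_curve <- function(object, ...) {
  long <- pivot_longer(object, -"dose", names_to = "readout", values_to = "response")
  ggplot(long, aes(.data$dose, .data$response, colour = .data$readout)) +
    geom_point() + geom_line() +
    scale_x_log10() +
    labs(x = paste0(attr(object, "channel"), " dose"), y = "level (a.u.)") +
    theme_minimal()
}

#' Pulse amplitude x duration commitment matrix
#'
#' For every combination of rosiglitazone pulse amplitude and duration, runs
#' a stochastic ensemble through pulse plus washout and reports the fraction
#' of cells locked in the high-PPARg state at the end, with binomial
#' confidence intervals. The same seed (hence the same sampled cells) is
#' used for every condition so that the matrix is comparable across cells.
#'
#' @param amplitudes Pulse amplitudes (units of `rosi_k`).
#' @param durations Pulse durations (h).
#' @param base Base `adipo_params`.
#' @param noise A `noise_spec`.
#' @param n_cells Cells per condition.
#' @param total_h Total simulated time; must allow >= 24 h washout after the
#'   longest pulse.
#' @param seed Integer seed.
#' @param threshold PPARg threshold separating low from high; default is the
#'   log-midpoint of the deterministic low and high reference states.
#' @return Tibble: `amplitude`, `duration_h`, `fraction`, `conf_lo`,
#'   `conf_hi`, `n`, `n_failed`.
#' @export
pulse_matrix <- function(amplitudes, durations, base = reference_params(),
                         noise = noise_spec(), n_cells = 300,
                         total_h = NULL, seed = 1, threshold = NULL) {
  total_h <- total_h %||% (max(durations) + 48)
  if (total_h < max(durations) + 24) abort("total_h must leave >= 24 h washout")
  if (is.null(threshold)) {
    refs <- pparg_reference_states(base)
    threshold <- exp(mean(log(refs)))
  }
  rows <- list()
  for (a in amplitudes) for (d in durations) {
    prot <- protocol_rosi_pulse(a, d, total_h)
    tab <- run_population(n_cells, prot, base, noise, sample_times = total_h,
                          seed = seed)
    fr <- fraction_differentiated(tab, "pparg", total_h, threshold = threshold)
    rows[[length(rows) + 1]] <- mutate(fr, amplitude = a, duration_h = d,
                                       n_failed = attr(tab, "n_failed"),
                                       .before = 1)
  }
  bind_rows(rows) |>
    select("amplitude", "duration_h", "fraction", "conf_lo", "conf_hi",
           "n", "n_failed")
}

#' @rdname pulse_matrix
#' @param matrix_tbl Result of `pulse_matrix()`.
#' @export
plot_pulse_matrix <- function(matrix_tbl) {
  ggplot(matrix_tbl, aes(factor(.data$duration_h), factor(.data$amplitude),
                         fill = .data$fraction)) +
    geom_tile() +
    labs(x = "pulse duration (h)", y = "amplitude (rosi_k units)",
         fill = "fraction\ndifferentiated") +
    theme_minimal()
}
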