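#' Effective PPARg activity under a direct activator
#'
#' Thiazolidinediones such as rosiglitazone are ligands: they boost the
#' transcriptional activity of the PPARg protein that is present without
#' adding protein. The boost is saturable,
#' `activity = pparg * (1 + rosi_gain * rosi / (rosi_k + rosi))`,
#' and this activity value replaces the PPARg concentration wherever PPARg
#' acts as a regulator (in the C/EBPb, C/EBPa and fat equations).
#'
#' @param pparg PPARg concentration (a.u., >= 0).
#' @param rosi_level Rosiglitazone dose (units of `rosi_k`, >= 0).
#' @param params An `adipo_params`.
#' @return PPARg activity (a.u.).
#' @examples
#' pparg_activity(1, 0, adipo_params())            # == 1
#' pparg_activity(1, adipo_params()$rosi_k, adipo_params(rosi_gain = 2))  # == 2
#' @export
pparg_activity <- function(pparg, rosi_level, params) {
  if (any(!is.finite(rosi_level)) || any(rosi_level < 0)) {
    abort("rosi_level must be finite and >= 0")
  }
  pparg * (1 + params$rosi_gain * rosi_level / (params$rosi_k + rosi_level))
}

.hill <- function(x, k, n, denom_n = n) x^n / (k^denom_n + x^n)

#' Time derivatives of the model state
#'
#' Evaluates the right-hand side of the six ODEs at one state. The circuit:
#' glucocorticoid times cAMP drives C/EBPb; C/EBPb plus C/EBPa (third-power
#' Hill, gated by pAKT) drives PPARg; PPARg activity drives C/EBPa
#' (third-power Hill) and feeds back on C/EBPb (second-power Hill, loop 2);
#' C/EBPa drives insulin-receptor expression (loop 3); insulin acts through
#' the receptor to produce pAKT, which cAMP and glucocorticoid suppress; and
#' fat accumulates under joint graded control of pAKT and PPARg activity.
#'
#' @param state Named numeric vector (or list) with entries
#'   `cebpb, pparg, cebpa, pakt, ir, fat`, all finite and >= 0.
#' @param params An `adipo_params`.
#' @param inputs Named list/vector of channel levels `gr`, `camp`, `insulin`,
#'   `rosi` (missing channels default to 0).
#' @param variant A `feedback_variant`.
#' @param alpha4_printed If `TRUE`, use the squared `alpha4` in the C/EBPa
#'   denominator (`alpha4^2 + activity^3`) instead of the default cubed form.
#'   The default matches the numerator's exponent, which keeps the term
#'   dimensionless; the squared form is retained as a documented alternative.
#' @return Named numeric vector of rates (a.u./h) in species order.
#' @export
adipo_derivatives <- function(state, params, inputs = list(),
                              variant = feedback_variant(),
                              alpha4_printed = FALSE) {
  s <- unlist(state)[adipo_species]
  if (any(is.na(s))) abort("state must contain cebpb, pparg, cebpa, pakt, ir, fat")
  if (any(!is.finite(s)) || any(s < 0)) abort("state components must be finite and >= 0")
  u <- lapply(c(gr = "gr", camp = "camp", insulin = "insulin", rosi = "rosi"),
              function(ch) inputs[[ch]] %||% 0)
  if (any(unlist(u) < 0)) abort("input levels must be >= 0")
  p <- params
  kd <- variant$knockdown
  gr <- u$gr * kd[["gr-pathway"]]
  act <- pparg_activity(s[["pparg"]], u$rosi, p)

  d_cebpb <- kd[["cebpb"]] * p$syn_cebpb *
    (p$base_cebpb + gr * u$camp +
       (if (variant$loop2_on) .hill(act, p$alpha1, 2) else 0)) -
    p$deg_cebpb * s[["cebpb"]]
  d_pparg <- kd[["pparg"]] * p$syn_pparg *
    (p$base_pparg +
       .hill(s[["cebpb"]] + s[["cebpa"]], p$alpha2, 3) *
         s[["pakt"]] / (p$alpha3 + s[["pakt"]])) -
    p$deg_pparg * s[["pparg"]]
  d_cebpa <- kd[["cebpa"]] * p$syn_cebpa *
    (p$base_cebpa + .hill(act, p$alpha4, 3, denom_n = if (alpha4_printed) 2 else 3)) -
    p$deg_cebpa * s[["cebpa"]]
  d_pakt <- kd[["pakt"]] * p$syn_pakt * u$insulin *
    (p$base_ir + s[["ir"]]) * p$alpha5 / (p$alpha5 + u$camp * gr) -
    p$deg_pakt * s[["pakt"]]
  d_ir <- kd[["ir"]] * p$syn_ir *
    (p$base_ir +
       (if (variant$loop3_on) s[["cebpa"]] / (p$alpha6 + s[["cebpa"]]) else 0)) -
    p$deg_ir * s[["ir"]]
  d_fat <- kd[["fat"]] * p$syn_fat *
    (s[["pakt"]] / (p$alpha7 + s[["pakt"]])) * (act / (p$alpha8 + act)) -
    p$deg_fat * s[["fat"]]

  setNames(c(d_cebpb, d_pparg, d_cebpa, d_pakt, d_ir, d_fat), adipo_species)
}

# deSolve-facing RHS: no validation, flat numeric constants for speed
# cs layout: 1 b0 (kd*syn_B*(base+GRcAMP)), 2 b1 (kd*syn_B*loop2), 3 a1^2,
# 4 deg_B, 5 p0 (kd*syn_P*base), 6 p1 (kd*syn_P), 7 a2^3, 8 a3, 9 deg_P,
# 10 a0 (kd*syn_A*base), 11 a1c (kd*syn_A), 12 a4 denom, 13 deg_A,
# 14 k1 (kd*syn_K*u_ins*a5f), 15 base_ir, 16 deg_K, 17 r0 (kd*syn_R*base_ir),
# 18 r1 (kd*syn_R*loop3), 19 a6, 20 deg_R, 21 f1 (kd*syn_F), 22 a7, 23 a8,
# 24 deg_F, 25 boost
.rhs_desolve <- function(t, y, cs) {
  act <- y[2] * cs[25]
  act2 <- act * act
  act3 <- act2 * act
  ba <- y[1] + y[3]
  ba3 <- ba^3
  list(c(
    cs[1] + cs[2] * act2 / (cs[3] + act2) - cs[4] * y[1],
    cs[5] + cs[6] * ba3 / (cs[7] + ba3) * y[4] / (cs[8] + y[4]) - cs[9] * y[2],
    cs[10] + cs[11] * act3 / (cs[12] + act3) - cs[13] * y[3],
    cs[14] * (cs[15] + y[5]) - cs[16] * y[4],
    cs[17] + cs[18] * y[3] / (cs[19] + y[3]) - cs[20] * y[5],
    cs[21] * (y[4] / (cs[22] + y[4])) * (act / (cs[23] + act)) - cs[24] * y[6]
  ))
}

.segment_ctx <- function(params, u, variant, alpha4_printed) {
  p <- params
  kd <- variant$knockdown
  gr <- u$gr * kd[["gr-pathway"]]
  a5f <- p$alpha5 / (p$alpha5 + u$camp * gr)
  c(
    kd[["cebpb"]] * p$syn_cebpb * (p$base_cebpb + gr * u$camp),
    kd[["cebpb"]] * p$syn_cebpb * as.numeric(variant$loop2_on),
    p$alpha1^2,
    p$deg_cebpb,
    kd[["pparg"]] * p$syn_pparg * p$base_pparg,
    kd[["pparg"]] * p$syn_pparg,
    p$alpha2^3,
    p$alpha3,
    p$deg_pparg,
    kd[["cebpa"]] * p$syn_cebpa * p$base_cebpa,
    kd[["cebpa"]] * p$syn_cebpa,
    if (alpha4_printed) p$alpha4^2 else p$alpha4^3,
    p$deg_cebpa,
    kd[["pakt"]] * p$syn_pakt * u$insulin * a5f,
    p$base_ir,
    p$deg_pakt,
    kd[["ir"]] * p$syn_ir * p$base_ir,
    kd[["ir"]] * p$syn_ir * as.numeric(variant$loop3_on),
    p$alpha6,
    p$deg_ir,
    kd[["fat"]] * p$syn_fat,
    p$alpha7,
    p$alpha8,
    p$deg_fat,
    1 + p$rosi_gain * u$rosi / (p$rosi_k + u$rosi)
  )
}

#' Simulate the model under a stimulus protocol
#'
#' Integrates the six ODEs with a stiff-capable adaptive solver
#' (`deSolve::lsoda`, rtol 1e-8 / atol 1e-10). The integrator is restarted at
#' every protocol breakpoint so that stimulus discontinuities are handled
#' exactly. Tiny negative overshoots (below the absolute tolerance) are
#' clipped to zero; anything larger raises an error.
#'
#' @param protocol A `stimulus_protocol`.
#' @param params An `adipo_params` (default: reference set).
#' @param variant A `feedback_variant`.
#' @param initial Initial `ModelState` as named vector; default is the basal
#'   fixed point of the given parameters and variant.
#' @param dt_out Output sampling interval (h), default 1.
#' @param times Optional explicit output times (overrides `dt_out`).
#' @param alpha4_printed See [adipo_derivatives()].
#' @return An `adipo_trajectory`: a tibble with `time_h` and one column per
#'   species, plus attributes `params`, `protocol`, `variant`.
#' @examples
#' \donttest{
#' traj <- simulate_adipo(protocol_dim(total_h = 96))
#' tail(traj)
#' }
#' @export
simulate_adipo <- function(protocol, params = reference_params(),
                           variant = feedback_variant(), initial = NULL,
                           dt_out = 1, times = NULL, alpha4_printed = FALSE) {
  total <- attr(protocol, "total_h")
  if (is.null(total) || total <= 0) abort("protocol must have positive total_h")
  params <- validate_params(params)
  if (is.null(initial)) initial <- basal_state(params, variant, alpha4_printed)
  y <- unlist(initial)[adipo_species]
  if (any(is.na(y) | !is.finite(y) | y < 0)) abort("initial state must be finite and >= 0")

  out_t <- if (is.null(times)) {
    tt <- seq(0, total, by = dt_out)
    if (tail(tt, 1) < total) tt <- c(tt, total)
    tt
  } else sort(unique(as.numeric(times)))
  if (any(out_t < 0 | out_t > total)) abort("output times must lie within the protocol")

  bps <- protocol_breakpoints(protocol)
  rows <- list()
  if (out_t[1] == 0) rows[[1]] <- c(time_h = 0, y)
  for (k in seq_len(length(bps) - 1)) {
    t0 <- bps[k]; t1 <- bps[k + 1]
    u <- as.list(protocol_levels(protocol, t0)[1, .channels])
    ctx <- .segment_ctx(params, u, variant, alpha4_printed)
    inside <- out_t[out_t > t0 & out_t <= t1]
    tt <- unique(c(t0, inside, t1))
    sol <- try(deSolve::lsoda(y, tt, .rhs_desolve, ctx, rtol = 1e-8, atol = 1e-10),
               silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(tt)) {
      abort(paste0("integration failed in segment [", t0, ", ", t1, ") h; ",
                   "state at failure: ", paste(signif(y, 6), collapse = ", ")))
    }
    m <- sol[, -1, drop = FALSE]
    if (any(m < -1e-10)) abort("integration produced negative concentrations")
    m[m < 0] <- 0
    keep <- sol[, 1] %in% inside
    if (any(keep)) {
      rows[[length(rows) + 1]] <- cbind(time_h = sol[keep, 1], m[keep, , drop = FALSE])
    }
    y <- m[nrow(m), ]
  }
  res <- as_tibble(as.data.frame(do.call(rbind, rows)))
  names(res) <- c("time_h", adipo_species)
  structure(res, params = params, protocol = protocol, variant = variant,
            class = c("adipo_trajectory", class(res)))
}

#' Basal (unstimulated) fixed point
#'
#' With all input channels at zero the system is feed-forward: insulin absence
#' forces pAKT to zero, which closes the gate on the PPARg feedback term, so
#' PPARg settles at its basal synthesis/degradation balance and every other
#' species follows explicitly. The fixed point is therefore computed in
#' closed form (residual is exactly zero to machine precision); it is the
#' lowest-valued stable state of the circuit and the day-0 initial condition
#' used throughout.
#'
#' @inheritParams adipo_derivatives
#' @return Named state vector at the basal fixed point.
#' @export
basal_state <- function(params, variant = feedback_variant(),
                        alpha4_printed = FALSE) {
  p <- validate_params(params)
  kd <- variant$knockdown
  P <- kd[["pparg"]] * p$syn_pparg * p$base_pparg / p$deg_pparg
  A <- kd[["cebpa"]] * p$syn_cebpa / p$deg_cebpa *
    (p$base_cebpa + .hill(P, p$alpha4, 3, denom_n = if (alpha4_printed) 2 else 3))
  B <- kd[["cebpb"]] * p$syn_cebpb / p$deg_cebpb *
    (p$base_cebpb + (if (variant$loop2_on) .hill(P, p$alpha1, 2) else 0))
  R <- kd[["ir"]] * p$syn_ir / p$deg_ir *
    (p$base_ir + (if (variant$loop3_on) A / (p$alpha6 + A) else 0))
  setNames(c(B, P, A, 0, R, 0), adipo_species)
}

#' @exportS3Method
autoplot.adipo_trajectory <- function(object, species = adipo_species, ...) {
  long <- pivot_longer(object[, c("time_h", species)], -"time_h",
                       names_to = "species", values_to = "level")
  ggplot(long, aes(.data$time_h, .data$level, colour = .data$species)) +
    geom_line() +
    labs(x = "time (h)", y = "level (a.u.)", colour = NULL) +
    theme_minimal()
}

#' Write / read a trajectory as CSV
#'
#' Column order is `time_h, cebpb, pparg, cebpa, pakt, ir, fat`.
#'
#' @param traj An `adipo_trajectory` (or compatible data frame).
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("time_h", adipo_species)], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  as_tibble(utils::read.csv(path))
}
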