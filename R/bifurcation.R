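rhs_at <- function(params, inputs, variant, alpha4_printed = FALSE) {
  u <- lapply(c(gr = "gr", camp = "camp", insulin = "insulin", rosi = "rosi"),
              function(ch) inputs[[ch]] %||% 0)
  ctx <- .segment_ctx(params, u, variant, alpha4_printed)
  function(y) unlist(.rhs_desolve(0, y, ctx))
}

#' Find fixed points of the model at constant inputs
#'
#' At constant inputs every species of the circuit is, at steady state, an
#' explicit function of the PPARg level alone (C/EBPb and C/EBPa through the
#' PPARg activity, the insulin receptor through C/EBPa, pAKT through the
#' receptor, fat through pAKT and activity). The fixed-point condition
#' therefore reduces exactly to a scalar equation in PPARg, which is
#' bracketed on a dense logarithmic grid and solved by bisection; the full
#' state is then reconstructed, verified (residual below `1e-8`),
#' de-duplicated (relative distance below `1e-4`) and classified stable or
#' unstable from the eigenvalues of the finite-difference Jacobian.
#'
#' @param params An `adipo_params`.
#' @param inputs Named channel levels, e.g. `list(insulin = 1)`.
#' @param variant A `feedback_variant`.
#' @param box Two-element `c(lo, hi)` bound on the PPARg search range
#'   (applied to all species when filtering), default `c(0, 40)`.
#' @param n_grid Number of grid points used to bracket crossings.
#' @param alpha4_printed See [adipo_derivatives()].
#' @return Tibble with one row per fixed point: the six species columns,
#'   `stable`, and `residual` (max absolute rate).
#' @export
find_fixed_points <- function(params = reference_params(),
                              inputs = list(insulin = 1),
                              variant = feedback_variant(),
                              box = c(0, 40), n_grid = 800,
                              alpha4_printed = FALSE) {
  box <- range(box)
  if (diff(box) <= 0) abort("box must have positive volume")
  p <- validate_params(params)
  u <- lapply(c(gr = "gr", camp = "camp", insulin = "insulin", rosi = "rosi"),
              function(ch) inputs[[ch]] %||% 0)
  cs <- .segment_ctx(p, u, variant, alpha4_printed)
  slaved <- function(P) {
    act <- P * cs[25]
    A <- (cs[10] + cs[11] * act^3 / (cs[12] + act^3)) / cs[13]
    B <- (cs[1] + cs[2] * act^2 / (cs[3] + act^2)) / cs[4]
    R <- (cs[17] + cs[18] * A / (cs[19] + A)) / cs[20]
    K <- cs[14] * (cs[15] + R) / cs[16]
    Fat <- cs[21] * (K / (cs[22] + K)) * (act / (cs[23] + act)) / cs[24]
    list(B = B, A = A, R = R, K = K, Fat = Fat)
  }
  g <- function(P) {
    s <- slaved(P)
    ba3 <- (s$B + s$A)^3
    (cs[5] + cs[6] * ba3 / (cs[7] + ba3) * s$K / (cs[8] + s$K)) / cs[9] - P
  }
  lo <- max(box[1], 1e-8)
  Pg <- c(0, exp(seq(log(lo), log(max(box[2], lo * 10)), length.out = n_grid)))
  gv <- vapply(Pg, g, 0)
  idx <- which(diff(sign(gv)) != 0 | gv[-length(gv)] == 0)
  f <- rhs_at(p, inputs, variant, alpha4_printed)
  roots <- list()
  for (i in idx) {
    P_star <- if (gv[i] == 0) Pg[i] else
      uniroot(g, c(Pg[i], Pg[i + 1]), tol = 1e-13)$root
    s <- slaved(P_star)
    y <- setNames(c(s$B, P_star, s$A, s$K, s$R, s$Fat), adipo_species)
    if (max(abs(f(y))) > 1e-8 || any(y < box[1] - 1e-8) || any(y > box[2] + 1e-8)) next
    roots[[length(roots) + 1]] <- y
  }
  if (!length(roots)) {
    warn("no fixed points found in the search box")
    return(tibble())
  }
  uni <- list()
  for (y in roots) {
    dup <- any(map_lgl(uni, function(z) {
      sqrt(sum((y - z)^2)) / max(1e-9, sqrt(sum(z^2))) < 1e-4
    }))
    if (!dup) uni[[length(uni) + 1]] <- y
  }
  rows <- map(uni, function(y) {
    J <- pracma::jacobian(f, y)
    stable <- all(Re(eigen(J, only.values = TRUE)$values) < 1e-8)
    as_tibble(as.list(setNames(y, adipo_species))) |>
      mutate(stable = stable, residual = max(abs(f(y))))
  })
  bind_rows(rows) |> arrange(.data$pparg)
}

#' Nullclines of the one-loop (PPARg--C/EBPa) subsystem
#'
#' Reconstructs the steady-state picture of a single-feedback-loop system:
#' for each constant C/EBPb level, the PPARg nullcline (`dPPARg/dt = 0`) in
#' the (C/EBPa, PPARg) plane, together with the single C/EBPa nullcline
#' (`dC/EBPa/dt = 0`). pAKT is clamped at a constant (default: its
#' insulin-on low-state value), so both nullclines are explicit curves.
#' Intersections of each pair are found by bisection and reported.
#'
#' @param params An `adipo_params`.
#' @param cebpb_levels Constant C/EBPb levels, one PPARg nullcline each.
#' @param cebpa_grid C/EBPa axis values for curve evaluation.
#' @param pakt_clamp pAKT clamp (a.u.); default from the insulin-on low state.
#' @param alpha4_printed See [adipo_derivatives()].
#' @return List with `curves` (tibble: `cebpb_level`, `cebpa`, `pparg`,
#'   `which` in `"pparg_nullcline"` / `"cebpa_nullcline"`) and
#'   `intersections` (tibble: `cebpb_level`, `cebpa`, `pparg`).
#' @export
nullclines_one_loop <- function(params = reference_params(),
                                cebpb_levels = c(0.5, 1, 2, 4),
                                cebpa_grid = seq(0, 8, length.out = 200),
                                pakt_clamp = NULL, alpha4_printed = FALSE) {
  p <- validate_params(params)
  if (any(cebpb_levels < 0)) abort("cebpb_levels must be >= 0")
  if (is.null(pakt_clamp)) {
    prot <- stimulus_protocol(
      tibble(channel = "insulin", start_h = 0, end_h = 600, level = 1), 600)
    pakt_clamp <- simulate_adipo(prot, p, dt_out = NULL, times = 600)$pakt[1]
  }
  kap <- pakt_clamp / (p$alpha3 + pakt_clamp)
  p_null <- function(A, B) {
    p$syn_pparg / p$deg_pparg * (p$base_pparg + .hill(B + A, p$alpha2, 3) * kap)
  }
  a_null <- function(P) {
    p$syn_cebpa / p$deg_cebpa *
      (p$base_cebpa + .hill(P, p$alpha4, 3, denom_n = if (alpha4_printed) 2 else 3))
  }
  curves <- list()
  inter <- list()
  for (B in cebpb_levels) {
    curves[[length(curves) + 1]] <- tibble(
      cebpb_level = B, cebpa = cebpa_grid, pparg = p_null(cebpa_grid, B),
      which = "pparg_nullcline")
    g <- function(P) p_null(a_null(P), B) - P
    Pg <- exp(seq(log(1e-3), log(60), length.out = 600))
    sg <- sign(g(Pg))
    idx <- which(diff(sg) != 0)
    if (!length(idx)) {
      warn(paste0("no nullcline intersection bracketed at cebpb = ", B,
                  "; refine the grid"))
    }
    for (i in idx) {
      P_star <- uniroot(g, c(Pg[i], Pg[i + 1]))$root
      inter[[length(inter) + 1]] <- tibble(cebpb_level = B,
                                           cebpa = a_null(P_star),
                                           pparg = P_star)
    }
  }
  Pg <- exp(seq(log(1e-3), log(60), length.out = 200))
  curves[[length(curves) + 1]] <- tibble(
    cebpb_level = NA_real_, cebpa = a_null(Pg), pparg = Pg,
    which = "cebpa_nullcline")
  list(curves = bind_rows(curves), intersections = bind_rows(inter))
}

relax_to_steady <- function(params, inputs, variant, y0, relax_h = 500) {
  u <- lapply(c(gr = "gr", camp = "camp", insulin = "insulin", rosi = "rosi"),
              function(ch) inputs[[ch]] %||% 0)
  ctx <- .segment_ctx(params, u, variant, FALSE)
  sol <- deSolve::lsoda(pmax(y0, 0), c(0, relax_h), .rhs_desolve, ctx,
                        rtol = 1e-8, atol = 1e-10)
  pmax(sol[nrow(sol), -1], 0)
}

#' Quasi-static stimulus sweep with hysteresis detection
#'
#' Sweeps one input channel up and then back down, relaxing the model at
#' least `relax_h` hours per level and warm-starting each level from the
#' previous steady state (naive continuation). The bistable window is the
#' range of levels where forward and backward PPARg branches differ by more
#' than 10% (relative).
#'
#' @param params An `adipo_params`.
#' @param variant A `feedback_variant`.
#' @param channel Swept channel (`"rosi"`, `"gr"`, `"camp"` or `"insulin"`).
#' @param levels Ascending stimulus levels (at least 8).
#' @param base_inputs Constant levels of the other channels
#'   (default `list(insulin = 1)`).
#' @param relax_h Relaxation time per level (h), default 500.
#' @return A `hysteresis_branches` tibble: `level`, `forward`, `backward`
#'   (PPARg), with attribute `window` (`c(lo, hi)` or `NULL`).
#' @export
stimulus_sweep_hysteresis <- function(params = reference_params(),
                                      variant = feedback_variant(),
                                      channel = "rosi", levels,
                                      base_inputs = list(insulin = 1),
                                      relax_h = 500) {
  if (length(levels) < 8) abort("need at least 8 sweep levels")
  if (is.unsorted(levels, strictly = TRUE)) abort("levels must be strictly ascending")
  p <- validate_params(params)
  mk_inputs <- function(lv) { u <- base_inputs; u[[channel]] <- lv; u }
  y <- basal_state(p, variant)
  fwd <- matrix(NA_real_, length(levels), 6)
  for (i in seq_along(levels)) {
    y <- relax_to_steady(p, mk_inputs(levels[i]), variant, y, relax_h)
    fwd[i, ] <- y
  }
  bwd <- matrix(NA_real_, length(levels), 6)
  for (i in rev(seq_along(levels))) {
    y <- relax_to_steady(p, mk_inputs(levels[i]), variant, y, relax_h)
    bwd[i, ] <- y
  }
  rel_gap <- abs(fwd[, 2] - bwd[, 2]) / pmax(fwd[, 2], bwd[, 2], 1e-12)
  win_idx <- which(rel_gap > 0.10)
  window <- if (length(win_idx)) c(lo = levels[min(win_idx)], hi = levels[max(win_idx)]) else NULL
  out <- tibble(level = levels, forward = fwd[, 2], backward = bwd[, 2])
  structure(out, window = window, channel = channel,
            class = c("hysteresis_branches", class(out)))
}

#' @exportS3Method
autoplot.hysteresis_branches <- function(object, ...) {
  long <- pivot_longer(object, c("forward", "backward"),
                       names_to = "branch", values_to = "pparg")
  ggplot(long, aes(.data$level, .data$pparg, colour = .data$branch)) +
    geom_line() + geom_point() +
    labs(x = paste0(attr(object, "channel"), " level"), y = "PPARg (a.u.)") +
    theme_minimal()
}

#' Test whether a protocol irreversibly commits the model
#'
#' Simulates a protocol that ends in a washout phase, relaxes for `relax_h`
#' further hours under the protocol's final input levels, and asks whether
#' the end-state PPARg is closer (in log distance) to the high fixed point
#' than to the basal one. If the system is monostable (no separate high
#' state), commitment is necessarily `FALSE` and a note says so.
#'
#' @param params An `adipo_params`.
#' @param variant A `feedback_variant`.
#' @param protocol A `stimulus_protocol` including a washout phase.
#' @param relax_h Extra relaxation beyond the protocol end (h), default 200.
#' @return One-row tibble: `committed`, `pparg_end`, `pparg_low`,
#'   `pparg_high`, `note`.
#' @export
irreversibility_test <- function(params = reference_params(),
                                 variant = feedback_variant(), protocol,
                                 relax_h = 200) {
  p <- validate_params(params)
  total <- attr(protocol, "total_h")
  tr <- simulate_adipo(protocol, p, variant, dt_out = NULL, times = total)
  y_end <- unlist(tr[1, adipo_species])
  u_end <- as.list(protocol_levels(protocol, total - 1e-9)[1, .channels])
  y_fin <- relax_to_steady(p, u_end, variant, y_end, relax_h)
  refs <- pparg_reference_states(p, variant)
  monostable <- refs["high"] / refs["low"] < 2
  note <- if (monostable) "system is monostable; committed evaluated against basal only" else ""
  committed <- if (monostable) FALSE else {
    abs(log(y_fin[2] / refs["high"])) < abs(log(y_fin[2] / refs["low"]))
  }
  tibble(committed = committed, pparg_end = y_fin[2],
         pparg_low = unname(refs["low"]), pparg_high = unname(refs["high"]),
         note = note)
}
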