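.noise_groups <- list(
  cebpb = c("syn_cebpb", "deg_cebpb", "base_cebpb"),
  pparg = c("syn_pparg", "deg_pparg", "base_pparg"),
  cebpa = c("syn_cebpa", "deg_cebpa", "base_cebpa"),
  pakt  = c("syn_pakt", "deg_pakt"),
  ir    = c("syn_ir", "deg_ir", "base_ir"),
  fat   = c("syn_fat", "deg_fat")
)

#' Cell-to-cell variability specification
#'
#' Extrinsic parameter noise: each cell draws, once, a multiplicative
#' lognormal factor for every synthesis, degradation and basal-expression
#' parameter of a species group, then keeps those values for its whole
#' lifetime. The lognormal is median-preserving (`mu = 0`,
#' `sigma = sqrt(log(1 + cv^2))`), so the deterministic model remains the
#' population median. Default coefficients of variation: 15% for the PPARg
#' group and 30% for the C/EBPb and C/EBPa groups; the insulin-pathway and
#' fat groups are unvaried by default.
#'
#' @param pparg_cv,cebpb_cv,cebpa_cv,pakt_cv,ir_cv,fat_cv Per-group CVs
#'   (fractions, >= 0).
#' @return A `noise_spec` object (named numeric vector of CVs).
#' @export
noise_spec <- function(pparg_cv = 0.15, cebpb_cv = 0.30, cebpa_cv = 0.30,
                       pakt_cv = 0, ir_cv = 0, fat_cv = 0) {
  cv <- c(cebpb = cebpb_cv, pparg = pparg_cv, cebpa = cebpa_cv,
          pakt = pakt_cv, ir = ir_cv, fat = fat_cv)
  if (any(!is.finite(cv)) || any(cv < 0)) abort("noise CVs must be finite and >= 0")
  structure(cv, class = "noise_spec")
}

#' Scale a noise specification
#'
#' Multiplies every group CV by a common factor while preserving the default
#' group ratios (PPARg varied half as much as the C/EBPs). `scale_noise(ns, s)`
#' with the default spec gives C/EBP CVs of `0.30 * s / 0.30 = s` when `s` is
#' interpreted as the C/EBP-group CV.
#'
#' @param noise A `noise_spec`.
#' @param cv Target CV for the C/EBPb group; all groups scale proportionally.
#' @return A `noise_spec`.
#' @export
scale_noise <- function(noise = noise_spec(), cv) {
  ref <- noise[["cebpb"]]
  if (ref <= 0) abort("cannot scale a spec whose cebpb group CV is 0")
  noise_spec(
    pparg_cv = noise[["pparg"]] * cv / ref,
    cebpb_cv = cv,
    cebpa_cv = noise[["cebpa"]] * cv / ref,
    pakt_cv = noise[["pakt"]] * cv / ref,
    ir_cv = noise[["ir"]] * cv / ref,
    fat_cv = noise[["fat"]] * cv / ref
  )
}

#' Sample per-cell parameter sets
#'
#' Draws `n_cells` parameter sets from the median-preserving lognormal noise
#' model. Draws are independent across cells and across parameters, in a
#' fixed parameter order from a single seed, so results are fully
#' reproducible.
#'
#' @param base Base `adipo_params`.
#' @param noise A `noise_spec`.
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed.
#' @return A tibble with `cell_id` and one column per model parameter.
#' @examples
#' sample_cell_params(adipo_params(), noise_spec(), n_cells = 3, seed = 1)
#' @export
sample_cell_params <- function(base, noise = noise_spec(), n_cells, seed) {
  base <- validate_params(base)
  if (n_cells < 1) abort("n_cells must be >= 1")
  varied <- unlist(lapply(names(.noise_groups), function(g) {
    if (noise[[g]] > 0) .noise_groups[[g]] else character()
  }))
  sig <- unlist(lapply(names(.noise_groups), function(g) {
    if (noise[[g]] > 0) rep(sqrt(log(1 + noise[[g]]^2)), length(.noise_groups[[g]]))
    else numeric()
  }))
  out <- matrix(rep(unlist(base), each = n_cells), nrow = n_cells,
                dimnames = list(NULL, .param_names))
  if (length(varied)) {
    withr_seed <- function(expr) { # local RNG, do not disturb caller's stream
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      expr
    }
    L <- withr_seed(matrix(rnorm(n_cells * length(varied)), nrow = n_cells))
    out[, varied] <- out[, varied] * exp(sweep(L, 2, sig, `*`))
  }
  as_tibble(cbind(data.frame(cell_id = seq_len(n_cells)), as.data.frame(out)))
}

row_params <- function(cell_row) {
  new_adipo_params(as.list(unlist(cell_row[.param_names])))
}

# lean trajectory sampler for ensembles: same integrator and tolerances as
# simulate_adipo(), but returns a bare matrix and skips per-cell validation
.simulate_raw <- function(segments, params, variant, times, alpha4_printed = FALSE) {
  # segments: list of (t0, t1, u) prepared once per protocol
  y <- basal_state(params, variant, alpha4_printed)
  out <- matrix(NA_real_, length(times), 6)
  if (any(times == 0)) out[times == 0, ] <- y
  for (seg in segments) {
    inside <- times[times > seg$t0 & times <= seg$t1]
    tt <- unique(c(seg$t0, inside, seg$t1))
    ctx <- .segment_ctx(params, seg$u, variant, alpha4_printed)
    sol <- deSolve::lsoda(y, tt, .rhs_desolve, ctx, rtol = 1e-8, atol = 1e-10)
    if (nrow(sol) < length(tt)) abort("integration failed")
    m <- pmax(sol[, -1, drop = FALSE], 0)
    keep <- sol[, 1] %in% inside
    if (any(keep)) out[match(sol[keep, 1], times), ] <- m[keep, , drop = FALSE]
    y <- m[nrow(m), ]
  }
  out
}

.protocol_segments <- function(protocol) {
  bps <- protocol_breakpoints(protocol)
  lapply(seq_len(length(bps) - 1), function(k) {
    list(t0 = bps[k], t1 = bps[k + 1],
         u = as.list(protocol_levels(protocol, bps[k])[1, .channels]))
  })
}

#' Simulate a heterogeneous cell population
#'
#' Runs one deterministic trajectory per cell, each with its own sampled
#' parameter set and starting from the basal fixed point of its own
#' parameters (cells are assumed equilibrated before day 0). Identical
#' arguments and seed give bit-identical results. Cells whose integration
#' fails are flagged (`NA` readouts) and the run continues.
#'
#' @param n_cells Number of cells.
#' @param protocol A `stimulus_protocol`.
#' @param base Base `adipo_params`.
#' @param noise A `noise_spec`.
#' @param variant A `feedback_variant`.
#' @param sample_times Times (h) at which readouts are recorded; must lie
#'   within the protocol.
#' @param seed Integer seed for the parameter draws.
#' @return A `cell_table`: tibble with columns `cell_id`, `time_h`, the six
#'   species, and `failed`; attributes `cell_params` (the sampled parameter
#'   tibble), `n_failed`, `seed`, `noise`, `params_hash`.
#' @examples
#' \donttest{
#' tab <- run_population(20, protocol_dim(total_h = 96), sample_times = 96, seed = 1)
#' dplyr::count(tab, time_h)
#' }
#' @export
run_population <- function(n_cells, protocol, base = reference_params(),
                           noise = noise_spec(), variant = feedback_variant(),
                           sample_times = c(48, 96), seed = 1) {
  total <- attr(protocol, "total_h")
  if (any(sample_times < 0 | sample_times > total)) {
    abort("sample_times must lie within the protocol duration")
  }
  cells <- sample_cell_params(base, noise, n_cells, seed)
  sample_times <- sort(unique(as.numeric(sample_times)))
  segs <- .protocol_segments(protocol)
  cell_mat <- as.matrix(cells[, .param_names])
  nt <- length(sample_times)
  big <- matrix(NA_real_, n_cells * nt, 6)
  failed <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    p_i <- new_adipo_params(as.list(cell_mat[i, ]))
    m <- tryCatch(.simulate_raw(segs, p_i, variant, sample_times),
                  error = function(e) NULL)
    if (is.null(m)) failed[i] <- TRUE else {
      big[((i - 1) * nt + 1):(i * nt), ] <- m
    }
  }
  n_failed <- sum(failed)
  out <- tibble(cell_id = rep(seq_len(n_cells), each = nt),
                time_h = rep(sample_times, n_cells))
  colnames(big) <- adipo_species
  out <- dplyr::bind_cols(out, as_tibble(big))
  out$failed <- rep(failed, each = nt)
  out <- out[, c("cell_id", "time_h", adipo_species, "failed")]
  structure(out, cell_params = cells, n_failed = n_failed, seed = seed,
            noise = noise, params_hash = params_hash(base),
            class = c("cell_table", class(out)))
}

#' Write a single-cell table (CSV plus JSON sidecar)
#'
#' The CSV holds one row per cell per sample time; the JSON sidecar records
#' the noise specification, seed and base-parameter hash needed to reproduce
#' the table.
#'
#' @param table A `cell_table`.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @export
write_cell_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- list(seed = attr(table, "seed"),
               noise = as.list(attr(table, "noise")),
               params_hash = attr(table, "params_hash"),
               n_failed = attr(table, "n_failed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
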