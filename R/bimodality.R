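#' Classify a single-cell readout distribution as unimodal or bimodal
#'
#' Fits one- and two-component Gaussian mixtures (unequal variances) to the
#' log10 readout values with [mclust::Mclust()] and calls the distribution
#' bimodal when the two-component model is preferred by BIC, both component
#' weights are at least 5%, and the component means are separated by at least
#' two pooled standard deviations. The reported threshold is the
#' equal-posterior point between the two component means, mapped back to the
#' original scale. These rules mirror the field's practice of calling
#' subpopulations from visibly separated histogram peaks.
#'
#' @param values Numeric vector of at least 50 finite, strictly positive
#'   single-cell measurements.
#' @param min_weight Minimum component weight for a real subpopulation (0.05).
#' @param min_separation Minimum mean separation in pooled-sd units (2).
#' @return A `bimodality_fit` list: `is_bimodal`, `threshold` (a.u.),
#'   `frac_low`, `frac_high`, `means`, `sds` (log10 scale), `delta_bic`
#'   (positive favours two components), `n`.
#' @examples
#' x <- c(rlnorm(500, 0, 0.2), rlnorm(500, log(12), 0.2))
#' classify_bimodality(x)$is_bimodal
#' @export
classify_bimodality <- function(values, min_weight = 0.05, min_separation = 2) {
  v <- values[is.finite(values)]
  if (length(v) < 50) abort("need at least 50 finite values")
  if (any(v <= 0)) abort("values must be strictly positive (log-scale fit)")
  x <- log10(v)
  base_out <- list(is_bimodal = FALSE, threshold = NA_real_,
                   frac_low = 1, frac_high = 0,
                   means = mean(x), sds = sd(x), delta_bic = -Inf, n = length(v))
  if (sd(x) < 1e-12) {
    return(structure(base_out, class = "bimodality_fit"))
  }
  fit1 <- Mclust(x, G = 1, modelNames = "V", verbose = FALSE)
  fit2 <- tryCatch(Mclust(x, G = 2, modelNames = "V", verbose = FALSE),
                   error = function(e) NULL)
  if (is.null(fit2)) return(structure(base_out, class = "bimodality_fit"))
  delta_bic <- as.numeric(fit2$bic - fit1$bic)   # mclust BIC: larger is better
  mu <- fit2$parameters$mean
  sg <- sqrt(fit2$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 2)
  w <- fit2$parameters$pro
  ord <- order(mu)
  mu <- mu[ord]; sg <- sg[ord]; w <- w[ord]
  pooled <- sqrt(mean(sg^2))
  sep <- (mu[2] - mu[1]) / pooled
  is_bi <- delta_bic > 0 && min(w) >= min_weight && sep >= min_separation
  thr <- NA_real_
  frac <- c(1, 0)
  if (is_bi) {
    post_diff <- function(t) {
      w[1] * dnorm(t, mu[1], sg[1]) - w[2] * dnorm(t, mu[2], sg[2])
    }
    thr_log <- tryCatch(uniroot(post_diff, c(mu[1], mu[2]))$root,
                        error = function(e) mean(mu))
    thr <- 10^thr_log
    frac_high <- mean(x > thr_log)
    frac <- c(1 - frac_high, frac_high)
  }
  structure(list(is_bimodal = is_bi, threshold = thr,
                 frac_low = frac[1], frac_high = frac[2],
                 means = mu, sds = sg, delta_bic = delta_bic, n = length(v)),
            class = "bimodality_fit")
}

#' @export
print.bimodality_fit <- function(x, ...) {
  cat("<bimodality_fit>", if (x$is_bimodal) "bimodal" else "unimodal",
      sprintf("(n=%d, dBIC=%.1f)\n", x$n, x$delta_bic))
  if (x$is_bimodal) {
    cat(sprintf("  threshold %.3g a.u.; frac low/high %.3f/%.3f\n",
                x$threshold, x$frac_low, x$frac_high))
  }
  invisible(x)
}

#' @exportS3Method
tidy.bimodality_fit <- function(x, ...) {
  k <- length(x$means)
  tibble(component = seq_len(k), mean_log10 = x$means, sd_log10 = x$sds,
         weight = if (k == 2) c(x$frac_low, x$frac_high) else 1)
}

#' @exportS3Method
glance.bimodality_fit <- function(x, ...) {
  tibble(is_bimodal = x$is_bimodal, threshold = x$threshold,
         frac_low = x$frac_low, frac_high = x$frac_high,
         delta_bic = x$delta_bic, n = x$n)
}

readout_at <- function(table, readout, time) {
  tt <- table$time_h
  if (!any(tt == time)) abort(paste0("time ", time, " h not present in table"))
  sub <- table[tt == time & !table$failed, ]
  sub[[readout]]
}

#' Fraction of differentiated cells
#'
#' Splits a single-cell readout at a threshold and reports the fraction above
#' it with an exact binomial confidence interval. With `threshold = "auto"`
#' the threshold comes from [classify_bimodality()]; if the distribution is
#' unimodal the supplied `fallback_threshold` is used instead (an error if
#' none is given).
#'
#' @param table A `cell_table`.
#' @param readout Species name, default `"pparg"`.
#' @param time Sample time (h), must be present in the table.
#' @param threshold `"auto"` or a fixed numeric threshold (a.u.).
#' @param fallback_threshold Numeric threshold used when `"auto"` finds a
#'   unimodal distribution.
#' @param conf_level Confidence level for the binomial interval.
#' @return One-row tibble: `fraction`, `n`, `conf_lo`, `conf_hi`,
#'   `threshold`, `bimodal`.
#' @export
fraction_differentiated <- function(table, readout = "pparg", time,
                                    threshold = "auto",
                                    fallback_threshold = NULL,
                                    conf_level = 0.95) {
  v <- readout_at(table, readout, time)
  bi <- NA
  if (identical(threshold, "auto")) {
    fit <- classify_bimodality(v)
    bi <- fit$is_bimodal
    if (fit$is_bimodal) {
      thr <- fit$threshold
    } else if (!is.null(fallback_threshold)) {
      thr <- fallback_threshold
    } else {
      abort("distribution is unimodal and no fallback_threshold was supplied")
    }
  } else {
    thr <- as.numeric(threshold)
  }
  k <- sum(v > thr)
  n <- length(v)
  ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
  tibble(fraction = k / n, n = n, conf_lo = ci[1], conf_hi = ci[2],
         threshold = thr, bimodal = bi)
}

#' High/low fixed-point references for the calibrated switch
#'
#' Relaxes the deterministic model (insulin on, no other stimulus) from the
#' basal state and from a high start, returning the low and high PPARg fixed
#' points. Used by the bistability-intact rule and as a fallback threshold.
#'
#' @param params An `adipo_params`.
#' @param variant A `feedback_variant`.
#' @return Named vector `c(low = ..., high = ...)` of PPARg levels.
#' @export
pparg_reference_states <- function(params = reference_params(),
                                   variant = feedback_variant()) {
  fps <- suppressWarnings(find_fixed_points(params, list(insulin = 1), variant,
                                            box = c(0, 100)))
  stable <- fps[fps$stable, ]
  if (nrow(stable) == 0) {
    # no fixed point resolved (degenerate parameters): fall back to relaxation
    prot <- stimulus_protocol(
      tibble(channel = "insulin", start_h = 0, end_h = 600, level = 1), 600)
    lo <- simulate_adipo(prot, params, variant, dt_out = NULL, times = 600)
    return(c(low = lo$pparg[1], high = lo$pparg[1]))
  }
  c(low = min(stable$pparg), high = max(stable$pparg))
}

#' Scan the cell-to-cell noise level for the bimodality window
#'
#' For each CV on a grid, runs an ensemble through a
#' stimulation-plus-washout protocol, classifies the end-state PPARg
#' distribution, and checks that bistability stays intact: at least
#' `1 - broken_tol` of cells end near one of the two reference fixed points
#' (below twice the basal PPARg, or above half the high-state PPARg).
#' Reports the smallest and largest CV at which the population is bimodal
#' with bistability intact.
#'
#' @param cv_grid Ascending CVs (fractions); interpreted as the C/EBP-group
#'   CV, with all groups scaled proportionally from the default ratios via
#'   [scale_noise()].
#' @param protocol Stimulation + washout protocol (default: 48 h DIM
#'   followed by 48 h washout).
#' @param base Base parameters.
#' @param n_cells Cells per CV.
#' @param seed Integer seed (one independent ensemble per CV).
#' @param broken_tol Maximum tolerated fraction of cells stranded away from
#'   both fixed points (default 0.05).
#' @return List with `cv_lo`, `cv_hi` (NA when no CV qualifies) and
#'   `diagnostics`, a tibble with one row per CV.
#' @export
noise_window_scan <- function(cv_grid, protocol = protocol_dim(48, 96),
                              base = reference_params(), n_cells = 500,
                              seed = 1, broken_tol = 0.05) {
  if (is.unsorted(cv_grid)) abort("cv_grid must be ascending")
  refs <- pparg_reference_states(base)
  t_end <- attr(protocol, "total_h")
  rows <- vector("list", length(cv_grid))
  for (i in seq_along(cv_grid)) {
    cv <- cv_grid[i]
    noise <- if (cv > 0) scale_noise(noise_spec(), cv) else
      noise_spec(0, 0, 0)
    tab <- run_population(n_cells, protocol, base, noise,
                          sample_times = t_end, seed = seed + i)
    P <- readout_at(tab, "pparg", t_end)
    bi <- if (sd(log10(P)) < 1e-9) FALSE else classify_bimodality(P)$is_bimodal
    near_low <- P < 2 * refs["low"]
    near_high <- P > 0.5 * refs["high"]
    stranded <- mean(!(near_low | near_high))
    rows[[i]] <- tibble(cv = cv, is_bimodal = bi, frac_stranded = stranded,
                        intact = stranded <= broken_tol,
                        frac_high = mean(near_high),
                        median_pparg = median(P))
  }
  diag <- bind_rows(rows)
  ok <- diag$is_bimodal & diag$intact
  if (any(ok)) {
    idx <- which(ok)
    if (any(diff(idx) > 1)) {
      warn("bimodality window is not contiguous on the supplied grid")
    }
    window <- c(cv_lo = cv_grid[min(idx)], cv_hi = cv_grid[max(idx)])
  } else {
    window <- c(cv_lo = NA_real_, cv_hi = NA_real_)
  }
  list(cv_lo = unname(window[1]), cv_hi = unname(window[2]), diagnostics = diag)
}

rank_auc <- function(score, label) {
  # probability that a random positive outranks a random negative
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) abort("need both classes to compute an AUC")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank transcription factors by pre-switch predictiveness
#'
#' Computes, for each transcription factor, the AUC (rank-based) for
#' predicting a cell's final differentiation label from its expression at an
#' earlier time, and ranks the factors by it.
#'
#' @param table A `cell_table` containing both times.
#' @param t_pre Early time (h), before commitment.
#' @param t_final Final time (h) at which cells are labelled high/low.
#' @param threshold `"auto"` (bimodality classifier at `t_final`) or numeric.
#' @return Tibble with `factor`, `auc`, ordered by decreasing AUC.
#' @export
preswitch_predictor_ranking <- function(table, t_pre, t_final,
                                        threshold = "auto") {
  final <- readout_at(table, "pparg", t_final)
  if (identical(threshold, "auto")) {
    fit <- classify_bimodality(final)
    if (!fit$is_bimodal) abort("final PPARg distribution is not bimodal; supply a threshold")
    thr <- fit$threshold
  } else thr <- as.numeric(threshold)
  label <- final > thr
  if (all(label) || !any(label)) abort("final labels are single-class")
  pre <- table[table$time_h == t_pre & !table$failed, ]
  if (!nrow(pre)) abort(paste0("time ", t_pre, " h not present in table"))
  aucs <- map_dbl(c(cebpb = "cebpb", pparg = "pparg", cebpa = "cebpa"),
                  function(f) rank_auc(pre[[f]], label))
  tibble(factor = names(aucs), auc = unname(aucs)) |>
    arrange(dplyr::desc(.data$auc))
}

#' Graded insulin control of fat accumulation
#'
#' Within the high-PPARg (differentiated) subpopulation at a given time,
#' compares how well pAKT versus PPARg predicts stored fat (Spearman rank
#' correlations), and checks that the fat-given-pAKT relation is graded
#' rather than switch-like: cells are binned into pAKT deciles and the fat
#' distribution within each (sufficiently large) bin must be unimodal.
#'
#' @param table A `cell_table`.
#' @param time Sample time (h); the PPARg distribution there must be bimodal.
#' @param n_bins Number of pAKT bins for the gradedness check (default 10).
#' @param min_bin Minimum cells per bin for the within-bin test (default 50).
#' @return One-row tibble: `cor_fat_pakt`, `cor_fat_pparg`, `graded`,
#'   `n_high`, `threshold`.
#' @export
graded_pakt_fat_relation <- function(table, time, n_bins = 10, min_bin = 50) {
  P <- readout_at(table, "pparg", time)
  fit <- classify_bimodality(P)
  if (!fit$is_bimodal) abort("PPARg distribution is not bimodal at this time")
  sub <- table[table$time_h == time & !table$failed, ]
  hi <- sub[sub$pparg > fit$threshold, ]
  cor_fp <- stats::cor(hi$fat, hi$pakt, method = "spearman")
  cor_fg <- stats::cor(hi$fat, hi$pparg, method = "spearman")
  qs <- quantile(hi$pakt, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(hi$pakt, breaks = unique(qs), include.lowest = TRUE)
  graded <- TRUE
  for (b in levels(bin)) {
    fv <- hi$fat[bin == b]
    fv <- fv[fv > 0]
    if (length(fv) >= min_bin) {
      if (classify_bimodality(fv)$is_bimodal) graded <- FALSE
    }
  }
  tibble(cor_fat_pakt = cor_fp, cor_fat_pparg = cor_fg, graded = graded,
         n_high = nrow(hi), threshold = fit$threshold)
}

#' Histogram of a single-cell readout with the mixture threshold
#'
#' @param table A `cell_table`.
#' @param readout Species, default `"pparg"`.
#' @param time Sample time (h).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_readout_histogram <- function(table, readout = "pparg", time, bins = 60) {
  v <- readout_at(table, readout, time)
  fit <- classify_bimodality(v)
  g <- ggplot(tibble(x = v), aes(.data$x)) +
    geom_histogram(bins = bins) +
    scale_x_log10() +
    labs(x = paste0(readout, " (a.u.)"), y = "cells") +
    theme_minimal()
  if (fit$is_bimodal) g <- g + geom_vline(xintercept = fit$threshold, linetype = 2)
  g
}
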