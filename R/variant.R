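#' Feedback-loop variants and siRNA-style knockdowns
#'
#' A `feedback_variant` switches individual feedback loops of the circuit on
#' or off and records per-species knockdowns. `loop2_on` gates the PPARg ->
#' C/EBPb feedback term; `loop3_on` gates the C/EBPa -> insulin-receptor
#' term. Knockdowns multiply the target's whole synthesis term (basal part
#' included) by a remaining fraction in `[0, 1]`, emulating siRNA; the special
#' target `"gr-pathway"` instead scales the glucocorticoid input channel.
#'
#' @param loop2_on,loop3_on Logical flags, default `TRUE`.
#' @param knockdown Named numeric vector of remaining-synthesis fractions,
#'   e.g. `c(cebpb = 0.1)` for a 90%-efficient C/EBPb knockdown.
#' @return A `feedback_variant` object.
#' @examples
#' feedback_variant(loop2_on = FALSE)
#' @export
feedback_variant <- function(loop2_on = TRUE, loop3_on = TRUE,
                             knockdown = numeric()) {
  kd_targets <- c(adipo_species, "gr-pathway")
  if (length(knockdown)) {
    bad <- setdiff(names(knockdown), kd_targets)
    if (length(bad)) abort(paste0("unknown knockdown target(s): ", paste(bad, collapse = ", ")))
    if (any(knockdown < 0 | knockdown > 1)) abort("knockdown fractions must be in [0, 1]")
  }
  kd <- setNames(rep(1, length(kd_targets)), kd_targets)
  kd[names(knockdown)] <- knockdown
  structure(list(loop2_on = isTRUE(loop2_on), loop3_on = isTRUE(loop3_on),
                 knockdown = kd),
            class = "feedback_variant")
}

#' @export
print.feedback_variant <- function(x, ...) {
  kd <- x$knockdown[x$knockdown < 1]
  cat("<feedback_variant> loop2_on:", x$loop2_on, " loop3_on:", x$loop3_on, "\n")
  if (length(kd)) cat("  knockdown:", paste(sprintf("%s=%.2f", names(kd), kd), collapse = " "), "\n")
  invisible(x)
}

#' Apply an siRNA-style knockdown to a variant
#'
#' @param variant A `feedback_variant`.
#' @param target One of `"cebpb"`, `"pparg"`, `"cebpa"`, `"ir"`,
#'   `"gr-pathway"`.
#' @param efficiency Knockdown efficiency in `[0, 1]`; the target keeps a
#'   `1 - efficiency` fraction of its synthesis (or, for `"gr-pathway"`, of
#'   the glucocorticoid input level).
#' @return A new `feedback_variant`.
#' @examples
#' feedback_variant() |> apply_knockdown("cebpa", 0.9)
#' @export
apply_knockdown <- function(variant, target, efficiency) {
  if (!inherits(variant, "feedback_variant")) abort("variant must be a feedback_variant")
  allowed <- c("cebpb", "pparg", "cebpa", "ir", "gr-pathway")
  if (!target %in% allowed) {
    abort(paste0("unknown knockdown target '", target, "'; use one of ",
                 paste(allowed, collapse = ", ")))
  }
  if (!is.finite(efficiency) || efficiency < 0 || efficiency > 1) {
    abort("efficiency must be in [0, 1]")
  }
  variant$knockdown[target] <- 1 - efficiency
  variant
}
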