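#' Model species
#'
#' The six state variables of the adipogenesis circuit, in canonical order:
#' C/EBPb, PPARg, C/EBPa, phosphorylated AKT, insulin receptor, and stored fat
#' (lipid-droplet content). All concentrations are relative units, normalized
#' so that each transcription factor's unstimulated fixed point equals 1 under
#' the reference calibration.
#'
#' @format Character vector of length 6.
#' @export
adipo_species <- c("cebpb", "pparg", "cebpa", "pakt", "ir", "fat")

.param_names <- c(
  paste0("syn_", adipo_species),
  paste0("deg_", adipo_species),
  "base_cebpb", "base_pparg", "base_cebpa", "base_ir",
  paste0("alpha", 1:8),
  "rosi_gain", "rosi_k"
)

#' Create a model parameter set
#'
#' Assembles the full rate-constant set of the six-ODE adipogenesis model:
#' synthesis rate scales (`syn_*`, a.u./h), first-order degradation rates
#' (`deg_*`, 1/h), dimensionless basal-expression terms (`base_*`),
#' half-saturation constants (`alpha1`--`alpha8`, a.u.) and the rosiglitazone
#' coupling (`rosi_gain`, maximal fold-boost of PPARg activity minus one, and
#' `rosi_k`, the half-saturating dose). Defaults are the reference calibrated
#' set shipped with the package.
#'
#' @param ... Named parameter overrides, e.g. `deg_pparg = 0.1`.
#' @param values Optional named list or vector of overrides (same effect as
#'   `...`; useful programmatically).
#' @return An object of class `adipo_params`: a named list with one numeric
#'   entry per parameter.
#' @examples
#' p <- adipo_params(deg_fat = 0.01)
#' p$deg_fat
#' @export
adipo_params <- function(..., values = NULL) {
  p <- reference_params()
  over <- c(list(...), as.list(values))
  if (length(over)) {
    bad <- setdiff(names(over), .param_names)
    if (length(bad)) {
      abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    }
    p[names(over)] <- lapply(over, as.numeric)
  }
  validate_params(new_adipo_params(p))
}

new_adipo_params <- function(p) {
  structure(p[.param_names], class = "adipo_params")
}

#' @export
print.adipo_params <- function(x, ...) {
  cat("<adipo_params>\n")
  v <- unlist(x)
  for (grp in list(grep("^syn_", names(v)), grep("^deg_", names(v)),
                   grep("^base_", names(v)), grep("^alpha", names(v)),
                   grep("^rosi", names(v)))) {
    cat(" ", paste(sprintf("%s=%.4g", names(v)[grp], v[grp]), collapse = " "), "\n")
  }
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks the structural invariants of a parameter set: every field present
#' and finite, all values non-negative, all degradation rates strictly
#' positive, and all half-saturation constants strictly positive.
#'
#' @param p An `adipo_params` object (or named list with the same fields).
#' @return The validated `adipo_params`, invisibly usable in a pipe.
#' @export
validate_params <- function(p) {
  miss <- setdiff(.param_names, names(p))
  if (length(miss)) abort(paste0("missing parameter(s): ", paste(miss, collapse = ", ")))
  v <- unlist(p[.param_names])
  if (any(!is.finite(v))) abort("non-finite parameter value")
  if (any(v < 0)) abort("parameters must be >= 0")
  if (any(v[grep("^deg_", names(v))] <= 0)) abort("degradation rates must be > 0")
  if (any(v[grep("^alpha", names(v))] <= 0)) abort("half-saturation constants must be > 0")
  new_adipo_params(as.list(v))
}

.reference_cache <- new.env(parent = emptyenv())

#' The reference calibrated parameter set
#'
#' Loads the parameter set shipped in `inst/extdata/reference_params.json`.
#' This set was produced by calibrating the model against the benchmark
#' behaviors of the circuit (bistability of the intact two-loop switch,
#' monostability of the one-loop variant, commitment after a 48-h hormonal
#' induction, an approximately two-fold insulin-driven PPARg boost between
#' 48 h and 72 h, Hill coefficients near 2.5 and a four-fold EC50 separation
#' in the rosiglitazone dose response) and is the default everywhere a
#' parameter set is needed.
#'
#' @return An `adipo_params` object.
#' @export
reference_params <- function() {
  if (is.null(.reference_cache$p)) {
    path <- system.file("extdata", "reference_params.json", package = "adiposwitch")
    if (path == "") path <- file.path("inst", "extdata", "reference_params.json")
    .reference_cache$p <- read_params(path)
  }
  .reference_cache$p
}

#' Read a parameter set from JSON
#'
#' The JSON file must be a flat object keyed by parameter names. Unknown keys
#' are rejected so that typos do not silently fall back to defaults.
#'
#' @param path Path to a JSON file.
#' @return An `adipo_params` object.
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(raw), .param_names)
  if (length(bad)) abort(paste0("unknown key(s) in parameter file: ", paste(bad, collapse = ", ")))
  miss <- setdiff(.param_names, names(raw))
  if (length(miss)) abort(paste0("missing key(s) in parameter file: ", paste(miss, collapse = ", ")))
  validate_params(new_adipo_params(as.list(raw)))
}

#' Write a parameter set to JSON
#'
#' @param p An `adipo_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  p <- validate_params(p)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @exportS3Method
tidy.adipo_params <- function(x, ...) {
  tibble(parameter = names(x), value = unname(unlist(x)))
}

params_hash <- function(p) {
  v <- unlist(validate_params(p))
  # small order-stable content hash; avoids a digest dependency
  s <- paste(sprintf("%s=%.12g", names(v), v), collapse = ";")
  sum_ <- 0
  for (ch in utf8ToInt(s)) sum_ <- (sum_ * 31 + ch) %% 2147483647
  sprintf("%08x", sum_)
}
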