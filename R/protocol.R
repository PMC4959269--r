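.channels <- c("gr", "camp", "insulin", "rosi")

#' Build a stimulus protocol
#'
#' A stimulus protocol is a piecewise-constant time course for the four input
#' channels of the model: glucocorticoid (`gr`), cAMP (`camp`), insulin
#' (`insulin`) and the direct PPARg activator rosiglitazone (`rosi`).
#' Channels default to level 0 wherever no segment is defined.
#'
#' @param segments A data frame with columns `channel`, `start_h`, `end_h`,
#'   `level` (one row per constant segment). May be empty.
#' @param total_h Total duration of the protocol in hours.
#' @return A `stimulus_protocol`: a tibble of segments with a `total_h`
#'   attribute.
#' @examples
#' stimulus_protocol(
#'   tibble::tibble(channel = "rosi", start_h = 0, end_h = 3, level = 1),
#'   total_h = 48
#' )
#' @export
stimulus_protocol <- function(segments = NULL, total_h) {
  if (is.null(segments)) {
    segments <- tibble(channel = character(), start_h = numeric(),
                       end_h = numeric(), level = numeric())
  }
  segments <- as_tibble(segments)[, c("channel", "start_h", "end_h", "level")]
  if (total_h <= 0) abort("protocol duration must be > 0")
  if (nrow(segments)) {
    if (!all(segments$channel %in% .channels)) {
      abort(paste0("unknown channel(s): ",
                   paste(setdiff(segments$channel, .channels), collapse = ", ")))
    }
    if (any(segments$level < 0)) abort("stimulus levels must be >= 0")
    if (any(segments$end_h < segments$start_h)) abort("segment end before start")
    segments <- segments[segments$end_h > segments$start_h, , drop = FALSE]
    # non-overlap within each channel
    for (ch in unique(segments$channel)) {
      s <- segments[segments$channel == ch, ]
      s <- s[order(s$start_h), ]
      if (nrow(s) > 1 && any(s$start_h[-1] < s$end_h[-nrow(s)])) {
        abort(paste0("overlapping segments on channel '", ch, "'"))
      }
    }
  }
  structure(arrange(segments, .data$channel, .data$start_h),
            total_h = as.numeric(total_h),
            class = c("stimulus_protocol", class(segments)))
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol> total", attr(x, "total_h"), "h\n")
  NextMethod()
}

#' Channel levels at given times
#'
#' Evaluates a protocol at time points, returning one row per time with the
#' level of every channel. Segment intervals are half-open `[start_h, end_h)`.
#'
#' @param protocol A `stimulus_protocol`.
#' @param time_h Numeric vector of times (hours).
#' @return Tibble with columns `time_h`, `gr`, `camp`, `insulin`, `rosi`.
#' @export
protocol_levels <- function(protocol, time_h) {
  out <- tibble(time_h = as.numeric(time_h))
  for (ch in .channels) {
    seg <- protocol[protocol$channel == ch, ]
    lv <- numeric(length(time_h))
    if (nrow(seg)) {
      for (i in seq_len(nrow(seg))) {
        sel <- time_h >= seg$start_h[i] & time_h < seg$end_h[i]
        lv[sel] <- seg$level[i]
      }
    }
    out[[ch]] <- lv
  }
  out
}

protocol_breakpoints <- function(protocol) {
  sort(unique(c(0, protocol$start_h, protocol$end_h, attr(protocol, "total_h"))))
}

#' Standard differentiation-induction protocol
#'
#' The standard adipogenic regimen: glucocorticoid and cAMP stimuli at level 1
#' for the first `stim_h` hours, then washed out; insulin present throughout
#' (or absent entirely, for the no-insulin control); no rosiglitazone.
#' "Day n" corresponds to `24 * n` hours.
#'
#' @param stim_h Duration of the glucocorticoid + cAMP phase (h), default 48.
#' @param total_h Total protocol duration (h), default 168 (7 days).
#' @param insulin_after If `TRUE` (default), insulin at level 1 for the whole
#'   protocol; if `FALSE`, the insulin channel is identically zero.
#' @return A `stimulus_protocol`.
#' @export
protocol_dim <- function(stim_h = 48, total_h = 168, insulin_after = TRUE) {
  if (stim_h < 0 || stim_h > total_h) abort("need 0 <= stim_h <= total_h")
  seg <- list()
  if (stim_h > 0) {
    seg <- list(
      tibble(channel = "gr", start_h = 0, end_h = stim_h, level = 1),
      tibble(channel = "camp", start_h = 0, end_h = stim_h, level = 1)
    )
  }
  if (insulin_after) {
    seg <- c(seg, list(tibble(channel = "insulin", start_h = 0, end_h = total_h, level = 1)))
  }
  stimulus_protocol(bind_rows(seg), total_h = total_h)
}

#' Rosiglitazone pulse protocol
#'
#' A single rosiglitazone pulse of the given amplitude starting at time 0,
#' followed by washout. Doses are expressed in units of the half-saturating
#' dose `rosi_k` (dose 1 boosts PPARg activity halfway to its maximum);
#' laboratory molar concentrations are not mapped. Insulin is kept at level 1
#' throughout by default, matching serum-containing culture media; pass
#' `insulin = 0` for an insulin-free run.
#'
#' @param amplitude Pulse amplitude (>= 0, units of `rosi_k`).
#' @param duration_h Pulse duration (h); 0 gives an identically-zero channel.
#' @param total_h Total duration (h), >= `duration_h`.
#' @param insulin Constant insulin level, default 1.
#' @return A `stimulus_protocol`.
#' @export
protocol_rosi_pulse <- function(amplitude, duration_h, total_h, insulin = 1) {
  if (amplitude < 0) abort("amplitude must be >= 0")
  if (duration_h < 0 || duration_h > total_h) abort("need 0 <= duration_h <= total_h")
  seg <- list()
  if (duration_h > 0 && amplitude > 0) {
    seg <- list(tibble(channel = "rosi", start_h = 0, end_h = duration_h, level = amplitude))
  }
  if (insulin > 0) {
    seg <- c(seg, list(tibble(channel = "insulin", start_h = 0, end_h = total_h, level = insulin)))
  }
  stimulus_protocol(bind_rows(seg), total_h = total_h)
}

#' Parse a protocol shorthand string
#'
#' Accepts compact strings such as
#' `"gr:0-48:1,camp:0-48:1,insulin:0-168:1"` where each comma-separated item
#' is `channel:start-end:level`.
#'
#' @param text Shorthand string.
#' @param total_h Total duration; defaults to the largest segment end.
#' @return A `stimulus_protocol`.
#' @export
parse_protocol <- function(text, total_h = NULL) {
  items <- strsplit(text, ",", fixed = TRUE)[[1]]
  seg <- map(items, function(it) {
    f <- strsplit(trimws(it), ":", fixed = TRUE)[[1]]
    if (length(f) != 3) abort(paste0("cannot parse protocol item '", it, "'"))
    tm <- as.numeric(strsplit(f[2], "-", fixed = TRUE)[[1]])
    tibble(channel = f[1], start_h = tm[1], end_h = tm[2], level = as.numeric(f[3]))
  })
  seg <- bind_rows(seg)
  stimulus_protocol(seg, total_h = total_h %||% max(seg$end_h))
}

#' Read / write protocols as JSON
#'
#' @param path File path.
#' @return `read_protocol` returns a `stimulus_protocol`; `write_protocol`
#'   returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_protocol(as_tibble(raw$segments), total_h = raw$total_h)
}

#' @param protocol A `stimulus_protocol`.
#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(
    list(total_h = attr(protocol, "total_h"),
         segments = as.data.frame(protocol)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
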