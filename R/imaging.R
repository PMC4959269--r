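.field_channels <- c("hoechst", "pparg", "cebpb", "cebpa", "bodipy", "pakt")

#' Specification of a synthetic immunofluorescence field
#'
#' Describes the virtual microscope used to render simulated cells into
#' multi-channel images: geometry (pixel size, default 1.6 um/px as plausible
#' for a 4x objective with a ~1.3-Mpx CCD), nucleus size distribution,
#' optical blur, per-channel photon gain, background level with an optional
#' linear gradient, and a Poisson-plus-Gaussian noise model.
#'
#' @param width_px,height_px Image size in pixels (>= 128).
#' @param pixel_size_um Pixel calibration (um/px), default 1.6.
#' @param n_cells Number of cells to place.
#' @param nucleus_radius_um Mean nucleus radius (um), default 4.8.
#' @param nucleus_radius_sd_um SD of the nucleus radius (um), default 0.6.
#' @param blur_sigma_px Gaussian optical blur (px), default 1.
#' @param background Background offset (counts), default 100.
#' @param gradient Linear background gradient across the field as a fraction
#'   of `background` per full field width, `c(x, y)`; default `c(0, 0)`.
#' @param poisson_gain Counts per photon for shot noise, default 1 (0
#'   disables Poisson noise).
#' @param read_sd Gaussian read noise SD (counts), default 2.
#' @param gain Named per-channel intensity gains (counts per a.u.).
#' @param min_separation_um Minimum distance between nuclear centroids (um).
#' @param seed Integer seed for placement and noise.
#' @return A `field_spec` list.
#' @export
field_spec <- function(width_px = 512, height_px = 512, pixel_size_um = 1.6,
                       n_cells = 100, nucleus_radius_um = 4.8,
                       nucleus_radius_sd_um = 0.6, blur_sigma_px = 1,
                       background = 100, gradient = c(0, 0),
                       poisson_gain = 1, read_sd = 2,
                       gain = c(hoechst = 400, pparg = 200, cebpb = 200,
                                cebpa = 200, bodipy = 120, pakt = 120),
                       min_separation_um = 16, seed = 1) {
  if (width_px < 128 || height_px < 128) abort("field must be at least 128 px per side")
  if (pixel_size_um <= 0) abort("pixel_size_um must be > 0")
  if (any(gain <= 0)) abort("channel gains must be > 0")
  structure(as.list(environment()), class = "field_spec")
}

place_centroids <- function(spec) {
  margin <- ceiling((spec$nucleus_radius_um + 8) / spec$pixel_size_um)
  min_sep_px <- spec$min_separation_um / spec$pixel_size_um
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0
  while (length(xs) < spec$n_cells) {
    tries <- tries + 1
    if (tries > 200 * spec$n_cells + 1000) {
      abort("cannot place n_cells at the requested minimum separation")
    }
    x <- runif(1, margin, spec$width_px - margin)
    y <- runif(1, margin, spec$height_px - margin)
    if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= min_sep_px^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  tibble(cell_id = seq_len(spec$n_cells), x_px = xs, y_px = ys)
}

disk_stamp <- function(img, x, y, radius, amplitude) {
  nx <- ncol(img); ny <- nrow(img)
  x0 <- max(1, floor(x - radius - 1)); x1 <- min(nx, ceiling(x + radius + 1))
  y0 <- max(1, floor(y - radius - 1)); y1 <- min(ny, ceiling(y + radius + 1))
  cx <- x0:x1; cy <- y0:y1
  d2 <- outer((cy - y)^2, (cx - x)^2, `+`)
  img[cy, cx] <- img[cy, cx] + amplitude * (d2 <= radius^2)
  img
}

annulus_stamp <- function(img, x, y, r_in, r_out, amplitude) {
  nx <- ncol(img); ny <- nrow(img)
  x0 <- max(1, floor(x - r_out - 1)); x1 <- min(nx, ceiling(x + r_out + 1))
  y0 <- max(1, floor(y - r_out - 1)); y1 <- min(ny, ceiling(y + r_out + 1))
  cx <- x0:x1; cy <- y0:y1
  d2 <- outer((cy - y)^2, (cx - x)^2, `+`)
  img[cy, cx] <- img[cy, cx] + amplitude * (d2 <= r_out^2 & d2 > r_in^2)
  img
}

#' Render a synthetic multi-channel immunofluorescence field
#'
#' Places nuclei at random non-overlapping positions and renders six
#' channels: Hoechst (nuclear, constant per cell), the three transcription
#' factors (nuclear, amplitude proportional to each cell's state), and
#' BODIPY / pAKT (cytosolic, rendered on the perinuclear annulus). Uniform
#' disks are blurred with a Gaussian PSF (which preserves integrated
#' signal), then background, optional linear gradient, Poisson shot noise
#' and Gaussian read noise are added. The ground-truth table records true
#' centroids and true mean amplitudes per channel.
#'
#' @param spec A `field_spec`.
#' @param cell_states Data frame / matrix with one row per cell and columns
#'   `cebpb, pparg, cebpa, pakt, ir, fat` (e.g. a slice of a `cell_table`).
#' @return A `synthetic_field`: list with `channels` (named list of numeric
#'   matrices, counts), `truth` (tibble) and `spec`.
#' @export
generate_field <- function(spec, cell_states) {
  cell_states <- as.data.frame(cell_states)
  if (nrow(cell_states) != spec$n_cells) {
    abort("cell_states must have exactly n_cells rows")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  truth <- place_centroids(spec)
  radius_px <- pmax(1.5, rnorm(spec$n_cells, spec$nucleus_radius_um,
                               spec$nucleus_radius_sd_um) / spec$pixel_size_um)
  truth$radius_px <- radius_px
  ring_px <- 7 / spec$pixel_size_um

  state_of <- list(hoechst = function(s) rep(1, nrow(s)),
                   pparg = function(s) s$pparg, cebpb = function(s) s$cebpb,
                   cebpa = function(s) s$cebpa, bodipy = function(s) s$fat,
                   pakt = function(s) s$pakt)
  channels <- list()
  for (ch in .field_channels) {
    vals <- state_of[[ch]](cell_states)
    amp <- spec$gain[[ch]] * vals
    img <- matrix(0, spec$height_px, spec$width_px)
    for (i in seq_len(spec$n_cells)) {
      if (spec$n_cells == 0) break
      if (ch %in% c("bodipy", "pakt")) {
        img <- annulus_stamp(img, truth$x_px[i], truth$y_px[i],
                             radius_px[i], radius_px[i] + ring_px, amp[i])
      } else {
        img <- disk_stamp(img, truth$x_px[i], truth$y_px[i], radius_px[i], amp[i])
      }
    }
    if (spec$blur_sigma_px > 0) {
      img <- EBImage::gblur(img, sigma = spec$blur_sigma_px)
    }
    gx <- spec$gradient[1]; gy <- spec$gradient[2]
    bg <- spec$background *
      (1 + gx * (col(img) - 1) / (ncol(img) - 1) + gy * (row(img) - 1) / (nrow(img) - 1))
    img <- img + bg
    if (spec$poisson_gain > 0) {
      img <- spec$poisson_gain * matrix(rpois(length(img), pmax(img, 0) / spec$poisson_gain),
                                        nrow(img))
    }
    if (spec$read_sd > 0) img <- img + rnorm(length(img), 0, spec$read_sd)
    channels[[ch]] <- pmax(img, 0)
    truth[[paste0("true_", ch)]] <- amp
  }
  structure(list(channels = channels, truth = truth, spec = spec),
            class = "synthetic_field")
}

#' Detect nuclear centroids in a Hoechst image
#'
#' Gaussian-smooths the image, estimates the background robustly
#' (median + k * MAD), and reports sub-pixel local maxima above that
#' threshold that are at least `min_separation_um` apart (the brighter
#' detection wins). Warns when more than half of the image is saturated.
#'
#' @param image Numeric matrix (single channel).
#' @param pixel_size_um Pixel calibration (um/px).
#' @param smooth_sigma_px Smoothing sigma (px), default 2.
#' @param min_separation_um Minimum accepted distance between detections.
#' @param k_mad Threshold is `median + k_mad * mad`, default 6.
#' @param max_count Saturation level for the warning, default `2^16 - 1`.
#' @return Tibble with sub-pixel `x_px`, `y_px` and `peak` intensity.
#' @export
find_nuclear_centroids <- function(image, pixel_size_um = 1.6,
                                   smooth_sigma_px = 2,
                                   min_separation_um = 16, k_mad = 6,
                                   max_count = 65535) {
  if (mean(image >= max_count) > 0.5) warn("more than half of the image is saturated")
  sm <- EBImage::gblur(image, sigma = smooth_sigma_px)
  thr <- median(sm) + k_mad * stats::mad(sm)
  r <- max(1, round(min_separation_um / pixel_size_um / 2))
  mx <- EBImage::dilate(sm, EBImage::makeBrush(2 * r + 1, "disc"))
  is_peak <- sm >= mx - 1e-9 & sm > thr
  idx <- which(is_peak, arr.ind = TRUE)
  if (!nrow(idx)) return(tibble(x_px = numeric(), y_px = numeric(), peak = numeric()))
  peaks <- tibble(y_px = as.numeric(idx[, 1]), x_px = as.numeric(idx[, 2]),
                  peak = sm[idx])
  peaks <- arrange(peaks, dplyr::desc(.data$peak))
  keep <- rep(TRUE, nrow(peaks))
  min_sep_px <- min_separation_um / pixel_size_um
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      j <- (i + 1):nrow(peaks)
      too_close <- (peaks$x_px[j] - peaks$x_px[i])^2 +
        (peaks$y_px[j] - peaks$y_px[i])^2 < min_sep_px^2
      keep[j][too_close] <- FALSE
    }
  }
  peaks <- peaks[keep, ]
  # sub-pixel refinement: intensity-weighted centroid in a small window
  w <- 2
  for (i in seq_len(nrow(peaks))) {
    cy <- round(peaks$y_px[i]); cx <- round(peaks$x_px[i])
    ys <- max(1, cy - w):min(nrow(sm), cy + w)
    xs <- max(1, cx - w):min(ncol(sm), cx + w)
    patch <- sm[ys, xs] - min(sm[ys, xs])
    if (sum(patch) > 0) {
      peaks$y_px[i] <- sum(row(patch) * patch) / sum(patch) + ys[1] - 1
      peaks$x_px[i] <- sum(col(patch) * patch) / sum(patch) + xs[1] - 1
    }
  }
  select(peaks, "x_px", "y_px", "peak")
}

#' Grow a nucleus mask from a centroid
#'
#' Region-grows from the centroid over all connected pixels whose intensity
#' is at least `cutoff` (default 30%) of the local peak, where the local
#' peak is the maximum within `peak_radius_px` of the centroid. Raising the
#' cutoff shrinks the mask monotonically.
#'
#' @param image Numeric matrix (nuclear channel).
#' @param centroid Numeric `c(x_px, y_px)`.
#' @param cutoff Intensity fraction of the local peak, default 0.30.
#' @param peak_radius_px Radius defining the local peak, default 3.
#' @param background Background estimate; an error is raised if the local
#'   peak does not exceed it (centroid on background).
#' @return Logical matrix mask containing the centroid pixel.
#' @export
grow_nucleus_mask <- function(image, centroid, cutoff = 0.30,
                              peak_radius_px = 3, background = 0) {
  cx <- round(centroid[1]); cy <- round(centroid[2])
  if (cx < 1 || cx > ncol(image) || cy < 1 || cy > nrow(image)) {
    abort("centroid lies outside the image")
  }
  ys <- max(1, cy - peak_radius_px):min(nrow(image), cy + peak_radius_px)
  xs <- max(1, cx - peak_radius_px):min(ncol(image), cx + peak_radius_px)
  peak <- max(image[ys, xs])
  if (peak <= background) abort("centroid sits on background (no local peak)")
  above <- image >= cutoff * peak
  above[cy, cx] <- TRUE   # the seed always belongs to its own mask
  lab <- EBImage::bwlabel(above)
  mask <- lab == lab[cy, cx]
  mask
}

#' Expand a nucleus mask into a cell mask
#'
#' Morphological dilation of the nucleus mask by 7 um (rounded to pixels),
#' covering the nucleus and the perinuclear region. A dilation radius of
#' zero (very large pixels) returns the nucleus mask itself. The result is
#' flagged (`attr(mask, "clipped")`) when it touches the image border.
#'
#' @param nucleus_mask Logical matrix.
#' @param pixel_size_um Pixel calibration (um/px).
#' @param expand_um Expansion distance (um), default 7.
#' @return Logical matrix mask containing the nucleus mask.
#' @export
make_cell_mask <- function(nucleus_mask, pixel_size_um = 1.6, expand_um = 7) {
  if (!any(nucleus_mask)) abort("nucleus mask is empty")
  r <- round(expand_um / pixel_size_um)
  if (r < 1) {
    out <- nucleus_mask
  } else {
    out <- EBImage::dilate(nucleus_mask, EBImage::makeBrush(2 * r + 1, "disc")) > 0
  }
  idx <- which(out, arr.ind = TRUE)
  clipped <- any(idx[, 1] %in% c(1, nrow(out))) || any(idx[, 2] %in% c(1, ncol(out)))
  structure(out | nucleus_mask, clipped = clipped)
}

#' Background-corrected per-cell intensities
#'
#' Local background is the per-channel median over an annulus 2--5 um
#' beyond the cell mask, excluding every cell's mask; if that annulus is
#' fully occluded by neighbours the field-wide median outside all cells is
#' used and the cell is flagged. Nuclear channels are averaged over the
#' nucleus mask, cytosolic channels over the cell mask, background is
#' subtracted and results floored at zero.
#'
#' @param channels Named list of channel matrices.
#' @param nucleus_mask,cell_mask Logical matrices for this cell.
#' @param all_cell_masks Logical matrix marking every cell's mask (union).
#' @param pixel_size_um Pixel calibration.
#' @return One-row tibble: one column per channel, plus `bg_<channel>` and
#'   `bg_fallback`.
#' @export
measure_cell <- function(channels, nucleus_mask, cell_mask, all_cell_masks,
                         pixel_size_um = 1.6) {
  r2 <- max(1, round(2 / pixel_size_um)); r5 <- max(r2 + 1, round(5 / pixel_size_um))
  inner <- EBImage::dilate(cell_mask, EBImage::makeBrush(2 * r2 + 1, "disc")) > 0
  outer <- EBImage::dilate(cell_mask, EBImage::makeBrush(2 * r5 + 1, "disc")) > 0
  annulus <- outer & !inner & !all_cell_masks
  fallback <- sum(annulus) == 0
  out <- list()
  for (ch in names(channels)) {
    img <- channels[[ch]]
    bg <- if (fallback) median(img[!all_cell_masks]) else median(img[annulus])
    roi <- if (ch %in% c("bodipy", "pakt")) cell_mask else nucleus_mask
    out[[ch]] <- max(0, mean(img[roi]) - bg)
    out[[paste0("bg_", ch)]] <- bg
  }
  out$bg_fallback <- fallback
  as_tibble(out)
}

#' Segment and quantify a synthetic field
#'
#' The full single-cell quantification pipeline: nuclear centroids from the
#' Hoechst channel, per-nucleus 30%-of-peak masks, 7-um cell-mask
#' expansion, local background subtraction, and per-channel mean
#' intensities (nuclear channels over the nucleus mask, cytosolic channels
#' over the cell mask).
#'
#' @param field A `synthetic_field` (or a named list of channel matrices
#'   including `hoechst`).
#' @param pixel_size_um Pixel calibration; defaults to the field's spec.
#' @param min_separation_um Passed to [find_nuclear_centroids()].
#' @return A tibble with `cell_id`, `x_px`, `y_px` and per-channel
#'   background-corrected mean intensities.
#' @export
quantify_field <- function(field, pixel_size_um = NULL,
                           min_separation_um = NULL) {
  channels <- if (inherits(field, "synthetic_field")) field$channels else field
  if (inherits(field, "synthetic_field")) {
    pixel_size_um <- pixel_size_um %||% field$spec$pixel_size_um
    min_separation_um <- min_separation_um %||% field$spec$min_separation_um
  } else {
    pixel_size_um <- pixel_size_um %||% 1.6
    min_separation_um <- min_separation_um %||% 16
  }
  cent <- find_nuclear_centroids(channels$hoechst, pixel_size_um,
                                 min_separation_um = min_separation_um)
  if (!nrow(cent)) return(tibble())
  masks <- map(seq_len(nrow(cent)), function(i) {
    nm <- grow_nucleus_mask(channels$hoechst, c(cent$x_px[i], cent$y_px[i]))
    cm <- make_cell_mask(nm, pixel_size_um)
    list(nucleus = nm, cell = cm)
  })
  all_masks <- Reduce(`|`, map(masks, "cell"))
  rows <- map(seq_len(nrow(cent)), function(i) {
    m <- measure_cell(channels, masks[[i]]$nucleus, masks[[i]]$cell,
                      all_masks, pixel_size_um)
    mutate(m, cell_id = i, x_px = cent$x_px[i], y_px = cent$y_px[i],
           .before = 1)
  })
  bind_rows(rows)
}

#' Write / read a synthetic field as a 16-bit multi-page TIFF
#'
#' One page per channel in the fixed order hoechst, pparg, cebpb, cebpa,
#' bodipy, pakt. Counts are clipped to the 16-bit range.
#'
#' @param field A `synthetic_field`.
#' @param path Output path.
#' @export
write_field_tiff <- function(field, path) {
  pages <- map(field$channels[.field_channels], function(img) {
    pmin(pmax(round(img), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_field_tiff
#' @return `read_field_tiff` returns a named list of channel matrices
#'   (counts).
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  setNames(map(pages, function(m) m * 65535), .field_channels[seq_along(pages)])
}
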