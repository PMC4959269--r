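mk_states <- function(n, pparg = 1, fat = 0.5) {
  tibble::tibble(cebpb = 1, pparg = pparg, cebpa = 1, pakt = 1, ir = 1,
                 fat = fat)[rep(1, n), ]
}

test_that("an empty field is pure background", {
  spec <- field_spec(width_px = 128, height_px = 128, n_cells = 0, seed = 1,
                     gradient = c(0, 0))
  fld <- generate_field(spec, mk_states(0))
  for (ch in names(fld$channels)) {
    m <- fld$channels[[ch]]
    expect_lt(abs(mean(m) - spec$background), 3)
    expect_lt(sd(m), 4 * sqrt(spec$background))
  }
})

test_that("integrated nuclear signal equals gain x state x disk area", {
  spec <- field_spec(width_px = 256, height_px = 256, n_cells = 1, seed = 4,
                     background = 0, poisson_gain = 0, read_sd = 0,
                     nucleus_radius_sd_um = 0)
  v <- 2.5
  fld <- generate_field(spec, mk_states(1, pparg = v))
  img <- fld$channels$pparg
  r_px <- fld$truth$radius_px[1]
  expect_equal(sum(img), spec$gain[["pparg"]] * v * sum(
    outer((1:256 - fld$truth$y_px[1])^2, (1:256 - fld$truth$x_px[1])^2, `+`) <= r_px^2
  ), tolerance = 0.02)
})

test_that("rendering is deterministic given the spec seed", {
  spec <- field_spec(width_px = 128, height_px = 128, n_cells = 5, seed = 7)
  f1 <- generate_field(spec, mk_states(5))
  f2 <- generate_field(spec, mk_states(5))
  expect_identical(f1$channels, f2$channels)
  expect_identical(f1$truth, f2$truth)
})

test_that("placement fails loudly when cells cannot fit", {
  spec <- field_spec(width_px = 128, height_px = 128, n_cells = 500,
                     min_separation_um = 30, seed = 1)
  expect_error(generate_field(spec, mk_states(500)), "cannot place")
})

test_that("centroid detection has high recall and precision on a dense field", {
  spec <- field_spec(width_px = 512, height_px = 512, n_cells = 150, seed = 5)
  fld <- generate_field(spec, mk_states(150))
  cent <- find_nuclear_centroids(fld$channels$hoechst, spec$pixel_size_um,
                                 min_separation_um = spec$min_separation_um)
  match_r <- 2
  matched <- 0
  used <- rep(FALSE, nrow(cent))
  for (i in seq_len(nrow(fld$truth))) {
    d2 <- (cent$x_px - fld$truth$x_px[i])^2 + (cent$y_px - fld$truth$y_px[i])^2
    j <- which(!used & d2 <= match_r^2)
    if (length(j)) { matched <- matched + 1; used[j[1]] <- TRUE }
  }
  expect_gte(matched / nrow(fld$truth), 0.95)   # recall
  expect_gte(matched / nrow(cent), 0.95)        # precision
  # blank image: nothing found
  blank <- matrix(rnorm(128^2, 100, 2), 128)
  expect_identical(nrow(find_nuclear_centroids(blank)), 0L)
})

test_that("nucleus mask of a Gaussian spot has the closed-form level-set radius", {
  s <- 6
  img <- 1000 * exp(-outer((1:128 - 64)^2, (1:128 - 64)^2, `+`) / (2 * s^2))
  mask <- grow_nucleus_mask(img, c(64, 64))
  r_expect <- s * sqrt(2 * log(1 / 0.3))
  r_got <- sqrt(sum(mask) / pi)
  expect_lt(abs(r_got - r_expect), 1)
  expect_true(mask[64, 64])
  # raising the cutoff shrinks the mask monotonically
  sizes <- sapply(c(0.2, 0.4, 0.6, 0.8), function(cf)
    sum(grow_nucleus_mask(img, c(64, 64), cutoff = cf)))
  expect_true(all(diff(sizes) < 0))
  # centroid on background errors
  expect_error(grow_nucleus_mask(img, c(5, 5), background = 10), "background")
})

test_that("cell-mask dilation follows the pixel calibration", {
  nm <- matrix(FALSE, 64, 64); nm[30:34, 30:34] <- TRUE
  cm <- make_cell_mask(nm, pixel_size_um = 1.6)   # radius round(7/1.6) = 4 px
  expect_true(all(cm[nm]))
  # width grows by 2 * 4 px
  expect_equal(diff(range(which(apply(cm, 1, any)))) -
                 diff(range(which(apply(nm, 1, any)))), 8)
  expect_gte(sum(cm), sum(nm))
  # degenerate huge pixels: dilation radius 0 keeps the nucleus mask
  cm0 <- make_cell_mask(nm, pixel_size_um = 20)
  expect_equal(sum(cm0), sum(nm))
})

test_that("measured intensities recover ground truth on a synthetic field", {
  set.seed(2)
  n <- 120
  states <- tibble::tibble(
    cebpb = exp(rnorm(n, 0, 0.4)), pparg = exp(rnorm(n, 0.5, 0.6)),
    cebpa = exp(rnorm(n, 0, 0.4)), pakt = exp(rnorm(n, 0, 0.3)),
    ir = 1, fat = exp(rnorm(n, -0.5, 0.5)))
  spec <- field_spec(width_px = 512, height_px = 512, n_cells = n, seed = 9)
  fld <- generate_field(spec, states)
  q <- quantify_field(fld)
  expect_gte(nrow(q), 0.9 * n)
  # match measured cells to truth by nearest centroid
  for (ch in c("pparg", "cebpb", "bodipy")) {
    truth_col <- paste0("true_", ch)
    idx <- sapply(seq_len(nrow(q)), function(i) {
      which.min((fld$truth$x_px - q$x_px[i])^2 + (fld$truth$y_px - q$y_px[i])^2)
    })
    r <- cor(q[[ch]], fld$truth[[truth_col]][idx])
    expect_gte(r, 0.95)
  }
})

test_that("uniform image measures to zero after background subtraction", {
  img <- matrix(500, 64, 64)
  channels <- setNames(rep(list(img), 6),
                       c("hoechst", "pparg", "cebpb", "cebpa", "bodipy", "pakt"))
  nm <- matrix(FALSE, 64, 64); nm[30:33, 30:33] <- TRUE
  cm <- make_cell_mask(nm, 1.6)
  m <- measure_cell(channels, nm, cm, cm, 1.6)
  expect_true(all(unlist(m[, c("pparg", "bodipy")]) == 0))
})

test_that("a 10% linear background gradient barely biases the means", {
  set.seed(3)
  n <- 40
  states <- mk_states(n, pparg = 2, fat = 1)
  flat <- generate_field(field_spec(width_px = 384, height_px = 384,
                                    n_cells = n, seed = 13), states)
  grad <- generate_field(field_spec(width_px = 384, height_px = 384,
                                    n_cells = n, seed = 13,
                                    gradient = c(0.1, 0)), states)
  qf <- quantify_field(flat); qg <- quantify_field(grad)
  mf <- merge(as.data.frame(qf), as.data.frame(qg), by = "cell_id")
  expect_lt(median(abs(mf$pparg.x - mf$pparg.y) / mf$pparg.x), 0.05)
})

test_that("measurement is linear in the underlying state", {
  spec <- field_spec(width_px = 256, height_px = 256, n_cells = 6, seed = 21)
  f1 <- generate_field(spec, mk_states(6, pparg = 1.2))
  f2 <- generate_field(spec, mk_states(6, pparg = 2.4))
  q1 <- quantify_field(f1); q2 <- quantify_field(f2)
  expect_equal(nrow(q1), nrow(q2))
  expect_lt(abs(median(q2$pparg) / median(q1$pparg) - 2), 0.1)
})

test_that("field TIFF round-trip preserves counts to 16-bit resolution", {
  spec <- field_spec(width_px = 128, height_px = 128, n_cells = 3, seed = 30)
  fld <- generate_field(spec, mk_states(3))
  f <- withr::local_tempfile(fileext = ".tif")
  write_field_tiff(fld, f)
  back <- read_field_tiff(f)
  expect_identical(names(back), names(fld$channels))
  expect_lt(max(abs(back$hoechst - round(fld$channels$hoechst))), 0.51)
})
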