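test_that("mixture classifier separates clear synthetic mixtures", {
  set.seed(11)
  # 50/50 lognormal mixture, 10-fold separated, sd 0.1 in log10
  x <- c(10^rnorm(1000, 0, 0.1), 10^rnorm(1000, 1, 0.1))
  fit <- classify_bimodality(x)
  expect_true(fit$is_bimodal)
  expect_lt(abs(fit$frac_high - 0.5), 0.03)
  expect_gt(fit$threshold, 10^0.25); expect_lt(fit$threshold, 10^0.75)

  # unimodal null with a realistic CV
  y <- exp(rnorm(2000, 0, sqrt(log(1 + 0.3^2))))
  expect_false(classify_bimodality(y)$is_bimodal)

  # degenerate: identical values
  expect_false(classify_bimodality(rep(2, 100))$is_bimodal)

  expect_error(classify_bimodality(runif(20) + 1), "at least 50")
  expect_error(classify_bimodality(c(rep(1, 60), -1)), "positive")
})

test_that("classifier accuracy is at least 95% on well-separated labelled mixtures", {
  set.seed(21)
  correct <- 0; total <- 0
  for (rep in 1:5) {
    frac <- runif(1, 0.25, 0.75)
    n <- 1200
    n1 <- rbinom(1, n, frac)
    lab <- c(rep(FALSE, n - n1), rep(TRUE, n1))
    # >= 4 pooled-sd separation in log10
    x <- ifelse(lab, 10^rnorm(n, 0.9, 0.15), 10^rnorm(n, 0, 0.15))
    fit <- classify_bimodality(x)
    expect_true(fit$is_bimodal)
    correct <- correct + sum((x > fit$threshold) == lab)
    total <- total + n
  }
  expect_gte(correct / total, 0.95)
})

test_that("fraction_differentiated handles trivial and labelled cases", {
  mk_tab <- function(v) {
    structure(tibble::tibble(cell_id = seq_along(v), time_h = 96,
                             cebpb = 1, pparg = v, cebpa = 1, pakt = 1,
                             ir = 1, fat = 0, failed = FALSE),
              class = c("cell_table", "tbl_df", "tbl", "data.frame"))
  }
  # all cells below a fixed threshold
  tab <- mk_tab(rep(0.5, 100))
  fr <- fraction_differentiated(tab, "pparg", 96, threshold = 1)
  expect_equal(fr$fraction, 0)
  # known-label mixture recovered within binomial error
  set.seed(5)
  v <- c(10^rnorm(1400, 0, 0.12), 10^rnorm(600, 1, 0.12))
  fr2 <- fraction_differentiated(mk_tab(v), "pparg", 96)
  expect_lt(abs(fr2$fraction - 0.3), 0.03)
  # unimodal + no fallback errors; with fallback it works
  u <- 10^rnorm(500, 0, 0.1)
  expect_error(fraction_differentiated(mk_tab(u), "pparg", 96), "fallback")
  fr3 <- fraction_differentiated(mk_tab(u), "pparg", 96, fallback_threshold = 3)
  expect_lt(fr3$fraction, 0.01)
})

test_that("rank AUC behaves as a discrimination score", {
  lab <- c(rep(FALSE, 50), rep(TRUE, 50))
  # perfectly separating predictor
  expect_equal(adiposwitch:::rank_auc(c(1:50, 101:150), lab), 1)
  # permutation null: AUC concentrates at 1/2
  set.seed(31)
  aucs <- replicate(200, adiposwitch:::rank_auc(rnorm(100), sample(lab)))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
  expect_true(all(aucs > 0.2 & aucs < 0.8))
})

test_that("rank AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  score <- rnorm(300)
  lab <- runif(300) < plogis(score)
  got <- adiposwitch:::rank_auc(score, lab)
  want <- as.numeric(suppressMessages(pROC::auc(pROC::roc(lab, score, quiet = TRUE))))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("predictor ranking works on a constructed table", {
  set.seed(51)
  n <- 400
  lab <- runif(n) < 0.5
  tab <- tibble::tibble(
    cell_id = rep(1:n, 2),
    time_h = rep(c(24, 96), each = n),
    cebpb = c(exp(rnorm(n, 0.2 * lab, 0.5)), rep(1, n)),
    pparg = c(exp(rnorm(n, 1.5 * lab, 0.3)), ifelse(lab, 10, 1)),
    cebpa = c(exp(rnorm(n, 0.5 * lab, 0.5)), rep(1, n)),
    pakt = 1, ir = 1, fat = 0, failed = FALSE
  )
  rk <- preswitch_predictor_ranking(tab, 24, 96, threshold = 3)
  expect_identical(rk$factor[1], "pparg")
  expect_gt(rk$auc[1], max(rk$auc[-1]))
})
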