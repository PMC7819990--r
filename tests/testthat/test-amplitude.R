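# independent oracle: one-sided binomial tail by direct summation of the pmf
binom_tail_direct <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, p))
}

# independent oracle: full scan by naive counting and direct-summation tails
brute_scan <- function(e, c_, side, n_steps = 100, alpha = 0.05,
                       limit = 1000) {
  p_e <- length(e) / (length(e) + length(c_))
  p_c <- 1 - p_e
  xs <- if (side == "negative") -seq_len(n_steps) * limit / n_steps
        else seq_len(n_steps) * limit / n_steps
  res <- t(vapply(xs, function(x) {
    ke <- if (side == "negative") sum(e < x) else sum(e > x)
    kc <- if (side == "negative") sum(c_ < x) else sum(c_ > x)
    c(ke, kc, binom_tail_direct(ke, ke + kc, p_e),
      binom_tail_direct(kc, ke + kc, p_c))
  }, numeric(4)))
  sig_e <- res[, 3] < alpha / (2 * n_steps)
  sel <- if (!any(sig_e)) NA_real_
         else if (side == "negative") max(xs[sig_e]) else min(xs[sig_e])
  list(thresholds = xs, k_edge = res[, 1], k_center = res[, 2],
       p_edge = res[, 3], p_center = res[, 4], selected = sel)
}

test_that("amplitude PDFs normalize exactly and keep tiny probabilities", {
  pool <- subsample_pool(matrix(rep(7.25, 100), 100, 1), step = 1)
  pdf <- amp_pdf(pool)
  expect_equal(sum(pdf$probability), 1, tolerance = 1e-12)
  expect_equal(sum(pdf$probability > 0), 1L)
  expect_equal(max(pdf$probability), 1)

  # one extreme sample in 1e5: probability 1e-5 stored exactly, not masked
  x <- c(rnorm(1e5 - 1), -900)
  pdf2 <- amp_pdf(subsample_pool(matrix(x, ncol = 1), step = 1))
  expect_equal(pdf2$probability[findInterval(-900, pdf2$bin_edges_uV)], 1e-5)
  expect_error(amp_pdf(subsample_pool(matrix(2000, 1, 1), step = 1)), "empty")
})

test_that("PDF bin counts follow the binomial sampling distribution", {
  set.seed(31)
  n <- 1e6
  x <- rnorm(n) * 10
  pdf <- amp_pdf(subsample_pool(matrix(x, ncol = 1), step = 1))
  p_true <- pnorm(pdf$bin_edges_uV[-1], sd = 10) -
    pnorm(pdf$bin_edges_uV[-length(pdf$bin_edges_uV)], sd = 10)
  keep <- p_true > 1e-6
  z <- (pdf$counts[keep] - n * p_true[keep]) /
    sqrt(n * p_true[keep] * (1 - p_true[keep]))
  expect_true(all(abs(z) < 5))
})

test_that("pooled RMS matches closed forms and the chi-distribution oracle", {
  expect_equal(pool_rms(rep(-3, 10)), 3)
  expect_equal(pool_rms(c(2, -2, 2, -2)), 2)
  set.seed(4)
  expect_lt(abs(pool_rms(rnorm(1e6, sd = 10)) - 10), 0.03)
  # pooling across recordings
  expect_equal(pool_rms(list(rep(1, 5), rep(7, 5))), sqrt(mean(c(1, 49))))
})

test_that("the exact null yields no significant threshold in either direction", {
  set.seed(5)
  x <- rnorm(2e4) * 15
  s <- cumulative_scan(x, x, "negative")
  expect_false(any(s$sig_edge) || any(s$sig_center))
  expect_true(is.na(s$threshold_edge_uV))
  s2 <- cumulative_scan(x, x, "positive")
  expect_false(any(s2$sig_edge) || any(s2$sig_center))
})

test_that("scan counts, p-values and selection match the brute-force oracle", {
  set.seed(6)
  e <- rnorm(8e3) * 12
  c_ <- rnorm(9e3) * 10
  for (side in c("negative", "positive")) {
    s <- cumulative_scan(e, c_, side)
    o <- brute_scan(e, c_, side)
    expect_equal(s$thresholds_uV, o$thresholds)
    expect_equal(s$k_edge, o$k_edge, ignore_attr = TRUE)
    expect_equal(s$k_center, o$k_center, ignore_attr = TRUE)
    expect_equal(s$p_edge_direction, o$p_edge, tolerance = 1e-10)
    expect_equal(s$p_center_direction, o$p_center, tolerance = 1e-10)
    expect_equal(s$threshold_edge_uV, o$selected)
  }
})

test_that("the Bonferroni correction spans both directions", {
  set.seed(7)
  s <- cumulative_scan(rnorm(100), rnorm(100), "negative",
                       n_steps = 100, alpha = 0.05)
  expect_equal(s$alpha_corrected, 0.05 / 200)
  expect_equal(s$alpha_corrected, 2.5e-4)
})

test_that("scan counts are monotone toward the extremes and anchored at the pool", {
  set.seed(8)
  e <- rnorm(5e3) * 12; c_ <- rnorm(5e3) * 10
  s <- cumulative_scan(e, c_, "negative")
  expect_true(all(diff(s$k_edge) <= 0))    # thresholds run 0 -> -1000
  expect_equal(s$k_edge[1], sum(e < -10))
  expect_lte(s$k_edge[length(s$k_edge)], sum(e < 0))
  sp <- cumulative_scan(e, c_, "positive")
  expect_true(all(diff(sp$k_edge) <= 0))
  expect_equal(sp$k_edge[1], sum(e > 10))
})

test_that("samples exactly at a threshold are not counted as beyond it", {
  e <- c(rep(-10, 50), rep(-15, 5))
  c_ <- rep(-5, 55)
  s <- cumulative_scan(e, c_, "negative")
  expect_equal(s$k_edge[s$thresholds_uV == -10], 5L)  # only the -15s
})

test_that("significance masks never fire in both directions at once", {
  set.seed(9)
  for (i in 1:5) {
    e <- rnorm(5e3) * runif(1, 8, 14)
    c_ <- rnorm(5e3) * 10
    s <- cumulative_scan(e, c_, "negative")
    expect_false(any(s$sig_edge & s$sig_center))
  }
})

test_that("stronger spread differences never push the selected threshold deeper", {
  sels <- vapply(c(1.05, 1.15, 1.3), function(ratio) {
    set.seed(12)
    found <- vapply(1:5, function(i) {
      e <- rnorm(2e5) * 10 * ratio
      c_ <- rnorm(2e5) * 10
      s <- cumulative_scan(e, c_, "negative")
      if (is.na(s$threshold_edge_uV)) -1000 else s$threshold_edge_uV
    }, 0)
    mean(found)
  }, 0)
  expect_true(all(diff(sels) >= 0))
})

test_that("pct_beyond counts sign-restricted tails", {
  expect_equal(pct_beyond(c(-100, -90, 5), -50, "negative"), 100)
  expect_equal(pct_beyond(c(-1, -2, 5), -50, "negative"), 0)
  set.seed(13)
  u <- -runif(2e4) * 100
  expect_lt(abs(pct_beyond(u, -50, "negative") - 50), 2)
  expect_error(pct_beyond(c(1, 2), -10, "negative"), "no negative")
})

test_that("Brown-Forsythe matches hand computation and detects spread", {
  # identical pools: no between-group deviation at all
  x <- c(1, 5, 2, 8, 3, 9)
  bf0 <- brown_forsythe(x, x)
  expect_equal(bf0$brown_forsythe_F, 0)
  expect_equal(bf0$p_value, 1)

  # 6-value worked fixture against the Levene-median formula written out
  a <- c(1, 2, 6); b <- c(10, 20, 60)
  za <- abs(a - median(a)); zb <- abs(b - median(b))
  zbar <- mean(c(za, zb))
  f_hand <- (4 * (3 * (mean(za) - zbar)^2 + 3 * (mean(zb) - zbar)^2)) /
    (sum((za - mean(za))^2) + sum((zb - mean(zb))^2))
  bf <- brown_forsythe(a, b)
  expect_equal(bf$brown_forsythe_F, f_hand, tolerance = 1e-10)
  expect_equal(bf$p_value, pf(f_hand, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)

  set.seed(14)
  strong <- brown_forsythe(rnorm(1000, sd = 1), rnorm(1000, sd = 2))
  expect_lt(strong$p_value, 1e-3)
  expect_error(brown_forsythe(rep(1, 5), rep(2, 5)), "zero within-group")
})

test_that("Brown-Forsythe agrees with the car reference implementation", {
  skip_if_not_installed("car")
  set.seed(15)
  for (i in 1:10) {
    a <- rnorm(30, sd = runif(1, 0.5, 3)); b <- rnorm(40, sd = 1)
    ours <- brown_forsythe(a, b)
    ref <- car::leveneTest(c(a, b), factor(rep(1:2, c(30, 40))),
                           center = median)
    expect_equal(ours$brown_forsythe_F, ref$`F value`[1], tolerance = 1e-8)
    expect_equal(ours$p_value, ref$`Pr(>F)`[1], tolerance = 1e-6)
  }
})

test_that("PDF ratios recover forced and analytic relationships", {
  mk_pdf <- function(x) amp_pdf(subsample_pool(matrix(x, ncol = 1), step = 1))
  # identical PDFs: ratio 1 everywhere it is defined
  set.seed(16); x <- rnorm(5e4) * 20
  r <- pdf_ratio_summary(mk_pdf(x), mk_pdf(x))
  expect_equal(r$mean_ratio, 1)
  expect_true(all(r$ratio$ratio[!is.na(r$ratio$ratio)] == 1))

  # edge holds twice the center probability in every occupied negative bin
  center <- c(rep(-5.5, 100), rep(5.5, 300))
  edge <- c(rep(-5.5, 200), rep(5.5, 200))
  r2 <- pdf_ratio_summary(mk_pdf(edge), mk_pdf(center))
  expect_equal(r2$mean_ratio, 2)

  # two analytic normal densities: per-bin ratio tracks the density ratio
  set.seed(17)
  e <- rnorm(5e5) * 12; c_ <- rnorm(5e5) * 10
  r3 <- pdf_ratio_summary(mk_pdf(e), mk_pdf(c_))
  centers <- r3$ratio$bin_center_uV
  keep <- centers < -5 & centers > -25
  expected <- dnorm(centers[keep], sd = 12) / dnorm(centers[keep], sd = 10)
  expect_lt(median(abs(r3$ratio$ratio[keep] - expected) / expected), 0.1)

  # infinite ratios are counted and excluded
  e4 <- c(rep(-700.5, 10), rep(-5.5, 90))
  c4 <- rep(-5.5, 100)
  expect_message(r4 <- pdf_ratio_summary(mk_pdf(e4), mk_pdf(c4)), "excluded")
  expect_equal(r4$n_infinite, 1L)
  expect_true(is.finite(r4$mean_ratio))
})
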