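# Amplitude-distribution analysis: PDFs, RMS power, the binomial cumulative
# threshold scan with Bonferroni correction, Brown-Forsythe power comparison,
# and edge-to-center PDF-ratio summaries.

as_samples <- function(x) {
  if (inherits(x, "amplitude_pool")) x$samples_uV else as.numeric(x)
}

# exact binomial survival function P(X >= k), X ~ Binomial(n, p); the
# regularized incomplete beta behind pbinom is numerically robust at the
# pool sizes (1e7+) this scan meets
binom_sf <- function(k, n, p) {
  out <- numeric(length(k))
  pos <- k > 0
  out[!pos] <- 1
  out[pos] <- stats::pbinom(k[pos] - 1, n[pos], p, lower.tail = FALSE)
  out
}

#' Amplitude probability density function
#'
#' Histogram-based PDF of an amplitude pool over the examined range
#' (uniform bins spanning `[-limit_uV, limit_uV]`), with probabilities
#' normalized by the pool size so they sum to one. Probabilities below 1e-9
#' are conventionally masked in plots but are stored exactly here.
#'
#' @param pool An [subsample_pool()] amplitude pool.
#' @param bin_width_uV Bin width (default 1 uV).
#' @param limit_uV Half-range of the binning (default 1000 uV).
#' @return Object of class `amplitude_pdf`: list with `bin_edges_uV`,
#'   `bin_centers_uV`, `probability`, `counts`, `n_total`.
#' @export
amp_pdf <- function(pool, bin_width_uV = 1, limit_uV = 1000) {
  s <- as_samples(pool)
  if (!length(s)) stop("empty amplitude pool")
  edges <- seq(-limit_uV, limit_uV, by = bin_width_uV)
  bin <- findInterval(s, edges, rightmost.closed = TRUE)
  stopifnot(all(bin >= 1 & bin <= length(edges) - 1))
  counts <- tabulate(bin, nbins = length(edges) - 1)
  structure(list(bin_edges_uV = edges,
                 bin_centers_uV = (edges[-1] + edges[-length(edges)]) / 2,
                 probability = counts / length(s),
                 counts = counts, n_total = length(s)),
            class = "amplitude_pdf")
}

#' Root-mean-square amplitude of pooled samples
#'
#' Total signal power measure: the RMS over the pooled samples of one or
#' several amplitude pools (samples of all recordings in a group are pooled
#' before the square root is taken).
#'
#' @param x An `amplitude_pool`, a list of pools, or a numeric vector.
#' @return RMS in microvolts.
#' @export
pool_rms <- function(x) {
  if (is.list(x) && !inherits(x, "amplitude_pool"))
    x <- unlist(lapply(x, as_samples), use.names = FALSE)
  s <- as_samples(x)
  if (!length(s)) stop("empty input")
  sqrt(mean(s^2))
}

#' Binomial cumulative amplitude threshold scan
#'
#' Compares how edge and center samples populate the amplitude tails. The
#' examined range on one side of zero is divided into `n_steps` uniform
#' thresholds (10 uV spacing by default). At each threshold `x` the numbers
#' of edge and center samples beyond it are counted (`a < x` strictly on the
#' negative side, `a > x` strictly on the positive side). Under the null
#' hypothesis that samples beyond `x` are drawn from edge sites with
#' probability `p_e = N_e / (N_e + N_c)` (`N_e`, `N_c`: total pool sizes),
#' the edge count follows a binomial distribution; a one-sided exact binomial
#' test is run in the edge direction, and symmetrically in the center
#' direction with `p_c = N_c / (N_e + N_c)`. Significance uses
#' `alpha / (2 * n_steps)` (Bonferroni over both directions; 200 comparisons
#' at the defaults). The selected threshold is the least extreme threshold
#' whose edge-direction test is significant: the maximal amplitude below
#' which edge samples are significantly more abundant (negative side), or
#' the minimal amplitude above which they are (positive side).
#'
#' @param edge,center Amplitude pools (or numeric vectors) of the two groups.
#' @param side `"negative"` or `"positive"`.
#' @param n_steps Number of uniform thresholds (default 100).
#' @param alpha Family-wise significance level (default 0.05).
#' @param limit_uV Extent of the scanned range (default 1000 uV).
#' @return Object of class `scan_result`: thresholds, per-threshold counts
#'   `k_edge`/`k_center`, one-sided p-values `p_edge_direction` /
#'   `p_center_direction`, success probabilities `p_e`/`p_c`,
#'   `alpha_corrected`, significance masks `sig_edge`/`sig_center`, the
#'   selected `threshold_edge_uV` (NA when no threshold is significant), and
#'   `pct_edge`/`pct_center`: the percentage of each group's same-sign
#'   samples beyond the selected threshold.
#' @export
cumulative_scan <- function(edge, center, side = c("negative", "positive"),
                            n_steps = 100, alpha = 0.05, limit_uV = 1000) {
  side <- match.arg(side)
  e <- as_samples(edge); c_ <- as_samples(center)
  if (!length(e) || !length(c_)) stop("both pools must be nonempty")
  n_e <- length(e); n_c <- length(c_)
  p_e <- n_e / (n_e + n_c); p_c <- n_c / (n_e + n_c)
  step <- limit_uV / n_steps
  thresholds <- if (side == "negative") -step * seq_len(n_steps)
                else step * seq_len(n_steps)
  se <- sort(e); sc <- sort(c_)
  if (side == "negative") {
    k_edge <- findInterval(thresholds, se, left.open = TRUE)    # a < x
    k_center <- findInterval(thresholds, sc, left.open = TRUE)
  } else {
    k_edge <- n_e - findInterval(thresholds, se)                # a > x
    k_center <- n_c - findInterval(thresholds, sc)
  }
  n_x <- k_edge + k_center
  p_edge_dir <- binom_sf(k_edge, n_x, p_e)
  p_center_dir <- binom_sf(k_center, n_x, p_c)
  p_edge_dir[n_x == 0] <- 1
  p_center_dir[n_x == 0] <- 1
  alpha_corr <- alpha / (2 * n_steps)
  sig_edge <- p_edge_dir < alpha_corr
  sig_center <- p_center_dir < alpha_corr

  sel <- NA_real_
  if (any(sig_edge)) {
    sel <- if (side == "negative") max(thresholds[sig_edge])
           else min(thresholds[sig_edge])
  }
  pct_edge <- pct_center <- NA_real_
  if (!is.na(sel)) {
    pct_edge <- pct_beyond(e, sel, side)
    pct_center <- pct_beyond(c_, sel, side)
  }
  structure(list(side = side, thresholds_uV = thresholds,
                 k_edge = k_edge, k_center = k_center,
                 p_edge_direction = p_edge_dir,
                 p_center_direction = p_center_dir,
                 p_e = p_e, p_c = p_c, n_e = n_e, n_c = n_c,
                 alpha_corrected = alpha_corr,
                 sig_edge = sig_edge, sig_center = sig_center,
                 threshold_edge_uV = sel,
                 pct_edge = pct_edge, pct_center = pct_center),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s side, %d thresholds, alpha' = %.2e\n",
              x$side, length(x$thresholds_uV), x$alpha_corrected))
  if (is.na(x$threshold_edge_uV)) {
    cat("  no threshold with significant edge excess\n")
  } else {
    cat(sprintf("  selected threshold %g uV (edge %.2f%%, center %.2f%% of same-sign samples beyond)\n",
                x$threshold_edge_uV, x$pct_edge, x$pct_center))
  }
  invisible(x)
}

#' Percentage of same-sign samples beyond a threshold
#'
#' On the negative side: the percentage of a group's negative samples that
#' lie strictly below the threshold; on the positive side, of its positive
#' samples strictly above.
#'
#' @param pool Amplitude pool or numeric vector.
#' @param threshold_uV Amplitude threshold (sign-consistent with `side`).
#' @param side `"negative"` or `"positive"`.
#' @return Percentage in `[0, 100]`.
#' @export
pct_beyond <- function(pool, threshold_uV, side = c("negative", "positive")) {
  side <- match.arg(side)
  s <- as_samples(pool)
  if (side == "negative") {
    base <- s[s < 0]
    if (!length(base)) stop("no negative samples in pool")
    100 * sum(base < threshold_uV) / length(base)
  } else {
    base <- s[s > 0]
    if (!length(base)) stop("no positive samples in pool")
    100 * sum(base > threshold_uV) / length(base)
  }
}

#' Brown-Forsythe comparison of signal power
#'
#' Tests equality of spread between the edge and center amplitude pools with
#' the Brown-Forsythe variant of Levene's test: a one-way F statistic on the
#' absolute deviations from each group's median, which is robust to
#' non-normal samples. The RMS of both pools is attached.
#'
#' @param edge,center Amplitude pools or numeric vectors (size >= 2 each).
#' @return Object of class `power_comparison`: `rms_edge_uV`,
#'   `rms_center_uV`, `brown_forsythe_F`, `df`, `p_value`, `n_edge`,
#'   `n_center`.
#' @export
brown_forsythe <- function(edge, center) {
  e <- as_samples(edge); c_ <- as_samples(center)
  if (length(e) < 2 || length(c_) < 2) stop("both pools need size >= 2")
  ze <- abs(e - stats::median(e)); zc <- abs(c_ - stats::median(c_))
  n1 <- length(ze); n2 <- length(zc); n <- n1 + n2
  m1 <- mean(ze); m2 <- mean(zc); m <- (n1 * m1 + n2 * m2) / n
  ss_between <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ss_within <- sum((ze - m1)^2) + sum((zc - m2)^2)
  if (ss_within == 0 && ss_between == 0)
    stop("zero within-group variance in both groups")
  F_ <- (ss_between / 1) / (ss_within / (n - 2))
  structure(list(rms_edge_uV = pool_rms(e), rms_center_uV = pool_rms(c_),
                 brown_forsythe_F = F_, df = c(1L, n - 2L),
                 p_value = stats::pf(F_, 1, n - 2, lower.tail = FALSE),
                 n_edge = n1, n_center = n2),
            class = "power_comparison")
}

#' @export
print.power_comparison <- function(x, ...) {
  cat(sprintf("<power_comparison> RMS edge %.2f uV vs center %.2f uV; Brown-Forsythe F(%d,%d) = %.3g, p = %.3g\n",
              x$rms_edge_uV, x$rms_center_uV, x$df[1], x$df[2],
              x$brown_forsythe_F, x$p_value))
  invisible(x)
}

#' Edge-to-center PDF ratio over the negative range
#'
#' Summarizes where in the negative amplitude range the edge group gains
#' probability mass relative to the center group: the per-bin probability
#' ratio from 0 down to the range limit, a single aggregated point formed by
#' the ratio of summed probabilities below `tail_cut_uV` (the large-spike
#' tail), and the mean of the per-bin ratio over the whole negative range.
#' Bins where both probabilities are zero are skipped; bins where only the
#' center probability is zero yield an infinite ratio, which is excluded from
#' the mean and counted.
#'
#' @param pdf_edge,pdf_center [amp_pdf()] results on identical bins.
#' @param tail_cut_uV Cut defining the large-spike tail (default -350 uV).
#' @return List with `ratio` (data frame `bin_center_uV`, `ratio`),
#'   `tail_sum_ratio`, `mean_ratio`, `n_infinite`.
#' @export
pdf_ratio_summary <- function(pdf_edge, pdf_center, tail_cut_uV = -350) {
  stopifnot(inherits(pdf_edge, "amplitude_pdf"),
            inherits(pdf_center, "amplitude_pdf"))
  if (!isTRUE(all.equal(pdf_edge$bin_edges_uV, pdf_center$bin_edges_uV)))
    stop("PDFs must share identical bins")
  neg <- pdf_edge$bin_centers_uV < 0
  ce <- pdf_edge$probability[neg]; cc <- pdf_center$probability[neg]
  centers <- pdf_edge$bin_centers_uV[neg]
  ratio <- ce / cc
  ratio[ce == 0 & cc == 0] <- NA_real_   # skipped bins
  n_inf <- sum(is.infinite(ratio))
  if (n_inf > 0)
    message(n_inf, " bin(s) with zero center probability excluded from the mean ratio")
  tail_bins <- centers < tail_cut_uV
  tail_ratio <- sum(ce[tail_bins]) / sum(cc[tail_bins])
  ord <- order(centers, decreasing = TRUE)   # 0 -> -limit
  list(ratio = data.frame(bin_center_uV = centers[ord], ratio = ratio[ord]),
       tail_sum_ratio = tail_ratio,
       mean_ratio = mean(ratio[is.finite(ratio)], na.rm = TRUE),
       n_infinite = n_inf)
}
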