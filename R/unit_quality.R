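# Post-sorting single-unit quality: refractory violations, peak-to-peak
# amplitude, well-isolation selection, isolation distance, unit yield, and
# the unit-amplitude threshold scan.

#' Fraction of spikes violating the refractory period
#'
#' The proportion of spikes whose preceding inter-spike interval is shorter
#' than the refractory period; each violating ISI counts one spike.
#'
#' @param spike_times_s Sorted spike times in seconds.
#' @param refractory_ms Refractory period (default 2 ms).
#' @return Proportion in `[0, 1]`; 0 (with a message) for fewer than 2
#'   spikes.
#' @export
refractory_fraction <- function(spike_times_s, refractory_ms = 2) {
  if (length(spike_times_s) < 2) {
    message("fewer than 2 spikes; refractory fraction set to 0")
    return(0)
  }
  if (is.unsorted(spike_times_s)) stop("spike times must be sorted")
  isi <- diff(spike_times_s)
  sum(isi < refractory_ms / 1000) / length(spike_times_s)
}

#' Peak-to-peak amplitude of a mean waveform
#'
#' Per channel, the amplitude difference between the trough (most negative
#' value, taken as 0 when the waveform never goes below baseline) and the
#' largest positive peak; the best channel is the one maximizing this
#' difference and its value is returned. A waveform with no positive
#' excursion uses 0 as the peak, and one with no negative excursion is
#' flagged atypical.
#'
#' @param mean_waveform `[channel x sample]` matrix in microvolts (a vector
#'   is treated as one channel).
#' @return List with `p2p_uV`, `best_channel`, `per_channel_uV`, `atypical`
#'   (TRUE when the best channel has no trough below baseline).
#' @export
p2p_amplitude <- function(mean_waveform) {
  w <- if (is.null(dim(mean_waveform))) matrix(mean_waveform, nrow = 1)
       else as.matrix(mean_waveform)
  if (!length(w)) stop("empty waveform")
  trough <- pmin(apply(w, 1, min), 0)
  peak <- pmax(apply(w, 1, max), 0)
  p2p <- peak - trough
  best <- which.max(p2p)
  list(p2p_uV = p2p[best], best_channel = best, per_channel_uV = p2p,
       atypical = trough[best] == 0 && p2p[best] > 0)
}

#' Compute quality metrics for a set of units
#'
#' @param units List of unit records; each a list with `unit_id`,
#'   `spike_times_s`, and `mean_waveform_uV` (`[channel x sample]`).
#' @param duration_s Recording duration used for firing rates.
#' @param refractory_ms Refractory period (default 2 ms).
#' @return Data frame with one row per unit: `unit_id`, `n_spikes`,
#'   `firing_rate_hz`, `refractory_fraction`, `p2p_uV`, `best_channel`.
#' @export
unit_quality <- function(units, duration_s, refractory_ms = 2) {
  rows <- lapply(units, function(u) {
    p <- p2p_amplitude(u$mean_waveform_uV)
    data.frame(unit_id = u$unit_id,
               n_spikes = length(u$spike_times_s),
               firing_rate_hz = length(u$spike_times_s) / duration_s,
               refractory_fraction = suppressMessages(
                 refractory_fraction(u$spike_times_s, refractory_ms)),
               p2p_uV = p$p2p_uV, best_channel = p$best_channel)
  })
  do.call(rbind, rows)
}

#' Select well-isolated units
#'
#' Applies the well-isolation criteria, all with strict inequalities: a
#' refractory-violation fraction below 0.02, a firing rate above 0.05 Hz
#' (or at least 100 spikes in the cluster), and a peak-to-peak amplitude
#' above 60 uV.
#'
#' @param quality Data frame from [unit_quality()].
#' @param max_refractory Violation-fraction criterion (default 0.02).
#' @param min_rate_hz Firing-rate criterion (default 0.05 Hz).
#' @param min_spikes Alternative spike-count criterion (default 100).
#' @param min_p2p_uV Amplitude criterion (default 60 uV).
#' @return The input data frame with a logical `well_isolated` column added.
#' @export
select_well_isolated <- function(quality, max_refractory = 0.02,
                                 min_rate_hz = 0.05, min_spikes = 100,
                                 min_p2p_uV = 60) {
  quality$well_isolated <-
    quality$refractory_fraction < max_refractory &
    (quality$firing_rate_hz > min_rate_hz | quality$n_spikes >= min_spikes) &
    quality$p2p_uV > min_p2p_uV
  quality
}

#' Isolation distance of a unit cluster
#'
#' The squared Mahalanobis distance — under the cluster's own mean and
#' covariance — of the n-th closest spike not belonging to the cluster,
#' where n is the cluster size. Larger values mean better separation.
#' Undefined (NA) when there are fewer other spikes than cluster spikes. A
#' singular cluster covariance is regularized by diagonal loading of
#' `1e-6 * trace / d` (reported with a message).
#'
#' @param cluster_features `[n x d]` feature matrix of the cluster's spikes.
#' @param other_features `[m x d]` feature matrix of all other spikes.
#' @return Nonnegative scalar, or `NA` when undefined.
#' @export
isolation_distance <- function(cluster_features, other_features) {
  X <- as.matrix(cluster_features); Y <- as.matrix(other_features)
  n <- nrow(X)
  if (nrow(Y) < n) return(NA_real_)
  if (n < ncol(X) + 2)
    stop("cluster too small for a stable covariance (need n >= d + 2)")
  mu <- colMeans(X)
  S <- stats::cov(X)
  d2 <- tryCatch(stats::mahalanobis(Y, mu, S), error = function(e) NULL)
  if (is.null(d2) || !all(is.finite(d2))) {
    message("singular cluster covariance; applying diagonal regularization")
    S <- S + diag(1e-6 * sum(diag(S)) / ncol(S), ncol(S))
    d2 <- stats::mahalanobis(Y, mu, S)
  }
  sort(d2)[n]
}

#' Reverse cumulative threshold scan on unit amplitudes
#'
#' Applies the binomial threshold-scan machinery of [cumulative_scan()] to
#' the peak-to-peak amplitudes of well-isolated units, in the positive
#' direction with thresholds starting at the unit-amplitude floor
#' (60 uV by default, the well-isolation amplitude criterion).
#'
#' @param edge_amps_uV,center_amps_uV Peak-to-peak amplitudes of the units
#'   recorded on edge and center sites.
#' @param start_uV First threshold (default 60 uV).
#' @param max_uV Last threshold (default 1000 uV).
#' @param step_uV Threshold spacing (default 10 uV).
#' @param alpha Family-wise level (default 0.05).
#' @return A `scan_result` (positive side; thresholds
#'   `start_uV, start_uV + step_uV, ..., max_uV`).
#' @export
unit_amplitude_scan <- function(edge_amps_uV, center_amps_uV, start_uV = 60,
                                max_uV = 1000, step_uV = 10, alpha = 0.05) {
  e <- as_samples(edge_amps_uV); c_ <- as_samples(center_amps_uV)
  if (!length(e) || !length(c_)) stop("both unit-amplitude sets must be nonempty")
  thresholds <- seq(start_uV, max_uV, by = step_uV)
  n_e <- length(e); n_c <- length(c_)
  p_e <- n_e / (n_e + n_c); p_c <- n_c / (n_e + n_c)
  k_edge <- vapply(thresholds, function(x) sum(e > x), 0L)
  k_center <- vapply(thresholds, function(x) sum(c_ > x), 0L)
  n_x <- k_edge + k_center
  p_edge_dir <- binom_sf(k_edge, n_x, p_e)
  p_center_dir <- binom_sf(k_center, n_x, p_c)
  p_edge_dir[n_x == 0] <- 1; p_center_dir[n_x == 0] <- 1
  alpha_corr <- alpha / (2 * length(thresholds))
  sig_edge <- p_edge_dir < alpha_corr
  sig_center <- p_center_dir < alpha_corr
  sel <- if (any(sig_edge)) min(thresholds[sig_edge]) else NA_real_
  structure(list(side = "positive", thresholds_uV = thresholds,
                 k_edge = k_edge, k_center = k_center,
                 p_edge_direction = p_edge_dir,
                 p_center_direction = p_center_dir,
                 p_e = p_e, p_c = p_c, n_e = n_e, n_c = n_c,
                 alpha_corrected = alpha_corr,
                 sig_edge = sig_edge, sig_center = sig_center,
                 threshold_edge_uV = sel,
                 pct_edge = if (is.na(sel)) NA_real_
                            else 100 * sum(e > sel) / n_e,
                 pct_center = if (is.na(sel)) NA_real_
                              else 100 * sum(c_ > sel) / n_c),
            class = "scan_result")
}

#' Unit yield per recording and group
#'
#' Counts well-isolated units per recording x group cell and the mean per
#' group. Units from different site groups of the same recording position are
#' counted independently (adjacent groups can detect the same neuron, so some
#' redundancy is expected and deliberate).
#'
#' @param unit_table Data frame with at least `recording`, `group`, and
#'   `well_isolated` columns.
#' @return List with `counts` (data frame `recording`, `group`, `n_units`)
#'   and `group_means` (data frame `group`, `mean_units`).
#' @export
unit_yield <- function(unit_table) {
  if (!nrow(unit_table)) {
    return(list(counts = data.frame(recording = character(),
                                    group = character(), n_units = integer()),
                group_means = data.frame(group = character(),
                                         mean_units = numeric())))
  }
  kept <- unit_table[unit_table$well_isolated, , drop = FALSE]
  cells <- unique(unit_table[c("recording", "group")])
  cells$n_units <- mapply(function(r, g)
    sum(kept$recording == r & kept$group == g), cells$recording, cells$group)
  rownames(cells) <- NULL
  means <- stats::aggregate(n_units ~ group, cells, mean)
  names(means)[2] <- "mean_units"
  list(counts = cells, group_means = means)
}

#' Cut spike waveforms from a recording
#'
#' Extracts fixed-length snippets around spike times: a window (default
#' 2 ms) centered on the trough sample of each spike. Spikes whose window
#' would cross the recording edge are dropped.
#'
#' @param mat `[time x channel]` matrix (wideband or filtered).
#' @param spike_times_s Spike times in seconds.
#' @param sampling_rate_hz Sampling rate.
#' @param window_ms Window length (default 2 ms).
#' @param channels Channels to keep (default all).
#' @return `[spike x channel x sample]` array (with attribute
#'   `spike_index`: which input spikes were kept).
#' @export
cut_spike_waveforms <- function(mat, spike_times_s, sampling_rate_hz,
                                window_ms = 2, channels = NULL) {
  mat <- as.matrix(mat)
  if (is.null(channels)) channels <- seq_len(ncol(mat))
  half <- as.integer(round(window_ms / 1000 * sampling_rate_hz / 2))
  centers <- as.integer(round(spike_times_s * sampling_rate_hz)) + 1L
  # re-center on the trough within +-half a window of the nominal time
  centers <- vapply(centers, function(k) {
    a <- max(1L, k - half); b <- min(nrow(mat), k + half)
    seg <- rowSums(mat[a:b, channels, drop = FALSE])
    a + which.min(seg) - 1L
  }, 0L)
  ok <- centers - half >= 1 & centers + half <= nrow(mat)
  centers <- centers[ok]
  out <- array(NA_real_, c(length(centers), length(channels), 2L * half + 1L))
  for (i in seq_along(centers)) {
    out[i, , ] <- t(mat[(centers[i] - half):(centers[i] + half), channels,
                        drop = FALSE])
  }
  attr(out, "spike_index") <- which(ok)
  out
}

#' Per-channel principal-component features for isolation distance
#'
#' Projects each spike's waveform, on a set of channels (typically the best
#' channel and its nearest neighbors), onto the first `n_pc` principal
#' components per channel, computed over all spikes supplied. The resulting
#' feature space (`length(channels) * n_pc` dimensions) is shared by the
#' cluster and its complement, as isolation distance requires.
#'
#' @param waveforms `[spike x channel x sample]` array (all spikes of the
#'   recording, cluster and non-cluster alike).
#' @param n_pc Principal components per channel (default 3).
#' @return `[spike x (channel * n_pc)]` feature matrix.
#' @export
waveform_features <- function(waveforms, n_pc = 3) {
  stopifnot(length(dim(waveforms)) == 3)
  n_ch <- dim(waveforms)[2]
  feats <- lapply(seq_len(n_ch), function(ch) {
    X <- waveforms[, ch, , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = dim(waveforms)[1])
    k <- min(n_pc, ncol(X), nrow(X) - 1)
    stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, seq_len(k), drop = FALSE]
  })
  do.call(cbind, feats)
}

#' Read a text-dialect sorted-units directory
#'
#' Reads sorting output saved as plain text: `spike_times.csv` (columns
#' `time_s`, `cluster`) and optionally `waveforms/cluster_<id>.csv` files,
#' each a `[channel x sample]` mean-waveform table in microvolts.
#'
#' @param dir Directory with the sorted output.
#' @param duration_s Recording duration (for firing rates); when `NULL`, the
#'   last spike time is used.
#' @return List of unit records (`unit_id`, `spike_times_s`,
#'   `mean_waveform_uV` or `NULL`), with attribute `duration_s`.
#' @export
read_sorting <- function(dir, duration_s = NULL) {
  st <- utils::read.csv(file.path(dir, "spike_times.csv"))
  stopifnot(all(c("time_s", "cluster") %in% names(st)))
  if (is.null(duration_s)) duration_s <- max(st$time_s)
  units <- lapply(sort(unique(st$cluster)), function(cl) {
    wf_path <- file.path(dir, "waveforms", sprintf("cluster_%s.csv", cl))
    wf <- if (file.exists(wf_path))
      as.matrix(utils::read.csv(wf_path, header = FALSE)) else NULL
    list(unit_id = cl, spike_times_s = sort(st$time_s[st$cluster == cl]),
         mean_waveform_uV = wf)
  })
  attr(units, "duration_s") <- duration_s
  units
}
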