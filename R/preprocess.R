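# Spike-band preprocessing: zero-phase Butterworth filtering, amplitude
# subsampling with range limiting, and rectification.

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each channel with a 3rd-order Butterworth band-pass (default
#' 500-5000 Hz, the single-unit band) applied forward and backward for zero
#' phase shift; the effective magnitude response is the squared one-pass
#' response. Edges are handled by odd-reflection padding of three times the
#' filter length, so the output has the same length as the input.
#'
#' @param recording `[time x channel]` matrix (or a vector) in microvolts.
#' @param sampling_rate_hz Sampling rate.
#' @param low_hz,high_hz Band edges (must lie below Nyquist).
#' @param order Butterworth prototype order (default 3).
#' @return An object of class `filtered_recording`: list with `matrix`,
#'   `band_hz`, `design`, `zero_phase = TRUE`, `sampling_rate_hz`.
#' @export
bandpass <- function(recording, sampling_rate_hz, low_hz = 500,
                     high_hz = 5000, order = 3) {
  mat <- as.matrix(recording)
  stopifnot(all(is.finite(mat)))
  nyq <- sampling_rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band must satisfy 0 < low < high < Nyquist")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  zi <- steady_state_zi(bf$b, bf$a)
  out <- apply(mat, 2, filtfilt_reflect, b = bf$b, a = bf$a, zi = zi)
  structure(list(matrix = out, band_hz = c(low_hz, high_hz),
                 design = sprintf("butterworth order %d band-pass", order),
                 zero_phase = TRUE, sampling_rate_hz = sampling_rate_hz),
            class = "filtered_recording")
}

#' Zero-phase low-pass filter
#'
#' Forward-backward Butterworth low-pass, used to smooth the summed
#' multiunit activity into its envelope.
#'
#' @inheritParams bandpass
#' @param cutoff_hz Cutoff frequency (below Nyquist).
#' @return Filtered vector or matrix of the same shape.
#' @export
lowpass <- function(recording, sampling_rate_hz, cutoff_hz, order = 3) {
  nyq <- sampling_rate_hz / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("cutoff must lie strictly between 0 and Nyquist")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  zi <- steady_state_zi(bf$b, bf$a)
  if (is.matrix(recording)) {
    apply(recording, 2, filtfilt_reflect, b = bf$b, a = bf$a, zi = zi)
  } else {
    filtfilt_reflect(recording, bf$b, bf$a, zi)
  }
}

# Steady-state initial conditions for a unit-amplitude step (direct-form II
# transposed): the state that keeps a constant input at its steady output.
# Same construction as scipy's lfilter_zi.
steady_state_zi <- function(b, a) {
  nz <- max(length(a), length(b)) - 1L
  bb <- c(b, rep(0, nz + 1 - length(b)))
  aa <- c(a, rep(0, nz + 1 - length(a)))
  companion <- rbind(-aa[-1] / aa[1],
                     cbind(diag(1, nz - 1), rep(0, nz - 1)))
  solve(diag(nz) - t(companion), bb[-1] - aa[-1] * bb[1])
}

# Forward-backward filtering with odd-reflection edge padding (pad length
# three times the coefficient length) and steady-state initialization of
# both passes, so start/end transients do not leak into the returned
# segment. The single-pass kernel is compiled (direct-form II transposed)
# because recordings run to tens of millions of samples.
filtfilt_reflect <- function(x, b, a, zi = NULL) {
  n <- length(x)
  pad <- min(3L * max(length(a), length(b)), n - 1L)
  if (pad < 1) stop("input too short to filter")
  if (is.null(zi)) zi <- steady_state_zi(b, a)
  pre <- 2 * x[1] - x[seq(pad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - pad)]
  ext <- c(pre, x, post)
  y <- iir_filtfilt_cpp(b, a, ext, zi)
  y[(pad + 1):(pad + n)]
}

#' Subsample a site group into an amplitude pool
#'
#' Takes every `step`-th sample (starting at the first sample) of each
#' channel of a filtered recording, drops samples whose magnitude exceeds
#' `limit_uV` (strictly; values exactly at the limit are retained) while
#' counting them, and pools the retained amplitudes across the group's
#' channels. The pool's `n_total` is the `N` entering the binomial threshold
#' tests.
#'
#' @param filtered A [bandpass()] result, or a plain `[time x channel]`
#'   matrix.
#' @param channels Column indices of the group's channels; default all.
#' @param step Subsampling stride (default every 50th sample).
#' @param limit_uV Magnitude limit of the examined range (default 1000 uV).
#' @param group_label Label stored with the pool.
#' @return An object of class `amplitude_pool`: list with `group_label`,
#'   `samples_uV`, `step`, `n_total`, `n_excluded_range`.
#' @export
subsample_pool <- function(filtered, channels = NULL, step = 50,
                           limit_uV = 1000, group_label = "") {
  mat <- if (inherits(filtered, "filtered_recording")) filtered$matrix
         else as.matrix(filtered)
  if (step < 1) stop("step must be at least 1")
  if (is.null(channels)) channels <- seq_len(ncol(mat))
  if (!length(channels)) stop("channel set is empty")
  idx <- seq(1L, nrow(mat), by = as.integer(step))
  samples <- as.vector(mat[idx, channels, drop = FALSE])
  out_of_range <- abs(samples) > limit_uV
  structure(list(group_label = group_label,
                 samples_uV = samples[!out_of_range],
                 step = as.integer(step),
                 n_total = sum(!out_of_range),
                 n_excluded_range = sum(out_of_range)),
            class = "amplitude_pool")
}

#' @export
print.amplitude_pool <- function(x, ...) {
  cat(sprintf("<amplitude_pool> '%s': %d samples (stride %d, %d out of range)\n",
              x$group_label, x$n_total, x$step, x$n_excluded_range))
  invisible(x)
}

#' Combine amplitude pools
#'
#' Pools the samples of several [subsample_pool()] results (e.g. the left and
#' right edge groups, or the same group across recordings) into one.
#'
#' @param ... `amplitude_pool` objects (or a single list of them).
#' @param group_label Label of the combined pool.
#' @return An `amplitude_pool`.
#' @export
combine_pools <- function(..., group_label = "") {
  pools <- list(...)
  if (length(pools) == 1 && !inherits(pools[[1]], "amplitude_pool"))
    pools <- pools[[1]]
  stopifnot(all(vapply(pools, inherits, TRUE, "amplitude_pool")))
  structure(list(group_label = group_label,
                 samples_uV = unlist(lapply(pools, `[[`, "samples_uV"),
                                     use.names = FALSE),
                 step = pools[[1]]$step,
                 n_total = sum(vapply(pools, `[[`, 0, "n_total")),
                 n_excluded_range = sum(vapply(pools, `[[`, 0,
                                               "n_excluded_range"))),
            class = "amplitude_pool")
}

#' Rectify a filtered recording
#'
#' Element-wise absolute value, extracting the multiunit activity (MUA) from
#' the band-passed signal.
#'
#' @param filtered A `filtered_recording` or numeric matrix/vector.
#' @return Matrix (or vector) of the same shape.
#' @export
rectify <- function(filtered) {
  mat <- if (inherits(filtered, "filtered_recording")) filtered$matrix
         else filtered
  abs(mat)
}
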