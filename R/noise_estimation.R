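# In vivo noise-floor estimation from the silent down-states of slow-wave
# activity: summed rectified MUA -> smoothed envelope -> threshold state
# detection -> RMS of short windows centered in long down-states.

#' Sample-wise sum of the rectified MUA across channels
#'
#' @param mua `[time x channel]` rectified (nonnegative) matrix, or a vector.
#' @return Per-sample sum vector.
#' @export
summed_mua <- function(mua) {
  if (is.null(dim(mua))) return(as.numeric(mua))
  rowSums(mua)
}

#' Smooth the summed MUA into its envelope
#'
#' Zero-phase Butterworth low-pass (default 50 Hz cutoff) of the summed MUA;
#' the result tracks the slow up/down alternation of population activity.
#'
#' @param summed Summed-MUA vector.
#' @param sampling_rate_hz Sampling rate.
#' @param cutoff_hz Low-pass cutoff (default 50 Hz).
#' @return Envelope vector of the same length.
#' @export
smooth_envelope <- function(summed, sampling_rate_hz, cutoff_hz = 50) {
  lowpass(as.numeric(summed), sampling_rate_hz, cutoff_hz)
}

#' Detect up and down states from the MUA envelope
#'
#' Thresholds the envelope at the midpoint of its 10th and 90th percentiles
#' (a rule that adapts to the bimodal envelope of slow-wave activity) and
#' keeps only state runs long enough to be physiological: sub-threshold runs
#' of at least `min_down_s` become down states, supra-threshold runs of at
#' least `min_up_s` become up states, and shorter runs are merged into the
#' surrounding state.
#'
#' @param envelope Smoothed summed-MUA vector.
#' @param sampling_rate_hz Sampling rate.
#' @param min_down_s Minimum down-state duration (default 0.2 s).
#' @param min_up_s Minimum up-state duration (default 0.1 s).
#' @return Object of class `state_segmentation`: list with `intervals`
#'   (data frame `start_s`, `end_s`, `label`), `threshold_value`,
#'   `sampling_rate_hz`.
#' @export
detect_states <- function(envelope, sampling_rate_hz, min_down_s = 0.2,
                          min_up_s = 0.1) {
  fs <- sampling_rate_hz
  n <- length(envelope)
  if (n < max(min_down_s, min_up_s) * fs)
    stop("envelope shorter than the minimum state duration")
  q <- stats::quantile(envelope, c(0.1, 0.9), names = FALSE)
  if (diff(q) <= 1e-9 * max(abs(q), 1e-300) || diff(q) == 0)
    stop("envelope has no dynamic range; segmentation invalid for noise estimation")
  thr <- mean(q)
  up <- envelope > thr
  min_len <- c(down = as.integer(round(min_down_s * fs)),
               up = as.integer(round(min_up_s * fs)))
  # iteratively absorb the shortest sub-minimum run into its neighbors
  repeat {
    r <- rle(up)
    short <- which(r$lengths < ifelse(r$values, min_len["up"],
                                      min_len["down"]))
    if (!length(short) || length(r$lengths) == 1) break
    i <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    up[starts[i]:ends[i]] <- !r$values[i]
  }
  r <- rle(up)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  intervals <- data.frame(start_s = (starts - 1) / fs, end_s = ends / fs,
                          label = ifelse(r$values, "up", "down"))
  structure(list(intervals = intervals, threshold_value = thr,
                 sampling_rate_hz = fs),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  tab <- table(x$intervals$label)
  cat(sprintf("<state_segmentation> %s; threshold %.3g\n",
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              x$threshold_value))
  invisible(x)
}

#' Estimate the noise floor from down-state windows
#'
#' For every down state of at least `min_down_s`, a `window_s`-long segment
#' centered in the state is cut from the rectified MUA. Per channel, the RMS
#' of each window is computed and averaged across windows; the scalar
#' estimate is the mean over channels. (RMS is invariant to rectification,
#' so raw band-passed segments give the identical value.) Comparisons
#' against in vitro measurements show this in vivo estimator reads high by
#' several tens of percent; it is intended for comparisons between site
#' groups, not as an absolute noise figure, and no correction is applied.
#'
#' @param mua `[time x channel]` rectified MUA matrix.
#' @param segmentation A [detect_states()] result.
#' @param window_s RMS window length (default 0.05 s).
#' @param min_down_s Minimum qualifying down-state duration (default 0.2 s).
#' @return Object of class `noise_estimate`: `per_channel_rms_uV`,
#'   `mean_rms_uV`, `n_windows`, `window_s`, `min_down_s`. When no down
#'   state qualifies, `n_windows` is 0 and the estimates are `NA`.
#' @export
estimate_noise <- function(mua, segmentation, window_s = 0.05,
                           min_down_s = 0.2) {
  stopifnot(inherits(segmentation, "state_segmentation"))
  mua <- as.matrix(mua)
  fs <- segmentation$sampling_rate_hz
  iv <- segmentation$intervals
  down <- iv[iv$label == "down" & (iv$end_s - iv$start_s) >= min_down_s, ,
             drop = FALSE]
  win <- as.integer(round(window_s * fs))
  rms_by_window <- list()
  for (i in seq_len(nrow(down))) {
    mid <- (down$start_s[i] + down$end_s[i]) / 2
    a <- as.integer(round(mid * fs - win / 2)) + 1L
    b <- a + win - 1L
    if (a < 1 || b > nrow(mua)) next
    seg <- mua[a:b, , drop = FALSE]
    rms_by_window[[length(rms_by_window) + 1]] <- sqrt(colMeans(seg^2))
  }
  n_win <- length(rms_by_window)
  if (n_win == 0) {
    per_ch <- rep(NA_real_, ncol(mua)); mean_rms <- NA_real_
  } else {
    per_ch <- colMeans(do.call(rbind, rms_by_window))
    mean_rms <- mean(per_ch)
  }
  structure(list(per_channel_rms_uV = per_ch, mean_rms_uV = mean_rms,
                 n_windows = n_win, window_s = window_s,
                 min_down_s = min_down_s),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  if (x$n_windows == 0) {
    cat("<noise_estimate> no qualifying down-state window; no estimate\n")
  } else {
    cat(sprintf("<noise_estimate> %.3g uV RMS (mean over %d channels, %d windows)\n",
                x$mean_rms_uV, length(x$per_channel_rms_uV), x$n_windows))
  }
  invisible(x)
}
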