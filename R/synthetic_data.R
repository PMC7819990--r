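# Ground-truth synthetic extracellular recordings.
#
# The generator emulates cortical activity under anesthesia-induced slow-wave
# alternation: up states with Poisson spiking (2 ms refractory), silent down
# states, spike amplitudes decaying exponentially with neuron-site distance,
# a Gaussian noise floor, and 16-bit quantization. A per-site multiplicative
# gain on edge-group sites provides a controllable edge-vs-center effect size
# (edge_gain = 1 is the null hypothesis).

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-recording generator. Defaults
#' follow the recording conditions the pipeline targets: 20 kHz sampling,
#' 16-bit quantization (0.195 uV/bit, or 2.34 uV/bit for Neuropixels
#' layouts), slow-wave alternation with mean up/down durations of 0.5/0.4 s,
#' and a 5 uV RMS Gaussian noise floor.
#'
#' @param layout A [build_layout()] probe layout.
#' @param duration_s Recording length in seconds.
#' @param sampling_rate_hz Samples per second per channel.
#' @param neurons Data frame of neuron specifications (see
#'   [default_neurons()]); columns `neuron_id`, `x_um`, `y_um`, `z_um`,
#'   `peak_amplitude_uV`, `rate_up_hz`, `rate_down_hz`.
#' @param decay_lambda_um Exponential decay constant of spike amplitude with
#'   neuron-site distance (default 28 um).
#' @param noise_rms_uV Per-channel white Gaussian noise RMS.
#' @param up_mean_s,down_mean_s Mean durations of up and down states.
#' @param edge_gain Multiplicative amplitude factor applied on edge-group
#'   sites; 1 means no edge/center asymmetry.
#' @param uv_per_bit Quantization step; `NULL` selects 2.34 for Neuropixels
#'   layouts and 0.195 otherwise.
#' @param seed RNG seed making the simulation reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(layout, duration_s = 60, sampling_rate_hz = 20000,
                       neurons = NULL, decay_lambda_um = 28,
                       noise_rms_uV = 5, up_mean_s = 0.5, down_mean_s = 0.4,
                       edge_gain = 1, uv_per_bit = NULL, seed = 1L) {
  stopifnot(inherits(layout, "probe_layout"), duration_s > 0,
            noise_rms_uV >= 0, edge_gain > 0)
  if (is.null(uv_per_bit))
    uv_per_bit <- if (grepl("^neuropixels", layout$probe_name)) 2.34 else 0.195
  if (is.null(neurons)) neurons <- default_neurons(layout, seed = seed)
  stopifnot(all(neurons$peak_amplitude_uV > 0),
            all(neurons$rate_down_hz <= neurons$rate_up_hz))
  structure(list(layout = layout, duration_s = duration_s,
                 sampling_rate_hz = sampling_rate_hz, neurons = neurons,
                 decay_lambda_um = decay_lambda_um,
                 noise_rms_uV = noise_rms_uV, up_mean_s = up_mean_s,
                 down_mean_s = down_mean_s, edge_gain = edge_gain,
                 uv_per_bit = uv_per_bit, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default neuron population for a layout
#'
#' The default population is position-balanced: a set of base neurons is
#' sampled relative to a reference column (lateral offset within +-25 um of
#' the column line, 8-40 um off the shank plane, longitudinal positions
#' spanning the site extent) and each base neuron is replicated at the same
#' relative position next to every column of the layout. Every column
#' therefore faces an identical multiset of neuron distances and amplitudes,
#' so at `edge_gain = 1` the edge and center groups differ only through
#' independent spike timing and noise — the null hypothesis of the
#' edge-vs-center comparison is true by construction, which is what a
#' gain-recovery experiment needs. (An unbalanced population, where site
#' groups sample genuinely different cells as in any single real
#' penetration, is available with `balanced = FALSE`.)
#'
#' Peak amplitudes are log-normal around ~220 uV (trough depth at zero
#' distance, consistent with the peak-to-peak amplitudes of well-isolated
#' cortical units), up-state rates 5-25 Hz (vigorous population firing, as
#' in deep cortical layers during slow-wave up states), down-state rate 0
#' (strict silence, so the down-state noise estimate has an unambiguous
#' ground truth).
#'
#' @param layout A `probe_layout`.
#' @param n Number of base neurons per column; default the per-column site
#'   count, capped so the total stays within ~120 neurons.
#' @param seed RNG seed.
#' @param balanced Replicate base neurons across all columns (default TRUE);
#'   otherwise place `n * n_columns` neurons independently around the shank.
#' @return Data frame usable as the `neurons` field of [sim_config()].
#' @export
default_neurons <- function(layout, n = NULL, seed = 1L, balanced = TRUE) {
  s <- layout$sites
  n_cols <- length(layout$columns)
  if (is.null(n))
    n <- min(as.integer(max(lengths(layout$columns))),
             max(1L, 120L %/% n_cols))
  set.seed(seed)
  total <- n * n_cols
  n_rows <- min(lengths(layout$columns))  # rows present in every column
  base <- data.frame(
    dx_um = stats::runif(n, -25, 25),
    anchor_row = sample.int(n_rows, n, replace = TRUE),
    dy_um = stats::runif(n, -25, 25),
    z_um = stats::runif(n, 8, 40),
    peak_amplitude_uV = stats::rlnorm(n, log(220), 0.5),
    rate_up_hz = stats::runif(n, 5, 25)
  )
  col_x <- vapply(layout$columns, function(ids)
    mean(s$x_um[match(ids, s$site_id)]), 0)
  if (balanced) {
    # anchor each replica to the same row index of its column so the
    # neuron-to-site geometry is identical across columns
    out <- base[rep(seq_len(n), n_cols), ]
    col_of <- rep(seq_len(n_cols), each = n)
    out$x_um <- col_x[col_of] + out$dx_um
    out$y_um <- mapply(function(cc, r, dy) {
      ys <- sort(s$y_um[match(layout$columns[[cc]], s$site_id)])
      ys[r] + dy
    }, col_of, out$anchor_row, out$dy_um)
  } else {
    out <- data.frame(
      dx_um = NA_real_,
      y_um = stats::runif(total, min(s$y_um) - 20, max(s$y_um) + 20),
      z_um = stats::runif(total, 8, 40),
      peak_amplitude_uV = stats::rlnorm(total, log(220), 0.5),
      rate_up_hz = stats::runif(total, 5, 25))
    out$x_um <- stats::runif(total, -20, layout$shank_width_um + 20)
  }
  data.frame(neuron_id = seq_len(nrow(out)), x_um = out$x_um,
             y_um = out$y_um, z_um = out$z_um,
             peak_amplitude_uV = out$peak_amplitude_uV,
             rate_up_hz = out$rate_up_hz, rate_down_hz = 0,
             row.names = NULL)
}

#' Generate alternating up/down state intervals
#'
#' Durations are drawn from gamma distributions with shape 4 and the given
#' means (an ad hoc but unimodal, strictly positive renewal model); states
#' alternate, the type of the first interval is random, and the sequence is
#' truncated to cover exactly `[0, duration_s]`.
#'
#' @param duration_s Total duration covered.
#' @param up_mean_s,down_mean_s Mean state durations (seconds, > 0).
#' @param seed RNG seed (`NULL` = use current RNG state).
#' @return Data frame with `start_s`, `end_s`, `state` (`"up"`/`"down"`);
#'   intervals tile `[0, duration_s]` without overlap.
#' @export
generate_states <- function(duration_s, up_mean_s, down_mean_s, seed = NULL) {
  stopifnot(duration_s > 0, up_mean_s > 0, down_mean_s > 0)
  if (!is.null(seed)) set.seed(seed)
  first_up <- stats::runif(1) < 0.5
  starts <- numeric(); ends <- numeric(); states <- character()
  t <- 0; up <- first_up
  while (t < duration_s) {
    m <- if (up) up_mean_s else down_mean_s
    len <- stats::rgamma(1, shape = 4, scale = m / 4)
    starts <- c(starts, t); ends <- c(ends, min(t + len, duration_s))
    states <- c(states, if (up) "up" else "down")
    t <- t + len; up <- !up
  }
  data.frame(start_s = starts, end_s = ends, state = states)
}

# Biphasic spike template on a 1.2 ms support: a negative trough followed by
# a smaller positive peak, normalized so the trough depth is exactly 1.
spike_template <- function(sampling_rate_hz) {
  t <- seq(0, 1.2e-3, by = 1 / sampling_rate_hz)
  w <- -exp(-((t - 0.35e-3) / 0.12e-3)^2) +
    0.35 * exp(-((t - 0.75e-3) / 0.25e-3)^2)
  w / abs(min(w))
}

# State-modulated Poisson spike train with an enforced 2 ms refractory
# period: candidate spikes are drawn per interval at that state's rate, then
# any spike closer than 2 ms to the last retained spike is discarded.
draw_spike_train <- function(states, rate_up, rate_down, refractory_s = 2e-3) {
  times <- unlist(lapply(seq_len(nrow(states)), function(i) {
    rate <- if (states$state[i] == "up") rate_up else rate_down
    len <- states$end_s[i] - states$start_s[i]
    if (rate <= 0 || len <= 0) return(numeric())
    n <- stats::rpois(1, rate * len)
    states$start_s[i] + sort(stats::runif(n, 0, len))
  }), use.names = FALSE)
  if (!length(times)) return(numeric())
  keep <- logical(length(times)); last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_s) { keep[i] <- TRUE; last <- times[i] }
  }
  times[keep]
}

#' Generate a synthetic multichannel recording
#'
#' Produces a `[time x channel]` microvolt matrix together with its ground
#' truth. The signal is the sum over neurons and spikes of a biphasic
#' template scaled per site by `peak_amplitude_uV * exp(-d / decay_lambda_um)`
#' (d = Euclidean neuron-site distance) and by `edge_gain` on edge-group
#' sites, plus white Gaussian noise, quantized to `uv_per_bit` and
#' de-quantized (emulating the 16-bit front end).
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (`[time x channel]`, microvolts, channels in
#'   site-id order) and `ground_truth`: `spike_times` (list per neuron),
#'   `amplitudes` (`[neuron x site]` trough depth in uV, gain included),
#'   `states` (interval data frame), `noise_rms_uV`, `edge_sites`,
#'   `n_clipped` (samples clipped at the int16 limit).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lay <- config$layout; s <- lay$sites; nrn <- config$neurons
  inside <- nrn$x_um >= 0 & nrn$x_um <= lay$shank_width_um &
    nrn$z_um > -lay$shank_thickness_um & nrn$z_um < 0
  if (any(inside))
    stop("neuron(s) placed inside the shank volume: ",
         paste(nrn$neuron_id[inside], collapse = ", "))
  set.seed(config$seed)
  fs <- config$sampling_rate_hz
  n_samp <- round(config$duration_s * fs)
  n_ch <- nrow(s)

  states <- generate_states(config$duration_s, config$up_mean_s,
                            config$down_mean_s, seed = NULL)
  grouping <- tryCatch(classify_edge_center(lay), error = function(e) NULL)
  if (is.null(grouping) && config$edge_gain != 1)
    stop("edge_gain != 1 requires a layout with a valid edge/center classification")
  edge_sites <- if (is.null(grouping)) integer() else
    unlist(grouping$groups[grep("^edge", names(grouping$groups))],
           use.names = FALSE)
  gain <- ifelse(s$site_id %in% edge_sites, config$edge_gain, 1)

  # [neuron x site] trough depths
  d <- sqrt(outer(nrn$x_um, s$x_um, "-")^2 +
            outer(nrn$y_um, s$y_um, "-")^2 +
            matrix(nrn$z_um^2, nrow(nrn), n_ch))
  amp <- nrn$peak_amplitude_uV * exp(-d / config$decay_lambda_um)
  amp <- sweep(amp, 2, gain, "*")

  tpl <- spike_template(fs); L <- length(tpl)
  mat <- if (config$noise_rms_uV > 0) {
    matrix(stats::rnorm(n_samp * n_ch, sd = config$noise_rms_uV), n_samp, n_ch)
  } else matrix(0, n_samp, n_ch)

  spike_times <- vector("list", nrow(nrn))
  for (i in seq_len(nrow(nrn))) {
    st <- draw_spike_train(states, nrn$rate_up_hz[i], nrn$rate_down_hz[i])
    spike_times[[i]] <- st
    if (!length(st)) next
    idx0 <- round(st * fs) + 1L
    sites_hit <- which(amp[i, ] > 0.05)  # skip negligible contributions
    block <- tpl %o% amp[i, sites_hit]
    for (k in idx0) {
      if (k + L - 1L <= n_samp) {
        mat[k:(k + L - 1L), sites_hit] <- mat[k:(k + L - 1L), sites_hit] + block
      } else {
        span <- k:n_samp
        mat[span, sites_hit] <- mat[span, sites_hit] +
          block[seq_along(span), , drop = FALSE]
      }
    }
  }
  names(spike_times) <- nrn$neuron_id

  q <- round(mat / config$uv_per_bit)
  rng <- range(q)
  if (rng[1] < -32768 || rng[2] > 32767) {
    n_clipped <- sum(q > 32767) + sum(q < -32768)
    q[q > 32767] <- 32767; q[q < -32768] <- -32768
  } else n_clipped <- 0L
  mat <- q * config$uv_per_bit

  list(matrix = mat,
       ground_truth = list(spike_times = spike_times, amplitudes = amp,
                           states = states,
                           noise_rms_uV = config$noise_rms_uV,
                           edge_sites = sort(edge_sites),
                           n_clipped = n_clipped))
}

#' Write a recording to disk
#'
#' Writes the flat binary dialect consumed by [read_recording()]: an int16
#' little-endian time-major binary (`recording.bin`), a JSON sidecar
#' (`recording.meta.json`) with the sampling rate, quantization step and
#' channel map, and — when ground truth is supplied — CSV tables of spike
#' times, per-site amplitudes and state intervals.
#'
#' @param mat `[time x channel]` microvolt matrix (finite values).
#' @param config The [sim_config()] the matrix came from (supplies the
#'   sampling rate, quantization and layout).
#' @param dir Output directory (created if missing).
#' @param ground_truth Optional ground-truth list from [generate_recording()].
#' @return Invisibly, the number of samples clipped at the int16 limit
#'   (clipping is reported with a warning).
#' @export
write_recording <- function(mat, config, dir, ground_truth = NULL) {
  stopifnot(all(is.finite(mat)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  q <- round(mat / config$uv_per_bit)
  n_clip <- sum(q > 32767 | q < -32768)
  if (n_clip > 0)
    warning(sprintf("%d sample(s) clipped at the int16 limit", n_clip))
  q[q > 32767] <- 32767; q[q < -32768] <- -32768
  con <- file(file.path(dir, "recording.bin"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(q)), con, size = 2L, endian = "little")
  meta <- list(sampling_rate_hz = config$sampling_rate_hz,
               uv_per_bit = config$uv_per_bit,
               n_channels = ncol(mat), n_samples = nrow(mat),
               dtype = "int16", byte_order = "little", time_major = TRUE,
               probe_name = config$layout$probe_name,
               channel_map = sort(config$layout$sites$site_id))
  jsonlite::write_json(meta, file.path(dir, "recording.meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(ground_truth)) {
    gt <- ground_truth
    spikes <- data.frame(
      neuron_id = rep(as.integer(names(gt$spike_times)),
                      lengths(gt$spike_times)),
      time_s = unlist(gt$spike_times, use.names = FALSE))
    utils::write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
    amps <- data.frame(
      neuron_id = rep(seq_len(nrow(gt$amplitudes)), ncol(gt$amplitudes)),
      site_id = rep(sort(config$layout$sites$site_id),
                    each = nrow(gt$amplitudes)),
      amplitude_uV = as.vector(gt$amplitudes))
    utils::write.csv(amps, file.path(dir, "amplitudes.csv"), row.names = FALSE)
    utils::write.csv(gt$states, file.path(dir, "states.csv"),
                     row.names = FALSE)
  }
  invisible(n_clip)
}

#' Read a flat binary recording
#'
#' Reads the int16 binary + sidecar dialect written by [write_recording()].
#' The sidecar may be the package's JSON (`recording.meta.json`) or a
#' SpikeGLX-style `key=value` `.meta` file, from which `imSampRate` /
#' `niSampRate` / `sRateHz` (sampling rate) and `nSavedChans` (channel count)
#' are understood; the microvolt scale then comes from `uV_per_bit` if
#' present, else defaults to 2.34.
#'
#' @param dir Directory containing `recording.bin` and its sidecar, or the
#'   path of the `.bin` file itself.
#' @return List with `matrix` (`[time x channel]`, microvolts) and `meta`.
#' @export
read_recording <- function(dir) {
  if (dir.exists(dir)) {
    bin <- file.path(dir, "recording.bin")
    meta_json <- file.path(dir, "recording.meta.json")
    meta_glx <- list.files(dir, pattern = "\\.meta$", full.names = TRUE)
  } else {
    bin <- dir
    meta_json <- sub("\\.bin$", ".meta.json", bin)
    meta_glx <- sub("\\.bin$", ".meta", bin)
    meta_glx <- meta_glx[file.exists(meta_glx)]
  }
  if (file.exists(meta_json)) {
    meta <- jsonlite::read_json(meta_json, simplifyVector = TRUE)
  } else if (length(meta_glx)) {
    kv <- read_spikeglx_meta(meta_glx[1])
    meta <- list(
      sampling_rate_hz = as.numeric(
        kv[["imSampRate"]] %||% kv[["niSampRate"]] %||% kv[["sRateHz"]] %||%
          kv[["sampling_rate_hz"]]),
      n_channels = as.integer(kv[["nSavedChans"]] %||% kv[["n_channels"]]),
      uv_per_bit = as.numeric(kv[["uV_per_bit"]] %||% kv[["uv_per_bit"]] %||%
                                2.34))
    meta$channel_map <- seq_len(meta$n_channels)
  } else stop("no sidecar metadata found next to ", bin)
  n_int <- file.size(bin) / 2
  con <- file(bin, "rb"); on.exit(close(con))
  raw <- readBin(con, "integer", n = n_int, size = 2L, signed = TRUE,
                 endian = "little")
  mat <- matrix(raw, ncol = meta$n_channels, byrow = TRUE)
  mat <- mat * meta$uv_per_bit
  list(matrix = mat, meta = meta)
}

read_spikeglx_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) trimws(paste(p[-1], collapse = "="))),
                  trimws(vapply(kv, `[[`, "", 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
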