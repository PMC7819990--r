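# Nonparametric group statistics with rank-based effect sizes, and the
# end-to-end pipeline: split -> filter -> pools -> scans / power test ->
# noise estimate -> unit metrics -> summary report.

#' Mann-Whitney U test with effect size
#'
#' Two-sided comparison of two groups. For small samples without ties
#' (both n <= `exact_max`) the exact U distribution is used; otherwise the
#' tie-corrected normal approximation (no continuity correction). The
#' z-score is positive when the first group is stochastically larger, and
#' the effect size is `r = Z / sqrt(N)` with `N = n_a + n_b`.
#'
#' @param a,b Numeric sample vectors.
#' @param exact_max Largest per-group size for the exact test (default 20).
#' @return Object of class `group_comparison`: `test`, `statistic` (U of the
#'   first group), `z_score`, `p_value`, `n_total`, `effect_size_r`,
#'   `groups`.
#' @export
mann_whitney <- function(a, b, exact_max = 20) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  mu <- n_a * n_b / 2
  sigma <- sqrt(n_a * n_b / 12 * (n + 1 - tie_term))
  z <- if (sigma > 0) (U - mu) / sigma else 0
  if (n_a <= exact_max && n_b <= exact_max && !any(ties > 1)) {
    p <- if (U > mu) {
      2 * stats::pwilcox(U - 1, n_a, n_b, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, n_a, n_b)
    }
    p <- min(1, p)
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(test = "mann_whitney", statistic = U, z_score = z,
                 p_value = p, n_total = n, effect_size_r = z / sqrt(n),
                 groups = c("a", "b")),
            class = "group_comparison")
}

#' Kruskal-Wallis test
#'
#' Rank-based comparison of three or more groups (tie-corrected H statistic,
#' chi-square p-value). Two groups should be compared with [mann_whitney()]
#' instead.
#'
#' @param groups List of numeric sample vectors (>= 3 groups).
#' @return A `group_comparison` with the H statistic; the z-score and effect
#'   size are `NA` (they are defined for the pairwise tests).
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) == 2)
    stop("two groups supplied; use mann_whitney() for two-group comparisons")
  if (length(groups) < 3)
    stop("kruskal_wallis needs at least 3 nonempty groups")
  kt <- stats::kruskal.test(groups)
  structure(list(test = "kruskal_wallis",
                 statistic = unname(kt$statistic), z_score = NA_real_,
                 p_value = kt$p.value, n_total = sum(lengths(groups)),
                 effect_size_r = NA_real_,
                 groups = names(groups) %||% as.character(seq_along(groups))),
            class = "group_comparison")
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' All pairwise comparisons after a Kruskal-Wallis test: pooled-rank z
#' statistics with tie correction, two-sided p-values multiplied by the
#' number of pairs (capped at 1), and effect sizes `r = z / sqrt(n_i + n_j)`.
#' A warning (not an error) is raised when the omnibus Kruskal-Wallis test
#' is not itself significant.
#'
#' @param groups Named list of numeric sample vectors.
#' @param alpha Level used only for the omnibus warning (default 0.05).
#' @return List of `group_comparison` objects, one per pair.
#' @export
dunn_posthoc <- function(groups, alpha = 0.05) {
  groups <- groups[lengths(groups) > 0]
  k <- length(groups)
  if (k < 2) stop("need at least 2 nonempty groups")
  if (is.null(names(groups))) names(groups) <- as.character(seq_len(k))
  if (k >= 3) {
    kw <- kruskal_wallis(groups)
    if (kw$p_value >= alpha)
      warning(sprintf("omnibus Kruskal-Wallis not significant (p = %.3g); post-hoc results are exploratory",
                      kw$p_value))
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  n_pairs <- length(pairs)
  lapply(pairs, function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    pv <- min(1, n_pairs * 2 * stats::pnorm(-abs(z)))
    structure(list(test = "dunn", statistic = z, z_score = z, p_value = pv,
                   n_total = ns[[i]] + ns[[j]],
                   effect_size_r = z / sqrt(ns[[i]] + ns[[j]]),
                   groups = c(i, j)),
              class = "group_comparison")
  })
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s): statistic = %.4g, p = %.3g",
              x$test, paste(x$groups, collapse = " vs "), x$statistic,
              x$p_value))
  if (is.finite(x$effect_size_r))
    cat(sprintf(", r = %.3f (N = %d)", x$effect_size_r, x$n_total))
  cat("\n")
  invisible(x)
}

#' Run the signal-quality pipeline end to end
#'
#' Executes the full comparison on one recording: edge/center channel
#' splitting, spike-band filtering, amplitude pooling, the binomial
#' threshold scans on both sides, RMS and Brown-Forsythe power comparison,
#' the down-state noise estimate per group, and (when ground truth is
#' available) single-unit metrics with yield and well-isolation selection.
#' Deterministic given the simulation seed.
#'
#' @param input A [sim_config()] (the recording is generated), a directory
#'   readable by [read_recording()], or a list with elements `matrix` and
#'   `sampling_rate_hz` (plus optional `ground_truth`).
#' @param layout Probe layout; defaults to the simulation's layout or the
#'   layout named in the recording metadata.
#' @param bad_sites,exclude_groups,center_columns Passed to
#'   [classify_edge_center()].
#' @param equalize Trim groups to equal channel counts (default TRUE).
#' @param pool_sides Pool left and right edge groups before edge-vs-center
#'   comparisons (default TRUE).
#' @param low_hz,high_hz,filter_order Spike band (defaults 500-5000 Hz,
#'   order 3).
#' @param step,limit_uV Amplitude subsampling stride and range limit.
#' @param n_steps,alpha Threshold-scan geometry and family-wise level.
#' @param compute_units Compute unit metrics from ground-truth spike labels
#'   (default: TRUE when ground truth is present).
#' @param min_detect_uV Ground-truth units are attributed to a group when
#'   their largest trough on the group's channels exceeds this (default
#'   30 uV, roughly the smallest spike a sorter separates from the noise
#'   floor).
#' @param out_dir When non-NULL, the report (JSON) and per-threshold scan
#'   tables (CSV) are written there.
#' @return A `summary_report` list: `groups` (channel counts), `rms`,
#'   `power_comparison`, `scan_negative`, `scan_positive`, `noise`,
#'   `units` (or NULL), and `provenance`.
#' @export
run_pipeline <- function(input, layout = NULL, bad_sites = integer(),
                         exclude_groups = character(), center_columns = NULL,
                         equalize = TRUE, pool_sides = TRUE,
                         low_hz = 500, high_hz = 5000, filter_order = 3,
                         step = 50, limit_uV = 1000,
                         n_steps = 100, alpha = 0.05,
                         compute_units = NULL, min_detect_uV = 30,
                         out_dir = NULL) {
  gt <- NULL; seed <- NA_integer_
  if (inherits(input, "sim_config")) {
    layout <- input$layout; seed <- input$seed
    sim <- generate_recording(input)
    mat <- sim$matrix; fs <- input$sampling_rate_hz; gt <- sim$ground_truth
  } else if (is.character(input)) {
    rec <- read_recording(input)
    mat <- rec$matrix; fs <- rec$meta$sampling_rate_hz
    if (is.null(layout)) layout <- build_layout(rec$meta$probe_name)
  } else {
    mat <- input$matrix; fs <- input$sampling_rate_hz
    gt <- input$ground_truth
    if (is.null(layout)) stop("layout required for matrix input")
  }
  if (is.null(compute_units)) compute_units <- !is.null(gt)

  grouping <- classify_edge_center(layout, bad_sites = bad_sites,
                                   exclude_groups = exclude_groups,
                                   center_columns = center_columns)
  split <- split_recording(mat, grouping, layout, equalize = equalize)
  filtered <- lapply(split, bandpass, sampling_rate_hz = fs,
                     low_hz = low_hz, high_hz = high_hz,
                     order = filter_order)
  pools <- lapply(names(filtered), function(g)
    subsample_pool(filtered[[g]], step = step, limit_uV = limit_uV,
                   group_label = g))
  names(pools) <- names(filtered)

  if (pool_sides) {
    edge_labels <- grep("^edge", names(pools), value = TRUE)
    edge_pool <- combine_pools(pools[edge_labels], group_label = "edge")
  } else {
    edge_labels <- grep("^edge", names(pools), value = TRUE)[1]
    edge_pool <- pools[[edge_labels]]
  }
  center_pool <- pools$center

  scan_neg <- cumulative_scan(edge_pool, center_pool, "negative",
                              n_steps = n_steps, alpha = alpha,
                              limit_uV = limit_uV)
  scan_pos <- cumulative_scan(edge_pool, center_pool, "positive",
                              n_steps = n_steps, alpha = alpha,
                              limit_uV = limit_uV)
  power <- brown_forsythe(edge_pool, center_pool)

  # one global segmentation from all grouped channels, per-group estimates
  all_filt <- do.call(cbind, lapply(filtered, `[[`, "matrix"))
  env <- smooth_envelope(summed_mua(rectify(all_filt)), fs)
  noise <- tryCatch({
    seg <- detect_states(env, fs)
    ests <- lapply(filtered, function(f) estimate_noise(rectify(f), seg))
    list(segmentation_threshold = seg$threshold_value,
         n_down_states = sum(seg$intervals$label == "down"),
         per_group = lapply(ests, function(e)
           list(mean_rms_uV = e$mean_rms_uV, n_windows = e$n_windows)))
  }, error = function(e) list(error = conditionMessage(e)))

  units <- NULL
  if (compute_units && !is.null(gt)) {
    units <- ground_truth_unit_metrics(filtered, grouping, layout, gt, fs,
                                       duration_s = nrow(mat) / fs,
                                       equalize = equalize,
                                       min_detect_uV = min_detect_uV)
  }

  report <- structure(list(
    groups = lapply(split, ncol),
    rms = c(list(edge = power$rms_edge_uV, center = power$rms_center_uV),
            lapply(pools, pool_rms)),
    power_comparison = list(F = power$brown_forsythe_F,
                            p_value = power$p_value,
                            n_edge = power$n_edge, n_center = power$n_center),
    scan_negative = scan_summary(scan_neg),
    scan_positive = scan_summary(scan_pos),
    noise = noise,
    units = units,
    provenance = list(probe = layout$probe_name, seed = seed,
                      sampling_rate_hz = fs,
                      band_hz = c(low_hz, high_hz), step = step,
                      n_steps = n_steps, alpha = alpha,
                      equalize = equalize, pool_sides = pool_sides)
  ), class = "summary_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_report(report, file.path(out_dir, "report.json"))
    utils::write.csv(scan_table(scan_neg),
                     file.path(out_dir, "scan_negative.csv"),
                     row.names = FALSE)
    utils::write.csv(scan_table(scan_pos),
                     file.path(out_dir, "scan_positive.csv"),
                     row.names = FALSE)
  }
  report
}

scan_summary <- function(s) {
  list(threshold_edge_uV = s$threshold_edge_uV,
       pct_edge = s$pct_edge, pct_center = s$pct_center,
       n_significant_edge = sum(s$sig_edge),
       n_significant_center = sum(s$sig_center),
       alpha_corrected = s$alpha_corrected)
}

scan_table <- function(s) {
  data.frame(threshold_uV = s$thresholds_uV, k_edge = s$k_edge,
             k_center = s$k_center, p_edge = s$p_edge_direction,
             p_center = s$p_center_direction, sig_edge = s$sig_edge,
             sig_center = s$sig_center)
}

# Perfect-label unit metrics: each ground-truth neuron detectable on a
# group's channels becomes one sorted unit of that group.
ground_truth_unit_metrics <- function(filtered, grouping, layout, gt, fs,
                                      duration_s, equalize,
                                      min_detect_uV = 30) {
  groups <- grouping$groups
  if (equalize) {
    target <- min(lengths(groups))
    groups <- lapply(groups, trim_symmetric, target = target)
  }
  site_order <- sort(layout$sites$site_id)
  rows <- list(); amps <- list()
  for (g in names(groups)) {
    ch_sites <- groups[[g]]
    amp_g <- gt$amplitudes[, match(ch_sites, site_order), drop = FALSE]
    detectable <- which(apply(amp_g, 1, max) > min_detect_uV &
                          lengths(gt$spike_times) >= 2)
    if (!length(detectable)) next
    units <- lapply(detectable, function(i) {
      st <- gt$spike_times[[i]]
      wf <- cut_spike_waveforms(filtered[[g]]$matrix, st, fs)
      mean_wf <- apply(wf, c(2, 3), mean)
      list(unit_id = i, spike_times_s = st, mean_waveform_uV = mean_wf)
    })
    q <- unit_quality(units, duration_s)
    q <- select_well_isolated(q)
    q$group <- g
    q$recording <- "sim"
    rows[[g]] <- q
  }
  if (!length(rows)) return(NULL)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  yield <- unit_yield(tab)
  kept <- tab[tab$well_isolated, , drop = FALSE]
  edge_amps <- kept$p2p_uV[grepl("^edge", kept$group)]
  center_amps <- kept$p2p_uV[kept$group == "center"]
  amp_scan <- if (length(edge_amps) && length(center_amps))
    scan_summary(unit_amplitude_scan(edge_amps, center_amps)) else NULL
  list(table = tab, yield = yield, amplitude_scan = amp_scan)
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("<summary_report> %s: groups %s\n", x$provenance$probe,
              paste(sprintf("%s=%d", names(x$groups),
                            unlist(x$groups)), collapse = ", ")))
  cat(sprintf("  RMS edge %.2f / center %.2f uV; Brown-Forsythe p = %.3g\n",
              x$rms$edge, x$rms$center, x$power_comparison$p_value))
  cat(sprintf("  selected thresholds: negative %s uV, positive %s uV\n",
              format(x$scan_negative$threshold_edge_uV),
              format(x$scan_positive$threshold_edge_uV)))
  invisible(x)
}

#' Write / read a summary report
#'
#' Lossless JSON serialization of a [run_pipeline()] report; serializing a
#' re-read report reproduces the file byte for byte.
#'
#' @param report A `summary_report` (for `write_report`).
#' @param path JSON file path.
#' @return `write_report`: `path`, invisibly. `read_report`: the report.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$units$table <- NULL  # the unit table goes to CSV, not JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
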