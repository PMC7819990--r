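# Shared fixtures: a tiny two-column layout for geometry edge cases, and a
# short simulated recording reused by several suites.

tiny_layout <- function() {
  # 6-site layout: one edge column (x = 8) and one inner column (x = 30)
  # on a 60 um wide shank; 20 um vertical pitch
  sites <- data.frame(
    site_id = 1:6,
    x_um = rep(c(8, 30), each = 3),
    y_um = rep(c(100, 120, 140), 2),
    area_um2 = 100, role = "recording", functional = TRUE)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(probe_name = "tiny2col", shank_width_um = 60,
                            shank_thickness_um = 20, edge_margin_um = 3,
                            sites = sites),
                       path, auto_unbox = TRUE, digits = NA)
  read_layout_json(path)
}

# one cached short recording per test run (neuronexus32, 12 s)
short_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lay <- build_layout("neuronexus32")
      cfg <- sim_config(lay, duration_s = 12, seed = 42)
      cache <<- list(layout = lay, config = cfg,
                     sim = generate_recording(cfg))
    }
    cache
  }
})

# band-power fraction of the forward-backward Butterworth band-pass,
# by numerical integration of |H|^4 over the frequency axis
filtfilt_band_power <- function(low_hz = 500, high_hz = 5000, fs = 20000,
                                order = 3, n_grid = 8192) {
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), "pass")
  h <- signal::freqz(bf, n = n_grid, Fs = fs)
  mean(abs(h$h)^4)
}
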