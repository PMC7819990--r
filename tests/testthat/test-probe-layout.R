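audit <- list(
  list(name = "neuronexus32", n_sites = 32, n_cols = 3,
       col_sizes = c(10, 12, 10), width = 125, v_pitch = 50, lat_pitch = 50),
  list(name = "neuroseeker128", n_sites = 128, n_cols = 4,
       col_sizes = rep(32, 4), width = 100, v_pitch = 22.5, lat_pitch = 22.5),
  list(name = "neuroseeker255", n_sites = 255, n_cols = 15,
       col_sizes = rep(17, 15), width = 100, v_pitch = 6, lat_pitch = 6),
  # checkerboards: in-row pitch 32 with a 16 um offset -> column lines every
  # 16 um; in-row pitch 21 with a 7 um offset -> lines at 7/14/7 um spacing
  list(name = "neuropixels70", n_sites = 384, n_cols = 4,
       col_sizes = rep(96, 4), width = 70, v_pitch = 40, lat_pitch = 16),
  list(name = "neuropixels50", n_sites = 384, n_cols = 4,
       col_sizes = rep(96, 4), width = 50, v_pitch = 40,
       lat_pitch = c(7, 14))
)

test_that("built-in layouts reproduce the published site counts and pitches", {
  for (a in audit) {
    lay <- build_layout(a$name)
    expect_s3_class(lay, "probe_layout")
    expect_equal(nrow(lay$sites), a$n_sites, info = a$name)
    expect_length(lay$columns, a$n_cols)
    expect_equal(unname(lengths(lay$columns)), a$col_sizes, info = a$name)
    expect_equal(lay$shank_width_um, a$width)
    # vertical pitch within each column
    for (ids in lay$columns) {
      ys <- sort(lay$sites$y_um[match(ids, lay$sites$site_id)])
      expect_equal(unique(round(diff(ys), 6)), a$v_pitch, info = a$name)
    }
    # lateral pitch between adjacent column lines
    xs <- sort(vapply(lay$columns, function(ids)
      mean(lay$sites$x_um[match(ids, lay$sites$site_id)]), 0))
    expect_equal(sort(unique(round(diff(xs), 6))), sort(unique(a$lat_pitch)),
                 info = a$name)
  }
})

test_that("unknown probe names and invalid layouts are rejected", {
  expect_error(build_layout("nonexistent_probe"), "unknown probe")
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(probe_name = "bad", shank_width_um = 20,
                            shank_thickness_um = 10, edge_margin_um = 3,
                            sites = data.frame(site_id = c(1, 1), x_um = c(5, 30),
                                               y_um = c(0, 0), area_um2 = 25,
                                               role = "recording",
                                               functional = TRUE)),
                       bad, auto_unbox = TRUE)
  expect_error(read_layout_json(bad))
})

test_that("layout JSON round-trips and probeinterface geometry loads", {
  lay <- build_layout("neuroseeker128")
  path <- tempfile(fileext = ".json")
  write_layout_json(lay, path)
  lay2 <- read_layout_json(path)
  expect_equal(lay2$sites$x_um, lay$sites$x_um)
  expect_equal(lengths(lay2$columns), lengths(lay$columns),
               ignore_attr = TRUE)
  g1 <- classify_edge_center(lay); g2 <- classify_edge_center(lay2)
  expect_equal(lapply(g2$groups, sort), lapply(g1$groups, sort))

  pi_path <- tempfile(fileext = ".json")
  pos <- cbind(rep(c(0, 22, 44), each = 4), rep(seq(0, 60, 20), 3))
  jsonlite::write_json(list(probes = list(list(contact_positions = pos))),
                       pi_path, auto_unbox = TRUE, digits = NA)
  pl <- read_layout_json(pi_path)
  expect_equal(nrow(pl$sites), 12)
  expect_length(pl$columns, 3)
})

test_that("edge/center classification matches the per-probe grouping rules", {
  g32 <- classify_edge_center(build_layout("neuronexus32"))
  expect_equal(lengths(g32$groups),
               c(edge_left = 10L, edge_right = 10L, center = 12L))

  g128 <- classify_edge_center(build_layout("neuroseeker128"))
  expect_equal(lengths(g128$groups),
               c(edge_left = 32L, edge_right = 32L, center = 64L))

  # dense grid: center defaults to the 8th column; the bad right edge can be
  # dropped by request
  l255 <- build_layout("neuroseeker255")
  g255 <- classify_edge_center(l255, exclude_groups = "edge_right")
  expect_named(g255$groups, c("edge_left", "center"))
  expect_equal(lengths(g255$groups), c(edge_left = 17L, center = 17L))
  expect_setequal(g255$groups$center, l255$columns[[8]])

  # internal reference and same/adjacent-row neighbors excluded (checkerboard)
  np <- build_layout("neuropixels70")
  gnp <- classify_edge_center(np)
  ref <- np$sites$site_id[np$sites$role == "internal_reference"]
  expect_length(gnp$excluded, 6)  # 3 rows x 2 sites per row
  expect_true(ref %in% gnp$excluded)
  expect_false(any(gnp$excluded %in% unlist(gnp$groups)))
})

test_that("groups partition the sites under every scheme", {
  for (name in c("neuronexus32", "neuroseeker128", "neuropixels50")) {
    lay <- build_layout(name)
    for (g in list(classify_edge_center(lay), per_column_grouping(lay),
                   longitudinal_grouping(lay, 4))) {
      ids <- unlist(g$groups, use.names = FALSE)
      expect_equal(anyDuplicated(ids), 0L)
      if (g$scheme != "edge_center" || is.null(lay$default_center_columns)) {
        expect_setequal(c(ids, g$excluded), lay$sites$site_id)
      }
      expect_false(any(g$excluded %in% ids))
    }
  }
})

test_that("classification fails when a group empties out", {
  lay <- build_layout("neuronexus32")
  expect_error(classify_edge_center(lay, bad_sites = lay$sites$site_id),
               "empty")
  expect_error(classify_edge_center(lay, bad_sites = lay$columns[[2]]),
               "center")
})

test_that("splitting reproduces the published per-group channel counts", {
  lay <- build_layout("neuronexus32")
  g <- classify_edge_center(lay)
  rec <- matrix(seq_len(100 * 32), 100, 32)
  sp <- split_recording(rec, g, lay, equalize = TRUE)
  expect_equal(vapply(sp, ncol, 0L),
               c(edge_left = 10L, edge_right = 10L, center = 10L))
  expect_equal(vapply(sp, nrow, 0L), rep(100L, 3), ignore_attr = TRUE)

  l128 <- build_layout("neuroseeker128")
  sp128 <- split_recording(matrix(0, 10, 128), per_column_grouping(l128), l128)
  expect_equal(unname(vapply(sp128, ncol, 0L)), rep(32L, 4))

  l255 <- build_layout("neuroseeker255")
  g255 <- classify_edge_center(l255, exclude_groups = "edge_right")
  sp255 <- split_recording(matrix(0, 10, 255), g255, l255)
  expect_equal(vapply(sp255, ncol, 0L), c(edge_left = 17L, center = 17L))
})

test_that("equalized trimming removes exactly the outermost center sites", {
  lay <- build_layout("neuronexus32")
  g <- classify_edge_center(lay)
  rec <- matrix(rep(sort(lay$sites$site_id), each = 5), 5, 32)  # value = site id
  sp <- split_recording(rec, g, lay, equalize = TRUE)
  center_ids <- g$groups$center
  kept <- sort(unique(as.vector(sp$center)))
  ys <- lay$sites$y_um[match(center_ids, lay$sites$site_id)]
  dropped <- center_ids[c(which.min(ys), which.max(ys))]
  expect_setequal(kept, setdiff(center_ids, dropped))
})

test_that("equalize is a no-op for equal-size groups and errors on mismatch", {
  lay <- build_layout("neuroseeker128")
  g <- per_column_grouping(lay)
  rec <- matrix(rnorm(50 * 128), 50, 128)
  expect_identical(split_recording(rec, g, lay, equalize = TRUE),
                   split_recording(rec, g, lay, equalize = FALSE))
  expect_error(split_recording(rec[, 1:100], g, lay), "channels")
})

test_that("channel maps reroute site ids to columns", {
  lay <- tiny_layout()
  g <- per_column_grouping(lay)
  rec <- matrix(rep(6:1, each = 4), 4, 6)  # channels in reversed site order
  sp <- split_recording(rec, g, lay, channel_map = 6:1)
  expect_equal(sort(unique(as.vector(sp$col_1))), 1:3)
})

test_that("longitudinal groups run from the tip and drop remainder rows on top", {
  l128 <- build_layout("neuroseeker128")
  lg <- longitudinal_grouping(l128, 4)
  expect_equal(unname(lengths(lg$groups)), rep(32L, 4))
  y_of <- function(ids) mean(l128$sites$y_um[match(ids, l128$sites$site_id)])
  expect_true(all(diff(vapply(lg$groups, y_of, 0)) > 0))  # group 1 at the tip

  expect_error(longitudinal_grouping(l128, 1), "at least 2")

  l255 <- build_layout("neuroseeker255")  # 17 rows: 4 groups of 4, top row dropped
  lg255 <- longitudinal_grouping(l255, 4)
  expect_equal(unname(lengths(lg255$groups)), rep(60L, 4))
  top_row <- l255$sites$site_id[l255$sites$y_um == max(l255$sites$y_um)]
  expect_true(all(top_row %in% lg255$excluded))
})
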