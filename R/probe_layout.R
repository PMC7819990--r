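# Probe geometries and recording-site classification.
#
# Coordinate convention: x_um is lateral, measured from the left edge of the
# silicon shank; y_um is longitudinal, measured from the probe tip. Both are
# continuous micrometers. Channel order follows site_id ascending unless a
# channel map says otherwise.

BUILTIN_PROBES <- c("neuronexus32", "neuroseeker128", "neuroseeker255",
                    "neuropixels70", "neuropixels50")

#' Build a probe layout
#'
#' Constructs the geometry of one of five built-in single-shank planar silicon
#' probes, or loads a user-defined layout from a JSON file. A layout records
#' the site coordinates, site areas and roles, the column structure, and the
#' shank dimensions needed to classify sites as edge or center.
#'
#' Built-in layouts:
#' \describe{
#'   \item{`neuronexus32`}{32 circular sites (177 um^2) in three columns of
#'     10/12/10, 50 um pitch, on a 125 um wide shank.}
#'   \item{`neuroseeker128`}{128 square sites (20 x 20 um) in four columns of
#'     32, 22.5 um pitch, on a 100 um wide shank.}
#'   \item{`neuroseeker255`}{255 sites (5 x 5 um) in a dense 17-row by
#'     15-column grid, 6 um pitch, on a 100 um wide shank.}
#'   \item{`neuropixels70`}{384 sites (12 x 12 um) in a checkerboard of four
#'     columns (96 sites each), 32 um in-row pitch with a 16 um offset between
#'     alternate columns, 40 um vertical pitch per column, 70 um wide shank.}
#'   \item{`neuropixels50`}{384 sites in four columns of 96, 21 um in-row
#'     pitch with a 7 um offset, 40 um vertical pitch, 50 um wide shank.}
#' }
#'
#' Internal reference sites of the Neuropixels layouts are placed at nominal
#' positions (the true map varies by device and should be loaded from JSON or
#' passed to [classify_edge_center()] when known).
#'
#' @param probe_name One of `"neuronexus32"`, `"neuroseeker128"`,
#'   `"neuroseeker255"`, `"neuropixels70"`, `"neuropixels50"`, or the path of
#'   a layout JSON file (see [read_layout_json()]).
#' @return An object of class `probe_layout`: a list with `probe_name`,
#'   `shank_width_um`, `shank_thickness_um`, `sites` (data frame with
#'   `site_id`, `x_um`, `y_um`, `area_um2`, `role`, `functional`), `columns`
#'   (list of site-id vectors ordered from the tip upward), `edge_margin_um`,
#'   and `default_center_columns` (column indices used as the center group by
#'   default, `NULL` meaning all non-edge columns).
#' @export
#' @examples
#' lay <- build_layout("neuronexus32")
#' lengths(lay$columns)
build_layout <- function(probe_name) {
  if (file.exists(probe_name)) return(read_layout_json(probe_name))
  switch(probe_name,
    neuronexus32 = {
      x <- c(12.5, 62.5, 112.5)
      cols <- list(
        data.frame(x = x[1], y = 125 + 0:9 * 50),
        data.frame(x = x[2], y = 100 + 0:11 * 50),
        data.frame(x = x[3], y = 125 + 0:9 * 50))
      new_layout("neuronexus32", 125, 50, cols, area = 177,
                 edge_margin = 5)
    },
    neuroseeker128 = {
      x <- 16.25 + 0:3 * 22.5
      cols <- lapply(x, function(xx) data.frame(x = xx, y = 300 + 0:31 * 22.5))
      new_layout("neuroseeker128", 100, 50, cols, area = 400,
                 edge_margin = 6.25)
    },
    neuroseeker255 = {
      x <- 8 + 0:14 * 6
      cols <- lapply(x, function(xx) data.frame(x = xx, y = 300 + 0:16 * 6))
      new_layout("neuroseeker255", 100, 50, cols, area = 25,
                 edge_margin = 5.5, default_center_columns = 8L)
    },
    neuropixels70 = {
      cols <- list(
        data.frame(x = 11, y = 195 + 0:95 * 40),
        data.frame(x = 27, y = 215 + 0:95 * 40),
        data.frame(x = 43, y = 195 + 0:95 * 40),
        data.frame(x = 59, y = 215 + 0:95 * 40))
      lay <- new_layout("neuropixels70", 70, 20, cols, area = 144,
                        edge_margin = 5)
      # nominal internal reference: one mid-shank site in the 2nd column
      ref <- lay$columns[[2]][48]
      lay$sites$role[lay$sites$site_id == ref] <- "internal_reference"
      lay
    },
    neuropixels50 = {
      cols <- list(
        data.frame(x = 11, y = 137 + 0:95 * 40),
        data.frame(x = 18, y = 157 + 0:95 * 40),
        data.frame(x = 32, y = 137 + 0:95 * 40),
        data.frame(x = 39, y = 157 + 0:95 * 40))
      lay <- new_layout("neuropixels50", 50, 20, cols, area = 144,
                        edge_margin = 5)
      # nominal internal references: 12 sites spread along columns 2 and 3
      rows <- round(seq(8, 90, length.out = 12))
      refs <- mapply(function(r, k) lay$columns[[k]][r], rows,
                     rep(c(2L, 3L), 6))
      lay$sites$role[lay$sites$site_id %in% refs] <- "internal_reference"
      lay
    },
    stop("unknown probe name: ", probe_name, call. = FALSE)
  )
}

new_layout <- function(name, width, thickness, col_frames, area, edge_margin,
                       default_center_columns = NULL) {
  n_per <- vapply(col_frames, nrow, 0L)
  ids <- split(seq_len(sum(n_per)), rep(seq_along(col_frames), n_per))
  sites <- do.call(rbind, col_frames)
  sites <- data.frame(site_id = seq_len(nrow(sites)),
                      x_um = sites$x, y_um = sites$y,
                      area_um2 = area, role = "recording",
                      functional = TRUE)
  lay <- structure(list(
    probe_name = name,
    shank_width_um = width,
    shank_thickness_um = thickness,
    sites = sites,
    columns = lapply(ids, function(i) i[order(sites$y_um[i])]),
    edge_margin_um = edge_margin,
    default_center_columns = default_center_columns
  ), class = "probe_layout")
  validate_layout(lay)
  lay
}

validate_layout <- function(lay) {
  s <- lay$sites
  if (anyDuplicated(s$site_id)) stop("duplicate site_id in layout")
  if (any(s$x_um < 0 | s$x_um > lay$shank_width_um))
    stop("site x coordinate outside the shank width")
  in_cols <- sort(unlist(lay$columns, use.names = FALSE))
  if (!identical(in_cols, sort(s$site_id)))
    stop("every site must belong to exactly one column")
  invisible(lay)
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("<probe_layout> %s: %d sites, %d columns (%s), shank %g x %g um\n",
              x$probe_name, nrow(x$sites), length(x$columns),
              paste(lengths(x$columns), collapse = "/"),
              x$shank_width_um, x$shank_thickness_um))
  invisible(x)
}

# Half extent of a site used when measuring the gap between the site boundary
# and the shank edge; square sites assumed (circular sites of equal area have
# a slightly larger radius, immaterial under the 10 um edge rule).
site_half_extent <- function(area_um2) sqrt(area_um2) / 2

#' Classify recording sites as edge or center
#'
#' Labels each column of a layout as edge or center and returns the site
#' grouping used to split a recording by site position. A column counts as
#' "edge" when the boundary of its sites lies within `edge_margin_threshold_um`
#' of a lateral shank edge; all other columns are "center" unless the layout
#' names specific center columns (the dense 17 x 15 grid uses its 8th column
#' as the default center group). Bad sites, non-functional sites, internal
#' reference sites and (for checkerboard layouts) the reference's row
#' neighbors are excluded from every group.
#'
#' @param layout A `probe_layout`.
#' @param bad_sites Integer site ids to exclude (unfunctional channels).
#' @param reference_sites Site ids of internal reference electrodes; defaults
#'   to the layout's sites with role `"internal_reference"`.
#' @param center_columns Column indices forming the center group; defaults to
#'   the layout's `default_center_columns`, else all non-edge columns.
#' @param exclude_groups Character vector of group labels to drop from the
#'   result (e.g. `"edge_right"` when that edge has too many bad channels).
#' @param exclude_reference_neighbors Logical; also exclude sites in the same
#'   and adjacent rows as each reference site. Default `TRUE` for the
#'   Neuropixels layouts, `FALSE` otherwise.
#' @param edge_margin_threshold_um Distance rule for edge classification
#'   (default 10 um, covering the 5-6.25 um margins of the built-ins).
#' @return An object of class `site_grouping`: list with `scheme`
#'   (`"edge_center"`), `groups` (named list of site-id vectors ordered from
#'   the tip upward), and `excluded` (site ids removed).
#' @export
classify_edge_center <- function(layout, bad_sites = integer(),
                                 reference_sites = NULL,
                                 center_columns = NULL,
                                 exclude_groups = character(),
                                 exclude_reference_neighbors = NULL,
                                 edge_margin_threshold_um = 10) {
  stopifnot(inherits(layout, "probe_layout"))
  s <- layout$sites
  if (is.null(reference_sites))
    reference_sites <- s$site_id[s$role == "internal_reference"]
  if (is.null(exclude_reference_neighbors))
    exclude_reference_neighbors <- grepl("^neuropixels", layout$probe_name)

  excluded <- unique(c(as.integer(bad_sites), as.integer(reference_sites),
                       s$site_id[!s$functional]))
  if (exclude_reference_neighbors && length(reference_sites)) {
    rows <- sort(unique(round(s$y_um)))
    row_of <- match(round(s$y_um), rows)
    ref_rows <- row_of[match(reference_sites, s$site_id)]
    nb <- s$site_id[row_of %in% unique(c(ref_rows - 1L, ref_rows, ref_rows + 1L))]
    excluded <- unique(c(excluded, nb))
  }

  cls <- classify_columns(layout, edge_margin_threshold_um)
  if (is.null(center_columns)) center_columns <- layout$default_center_columns
  if (is.null(center_columns)) center_columns <- which(cls == "center")

  groups <- list()
  left <- which(cls == "edge_left"); right <- which(cls == "edge_right")
  if (length(left))
    groups$edge_left <- unlist(layout$columns[left], use.names = FALSE)
  if (length(right))
    groups$edge_right <- unlist(layout$columns[right], use.names = FALSE)
  groups$center <- unlist(layout$columns[center_columns], use.names = FALSE)

  groups <- lapply(groups, function(g) order_by_position(setdiff(g, excluded), s))
  groups <- groups[setdiff(names(groups), exclude_groups)]
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty))
    stop("group(s) empty after exclusions: ", paste(empty, collapse = ", "))

  structure(list(scheme = "edge_center", groups = groups,
                 excluded = sort(excluded), probe_name = layout$probe_name),
            class = "site_grouping")
}

classify_columns <- function(layout, threshold_um) {
  s <- layout$sites
  vapply(layout$columns, function(ids) {
    i <- match(ids, s$site_id)
    half <- site_half_extent(s$area_um2[i])
    d_left <- min(s$x_um[i] - half)
    d_right <- min(layout$shank_width_um - s$x_um[i] - half)
    if (min(d_left, d_right) > threshold_um) return("center")
    if (d_left <= d_right) "edge_left" else "edge_right"
  }, "")
}

order_by_position <- function(ids, sites) {
  i <- match(ids, sites$site_id)
  ids[order(sites$y_um[i], sites$x_um[i])]
}

#' Group sites by longitudinal position
#'
#' Splits the rows of a layout into `n_groups` groups of equal row count,
#' ordered from the probe tip upward (group 1 is closest to the tip). When the
#' row count is not divisible by `n_groups`, the remainder rows are dropped
#' from the top of the shank.
#'
#' @inheritParams classify_edge_center
#' @param n_groups Number of longitudinal groups (at least 2).
#' @return A `site_grouping` with scheme `"longitudinal"` and groups named
#'   `long_1` (tip) to `long_n`.
#' @export
longitudinal_grouping <- function(layout, n_groups, bad_sites = integer(),
                                  reference_sites = NULL) {
  stopifnot(inherits(layout, "probe_layout"))
  if (n_groups < 2) stop("n_groups must be at least 2")
  s <- layout$sites
  if (is.null(reference_sites))
    reference_sites <- s$site_id[s$role == "internal_reference"]
  excluded <- unique(c(as.integer(bad_sites), as.integer(reference_sites),
                       s$site_id[!s$functional]))
  keep <- s[!(s$site_id %in% excluded), ]
  rows <- sort(unique(keep$y_um))
  per <- length(rows) %/% n_groups
  if (per < 1) stop("fewer rows than groups")
  dropped_rows <- if (length(rows) > per * n_groups)
    rows[(per * n_groups + 1):length(rows)] else numeric()
  groups <- lapply(seq_len(n_groups), function(g) {
    gr <- rows[((g - 1) * per + 1):(g * per)]
    order_by_position(keep$site_id[keep$y_um %in% gr], s)
  })
  names(groups) <- paste0("long_", seq_len(n_groups))
  excluded <- sort(unique(c(excluded, keep$site_id[keep$y_um %in% dropped_rows])))
  structure(list(scheme = "longitudinal", groups = groups,
                 excluded = excluded, probe_name = layout$probe_name),
            class = "site_grouping")
}

#' Group sites column by column
#'
#' One group per column of the layout, ordered from the tip upward.
#'
#' @inheritParams classify_edge_center
#' @return A `site_grouping` with scheme `"per_column"` and groups `col_1`,
#'   `col_2`, ...
#' @export
per_column_grouping <- function(layout, bad_sites = integer(),
                                reference_sites = NULL) {
  stopifnot(inherits(layout, "probe_layout"))
  s <- layout$sites
  if (is.null(reference_sites))
    reference_sites <- s$site_id[s$role == "internal_reference"]
  excluded <- unique(c(as.integer(bad_sites), as.integer(reference_sites),
                       s$site_id[!s$functional]))
  groups <- lapply(layout$columns, function(g)
    order_by_position(setdiff(g, excluded), s))
  names(groups) <- paste0("col_", seq_along(groups))
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty))
    stop("group(s) empty after exclusions: ", paste(empty, collapse = ", "))
  structure(list(scheme = "per_column", groups = groups,
                 excluded = sort(excluded), probe_name = layout$probe_name),
            class = "site_grouping")
}

#' @export
print.site_grouping <- function(x, ...) {
  cat(sprintf("<site_grouping> %s (%s): %s; %d excluded\n", x$scheme,
              x$probe_name,
              paste(sprintf("%s=%d", names(x$groups), lengths(x$groups)),
                    collapse = ", "),
              length(x$excluded)))
  invisible(x)
}

#' Split a multichannel recording by site group
#'
#' Cuts a `[time x channel]` matrix into one sub-matrix per group of a
#' [site_grouping]. With `equalize = TRUE`, groups larger than the smallest
#' group are trimmed symmetrically — sites removed alternately from the top
#' and bottom of the shank (the extra site from the top when the excess is
#' odd) — so that all groups have the same channel count, as done when
#' constructing a 10-channel center file from a 12-site middle column.
#'
#' @param recording Numeric matrix `[time x channel]` in microvolts.
#' @param grouping A `site_grouping`.
#' @param layout The `probe_layout` the grouping was derived from.
#' @param equalize Trim larger groups to the smallest group's channel count.
#' @param channel_map Integer vector: `channel_map[k]` is the site id recorded
#'   on channel `k`. Default: site ids ascending.
#' @return Named list of `[time x channels]` matrices, one per group; channel
#'   order within each group runs from the tip upward.
#' @export
split_recording <- function(recording, grouping, layout, equalize = FALSE,
                            channel_map = NULL) {
  stopifnot(inherits(grouping, "site_grouping"),
            inherits(layout, "probe_layout"))
  recording <- as.matrix(recording)
  if (ncol(recording) != nrow(layout$sites))
    stop(sprintf("recording has %d channels but layout has %d sites",
                 ncol(recording), nrow(layout$sites)))
  if (is.null(channel_map)) channel_map <- sort(layout$sites$site_id)
  groups <- grouping$groups
  if (equalize) {
    target <- min(lengths(groups))
    groups <- lapply(groups, trim_symmetric, target = target)
  }
  lapply(groups, function(ids) {
    recording[, match(ids, channel_map), drop = FALSE]
  })
}

# ids are ordered tip -> top; drop excess sites half from the bottom,
# half (rounded up) from the top
trim_symmetric <- function(ids, target) {
  excess <- length(ids) - target
  if (excess <= 0) return(ids)
  from_bottom <- excess %/% 2
  from_top <- excess - from_bottom
  ids[seq(from_bottom + 1, length(ids) - from_top)]
}

#' Write a probe layout to JSON
#'
#' @param layout A `probe_layout`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  obj <- list(probe_name = layout$probe_name,
              shank_width_um = layout$shank_width_um,
              shank_thickness_um = layout$shank_thickness_um,
              edge_margin_um = layout$edge_margin_um,
              default_center_columns = layout$default_center_columns,
              sites = layout$sites)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a probe layout from JSON
#'
#' Accepts the package's own layout JSON (as written by [write_layout_json()])
#' or a probeinterface-style geometry (an object with a `probes` array whose
#' entries carry `contact_positions`).
#'
#' @param path JSON file path.
#' @return A `probe_layout`. Columns are inferred from the distinct lateral
#'   positions of the sites.
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$probes)) {
    pos <- if (is.data.frame(obj$probes)) obj$probes$contact_positions[[1]]
           else obj$probes[[1]]$contact_positions
    if (is.list(pos)) pos <- do.call(rbind, lapply(pos, unlist))
    pos <- matrix(as.numeric(pos), ncol = 2)
    x <- pos[, 1] - min(pos[, 1]) + 5  # re-origin with a nominal 5 um margin
    sites <- data.frame(site_id = seq_len(nrow(pos)), x_um = x,
                        y_um = pos[, 2] - min(pos[, 2]),
                        area_um2 = 144, role = "recording", functional = TRUE)
    obj <- list(probe_name = "probeinterface_import",
                shank_width_um = max(x) + 5 + site_half_extent(144),
                shank_thickness_um = NA_real_, edge_margin_um = 5,
                sites = sites)
  }
  sites <- as.data.frame(obj$sites)
  sites$site_id <- as.integer(sites$site_id)
  dcc <- as.integer(unlist(obj$default_center_columns))
  obj$default_center_columns <- if (length(dcc)) dcc else NULL
  xs <- sort(unique(sites$x_um))
  cols <- lapply(xs, function(xx)
    sites$site_id[sites$x_um == xx][order(sites$y_um[sites$x_um == xx])])
  lay <- structure(list(
    probe_name = obj$probe_name,
    shank_width_um = obj$shank_width_um,
    shank_thickness_um = obj$shank_thickness_um,
    sites = sites,
    columns = cols,
    edge_margin_um = obj$edge_margin_um,
    default_center_columns = obj$default_center_columns
  ), class = "probe_layout")
  validate_layout(lay)
  lay
}
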