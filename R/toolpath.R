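#' Construct a toolpath from a move table
#'
#' A toolpath is an ordered, chained sequence of linear moves in millimetres:
#' the machine travels each move from its start to its end point, and every
#' move starts exactly where the previous one ended. Print moves deposit
#' material; travel moves only reposition the needle.
#'
#' @param moves data.frame with columns `kind` ("print" or "travel"),
#'   `x0,y0,z0,x1,y1,z1` (mm) and optionally `feed` (mm/s, `NA` = inherited
#'   from the previous move at execution time) and `m102` (integer LED code
#'   annotation carried by the move, `NA` = none).
#' @param layer_thickness Layer thickness in mm (> 0).
#' @param meta Free-form provenance list.
#' @return An object of class `toolpath`.
#' @export
toolpath <- function(moves, layer_thickness = 0.2, meta = list()) {
  stopifnot(is.data.frame(moves))
  req <- c("kind", "x0", "y0", "z0", "x1", "y1", "z1")
  missing_cols <- setdiff(req, names(moves))
  if (length(missing_cols) > 0L)
    stop("moves is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!("feed" %in% names(moves))) moves$feed <- NA_real_
  if (!("m102" %in% names(moves))) moves$m102 <- NA_integer_
  moves <- moves[, c(req, "feed", "m102")]
  moves$kind <- as.character(moves$kind)
  if (!all(moves$kind %in% c("print", "travel")))
    stop("move kind must be 'print' or 'travel'")
  num <- c("x0", "y0", "z0", "x1", "y1", "z1", "feed")
  for (cl in num) moves[[cl]] <- as.numeric(moves[[cl]])
  coords <- as.matrix(moves[, c("x0", "y0", "z0", "x1", "y1", "z1")])
  if (nrow(moves) > 0L && !all(is.finite(coords)))
    stop("toolpath coordinates must be finite")
  if (!is.numeric(layer_thickness) || length(layer_thickness) != 1L ||
      layer_thickness <= 0)
    stop("layer_thickness must be a single positive number (mm)")
  if (nrow(moves) > 1L) {
    gap <- abs(coords[-1L, 1:3, drop = FALSE] -
               coords[-nrow(moves), 4:6, drop = FALSE])
    if (max(gap) > 1e-9)
      stop("moves are not chained: move ", which(rowSums(gap > 1e-9) > 0)[1] + 1L,
           " does not start where the previous move ended")
  }
  len <- move_lengths(moves)
  bad_print <- moves$kind == "print" & len <= 1e-12
  if (any(bad_print))
    stop("print move ", which(bad_print)[1],
         " has zero length; print moves must advance in XY or Z")
  if (any(!is.na(moves$feed) & moves$feed <= 0))
    stop("feed rates must be positive (mm/s)")
  structure(list(moves = moves, layer_thickness = layer_thickness, meta = meta),
            class = "toolpath")
}

# Euclidean 3D length of each move (mm)
move_lengths <- function(moves) {
  sqrt((moves$x1 - moves$x0)^2 + (moves$y1 - moves$y0)^2 +
       (moves$z1 - moves$z0)^2)
}

#' Build a toolpath from an ordered list of Cartesian coordinates
#'
#' This is the planner-facing input form: an ordered sequence of XYZ waypoints
#' (mm). Consecutive waypoints become moves; the first waypoint is reached by
#' a travel move from `start`.
#'
#' @param xyz data.frame or matrix with columns x, y, z (mm), one row per
#'   ordered waypoint.
#' @param kind "print" (default) or "travel", recycled over the segments
#'   (including the one leaving `start`), or a vector of one kind per
#'   segment.
#' @param feed Feed rate in mm/s, recycled per segment.
#' @param start Starting position of the needle, default the machine origin.
#' @param layer_thickness,meta Passed to [toolpath()].
#' @return A `toolpath`.
#' @export
toolpath_from_coords <- function(xyz, kind = "print", feed = NA_real_,
                                 start = c(0, 0, 0), layer_thickness = 0.2,
                                 meta = list()) {
  xyz <- as.data.frame(xyz)
  names(xyz)[1:3] <- c("x", "y", "z")
  n <- nrow(xyz)
  if (n < 1L) stop("need at least one waypoint")
  pts <- rbind(data.frame(x = start[1], y = start[2], z = start[3]),
               xyz[, c("x", "y", "z")])
  nseg <- n
  kinds <- rep_len(as.character(kind), nseg)
  feeds <- rep_len(as.numeric(feed), nseg)
  moves <- data.frame(
    kind = kinds,
    x0 = pts$x[-(nseg + 1L)], y0 = pts$y[-(nseg + 1L)], z0 = pts$z[-(nseg + 1L)],
    x1 = pts$x[-1L], y1 = pts$y[-1L], z1 = pts$z[-1L],
    feed = feeds)
  # drop a zero-length leading travel (already at the first waypoint)
  len <- move_lengths(moves)
  if (len[1] <= 1e-12 && nrow(moves) > 1L) moves <- moves[-1L, ]
  rownames(moves) <- NULL
  toolpath(moves, layer_thickness = layer_thickness, meta = meta)
}

#' @export
print.toolpath <- function(x, ...) {
  st <- toolpath_stats(x)
  cat(sprintf("<toolpath> %d moves (%d print, %d travel), layer %.3g mm\n",
              nrow(x$moves), sum(x$moves$kind == "print"),
              sum(x$moves$kind == "travel"), x$layer_thickness))
  cat(sprintf("  print length %.2f mm, bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              st$print_length_mm, st$bbox["xmin"], st$bbox["xmax"],
              st$bbox["ymin"], st$bbox["ymax"], st$bbox["zmin"], st$bbox["zmax"]))
  invisible(x)
}

#' Summary statistics of a toolpath
#'
#' @param path A `toolpath`.
#' @return List with total print/travel length (mm), the XYZ bounding box over
#'   all move endpoints, the distinct print Z levels and per-layer print move
#'   counts.
#' @export
toolpath_stats <- function(path) {
  stopifnot(inherits(path, "toolpath"))
  m <- path$moves
  len <- move_lengths(m)
  xs <- c(m$x0, m$x1); ys <- c(m$y0, m$y1); zs <- c(m$z0, m$z1)
  if (nrow(m) == 0L) xs <- ys <- zs <- 0
  pz <- sort(unique(round(m$z1[m$kind == "print"], 6)))
  per_layer <- if (length(pz)) {
    cnt <- vapply(pz, function(z) sum(m$kind == "print" & abs(m$z1 - z) < 1e-6),
                  integer(1))
    stats::setNames(cnt, format(pz))
  } else integer(0)
  structure(list(
    n_moves = nrow(m),
    print_length_mm = sum(len[m$kind == "print"]),
    travel_length_mm = sum(len[m$kind == "travel"]),
    bbox = c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys),
             zmin = min(zs), zmax = max(zs)),
    z_levels = pz,
    print_moves_per_layer = per_layer),
    class = "toolpath_stats")
}

#' @export
print.toolpath_stats <- function(x, ...) {
  cat(sprintf("moves: %d | print %.2f mm | travel %.2f mm\n",
              x$n_moves, x$print_length_mm, x$travel_length_mm))
  cat(sprintf("bbox: %.2f x %.2f x %.2f mm | %d layer(s)\n",
              x$bbox["xmax"] - x$bbox["xmin"], x$bbox["ymax"] - x$bbox["ymin"],
              x$bbox["zmax"] - x$bbox["zmin"], length(x$z_levels)))
  invisible(x)
}

#' Resolve per-move feed rates, inheriting from previous moves
#'
#' @param path A `toolpath`.
#' @param default Feed (mm/s) used before the first explicit feed; `NULL`
#'   leaves such moves `NA`.
#' @return Numeric vector of feeds, one per move.
#' @export
resolve_feeds <- function(path, default = NULL) {
  f <- path$moves$feed
  cur <- if (is.null(default)) NA_real_ else default
  for (i in seq_along(f)) {
    if (is.na(f[i])) f[i] <- cur else cur <- f[i]
  }
  f
}

#' Read a toolpath from a CSV of ordered waypoints
#'
#' Expected columns: `x,y,z` and optionally `kind` ("print"/"travel") and
#' `feed` (mm/s). Each row is a waypoint; rows after the first define segments.
#'
#' @param file Path to a CSV file.
#' @param layer_thickness Layer thickness in mm.
#' @return A `toolpath`.
#' @export
read_toolpath_csv <- function(file, layer_thickness = 0.2) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  if (!all(c("x", "y", "z") %in% names(d)))
    stop("CSV must have columns x, y, z")
  n <- nrow(d)
  if (n < 2L) stop("need at least two waypoints")
  kind <- if ("kind" %in% names(d)) d$kind[-1L] else "print"
  feed <- if ("feed" %in% names(d)) d$feed[-1L] else NA_real_
  toolpath_from_coords(d[-1L, c("x", "y", "z")], kind = kind, feed = feed,
                       start = as.numeric(d[1L, c("x", "y", "z")]),
                       layer_thickness = layer_thickness,
                       meta = list(source = file))
}

#' Write a toolpath as a CSV of ordered waypoints
#'
#' @param path A `toolpath`.
#' @param file Output file.
#' @export
write_toolpath_csv <- function(path, file) {
  stopifnot(inherits(path, "toolpath"))
  m <- path$moves
  d <- data.frame(x = c(m$x0[1], m$x1), y = c(m$y0[1], m$y1),
                  z = c(m$z0[1], m$z1),
                  kind = c("travel", m$kind), feed = c(NA_real_, m$feed))
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}
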