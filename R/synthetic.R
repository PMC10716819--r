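#' Serpentine monolayer grid toolpath
#'
#' Rectilinear raster covering a rectangular bounding box at a single Z
#' level: rows along +x/-x alternately, joined by short +y connector strands.
#' Connectors are print moves, as in a continuously extruded serpentine. The
#' requested pitch is rounded so an integer number of rows spans the box
#' exactly.
#'
#' @param width,height Bounding box extents in XY, mm.
#' @param pitch Nominal row spacing, mm. The default 0.8 mm corresponds to
#'   50% infill with a 0.4 mm needle (spacing = 2 x line width).
#' @param layer_thickness Layer thickness, mm; the single layer prints at
#'   this Z.
#' @param feed Print feed, mm/s.
#' @return A `toolpath`. The path starts with a travel move from the origin.
#' @export
gen_grid_monolayer <- function(width = 20, height = 20, pitch = 0.8,
                               layer_thickness = 0.2, feed = 5) {
  stopifnot(width > 0, height > 0, pitch > 0)
  pts <- serpentine_rows(width, height, pitch)
  pts$z <- layer_thickness
  toolpath_from_coords(pts, kind = c("travel", rep("print", nrow(pts) - 1L)),
                       feed = feed,
                       layer_thickness = layer_thickness,
                       meta = list(fixture = "grid_monolayer",
                                   width = width, height = height,
                                   pitch = pitch))
}

# waypoints of one serpentine layer in the XY rectangle [0,w] x [0,h];
# n_rows = round(h / pitch), rows evenly spaced to span [0, h] exactly
serpentine_rows <- function(width, height, pitch, flip_axes = FALSE) {
  n_rows <- max(2L, round(height / pitch))
  ys <- seq(0, height, length.out = n_rows)
  xs <- rep(c(0, width, width, 0), length.out = 2L * n_rows)
  pts <- data.frame(x = xs, y = rep(ys, each = 2L))
  if (flip_axes) pts <- data.frame(x = pts$y, y = pts$x)
  pts
}

#' Multilayer square infill toolpath
#'
#' Stacked square layers with rectilinear infill whose direction alternates
#' 0/90 degrees between layers. Line spacing follows the infill percentage:
#' `pitch = line_width * 100 / infill` (0.8 mm at 50% infill with a 0.4 mm
#' needle). Layers are joined by travel moves.
#'
#' @param size Square edge, mm.
#' @param n_layers Number of layers.
#' @param layer_thickness Layer thickness, mm.
#' @param infill Infill percentage in (0, 100].
#' @param line_width Deposited line width (needle inner diameter), mm.
#' @param feed Print feed, mm/s.
#' @return A `toolpath`.
#' @export
gen_multilayer_square <- function(size = 20, n_layers = 6,
                                  layer_thickness = 0.2, infill = 50,
                                  line_width = 0.4, feed = 5) {
  stopifnot(size > 0, n_layers >= 1, infill > 0, infill <= 100)
  pitch <- line_width * 100 / infill
  moves <- NULL
  pos <- c(0, 0, 0)
  for (k in seq_len(n_layers)) {
    z <- k * layer_thickness
    pts <- serpentine_rows(size, size, pitch, flip_axes = (k %% 2L == 0L))
    pts$z <- z
    first <- as.numeric(pts[1, c("x", "y", "z")])
    seg <- data.frame(
      kind = c("travel", rep("print", nrow(pts) - 1L)),
      x0 = c(pos[1], pts$x[-nrow(pts)]), y0 = c(pos[2], pts$y[-nrow(pts)]),
      z0 = c(pos[3], pts$z[-nrow(pts)]),
      x1 = pts$x, y1 = pts$y, z1 = pts$z, feed = feed)
    if (max(abs(first - pos)) < 1e-12) seg <- seg[-1L, ]
    moves <- rbind(moves, seg)
    pos <- as.numeric(pts[nrow(pts), c("x", "y", "z")])
  }
  rownames(moves) <- NULL
  toolpath(moves, layer_thickness = layer_thickness,
           meta = list(fixture = "multilayer_square", size = size,
                       n_layers = n_layers, infill = infill, pitch = pitch))
}

#' Non-planar spherical-cap infill toolpath
#'
#' Stand-in for conformal printing into an anatomical defect: the serpentine
#' XY pattern of [gen_multilayer_square()] with Z following a spherical cap
#' of radius `cap_radius` centred over the square, stacked as layers offset
#' vertically by the layer thickness (a shallow-cap approximation of a
#' constant normal offset). Rows are subdivided so the path follows the
#' curvature. XY-projected segment directions are identical to the flat
#' fixture, so LED scheduling is unaffected by the non-planarity.
#' `cap_radius = Inf` degenerates to the flat multilayer geometry.
#'
#' @param size Square edge, mm.
#' @param cap_radius Sphere radius, mm; must exceed half the square diagonal.
#' @param n_layers Number of conformal layers.
#' @param layer_thickness Layer thickness, mm.
#' @param infill Infill percentage in (0, 100].
#' @param line_width Deposited line width, mm.
#' @param feed Print feed, mm/s.
#' @param max_seg Maximum segment length when following the curvature, mm.
#' @return A `toolpath`; `meta$depth_warning` is `TRUE` when the Z range
#'   exceeds the 15 mm depth the slider geometry can reach.
#' @export
gen_spherical_cap_infill <- function(size = 20, cap_radius = 30, n_layers = 6,
                                     layer_thickness = 0.2, infill = 50,
                                     line_width = 0.4, feed = 5, max_seg = 1) {
  stopifnot(size > 0, n_layers >= 1, infill > 0, infill <= 100)
  half_diag <- size * sqrt(2) / 2
  if (cap_radius <= half_diag)
    stop("cap_radius must exceed half the square diagonal (", half_diag, " mm)")
  pitch <- line_width * 100 / infill
  ctr <- c(size / 2, size / 2)
  zs <- function(x, y) {
    if (!is.finite(cap_radius)) return(rep(0, length(x)))
    rho2 <- (x - ctr[1])^2 + (y - ctr[2])^2
    sqrt(cap_radius^2 - rho2) - sqrt(cap_radius^2 - half_diag^2)
  }
  moves <- NULL
  pos <- c(0, 0, 0)
  for (k in seq_len(n_layers)) {
    pts <- serpentine_rows(size, size, pitch, flip_axes = (k %% 2L == 0L))
    pts <- densify(pts, max_seg)
    pts$z <- zs(pts$x, pts$y) + k * layer_thickness
    first <- as.numeric(pts[1, c("x", "y", "z")])
    seg <- data.frame(
      kind = c("travel", rep("print", nrow(pts) - 1L)),
      x0 = c(pos[1], pts$x[-nrow(pts)]), y0 = c(pos[2], pts$y[-nrow(pts)]),
      z0 = c(pos[3], pts$z[-nrow(pts)]),
      x1 = pts$x, y1 = pts$y, z1 = pts$z, feed = feed)
    if (max(abs(first - pos)) < 1e-12) seg <- seg[-1L, ]
    moves <- rbind(moves, seg)
    pos <- as.numeric(pts[nrow(pts), c("x", "y", "z")])
  }
  rownames(moves) <- NULL
  zr <- diff(range(c(moves$z0[-1L], moves$z1)))
  toolpath(moves, layer_thickness = layer_thickness,
           meta = list(fixture = "spherical_cap", size = size,
                       cap_radius = cap_radius, n_layers = n_layers,
                       infill = infill, pitch = pitch,
                       depth_warning = zr > 15))
}

# insert intermediate waypoints so no XY segment exceeds max_seg
densify <- function(pts, max_seg) {
  out <- pts[1, , drop = FALSE]
  for (i in seq_len(nrow(pts) - 1L)) {
    d <- sqrt((pts$x[i + 1L] - pts$x[i])^2 + (pts$y[i + 1L] - pts$y[i])^2)
    nseg <- max(1L, ceiling(d / max_seg))
    t <- seq_len(nseg) / nseg
    out <- rbind(out, data.frame(x = pts$x[i] + t * (pts$x[i + 1L] - pts$x[i]),
                                 y = pts$y[i] + t * (pts$y[i + 1L] - pts$y[i])))
  }
  rownames(out) <- NULL
  out
}
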