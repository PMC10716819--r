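# Independent oracles used across tests; these stay deliberately naive and
# separate from the package code paths they check.

# Brute-force nearest-centre sector assignment over the 8 principal
# directions. Ties (exact half-way angles) go to the sector whose lower
# boundary includes the angle, i.e. signed difference -22.5.
oracle_sector <- function(theta) {
  centers <- seq(0, 315, by = 45)
  vapply(theta, function(t) {
    d <- ((t - centers + 180) %% 360) - 180   # signed diff in [-180, 180)
    ad <- abs(d)
    cand <- which(ad == min(ad))
    if (length(cand) > 1L) cand <- cand[d[cand] < 0]
    cand[1] - 1L
  }, integer(1))
}

# Expected LED code of an axis-aligned direction, spelled out by hand.
oracle_axis_code <- function(dx, dy) {
  if (dx > 0 && dy == 0) 1L
  else if (dx == 0 && dy > 0) 3L
  else if (dx < 0 && dy == 0) 5L
  else if (dx == 0 && dy < 0) 7L
  else stop("not axis-aligned")
}

# Row-by-row expected code sequence of a serpentine layer: apply the
# axis-aligned table to each waypoint pair, independent of schedule_path().
oracle_serpentine_codes <- function(path) {
  m <- path$moves
  codes <- integer(0)
  prev <- 0L
  for (i in seq_len(nrow(m))) {
    if (m$kind[i] == "print") {
      dx <- m$x1[i] - m$x0[i]; dy <- m$y1[i] - m$y0[i]
      if (abs(dx) > 1e-9 || abs(dy) > 1e-9)
        prev <- oracle_axis_code(sign(dx) * (abs(dx) > 1e-9),
                                 sign(dy) * (abs(dy) > 1e-9))
    }
    codes <- c(codes, prev)
  }
  codes
}

# Number of M102 lines an emitted document should contain for a code
# sequence: one per run of equal consecutive codes.
oracle_m102_count <- function(codes) length(rle(codes)$lengths)

count_m102 <- function(gcode) sum(grepl("^M102 P", gcode))

m102_codes <- function(gcode) {
  as.integer(sub("^M102 P", "", grep("^M102 P", gcode, value = TRUE)))
}

# Saturating-exponential swelling replicate on the standard immersion grid.
synthetic_swelling <- function(plateau = 4, tau = 1, W_0 = 100, noise_sd = 0,
                               time = c(0.5, 1, 1.5, 2, 3, 4, 24)) {
  sw <- plateau * (1 - exp(-time / tau))
  if (noise_sd > 0) sw <- sw + stats::rnorm(length(time), sd = noise_sd)
  swelling_series(time, W_0 * (1 + sw / 100), W_0)
}

# Random printable path with n XY waypoints (no degenerate segments).
random_path <- function(n = 6, feed = 5) {
  repeat {
    pts <- data.frame(x = stats::runif(n, 0, 30), y = stats::runif(n, 0, 30),
                      z = 0.2)
    dd <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)
    if (all(dd > 1e-3) && (abs(pts$x[1]) > 1e-3 || abs(pts$y[1]) > 1e-3))
      return(toolpath_from_coords(pts, feed = feed))
  }
}

fixture_set <- function() list(
  grid = gen_grid_monolayer(20, 20, pitch = 1, feed = 5),
  square = gen_multilayer_square(20, n_layers = 6, feed = 5),
  cap = gen_spherical_cap_infill(20, cap_radius = 30, n_layers = 3, feed = 5))
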