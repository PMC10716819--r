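#' LED ring illumination geometry
#'
#' Four LED couples sit around the needle at 90 degrees from each other,
#' 10.6 mm from the needle axis, and are aimed at the deposition zone: the
#' luminous spot of a couple is modeled as a top-hat disk of diameter `w_0`
#' whose centre is displaced from the nozzle toward the couple's azimuth by
#' `spot_offset_frac * w_0 / 2` (default half the spot radius), so the
#' deposition point always sits inside an active spot while most of the light
#' falls on the trailing side. Set `spot_offset_mm` to override with a fixed
#' displacement (e.g. the 10.6 mm mechanical offset, which models LEDs
#' pointing straight down and leaves the needle outside every spot).
#'
#' @param mount_offset Mechanical distance of each couple from the needle
#'   axis, mm.
#' @param couple_azimuths Azimuths of the four couples, degrees.
#' @param spot_offset_frac Spot-centre displacement as a fraction of the spot
#'   radius; ignored when `spot_offset_mm` is given.
#' @param spot_offset_mm Fixed spot-centre displacement, mm, or `NULL`.
#' @param needle_radius Effective needle radius for exposure accounting, mm.
#' @return An object of class `led_geometry`.
#' @export
led_geometry <- function(mount_offset = 10.6,
                         couple_azimuths = c(0, 90, 180, 270),
                         spot_offset_frac = 0.5, spot_offset_mm = NULL,
                         needle_radius = 0) {
  stopifnot(mount_offset > 0, needle_radius >= 0)
  structure(list(mount_offset = mount_offset,
                 couple_azimuths = as.numeric(couple_azimuths) %% 360,
                 spot_offset_frac = spot_offset_frac,
                 spot_offset_mm = spot_offset_mm,
                 needle_radius = needle_radius),
            class = "led_geometry")
}

spot_offset_of <- function(geom, w_0) {
  if (!is.null(geom$spot_offset_mm)) geom$spot_offset_mm
  else geom$spot_offset_frac * w_0 / 2
}

#' Create an empty exposure grid
#'
#' A raster of accumulated areal light energy (mJ/mm^2) on the substrate
#' plane. Cells are square; values only ever accumulate.
#'
#' @param xlim,ylim Grid extents, mm.
#' @param cell Cell edge length, mm.
#' @return An object of class `exposure_grid` with fields `x`, `y` (cell
#'   centre coordinates), `cell` and `energy` (matrix, rows = x, cols = y).
#' @export
exposure_grid <- function(xlim, ylim, cell = 0.5) {
  stopifnot(cell > 0, diff(xlim) > 0, diff(ylim) > 0)
  nx <- max(1L, ceiling(diff(xlim) / cell))
  ny <- max(1L, ceiling(diff(ylim) / cell))
  x <- xlim[1] + (seq_len(nx) - 0.5) * cell
  y <- ylim[1] + (seq_len(ny) - 0.5) * cell
  structure(list(x = x, y = y, cell = cell,
                 energy = matrix(0, nrow = nx, ncol = ny)),
            class = "exposure_grid")
}

#' @export
print.exposure_grid <- function(x, ...) {
  cat(sprintf("<exposure_grid> %d x %d cells of %.3g mm | total %.4g mJ | peak %.4g mJ/mm^2\n",
              length(x$x), length(x$y), x$cell,
              sum(x$energy) * x$cell^2, max(x$energy)))
  invisible(x)
}

#' Default grid covering a path's illuminated footprint
#'
#' @param path A `toolpath`.
#' @param w_0 Spot diameter, mm.
#' @param geom A [led_geometry()].
#' @param cell Cell size, mm.
#' @param margin Extra margin, mm.
#' @return An `exposure_grid` large enough that no spot ever leaves it.
#' @export
auto_exposure_grid <- function(path, w_0, geom = led_geometry(), cell = 0.5,
                               margin = 0.5) {
  st <- toolpath_stats(path)
  reach <- spot_offset_of(geom, w_0) + w_0 / 2 + margin
  exposure_grid(c(st$bbox["xmin"] - reach, st$bbox["xmax"] + reach),
                c(st$bbox["ymin"] - reach, st$bbox["ymax"] + reach),
                cell = cell)
}

# Analytic dwell time of a moving disk over lattice points.
# Spot centre travels c0 -> c1 over time t_total; for each lattice point the
# time spent within radius r of the centre is the chord interval of the
# segment inside the disk around the point (exact; no time sub-stepping).
disk_dwell <- function(qx, qy, c0, c1, r, t_total) {
  dx <- c1[1] - c0[1]; dy <- c1[2] - c0[2]
  L <- sqrt(dx^2 + dy^2)
  if (L < 1e-12) {
    inside <- (qx - c0[1])^2 + (qy - c0[2])^2 <= r^2
    return(ifelse(inside, t_total, 0))
  }
  ux <- dx / L; uy <- dy / L
  # projection of lattice point onto the centre line, arc-length coordinate
  t_star <- (qx - c0[1]) * ux + (qy - c0[2]) * uy
  d_perp2 <- (qx - c0[1])^2 + (qy - c0[2])^2 - t_star^2
  d_perp2 <- pmax(d_perp2, 0)
  h2 <- r^2 - d_perp2
  h <- sqrt(pmax(h2, 0))
  lo <- pmax(t_star - h, 0)
  hi <- pmin(t_star + h, L)
  len <- pmax(hi - lo, 0)
  len[h2 <= 0] <- 0
  len / L * t_total
}

# Deposit one couple's energy for one move into the grid (in place value
# return). Energy-conserving: the emitted energy P*t is distributed over the
# analytic dwell pattern computed on a virtual lattice aligned with the grid
# but unbounded by it, so cells outside the grid account for lost light and
# the in-grid total never exceeds the emitted energy.
deposit_segment <- function(grid, c0, c1, r, P, t_total, model = "tophat",
                            substeps = 32L) {
  cell <- grid$cell
  x0 <- grid$x[1]; y0 <- grid$y[1]
  xmin <- min(c0[1], c1[1]) - r; xmax <- max(c0[1], c1[1]) + r
  ymin <- min(c0[2], c1[2]) - r; ymax <- max(c0[2], c1[2]) + r
  # virtual lattice indices (may fall outside the stored grid)
  ix <- seq(floor((xmin - x0) / cell), ceiling((xmax - x0) / cell))
  iy <- seq(floor((ymin - y0) / cell), ceiling((ymax - y0) / cell))
  qx <- x0 + ix * cell
  qy <- y0 + iy * cell
  Q <- expand.grid(x = qx, y = qy)
  if (model == "tophat") {
    tau <- disk_dwell(Q$x, Q$y, c0, c1, r, t_total)
  } else {
    # Gaussian spot (1/e^2 radius r): time-quadrature over the sweep
    tau <- numeric(nrow(Q))
    ts <- (seq_len(substeps) - 0.5) / substeps
    dt <- t_total / substeps
    for (s in ts) {
      cx <- c0[1] + s * (c1[1] - c0[1]); cy <- c0[2] + s * (c1[2] - c0[2])
      tau <- tau + exp(-2 * ((Q$x - cx)^2 + (Q$y - cy)^2) / r^2) * dt
    }
  }
  S <- sum(tau) * cell^2
  if (S <= 0) return(grid)
  scale <- P * t_total / S   # mJ/mm^2 per unit dwell
  keep <- which(ix >= 0 & ix < length(grid$x))
  keepy <- which(iy >= 0 & iy < length(grid$y))
  if (length(keep) && length(keepy)) {
    tm <- matrix(tau, nrow = length(ix))
    grid$energy[ix[keep] + 1L, iy[keepy] + 1L] <-
      grid$energy[ix[keep] + 1L, iy[keepy] + 1L] +
      scale * tm[keep, keepy, drop = FALSE]
  }
  grid
}

#' Simulate light energy deposited on the substrate
#'
#' Sweeps the scheduled LED spots along the toolpath and accumulates areal
#' energy on a raster of the substrate plane. Each active couple projects a
#' top-hat disk of diameter `w_0` displaced toward its azimuth (see
#' [led_geometry()]); the dwell of the moving disk over each cell is computed
#' analytically per segment and the deposited energy is normalized so that
#' the total emitted energy `P * t` of each (segment, couple) pair is
#' conserved exactly, cells beyond the grid edge accounting for lost light.
#'
#' @param path A `toolpath`.
#' @param schedule A `led_schedule` covering the path.
#' @param src A [source_params()] (per-couple power `P_L`, spot via
#'   `distance`). Feeds come from the path; `src$v_s` is the default feed for
#'   moves that never received one.
#' @param grid An [exposure_grid()], or `NULL` for an automatic grid that
#'   contains every spot.
#' @param geom A [led_geometry()].
#' @param spot_model `"tophat"` (default, analytic) or `"gaussian"`.
#' @param allow_clip If `FALSE` (default) a user-supplied grid that cannot
#'   contain every spot raises an error stating the required extent; if
#'   `TRUE` the out-of-grid light is silently lost.
#' @return The `exposure_grid` with accumulated energy (mJ/mm^2) and
#'   attribute `emitted_mJ`, the total energy emitted toward the substrate.
#' @export
simulate_substrate_exposure <- function(path, schedule = schedule_path(path),
                                        src = source_params(), grid = NULL,
                                        geom = led_geometry(),
                                        spot_model = c("tophat", "gaussian"),
                                        allow_clip = FALSE) {
  stopifnot(inherits(path, "toolpath"))
  spot_model <- match.arg(spot_model)
  w0 <- src$w_0
  r <- w0 / 2
  off <- spot_offset_of(geom, w0)
  if (is.null(grid)) {
    grid <- auto_exposure_grid(path, w0, geom, cell = 0.5)
  } else if (!allow_clip) {
    st <- toolpath_stats(path)
    reach <- off + r
    need <- c(st$bbox["xmin"] - reach, st$bbox["xmax"] + reach,
              st$bbox["ymin"] - reach, st$bbox["ymax"] + reach)
    have <- c(grid$x[1] - grid$cell / 2, grid$x[length(grid$x)] + grid$cell / 2,
              grid$y[1] - grid$cell / 2, grid$y[length(grid$y)] + grid$cell / 2)
    if (need[1] < have[1] || need[2] > have[2] ||
        need[3] < have[3] || need[4] > have[4])
      stop(sprintf(paste0("grid too small for the illuminated footprint: need ",
                          "x in [%.2f, %.2f], y in [%.2f, %.2f] mm ",
                          "(use allow_clip = TRUE to permit lost light)"),
                   need[1], need[2], need[3], need[4]))
  }
  if (nrow(schedule) != nrow(path$moves))
    stop("schedule does not cover the path")
  feeds <- resolve_feeds(path, default = src$v_s)
  m <- path$moves
  lens <- move_lengths(m)
  emitted <- 0
  conv <- sector_convention(couple_azimuths = geom$couple_azimuths)
  for (i in seq_len(nrow(m))) {
    code <- schedule$code[i]
    if (is.na(code) || code == 0L) next
    t_total <- lens[i] / feeds[i]
    if (!is.finite(t_total) || t_total <= 0) next
    for (a in code_to_azimuths(code, conv)) {
      u <- c(cos(a * pi / 180), sin(a * pi / 180))
      c0 <- c(m$x0[i], m$y0[i]) + off * u
      c1 <- c(m$x1[i], m$y1[i]) + off * u
      grid <- deposit_segment(grid, c0, c1, r, src$P_L, t_total,
                              model = spot_model)
      emitted <- emitted + src$P_L * t_total
    }
  }
  attr(grid, "emitted_mJ") <- emitted
  grid
}

#' Stationary exposure of a single couple
#'
#' Closed-form reference case: the nozzle holds still for `duration` seconds
#' with one couple lit; every cell inside the (displaced) spot accumulates
#' the nominal top-hat dose `P / (pi r^2) * duration`.
#'
#' @param src A [source_params()].
#' @param duration Exposure time, s.
#' @param position Nozzle XY position, mm.
#' @param azimuth Active couple azimuth, degrees.
#' @param grid An [exposure_grid()], or `NULL` for an automatic one.
#' @param geom A [led_geometry()].
#' @return An `exposure_grid` with attribute `emitted_mJ`.
#' @export
simulate_stationary_exposure <- function(src, duration, position = c(0, 0),
                                         azimuth = 180, grid = NULL,
                                         geom = led_geometry()) {
  r <- src$w_0 / 2
  off <- spot_offset_of(geom, src$w_0)
  u <- c(cos(azimuth * pi / 180), sin(azimuth * pi / 180))
  ctr <- position + off * u
  if (is.null(grid))
    grid <- exposure_grid(ctr[1] + c(-r - 1, r + 1), ctr[2] + c(-r - 1, r + 1),
                          cell = 0.25)
  grid <- deposit_segment(grid, ctr, ctr, r, src$P_L, duration)
  attr(grid, "emitted_mJ") <- src$P_L * duration
  grid
}

#' Light energy incident on the needle tip
#'
#' Tracks the needle tip at the nozzle XY position along the path. An active
#' couple exposes the needle whenever the tip lies within its spot (spot
#' centre displacement vs. spot radius plus the effective needle radius); the
#' contribution is the nominal top-hat irradiance `P / (pi r^2)` integrated
#' over the segment dwell time. Stray light on the tip polymerizes ink inside
#' the nozzle, so schedules are ranked by this total.
#'
#' @param path A `toolpath`.
#' @param schedule A `led_schedule` covering the path, or the result of
#'   [all_on_schedule()] / [off_schedule()].
#' @param src A [source_params()].
#' @param geom A [led_geometry()].
#' @return Object of class `needle_report`: per-move table `contributions`
#'   (`move`, `duration_s`, `n_couples`, `energy`), and `total` (mJ/mm^2).
#' @export
needle_incident_energy <- function(path, schedule = schedule_path(path),
                                   src = source_params(),
                                   geom = led_geometry()) {
  stopifnot(inherits(path, "toolpath"))
  if (nrow(schedule) != nrow(path$moves))
    stop("schedule does not cover the path")
  r <- src$w_0 / 2
  off <- spot_offset_of(geom, src$w_0)
  needle_in_spot <- off <= r + geom$needle_radius
  irr <- src$P_L / (pi * r^2)   # mW/mm^2 per active couple
  feeds <- resolve_feeds(path, default = src$v_s)
  lens <- move_lengths(path$moves)
  dur <- lens / feeds
  dur[!is.finite(dur)] <- 0
  ncp <- vapply(schedule$code, function(cd) {
    if (is.na(cd) || cd == 0L) 0L else length(code_to_azimuths(cd))
  }, integer(1))
  energy <- if (needle_in_spot) irr * dur * ncp else rep(0, length(dur))
  tab <- data.frame(move = seq_along(dur), duration_s = dur,
                    n_couples = ncp, energy = energy)
  structure(list(contributions = tab, total = sum(energy),
                 needle_in_spot = needle_in_spot),
            class = "needle_report")
}

#' @export
print.needle_report <- function(x, ...) {
  cat(sprintf("<needle_report> total %.4g mJ/mm^2 over %d moves%s\n",
              x$total, nrow(x$contributions),
              if (!x$needle_in_spot) " (needle outside every spot)" else ""))
  invisible(x)
}

#' All-on control schedule (code 9 on every move)
#'
#' Reproduces the control configuration with every LED lit for the whole
#' print — the configuration under which the needle clogs immediately.
#'
#' @param path A `toolpath`.
#' @return A `led_schedule`.
#' @export
all_on_schedule <- function(path) {
  s <- schedule_path(path)
  s$code <- 9L
  s$n_couples <- 4L
  s
}

#' All-off schedule (code 0 on every move)
#'
#' @param path A `toolpath`.
#' @return A `led_schedule`.
#' @export
off_schedule <- function(path) {
  s <- schedule_path(path)
  s$code <- 0L
  s$n_couples <- 0L
  s
}

#' Compare the needle exposure of two schedules
#'
#' @param path A `toolpath`.
#' @param schedule_a,schedule_b Schedules covering the path.
#' @param src A [source_params()].
#' @param geom A [led_geometry()].
#' @return List with `ratio` (needle energy A / B; `Inf` with
#'   `zero_denominator = TRUE` when B receives none while A does, `NaN` when
#'   neither receives any), totals, and a per-move `table`.
#' @export
compare_schedules <- function(path, schedule_a, schedule_b,
                              src = source_params(), geom = led_geometry()) {
  ra <- needle_incident_energy(path, schedule_a, src, geom)
  rb <- needle_incident_energy(path, schedule_b, src, geom)
  ratio <- if (rb$total > 0) ra$total / rb$total
           else if (ra$total > 0) Inf else NaN
  tab <- data.frame(move = ra$contributions$move,
                    energy_a = ra$contributions$energy,
                    energy_b = rb$contributions$energy)
  list(ratio = ratio, total_a = ra$total, total_b = rb$total,
       zero_denominator = rb$total == 0, table = tab)
}

#' Export an exposure grid as a CSV matrix
#'
#' @param grid An `exposure_grid`.
#' @param file Output file.
#' @export
write_exposure_csv <- function(grid, file) {
  stopifnot(inherits(grid, "exposure_grid"))
  m <- t(grid$energy)  # rows = y for a conventional image orientation
  colnames(m) <- format(grid$x)
  utils::write.csv(data.frame(y = grid$y, m, check.names = FALSE), file,
                   row.names = FALSE)
  invisible(file)
}
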