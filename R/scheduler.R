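#' Sector convention for direction classification
#'
#' The XY plane is divided into eight 45-degree angular sectors. Sectors are
#' centred on the eight principal directions (0, 45, ..., 315 degrees,
#' counterclockwise from the machine +x axis) with half-open boundaries
#' `[centre - 22.5, centre + 22.5)`, so cardinal and diagonal motion are
#' treated symmetrically. Each sector maps to a numeric LED code (default
#' `code = sector + 1`, i.e. codes 1..8) sent to the controller as
#' `M102 P<code>`; the mapping table is configurable so the software
#' convention can be matched to the physical wiring of the device.
#'
#' @param centers Sector centre angles in degrees, counterclockwise from +x.
#' @param half_width Sector half-width in degrees (45/2 for eight sectors).
#' @param code_map Integer vector: `code_map[k]` is the LED code of sector
#'   `k - 1`. Must be a bijection onto 1..8 for eight sectors.
#' @param couple_azimuths Azimuths (degrees) of the four LED couples mounted
#'   around the needle, at 90 degrees from each other.
#' @return An object of class `sector_convention`.
#' @export
sector_convention <- function(centers = seq(0, 315, by = 45),
                              half_width = 22.5,
                              code_map = seq_along(centers),
                              couple_azimuths = c(0, 90, 180, 270)) {
  centers <- as.numeric(centers) %% 360
  if (length(code_map) != length(centers) ||
      !setequal(code_map, seq_along(centers)))
    stop("code_map must be a bijection from sectors onto 1..", length(centers))
  if (abs(2 * half_width * length(centers) - 360) > 1e-9)
    stop("sectors must tile the full circle: 2 * half_width * n == 360")
  structure(list(centers = centers, half_width = half_width,
                 code_map = as.integer(code_map),
                 couple_azimuths = as.numeric(couple_azimuths) %% 360),
            class = "sector_convention")
}

#' XY direction versor of a print move
#'
#' Projects the move onto the XY plane (the Z component of the motion is
#' ignored) and returns the unit direction vector together with its polar
#' angle, measured counterclockwise from the machine +x axis. Moves with no
#' XY displacement (pure-Z hops, zero-length segments) are flagged degenerate.
#'
#' @param move One-row move data.frame (or list) with `x0,y0,x1,y1` and `kind`.
#' @param tol XY displacement below which the move counts as degenerate (mm).
#' @return List with `vx`, `vy` (unit vector), `theta` (degrees in \[0, 360))
#'   and `degenerate` (logical). For degenerate moves the vector and angle are
#'   `NA`.
#' @export
xy_direction <- function(move, tol = 1e-9) {
  if (!is.null(move$kind) && move$kind != "print")
    stop("xy_direction is defined for print moves only")
  dx <- move$x1 - move$x0
  dy <- move$y1 - move$y0
  len <- sqrt(dx^2 + dy^2)
  if (len < tol)
    return(list(vx = NA_real_, vy = NA_real_, theta = NA_real_,
                degenerate = TRUE))
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  list(vx = dx / len, vy = dy / len, theta = theta, degenerate = FALSE)
}

#' Classify a polar angle into an angular sector
#'
#' Sector `k` covers the half-open arc `[center_k - hw, center_k + hw)`
#' modulo 360. Vectorized over `theta`.
#'
#' @param theta Angle(s) in degrees, any real value (reduced modulo 360).
#' @param conv A [sector_convention()].
#' @return Integer sector index/indices in `0..(n_sectors - 1)`.
#' @export
classify_sector <- function(theta, conv = sector_convention()) {
  theta <- as.numeric(theta) %% 360
  hw <- conv$half_width
  # signed angular difference to each centre, in [-180, 180)
  d <- outer(theta, conv$centers, function(t, c) ((t - c + 180) %% 360) - 180)
  hit <- d >= -hw & d < hw
  sec <- max.col(hit, ties.method = "first") - 1L
  if (any(rowSums(hit) != 1L))
    stop("sector convention does not partition the circle at theta = ",
         theta[which(rowSums(hit) != 1L)[1]])
  sec
}

#' Active LED couples for a sector
#'
#' The couple(s) opposite the printing direction are switched on, curing the
#' strand just deposited behind the moving needle. For a cardinal sector
#' (direction along a machine axis) that is the single couple at
#' `(centre + 180) mod 360`; for a diagonal sector it is the two couples
#' flanking the opposite diagonal.
#'
#' @param sector Integer sector index in `0..7`.
#' @param conv A [sector_convention()].
#' @return List with `azimuths` (couple azimuths in degrees), `n_couples`
#'   and `code` (the `M102` numeric code of the sector).
#' @export
sector_to_leds <- function(sector, conv = sector_convention()) {
  if (length(sector) != 1L || sector != round(sector) ||
      sector < 0 || sector >= length(conv$centers))
    stop("sector must be a single integer in 0..", length(conv$centers) - 1L)
  opp <- (conv$centers[sector + 1L] + 180) %% 360
  az <- conv$couple_azimuths
  on_axis <- abs(((opp - az + 180) %% 360) - 180) < 1e-9
  if (any(on_axis)) {
    act <- az[on_axis]
  } else {
    # diagonal: the two couples adjacent to the opposite direction
    d <- abs(((opp - az + 180) %% 360) - 180)
    act <- sort(az[order(d)[1:2]])
  }
  list(azimuths = act, n_couples = length(act),
       code = conv$code_map[sector + 1L])
}

#' Schedule LED codes along a toolpath
#'
#' Walks the ordered moves of the path; every non-degenerate print move is
#' classified by its XY direction versor and assigned the LED code of its
#' sector. Travel moves and degenerate segments (pure-Z) hold the previous
#' LED state, avoiding flicker mid-layer; segments before the first
#' classifiable print move get code 0 (all off).
#'
#' @param path A `toolpath`.
#' @param conv A [sector_convention()].
#' @param off_on_travel If `TRUE`, travel moves are assigned code 0 instead of
#'   holding the previous state.
#' @return A data.frame of class `led_schedule` with one row per move:
#'   `move`, `kind`, `degenerate`, `vx`, `vy`, `theta`, `sector`, `code`,
#'   `n_couples`.
#' @export
schedule_path <- function(path, conv = sector_convention(),
                          off_on_travel = FALSE) {
  stopifnot(inherits(path, "toolpath"))
  m <- path$moves
  n <- nrow(m)
  out <- data.frame(move = seq_len(n), kind = m$kind, degenerate = NA,
                    vx = NA_real_, vy = NA_real_, theta = NA_real_,
                    sector = NA_integer_, code = NA_integer_,
                    n_couples = NA_integer_)
  if (n == 0L) {
    class(out) <- c("led_schedule", "data.frame")
    return(out)
  }
  prev_code <- 0L
  prev_n <- 0L
  for (i in seq_len(n)) {
    if (m$kind[i] == "print") {
      d <- xy_direction(m[i, ])
      out$degenerate[i] <- d$degenerate
      if (!d$degenerate) {
        sec <- classify_sector(d$theta, conv)
        leds <- sector_to_leds(sec, conv)
        out[i, c("vx", "vy", "theta")] <- list(d$vx, d$vy, d$theta)
        out$sector[i] <- sec
        out$code[i] <- leds$code
        out$n_couples[i] <- leds$n_couples
        prev_code <- leds$code
        prev_n <- leds$n_couples
      } else {
        out$code[i] <- prev_code
        out$n_couples[i] <- prev_n
      }
    } else {
      out$degenerate[i] <- FALSE
      if (off_on_travel) {
        out$code[i] <- 0L
        out$n_couples[i] <- 0L
        prev_code <- 0L
        prev_n <- 0L
      } else {
        out$code[i] <- prev_code
        out$n_couples[i] <- prev_n
      }
    }
  }
  class(out) <- c("led_schedule", "data.frame")
  out
}

#' Azimuths of the couples active under a numeric LED code
#'
#' Code 0 means all off and code 9 all four couples on (the all-on control
#' configuration); codes 1..8 are the per-sector combinations.
#'
#' @param code Integer code in 0..9.
#' @param conv A [sector_convention()].
#' @return Numeric vector of active couple azimuths (degrees), possibly empty.
#' @export
code_to_azimuths <- function(code, conv = sector_convention()) {
  if (length(code) != 1L || is.na(code) || code != round(code) ||
      code < 0 || code > 9)
    stop("code must be an integer in 0..9")
  if (code == 0) return(numeric(0))
  if (code == 9) return(conv$couple_azimuths)
  sector <- which(conv$code_map == code) - 1L
  sector_to_leds(sector, conv)$azimuths
}

#' Inject LED commands into a toolpath's G-code
#'
#' Converts a schedule into `M102` commands (one wherever the code changes,
#' starting at the first move) and delegates to [emit_gcode()]. In all-on
#' control mode a single `M102 P9` is emitted instead, reproducing the
#' configuration in which every LED is lit for the whole print.
#'
#' @param path A `toolpath`.
#' @param schedule A `led_schedule` covering the path (ignored when
#'   `all_on = TRUE`).
#' @param all_on Emit the all-on control schedule instead.
#' @param trailing_off Append a final `M102 P0` after the last move.
#' @return Character vector of G-code lines.
#' @export
inject_led_commands <- function(path, schedule = schedule_path(path),
                                all_on = FALSE, trailing_off = FALSE) {
  stopifnot(inherits(path, "toolpath"))
  n <- nrow(path$moves)
  if (all_on) {
    cmds <- data.frame(move = if (n > 0L) 1L else integer(0),
                       code = if (n > 0L) 9L else integer(0))
    return(emit_gcode(path, cmds, trailing_off = trailing_off))
  }
  if (nrow(schedule) != n)
    stop("schedule does not cover the path (", nrow(schedule), " rows for ",
         n, " moves)")
  emit_gcode(path, data.frame(move = schedule$move, code = schedule$code),
             trailing_off = trailing_off)
}
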