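#' Resin photopolymerization parameters
#'
#' Working-curve parameters of the photo-crosslinkable ink: the penetration
#' depth `D_p` (mm), the exponential attenuation scale of light in the resin,
#' and the critical energy `E_c` (mJ/mm^2), the minimum areal exposure for
#' gelation. Defaults are the values for 5% w/v GelMA + 0.5% w/v LAP at
#' 405 nm.
#'
#' @param D_p Penetration depth, mm (> 0). Default 0.61.
#' @param E_c Critical energy, mJ/mm^2 (> 0). Default 0.48.
#' @return An object of class `resin_params`.
#' @export
resin_params <- function(D_p = 0.61, E_c = 0.48) {
  if (!is.numeric(D_p) || D_p <= 0) stop("D_p must be positive (mm)")
  if (!is.numeric(E_c) || E_c <= 0) stop("E_c must be positive (mJ/mm^2)")
  structure(list(D_p = D_p, E_c = E_c), class = "resin_params")
}

#' Luminous spot diameter on the substrate
#'
#' The slider lets the LED ring sit between 1 and 15 mm above the printing
#' substrate; the spot a couple projects grows linearly from 10 mm diameter
#' at the minimum distance to 20 mm at the maximum. Only the two endpoints
#' are characterized, so the model interpolates linearly between them.
#'
#' @param distance LED-substrate distance, mm, in \[1, 15\].
#' @return Spot diameter `w_0` in mm.
#' @export
spot_diameter <- function(distance) {
  if (any(!is.finite(distance) | distance < 1 | distance > 15))
    stop("LED-substrate distance must lie in [1, 15] mm")
  10 + (distance - 1) * (20 - 10) / (15 - 1)
}

#' Light source parameters for the cure model
#'
#' @param P_L Optical power of the active couple(s), mW. A single LED emits
#'   30 mW, a couple 60 mW; a diagonal segment drives two couples (120 mW).
#' @param v_s Scanning speed (the printing speed), mm/s.
#' @param distance LED-substrate distance, mm in \[1, 15\].
#' @param w_0 Spot diameter on the substrate, mm. Defaults to
#'   [spot_diameter()] of `distance`; if supplied explicitly it must agree
#'   with the distance model.
#' @param kappa Dimensionless exposure prefactor of the working-curve model
#'   (see [peak_exposure()]); default 1. Use [calibrate_kappa()] to anchor it
#'   to a characterized cure depth.
#' @return An object of class `source_params`.
#' @export
source_params <- function(P_L = 60, v_s = 5, distance = 15,
                          w_0 = spot_diameter(distance), kappa = 1) {
  if (P_L < 0) stop("P_L must be non-negative (mW)")
  if (v_s <= 0) stop("v_s must be positive (mm/s)")
  if (w_0 <= 0) stop("w_0 must be positive (mm)")
  if (kappa <= 0) stop("kappa must be positive")
  if (abs(w_0 - spot_diameter(distance)) > 1e-6)
    stop("w_0 = ", w_0, " mm is inconsistent with distance = ", distance,
         " mm (spot model gives ", spot_diameter(distance), " mm)")
  structure(list(P_L = P_L, v_s = v_s, distance = distance, w_0 = w_0,
                 kappa = kappa), class = "source_params")
}

#' Areal exposure delivered by a scanning light spot
#'
#' The exposure entering the working curve is modeled as
#' `E = kappa * P_L / (w_0 * v_s)` (mJ/mm^2): power spread over a strip of
#' width `w_0` swept at speed `v_s`, with `kappa` a dimensionless prefactor
#' absorbing the spot's irradiance profile and the dwell geometry. `kappa` is
#' calibrated against a characterized cure depth (see [calibrate_kappa()]).
#'
#' @param src A [source_params()].
#' @return Exposure in mJ/mm^2.
#' @export
peak_exposure <- function(src) {
  stopifnot(inherits(src, "source_params"))
  src$kappa * src$P_L / (src$w_0 * src$v_s)
}

#' Cure depth of the working curve
#'
#' Depth of polymerized material under exposure `E`:
#' `C_d = D_p * ln(E / E_c)`. Exposures at or below the critical energy cure
#' nothing; the returned depth is clamped at 0 and flagged via the `no_cure`
#' attribute.
#'
#' @param resin A [resin_params()].
#' @param src A [source_params()], or a numeric exposure in mJ/mm^2.
#' @return Cure depth in mm (>= 0), with attribute `no_cure` (logical).
#' @export
cure_depth <- function(resin, src) {
  stopifnot(inherits(resin, "resin_params"))
  E <- if (inherits(src, "source_params")) peak_exposure(src) else as.numeric(src)
  if (any(E <= 0)) stop("exposure must be positive to evaluate the working curve")
  cd <- resin$D_p * log(E / resin$E_c)
  no_cure <- cd <= 0
  cd[no_cure] <- 0
  attr(cd, "no_cure") <- no_cure
  cd
}

#' Calibrate the exposure prefactor against a characterized cure depth
#'
#' Solves `C_d_ref = D_p * ln(kappa * P_L / (w_0 * v_s) / E_c)` for `kappa`.
#' The default anchor is the characterized worst-case operating point of the
#' device: a single couple (60 mW) at the maximum LED-substrate distance
#' (spot diameter 20 mm) scanning at 5 mm/s, which cures 0.34 mm of 5% GelMA
#' + 0.5% LAP.
#'
#' @param resin A [resin_params()].
#' @param C_d_ref Characterized cure depth at the anchor point, mm.
#' @param P_L,w_0,v_s Anchor operating point (mW, mm, mm/s).
#' @return The dimensionless prefactor `kappa`.
#' @export
calibrate_kappa <- function(resin = resin_params(), C_d_ref = 0.34,
                            P_L = 60, w_0 = 20, v_s = 5) {
  stopifnot(inherits(resin, "resin_params"))
  if (C_d_ref < 0) stop("C_d_ref must be non-negative")
  resin$E_c * exp(C_d_ref / resin$D_p) * w_0 * v_s / P_L
}

#' Verify per-segment curing along a scheduled toolpath
#'
#' Evaluates the working curve for every print move of the path: the scanning
#' speed is the move's feed, the couple power follows the schedule (two
#' couples on diagonal segments double `P_L`), and the spot diameter follows
#' the LED-substrate distance. A segment passes when its cure depth is at
#' least the layer thickness, guaranteeing that each deposited layer
#' polymerizes through and bonds to the one below.
#'
#' @param path A `toolpath`.
#' @param schedule A `led_schedule` covering the path; default computed.
#' @param resin A [resin_params()].
#' @param distance LED-substrate distance, mm in \[1, 15\].
#' @param power_per_couple Optical power of one couple, mW (two 30 mW LEDs).
#' @param kappa Exposure prefactor; `NULL` (default) uses
#'   [calibrate_kappa()] with its characterized anchor.
#' @param default_feed Feed (mm/s) for moves before the first explicit feed.
#' @return An object of class `cure_report`: per-segment table (`segments`)
#'   plus summary fields `all_pass`, `worst_move`, `min_C_d`,
#'   `layer_thickness`, `distance`, `kappa`.
#' @export
check_cure_path <- function(path, schedule = schedule_path(path),
                            resin = resin_params(), distance = 15,
                            power_per_couple = 60, kappa = NULL,
                            default_feed = NULL) {
  stopifnot(inherits(path, "toolpath"))
  if (is.null(kappa)) kappa <- calibrate_kappa(resin)
  if (nrow(schedule) != nrow(path$moves))
    stop("schedule does not cover the path")
  w0 <- spot_diameter(distance)
  feeds <- resolve_feeds(path, default = default_feed)
  idx <- which(path$moves$kind == "print")
  if (length(idx) == 0L) stop("path has no print moves")
  nc <- schedule$n_couples[idx]
  nc[is.na(nc) | nc == 0L] <- NA_integer_
  if (any(is.na(feeds[idx])))
    stop("print move ", idx[which(is.na(feeds[idx]))[1]],
         " has no feed rate; supply one in the path or via default_feed")
  P <- power_per_couple * nc
  E <- kappa * P / (w0 * feeds[idx])
  cd <- rep(NA_real_, length(idx))
  no_cure <- rep(TRUE, length(idx))
  pos <- which(!is.na(E) & E > 0)
  if (length(pos)) {
    d <- cure_depth(resin, E[pos])
    cd[pos] <- as.numeric(d)
    no_cure[pos] <- attr(d, "no_cure")
  }
  cd[is.na(cd)] <- 0
  seg <- data.frame(move = idx, v_s = feeds[idx], n_couples = nc,
                    P_L = P, E = E, C_d = cd, no_cure = no_cure,
                    pass = cd >= path$layer_thickness)
  worst <- seg$move[which.min(seg$C_d)]
  structure(list(segments = seg, all_pass = all(seg$pass),
                 worst_move = worst, min_C_d = min(seg$C_d),
                 layer_thickness = path$layer_thickness,
                 distance = distance, kappa = kappa),
            class = "cure_report")
}

#' @export
print.cure_report <- function(x, ...) {
  cat(sprintf("<cure_report> %d print segments | layer %.3g mm | distance %.3g mm\n",
              nrow(x$segments), x$layer_thickness, x$distance))
  cat(sprintf("  %s | min C_d = %.3f mm at move %d\n",
              if (x$all_pass) "PASS: every segment cures through the layer"
              else "FAIL: some segments undercure",
              x$min_C_d, x$worst_move))
  invisible(x)
}

#' Serialize a cure report to JSON
#'
#' @param report A `cure_report`.
#' @param file Output file, or `NULL` to return the JSON string.
#' @return The file path (invisibly) or a JSON string.
#' @export
write_cure_report_json <- function(report, file = NULL) {
  stopifnot(inherits(report, "cure_report"))
  obj <- list(summary = list(all_pass = report$all_pass,
                             worst_move = report$worst_move,
                             min_C_d_mm = report$min_C_d,
                             layer_thickness_mm = report$layer_thickness,
                             distance_mm = report$distance,
                             kappa = report$kappa),
              segments = report$segments)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (is.null(file)) return(as.character(js))
  writeLines(js, file)
  invisible(file)
}
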