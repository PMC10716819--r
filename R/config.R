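#' Hardware configuration of the photo-crosslinking device
#'
#' Bundles every tunable of the device and ink in one object: the LED ring
#' geometry, the slider (LED-substrate) distance, the per-couple optical
#' power, the sector convention of the scheduling software and the resin
#' working-curve parameters.
#'
#' @param distance LED-substrate distance, mm in \[1, 15\] (slider position).
#' @param power_per_couple Optical power of one LED couple, mW.
#' @param mount_offset LED couple distance from the needle axis, mm.
#' @param couple_azimuths Azimuths of the four couples, degrees.
#' @param D_p,E_c Resin working-curve parameters (mm, mJ/mm^2).
#' @param kappa Exposure prefactor; `NULL` uses the calibrated default.
#' @param sector_centers,code_map Sector convention (see
#'   [sector_convention()]).
#' @return Object of class `hardware_config`.
#' @export
hardware_config <- function(distance = 15, power_per_couple = 60,
                            mount_offset = 10.6,
                            couple_azimuths = c(0, 90, 180, 270),
                            D_p = 0.61, E_c = 0.48, kappa = NULL,
                            sector_centers = seq(0, 315, by = 45),
                            code_map = seq_along(sector_centers)) {
  if (distance < 1 || distance > 15)
    stop("slider distance must lie in [1, 15] mm")
  resin <- resin_params(D_p, E_c)
  if (is.null(kappa)) kappa <- calibrate_kappa(resin)
  structure(list(distance = distance, power_per_couple = power_per_couple,
                 mount_offset = mount_offset,
                 couple_azimuths = couple_azimuths,
                 resin = resin, kappa = kappa,
                 convention = sector_convention(centers = sector_centers,
                                                code_map = code_map,
                                                couple_azimuths = couple_azimuths)),
            class = "hardware_config")
}

#' @export
print.hardware_config <- function(x, ...) {
  cat(sprintf("<hardware_config> distance %.3g mm (spot %.3g mm) | %g mW/couple | kappa %.4g\n",
              x$distance, spot_diameter(x$distance), x$power_per_couple,
              x$kappa))
  cat(sprintf("  resin: D_p %.3g mm, E_c %.3g mJ/mm^2 | couples at %s deg\n",
              x$resin$D_p, x$resin$E_c,
              paste(x$couple_azimuths, collapse = "/")))
  invisible(x)
}

#' Read a hardware configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [hardware_config()]; missing keys
#' fall back to the defaults.
#'
#' @param file YAML file path.
#' @return A `hardware_config`.
#' @export
read_hardware_config <- function(file) {
  y <- yaml::read_yaml(file)
  allowed <- names(formals(hardware_config))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(hardware_config, y)
}

#' Write a hardware configuration to a YAML file
#'
#' @param config A `hardware_config`.
#' @param file Output path.
#' @export
write_hardware_config <- function(config, file) {
  stopifnot(inherits(config, "hardware_config"))
  yaml::write_yaml(list(distance = config$distance,
                        power_per_couple = config$power_per_couple,
                        mount_offset = config$mount_offset,
                        couple_azimuths = config$couple_azimuths,
                        D_p = config$resin$D_p, E_c = config$resin$E_c,
                        kappa = config$kappa,
                        sector_centers = config$convention$centers,
                        code_map = config$convention$code_map),
                   file)
  invisible(file)
}
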