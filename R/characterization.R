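#' Swelling percentage
#'
#' Relative weight change of a hydrogel sample immersed in water:
#' `100 * (W_i - W_0) / W_0`, where `W_i` is the weight at the i-th time
#' point and `W_0` the initial weight. Negative values (deswelling) are
#' allowed. Scale-invariant: the units of weight cancel.
#'
#' @param W_i Weight(s) at the measurement time point(s), mg.
#' @param W_0 Initial weight, mg (> 0).
#' @return Swelling percentage(s).
#' @export
swelling_percent <- function(W_i, W_0) {
  if (!is.numeric(W_0) || length(W_0) != 1L || !is.finite(W_0) || W_0 <= 0)
    stop("W_0 must be a single positive weight")
  100 * (W_i - W_0) / W_0
}

#' A single swelling time series
#'
#' @param time Time points, hours, strictly increasing.
#' @param weight Weights at each time point, mg.
#' @param W_0 Initial (pre-immersion) weight, mg.
#' @return Object of class `swelling_series` with the computed swelling
#'   percentages.
#' @export
swelling_series <- function(time, weight, W_0) {
  if (length(time) != length(weight)) stop("time and weight lengths differ")
  if (any(diff(time) <= 0)) stop("time points must be strictly increasing")
  structure(list(time = as.numeric(time), weight = as.numeric(weight),
                 W_0 = W_0, swelling = swelling_percent(weight, W_0)),
            class = "swelling_series")
}

#' Summarize replicate swelling series and detect the plateau
#'
#' All series must share the same time grid. Returns the per-time mean and
#' standard deviation of the swelling percentage and the plateau onset: the
#' first time point at which the mean changes by less than `tol` percentage
#' points from the previous time point.
#'
#' @param series List of [swelling_series()] objects (one per replicate).
#' @param tol Plateau tolerance in swelling percentage points between
#'   successive time points.
#' @return List of class `swelling_summary`: `table` (time, mean, sd, n) and
#'   `plateau_time` (hours; `NA` if never reached).
#' @export
swelling_summary <- function(series, tol = 0.5) {
  if (!length(series)) stop("need at least one swelling series")
  if (inherits(series, "swelling_series")) series <- list(series)
  grid <- series[[1]]$time
  for (s in series)
    if (length(s$time) != length(grid) || any(abs(s$time - grid) > 1e-9))
      stop("all series must share the same time grid")
  sw <- do.call(rbind, lapply(series, function(s) s$swelling))
  mu <- colMeans(sw)
  sdv <- if (nrow(sw) > 1L) apply(sw, 2, stats::sd) else rep(0, ncol(sw))
  tab <- data.frame(time_h = grid, mean = mu, sd = sdv, n = nrow(sw))
  plateau <- NA_real_
  if (length(grid) > 1L) {
    flat <- abs(diff(mu)) < tol
    if (any(flat)) plateau <- grid[which(flat)[1] + 1L]
  }
  structure(list(table = tab, plateau_time = plateau, tol = tol),
            class = "swelling_summary")
}

#' @export
print.swelling_summary <- function(x, ...) {
  cat(sprintf("<swelling_summary> %d time points, n = %d replicates\n",
              nrow(x$table), x$table$n[1]))
  print(format(x$table, digits = 3), row.names = FALSE)
  cat(if (is.na(x$plateau_time)) "no plateau reached\n"
      else sprintf("plateau from %.2g h (mean change < %.2g%% per step)\n",
                   x$plateau_time, x$tol))
  invisible(x)
}

#' Elastic modulus from a compression stress-strain curve
#'
#' Least-squares slope of stress against strain over the linear portion of
#' the curve. If no window is given, the linear portion is found by a
#' lack-of-fit rule: the measurement noise variance is estimated from the
#' second differences of the stress series (which annihilate any local
#' linear trend), and the widest contiguous run of at least `min_points`
#' samples whose residual mean square stays within `lof_factor` times that
#' noise level is selected (ties broken by the smaller residual). This
#' rejects the low-strain toe region typical of hydrogel compression tests
#' — toe points produce structural residuals far above the noise floor —
#' while tolerating genuinely noisy but linear data, which no fixed
#' r-squared cutoff can do at both ends.
#'
#' @param strain Strain values, dimensionless fraction (or percent with
#'   `strain_unit = "percent"`), non-decreasing, within \[0, 0.30\].
#' @param stress Stress values, kPa, paired with `strain`.
#' @param window Numeric length-2 strain range (fraction) of the linear
#'   portion, or `NULL` for automatic selection.
#' @param strain_unit `"fraction"` (default) or `"percent"`.
#' @param lof_factor Lack-of-fit tolerance: a window is linear when its
#'   residual mean square is at most `lof_factor` times the estimated noise
#'   variance.
#' @param min_points Minimum points in the fit window.
#' @return List of class `modulus_fit`: `modulus_kPa`, `intercept_kPa`, `r2`,
#'   `window` (strain range used), `n` and the `lm` fit.
#' @export
elastic_modulus <- function(strain, stress, window = NULL,
                            strain_unit = c("fraction", "percent"),
                            lof_factor = 2, min_points = 3L) {
  strain_unit <- match.arg(strain_unit)
  if (strain_unit == "percent") strain <- strain / 100
  if (length(strain) != length(stress)) stop("strain and stress lengths differ")
  if (any(diff(strain) < 0)) stop("strain must be non-decreasing")
  if (any(strain < -1e-9 | strain > 0.30 + 1e-9))
    stop("strain must lie within [0, 0.30] (compression to 30% of height)")
  fit_range <- function(i, j) {
    f <- stats::lm(stress[i:j] ~ strain[i:j])
    r2 <- suppressWarnings(summary(f)$r.squared)
    list(fit = f, r2 = if (is.na(r2)) 0 else r2,
         rms = mean(stats::residuals(f)^2), i = i, j = j)
  }
  if (!is.null(window)) {
    sel <- which(strain >= window[1] - 1e-12 & strain <= window[2] + 1e-12)
    if (length(sel) < min_points)
      stop("fewer than ", min_points, " points in the requested strain window")
    best <- fit_range(min(sel), max(sel))
  } else {
    n <- length(strain)
    if (n < min_points) stop("need at least ", min_points, " points")
    # noise floor from second differences (kills any local linear trend);
    # the floor never drops below machine-level scale so exact data pass
    d2 <- diff(stress, differences = 2)
    sigma2 <- if (length(d2)) mean(d2^2) / 6 else 0
    tol <- max(lof_factor * sigma2, (1e-8 * max(abs(stress)))^2)
    best <- NULL
    for (width in seq(n, min_points)) {      # widest first
      cands <- list()
      for (i in seq_len(n - width + 1L)) {
        fr <- fit_range(i, i + width - 1L)
        if (fr$rms <= tol) cands[[length(cands) + 1L]] <- fr
      }
      if (length(cands)) {
        best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "rms"))]]
        break
      }
    }
    if (is.null(best))
      stop("no contiguous run of >= ", min_points,
           " points is linear within the lack-of-fit tolerance; ",
           "supply the linear window explicitly")
  }
  co <- stats::coef(best$fit)
  structure(list(modulus_kPa = unname(co[2]), intercept_kPa = unname(co[1]),
                 r2 = best$r2,
                 window = c(strain[best$i], strain[best$j]),
                 n = best$j - best$i + 1L, fit = best$fit),
            class = "modulus_fit")
}

#' @export
print.modulus_fit <- function(x, ...) {
  cat(sprintf("<modulus_fit> E = %.2f kPa (r^2 = %.4f, %d points, strain %.3f-%.3f)\n",
              x$modulus_kPa, x$r2, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Read swelling replicates from CSV
#'
#' Expected columns: `time` (h), `weight` (mg) and optionally `replicate`.
#' The weight at the earliest time point of each replicate is taken as `W_0`
#' unless a `w0` column is present.
#'
#' @param file CSV file path.
#' @return List of [swelling_series()], one per replicate.
#' @export
read_swelling_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  if (!all(c("time", "weight") %in% names(d)))
    stop("CSV must have columns time, weight")
  if (!("replicate" %in% names(d))) d$replicate <- 1L
  lapply(split(d, d$replicate), function(g) {
    g <- g[order(g$time), ]
    W0 <- if ("w0" %in% names(g)) g$w0[1] else g$weight[1]
    swelling_series(g$time, g$weight, W0)
  })
}

#' Read a stress-strain curve from CSV
#'
#' Expected columns: `strain` and `stress` (kPa), optionally `replicate`.
#'
#' @param file CSV file path.
#' @param strain_unit `"fraction"` or `"percent"`.
#' @return data.frame ordered by strain with columns `strain` (fraction),
#'   `stress`, `replicate`.
#' @export
read_stress_strain_csv <- function(file, strain_unit = c("fraction", "percent")) {
  strain_unit <- match.arg(strain_unit)
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  if (!all(c("strain", "stress") %in% names(d)))
    stop("CSV must have columns strain, stress")
  if (strain_unit == "percent") d$strain <- d$strain / 100
  if (!("replicate" %in% names(d))) d$replicate <- 1L
  d[order(d$replicate, d$strain), c("strain", "stress", "replicate")]
}
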