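# Ratiometric read-out: intensity-weighted log-ratio extraction and the
# monotone calibration curve mapping green/red ratios to pH.

window_indices <- function(dim_n, center, scale) {
  lo <- max(1L, as.integer(round(center)) - as.integer(scale))
  hi <- min(dim_n, as.integer(round(center)) + as.integer(scale))
  lo:hi
}

#' Extract the green/red intensity ratio at a detection
#'
#' For each channel the estimator averages `log(I)` weighted by the
#' intensity `I` itself over a square window of side `2*scale + 1`:
#' `W_C = sum(I_C * log(I_C)) / sum(I_C)`, and returns
#' `exp(W_G - W_R)`.  Bright probe pixels dominate the average, which
#' makes the read-out nearly independent of the window scale and exactly
#' invariant under joint rescaling of both channels.  Zero-intensity
#' pixels carry zero weight; intensities are floored at one quantization
#' unit before the logarithm.
#'
#' @param frame a list with matrices `green` and `red`.
#' @param center detection position `c(row, col)`.
#' @param scale window half-width, pixels.
#' @return the ratio (positive scalar); `NA` with a warning if a channel
#'   window has zero total intensity.
#' @export
extract_ratio <- function(frame, center, scale) {
  stopifnot(is.list(frame), all(c("green", "red") %in% names(frame)))
  ri <- window_indices(nrow(frame$red), center[1], scale)
  ci <- window_indices(ncol(frame$red), center[2], scale)
  w <- function(img) {
    v <- img[ri, ci]
    tot <- sum(v)
    if (tot <= 0) return(NA_real_)
    sum(v * log(pmax(v, 1))) / tot
  }
  wg <- w(frame$green); wr <- w(frame$red)
  if (is.na(wg) || is.na(wr)) {
    warning("zero total intensity in a channel window; ratio undefined")
    return(NA_real_)
  }
  exp(wg - wr)
}

#' Plain summed-intensity ratio (legacy estimator)
#'
#' The older read-out `sum(I_G) / sum(I_R)` over the same square window.
#' Retained as a comparison baseline: it drifts with the window scale on
#' probes with a non-uniform profile over background, which is why the
#' weighted log-ratio of [extract_ratio()] is preferred.
#'
#' @inheritParams extract_ratio
#' @return the ratio; `NA` with a warning if the red window sums to zero.
#' @export
extract_ratio_legacy <- function(frame, center, scale) {
  stopifnot(is.list(frame), all(c("green", "red") %in% names(frame)))
  ri <- window_indices(nrow(frame$red), center[1], scale)
  ci <- window_indices(ncol(frame$red), center[2], scale)
  sr <- sum(frame$red[ri, ci])
  if (sr <= 0) {
    warning("zero total red intensity in window; ratio undefined")
    return(NA_real_)
  }
  sum(frame$green[ri, ci]) / sr
}

#' Ratio averaged over a range of window scales
#'
#' Evaluates the estimator at every integer scale in
#' `[scale_min, scale_max]` and returns the mean; the per-scale values are
#' attached as attribute `per_scale` for diagnostics.  The default range
#' 20-30 px brackets the apparent probe size.
#'
#' @inheritParams extract_ratio
#' @param scale_min,scale_max window half-width range, pixels.
#' @param method `"weighted"` ([extract_ratio()]) or `"legacy"`.
#' @return mean ratio with attribute `per_scale`.
#' @export
extract_ratio_multiscale <- function(frame, center, scale_min = 20,
                                     scale_max = 30,
                                     method = c("weighted", "legacy")) {
  method <- match.arg(method)
  if (!(scale_min > 0 && scale_min <= scale_max)) {
    stop("need 0 < scale_min <= scale_max")
  }
  f <- if (method == "weighted") extract_ratio else extract_ratio_legacy
  scales <- seq(as.integer(scale_min), as.integer(scale_max))
  per <- vapply(scales, function(s) f(frame, center, s), numeric(1))
  structure(mean(per), per_scale = stats::setNames(per, scales))
}

#' Fit a monotone calibration curve from (ratio, pH) pairs
#'
#' Duplicated pH levels are averaged, pH is smoothed against ratio by
#' LOESS-style local regression ([stats::lowess()]), and the smooth is
#' projected onto the nearest monotone sequence (isotonic projection in
#' the direction of the raw trend) so the curve is invertible.  The
#' +/-1 sigma band is the standard deviation of the support-point
#' residuals.
#'
#' @param pairs data frame with columns `ratio` and `ph` (one row per
#'   calibration read), or a list as returned by calibration fixtures.
#' @param span LOESS smoother span (fraction of points per local fit).
#'   The smoother runs on level-averaged support points, of which a
#'   calibration typically has fewer than ten, so the default keeps each
#'   local fit to 2-3 points; larger spans flatten the sigmoid's shoulders.
#' @param mono_tol tolerated non-monotonicity of the level-averaged
#'   ratios, as a fraction of the ratio range, before the fit is refused.
#' @return an object of class `calibration_curve` with elements
#'   `support` (averaged levels), `grid` (smoothed ratio/pH grid),
#'   `direction` (+1 if pH increases with ratio), `valid_ph_range`,
#'   `sigma`, `sensitivity` (d pH / d ratio on the grid).
#' @export
fit_calibration <- function(pairs, span = 0.4, mono_tol = 0.1) {
  stopifnot(is.data.frame(pairs), all(c("ratio", "ph") %in% names(pairs)),
            all(is.finite(pairs$ratio)), all(is.finite(pairs$ph)))
  lev <- aggregate(ratio ~ ph, data = pairs, FUN = mean)
  lev <- lev[order(lev$ph), ]
  if (nrow(lev) < 4) {
    stop("calibration needs at least 4 distinct pH levels")
  }
  d <- diff(lev$ratio)
  direction <- if (sum(sign(d)) >= 0) 1 else -1
  viol <- which(direction * d < -mono_tol * diff(range(lev$ratio)))
  if (length(viol)) {
    stop(sprintf(
      "calibration ratios are not monotone in pH beyond tolerance at level(s) %s",
      paste(signif(lev$ph[viol + 1], 4), collapse = ", ")))
  }

  sm <- lowess(lev$ratio, lev$ph, f = span, iter = 3)
  grid_ratio <- seq(min(lev$ratio), max(lev$ratio), length.out = 201)
  grid_ph <- approx(sm$x, sm$y, xout = grid_ratio, rule = 2)$y
  # isotonic projection in the trend direction guarantees invertibility
  grid_ph <- if (direction > 0) pava_fit(grid_ph, decreasing = FALSE)
             else pava_fit(grid_ph, decreasing = TRUE)
  fitted_at_support <- approx(grid_ratio, grid_ph, xout = lev$ratio,
                              rule = 2)$y
  sigma <- if (nrow(pairs) > nrow(lev) || nrow(lev) > 2) {
    sd(pairs$ph - approx(grid_ratio, grid_ph, xout = pairs$ratio,
                         rule = 2)$y)
  } else NA_real_
  sens <- c(diff(grid_ph) / diff(grid_ratio), NA_real_)
  structure(list(support = lev,
                 grid = data.frame(ratio = grid_ratio, ph = grid_ph),
                 direction = direction,
                 valid_ph_range = range(lev$ph),
                 sigma = sigma, sensitivity = sens,
                 fitted_at_support = fitted_at_support),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration_curve: %d levels, pH %.2f-%.2f, ratio %.3g-%.3g, %s, sigma %.3g\n",
    nrow(x$support), x$valid_ph_range[1], x$valid_ph_range[2],
    min(x$grid$ratio), max(x$grid$ratio),
    if (x$direction > 0) "increasing" else "decreasing", x$sigma))
  invisible(x)
}

#' Convert ratios to pH through a calibration curve
#'
#' Ratios outside the calibrated support are clamped to the nearest end of
#' the curve and flagged (`in_range = FALSE`) rather than extrapolated —
#' the sigmoidal sensor saturates outside its quasi-linear segment.
#'
#' @param curve a [fit_calibration()] result.
#' @param ratio numeric vector of green/red ratios.
#' @return data frame with columns `ph` and `in_range`.
#' @export
ratio_to_ph <- function(curve, ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(ratio))) stop("ratio must be finite")
  rng <- range(curve$grid$ratio)
  in_range <- ratio >= rng[1] & ratio <= rng[2]
  clamped <- pmin(pmax(ratio, rng[1]), rng[2])
  ph <- approx(curve$grid$ratio, curve$grid$ph, xout = clamped, rule = 2)$y
  data.frame(ph = ph, in_range = in_range)
}

#' Save / load a calibration curve as JSON
#' @param curve a `calibration_curve`.
#' @param path file path.
#' @return (load) the restored `calibration_curve`.
#' @export
write_calibration_json <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$support <- as.data.frame(x$support)
  x$grid <- as.data.frame(x$grid)
  x$valid_ph_range <- as.numeric(x$valid_ph_range)
  structure(x, class = "calibration_curve")
}

#' Calibrate from rendered fixtures
#'
#' Runs detection and multiscale ratio extraction on each fixture image
#' and fits the calibration curve on the resulting (ratio, pH) pairs.
#'
#' @param fixtures list from [generate_calibration_fixture()].
#' @param dp a [detect_params()].
#' @param scale_min,scale_max ratio-extraction scale range, pixels.
#' @param ... passed to [fit_calibration()].
#' @return a `calibration_curve`.
#' @export
calibrate_from_fixtures <- function(fixtures, dp = detect_params(),
                                    scale_min = 20, scale_max = 30, ...) {
  pairs <- do.call(rbind, lapply(fixtures, function(fx) {
    frame <- fx$stack[[1]]
    det <- find_particles(bandpass(to_grayscale(frame), dp), dp)
    if (!nrow(det)) return(NULL)
    det <- det[which.max(det$value), ]
    r <- extract_ratio_multiscale(frame, c(det$row, det$col),
                                  scale_min, scale_max)
    data.frame(ratio = as.numeric(r), ph = fx$nominal_ph)
  }))
  fit_calibration(pairs, ...)
}
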