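#' Fit a weighted (1/x) linear calibration curve
#'
#' Weighted least squares of peak-area ratio on nominal concentration with
#' weights \eqn{w_i = 1/x_i}, the weighting that stabilises relative
#' (heteroscedastic) noise on LC-MS/MS response ratios. Solves the weighted
#' normal equations directly:
#' \deqn{m = \frac{S_w S_{wxy} - S_{wx} S_{wy}}{S_w S_{wxx} - S_{wx}^2},
#'       \quad b = \frac{S_{wy} - m S_{wx}}{S_w}}
#' Standard errors of slope and intercept come from the weighted residual
#' variance with n - 2 degrees of freedom; the coefficient of determination
#' is weighted, \eqn{R^2 = 1 - SSE_w / SST_w}, with the weighted mean of y
#' in the total sum of squares.
#'
#' When the samples carry a \code{replicate} column with at least two
#' replicate curves, the curve is additionally fitted per replicate and the
#' standard deviation of the per-replicate \eqn{R^2} is reported as
#' \code{sd_r2}.
#'
#' @param samples Data frame of calibration samples with columns
#'   \code{nominal_conc} and \code{area_ratio} (or \code{analyte_area} and
#'   \code{is_area}, from which the ratio is formed), optionally
#'   \code{replicate} and \code{matrix}. Blanks (nominal 0) are not allowed
#'   in the fit set: 1/x weights are undefined at zero.
#' @param weighting \code{"1/x"} (default) or \code{"none"} for ordinary
#'   least squares.
#' @return An object of class \code{"calibration_curve"}: slope \code{m},
#'   intercept \code{b}, \code{r2}, standard errors \code{sd_slope},
#'   \code{sd_intercept}, \code{sd_r2} (NA without replicate structure),
#'   \code{weighting}, \code{n_levels}, \code{range}, \code{n}.
#' @examples
#' d <- data.frame(nominal_conc = rep(c(10, 100, 1000), each = 3))
#' d$area_ratio <- 0.01 * d$nominal_conc
#' fit_weighted_curve(d)
#' @export
fit_weighted_curve <- function(samples, weighting = c("1/x", "none")) {
  weighting <- match.arg(weighting)
  samples <- as.data.frame(samples)
  if (!"area_ratio" %in% names(samples)) {
    if (!all(c("analyte_area", "is_area") %in% names(samples))) {
      stop("samples need 'area_ratio' or both 'analyte_area' and 'is_area'",
           call. = FALSE)
    }
    if (any(samples$is_area <= 0)) {
      stop("internal-standard area must be positive", call. = FALSE)
    }
    samples$area_ratio <- samples$analyte_area / samples$is_area
  }
  x <- samples$nominal_conc
  y <- samples$area_ratio
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (any(x <= 0)) {
    stop("nonpositive concentration in fit set; exclude blanks before ",
         "fitting (1/x weight undefined at x = 0)", call. = FALSE)
  }
  levels_x <- sort(unique(x))
  if (length(levels_x) < 2L) {
    stop("singular design: need >= 2 distinct concentration levels",
         call. = FALSE)
  }

  w <- if (weighting == "1/x") 1 / x else rep(1, length(x))
  fit <- wls_fit(x, y, w)

  sd_r2 <- NA_real_
  if ("replicate" %in% names(samples)) {
    reps <- samples$replicate[keep]
    ids <- unique(reps)
    if (length(ids) >= 2L &&
        all(vapply(ids, function(r) length(unique(x[reps == r])) >= 2L,
                   logical(1)))) {
      r2s <- vapply(ids, function(r) {
        wls_fit(x[reps == r], y[reps == r], w[reps == r])$r2
      }, numeric(1))
      sd_r2 <- stats::sd(r2s)
    }
  }

  structure(list(
    m = fit$m, b = fit$b, r2 = fit$r2,
    sd_slope = fit$sd_slope, sd_intercept = fit$sd_intercept,
    sd_r2 = sd_r2, weighting = weighting,
    n_levels = length(levels_x), range = range(levels_x), n = length(x)
  ), class = "calibration_curve")
}

# Weighted normal equations; w need not be normalised.
wls_fit <- function(x, y, w) {
  sw <- sum(w)
  swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x * x); swxy <- sum(w * x * y)
  den <- sw * swxx - swx^2
  if (abs(den) < .Machine$double.eps * sw * swxx) {
    stop("singular design in weighted fit", call. = FALSE)
  }
  m <- (sw * swxy - swx * swy) / den
  b <- (swy - m * swx) / sw
  res <- y - (m * x + b)
  sse <- sum(w * res^2)
  ybar_w <- swy / sw
  sst <- sum(w * (y - ybar_w)^2)
  n <- length(x)
  s2 <- if (n > 2L) sse / (n - 2L) else NA_real_
  list(
    m = m, b = b,
    r2 = if (sst > 0) 1 - sse / sst else 1,
    sd_slope = if (is.na(s2)) NA_real_ else sqrt(s2 * sw / den),
    sd_intercept = if (is.na(s2)) NA_real_ else sqrt(s2 * swxx / den)
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration curve (weighting %s): y = %.6g x %+.6g\n",
    x$weighting, x$m, x$b))
  cat(sprintf("  R^2 = %.4f (sd over replicate curves %s)\n", x$r2,
              if (is.na(x$sd_r2)) "n/a" else sprintf("%.4f", x$sd_r2)))
  cat(sprintf("  Sm = %.3g, Sb = %.3g; %d levels over [%g, %g], n = %d\n",
              x$sd_slope, x$sd_intercept, x$n_levels,
              x$range[1], x$range[2], x$n))
  if (x$n_levels < 5L) {
    cat("  note: fewer than 5 levels; curve not reportable under guidance\n")
  }
  invisible(x)
}

#' Predict area ratio from concentration
#' @param object A \code{calibration_curve}.
#' @param conc Concentrations.
#' @param ... Unused.
#' @return Predicted area ratios \code{m * conc + b}.
#' @export
predict.calibration_curve <- function(object, conc, ...) {
  object$m * conc + object$b
}

#' Back-calculate concentration from an area ratio
#'
#' Inverts the calibration line: \code{(area_ratio - b) / m}. Values below
#' zero are returned as-is with a warning — negative back-calculated
#' concentrations are diagnostic (blank-level signal), not data errors.
#'
#' @param curve A \code{calibration_curve}.
#' @param area_ratio Peak-area ratio(s).
#' @return Concentration(s) in the curve's units.
#' @export
back_calculate <- function(curve, area_ratio) {
  if (!inherits(curve, "calibration_curve")) {
    stop("curve must be a calibration_curve", call. = FALSE)
  }
  if (curve$m == 0) stop("slope is zero; cannot invert", call. = FALSE)
  conc <- (area_ratio - curve$b) / curve$m
  if (any(conc < 0, na.rm = TRUE)) {
    warning(sum(conc < 0, na.rm = TRUE),
            " back-calculated concentration(s) below zero", call. = FALSE)
  }
  conc
}

#' Estimate LOD and LOQ from a spiked-blank panel
#'
#' EU-guidance estimator from replicate analyses of blanks spiked at the
#' lowest calibration level:
#' \deqn{LOD = 3.9 \cdot SD(\mathrm{signals}) / m, \qquad LOQ = 3.3 \cdot LOD}
#' SD is the n-1 sample standard deviation of the replicate area ratios
#' (signal domain); dividing by the slope converts to concentration units.
#'
#' @param panel Data frame of replicate spiked samples at a single level,
#'   with columns \code{nominal_conc} and \code{area_ratio}; at least 3
#'   replicates.
#' @param curve A \code{calibration_curve} supplying the slope.
#' @param lod_multiplier Guidance constant applied to SD/slope (default 3.9).
#' @param loq_multiplier Guidance constant applied to LOD (default 3.3).
#' @return An object of class \code{"detection_limits"} with \code{lod},
#'   \code{loq}, \code{sd_signals}, \code{n_blank_spikes}, the multipliers
#'   and the panel level.
#' @examples
#' d <- data.frame(nominal_conc = rep(c(10, 100, 1000), each = 3))
#' d$area_ratio <- 0.01 * d$nominal_conc
#' curve <- fit_weighted_curve(d)
#' panel <- data.frame(nominal_conc = 10,
#'                     area_ratio = 0.1 + c(-1, 0, 1, 2, -2, 0, 1, -1, 0, 0) * 0.005)
#' estimate_lod_loq(panel, curve)
#' @export
estimate_lod_loq <- function(panel, curve, lod_multiplier = 3.9,
                             loq_multiplier = 3.3) {
  panel <- as.data.frame(panel)
  stopifnot(all(c("nominal_conc", "area_ratio") %in% names(panel)))
  lv <- unique(panel$nominal_conc)
  if (length(lv) != 1L) {
    stop("LOD panel must contain a single spike level; got ",
         length(lv), call. = FALSE)
  }
  n <- nrow(panel)
  if (n < 3L) {
    stop("LOD panel needs >= 3 replicates (SD unreliable below that); got ",
         n, call. = FALSE)
  }
  sd_sig <- stats::sd(panel$area_ratio)
  lod <- lod_multiplier * sd_sig / curve$m
  structure(list(
    lod = lod, loq = loq_multiplier * lod,
    lod_multiplier = lod_multiplier, loq_multiplier = loq_multiplier,
    sd_signals = sd_sig, n_blank_spikes = n, level = lv
  ), class = "detection_limits")
}

#' LOQ from a known LOD
#'
#' The guidance rule applied on its own: \code{loq_multiplier * lod}. Useful
#' when the LOD is already reported and only the quantification limit is
#' needed.
#'
#' @param lod Limit of detection (concentration units).
#' @param loq_multiplier Multiplier (default 3.3).
#' @return Limit of quantification.
#' @export
loq_from_lod <- function(lod, loq_multiplier = 3.3) {
  stopifnot(all(lod >= 0))
  loq_multiplier * lod
}

#' @export
print.detection_limits <- function(x, ...) {
  cat(sprintf(
    "LOD = %.3f, LOQ = %.3f (x%g SD/slope, x%g LOD; SD = %.4g over %d spikes at level %g)\n",
    x$lod, x$loq, x$lod_multiplier, x$loq_multiplier,
    x$sd_signals, x$n_blank_spikes, x$level))
  invisible(x)
}
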