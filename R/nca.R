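#' Build a group-mean concentration-time profile
#'
#' Destructive-sampling PK designs yield one sample per animal, so the
#' profile is the per-time-point group mean with its SD. Censored
#' observations (below the LLOQ) are dropped by default or imputed as zero;
#' excluded time points (e.g. a contaminated first interval) are removed
#' and recorded with their reason.
#'
#' @param samples Data frame with columns \code{time} (h), \code{conc}
#'   (mg/L) and optionally \code{censored} (logical) and \code{animal_id}.
#' @param exclude Numeric times to drop, or a named character vector /
#'   named list mapping \code{"time"} to a reason string.
#' @param censored One of \code{"drop"} (default) or \code{"zero"}.
#' @return Object of class \code{"pk_profile"}: \code{times},
#'   \code{mean_conc}, \code{sd_conc}, \code{n_per_time},
#'   \code{excluded} (data.frame time/reason).
#' @examples
#' d <- data.frame(time = rep(c(0.25, 1, 2), each = 2),
#'                 conc = c(1.8, 1.9, 0.9, 1.0, 0.4, 0.5))
#' build_profile(d)
#' @export
build_profile <- function(samples, exclude = numeric(0),
                          censored = c("drop", "zero")) {
  censored <- match.arg(censored)
  samples <- as.data.frame(samples)
  stopifnot(all(c("time", "conc") %in% names(samples)))

  if (is.list(exclude) || !is.null(names(exclude))) {
    ex_times <- as.numeric(names(exclude))
    ex_reason <- as.character(unlist(exclude))
  } else {
    ex_times <- as.numeric(exclude)
    ex_reason <- rep("excluded by request", length(ex_times))
  }
  excluded <- data.frame(time = ex_times, reason = ex_reason)

  if (!"censored" %in% names(samples)) samples$censored <- FALSE
  samples$censored <- as.logical(samples$censored)  # CSV reads as character
  if (anyNA(samples$censored)) {
    stop("censored column must be logical (TRUE/FALSE)", call. = FALSE)
  }
  if (censored == "drop") {
    samples <- samples[!samples$censored, , drop = FALSE]
  } else {
    samples$conc[samples$censored] <- 0
  }
  keep <- !samples$time %in% ex_times
  samples <- samples[keep, , drop = FALSE]
  if (nrow(samples) == 0L) {
    stop("no observations remain after exclusion/censoring", call. = FALSE)
  }
  times <- sort(unique(samples$time))
  agg <- lapply(times, function(tt) {
    v <- samples$conc[samples$time == tt]
    c(mean(v), if (length(v) > 1L) stats::sd(v) else NA_real_, length(v))
  })
  agg <- do.call(rbind, agg)
  structure(list(
    times = times, mean_conc = agg[, 1], sd_conc = agg[, 2],
    n_per_time = as.integer(agg[, 3]), excluded = excluded
  ), class = "pk_profile")
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf("PK profile: %d time points over [%g, %g] h\n",
              length(x$times), min(x$times), max(x$times)))
  print(data.frame(time_h = x$times, mean_conc = x$mean_conc,
                   sd = x$sd_conc, n = x$n_per_time), row.names = FALSE)
  if (nrow(x$excluded)) {
    cat("Excluded:\n")
    for (i in seq_len(nrow(x$excluded))) {
      cat(sprintf("  t = %g h: %s\n", x$excluded$time[i],
                  x$excluded$reason[i]))
    }
  }
  invisible(x)
}

#' Cmax and Tmax read from the profile
#'
#' The maximum mean concentration and the time it occurs; ties are broken
#' toward the earlier time.
#'
#' @param profile A \code{pk_profile}.
#' @return Named list \code{cmax}, \code{tmax}.
#' @export
cmax_tmax <- function(profile) {
  stopifnot(inherits(profile, "pk_profile"), length(profile$times) >= 1L)
  i <- which(profile$mean_conc == max(profile$mean_conc))[1]
  list(cmax = profile$mean_conc[i], tmax = profile$times[i])
}

#' Terminal elimination rate constant
#'
#' Ordinary least squares of ln(concentration) on time over the terminal
#' (elimination) points; Kel is the negative slope. Window strategies:
#' \code{"last_n"} uses the last \code{n} quantifiable points after Tmax;
#' \code{"best_adjusted_r2"} scans all terminal windows of >= 3 points and
#' keeps the one with the largest adjusted R^2 (the usual lambda-z
#' selection rule).
#'
#' @param profile A \code{pk_profile}.
#' @param selection \code{"last_n"} (default) or \code{"best_adjusted_r2"}.
#' @param n Number of terminal points for \code{"last_n"} (default 4).
#' @return Object of class \code{"kel_fit"}: \code{kel}, \code{se},
#'   \code{r2}, \code{points} (times used), \code{n_points}.
#' @examples
#' p <- build_profile(data.frame(time = c(1, 2, 3, 4, 6),
#'                               conc = 5 * exp(-0.8 * c(1, 2, 3, 4, 6))))
#' fit_kel(p)
#' @export
fit_kel <- function(profile, selection = c("last_n", "best_adjusted_r2"),
                    n = 4L) {
  selection <- match.arg(selection)
  stopifnot(inherits(profile, "pk_profile"))
  tmax <- cmax_tmax(profile)$tmax
  post <- profile$times > tmax & profile$mean_conc > 0
  if (any(profile$mean_conc[profile$times > tmax] <= 0)) {
    # trailing zero/negative means cannot enter a log fit; they are simply
    # not quantifiable
    post <- post & profile$mean_conc > 0
  }
  tt <- profile$times[post]
  cc <- profile$mean_conc[post]
  if (length(tt) < 2L) {
    stop("need >= 2 positive post-Tmax points for an elimination fit",
         call. = FALSE)
  }
  if (length(tt) == 2L) {
    warning("elimination fit on only 2 points", call. = FALSE)
  }

  ols <- function(t, lc) {
    tb <- mean(t); lb <- mean(lc)
    sxx <- sum((t - tb)^2)
    slope <- sum((t - tb) * (lc - lb)) / sxx
    res <- lc - (lb + slope * (t - tb))
    m <- length(t)
    s2 <- if (m > 2L) sum(res^2) / (m - 2L) else NA_real_
    sst <- sum((lc - lb)^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
    list(slope = slope, se = if (is.na(s2)) NA_real_ else sqrt(s2 / sxx),
         r2 = r2, m = m)
  }

  if (selection == "last_n") {
    idx <- seq(max(1L, length(tt) - n + 1L), length(tt))
    fit <- ols(tt[idx], log(cc[idx]))
    pts <- tt[idx]
  } else {
    best <- NULL
    for (start in seq_len(length(tt) - 2L)) {
      f <- ols(tt[start:length(tt)], log(cc[start:length(tt)]))
      adj <- 1 - (1 - f$r2) * (f$m - 1) / (f$m - 2)
      if (is.null(best) || adj > best$adj + 1e-12) {
        best <- c(f, list(adj = adj, start = start))
      }
    }
    fit <- best
    pts <- tt[best$start:length(tt)]
  }
  kel <- -fit$slope
  if (!is.finite(kel) || kel <= 0) {
    warning("fitted Kel is not positive; elimination phase not identified",
            call. = FALSE)
  }
  structure(list(kel = kel, se = fit$se, r2 = fit$r2, points = pts,
                 n_points = length(pts), selection = selection),
            class = "kel_fit")
}

#' Elimination half-life
#'
#' \code{t1/2 = ln(2) / kel}. Summaries print it to two decimals.
#'
#' @param kel Elimination rate constant (1/h), > 0.
#' @return Half-life in hours.
#' @examples
#' half_life(0.80)
#' @export
half_life <- function(kel) {
  if (any(!is.finite(kel)) || any(kel <= 0)) {
    stop("kel must be positive", call. = FALSE)
  }
  log(2) / kel
}

#' Linear trapezoidal AUC
#'
#' Area under the piecewise-linear concentration-time curve from the first
#' profile time (or 0, with the pre-dose anchor) to \code{t_end}:
#' \deqn{AUC = \sum (t_{i+1}-t_i)(C_i + C_{i+1})/2.}
#' For oral dosing a (0, 0) anchor is prepended by default, since the
#' pre-dose concentration is zero. \code{t_end} must lie within the observed
#' range (the exponential tail beyond the last sample is
#' [auc_extrapolate()]'s job); an interior \code{t_end} lands on the linear
#' interpolant.
#'
#' @param profile A \code{pk_profile}.
#' @param t_end Upper integration limit in hours (default: last observed
#'   time).
#' @param t_start Lower limit (default 0 with the anchor, else first
#'   observed time).
#' @param anchor_zero Prepend a (0, 0) point when the profile does not start
#'   at t = 0 (default TRUE).
#' @return AUC in mg.h/L.
#' @examples
#' p <- build_profile(data.frame(time = c(1, 2), conc = c(2, 0)))
#' auc_trapezoid(p)  # triangle 0-1 plus triangle 1-2
#' @export
auc_trapezoid <- function(profile, t_end = max(profile$times),
                          t_start = NULL, anchor_zero = TRUE) {
  stopifnot(inherits(profile, "pk_profile"))
  tt <- profile$times
  cc <- profile$mean_conc
  if (anchor_zero && tt[1] > 0) {
    tt <- c(0, tt)
    cc <- c(0, cc)
  }
  if (is.null(t_start)) t_start <- tt[1]
  if (t_end > max(tt) + 1e-12) {
    stop(sprintf(
      "t_end = %g h beyond last observed time %g h; use auc_extrapolate() for the tail",
      t_end, max(tt)), call. = FALSE)
  }
  if (t_start < tt[1] - 1e-12 || t_end < t_start) {
    stop("integration limits outside the observed profile", call. = FALSE)
  }
  interp <- function(t0) stats::approx(tt, cc, xout = t0)$y
  grid <- sort(unique(c(t_start, tt[tt > t_start & tt < t_end], t_end)))
  cg <- interp(grid)
  sum(diff(grid) * (utils::head(cg, -1) + utils::tail(cg, -1)) / 2)
}

#' Exponential tail AUC beyond the last sample
#'
#' Extrapolated area from the last observed concentration to infinity under
#' first-order elimination: \code{c_last / kel}.
#'
#' @param c_last Last quantifiable (mean) concentration, >= 0.
#' @param kel Elimination rate constant, > 0.
#' @return Tail AUC in mg.h/L.
#' @export
auc_extrapolate <- function(c_last, kel) {
  if (any(c_last < 0)) stop("c_last must be >= 0", call. = FALSE)
  if (any(!is.finite(kel)) || any(kel <= 0)) {
    stop("kel must be positive", call. = FALSE)
  }
  c_last / kel
}

#' Non-compartmental analysis of a PK profile
#'
#' Composes the individual NCA steps: Cmax/Tmax read-off, terminal Kel fit,
#' half-life, trapezoidal AUC to the last observed time and the exponential
#' tail, with the exact additive decomposition
#' \code{auc_0_inf = auc_0_last + auc_last_inf}.
#'
#' @param profile A \code{pk_profile}.
#' @param selection,n Passed to [fit_kel()].
#' @param anchor_zero Passed to [auc_trapezoid()].
#' @return Object of class \code{"nca_result"} with fields \code{cmax},
#'   \code{tmax}, \code{kel}, \code{kel_se}, \code{t_half},
#'   \code{auc_0_last}, \code{auc_last_inf}, \code{auc_0_inf},
#'   \code{t_last}, \code{elimination_points}.
#' @examples
#' d <- data.frame(time = c(0.25, 0.5, 1, 2, 3, 4, 6),
#'                 conc = 2.4 * (exp(-0.8 * c(0.25, 0.5, 1, 2, 3, 4, 6)) -
#'                               exp(-11.4 * c(0.25, 0.5, 1, 2, 3, 4, 6))))
#' run_nca(build_profile(d))
#' @export
run_nca <- function(profile, selection = "last_n", n = 4L,
                    anchor_zero = TRUE) {
  ct <- cmax_tmax(profile)
  kf <- fit_kel(profile, selection = selection, n = n)
  t_last <- max(profile$times[profile$mean_conc > 0])
  c_last <- profile$mean_conc[profile$times == t_last]
  auc_last <- auc_trapezoid(profile, t_end = t_last,
                            anchor_zero = anchor_zero)
  tail_auc <- auc_extrapolate(c_last, kf$kel)
  structure(list(
    cmax = ct$cmax, tmax = ct$tmax,
    kel = kf$kel, kel_se = kf$se, t_half = half_life(kf$kel),
    auc_0_last = auc_last, auc_last_inf = tail_auc,
    auc_0_inf = auc_last + tail_auc,
    t_last = t_last, elimination_points = kf$points,
    kel_r2 = kf$r2
  ), class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("Non-compartmental analysis\n")
  cat(sprintf("  Cmax  = %.3g mg/L at Tmax = %g h\n", x$cmax, x$tmax))
  cat(sprintf("  Kel   = %.3g 1/h (SE %.2g, R^2 %.4f over t = %s h)\n",
              x$kel, x$kel_se, x$kel_r2,
              paste(x$elimination_points, collapse = ", ")))
  cat(sprintf("  T1/2  = %.2f h\n", x$t_half))
  cat(sprintf("  AUC 0-%g h = %.3g; tail = %.3g; AUC 0-inf = %.3g mg.h/L\n",
              x$t_last, x$auc_0_last, x$auc_last_inf, x$auc_0_inf))
  invisible(x)
}
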