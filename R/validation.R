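#' Recovery against nominal concentrations
#'
#' Accuracy expressed as percentage recovery,
#' \deqn{Recovery(\%) = \frac{measured}{expected} \times 100,}
#' computed per fortification level from the mean of the back-calculated
#' concentrations, then averaged (unweighted) across levels. The VICH GL49
#' acceptance window is -20\% to +10\% of the expected concentration, i.e.
#' mean recovery in [80, 110].
#'
#' @param measured Data frame with columns \code{level} (nominal
#'   concentration, > 0) and \code{calculated_conc} (back-calculated
#'   concentration).
#' @param acceptance Length-2 numeric, the acceptance interval on percent
#'   recovery (default \code{c(80, 110)}).
#' @return Object of class \code{"recovery_result"}: \code{per_level} table
#'   (level, n, mean_measured, recovery), \code{mean_recovery},
#'   \code{acceptance}, \code{pass}.
#' @examples
#' compute_recovery(data.frame(level = c(10, 500, 2000),
#'                             calculated_conc = c(7.71, 513.73, 2076.28)))
#' @export
compute_recovery <- function(measured, acceptance = c(80, 110)) {
  measured <- as.data.frame(measured)
  stopifnot(all(c("level", "calculated_conc") %in% names(measured)))
  if (any(measured$level <= 0)) {
    stop("nominal level must be positive", call. = FALSE)
  }
  levels <- sort(unique(measured$level))
  per <- do.call(rbind, lapply(levels, function(lv) {
    v <- measured$calculated_conc[measured$level == lv]
    data.frame(level = lv, n = length(v), mean_measured = mean(v),
               recovery = mean(v) / lv * 100)
  }))
  mean_rec <- mean(per$recovery)
  # tolerance so a recovery of exactly 110% (the rule boundary) passes
  # despite floating-point round-off
  eps <- 1e-9
  structure(list(
    per_level = per, mean_recovery = mean_rec, acceptance = acceptance,
    pass = mean_rec >= acceptance[1] - eps && mean_rec <= acceptance[2] + eps
  ), class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("Mean recovery %.1f%% (acceptance %g-%g%%): %s\n",
              x$mean_recovery, x$acceptance[1], x$acceptance[2],
              if (x$pass) "PASS" else "FAIL"))
  print(x$per_level, row.names = FALSE)
  invisible(x)
}

#' Within-run precision (repeatability)
#'
#' Coefficient of variation of replicate determinations at each
#' concentration level, \code{CV = 100 * SD / mean}, judged against the
#' guideline thresholds: CV must not exceed 15\% at levels below
#' \code{cv_breakpoint} (default 100, the 10 and 50 unit levels) and 10\% at
#' levels at or above it.
#'
#' @param replicates Data frame with columns \code{level} and
#'   \code{measured}; at least 2 replicates per level.
#' @param cv_limit_low,cv_limit_high CV limits (\%) below / at-or-above the
#'   breakpoint. Defaults 15 and 10.
#' @param cv_breakpoint Concentration separating the two regimes
#'   (default 100).
#' @return Object of class \code{"precision_result"}: \code{per_level}
#'   (level, n, mean, sd, cv, threshold, pass) and overall \code{pass}.
#' @examples
#' compute_precision(data.frame(level = rep(100, 3), measured = c(90, 100, 110)))
#' @export
compute_precision <- function(replicates, cv_limit_low = 15,
                              cv_limit_high = 10, cv_breakpoint = 100) {
  replicates <- as.data.frame(replicates)
  stopifnot(all(c("level", "measured") %in% names(replicates)))
  levels <- sort(unique(replicates$level))
  per <- do.call(rbind, lapply(levels, function(lv) {
    v <- replicates$measured[replicates$level == lv]
    if (length(v) < 2L) {
      stop("level ", lv, ": need >= 2 replicates for a CV", call. = FALSE)
    }
    m <- mean(v)
    if (m <= 0) {
      stop("level ", lv, ": nonpositive mean, CV undefined", call. = FALSE)
    }
    cv <- 100 * stats::sd(v) / m
    thr <- if (lv < cv_breakpoint) cv_limit_low else cv_limit_high
    data.frame(level = lv, n = length(v), mean = m, sd = stats::sd(v),
               cv = cv, threshold = thr, pass = cv <= thr + 1e-9)
  }))
  structure(list(per_level = per, pass = all(per$pass)),
            class = "precision_result")
}

#' @export
print.precision_result <- function(x, ...) {
  cat("Within-run precision:", if (x$pass) "PASS" else "FAIL", "\n")
  print(x$per_level, row.names = FALSE)
  invisible(x)
}

#' Specificity from blank and fortified panels
#'
#' A blank offends when its response in the analyte retention window exceeds
#' \code{threshold_fraction} of the response at the lowest quantifiable
#' level; every fortified sample must respond above that LLOQ response. The
#' method is specific when no blank offends and all fortified samples are
#' detected. Panels smaller than \code{expected_n} per arm trigger a
#' warning, not an error.
#'
#' @param blanks Data frame (or numeric vector) of blank responses; column
#'   \code{response} if a data frame, optionally \code{sample_id}.
#' @param fortified Same layout for fortified samples.
#' @param lloq_response Response (area ratio) at the LLOQ; must be > 0.
#' @param threshold_fraction Fraction of \code{lloq_response} a blank may
#'   reach (default 0.2, the common bioanalytical convention).
#' @param expected_n Expected panel size per arm (default 20).
#' @return Object of class \code{"specificity_result"}: counts, offending
#'   blank ids, undetected fortified ids, \code{pass}.
#' @export
evaluate_specificity <- function(blanks, fortified, lloq_response,
                                 threshold_fraction = 0.2,
                                 expected_n = 20L) {
  as_panel <- function(x, label) {
    if (is.numeric(x)) x <- data.frame(response = x)
    x <- as.data.frame(x)
    if (!"response" %in% names(x)) {
      stop(label, " panel needs a 'response' column", call. = FALSE)
    }
    if (nrow(x) == 0L) stop(label, " panel is empty", call. = FALSE)
    if (!"sample_id" %in% names(x)) x$sample_id <- seq_len(nrow(x))
    x
  }
  blanks <- as_panel(blanks, "blank")
  fortified <- as_panel(fortified, "fortified")
  if (!is.finite(lloq_response) || lloq_response <= 0) {
    stop("lloq_response must be positive", call. = FALSE)
  }
  if (nrow(blanks) < expected_n || nrow(fortified) < expected_n) {
    warning(sprintf(
      "panel smaller than the recommended %d/%d (got %d blanks, %d fortified)",
      expected_n, expected_n, nrow(blanks), nrow(fortified)), call. = FALSE)
  }
  thr <- threshold_fraction * lloq_response
  offending <- blanks$sample_id[blanks$response > thr]
  undetected <- fortified$sample_id[fortified$response < lloq_response]
  structure(list(
    n_blanks = nrow(blanks), n_fortified = nrow(fortified),
    blank_threshold = thr, threshold_fraction = threshold_fraction,
    offending_blanks = offending, undetected_fortified = undetected,
    pass = length(offending) == 0L && length(undetected) == 0L
  ), class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat("Specificity:", if (x$pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  %d blanks (threshold %.4g), %d fortified\n",
              x$n_blanks, x$blank_threshold, x$n_fortified))
  if (length(x$offending_blanks)) {
    cat("  offending blanks:", paste(x$offending_blanks, collapse = ", "), "\n")
  }
  if (length(x$undetected_fortified)) {
    cat("  undetected fortified:",
        paste(x$undetected_fortified, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Storage-stability evaluation
#'
#' Percent of the nominal concentration remaining after storage, per
#' condition x time x nominal cell (mean over the triplicate measurements),
#' with a stable/unstable flag per cell against a remaining-fraction
#' threshold, and a per-condition summary of the first time instability is
#' observed.
#'
#' @param series Data frame with columns \code{condition}, \code{time}
#'   (storage time; weeks for freezer conditions, hours for benchtop),
#'   \code{nominal_conc} (> 0), \code{measured_conc}.
#' @param threshold Remaining fraction below which a cell is unstable
#'   (default 0.85).
#' @return Object of class \code{"stability_result"}: \code{cells} table
#'   (condition, time, nominal_conc, n, percent_remaining, sd_remaining,
#'   stable) and \code{by_condition} (first unstable time, or NA when the
#'   condition stayed stable).
#' @export
evaluate_stability <- function(series, threshold = 0.85) {
  series <- as.data.frame(series)
  need <- c("condition", "time", "nominal_conc", "measured_conc")
  stopifnot(all(need %in% names(series)))
  if (any(series$nominal_conc <= 0)) {
    stop("nominal concentration must be positive", call. = FALSE)
  }
  if (any(series$time < 0)) stop("negative storage time", call. = FALSE)
  key <- interaction(series$condition, series$time, series$nominal_conc,
                     drop = TRUE)
  cells <- do.call(rbind, lapply(split(series, key), function(d) {
    pr <- d$measured_conc / d$nominal_conc * 100
    if (nrow(d) < 3L) {
      warning(sprintf("cell %s / t=%g / %g has %d replicate(s), expected 3",
                      d$condition[1], d$time[1], d$nominal_conc[1], nrow(d)),
              call. = FALSE)
    }
    data.frame(condition = d$condition[1], time = d$time[1],
               nominal_conc = d$nominal_conc[1], n = nrow(d),
               percent_remaining = mean(pr),
               sd_remaining = if (nrow(d) > 1L) stats::sd(pr) else NA_real_)
  }))
  rownames(cells) <- NULL
  cells <- cells[order(cells$condition, cells$time, cells$nominal_conc), ]
  cells$stable <- cells$percent_remaining >= threshold * 100
  by_condition <- do.call(rbind, lapply(split(cells, cells$condition),
                                        function(d) {
    bad <- d$time[!d$stable]
    data.frame(condition = d$condition[1],
               first_unstable_time = if (length(bad)) min(bad) else NA_real_)
  }))
  rownames(by_condition) <- NULL
  structure(list(cells = cells, by_condition = by_condition,
                 threshold = threshold),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Stability (threshold %.0f%% remaining):\n", x$threshold * 100))
  print(x$by_condition, row.names = FALSE)
  invisible(x)
}
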