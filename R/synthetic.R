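#' Synthetic-study configuration
#'
#' Bundles every parameter of the synthetic data generator. The defaults
#' reproduce the design of the chicken plasma/meat study the package
#' models: a 6-level 10-2000 ug/L calibration in plasma and acetonitrile
#' (7 levels, 50-2000 ug/kg, in meat), triplicate levels, level-dependent
#' relative noise anchored at the observed within-run CVs, a destructive
#' 14-group x 8-bird PK design under a one-compartment oral-absorption
#' model in the observed parameter regime (Cmax near 1.82 mg/L at 0.25 h,
#' ke = 0.80 1/h), and first-order storage decay by condition.
#'
#' @param seed Integer seed; the same seed and config give byte-identical
#'   datasets.
#' @param response_slope Area-ratio per unit concentration (default 0.0113,
#'   plasma-like).
#' @param response_intercept Area-ratio intercept (default -0.1093).
#' @param calibration_levels Concentrations of the calibration scale.
#' @param cv_by_level Named numeric: relative SD (fraction) at each
#'   calibration level. Must cover every level used.
#' @param replicates_per_level Replicates per calibration level (default 3).
#' @param pk_model List: \code{dose_mgkg}, \code{ka} (1/h), \code{ke} (1/h),
#'   \code{V_over_F} (L/kg), \code{between_animal_cv} (fraction).
#' @param sampling_times Sacrifice times in hours, strictly increasing.
#' @param animals_per_group Birds per time group (default 8).
#' @param lloq PK lower limit of quantification in mg/L (default 0.01, i.e.
#'   10 ug/L); simulated concentrations below it are reported censored.
#' @param decay_rate_by_condition Named numeric, first-order decay rate per
#'   storage condition (per week for freezer conditions, per hour for
#'   benchtop ones).
#' @param stability_nominals Nominal concentrations of the stability panel.
#' @param contaminated_first_point Multiply the first sampling group's
#'   concentrations by \code{contamination_factor} (emulates dose reflux at
#'   the 5-min interval); default FALSE.
#' @param contamination_factor Factor applied when contaminated (default 6).
#' @return Object of class \code{"synthetic_config"} (a validated list).
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' cfg$pk_model$ke
#' @export
synthetic_config <- function(
    seed = 1L,
    response_slope = 0.0113,
    response_intercept = -0.1093,
    calibration_levels = c(10, 50, 100, 500, 1000, 2000),
    cv_by_level = c("10" = 0.109, "50" = 0.08, "100" = 0.06,
                    "500" = 0.028, "1000" = 0.04, "2000" = 0.053),
    replicates_per_level = 3L,
    pk_model = list(dose_mgkg = 2.5, ka = 11.4, ke = 0.80,
                    V_over_F = 1.124, between_animal_cv = 0.5),
    sampling_times = c(0.08, 0.2, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6,
                       12, 24),
    animals_per_group = 8L,
    lloq = 0.01,
    decay_rate_by_condition = c("4C" = 0.5, "-20C" = 0.25, "-80C" = 0.03),
    stability_nominals = c(100, 200, 1000, 2000),
    contaminated_first_point = FALSE,
    contamination_factor = 6) {
  cfg <- list(
    seed = as.integer(seed),
    response_slope = response_slope,
    response_intercept = response_intercept,
    calibration_levels = calibration_levels,
    cv_by_level = cv_by_level,
    replicates_per_level = as.integer(replicates_per_level),
    pk_model = pk_model,
    sampling_times = sampling_times,
    animals_per_group = as.integer(animals_per_group),
    lloq = lloq,
    decay_rate_by_condition = decay_rate_by_condition,
    stability_nominals = stability_nominals,
    contaminated_first_point = isTRUE(contaminated_first_point),
    contamination_factor = contamination_factor
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, is.finite(cfg$seed))
  if (any(cfg$calibration_levels <= 0)) {
    stop("calibration levels must be positive", call. = FALSE)
  }
  if (any(cfg$cv_by_level < 0)) stop("CVs must be >= 0", call. = FALSE)
  pk <- cfg$pk_model
  need <- c("dose_mgkg", "ka", "ke", "V_over_F", "between_animal_cv")
  if (!all(need %in% names(pk))) {
    stop("pk_model must define ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(unlist(pk[need]) < 0)) {
    stop("pk_model parameters must be >= 0", call. = FALSE)
  }
  if (pk$ka == pk$ke) {
    stop("degenerate PK model: ka == ke (flip-flop limit not supported)",
         call. = FALSE)
  }
  if (is.unsorted(cfg$sampling_times, strictly = TRUE)) {
    stop("sampling_times must be strictly increasing", call. = FALSE)
  }
  if (any(cfg$decay_rate_by_condition < 0)) {
    stop("decay rates must be >= 0", call. = FALSE)
  }
  if (any(cfg$stability_nominals <= 0)) {
    stop("stability nominals must be positive", call. = FALSE)
  }
  invisible(cfg)
}

# Run code under a deterministic seed without disturbing the caller's RNG
# stream. offset separates the generator functions so their draws are
# independent of one another.
with_config_seed <- function(cfg, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((cfg$seed + offset) %% .Machine$integer.max)
  force(code)
}

cv_at_level <- function(cfg, level) {
  key <- as.character(level)
  if (!key %in% names(cfg$cv_by_level)) {
    stop("cv_by_level does not cover level ", level, call. = FALSE)
  }
  unname(cfg$cv_by_level[[key]])
}

#' Simulate a calibration set
#'
#' For each level and replicate, draws a peak-area ratio from
#' Normal(mean = slope * conc + intercept, sd = cv(level) * mean) — relative
#' noise, matching the premise of 1/x weighting. Ratios that sample
#' negative are truncated at 0 and flagged \code{truncated}. Optional blank
#' rows (nominal 0) carry zero response and are intended for specificity,
#' not the fit.
#'
#' @param config A [synthetic_config()].
#' @param matrix Matrix label (default \code{"plasma"}).
#' @param include_blanks Add \code{replicates_per_level} blank rows.
#' @param run Run index; different runs draw independent noise under the
#'   same seed (run 1 is the calibration run, run 2 a validation run, ...).
#' @return Data frame of calibration samples: \code{matrix},
#'   \code{nominal_conc}, \code{area_ratio}, \code{replicate},
#'   \code{truncated}.
#' @export
simulate_calibration_set <- function(config, matrix = "plasma",
                                     include_blanks = FALSE, run = 1L) {
  validate_synthetic_config(config)
  for (lv in config$calibration_levels) cv_at_level(config, lv)
  with_config_seed(config, 101L + 1009L * (as.integer(run) - 1L), {
    rows <- lapply(config$calibration_levels, function(lv) {
      mu <- config$response_slope * lv + config$response_intercept
      cv <- cv_at_level(config, lv)
      y <- stats::rnorm(config$replicates_per_level, mu, abs(cv * mu))
      data.frame(matrix = matrix, nominal_conc = lv,
                 area_ratio = pmax(y, 0),
                 replicate = seq_len(config$replicates_per_level),
                 truncated = y < 0)
    })
    out <- do.call(rbind, rows)
    if (include_blanks) {
      out <- rbind(out, data.frame(
        matrix = matrix, nominal_conc = 0, area_ratio = 0,
        replicate = seq_len(config$replicates_per_level),
        truncated = FALSE))
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate a spiked-blank LOD panel
#'
#' n replicate blanks spiked at the lowest calibration level, with that
#' level's relative noise, for downstream LOD/LOQ estimation.
#'
#' @param config A [synthetic_config()].
#' @param lowest_level Spike concentration (default: smallest calibration
#'   level).
#' @param n Number of replicates (default 10; must be >= 3).
#' @param matrix Matrix label.
#' @return Data frame like [simulate_calibration_set()].
#' @export
simulate_lod_panel <- function(config, lowest_level = NULL, n = 10L,
                               matrix = "plasma") {
  validate_synthetic_config(config)
  if (is.null(lowest_level)) lowest_level <- min(config$calibration_levels)
  if (n < 3L) {
    stop("LOD panel needs n >= 3 replicates for a meaningful SD",
         call. = FALSE)
  }
  cv <- cv_at_level(config, lowest_level)
  with_config_seed(config, 211L, {
    mu <- config$response_slope * lowest_level + config$response_intercept
    y <- stats::rnorm(n, mu, abs(cv * mu))
    data.frame(matrix = matrix, nominal_conc = lowest_level,
               area_ratio = pmax(y, 0), replicate = seq_len(n),
               truncated = y < 0)
  })
}

#' One-compartment oral concentration curve
#'
#' \deqn{C(t) = \frac{D k_a}{(V/F)(k_a - k_e)} (e^{-k_e t} - e^{-k_a t})}
#' with dose D per kg, absorption and elimination rate constants ka, ke and
#' apparent distribution volume V/F.
#'
#' @param t Time(s) in hours.
#' @param pk \code{pk_model} list (see [synthetic_config()]).
#' @return Concentration(s) in mg/L.
#' @export
pk_concentration <- function(t, pk) {
  if (pk$ka == pk$ke) {
    stop("degenerate PK model: ka == ke", call. = FALSE)
  }
  pk$dose_mgkg * pk$ka / (pk$V_over_F * (pk$ka - pk$ke)) *
    (exp(-pk$ke * t) - exp(-pk$ka * t))
}

#' Closed-form Tmax of the one-compartment oral model
#' @param pk \code{pk_model} list.
#' @return Time of maximum concentration, \code{log(ka/ke)/(ka - ke)} hours.
#' @export
pk_tmax <- function(pk) {
  if (pk$ka == pk$ke) stop("degenerate PK model: ka == ke", call. = FALSE)
  log(pk$ka / pk$ke) / (pk$ka - pk$ke)
}

#' Simulate a destructive-sampling PK dataset
#'
#' One concentration per animal: the model curve at the animal's sacrifice
#' time multiplied by a log-normal animal effect with the configured
#' between-animal CV (mean 1). Concentrations below the LLOQ are reported
#' with their value but flagged \code{censored}. With
#' \code{contaminated_first_point} the first time group is multiplied by
#' the contamination factor, emulating unabsorbed dose refluxed at
#' sacrifice.
#'
#' @param config A [synthetic_config()].
#' @return Data frame: \code{animal_id}, \code{group}, \code{time},
#'   \code{conc} (mg/L), \code{censored}.
#' @export
simulate_pk_dataset <- function(config) {
  validate_synthetic_config(config)
  pk <- config$pk_model
  cv <- pk$between_animal_cv
  # lognormal with mean 1 and CV cv
  sdlog <- sqrt(log(1 + cv^2))
  mulog <- -sdlog^2 / 2
  with_config_seed(config, 307L, {
    rows <- lapply(seq_along(config$sampling_times), function(g) {
      tt <- config$sampling_times[g]
      base <- pk_concentration(tt, pk)
      eff <- if (cv > 0) {
        stats::rlnorm(config$animals_per_group, mulog, sdlog)
      } else rep(1, config$animals_per_group)
      conc <- base * eff
      if (config$contaminated_first_point && g == 1L) {
        conc <- conc * config$contamination_factor
      }
      data.frame(
        animal_id = sprintf("G%02d_A%d", g, seq_len(config$animals_per_group)),
        group = g, time = tt, conc = conc,
        censored = conc < config$lloq)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a storage-stability series
#'
#' Measured concentration = nominal * exp(-k_condition * t) * relative
#' noise, in triplicate for every condition x time x nominal combination.
#'
#' @param config A [synthetic_config()].
#' @param times Storage times (default weeks 1, 2, 4, 12; use hours for
#'   benchtop conditions with per-hour rates).
#' @param noise_cv Relative SD of the measurement noise (default 0.05).
#' @return Data frame: \code{condition}, \code{time}, \code{nominal_conc},
#'   \code{replicate}, \code{measured_conc}.
#' @export
simulate_stability_series <- function(config, times = c(1, 2, 4, 12),
                                      noise_cv = 0.05) {
  validate_synthetic_config(config)
  if (any(times < 0)) stop("negative storage time", call. = FALSE)
  with_config_seed(config, 401L, {
    grid <- expand.grid(
      condition = names(config$decay_rate_by_condition),
      time = times, nominal_conc = config$stability_nominals,
      replicate = 1:3, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    k <- config$decay_rate_by_condition[grid$condition]
    mu <- grid$nominal_conc * exp(-unname(k) * grid$time)
    grid$measured_conc <- pmax(stats::rnorm(nrow(grid), mu, noise_cv * mu), 0)
    out <- grid[order(grid$condition, grid$time, grid$nominal_conc,
                      grid$replicate),
                c("condition", "time", "nominal_conc", "replicate",
                  "measured_conc")]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a specificity panel
#'
#' 20 blank and 20 fortified samples per the guideline comparison: blanks
#' carry baseline-only response (small positive noise), fortified samples
#' the response at the fortification level with its relative noise.
#' Interferent responses can be injected into chosen blanks for
#' negative-control testing.
#'
#' @param config A [synthetic_config()].
#' @param level Fortification level (default 100, the level used for the
#'   study's specificity chromatograms; must be covered by
#'   \code{cv_by_level}).
#' @param n_blank,n_fortified Panel sizes (default 20/20).
#' @param baseline_sd SD of the blank baseline response (default 1e-4).
#' @param interference Named numeric: responses to force into specific
#'   blank positions, e.g. \code{c("7" = 0.05)}.
#' @param matrix Matrix label.
#' @return List with data frames \code{blanks} and \code{fortified}
#'   (columns \code{matrix}, \code{sample_id}, \code{response}) and the
#'   \code{level}.
#' @export
simulate_specificity_panel <- function(config, level = 100,
                                       n_blank = 20L, n_fortified = 20L,
                                       baseline_sd = 1e-4,
                                       interference = NULL,
                                       matrix = "plasma") {
  validate_synthetic_config(config)
  cv <- cv_at_level(config, level)
  with_config_seed(config, 503L, {
    blank_resp <- abs(stats::rnorm(n_blank, 0, baseline_sd))
    if (!is.null(interference)) {
      idx <- as.integer(names(interference))
      blank_resp[idx] <- as.numeric(interference)
    }
    mu <- config$response_slope * level + config$response_intercept
    fort_resp <- pmax(stats::rnorm(n_fortified, mu, abs(cv * mu)), 0)
    list(
      blanks = data.frame(matrix = matrix, sample_id = seq_len(n_blank),
                          response = blank_resp),
      fortified = data.frame(matrix = matrix,
                             sample_id = seq_len(n_fortified),
                             response = fort_resp),
      level = level)
  })
}
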