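#' Read a typed sample table from CSV
#'
#' Strict CSV reader: required columns must be present, declared numeric
#' columns must parse as numbers, and a malformed numeric value raises an
#' error naming its file line. Extra columns are kept but flagged with a
#' warning when a full schema is declared.
#'
#' @param path CSV file path.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numeric.
#' @param schema Optional full set of expected columns; extras warn.
#' @return A data.frame.
#' @export
read_samples <- function(path, required = character(0),
                         numeric_cols = character(0), schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(schema)) {
    extra <- setdiff(names(df), schema)
    if (length(extra)) {
      warning("ignoring unexpected column(s) in ", path, ": ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    blank <- is.na(raw) | !nzchar(trimws(raw))
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(val))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric value '%s' in column '%s' at line %d of %s",
        raw[bad[1]], col, bad[1] + 1L, path), call. = FALSE)
    }
    df[[col]] <- val
  }
  df
}

#' Write a sample table to CSV
#' @param table Data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_samples <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The configuration file is plain YAML; recognised top-level keys are
#' passed to [pipeline_config()]. The \code{generator} block (if present)
#' overrides [synthetic_config()] defaults.
#'
#' @param path YAML file path.
#' @return A \code{pipeline_config} list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gen <- raw$generator
  raw$generator <- NULL
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(gen)) {
    if (!is.null(gen$cv_by_level)) gen$cv_by_level <- unlist(gen$cv_by_level)
    if (!is.null(gen$decay_rate_by_condition)) {
      gen$decay_rate_by_condition <- unlist(gen$decay_rate_by_condition)
    }
    gen$seed <- cfg$seed
    cfg$generator <- do.call(synthetic_config, gen)
  }
  cfg
}

#' Pipeline configuration
#'
#' Holds stage inputs, guideline thresholds and analysis options for
#' [run_pipeline()]. When an input path is NULL the corresponding dataset
#' is generated by the synthetic module under \code{seed}.
#'
#' @param seed Integer seed used for all generated data.
#' @param matrix Matrix label for generated calibration data.
#' @param inputs Named list of optional CSV paths: \code{calibration},
#'   \code{validation} (independent replicates for recovery/precision),
#'   \code{lod_panel}, \code{stability}, \code{pk}, \code{ions}.
#' @param ma_limit Mass-accuracy confirmation limit in ppm (default 5).
#' @param recovery_range Acceptance interval on percent recovery
#'   (default \code{c(80, 110)}, i.e. -20\%/+10\%).
#' @param cv_limits CV limits as \code{c(low, high)} percent around the
#'   breakpoint (default \code{c(15, 10)}).
#' @param cv_breakpoint Level at which the tighter CV limit starts
#'   (default 100).
#' @param precision_levels Levels evaluated for within-run precision
#'   (default \code{c(10, 500, 2000)}).
#' @param specificity_threshold Blank-response threshold as fraction of the
#'   LLOQ response (default 0.2).
#' @param stability_threshold Remaining fraction below which a stability
#'   cell is unstable (default 0.85).
#' @param nca Options list: \code{exclude} (times, default the 0.08 h
#'   interval with its reason), \code{selection}, \code{n},
#'   \code{anchor_zero}, \code{censored}.
#' @param generator A [synthetic_config()]; default one built from
#'   \code{seed}.
#' @param run_nca_stage,run_validation_stage Logical switches (default both
#'   TRUE).
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1L, matrix = "plasma",
                            inputs = list(),
                            ma_limit = 5,
                            recovery_range = c(80, 110),
                            cv_limits = c(15, 10), cv_breakpoint = 100,
                            precision_levels = c(10, 500, 2000),
                            specificity_threshold = 0.2,
                            stability_threshold = 0.85,
                            nca = list(), generator = NULL,
                            run_nca_stage = TRUE,
                            run_validation_stage = TRUE) {
  stopifnot(ma_limit > 0, stability_threshold > 0, stability_threshold <= 1,
            specificity_threshold > 0, specificity_threshold <= 1)
  nca_defaults <- list(
    exclude = stats::setNames(list(
      "improbably high concentration at the 5-min interval (dose reflux)"),
      "0.08"),
    selection = "last_n", n = 4L, anchor_zero = TRUE, censored = "drop")
  nca <- utils::modifyList(nca_defaults, nca)
  if (is.null(generator)) generator <- synthetic_config(seed = seed)
  structure(list(
    seed = as.integer(seed), matrix = matrix, inputs = inputs,
    ma_limit = ma_limit, recovery_range = recovery_range,
    cv_limits = cv_limits, cv_breakpoint = cv_breakpoint,
    precision_levels = precision_levels,
    specificity_threshold = specificity_threshold,
    stability_threshold = stability_threshold,
    nca = nca, generator = generator,
    run_nca_stage = isTRUE(run_nca_stage),
    run_validation_stage = isTRUE(run_validation_stage)
  ), class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  clean <- unclass(config)
  clean$generator <- unclass(clean$generator)
  yaml::write_yaml(clean, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analytical pipeline
#'
#' Executes, in the study's order: identity confirmation, weighted
#' calibration with LOD/LOQ, guideline validation (recovery, within-run
#' precision, specificity, stability) and non-compartmental PK analysis.
#' Inputs not supplied as files are generated by the synthetic module under
#' the configured seed, so a default run is fully self-contained and
#' deterministic.
#'
#' @param config A [pipeline_config()] or path to a YAML config file.
#' @return Object of class \code{"validation_report"}: per-stage results
#'   plus provenance (seed, config hash).
#' @examples
#' rep <- run_pipeline(pipeline_config(seed = 7))
#' rep$nca$cmax
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  gen <- config$generator
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ions <- stage("identification", {
    tbl <- if (!is.null(config$inputs$ions)) {
      read_ion_csv(config$inputs$ions)
    } else {
      # default: reference transitions measured exactly on target
      tbl <- clavulanate_ions()
      tbl$measured_mz <- tbl$theoretical_mz
      tbl
    }
    confirm_identity(tbl, ma_limit = config$ma_limit)
  })

  cal <- stage("calibration", {
    samples <- if (!is.null(config$inputs$calibration)) {
      read_samples(config$inputs$calibration,
                   required = c("nominal_conc", "area_ratio"),
                   numeric_cols = c("nominal_conc", "area_ratio",
                                    "replicate"))
    } else simulate_calibration_set(gen, matrix = config$matrix)
    curve <- fit_weighted_curve(samples)
    panel <- if (!is.null(config$inputs$lod_panel)) {
      read_samples(config$inputs$lod_panel,
                   required = c("nominal_conc", "area_ratio"),
                   numeric_cols = c("nominal_conc", "area_ratio"))
    } else simulate_lod_panel(gen, matrix = config$matrix)
    limits <- estimate_lod_loq(panel, curve)
    list(samples = samples, curve = curve, limits = limits)
  })

  validation <- NULL
  if (config$run_validation_stage) {
    validation <- stage("validation", {
      # recovery/precision are judged on an independent validation run:
      # evaluating the weighted fit on its own calibration samples gives a
      # mean recovery of exactly 100% by the 1/x normal equations
      samples <- if (!is.null(config$inputs$validation)) {
        read_samples(config$inputs$validation,
                     required = c("nominal_conc", "area_ratio"),
                     numeric_cols = c("nominal_conc", "area_ratio",
                                      "replicate"))
      } else simulate_calibration_set(gen, matrix = config$matrix, run = 2L)
      samples$calculated_conc <- back_calculate(cal$curve,
                                                samples$area_ratio)
      recovery <- compute_recovery(
        data.frame(level = samples$nominal_conc,
                   calculated_conc = samples$calculated_conc),
        acceptance = config$recovery_range)
      prec_levels <- intersect(config$precision_levels,
                               unique(samples$nominal_conc))
      precision <- compute_precision(
        data.frame(level = samples$nominal_conc,
                   measured = samples$calculated_conc)[
          samples$nominal_conc %in% prec_levels, ],
        cv_limit_low = config$cv_limits[1],
        cv_limit_high = config$cv_limits[2],
        cv_breakpoint = config$cv_breakpoint)
      panel <- simulate_specificity_panel(gen, matrix = config$matrix)
      # detection is judged against the response at the lowest calibration
      # level (the LLOQ), not at the fortification level
      lloq_resp <- gen$response_slope * min(gen$calibration_levels) +
        gen$response_intercept
      if (lloq_resp <= 0) {
        stop("predicted response at the lowest calibration level is not ",
             "positive; cannot set a specificity threshold", call. = FALSE)
      }
      specificity <- evaluate_specificity(
        panel$blanks, panel$fortified, lloq_response = lloq_resp,
        threshold_fraction = config$specificity_threshold)
      stab_series <- if (!is.null(config$inputs$stability)) {
        read_samples(config$inputs$stability,
                     required = c("condition", "time", "nominal_conc",
                                  "measured_conc"),
                     numeric_cols = c("time", "nominal_conc",
                                      "measured_conc"))
      } else simulate_stability_series(gen)
      stability <- evaluate_stability(stab_series,
                                      threshold = config$stability_threshold)
      list(recovery = recovery, precision = precision,
           specificity = specificity, stability = stability)
    })
  }

  nca_res <- NULL
  if (config$run_nca_stage) {
    nca_res <- stage("nca", {
      pk <- if (!is.null(config$inputs$pk)) {
        read_samples(config$inputs$pk, required = c("time", "conc"),
                     numeric_cols = c("time", "conc"))
      } else simulate_pk_dataset(gen)
      profile <- build_profile(pk, exclude = config$nca$exclude,
                               censored = config$nca$censored)
      run_nca(profile, selection = config$nca$selection, n = config$nca$n,
              anchor_zero = config$nca$anchor_zero)
    })
  }

  structure(list(
    confirmation = ions,
    calibration = cal$curve,
    detection_limits = cal$limits,
    validation = validation,
    nca = nca_res,
    provenance = list(seed = config$seed, config_hash = config_hash(config),
                      package_version = as.character(
                        utils::packageVersion("clavpk")))
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("=== Validation report (seed ", x$provenance$seed, ") ===\n", sep = "")
  print(x$confirmation)
  print(x$calibration)
  print(x$detection_limits)
  if (!is.null(x$validation)) {
    print(x$validation$recovery)
    print(x$validation$precision)
    print(x$validation$specificity)
    print(x$validation$stability)
  }
  if (!is.null(x$nca)) print(x$nca)
  invisible(x)
}

# Recursively convert S3 result objects into plain lists for JSON export,
# attaching unit strings where the quantity has one.
report_to_list <- function(report) {
  units_plasma <- "ug/L"
  conf <- report$confirmation
  out <- list(
    confirmation = list(
      confirmed = conf$confirmed,
      ma_limit_ppm = conf$ma_limit,
      failures = conf$failures,
      per_ion = conf$per_ion[, c("name", "role", "theoretical_mz",
                                 "measured_mz", "ma_ppm", "ma_pass")]
    ),
    calibration = {
      cv <- report$calibration
      list(slope = cv$m, intercept = cv$b, r2 = cv$r2,
           sd_slope = cv$sd_slope, sd_intercept = cv$sd_intercept,
           sd_r2 = cv$sd_r2, weighting = cv$weighting,
           n_levels = cv$n_levels,
           range = list(value = cv$range, units = units_plasma))
    },
    detection_limits = {
      dl <- report$detection_limits
      list(lod = list(value = dl$lod, units = units_plasma),
           loq = list(value = dl$loq, units = units_plasma),
           lod_multiplier = dl$lod_multiplier,
           loq_multiplier = dl$loq_multiplier,
           sd_signals = dl$sd_signals, n_blank_spikes = dl$n_blank_spikes)
    },
    provenance = report$provenance
  )
  if (!is.null(report$validation)) {
    v <- report$validation
    out$validation <- list(
      recovery = list(mean_recovery_pct = v$recovery$mean_recovery,
                      acceptance_pct = v$recovery$acceptance,
                      pass = v$recovery$pass,
                      per_level = v$recovery$per_level),
      precision = list(pass = v$precision$pass,
                       per_level = v$precision$per_level),
      specificity = list(pass = v$specificity$pass,
                         n_blanks = v$specificity$n_blanks,
                         n_fortified = v$specificity$n_fortified,
                         offending_blanks = v$specificity$offending_blanks),
      stability = list(threshold_fraction = v$stability$threshold,
                       by_condition = v$stability$by_condition,
                       cells = v$stability$cells)
    )
  }
  if (!is.null(report$nca)) {
    n <- report$nca
    out$nca <- list(
      cmax = list(value = n$cmax, units = "mg/L"),
      tmax = list(value = n$tmax, units = "h"),
      kel = list(value = n$kel, se = n$kel_se, units = "1/h"),
      t_half = list(value = n$t_half, units = "h"),
      auc_0_last = list(value = n$auc_0_last, units = "mg.h/L"),
      auc_last_inf = list(value = n$auc_last_inf, units = "mg.h/L"),
      auc_0_inf = list(value = n$auc_0_inf, units = "mg.h/L"),
      t_last = list(value = n$t_last, units = "h"),
      elimination_points = n$elimination_points
    )
  }
  out
}

#' Write a validation report to JSON
#'
#' Serialises a [run_pipeline()] report to pretty-printed JSON with unit
#' strings on dimensioned quantities and provenance (seed, config hash)
#' included.
#'
#' @param report A \code{validation_report}.
#' @param path Output JSON path.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}
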