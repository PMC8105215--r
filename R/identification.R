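#' Construct an ion definition table
#'
#' Builds the table of targeted ions used for identity confirmation. Each row
#' is one monitored ion: the precursor or one of its product ions. The
#' theoretical m/z is computed from the elemental composition when one is
#' given; product ions whose composition is unknown carry their library
#' (printed) theoretical m/z instead.
#'
#' @param name Ion label, e.g. \code{"clavulanate [M-H]-"}.
#' @param composition Elemental formula string, or \code{NA} when unknown.
#' @param charge Signed integer charge (default -1, negative-mode ESI).
#' @param role One of \code{"precursor"}, \code{"qualifier-product"},
#'   \code{"quantifier-product"}.
#' @param energy_eV HCD fragmentation energy in eV (optional).
#' @param theoretical_mz Theoretical m/z; required when \code{composition} is
#'   \code{NA}, otherwise computed and any supplied value must agree within
#'   5e-5 u.
#' @param measured_mz Measured m/z (optional, \code{NA} when not measured).
#' @param rt_min Retention time in minutes (optional).
#' @return A \code{data.frame} with class \code{"ion_table"}.
#' @seealso [clavulanate_ions()], [confirm_identity()]
#' @export
ion_definition <- function(name, composition = NA_character_, charge = -1L,
                           role = c("precursor", "qualifier-product",
                                    "quantifier-product"),
                           energy_eV = NA_real_, theoretical_mz = NA_real_,
                           measured_mz = NA_real_, rt_min = NA_real_) {
  role <- match.arg(role)
  if (is.na(composition)) {
    if (is.na(theoretical_mz)) {
      stop("ion '", name, "': need either a composition or a theoretical m/z",
           call. = FALSE)
    }
    mz_theor <- theoretical_mz
  } else {
    mz_theor <- monoisotopic_mz(composition, charge)
    if (!is.na(theoretical_mz) && abs(theoretical_mz - mz_theor) > 5e-5) {
      stop(sprintf(
        "ion '%s': supplied theoretical m/z %.5f disagrees with %.5f computed from %s",
        name, theoretical_mz, mz_theor, composition), call. = FALSE)
    }
  }
  if (mz_theor <= 0) stop("theoretical m/z must be positive", call. = FALSE)
  out <- data.frame(
    name = name, composition = composition, charge = as.integer(charge),
    role = role, energy_eV = energy_eV, theoretical_mz = mz_theor,
    measured_mz = measured_mz, rt_min = rt_min,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ion_table", "data.frame")
  out
}

#' Combine ion definitions into one table
#' @param ... \code{ion_table} rows from [ion_definition()].
#' @return An \code{ion_table} data.frame.
#' @export
ion_table <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("ion_table", "data.frame")
  out
}

#' Reference PRM transitions for clavulanic acid and tazobactam
#'
#' The targeted negative-mode transitions monitored for the clavulanate
#' anion [C8H8NO5]- (precursor m/z 198.04080; products 136.04040, 108.04549,
#' 82.02984 at 17 eV) and for the tazobactam internal standard
#' [C10H11N4O5S]- (precursor 299.04556; products 255.05573, 207.08875,
#' 138.05605 at 30 eV). Product-ion compositions are not assigned, so their
#' theoretical m/z are library values rather than recomputed masses.
#'
#' @param analyte \code{"clavulanate"} or \code{"tazobactam"}.
#' @return An \code{ion_table} with one precursor and three product ions.
#' @examples
#' clavulanate_ions()
#' @export
clavulanate_ions <- function(analyte = c("clavulanate", "tazobactam")) {
  analyte <- match.arg(analyte)
  if (analyte == "clavulanate") {
    ion_table(
      ion_definition("clavulanate [M-H]-", "C8H8NO5", -1L, "precursor",
                     energy_eV = 17),
      ion_definition("clavulanate f136", NA, -1L, "qualifier-product",
                     energy_eV = 17, theoretical_mz = 136.04040),
      ion_definition("clavulanate f108", NA, -1L, "quantifier-product",
                     energy_eV = 17, theoretical_mz = 108.04549),
      ion_definition("clavulanate f82", NA, -1L, "qualifier-product",
                     energy_eV = 17, theoretical_mz = 82.02984)
    )
  } else {
    ion_table(
      ion_definition("tazobactam [M-H]-", "C10H11N4O5S", -1L, "precursor",
                     energy_eV = 30),
      ion_definition("tazobactam f255", NA, -1L, "qualifier-product",
                     energy_eV = 30, theoretical_mz = 255.05573),
      ion_definition("tazobactam f207", NA, -1L, "qualifier-product",
                     energy_eV = 30, theoretical_mz = 207.08875),
      ion_definition("tazobactam f138", NA, -1L, "quantifier-product",
                     energy_eV = 30, theoretical_mz = 138.05605)
    )
  }
}

#' Confirm analyte identity from measured ions
#'
#' Applies the confirmation rule for targeted high-resolution MS: the
#' precursor ion and at least \code{min_products} product ions must each show
#' an absolute mass accuracy below \code{ma_limit} ppm; when both a measured
#' and a reference retention time are present they must agree within
#' \code{rt_tolerance} minutes (the RT criterion is skipped for ions without
#' a measured RT, since matrix shifts the observed RT). Every violated
#' criterion is enumerated in \code{failures}.
#'
#' @param ions An \code{ion_table}; exactly one row with role
#'   \code{"precursor"}, and product rows with measured m/z.
#' @param ma_limit Mass-accuracy limit in ppm (default 5, the confirmation
#'   criterion used for PRM identification).
#' @param rt_tolerance Retention-time tolerance in minutes (default 0.2).
#' @param reference_rt Reference retention time in minutes, or \code{NA} to
#'   skip RT checking.
#' @param min_products Minimum number of in-limit product ions (default 3).
#' @return A list of class \code{"confirmation_result"}: per-ion table with
#'   ppm accuracies, \code{confirmed} flag, and a character vector of
#'   \code{failures} (empty iff confirmed).
#' @examples
#' ions <- clavulanate_ions()
#' ions$measured_mz <- ions$theoretical_mz * (1 + c(-1.62, -2.65, -1.20, -3.41) * 1e-6)
#' confirm_identity(ions)
#' @export
confirm_identity <- function(ions, ma_limit = 5, rt_tolerance = 0.2,
                             reference_rt = NA_real_, min_products = 3L) {
  stopifnot(is.data.frame(ions), nrow(ions) >= 1L)
  n_prec <- sum(ions$role == "precursor")
  if (n_prec == 0L) stop("no precursor ion defined", call. = FALSE)
  if (n_prec > 1L) stop("duplicate precursor roles", call. = FALSE)

  measured <- ions[!is.na(ions$measured_mz), , drop = FALSE]
  failures <- character(0)

  per_ion <- measured
  per_ion$ma_ppm <- mass_accuracy_ppm(per_ion$measured_mz,
                                      per_ion$theoretical_mz)
  per_ion$ma_pass <- abs(per_ion$ma_ppm) < ma_limit
  per_ion$rt_delta <- if (is.na(reference_rt)) NA_real_ else
    per_ion$rt_min - reference_rt
  per_ion$rt_pass <- is.na(per_ion$rt_delta) |
    abs(per_ion$rt_delta) <= rt_tolerance

  prec <- per_ion[per_ion$role == "precursor", , drop = FALSE]
  if (nrow(prec) == 0L) {
    failures <- c(failures, "precursor ion has no measured m/z")
  } else if (!prec$ma_pass) {
    failures <- c(failures, sprintf(
      "precursor '%s': |MA| = %.2f ppm exceeds limit %g ppm",
      prec$name, abs(prec$ma_ppm), ma_limit))
  }

  prods <- per_ion[per_ion$role != "precursor", , drop = FALSE]
  bad <- prods[!prods$ma_pass, , drop = FALSE]
  for (i in seq_len(nrow(bad))) {
    failures <- c(failures, sprintf(
      "product '%s': |MA| = %.2f ppm exceeds limit %g ppm",
      bad$name[i], abs(bad$ma_ppm[i]), ma_limit))
  }
  n_ok <- sum(prods$ma_pass)
  if (n_ok < min_products) {
    failures <- c(failures, sprintf(
      "insufficient product ions: %d within %g ppm, need %d",
      n_ok, ma_limit, min_products))
  }
  rt_bad <- per_ion[!per_ion$rt_pass, , drop = FALSE]
  for (i in seq_len(nrow(rt_bad))) {
    failures <- c(failures, sprintf(
      "ion '%s': retention-time deviation %.3f min exceeds %.3f min",
      rt_bad$name[i], abs(rt_bad$rt_delta[i]), rt_tolerance))
  }

  structure(list(
    per_ion = per_ion,
    ma_limit = ma_limit,
    rt_tolerance = rt_tolerance,
    confirmed = length(failures) == 0L,
    failures = failures
  ), class = "confirmation_result")
}

#' @export
print.confirmation_result <- function(x, ...) {
  cat("Identity confirmation:",
      if (x$confirmed) "CONFIRMED" else "NOT confirmed", "\n")
  cat(sprintf("  MA limit %g ppm; %d ion(s) measured\n",
              x$ma_limit, nrow(x$per_ion)))
  print(x$per_ion[, c("name", "role", "theoretical_mz", "measured_mz",
                      "ma_ppm", "ma_pass")], row.names = FALSE)
  if (!x$confirmed) {
    cat("Failures:\n")
    for (f in x$failures) cat("  -", f, "\n")
  }
  invisible(x)
}

#' Read ion definitions from CSV
#'
#' Expected columns: \code{name, composition, charge, role, energy_eV,
#' measured_mz, rt_min}; \code{theoretical_mz} optional. Extra columns are
#' ignored with a warning.
#'
#' @param path CSV file path.
#' @return An \code{ion_table}.
#' @export
read_ion_csv <- function(path) {
  df <- read_samples(path,
    required = c("name", "composition", "charge", "role"),
    numeric_cols = c("charge", "energy_eV", "measured_mz", "rt_min",
                     "theoretical_mz"))
  for (col in c("energy_eV", "measured_mz", "rt_min", "theoretical_mz")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    ion_definition(df$name[i],
                   composition = if (is.na(df$composition[i]) ||
                                     !nzchar(df$composition[i]))
                     NA_character_ else df$composition[i],
                   charge = df$charge[i], role = df$role[i],
                   energy_eV = df$energy_eV[i],
                   theoretical_mz = df$theoretical_mz[i],
                   measured_mz = df$measured_mz[i], rt_min = df$rt_min[i])
  })
  do.call(ion_table, rows)
}
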