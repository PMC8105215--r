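#' Monoisotopic masses of the principal isotopes
#'
#' Masses (u) of the lightest stable / principal isotope of each supported
#' element, to at least six decimals, plus the electron mass. These suffice
#' for small-molecule beta-lactam work; extend here if other elements are
#' needed.
#'
#' @format Named numeric vector, one element per symbol.
#' @keywords internal
.isotope_masses <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  Na = 22.9897692809,
  K  = 38.96370668,
  Li = 7.01600455,
  Si = 27.9769265325
)

.electron_mass <- 0.000548579909

#' Parse an elemental formula
#'
#' Turns a Hill-style formula string such as \code{"C8H8NO5"} into a named
#' vector of element counts. Only element symbols in the internal isotope
#' table are accepted; an unknown symbol is an error naming the offending
#' token. Counts of one may be omitted (\code{"NO5"} means one N, five O).
#'
#' @param composition Formula string, e.g. \code{"C10H11N4O5S"}.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C8H8NO5")
#' @export
parse_formula <- function(composition) {
  stopifnot(is.character(composition), length(composition) == 1L)
  comp <- gsub("\\s", "", composition)
  if (!nzchar(comp)) {
    stop("empty elemental formula", call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", comp)[[1]]
  tokens <- regmatches(comp, gregexpr("[A-Z][a-z]?[0-9]*", comp))[[1]]
  if (sum(attr(m, "match.length")) != nchar(comp)) {
    stop("cannot parse elemental formula: '", composition, "'", call. = FALSE)
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(.isotope_masses)) {
      stop("unknown element symbol '", sym, "' in formula '", composition,
           "'", call. = FALSE)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts
}

#' Theoretical monoisotopic m/z of an ion
#'
#' Sums the principal-isotope masses of the elemental composition, corrects
#' for electron gain or loss (one electron mass added per negative charge,
#' subtracted per positive charge), and divides by the absolute charge.
#' With \code{charge = 0} the neutral monoisotopic mass is returned.
#'
#' @param composition Elemental formula string (see [parse_formula()]).
#' @param charge Signed integer charge of the ion; 0 for the neutral mass.
#' @return Monoisotopic m/z (or neutral mass) in u, full double precision.
#' @examples
#' monoisotopic_mz("C8H8NO5", -1)    # clavulanate anion, 198.04080
#' monoisotopic_mz("C10H11N4O5S", -1) # tazobactam anion, 299.04556
#' @export
monoisotopic_mz <- function(composition, charge = -1L) {
  stopifnot(is.numeric(charge), length(charge) == 1L, charge == round(charge))
  counts <- parse_formula(composition)
  mass <- sum(.isotope_masses[names(counts)] * counts)
  if (charge == 0) {
    return(mass)
  }
  mass <- mass - charge * .electron_mass
  mass / abs(charge)
}

#' Mass accuracy in parts per million
#'
#' Signed relative deviation of a measured m/z from the theoretical value:
#' \deqn{MA = (m/z_{exp} - m/z_{theor}) / m/z_{theor} \times 10^6}
#' No clamping is applied; wildly wrong measurements give wildly large ppm.
#'
#' @param measured Measured m/z (> 0). Vectorised.
#' @param theoretical Theoretical m/z (> 0).
#' @return Signed mass accuracy in ppm.
#' @examples
#' mass_accuracy_ppm(198.04048, 198.04080)
#' @export
mass_accuracy_ppm <- function(measured, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  if (any(!is.finite(measured)) || any(measured <= 0)) {
    stop("measured m/z must be positive", call. = FALSE)
  }
  (measured - theoretical) / theoretical * 1e6
}
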