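## Elemental monoisotopic masses and isotope tables (IUPAC/CODATA values).
## Masses of the most abundant isotope, used for accurate-mass arithmetic.

.MONO <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668
)

## Per-element isotope tables: mass and natural abundance, ordered by
## increasing neutron count. Monoisotopic = first row by construction.
.ISOTOPES <- list(
  C = list(mass = c(12.0, 13.0033548378),
           abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.00782503207, 2.0141017778),
           abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740048, 15.0001088982),
           abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.9949146196, 16.9991317, 17.9991610),
           abundance = c(0.99757, 0.00038, 0.00205)),
  P = list(mass = 30.97376163, abundance = 1.0),
  S = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Na = list(mass = 22.9897692809, abundance = 1.0),
  K = list(mass = c(38.96370668, 39.96399848, 40.96182576),
           abundance = c(0.932581, 0.000117, 0.067302))
)

## Mass of a proton; the deprotonated-ion convention [M-H]- subtracts this
## (the electron stays with the ion; the ~0.5 mDa electron mass is below
## the 2-decimal reporting precision used throughout).
.PROTON <- 1.007276

#' Parse an elemental formula string
#'
#' Parses a Hill-style elemental formula such as `"C47H83O13P"` into a
#' named integer vector of element counts. Only the elements relevant to
#' lipid chemistry (C, H, N, O, P, S, Na, K) are accepted.
#'
#' @param formula Character scalar, e.g. `"C42H80NO10P"`.
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C47H83O13P")
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula: '", formula, "'")
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  n[is.na(n)] <- 1L
  bad <- setdiff(el, names(.MONO))
  if (length(bad))
    stop("unknown element(s) in formula '", formula, "': ",
         paste(bad, collapse = ", "))
  counts <- tapply(n, factor(el, levels = names(.MONO)), sum)
  counts <- counts[!is.na(counts)]
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

.formatFormula <- function(counts) {
  counts <- counts[counts > 0]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of an elemental formula
#'
#' Sums most-abundant-isotope masses over the formula's element counts.
#'
#' @param formula Formula string or named count vector from
#'   [parseFormula()].
#' @return Mass in Da.
#' @examples
#' monoisotopicMass("H2O")        # 18.01056
#' monoisotopicMass("C47H83O13P") # neutral PI(38:4)
#' @export
monoisotopicMass <- function(formula) {
  counts <- if (is.character(formula)) parseFormula(formula) else formula
  bad <- setdiff(names(counts), names(.MONO))
  if (length(bad))
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("negative element count")
  sum(.MONO[names(counts)] * counts)
}

#' Aggregated isotope envelope of a formula
#'
#' Computes the isotopologue envelope aggregated by neutron count: the
#' relative abundance and abundance-weighted exact mass offset of the
#' M+0, M+1, ... M+j species, by convolving the per-element natural
#' isotope distributions (binomial/multinomial convolution expressed as
#' polynomial multiplication over neutron-number offsets).
#'
#' For CHNOPS lipids the offsets are close to `1.00336 * j`; the exact
#' aggregated offsets returned here reproduce, e.g., the M+2 isotopologue
#' of PI(38:4) falling within 0.01 m/z of the monoisotopic peak of
#' PI(38:3) — an isobaric interference that survives centroiding.
#'
#' @param formula Formula string or named count vector.
#' @param nIsotopes Number of isotope peaks beyond monoisotopic to return.
#' @return `data.frame` with columns `offset` (Da above monoisotopic),
#'   `abundance` (relative to total, sums to <= 1 over returned rows).
#' @examples
#' isotopeEnvelope("C", 1)                # M+1 = 1.07%
#' isotopeEnvelope("C47H83O13P", 2)       # PI(38:4) envelope
#' @export
isotopeEnvelope <- function(formula, nIsotopes = 2L) {
  counts <- if (is.character(formula)) parseFormula(formula) else formula
  nI <- as.integer(nIsotopes)
  stopifnot(nI >= 0L)
  ## polynomial coefficients: p[j+1] = probability of j extra neutrons,
  ## pm[j+1] = probability-weighted total mass at j extra neutrons
  p <- c(1, rep(0, nI))
  pm <- rep(0, nI + 1L)
  for (el in names(counts)) {
    iso <- .ISOTOPES[[el]]
    if (is.null(iso)) stop("unknown element: ", el)
    ep <- iso$abundance
    emass <- iso$mass
    for (i in seq_len(counts[[el]])) {
      np <- rep(0, nI + 1L)
      npm <- rep(0, nI + 1L)
      for (k in seq_along(ep)) {
        j <- k - 1L
        if (j > nI) break
        idx <- seq_len(nI + 1L - j)
        np[idx + j] <- np[idx + j] + p[idx] * ep[k]
        npm[idx + j] <- npm[idx + j] + (pm[idx] + p[idx] * emass[k]) * ep[k]
      }
      p <- np
      pm <- npm
    }
  }
  mono <- monoisotopicMass(counts)
  off <- ifelse(p > 0, pm / p - mono, NA_real_)
  off[1] <- 0
  ## abundances are absolute isotopologue probabilities, so the returned
  ## (truncated) envelope sums to at most 1
  data.frame(offset = off, abundance = p)
}
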