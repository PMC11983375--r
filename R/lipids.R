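## Lipid shorthand -> elemental formula, ion hypotheses, theoretical m/z.

## Composition of a diacyl/ether/sphingo lipid class as a function of the
## total acyl (or sphingoid + N-acyl) carbon count C and total double-bond
## count D. Each entry gives the element counts as intercepts plus the C
## and D coefficients of the hydrogen count: H = 2*C + hInt - 2*D.
.LIPID_CLASSES <- list(
  ##            extra C  hInt   N   O   P   S
  "PA"      = c(cExt = 3, hInt = 5,  N = 0, O = 8,  P = 1, S = 0),
  "PA-O"    = c(cExt = 3, hInt = 7,  N = 0, O = 7,  P = 1, S = 0),
  "PE"      = c(cExt = 5, hInt = 10, N = 1, O = 8,  P = 1, S = 0),
  "PE-O"    = c(cExt = 5, hInt = 12, N = 1, O = 7,  P = 1, S = 0),
  "PS"      = c(cExt = 6, hInt = 10, N = 1, O = 10, P = 1, S = 0),
  "PG"      = c(cExt = 6, hInt = 11, N = 0, O = 10, P = 1, S = 0),
  "PI"      = c(cExt = 9, hInt = 15, N = 0, O = 13, P = 1, S = 0),
  "LPI"     = c(cExt = 9, hInt = 17, N = 0, O = 12, P = 1, S = 0),
  "SM"      = c(cExt = 5, hInt = 13, N = 2, O = 6,  P = 1, S = 0),
  "SHexCer" = c(cExt = 6, hInt = 11, N = 1, O = 11, P = 0, S = 1),
  "SHex2Cer" = c(cExt = 12, hInt = 21, N = 1, O = 16, P = 0, S = 1),
  "NeuAcHex2Cer" = c(cExt = 23, hInt = 38, N = 2, O = 21, P = 0, S = 0)
)

#' Elemental formula of a lipid from class shorthand
#'
#' Builds the elemental formula of a lipid given its class, total carbon
#' count and total double-bond count in the usual `class C:D` shorthand
#' (e.g. `PI 38:4`). Ether-linked glycerophospholipids use the `-O`
#' suffixed classes (`PE-O`, `PA-O`); `hydroxyl` adds additional oxygens
#' for the `(OH)` sphingolipid variants. Sphingolipid shorthand counts the
#' sphingoid-base double bond in `D`.
#'
#' @param class Lipid class, one of `names(simsLipids:::.LIPID_CLASSES)`.
#' @param carbons Total acyl/sphingoid carbons.
#' @param doubleBonds Total double bonds.
#' @param hydroxyl Extra hydroxyl count (0 for the plain species).
#' @return Formula string, e.g. `"C47H83O13P"`.
#' @examples
#' lipidFormula("PI", 38, 4)   # "C47H83O13P"
#' lipidFormula("PS", 36, 1)   # "C42H80NO10P"
#' @export
lipidFormula <- function(class, carbons, doubleBonds, hydroxyl = 0L) {
  cls <- .LIPID_CLASSES[[class]]
  if (is.null(cls))
    stop("unknown lipid class: '", class, "'")
  C <- as.integer(carbons); D <- as.integer(doubleBonds)
  stopifnot(C > 0, D >= 0)
  h <- 2L * C + cls[["hInt"]] - 2L * D
  if (h <= 0) stop("double-bond count too high for ", class, " ", C, ":", D)
  counts <- c(C = C + cls[["cExt"]], H = h, N = cls[["N"]],
              O = cls[["O"]] + as.integer(hydroxyl), P = cls[["P"]],
              S = cls[["S"]])
  .formatFormula(counts[counts > 0])
}

## Neutral-loss compositions for the supported fragment-ion types.
## PS loses its serine head group (C3H5NO2, 87.0320 Da) to give a PA-like
## ion; sulfoglycosphingolipids lose N-acetylhexosamine-H2O (C8H13NO5) or
## a monosaccharide (C6H10O5). Sphingomyelin is observed demethylated.
.ION_TYPES <- list(
  "[M-H]-" = list(loss = NULL, demethyl = FALSE),
  "[M-CH3]-" = list(loss = NULL, demethyl = TRUE),
  "[M-H-C3H5O2N]-" = list(loss = "C3H5NO2", demethyl = FALSE),
  "[M-C8H13NO5]-" = list(loss = "C8H13NO5", demethyl = FALSE),
  "[M-C6H10O5]-" = list(loss = "C6H10O5", demethyl = FALSE)
)

#' Theoretical m/z of a lipid ion
#'
#' Computes the theoretical m/z of a negative-mode lipid ion from an
#' elemental formula. The deprotonated ion `[M-H]-` is the neutral
#' monoisotopic mass minus 1.007276 Da (proton; the electron stays with
#' the ion and its mass is below 2-decimal reporting precision).
#' Neutral-loss fragment ions subtract the loss composition from the
#' `[M-H]-` composition; sphingomyelins are observed as the demethylated
#' `[M-CH3]-` species (neutral mass minus CH3).
#'
#' @param formula Elemental formula of the intact (neutral) species.
#' @param ionType One of `"[M-H]-"`, `"[M-CH3]-"`, `"[M-H-C3H5O2N]-"`
#'   (PS fragment), `"[M-C8H13NO5]-"`, `"[M-C6H10O5]-"`.
#' @return Theoretical m/z.
#' @examples
#' mzIon("C47H83O13P")                        # PI(38:4) [M-H]- 885.5499
#' mzIon(lipidFormula("PS", 40, 5), "[M-H-C3H5O2N]-")
#' @export
mzIon <- function(formula, ionType = "[M-H]-") {
  it <- .ION_TYPES[[ionType]]
  if (is.null(it))
    stop("unknown ion type: '", ionType, "'; supported: ",
         paste(names(.ION_TYPES), collapse = ", "))
  counts <- if (is.character(formula)) parseFormula(formula) else formula
  if (it$demethyl) {
    mz <- monoisotopicMass(counts) - monoisotopicMass("CH3")
    return(mz)
  }
  mz <- monoisotopicMass(counts) - .PROTON
  if (!is.null(it$loss)) {
    loss <- parseFormula(it$loss)
    full <- counts
    for (el in names(loss)) {
      have <- if (el %in% names(full)) full[[el]] else 0L
      if (have < loss[[el]])
        stop("neutral loss ", it$loss, " exceeds composition of ",
             .formatFormula(counts))
    }
    mz <- mz - monoisotopicMass(loss)
  }
  mz
}

#' Load a lipid reference database
#'
#' Reads a lipid species table (CSV with columns `name`, `class`,
#' `carbons`, `doubleBonds`, `hydroxyl`, `formula`, `prior`) such as the
#' bundled reference reproducing the species discussed in the
#' lymphoma-tissue application, plus decoy species flagged `prior = 0`.
#' When `formula` is empty it is derived from the class shorthand with
#' [lipidFormula()].
#'
#' @param path CSV path; default is the bundled database.
#' @return `data.frame` of species with parsed formulas.
#' @export
loadLipidDb <- function(path = system.file("extdata", "lipid_db.csv",
                                           package = "simsLipids")) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "class", "carbons", "doubleBonds", "hydroxyl",
            "formula", "prior")
  if (!all(need %in% names(db)))
    stop("lipid database must have columns: ", paste(need, collapse = ", "))
  fill <- is.na(db$formula) | db$formula == ""
  if (any(fill))
    db$formula[fill] <- mapply(lipidFormula, db$class[fill],
                               db$carbons[fill], db$doubleBonds[fill],
                               db$hydroxyl[fill])
  if (anyDuplicated(db$name))
    stop("duplicate species names in database: ",
         paste(unique(db$name[duplicated(db$name)]), collapse = ", "))
  db
}

#' Expand a species table into ion hypotheses
#'
#' For every species, generates the ion hypotheses that the imaging
#' experiment can observe in negative mode: `[M-H]-` for
#' glycerophospholipids and sulfoglycosphingolipids, `[M-CH3]-` for
#' sphingomyelins, plus the PS serine-loss fragment for PS species and
#' the N-acetylhexosamine / monosaccharide losses for sulfatide species
#' when `fragments = TRUE`.
#'
#' @param db Species table from [loadLipidDb()].
#' @param fragments Include fragment-ion hypotheses.
#' @return `data.frame` with columns `name`, `class`, `formula`,
#'   `ionType`, `theoreticalMz`, `prior`.
#' @export
ionHypotheses <- function(db, fragments = TRUE) {
  rows <- lapply(seq_len(nrow(db)), function(i) {
    sp <- db[i, ]
    types <- if (sp$class == "SM") "[M-CH3]-" else "[M-H]-"
    if (fragments) {
      if (sp$class == "PS")
        types <- c(types, "[M-H-C3H5O2N]-")
      if (sp$class %in% c("SHexCer", "SHex2Cer"))
        types <- c(types, "[M-C6H10O5]-")
      if (sp$class == "NeuAcHex2Cer")
        types <- c(types, "[M-C8H13NO5]-")
    }
    data.frame(name = sp$name, class = sp$class, formula = sp$formula,
               ionType = types,
               theoreticalMz = vapply(types, function(t)
                 tryCatch(mzIon(sp$formula, t), error = function(e) NA_real_),
                 numeric(1)),
               prior = sp$prior, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$theoreticalMz), , drop = FALSE]
  rownames(out) <- NULL
  out
}
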