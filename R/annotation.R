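## Accurate-mass lipid annotation: windowed database search, the PS->PA
## fragment rule, reporting-confidence levels, ppm accuracy summaries.

.PS_LOSS <- 87.03203  # serine head group C3H5NO2, monoisotopic

#' Reporting confidence of an assignment
#'
#' Putative accurate-mass assignments below m/z 900 get metabolomics
#' reporting confidence level 2; species at or above m/z 900 may be
#' in-source fragments of larger glycosphingolipids and are reported as
#' level 2/3. The boundary value 900.00 is assigned to the upper class.
#'
#' @param measuredMz Measured m/z (vectorized).
#' @return `"level2"` or `"level2_3"` per value.
#' @export
confidenceOf <- function(measuredMz) {
  ifelse(measuredMz < 900, "level2", "level2_3")
}

#' Windowed accurate-mass search
#'
#' Returns every ion hypothesis whose theoretical m/z lies within
#' `window` of the measured value, ranked by absolute ppm error (ties by
#' the optional biological-plausibility `prior`, then by m/z).
#'
#' @param measuredMz A single measured m/z.
#' @param hypotheses Ion-hypothesis table from [ionHypotheses()].
#' @param window Search half-width in m/z (the +/- 0.01 convention).
#' @return `data.frame` of candidate assignments (possibly empty) with
#'   `measuredMz`, `name`, `class`, `formula`, `ionType`,
#'   `theoreticalMz`, `deltaMz`, `ppm`, `confidence`, `psPaRuleApplied`.
#' @export
searchAssignments <- function(measuredMz, hypotheses, window = 0.01) {
  stopifnot(length(measuredMz) == 1L, window > 0)
  delta <- measuredMz - hypotheses$theoreticalMz
  hit <- abs(delta) <= window
  out <- hypotheses[hit, , drop = FALSE]
  if (nrow(out) == 0L)
    return(data.frame(measuredMz = numeric(), name = character(),
                      class = character(), formula = character(),
                      ionType = character(), theoreticalMz = numeric(),
                      deltaMz = numeric(), ppm = numeric(),
                      confidence = character(),
                      psPaRuleApplied = logical()))
  out$measuredMz <- measuredMz
  out$deltaMz <- delta[hit]
  out$ppm <- 1e6 * out$deltaMz / out$theoreticalMz
  out$confidence <- confidenceOf(measuredMz)
  out$psPaRuleApplied <- FALSE
  prior <- if (is.null(out$prior)) rep(0, nrow(out)) else out$prior
  ## exact ppm ties (e.g. a PA [M-H]- vs the isobaric PS fragment) rank
  ## the intact deprotonated ion first; the PS->PA rule may then demote it
  out <- out[order(abs(out$ppm), -prior, out$ionType != "[M-H]-",
                   out$theoreticalMz), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("measuredMz", "name", "class", "formula", "ionType",
          "theoreticalMz", "deltaMz", "ppm", "confidence",
          "psPaRuleApplied")]
}

#' Annotate a peak table against a lipid database
#'
#' Assigns each centroid its best in-window ion hypothesis (one row per
#' annotated centroid; centroids with no hit are omitted), then applies
#' the PS->PA fragment rule when requested.
#'
#' @param table A [PeakTable-class].
#' @param hypotheses Ion-hypothesis table from [ionHypotheses()].
#' @param window Search half-width (m/z).
#' @param psRule Apply [applyPsPaRule()].
#' @param psThreshold Intensity threshold for a "significant" intact PS
#'   peak, as a fraction of the table's base-peak apex intensity.
#' @return Assignment `data.frame` (see [searchAssignments()]).
#' @export
annotatePeaks <- function(table, hypotheses, window = 0.01, psRule = TRUE,
                          psThreshold = 0.01) {
  p <- peaks(table)
  rows <- lapply(p$mzCenter, function(m) {
    hits <- searchAssignments(m, hypotheses, window = window)
    if (nrow(hits)) hits[1, , drop = FALSE] else NULL
  })
  ann <- do.call(rbind, rows)
  if (is.null(ann))
    return(searchAssignments(0, hypotheses[0, , drop = FALSE], window))
  rownames(ann) <- NULL
  if (psRule)
    ann <- applyPsPaRule(ann, table, hypotheses, window = window,
                         significanceThreshold = psThreshold)
  ann
}

#' Reassign PA peaks that are PS in-source fragments
#'
#' PS lipids lose their serine head group (87.0320 Da) in SIMS, yielding
#' a PA-like ion, so a PA assignment is withdrawn when a significant
#' intact PS signal sits 87.0320 above it: the assignment at that m/z is
#' replaced by the corresponding PS fragment hypothesis and flagged. The
#' number of annotated peaks never changes — only their hypotheses.
#'
#' @param assignments Assignment table ([annotatePeaks()] output).
#' @param table The [PeakTable-class] searched for intact PS peaks.
#' @param hypotheses Ion-hypothesis table (must include PS fragment
#'   hypotheses).
#' @param window Match half-width (m/z).
#' @param significanceThreshold Fraction of the base-peak apex intensity
#'   an intact PS peak must exceed to count as significant.
#' @return The assignment table with PA rows reassigned where the rule
#'   fires.
#' @export
applyPsPaRule <- function(assignments, table, hypotheses, window = 0.01,
                          significanceThreshold = 0.01) {
  p <- peaks(table)
  if (nrow(p) == 0L || nrow(assignments) == 0L) return(assignments)
  basePeak <- max(p$apexIntensity)
  thr <- significanceThreshold * basePeak
  paRows <- which(assignments$class %in% c("PA", "PA-O") &
                  assignments$ionType == "[M-H]-")
  psFrag <- hypotheses[hypotheses$ionType == "[M-H-C3H5O2N]-", ,
                       drop = FALSE]
  for (i in paRows) {
    target <- assignments$measuredMz[i] + .PS_LOSS
    cand <- which(abs(p$mzCenter - target) <= window &
                  p$apexIntensity > thr)
    if (!length(cand)) next
    ## the intact peak must itself carry an intact PS assignment
    intactIsPS <- any(vapply(p$mzCenter[cand], function(m) {
      hits <- searchAssignments(m, hypotheses, window = window)
      nrow(hits) > 0L && hits$class[1] == "PS" &&
        hits$ionType[1] == "[M-H]-"
    }, logical(1)))
    if (!intactIsPS) next
    frag <- searchAssignments(assignments$measuredMz[i], psFrag,
                              window = window)
    if (nrow(frag) == 0L) next
    frag <- frag[1, , drop = FALSE]
    frag$psPaRuleApplied <- TRUE
    assignments[i, ] <- frag
  }
  assignments
}

#' Mass-accuracy summary of an assignment list
#'
#' @param assignments Assignment table with a `ppm` column.
#' @return List with `meanAbsPpm` (arithmetic mean of absolute ppm
#'   errors) and `fractionBelow5ppm` (percentage of assignments with
#'   absolute error under 5 ppm).
#' @export
accuracySummary <- function(assignments) {
  if (is.null(assignments$ppm) || nrow(assignments) == 0L)
    stop("empty assignment list")
  absPpm <- abs(assignments$ppm)
  list(meanAbsPpm = mean(absPpm),
       fractionBelow5ppm = 100 * mean(absPpm < 5))
}

#' Write assignments as CSV
#' @param assignments Assignment table.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeAssignments <- function(assignments, path) {
  utils::write.csv(assignments, path, row.names = FALSE)
  invisible(path)
}
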