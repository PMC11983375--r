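## End-to-end orchestration: simulate/ingest -> peak tables -> centroid
## -> normalize -> mask -> composite -> PCA/k-means -> annotate -> report.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with the defaults used
#' throughout: dual peak-table ranges within the m/z 590-1190 analysis
#' window, the +/- 0.01 annotation window, and explicit seeds for the
#' masking and clustering stages so reruns are bit-reproducible.
#'
#' @param picker [pickerParams()].
#' @param analysisRange `(lo, hi)` m/z restriction for the analysis.
#' @param maskSeed,mvaSeed RNG seeds.
#' @param nComponents PCA components.
#' @param k k-means cluster count for the main run.
#' @param kSweep Cluster counts for the sweep (NULL skips it).
#' @param annotationWindow Accurate-mass search half-width (m/z).
#' @param psThreshold Significant-PS threshold (fraction of base peak).
#' @return A config list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(picker = pickerParams(),
                           analysisRange = c(590, 1190),
                           maskSeed = 11L, mvaSeed = 17L,
                           nComponents = 5L, k = 3L, kSweep = NULL,
                           annotationWindow = 0.01, psThreshold = 0.01) {
  stopifnot(inherits(picker, "PickerParams"), analysisRange[1] <
              analysisRange[2], annotationWindow > 0)
  structure(list(picker = picker, analysisRange = analysisRange,
                 maskSeed = as.integer(maskSeed),
                 mvaSeed = as.integer(mvaSeed),
                 nComponents = as.integer(nComponents), k = as.integer(k),
                 kSweep = kSweep, annotationWindow = annotationWindow,
                 psThreshold = psThreshold), class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; recognized keys mirror [pipelineConfig()]
#'   arguments (`picker` as a sub-map of [pickerParams()] arguments).
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  picker <- do.call(pickerParams, c(
    y$picker[setdiff(names(y$picker), "ranges")],
    if (!is.null(y$picker$ranges)) list(ranges = y$picker$ranges)))
  args <- y[setdiff(names(y), "picker")]
  do.call(pipelineConfig, c(list(picker = picker), args))
}

#' Run the full analysis pipeline
#'
#' Executes the whole chain on either a [SceneSpec-class] (simulating
#' the input cube first) or an existing multi-sample
#' [SpectralImageCube-class]: per-image mean TIC spectra, the combined
#' dual-range peak table, per-pixel centroiding, per-pixel sum
#' normalization with square root, the two-cluster substrate mask with
#' zero filling, imaging PCA and k-means, cluster difference spectra,
#' and accurate-mass annotation of the analyzed centroids. If `outDir`
#' is given, the stage artifacts (peak table, mask, scores, labels,
#' loadings, assignments, manifest) are written there as CSV/PNG/JSON.
#'
#' @param input A [SceneSpec-class] or [SpectralImageCube-class].
#' @param config [pipelineConfig()].
#' @param db Lipid species table from [loadLipidDb()].
#' @param outDir Output directory (`NULL` = no artifacts written).
#' @return Invisibly, a list with every stage object (`cube`, `truth`,
#'   `meanSpectra`, `peakTable`, `features`, `mask`, `pca`, `kmeans`,
#'   `sweep`, `differences`, `assignments`, `accuracy`, `manifest`).
#' @export
runPipeline <- function(input, config = pipelineConfig(),
                        db = loadLipidDb(), outDir = NULL) {
  truth <- NULL
  if (is(input, "SceneSpec")) {
    sim <- simulateCube(makeScene(input, db))
    cube <- sim$cube
    truth <- sim$truth
  } else if (is(input, "SpectralImageCube")) {
    cube <- input
  } else stop("input must be a SceneSpec or a SpectralImageCube")

  grid <- seq(config$analysisRange[1], config$analysisRange[2], by = 0.005)
  perImage <- splitCube(cube)
  meanSpectra <- lapply(perImage, meanTicSpectrum, grid = grid)
  peakTable <- buildPeakTables(meanSpectra, config$picker)
  features <- centroidImage(cube, peakTable)
  features <- normalizePixels(features)
  mask <- substrateMask(features, seed = config$maskSeed)
  features <- applyMask(features, mask)
  pca <- runPCA(features, nComponents = config$nComponents)
  km <- runKMeans(features, k = config$k, seed = config$mvaSeed)
  sweep <- if (!is.null(config$kSweep))
    sweepKMeans(features, ks = config$kSweep, seed = config$mvaSeed)
  diffs <- differenceSpectra(km, features)
  hyp <- ionHypotheses(db)
  assignments <- annotatePeaks(peakTable, hyp,
                               window = config$annotationWindow,
                               psThreshold = config$psThreshold)
  accuracy <- if (nrow(assignments)) accuracySummary(assignments)

  manifest <- list(
    stages = c("input", "mean_spectra", "peak_table", "centroid",
               "normalize", "mask", "mva", "annotate"),
    nPixels = nPixels(cube), nImages = length(perImage),
    nCentroids = length(peakTable),
    nTissuePixels = sum(mask@tissue),
    seeds = list(mask = config$maskSeed, mva = config$mvaSeed,
                 scene = if (is(input, "SceneSpec")) input@seed),
    analysisRange = config$analysisRange,
    annotationWindow = config$annotationWindow,
    nAssigned = nrow(assignments))

  res <- list(cube = cube, truth = truth, meanSpectra = meanSpectra,
              peakTable = peakTable, features = features, mask = mask,
              pca = pca, kmeans = km, sweep = sweep, differences = diffs,
              assignments = assignments, accuracy = accuracy,
              manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writePeakTable(peakTable, file.path(outDir, "peak_table.csv"))
    writeMask(features, csvPath = file.path(outDir, "mask.csv"),
              pngPath = file.path(outDir, "mask.png"))
    utils::write.csv(data.frame(pca@pixelInfo[c("row", "col", "sampleId")],
                                pca@scores),
                     file.path(outDir, "pca_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(mz = pca@mz, pca@loadings),
                     file.path(outDir, "pca_loadings.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(km@pixelInfo[c("row", "col", "sampleId")],
                                cluster = km@labels),
                     file.path(outDir, "kmeans_labels.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(mz = diffs@mz, t(diffs@perCluster)),
                     file.path(outDir, "difference_spectra.csv"),
                     row.names = FALSE)
    writeAssignments(assignments, file.path(outDir, "assignments.csv"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(res)
}

#' Human-readable pipeline report
#'
#' Prints a stage-by-stage summary: pixel and centroid counts, mask
#' diagnostics, variance explained, cluster sizes, the annotated loading
#' table of each requested component (flagged "unannotated" when the
#' annotation stage was skipped) and the ppm accuracy summary.
#'
#' @param run Result of [runPipeline()].
#' @param components Components whose loading tables to include.
#' @param topN Peaks per loading sign.
#' @return The report lines, invisibly; printed as a side effect.
#' @export
pipelineReport <- function(run, components = 2L, topN = 5L) {
  out <- c(
    sprintf("Pipeline run: %d pixels in %d images, %d centroids",
            run$manifest$nPixels, run$manifest$nImages,
            run$manifest$nCentroids),
    sprintf("Tissue pixels after masking: %d / %d",
            run$manifest$nTissuePixels, run$manifest$nPixels),
    sprintf("PCA variance explained (top %d): %s", ncol(run$pca@scores),
            paste(sprintf("%.1f%%", 100 * run$pca@explainedVariance /
                            run$pca@totalVariance), collapse = " ")),
    sprintf("k-means (k = %d) cluster sizes: %s", run$kmeans@k,
            paste(tabulate(run$kmeans@labels[!is.na(run$kmeans@labels)],
                           run$kmeans@k), collapse = " ")))
  annotated <- nrow(run$assignments) > 0L
  for (comp in components) {
    tab <- loadingReport(run$pca, comp, topN = topN)
    if (annotated) {
      idx <- vapply(tab$mzCenter, function(m) {
        j <- which(abs(run$assignments$measuredMz - m) < 1e-9)
        if (length(j)) j[1] else NA_integer_
      }, integer(1))
      tab$lipid <- ifelse(is.na(idx), "", run$assignments$name[idx])
    } else tab$lipid <- "unannotated"
    out <- c(out, sprintf("PC%d loading peaks:", comp),
             utils::capture.output(print(tab, digits = 4)))
  }
  if (!is.null(run$accuracy))
    out <- c(out, sprintf(
      "Annotation accuracy: mean |ppm| = %.1f, %.0f%% below 5 ppm",
      run$accuracy$meanAbsPpm, run$accuracy$fractionBelow5ppm))
  cat(out, sep = "\n")
  invisible(out)
}
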