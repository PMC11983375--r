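## Shared fixtures, all generated in code.

## A tiny hand-built cube: n pixels on a shared or per-pixel m/z axis.
tinyCube <- function(nPixels = 4L, sharedAxis = TRUE, rasterPx = 2L) {
  layout <- TileLayout(tileEdgeUm = 100, rasterPx = rasterPx)
  coords <- cbind(row = (seq_len(nPixels) - 1L) %/% rasterPx,
                  col = (seq_len(nPixels) - 1L) %% rasterPx)
  spectra <- lapply(seq_len(nPixels), function(i) {
    mz <- if (sharedAxis) seq(600, 610, by = 0.5)
          else seq(600, 610, by = 0.5) + i * 0.01
    list(mz = mz, intensity = abs(sin(mz + i)) * 10 + i)
  })
  SpectralImageCube(layout, coords, spectra, sampleId = "toy",
                    condition = "unknown")
}

## Noiseless sum of Gaussian lines on a uniform grid.
gaussSpectrum <- function(centers, sigmas, heights,
                          grid = seq(590, 1190, by = 0.005)) {
  y <- numeric(length(grid))
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-(grid - centers[i])^2 / (2 * sigmas[i]^2))
  list(mz = grid, intensity = y)
}

## One shared end-to-end run on the default scene at reduced raster;
## computed once per test session (pixel count scaled for test runtime,
## profiles/noise/geometry at generator defaults).
.fixtures <- new.env(parent = emptyenv())

defaultRun <- function() {
  if (is.null(.fixtures$run)) {
    spec <- defaultSceneSpec(rasterPx = 20L, seed = 101L)
    cfg <- pipelineConfig(picker = pickerParams(nKeep = 150L))
    .fixtures$run <- suppressMessages(runPipeline(spec, cfg))
  }
  .fixtures$run
}

## Coarse ground-truth labels {substrate, healthy, cancer} for recovery.
coarseTruth <- function(run) {
  reg <- run$truth$region
  ifelse(reg == "substrate", "substrate",
         ifelse(reg %in% c("dlbcl", "dlbcl_aggressive"), "cancer",
                "healthy"))
}

## A raw-stage FeatureImage straight from a counts matrix
## (centroids x pixels), laid out on a square canvas.
.rawImage <- function(counts) {
  nPix <- ncol(counts)
  side <- max(2L, as.integer(ceiling(sqrt(nPix))))
  pt <- PeakTable(data.frame(
    mzCenter = seq(700, by = 10, length.out = nrow(counts)),
    windowLo = seq(699.9, by = 10, length.out = nrow(counts)),
    windowHi = seq(700.1, by = 10, length.out = nrow(counts)),
    apexIntensity = 1, merged = FALSE))
  pd <- data.frame(row = (seq_len(nPix) - 1L) %/% side,
                   col = (seq_len(nPix) - 1L) %% side,
                   sampleId = "s", condition = "unknown")
  FeatureImage(counts, pt, pd, TileLayout(100, side))
}

## The same from a pixels x channels matrix, already on the normalized
## stage so multivariate analysis accepts it directly. Translating all
## values to be non-negative satisfies the intensity invariant without
## changing covariance structure or cluster geometry.
.normImage <- function(x) {
  if (min(x) < 0) x <- x - min(x)
  img <- .rawImage(t(x))
  img@normStage <- "sum1_sqrt"
  img
}

## The published 2-decimal m/z values of the annotated loading tables
## (union over the reported healthy/cancer, aggressive-subtype and
## histiocyte contrasts), used to reconstruct the assignment list for
## the accuracy summary.
printedTableMz <- function() {
  sort(unique(c(
    885.55, 857.52, 812.55, 810.53, 788.54, 766.54, 750.54, 749.52,
    738.51, 722.51, 619.28, 599.32, 1151.72, 1050.68, 915.59, 913.58,
    909.55, 889.58, 863.56, 861.55, 859.53, 835.54, 786.53, 775.55,
    773.54, 747.51, 744.55, 742.54, 740.52, 716.53, 714.51, 1078.72,
    1052.69, 1048.67, 1024.66, 996.63, 968.59, 940.57, 906.63, 904.62,
    892.62, 890.63, 878.60, 778.57, 774.55, 887.56, 911.57, 836.55,
    834.53, 812.54, 797.64, 728.55, 725.52, 723.50, 716.54, 715.57,
    702.53, 700.53, 699.50, 687.55, 863.57)))
}
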