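#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   rowData colData colData<-
NULL

## ---------------------------------------------------------------------
## TileLayout: mosaic geometry
## ---------------------------------------------------------------------

#' Mosaic tile geometry of a SIMS image
#'
#' Describes the tiled/mosaic acquisition geometry: the physical edge
#' length of one tile, the pixel raster per tile edge, and the number of
#' tiles in each mosaic direction. Pixel indices are 0-based, row-major,
#' origin top-left; physical coordinates refer to pixel centers.
#'
#' @slot tileEdgeUm Tile edge length in micrometers.
#' @slot rasterPx Pixels per tile edge.
#' @slot mosaicRows,mosaicCols Tile counts in each direction.
#' @slot originUm Physical (x, y) coordinate of pixel (0, 0), micrometers.
#' @export
setClass("TileLayout", representation(
  tileEdgeUm = "numeric", rasterPx = "integer",
  mosaicRows = "integer", mosaicCols = "integer", originUm = "numeric"))

setValidity("TileLayout", function(object) {
  msg <- NULL
  if (object@tileEdgeUm <= 0) msg <- c(msg, "tileEdgeUm must be > 0")
  if (object@rasterPx < 2L) msg <- c(msg, "rasterPx must be >= 2")
  if (object@mosaicRows < 1L || object@mosaicCols < 1L)
    msg <- c(msg, "mosaic dimensions must be >= 1")
  if (length(object@originUm) != 2L) msg <- c(msg, "originUm must be (x, y)")
  if (is.null(msg)) TRUE else msg
})

#' @param tileEdgeUm,rasterPx,mosaicRows,mosaicCols,originUm See slots.
#' @rdname TileLayout-class
#' @export
TileLayout <- function(tileEdgeUm = 900, rasterPx = 128L, mosaicRows = 1L,
                       mosaicCols = 1L, originUm = c(0, 0)) {
  new("TileLayout", tileEdgeUm = as.numeric(tileEdgeUm),
      rasterPx = as.integer(rasterPx), mosaicRows = as.integer(mosaicRows),
      mosaicCols = as.integer(mosaicCols), originUm = as.numeric(originUm))
}

setMethod("show", "TileLayout", function(object) {
  cat(sprintf(paste0("TileLayout: %d x %d tiles of %d x %d px, ",
                     "tile edge %g um (pixel size %.5g um)\n"),
              object@mosaicRows, object@mosaicCols, object@rasterPx,
              object@rasterPx, object@tileEdgeUm,
              object@tileEdgeUm / object@rasterPx))
})

#' Canvas dimensions (pixels) of a TileLayout
#' @param layout A [TileLayout-class] object.
#' @return Integer `(rows, cols)`.
#' @export
canvasDim <- function(layout) {
  c(layout@mosaicRows * layout@rasterPx, layout@mosaicCols * layout@rasterPx)
}

## ---------------------------------------------------------------------
## SpectralImageCube: pixel grid of mass spectra
## ---------------------------------------------------------------------

#' Pixel grid of mass spectra with mosaic geometry
#'
#' Holds one mass spectrum per pixel (paired ascending m/z and
#' non-negative intensity arrays; per-pixel axes may differ, as in
#' processed-mode imzML), the mosaic [TileLayout-class], per-pixel sample
#' membership and condition labels.
#'
#' @slot layout [TileLayout-class].
#' @slot coords Integer matrix (pixels x 2) of 0-based (row, col).
#' @slot spectra List of `list(mz=, intensity=)` per pixel.
#' @slot mzRange Numeric `(lo, hi)` m/z.
#' @slot sampleId Per-pixel sample label.
#' @slot condition Per-pixel condition: `cancer`, `healthy` or `unknown`.
#' @slot polarity Scan polarity (`"negative"` for this application).
#' @export
setClass("SpectralImageCube", representation(
  layout = "TileLayout", coords = "matrix", spectra = "list",
  mzRange = "numeric", sampleId = "character", condition = "character",
  polarity = "character"))

setValidity("SpectralImageCube", function(object) {
  msg <- NULL
  n <- length(object@spectra)
  if (nrow(object@coords) != n)
    msg <- c(msg, "coords and spectra lengths differ")
  if (length(object@sampleId) != n || length(object@condition) != n)
    msg <- c(msg, "per-pixel labels must match pixel count")
  if (!all(object@condition %in% c("cancer", "healthy", "unknown")))
    msg <- c(msg, "condition must be cancer/healthy/unknown")
  if (anyDuplicated(object@coords))
    msg <- c(msg, "pixel coordinates must be unique")
  cd <- canvasDim(object@layout)
  if (n && (min(object@coords) < 0L || max(object@coords[, 1]) >= cd[1] ||
            max(object@coords[, 2]) >= cd[2]))
    msg <- c(msg, "pixel coordinates outside layout bounds")
  for (i in seq_len(min(n, 25L))) {  # spot-check invariants cheaply
    sp <- object@spectra[[i]]
    if (!is.numeric(sp$mz) || !is.numeric(sp$intensity) ||
        length(sp$mz) != length(sp$intensity)) {
      msg <- c(msg, "spectra must be paired numeric mz/intensity arrays")
      break
    }
    if (is.unsorted(sp$mz, strictly = TRUE)) {
      msg <- c(msg, sprintf("spectrum %d: m/z not strictly increasing", i))
      break
    }
    if (any(sp$intensity < 0)) {
      msg <- c(msg, sprintf("spectrum %d: negative intensity", i))
      break
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' @param layout,coords,spectra,mzRange,sampleId,condition,polarity See
#'   slots; `sampleId`/`condition` scalars are recycled over pixels.
#' @rdname SpectralImageCube-class
#' @export
SpectralImageCube <- function(layout, coords, spectra, mzRange = NULL,
                              sampleId = "sample", condition = "unknown",
                              polarity = "negative") {
  n <- length(spectra)
  coords <- matrix(as.integer(coords), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  if (is.null(mzRange)) {
    lims <- unlist(lapply(spectra, function(s)
      if (length(s$mz)) range(s$mz) else NULL))
    mzRange <- if (length(lims)) range(lims) else c(0, 0)
  }
  new("SpectralImageCube", layout = layout, coords = coords,
      spectra = spectra, mzRange = as.numeric(mzRange),
      sampleId = rep_len(as.character(sampleId), n),
      condition = rep_len(as.character(condition), n),
      polarity = polarity)
}

setMethod("show", "SpectralImageCube", function(object) {
  cat(sprintf("SpectralImageCube: %d pixels, m/z %.2f-%.2f, %s mode\n",
              length(object@spectra), object@mzRange[1], object@mzRange[2],
              object@polarity))
  cat("  samples:", paste(unique(object@sampleId), collapse = ", "), "\n")
  show(object@layout)
})

#' Number of pixels in a cube
#' @param cube A [SpectralImageCube-class].
#' @return Integer pixel count.
#' @export
nPixels <- function(cube) length(cube@spectra)

#' Split a multi-sample cube into per-sample cubes
#' @param cube A [SpectralImageCube-class].
#' @return Named list of single-sample cubes.
#' @export
splitCube <- function(cube) {
  ids <- unique(cube@sampleId)
  out <- lapply(ids, function(id) {
    keep <- cube@sampleId == id
    new("SpectralImageCube", layout = cube@layout,
        coords = cube@coords[keep, , drop = FALSE],
        spectra = cube@spectra[keep], mzRange = cube@mzRange,
        sampleId = cube@sampleId[keep], condition = cube@condition[keep],
        polarity = cube@polarity)
  })
  names(out) <- ids
  out
}

## ---------------------------------------------------------------------
## PeakTable: centroided peak list
## ---------------------------------------------------------------------

#' Centroided peak table
#'
#' A list of centroids with half-open integration windows `[lo, hi)`,
#' apex intensities and a flag marking centroids that merged several
#' unresolved (isobaric) derivative features.
#'
#' @slot peaks `data.frame` with columns `mzCenter`, `windowLo`,
#'   `windowHi`, `apexIntensity`, `merged`.
#' @export
setClass("PeakTable", representation(peaks = "data.frame"))

setValidity("PeakTable", function(object) {
  p <- object@peaks
  need <- c("mzCenter", "windowLo", "windowHi", "apexIntensity", "merged")
  if (!all(need %in% names(p)))
    return(paste("peaks must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) == 0L) return(TRUE)
  msg <- NULL
  if (is.unsorted(p$mzCenter)) msg <- c(msg, "centroids must be ascending")
  if (any(p$windowLo >= p$mzCenter | p$mzCenter >= p$windowHi))
    msg <- c(msg, "windows must satisfy lo < center < hi")
  if (nrow(p) > 1L && any(p$windowHi[-nrow(p)] > p$windowLo[-1] + 1e-12))
    msg <- c(msg, "windows must be non-overlapping")
  if (is.null(msg)) TRUE else msg
})

#' @param peaks See slot.
#' @rdname PeakTable-class
#' @export
PeakTable <- function(peaks) {
  peaks <- peaks[order(peaks$mzCenter), , drop = FALSE]
  rownames(peaks) <- NULL
  new("PeakTable", peaks = peaks)
}

setMethod("show", "PeakTable", function(object) {
  p <- object@peaks
  cat(sprintf("PeakTable: %d centroids (%d merged)", nrow(p),
              sum(p$merged)))
  if (nrow(p))
    cat(sprintf(", m/z %.4f-%.4f", min(p$mzCenter), max(p$mzCenter)))
  cat("\n")
})

#' @rdname PeakTable-class
#' @param x,object A `PeakTable` (or an object carrying one).
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname PeakTable-class
#' @export
setMethod("peaks", "PeakTable", function(x) x@peaks)

setMethod("length", "PeakTable", function(x) nrow(x@peaks))

#' Write/read a PeakTable as CSV
#' @param table A [PeakTable-class].
#' @param path CSV file path.
#' @return `readPeakTable` returns a [PeakTable-class]; `writePeakTable`
#'   returns `path` invisibly.
#' @export
writePeakTable <- function(table, path) {
  utils::write.csv(peaks(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePeakTable
#' @export
readPeakTable <- function(path) PeakTable(utils::read.csv(path))

## ---------------------------------------------------------------------
## FeatureImage: pixels x centroids matrix (SummarizedExperiment)
## ---------------------------------------------------------------------

#' Centroided feature image
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' whose assay holds centroid intensities (rows = centroids, columns =
#' pixels), with the [PeakTable-class] in `rowData`, per-pixel canvas
#' coordinates, sample membership, raw TIC and tissue mask in `colData`,
#' and the normalization stage tracked in a dedicated slot (`"raw"`,
#' `"sum1"` or `"sum1_sqrt"`).
#'
#' @slot normStage Normalization stage marker.
#' @slot layout The mosaic/canvas [TileLayout-class].
#' @export
setClass("FeatureImage", contains = "SummarizedExperiment",
         representation(normStage = "character", layout = "TileLayout"))

setValidity("FeatureImage", function(object) {
  msg <- NULL
  if (!object@normStage %in% c("raw", "sum1", "sum1_sqrt"))
    msg <- c(msg, "normStage must be raw/sum1/sum1_sqrt")
  need <- c("row", "col", "sampleId", "condition", "tic")
  if (!all(need %in% names(colData(object))))
    msg <- c(msg, paste("colData must have:", paste(need, collapse = ", ")))
  if (!all(c("mzCenter", "windowLo", "windowHi") %in%
           names(rowData(object))))
    msg <- c(msg, "rowData must carry the peak-table columns")
  if (any(assay(object) < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' @param counts Matrix, centroids x pixels.
#' @param peakTable [PeakTable-class] describing the rows.
#' @param pixelData `DataFrame`/`data.frame` with per-pixel `row`, `col`,
#'   `sampleId`, `condition` (raw TIC is computed if absent).
#' @param layout Canvas [TileLayout-class].
#' @param normStage Stage marker.
#' @rdname FeatureImage-class
#' @export
FeatureImage <- function(counts, peakTable, pixelData, layout,
                         normStage = "raw") {
  pixelData <- as(pixelData, "DataFrame")
  if (is.null(pixelData$tic)) pixelData$tic <- colSums(counts)
  if (is.null(pixelData$tissue)) pixelData$tissue <- NA
  se <- SummarizedExperiment(
    assays = list(intensity = counts),
    rowData = DataFrame(peaks(peakTable)), colData = pixelData)
  new("FeatureImage", se, normStage = normStage, layout = layout)
}

#' @rdname FeatureImage-class
#' @export
setMethod("peaks", "FeatureImage", function(x)
  as.data.frame(rowData(x)[c("mzCenter", "windowLo", "windowHi",
                             "apexIntensity", "merged")]))

#' Accessors for FeatureImage
#'
#' `normStage` returns the normalization stage marker; `mzCenters` the
#' centroid m/z values; `intensityMatrix` the pixels-by-centroids matrix
#' (the assay, transposed to the orientation multivariate analysis uses);
#' `tissueMask` the per-pixel logical tissue mask (NA before masking).
#'
#' @param x A [FeatureImage-class].
#' @name FeatureImage-accessors
#' @export
normStage <- function(x) x@normStage

#' @rdname FeatureImage-accessors
#' @export
mzCenters <- function(x) rowData(x)$mzCenter

#' @rdname FeatureImage-accessors
#' @export
intensityMatrix <- function(x) t(assay(x, "intensity"))

#' @rdname FeatureImage-accessors
#' @export
tissueMask <- function(x) colData(x)$tissue

setMethod("show", "FeatureImage", function(object) {
  cat(sprintf("FeatureImage: %d centroids x %d pixels [%s]\n",
              nrow(object), ncol(object), object@normStage))
  cat("  samples:", paste(unique(colData(object)$sampleId), collapse = ", "),
      "\n")
  mk <- tissueMask(object)
  if (!all(is.na(mk)))
    cat(sprintf("  tissue pixels: %d / %d\n", sum(mk), length(mk)))
})

## ---------------------------------------------------------------------
## Small result classes
## ---------------------------------------------------------------------

#' Substrate mask result
#'
#' @slot tissue Per-pixel logical, `TRUE` = tissue.
#' @slot method Masking method (`"kmeans2"`).
#' @slot clusterAssignment Per-pixel cluster id (1/2).
#' @slot substrateCluster Which cluster was zero-filled.
#' @slot diagnostics Per-cluster mean raw TIC and size.
#' @export
setClass("MaskResult", representation(
  tissue = "logical", method = "character",
  clusterAssignment = "integer", substrateCluster = "integer",
  diagnostics = "data.frame"))

setValidity("MaskResult", function(object) {
  if (!identical(object@tissue,
                 object@clusterAssignment != object@substrateCluster))
    return("tissue mask must equal 'not in substrate cluster'")
  TRUE
})

setMethod("show", "MaskResult", function(object) {
  cat(sprintf("MaskResult (%s): %d tissue / %d substrate pixels\n",
              object@method, sum(object@tissue), sum(!object@tissue)))
  print(object@diagnostics)
})

#' Imaging PCA model
#'
#' @slot loadings Centroids x components orthonormal loading matrix.
#' @slot scores Pixels x components score matrix.
#' @slot explainedVariance Variance per retained component.
#' @slot totalVariance Total pixel variance (sum over all components).
#' @slot center Feature means used for centering.
#' @slot mz Centroid m/z values.
#' @slot pixelInfo Per-pixel canvas coordinates and labels.
#' @slot fitPixels Logical: pixels used in fitting.
#' @export
setClass("PcaModel", representation(
  loadings = "matrix", scores = "matrix", explainedVariance = "numeric",
  totalVariance = "numeric", center = "numeric", mz = "numeric",
  pixelInfo = "data.frame", fitPixels = "logical"))

setMethod("show", "PcaModel", function(object) {
  k <- ncol(object@loadings)
  cat(sprintf("PcaModel: %d components over %d centroids, %d pixels\n",
              k, nrow(object@loadings), nrow(object@scores)))
  pct <- 100 * object@explainedVariance / object@totalVariance
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), pct), collapse = ", "), "\n")
})

#' k-means clustering model
#'
#' @slot k Cluster count.
#' @slot labels Per-pixel cluster id (1..k).
#' @slot centers k x centroids cluster mean spectra.
#' @slot inertia Total within-cluster sum of squares.
#' @slot seed RNG seed used.
#' @slot mz Centroid m/z values.
#' @slot pixelInfo Per-pixel canvas coordinates and labels.
#' @export
setClass("ClusterModel", representation(
  k = "integer", labels = "integer", centers = "matrix",
  inertia = "numeric", seed = "integer", mz = "numeric",
  pixelInfo = "data.frame"))

setValidity("ClusterModel", function(object) {
  if (any(object@labels < 1L | object@labels > object@k))
    return("labels out of 1..k")
  TRUE
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d, %d pixels, inertia %.4g (seed %d)\n",
              object@k, length(object@labels), object@inertia, object@seed))
  print(table(cluster = object@labels))
})

#' Cluster difference spectra
#'
#' Per-cluster mean spectrum minus the overall mean spectrum. The
#' cluster-size-weighted sum of the differences is the zero vector by
#' construction. `displayInversion` flags clusters whose trace is sign-
#' flipped for plotting only; stored values are never inverted.
#'
#' @slot overallMean Overall mean spectrum.
#' @slot perCluster k x centroids matrix of (cluster mean - overall mean).
#' @slot clusterSizes Pixels per cluster.
#' @slot displayInversion Logical per cluster, rendering hint only.
#' @slot mz Centroid m/z values.
#' @export
setClass("DifferenceSpectra", representation(
  overallMean = "numeric", perCluster = "matrix", clusterSizes = "integer",
  displayInversion = "logical", mz = "numeric"))

setMethod("show", "DifferenceSpectra", function(object) {
  cat(sprintf("DifferenceSpectra: %d clusters x %d centroids\n",
              nrow(object@perCluster), ncol(object@perCluster)))
})
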