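## Imaging PCA and k-means over (composite) feature images, cluster
## difference spectra, ion images and loading reports.

.checkNormalized <- function(img) {
  if (normStage(img) != "sum1_sqrt")
    stop("multivariate analysis expects a sum-normalized, square-rooted ",
         "image; run normalizePixels() first (stage is '", normStage(img),
         "')")
}

.pixelInfo <- function(img) {
  cd <- colData(img)
  data.frame(row = cd$row, col = cd$col, sampleId = cd$sampleId,
             condition = cd$condition,
             tissue = if (is.null(cd$tissue)) NA else cd$tissue)
}

#' Imaging principal components analysis
#'
#' Mean-centered PCA (no variance scaling: the square-root transform
#' already stabilizes variance) of the pixels-by-centroids matrix. By
#' default zero-filled substrate pixels stay in the fit, so the first
#' component captures tissue versus substrate; with
#' `fitTissueOnly = TRUE` the rotation is fit on tissue pixels only and
#' substrate pixels are scored as zero-filled rows. Component signs are
#' normalized so each component's largest-magnitude loading is positive.
#'
#' @param img A normalized [FeatureImage-class] (composite or single).
#' @param nComponents Components to retain.
#' @param fitTissueOnly Exclude masked pixels from the fit.
#' @return A [PcaModel-class].
#' @export
runPCA <- function(img, nComponents = 6L, fitTissueOnly = FALSE) {
  .checkNormalized(img)
  x <- intensityMatrix(img)
  nComponents <- as.integer(nComponents)
  if (nComponents > min(dim(x)))
    stop("nComponents (", nComponents, ") exceeds min(pixels, centroids) = ",
         min(dim(x)))
  fitPixels <- rep(TRUE, nrow(x))
  if (fitTissueOnly) {
    tm <- tissueMask(img)
    if (all(is.na(tm))) stop("fitTissueOnly requires a mask; see applyMask")
    fitPixels <- tm
  }
  xf <- x[fitPixels, , drop = FALSE]
  ctr <- colMeans(xf)
  xc <- sweep(xf, 2, ctr)
  sv <- svd(xc, nu = 0)
  totVar <- sum(sv$d^2) / (nrow(xf) - 1L)
  if (totVar <= 0) {
    warning("constant image: no variance to decompose")
    return(new("PcaModel", loadings = matrix(numeric(), ncol(x), 0L),
               scores = matrix(numeric(), nrow(x), 0L),
               explainedVariance = numeric(), totalVariance = 0,
               center = ctr, mz = mzCenters(img),
               pixelInfo = .pixelInfo(img), fitPixels = fitPixels))
  }
  load <- sv$v[, seq_len(nComponents), drop = FALSE]
  ## sign convention: largest |loading| positive per component
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- sweep(x, 2, ctr) %*% load
  dimnames(load) <- list(NULL, paste0("PC", seq_len(ncol(load))))
  colnames(scores) <- colnames(load)
  new("PcaModel", loadings = load,
      scores = scores,
      explainedVariance = (sv$d^2 / (nrow(xf) - 1L))[seq_len(nComponents)],
      totalVariance = totVar, center = ctr, mz = mzCenters(img),
      pixelInfo = .pixelInfo(img), fitPixels = fitPixels)
}

#' k-means clustering of a feature image
#'
#' Clusters pixel spectra with k-means (k-means++ seeding, `nstart`
#' restarts, best inertia kept), deterministic under the seed. With
#' substrate pixels zero-filled and included, the substrate separates
#' into its own cluster for any adequate k, as in a k = 3 run targeting
#' substrate / healthy / cancerous tissue.
#'
#' @param img A normalized [FeatureImage-class].
#' @param k Cluster count (>= 2, <= pixel count).
#' @param seed RNG seed.
#' @param nstart Restarts.
#' @param tissueOnly Cluster tissue pixels only (requires a mask);
#'   substrate pixels then receive label `NA`.
#' @return A [ClusterModel-class].
#' @export
runKMeans <- function(img, k, seed = 1L, nstart = 10L, tissueOnly = FALSE) {
  .checkNormalized(img)
  x <- intensityMatrix(img)
  keep <- rep(TRUE, nrow(x))
  if (tissueOnly) {
    tm <- tissueMask(img)
    if (all(is.na(tm))) stop("tissueOnly requires a mask; see applyMask")
    keep <- tm
  }
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > sum(keep)) stop("k (", k, ") exceeds pixel count (", sum(keep), ")")
  fit <- .kmeansPP(x[keep, , drop = FALSE], k, seed = seed, nstart = nstart)
  labels <- rep(NA_integer_, nrow(x))
  labels[keep] <- as.integer(fit$cluster)
  new("ClusterModel", k = k, labels = labels, centers = fit$centers,
      inertia = fit$tot.withinss, seed = as.integer(seed),
      mz = mzCenters(img), pixelInfo = .pixelInfo(img))
}

#' Sweep k-means over a range of cluster counts
#'
#' @param img A normalized [FeatureImage-class].
#' @param ks Cluster counts, default 3 to 10.
#' @param ... Passed to [runKMeans()].
#' @return Named list of [ClusterModel-class], one per k.
#' @export
sweepKMeans <- function(img, ks = 3:10, ...) {
  out <- lapply(ks, function(k) runKMeans(img, k, ...))
  names(out) <- paste0("k", ks)
  out
}

#' Cluster mean spectra minus the overall mean
#'
#' Recomputes each cluster's mean spectrum from the image, subtracts the
#' overall mean over all clustered pixels, and returns the differences.
#' The cluster-size-weighted differences sum to the zero vector by
#' construction. `invert` marks clusters whose trace should be drawn
#' sign-flipped for easier visual comparison; stored values are never
#' flipped.
#'
#' @param model A [ClusterModel-class] fit on `img`.
#' @param img The [FeatureImage-class] the model was fit on.
#' @param invert Integer vector of cluster ids to flag for display
#'   inversion.
#' @return A [DifferenceSpectra-class].
#' @export
differenceSpectra <- function(model, img, invert = integer()) {
  .checkNormalized(img)
  x <- intensityMatrix(img)
  lab <- model@labels
  if (length(lab) != nrow(x)) stop("model was not fit on this image")
  used <- !is.na(lab)
  overall <- colMeans(x[used, , drop = FALSE])
  k <- model@k
  per <- matrix(0, k, ncol(x),
                dimnames = list(paste0("cluster", seq_len(k)), NULL))
  sizes <- integer(k)
  for (j in seq_len(k)) {
    sel <- used & lab == j
    sizes[j] <- sum(sel)
    if (sizes[j] > 0L)
      per[j, ] <- colMeans(x[sel, , drop = FALSE]) - overall
  }
  new("DifferenceSpectra", overallMean = overall, perCluster = per,
      clusterSizes = sizes,
      displayInversion = seq_len(k) %in% invert, mz = model@mz)
}

#' Render per-pixel values on the image canvas
#'
#' @param values Per-pixel numeric vector (scores, labels, intensities).
#' @param pixelInfo `data.frame` with `row`, `col` (0-based canvas).
#' @return Numeric matrix (canvas rows x cols), `NA` where no pixel.
#' @export
renderImage <- function(values, pixelInfo) {
  out <- matrix(NA_real_, max(pixelInfo$row) + 1L, max(pixelInfo$col) + 1L)
  out[cbind(pixelInfo$row + 1L, pixelInfo$col + 1L)] <- values
  out
}

#' Extract a single-ion image
#'
#' Renders the intensity of the centroid nearest to `mz` (within `tol`;
#' ties go to the lower m/z) on the pixel canvas — the standard check
#' that a loading or cluster marker really localizes where the
#' multivariate result says it does.
#'
#' @param img A [FeatureImage-class].
#' @param mz Target m/z.
#' @param tol Match tolerance in m/z.
#' @return Canvas matrix of intensities (`NA` off-canvas).
#' @export
ionImage <- function(img, mz, tol = 0.25) {
  ctr <- mzCenters(img)
  d <- abs(ctr - mz)
  if (min(d) > tol)
    stop(sprintf(
      "no centroid within %.4g of m/z %.4f; nearest is %.4f (delta %.4f)",
      tol, mz, ctr[which.min(d)], min(d)))
  j <- which(d == min(d))[1]   # tie -> lower m/z (centroids ascending)
  cd <- colData(img)
  renderImage(assay(img, "intensity")[j, ], .pixelInfo(img))
}

#' Most prominent positive and negative loading peaks
#'
#' Returns the `topN` most positive and `topN` most negative loading
#' centroids of one component — the table a reader uses to interpret a
#' score image. If a lipid ion-hypothesis table is supplied the peaks
#' are annotated with their best accurate-mass assignment.
#'
#' @param model A [PcaModel-class].
#' @param component 1-based component index.
#' @param topN Peaks per sign.
#' @param hypotheses Optional ion-hypothesis table from
#'   [ionHypotheses()]; enables annotation.
#' @param window Annotation search window (m/z).
#' @return `data.frame` with `mzCenter`, `loading`, `sign` and, when
#'   annotated, `name`, `ionType`, `ppm`.
#' @export
loadingReport <- function(model, component, topN = 10L, hypotheses = NULL,
                          window = 0.01) {
  if (component < 1L || component > ncol(model@loadings))
    stop("component out of range 1..", ncol(model@loadings))
  l <- model@loadings[, component]
  topN <- as.integer(topN)
  if (topN > length(l)) {
    warning("topN exceeds centroid count; truncating")
    topN <- length(l)
  }
  posIdx <- order(l, decreasing = TRUE)[seq_len(topN)]
  posIdx <- posIdx[l[posIdx] > 0]
  negIdx <- order(l)[seq_len(topN)]
  negIdx <- negIdx[l[negIdx] < 0]
  df <- data.frame(
    mzCenter = model@mz[c(posIdx, negIdx)],
    loading = l[c(posIdx, negIdx)],
    sign = rep(c("positive", "negative"),
               c(length(posIdx), length(negIdx))))
  if (!is.null(hypotheses)) {
    ann <- lapply(df$mzCenter, function(m) {
      hits <- searchAssignments(m, hypotheses, window = window)
      if (nrow(hits) == 0L)
        data.frame(name = NA_character_, ionType = NA_character_,
                   ppm = NA_real_)
      else hits[1, c("name", "ionType", "ppm")]
    })
    df <- cbind(df, do.call(rbind, ann))
  }
  rownames(df) <- NULL
  df
}
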