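## Per-pixel normalization, substrate detection (k-means, k = 2) and
## zero-filling.

#' Sum-normalize and square-root transform every pixel
#'
#' Each nonzero pixel's centroid intensities are divided by their sum
#' (per-pixel sum = 1) and then square-rooted, the usual variance
#' stabilization before multivariate analysis of count data. Applying it
#' twice is a staging error; all-zero pixels pass through unchanged and
#' are counted.
#'
#' @param img A raw-stage [FeatureImage-class].
#' @return The image at stage `"sum1_sqrt"`.
#' @export
normalizePixels <- function(img) {
  if (normStage(img) != "raw")
    stop("stage misuse: image is already at stage '", normStage(img), "'")
  m <- assay(img, "intensity")
  s <- colSums(m)
  zero <- s <= 0
  if (any(zero))
    message(sum(zero), " all-zero pixel(s) left unchanged by normalization")
  nz <- !zero
  m[, nz] <- sqrt(sweep(m[, nz, drop = FALSE], 2, s[nz], "/"))
  assay(img, "intensity") <- m
  img@normStage <- "sum1_sqrt"
  validObject(img)
  img
}

## Deterministic k-means++ seeding followed by stats::kmeans refinement,
## best of `nstart` restarts by within-cluster sum of squares.
.kmeansPP <- function(x, k, seed, nstart = 10L, iterMax = 100L) {
  n <- nrow(x)
  stopifnot(k >= 2L, k <= n)
  if (k == n) {  # each point its own cluster; zero inertia
    return(list(cluster = seq_len(n), centers = x,
                tot.withinss = 0))
  }
  best <- NULL
  set.seed(seed)
  for (r in seq_len(nstart)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1L), ]
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j, ] <- x[sample.int(n, 1L), ]
      } else {
        centers[j, ] <- x[sample.int(n, 1L, prob = d2), ]
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
    centers <- centers[!duplicated(centers), , drop = FALSE]
    fit <- suppressWarnings(stats::kmeans(x, centers = centers,
                                          iter.max = iterMax))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Detect substrate pixels with a two-cluster mask
#'
#' Partitions the pixels into two k-means clusters and labels as
#' substrate the cluster with the lower mean raw TIC — conductive-slide
#' (ITO) pixels carry far less lipid signal than tissue. Clustering is
#' deterministic under the seed; the substrate label is invariant to the
#' arbitrary cluster indexing because it is tied to TIC, not to index.
#'
#' @param img A [FeatureImage-class]; clustering runs on its current
#'   intensity matrix (`featureSpace = "profiles"`) or on raw TIC alone
#'   (`featureSpace = "tic"`).
#' @param seed RNG seed for the clustering.
#' @param nstart Restarts (best inertia kept).
#' @param featureSpace `"profiles"` (default) or `"tic"`.
#' @return A [MaskResult-class].
#' @export
substrateMask <- function(img, seed = 1L, nstart = 10L,
                          featureSpace = c("profiles", "tic")) {
  featureSpace <- match.arg(featureSpace)
  x <- switch(featureSpace,
              profiles = intensityMatrix(img),
              tic = matrix(colData(img)$tic, ncol = 1L))
  if (nrow(unique(x)) < 2L)
    stop("degenerate clustering input: fewer than 2 distinct pixel profiles")
  fit <- .kmeansPP(x, 2L, seed = seed, nstart = nstart)
  assign <- as.integer(fit$cluster)
  rawTic <- colData(img)$tic
  diag <- data.frame(cluster = 1:2,
                     meanTic = vapply(1:2, function(j)
                       mean(rawTic[assign == j]), numeric(1)),
                     size = tabulate(assign, 2L))
  substrate <- which.min(diag$meanTic)
  new("MaskResult", tissue = assign != substrate, method = "kmeans2",
      clusterAssignment = assign, substrateCluster = as.integer(substrate),
      diagnostics = diag)
}

#' Zero-fill substrate pixels
#'
#' Sets the intensity rows of substrate pixels to zero and records the
#' tissue mask on the image, so the substrate contributes nothing but a
#' constant zero profile to downstream multivariate analysis.
#'
#' @param img A [FeatureImage-class].
#' @param mask A [MaskResult-class] (or logical per-pixel vector,
#'   `TRUE` = tissue) computed on the same pixels.
#' @return The masked image.
#' @export
applyMask <- function(img, mask) {
  tissue <- if (is(mask, "MaskResult")) mask@tissue else as.logical(mask)
  if (length(tissue) != ncol(img))
    stop("mask length (", length(tissue), ") does not match pixel count (",
         ncol(img), ")")
  m <- assay(img, "intensity")
  m[, !tissue] <- 0
  assay(img, "intensity") <- m
  colData(img)$tissue <- tissue
  img
}

#' Write a mask as CSV and binary PNG
#'
#' @param img The masked [FeatureImage-class] (after [applyMask()]).
#' @param csvPath,pngPath Output paths (`NULL` skips either).
#' @return Invisibly, the per-pixel assignment `data.frame`.
#' @export
writeMask <- function(img, csvPath = NULL, pngPath = NULL) {
  tissue <- tissueMask(img)
  if (all(is.na(tissue))) stop("image carries no mask; run applyMask first")
  cd <- colData(img)
  df <- data.frame(row = cd$row, col = cd$col, sampleId = cd$sampleId,
                   tissue = tissue)
  if (!is.null(csvPath)) utils::write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(pngPath)) {
    dims <- c(max(cd$row) + 1L, max(cd$col) + 1L)
    im <- matrix(0, dims[1], dims[2])
    im[cbind(cd$row + 1L, cd$col + 1L)] <- as.numeric(tissue)
    png::writePNG(im, pngPath)
  }
  invisible(df)
}
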