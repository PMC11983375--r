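test_that("a symmetric two-channel image loads PC1 as an equal contrast", {
  x <- rbind(matrix(rep(c(1, 0), 8), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 1), 8), ncol = 2, byrow = TRUE))
  pca <- runPCA(.normImage(x), nComponents = 1L)
  l <- pca@loadings[, 1]
  expect_equal(abs(l), c(0.7071, 0.7071), tolerance = 1e-4)
  expect_lt(l[1] * l[2], 0)  # opposite signs on the two channels
})

test_that("PCA loadings are orthonormal and variance is conserved", {
  set.seed(11)
  x <- matrix(stats::rnorm(200 * 8, sd = rep(8:1, each = 200)), 200, 8)
  img <- .normImage(x)
  pca <- runPCA(img, nComponents = 8L)
  gram <- crossprod(pca@loadings)
  expect_equal(unname(gram), diag(8), tolerance = 1e-8)
  expect_true(all(diff(pca@explainedVariance) <= 1e-9))
  # total variance conservation
  totVar <- sum(apply(x, 2, stats::var))
  expect_equal(sum(pca@explainedVariance), totVar, tolerance = 1e-6 * totVar)
  expect_equal(pca@totalVariance, totVar, tolerance = 1e-6 * totVar)
  # scores covariance is diagonal
  sc <- unname(stats::cov(pca@scores))
  expect_equal(sc, diag(diag(sc)), tolerance = 1e-8 * max(abs(sc)))
})

test_that("PCA agrees with an exact eigen-decomposition oracle on small instances", {
  for (seed in 1:3) {
    set.seed(seed)
    nCh <- sample(3:10, 1)
    x <- matrix(stats::rnorm(60 * nCh), 60, nCh) %*%
      matrix(stats::rnorm(nCh * nCh), nCh, nCh)
    pca <- runPCA(.normImage(x), nComponents = nCh)
    eig <- eigen(stats::cov(x), symmetric = TRUE)
    expect_equal(pca@explainedVariance, eig$values[seq_len(nCh)],
                 tolerance = 1e-8)
    for (j in seq_len(nCh - 1L)) {   # last vector can be noise-level
      dot <- abs(sum(pca@loadings[, j] * eig$vectors[, j]))
      expect_equal(dot, 1, tolerance = 1e-6)
    }
  }
})

test_that("a constant image yields an empty model with a warning", {
  img <- .normImage(matrix(0.5, 20, 3))
  expect_warning(pca <- runPCA(img, nComponents = 2L), "constant image")
  expect_identical(ncol(pca@loadings), 0L)
  expect_error(runPCA(.normImage(matrix(1, 5, 3)), nComponents = 4L),
               "exceeds")
})

test_that("k-means separates well-separated profiles and is seed reproducible", {
  set.seed(21)
  x <- rbind(matrix(stats::rnorm(50 * 4, mean = 0, sd = 0.05), 50, 4),
             matrix(stats::rnorm(50 * 4, mean = 1, sd = 0.05), 50, 4))
  img <- .normImage(x)
  km1 <- runKMeans(img, k = 2L, seed = 9L)
  truth <- rep(1:2, each = 50)
  expect_gte(mclust::adjustedRandIndex(km1@labels, truth), 1)
  km2 <- runKMeans(img, k = 2L, seed = 9L)
  expect_identical(km1@labels, km2@labels)
  expect_identical(km1@inertia, km2@inertia)
  # restarts never worsen the returned inertia
  kmSingle <- runKMeans(img, k = 2L, seed = 9L, nstart = 1L)
  expect_lte(km1@inertia, kmSingle@inertia + 1e-12)
  # k equal to the number of distinct profiles: zero inertia
  y <- matrix(rep(c(0, 1, 5), each = 4), ncol = 1)[, c(1, 1, 1), drop = FALSE]
  kmz <- runKMeans(.normImage(y), k = 3L, seed = 1L)
  expect_equal(kmz@inertia, 0, tolerance = 1e-12)
  expect_error(runKMeans(img, k = 1L), "k must be")
  expect_error(runKMeans(img, k = 200L), "exceeds pixel count")
})

test_that("cluster means recompute from labels and differences cancel when weighted", {
  run <- defaultRun()
  km <- run$kmeans
  x <- intensityMatrix(run$features)
  for (j in seq_len(km@k)) {
    sel <- which(km@labels == j)
    expect_equal(unname(km@centers[j, ]), unname(colMeans(x[sel, ])),
                 tolerance = 1e-9)
  }
  ds <- run$differences
  weighted <- colSums(ds@perCluster * ds@clusterSizes)
  expect_equal(unname(weighted), rep(0, ncol(ds@perCluster)),
               tolerance = 1e-9)
})

test_that("difference spectra follow the two-cluster algebra", {
  x <- rbind(matrix(rep(c(1, 0, 0), 6), ncol = 3, byrow = TRUE),
             matrix(rep(c(0, 1, 0), 6), ncol = 3, byrow = TRUE))
  img <- .normImage(x)
  km <- runKMeans(img, k = 2L, seed = 1L)
  ds <- differenceSpectra(km, img)
  a <- c(1, 0, 0); b <- c(0, 1, 0)
  want <- (a - b) / 2
  got <- ds@perCluster[km@labels[1], ]
  expect_equal(unname(got), want, tolerance = 1e-9)
  expect_equal(unname(ds@perCluster[3 - km@labels[1], ]), -want,
               tolerance = 1e-9)
  # display inversion is a rendering flag only
  ds2 <- differenceSpectra(km, img, invert = 2L)
  expect_identical(ds2@perCluster, ds@perCluster)
  expect_identical(ds2@displayInversion, c(FALSE, TRUE))
})

test_that("ion images select the nearest centroid with deterministic ties", {
  run <- defaultRun()
  fi <- run$features
  p <- peaks(run$peakTable)
  im <- ionImage(fi, p$mzCenter[5], tol = 1e-6)
  expect_equal(im[cbind(SummarizedExperiment::colData(fi)$row + 1L,
                        SummarizedExperiment::colData(fi)$col + 1L)],
               unname(SummarizedExperiment::assay(fi)[5, ]))
  expect_error(ionImage(fi, 594.0, tol = 0.001), "nearest")
  # sulfatide channel is brightest inside the aggressive region
  # (SHex2Cer 38:1 sits isolated, free of isotopic neighbors)
  target <- mzIon(lipidFormula("SHex2Cer", 38, 1))
  imS <- ionImage(fi, target, tol = 0.05)
  truth <- run$truth
  inside <- imS[cbind(truth$row + 1, truth$col + 1)[
    truth$region == "dlbcl_aggressive", , drop = FALSE]]
  tissueOut <- imS[cbind(truth$row + 1, truth$col + 1)[
    !truth$region %in% c("dlbcl_aggressive", "substrate"), ,
    drop = FALSE]]
  expect_gt(mean(inside), 3 * mean(tissueOut))
})

test_that("loading reports rank signed loadings and annotate against the database", {
  run <- defaultRun()
  rep2 <- loadingReport(run$pca, 2L, topN = 10L,
                        hypotheses = ionHypotheses(loadLipidDb()))
  expect_true(all(rep2$loading[rep2$sign == "positive"] > 0))
  expect_true(all(rep2$loading[rep2$sign == "negative"] < 0))
  # the generator's healthy/cancer contrast shows up in the signs:
  # PC2-positive peaks annotate to the healthy-enriched set
  posNames <- rep2$name[rep2$sign == "positive"]
  negNames <- rep2$name[rep2$sign == "negative"]
  healthySet <- c("PI 38:4", "PI 36:4", "PS 38:3", "PS 38:4", "PS 36:1",
                  "PE 38:4", "PE O-38:5", "PA 40:5", "PE 36:4",
                  "PE O-36:5", "LPI 20:4", "LPI 18:0")
  sameSide <- mean(posNames %in% healthySet) > 0.7 &&
    mean(negNames %in% healthySet) < 0.3
  flipSide <- mean(negNames %in% healthySet) > 0.7 &&
    mean(posNames %in% healthySet) < 0.3
  expect_true(sameSide || flipSide)
  expect_error(loadingReport(run$pca, 99L), "out of range")
  expect_warning(loadingReport(run$pca, 2L, topN = 1e5L), "truncating")
})
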