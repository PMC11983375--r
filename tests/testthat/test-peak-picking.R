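test_that("mean TIC spectrum is scale invariant and weights regions by pixel count", {
  grid <- seq(600, 620, by = 0.01)
  a <- abs(sin(grid)) + 0.1
  layout <- TileLayout(100, 2L)
  mkcube <- function(specs) {
    n <- length(specs)
    SpectralImageCube(layout, cbind((seq_len(n) - 1L) %/% 2L,
                                    (seq_len(n) - 1L) %% 2L),
                      specs)
  }
  # identical pixels -> the common spectrum, TIC-scaled to sum 1
  cube1 <- mkcube(list(list(mz = grid, intensity = a),
                       list(mz = grid, intensity = a)))
  m1 <- meanTicSpectrum(cube1, grid)
  expect_equal(sum(m1$intensity), 1, tolerance = 1e-12)
  expect_equal(m1$intensity, a / sum(a), tolerance = 1e-12)
  # two pixels a and 10a: identical result to a single pixel of a
  cube2 <- mkcube(list(list(mz = grid, intensity = a),
                       list(mz = grid, intensity = 10 * a)))
  expect_equal(meanTicSpectrum(cube2, grid)$intensity, m1$intensity,
               tolerance = 1e-12)
  # two-region cube: average = pixel-count-weighted mean of profiles
  b <- abs(cos(grid)) + 0.2
  cube3 <- mkcube(list(list(mz = grid, intensity = a),
                       list(mz = grid, intensity = a),
                       list(mz = grid, intensity = b)))
  oracle <- (2 * a / sum(a) + b / sum(b)) / 3
  expect_equal(meanTicSpectrum(cube3, grid)$intensity, oracle,
               tolerance = 1e-12)
  # zero-TIC pixels are excluded and counted
  cube4 <- mkcube(list(list(mz = grid, intensity = a),
                       list(mz = grid, intensity = 0 * a)))
  expect_message(m4 <- meanTicSpectrum(cube4, grid), "zero-TIC")
  expect_identical(m4$nExcluded, 1L)
  expect_equal(m4$intensity, m1$intensity, tolerance = 1e-12)
})

test_that("a single noiseless Gaussian centroids to its true center", {
  sp <- gaussSpectrum(800.00, 0.02, 100, grid = seq(795, 805, by = 0.005))
  pt <- pickPeaks(sp, pickerParams(ranges = NULL))
  expect_identical(length(pt), 1L)
  expect_lt(abs(peaks(pt)$mzCenter - 800.00), 0.005)
  expect_false(peaks(pt)$merged)
})

## brute-force oracle: recompute the processed second derivative with
## plain finite differences on the smoothed signal and count its
## positive-lobe local maxima
.oraclePeakCount <- function(sp, sigma) {
  d <- diff(sp$mz)[1]
  half <- ceiling(4 * sigma / d)
  n <- length(sp$intensity)
  k <- dnorm(seq(-half, half), sd = sigma / d); k <- k / sum(k)
  y <- as.numeric(stats::filter(c(numeric(half), sp$intensity,
                                  numeric(half)), k, sides = 2))
  w <- as.numeric(stats::filter(c(numeric(half), rep(1, n),
                                  numeric(half)), k, sides = 2))
  y <- y[(half + 1):(half + n)] / w[(half + 1):(half + n)]
  d2 <- c(0, diff(diff(y)), 0)
  proc <- pmax(-d2, 0)
  proc[proc <= 1e-12 * max(abs(y))] <- 0
  r <- rle(proc > 0)
  sum(r$values)
}

test_that("resolved peaks give two centroids; unresolved peaks merge into one", {
  grid <- seq(880, 895, by = 0.005)
  # sigma = 0.02: the 885.55 / 887.56 pair is fully resolved
  sp <- gaussSpectrum(c(885.55, 887.56), c(0.02, 0.02), c(100, 80), grid)
  pt <- pickPeaks(sp, pickerParams(ranges = NULL))
  expect_identical(length(pt), 2L)
  expect_identical(.oraclePeakCount(sp, 0.02), 2L)
  expect_equal(peaks(pt)$mzCenter, c(885.55, 887.56), tolerance = 0.005)
  # broadened until the second-derivative lobes touch: one merged
  # centroid (the oracle confirms a single contiguous feature)
  sp2 <- gaussSpectrum(c(885.55, 887.56), c(1.2, 1.2), c(100, 80), grid)
  pt2 <- pickPeaks(sp2, pickerParams(ranges = NULL))
  expect_identical(length(pt2), 1L)
  expect_identical(.oraclePeakCount(sp2, 0.02), 1L)
  expect_true(peaks(pt2)$merged)
})

test_that("peaks closer than 0.01 m/z merge at the default 0.05 FWHM line width", {
  sigma <- 0.05 / (2 * sqrt(2 * log(2)))
  grid <- seq(884, 890, by = 0.005)
  sp <- gaussSpectrum(c(887.556, 887.5655), rep(sigma, 2), c(30, 100), grid)
  pt <- pickPeaks(sp, pickerParams(ranges = NULL))
  expect_identical(length(pt), 1L)
  expect_identical(.oraclePeakCount(sp, 0.02), 1L)
})

test_that("top-N retention keeps the most intense peaks with deterministic ties", {
  grid <- seq(600, 700, by = 0.005)
  centers <- seq(605, 695, by = 10)
  sp <- gaussSpectrum(centers, rep(0.02, 10), 10:1, grid)
  pt <- pickPeaks(sp, pickerParams(nKeep = 5L, ranges = list(c(600, 700))))
  expect_identical(length(pt), 5L)
  expect_equal(peaks(pt)$mzCenter, centers[1:5], tolerance = 0.01)
  # apex ties break toward lower m/z
  spTie <- gaussSpectrum(c(620, 660), c(0.02, 0.02), c(5, 5), grid)
  ptTie <- pickPeaks(spTie, pickerParams(nKeep = 1L,
                                         ranges = list(c(600, 700))))
  expect_equal(peaks(ptTie)$mzCenter, 620, tolerance = 0.01)
})

test_that("picker output is invariant to zero-intensity padding", {
  grid <- seq(650, 660, by = 0.005)
  sp <- gaussSpectrum(c(653, 656), c(0.02, 0.02), c(10, 20), grid)
  padded <- list(mz = seq(640, 670, by = 0.005), intensity = numeric(6001))
  padded$intensity[match(round(grid, 3), round(padded$mz, 3))] <-
    sp$intensity
  p1 <- peaks(pickPeaks(sp, pickerParams(ranges = NULL)))
  p2 <- peaks(pickPeaks(padded, pickerParams(ranges = NULL)))
  expect_equal(p1$mzCenter, p2$mzCenter, tolerance = 1e-9)
  expect_equal(p1$apexIntensity, p2$apexIntensity, tolerance = 1e-9)
})

test_that("picker edge cases behave as declared", {
  expect_error(pickPeaks(list(mz = 1:3 + 0.0, intensity = c(1, 2, 1)),
                         pickerParams(derivWindow = 7L, ranges = NULL)),
               "shorter than")
  flat <- list(mz = seq(600, 601, by = 0.005),
               intensity = rep(1, 201))
  expect_identical(length(pickPeaks(flat, pickerParams(ranges = NULL))), 0L)
  expect_error(pickerParams(ranges = list(c(590, 810), c(800, 1190))),
               "non-overlapping")
  expect_error(pickerParams(derivWindow = 4L))
})

test_that("dual-range tables combine into one ascending table bounded by nKeep", {
  grid <- seq(590, 1190, by = 0.005)
  centers <- c(seq(600, 790, by = 10), seq(810, 1180, by = 10))
  sp <- gaussSpectrum(centers, rep(0.02, length(centers)),
                      rep(50, length(centers)), grid)
  params <- pickerParams(nKeep = 12L)
  pt <- buildPeakTables(list(sp), params)
  expect_lte(length(pt), 24L)
  p <- peaks(pt)
  expect_false(is.unsorted(p$mzCenter))
  perRange <- c(sum(p$mzCenter < 800), sum(p$mzCenter >= 800))
  expect_true(all(perRange <= 12L))
  # single image: identical to pickPeaks on its mean spectrum
  expect_equal(p, peaks(pickPeaks(sp, params)), tolerance = 1e-12)
  # duplicated image list: mean is idempotent
  expect_equal(peaks(buildPeakTables(list(sp, sp), params)), p,
               tolerance = 1e-12)
})

test_that("centroiding integrates windows with half-open boundaries", {
  pt <- PeakTable(data.frame(
    mzCenter = c(700.0, 700.2), windowLo = c(699.9, 700.1),
    windowHi = c(700.1, 700.3), apexIntensity = c(1, 1),
    merged = FALSE))
  layout <- TileLayout(100, 2L)
  mkpix <- function(mz, i) list(mz = mz, intensity = i)
  cube <- SpectralImageCube(layout, cbind(c(0L, 0L), c(0L, 1L)), list(
    # a point landing exactly on the shared edge 700.1 belongs to the
    # upper window only
    mkpix(c(700.0, 700.1), c(5, 7)),
    mkpix(c(650.0, 651.0), c(3, 4))))  # nothing inside any window
  fi <- centroidImage(cube, pt)
  m <- SummarizedExperiment::assay(fi)
  expect_equal(m[, 1], c(5, 7))
  expect_equal(m[, 2], c(0, 0))       # all-zero row for no-signal pixel
  # conservation: row sum equals raw intensity within the window union
  expect_equal(sum(m[, 1]), 12)
})

test_that("centroid areas recover known per-region areas within Poisson error", {
  run <- defaultRun()
  truth <- run$truth
  fiRaw <- centroidImage(run$cube, run$peakTable)
  m <- intensityMatrix(fiRaw)
  p <- peaks(run$peakTable)
  scene <- makeScene(defaultSceneSpec(rasterPx = 20L, seed = 101L))
  # direct-integration oracle: sum the generator's expected (noise-free)
  # spectrum over the centroid window around the PI(38:4) line
  target <- mzIon(lipidFormula("PI", 38, 4))
  j <- which(p$windowLo <= target & target < p$windowHi)
  expect_identical(length(j), 1L)
  inWin <- scene$grid >= p$windowLo[j] & scene$grid < p$windowHi[j]
  expArea <- sum(scene$expected[inWin, "healthy_lymphoid"])
  pix <- truth$region == "healthy_lymphoid"
  got <- mean(m[pix, j])
  # Poisson spread: SE of the mean is sqrt(area / n)
  expect_lt(abs(got - expArea), 5 * sqrt(expArea / sum(pix)))
})
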