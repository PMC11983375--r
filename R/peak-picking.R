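## Averaged TIC-normalized spectra, second-derivative peak picking and
## centroiding, dual-range peak tables, and per-pixel centroid images.

#' Peak-picker parameters
#'
#' @param gaussianSigma Width (m/z) of the Gaussian smoothing kernel.
#' @param derivWindow Savitzky-Golay window (samples, odd, >= 3) for the
#'   smoothed second derivative.
#' @param nKeep Number of most-intense centroids kept per mass range.
#' @param ranges List of ascending, non-overlapping `(lo, hi)` m/z
#'   intervals; `NULL` picks over the whole spectrum.
#' @return A validated parameter list of class `PickerParams`.
#' @export
pickerParams <- function(gaussianSigma = 0.02, derivWindow = 7L,
                         nKeep = 300L,
                         ranges = list(c(590, 800), c(800, 1190))) {
  derivWindow <- as.integer(derivWindow)
  nKeep <- as.integer(nKeep)
  stopifnot(gaussianSigma > 0, derivWindow >= 3L, derivWindow %% 2L == 1L,
            nKeep >= 1L)
  if (!is.null(ranges)) {
    lo <- vapply(ranges, `[`, numeric(1), 1L)
    hi <- vapply(ranges, `[`, numeric(1), 2L)
    if (any(hi <= lo)) stop("each range must have lo < hi")
    if (length(lo) > 1L &&
        (is.unsorted(lo) || any(hi[-length(hi)] > lo[-1])))
      stop("ranges must be ascending and non-overlapping")
  }
  structure(list(gaussianSigma = gaussianSigma, derivWindow = derivWindow,
                 nKeep = nKeep, ranges = ranges), class = "PickerParams")
}

#' Mean TIC-normalized spectrum of an image
#'
#' Resamples every pixel spectrum onto a common m/z grid (linear
#' interpolation, zero outside the pixel's own axis), divides each by its
#' total ion current, and averages over pixels. Pixels with zero TIC are
#' excluded from the average and counted.
#'
#' @param cube A [SpectralImageCube-class].
#' @param grid Common ascending m/z axis spanning `cube@mzRange`; default
#'   is a uniform 0.005 m/z grid over the cube's range.
#' @return List with `mz`, `intensity` (mean normalized spectrum, unit
#'   total), and `nExcluded`.
#' @export
meanTicSpectrum <- function(cube, grid = NULL) {
  if (is.null(grid))
    grid <- seq(cube@mzRange[1], cube@mzRange[2], by = 0.005)
  stopifnot(!is.unsorted(grid, strictly = TRUE))
  acc <- numeric(length(grid))
  used <- 0L
  excluded <- 0L
  for (sp in cube@spectra) {
    y <- stats::approx(sp$mz, sp$intensity, xout = grid, rule = 1)$y
    y[is.na(y)] <- 0
    tic <- sum(y)
    if (tic <= 0) { excluded <- excluded + 1L; next }
    acc <- acc + y / tic
    used <- used + 1L
  }
  if (used == 0L) stop("all pixels have zero TIC on the requested grid")
  if (excluded > 0L)
    message(excluded, " zero-TIC pixel(s) excluded from the mean spectrum")
  list(mz = grid, intensity = acc / used, nExcluded = excluded)
}

## Gaussian smoothing with zero-padded convolution; sigma in m/z units.
.gaussSmooth <- function(y, sigmaSamples) {
  half <- max(1L, ceiling(4 * sigmaSamples))
  k <- stats::dnorm(seq(-half, half), sd = sigmaSamples)
  k <- k / sum(k)
  n <- length(y)
  yp <- c(numeric(half), y, numeric(half))
  out <- stats::filter(yp, k, sides = 2)[(half + 1):(half + n)]
  ## renormalize by the in-range kernel mass so edges are not attenuated
  ## (a constant signal stays exactly constant)
  w <- stats::filter(c(numeric(half), rep(1, n), numeric(half)),
                     k, sides = 2)[(half + 1):(half + n)]
  as.numeric(out / w)
}

.localMaximaCount <- function(x) {
  if (length(x) < 3L) return(1L)
  max(1L, sum(diff(sign(diff(x))) < 0))
}

## Core of the second-derivative picker on one (sub)spectrum; returns an
## unfiltered centroid data.frame.
.pickCore <- function(mz, y, sigma, derivWindow) {
  n <- length(y)
  if (n < derivWindow)
    stop("spectrum shorter than the derivative window (", n, " < ",
         derivWindow, ")")
  d <- stats::median(diff(mz))
  smoothed <- .gaussSmooth(y, sigma / d)
  p <- max(2L, min(3L, derivWindow - 1L))
  d2 <- signal::sgolayfilt(smoothed, p = p, n = derivWindow, m = 2)
  d2[d2 > 0] <- 0          # positive second-derivative features removed
  proc <- -d2              # inverted: peaks are positive lobes
  ## numerical-noise floor so featureless (e.g. constant) signal yields
  ## no spurious features
  proc[proc <= 1e-12 * max(abs(smoothed))] <- 0
  pos <- proc > 0
  if (!any(pos)) {
    return(data.frame(mzCenter = numeric(), windowLo = numeric(),
                      windowHi = numeric(), apexIntensity = numeric(),
                      merged = logical()))
  }
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  out <- lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    w <- proc[idx]
    ctr <- sum(mz[idx] * w) / sum(w)
    data.frame(mzCenter = ctr,
               windowLo = mz[starts[i]] - d / 2,
               windowHi = mz[ends[i]] + d / 2,
               apexIntensity = max(smoothed[idx]),
               merged = .localMaximaCount(w) > 1L)
  })
  do.call(rbind, out)
}

.topN <- function(df, nKeep) {
  if (nrow(df) <= nKeep) return(df)
  ## ties in apex intensity break toward lower m/z
  ord <- order(-df$apexIntensity, df$mzCenter)
  df[sort(ord[seq_len(nKeep)]), , drop = FALSE]
}

#' Pick and centroid peaks from a spectrum
#'
#' Implements the second-derivative picker: (1) Gaussian smoothing,
#' (2) smoothed (Savitzky-Golay) second derivative, (3) positive
#' derivative values set to zero, (4) inversion, (5) every contiguous
#' positive lobe of the inverted derivative becomes one centroid whose
#' half-open integration window `[lo, hi)` spans the lobe — so peaks
#' unresolved at the instrumental line width collapse into a single
#' centroid, flagged `merged`, (6) within each mass range, the `nKeep`
#' centroids of highest apex intensity are retained (ties break toward
#' lower m/z).
#'
#' @param spectrum List with ascending `mz` (uniform or near-uniform
#'   grid) and `intensity`.
#' @param params [pickerParams()].
#' @return A [PeakTable-class]; empty (no rows) if no peaks are found.
#' @export
pickPeaks <- function(spectrum, params = pickerParams()) {
  stopifnot(inherits(params, "PickerParams"))
  mz <- spectrum$mz; y <- spectrum$intensity
  ranges <- params$ranges
  if (is.null(ranges)) ranges <- list(range(mz))
  picked <- lapply(ranges, function(rg) {
    sel <- mz >= rg[1] & mz < rg[2]
    if (!any(sel)) return(NULL)
    df <- .pickCore(mz[sel], y[sel], params$gaussianSigma,
                    params$derivWindow)
    df <- df[df$mzCenter >= rg[1] & df$mzCenter < rg[2], , drop = FALSE]
    if (nrow(df) == 0L) return(df)
    ## clip windows to the range so tables from adjacent ranges never
    ## overlap at the seam
    df$windowLo <- pmax(df$windowLo, rg[1])
    df$windowHi <- pmin(df$windowHi, rg[2])
    .topN(df, params$nKeep)
  })
  picked <- do.call(rbind, picked)
  if (is.null(picked))
    picked <- data.frame(mzCenter = numeric(), windowLo = numeric(),
                         windowHi = numeric(), apexIntensity = numeric(),
                         merged = logical())
  PeakTable(picked)
}

#' Build the combined averaged peak table
#'
#' Averages the per-image mean TIC spectra into a grand mean, runs the
#' picker per mass range, and concatenates the per-range tables into one
#' ascending [PeakTable-class] (the dual mass ranges are combined into a
#' single table).
#'
#' @param meanSpectra List of mean spectra from [meanTicSpectrum()]; all
#'   must share the same m/z grid.
#' @param params [pickerParams()].
#' @return A [PeakTable-class].
#' @export
buildPeakTables <- function(meanSpectra, params = pickerParams()) {
  stopifnot(length(meanSpectra) >= 1L)
  grid <- meanSpectra[[1]]$mz
  for (s in meanSpectra)
    if (length(s$mz) != length(grid) || any(abs(s$mz - grid) > 1e-9))
      stop("all mean spectra must share one m/z grid")
  grand <- Reduce(`+`, lapply(meanSpectra, `[[`, "intensity")) /
    length(meanSpectra)
  pickPeaks(list(mz = grid, intensity = grand), params)
}

#' Centroid every pixel of a cube against a peak table
#'
#' For each pixel, the intensity of centroid j is the summed spectral
#' intensity inside the half-open window `[lo_j, hi_j)`. The result is a
#' raw-stage [FeatureImage-class]; per-pixel raw TIC (full spectrum sum)
#' is kept in `colData` for later substrate diagnostics.
#'
#' @param cube A [SpectralImageCube-class].
#' @param table A [PeakTable-class] whose windows lie within the cube's
#'   m/z range.
#' @return A [FeatureImage-class] (`normStage = "raw"`).
#' @export
centroidImage <- function(cube, table) {
  p <- peaks(table)
  np <- nrow(p)
  stopifnot(np > 0L)
  breaks <- as.vector(rbind(p$windowLo, p$windowHi))
  n <- nPixels(cube)
  counts <- matrix(0, nrow = np, ncol = n)
  tic <- numeric(n)
  for (i in seq_len(n)) {
    sp <- cube@spectra[[i]]
    tic[i] <- sum(sp$intensity)
    pos <- findInterval(sp$mz, breaks)
    inWin <- pos %% 2L == 1L
    if (!any(inWin)) next
    j <- (pos[inWin] + 1L) %/% 2L
    agg <- rowsum(sp$intensity[inWin], j)
    counts[as.integer(rownames(agg)), i] <- agg
  }
  pd <- DataFrame(row = cube@coords[, "row"], col = cube@coords[, "col"],
                  sampleId = cube@sampleId, condition = cube@condition,
                  tic = tic)
  FeatureImage(counts, table, pd, cube@layout, normStage = "raw")
}
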