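test_that("imzML write/read round-trips spectra and geometry", {
  cube <- tinyCube(4L)
  path <- file.path(withr::local_tempdir(), "toy.imzML")
  writeImzML(cube, path)
  expect_true(file.exists(sub("imzML$", "ibd", path)))
  back <- readImzML(path, layout = cube@layout, sampleId = "toy")
  expect_identical(nPixels(back), 4L)
  expect_identical(back@polarity, "negative")
  ord <- order(back@coords[, 1], back@coords[, 2])
  for (i in seq_len(4L)) {
    j <- ord[i]
    expect_equal(back@spectra[[j]]$mz, cube@spectra[[i]]$mz,
                 tolerance = 1e-12)   # float64 m/z: exact
    expect_equal(back@spectra[[j]]$intensity, cube@spectra[[i]]$intensity,
                 tolerance = 1e-6)    # float32 intensity
  }
  # second generation is bit-compatible: float32 is now exact
  path2 <- file.path(withr::local_tempdir(), "toy2.imzML")
  writeImzML(back, path2)
  back2 <- readImzML(path2, layout = cube@layout)
  expect_identical(lapply(back2@spectra[ord], `[[`, "intensity"),
                   lapply(back@spectra[ord], `[[`, "intensity"))
})

test_that("processed-mode files with per-pixel m/z axes are accepted", {
  cube <- tinyCube(4L, sharedAxis = FALSE)
  path <- file.path(withr::local_tempdir(), "proc.imzML")
  writeImzML(cube, path)
  back <- readImzML(path, layout = cube@layout)
  axes <- unique(lapply(back@spectra, function(s) round(s$mz, 6)))
  expect_identical(length(axes), 4L)
})

test_that("format defects are reported as format errors", {
  cube <- tinyCube(2L)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "x.imzML")
  writeImzML(cube, path)
  # missing .ibd companion
  file.rename(sub("imzML$", "ibd", path), file.path(dir, "gone.ibd"))
  expect_error(readImzML(path), "missing .ibd")
  file.rename(file.path(dir, "gone.ibd"), sub("imzML$", "ibd", path))
  # negative intensity planted in the binary companion
  con <- file(sub("imzML$", "ibd", path), "r+b")
  seek(con, 16 + 21 * 8, rw = "write")  # first intensity value (float32)
  writeBin(-5, con, size = 4L, endian = "little")
  close(con)
  expect_error(readImzML(path), "negative intensity")
  # malformed XML
  bad <- file.path(dir, "bad.imzML")
  writeLines("<mzML><oops", bad)
  file.create(file.path(dir, "bad.ibd"))
  suppressWarnings(expect_error(readImzML(bad), "malformed XML"))
  # empty cube refuses to write
  expect_error(writeImzML(SpectralImageCube(cube@layout,
                                            matrix(integer(), 0, 2),
                                            list()), path), "no pixels")
})

test_that("written imzML is readable by an independent parser", {
  # cross-check against pyimzml, a reader this package shares no code with
  py <- Sys.which("python")
  if (!nzchar(py)) skip("no python available for the cross-check")
  ok <- system2(py, c("-c", shQuote("import pyimzml")),
                stdout = FALSE, stderr = FALSE) == 0
  if (!ok) skip("pyimzml not importable; cross-check only")
  cube <- tinyCube(4L)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "xchk.imzML")
  writeImzML(cube, path)
  script <- file.path(dir, "chk.py")
  writeLines(c(
    "from pyimzml.ImzMLParser import ImzMLParser",
    sprintf("p = ImzMLParser(r'%s')", path),
    "tot = 0.0",
    "n = 0",
    "for i in range(len(p.coordinates)):",
    "    mz, ints = p.getspectrum(i)",
    "    tot += float(ints.sum()); n += len(mz)",
    "print(f'{n} {tot:.4f}')"), script)
  out <- system2(py, script, stdout = TRUE)
  got <- strsplit(out[length(out)], " ")[[1]]
  expTot <- sum(vapply(cube@spectra, function(s) sum(s$intensity),
                       numeric(1)))
  expN <- sum(vapply(cube@spectra, function(s) length(s$mz), integer(1)))
  expect_identical(as.integer(got[1]), expN)
  expect_equal(as.numeric(got[2]), expTot, tolerance = 1e-5)
})

test_that("pixel size follows the tile geometry and is scale invariant", {
  ps <- pixelSizeUm(900, 128)
  expect_equal(ps$um, 7.03125)
  expect_identical(ps$nearestUm, 7L)
  expect_equal(pixelSizeUm(900, 900)$um, 1.0)
  expect_equal(pixelSizeUm(128, 128)$um, 1.0)
  for (k in c(0.5, 2, 17.3))
    expect_equal(pixelSizeUm(k * 900, k * 128)$um, pixelSizeUm(900, 128)$um)
  expect_error(pixelSizeUm(-1, 128), "positive")
  expect_error(pixelSizeUm(900, 0), "positive")
})

.memberImage <- function(id, n = 3L, seed = 1L, nPeaks = 4L) {
  set.seed(seed)
  pt <- PeakTable(data.frame(
    mzCenter = seq(700, by = 10, length.out = nPeaks),
    windowLo = seq(699.9, by = 10, length.out = nPeaks),
    windowHi = seq(700.1, by = 10, length.out = nPeaks),
    apexIntensity = 1, merged = FALSE))
  counts <- matrix(stats::rpois(nPeaks * n * n, 20), nPeaks, n * n)
  pd <- data.frame(row = rep(seq_len(n) - 1L, each = n),
                   col = rep(seq_len(n) - 1L, times = n),
                   sampleId = id, condition = "unknown")
  FeatureImage(counts, pt, pd, TileLayout(100, n))
}

test_that("composite assembly conserves pixels and intensity with an exact reverse map", {
  members <- lapply(1:12, function(i)
    .memberImage(paste0("s", i), seed = i))
  comp <- assembleComposite(members, nrowGrid = 3L)
  expect_identical(ncol(comp), sum(vapply(members, ncol, integer(1))))
  expect_equal(sum(SummarizedExperiment::assay(comp)),
               sum(vapply(members, function(m)
                 sum(SummarizedExperiment::assay(m)), numeric(1))))
  # reverse map: canvas -> (member, local pixel) -> canvas is identity
  cd <- as.data.frame(SummarizedExperiment::colData(comp))
  man <- S4Vectors::metadata(comp)$members
  off <- man[match(cd$sampleId, man$sampleId), ]
  expect_identical(as.integer(cd$memberRow + off$rowOffset),
                   as.integer(cd$row))
  expect_identical(as.integer(cd$memberCol + off$colOffset),
                   as.integer(cd$col))
  expect_false(anyDuplicated(cd[, c("row", "col")]) > 0)
  # manifest round-trips as CSV
  path <- file.path(withr::local_tempdir(), "manifest.csv")
  writeCompositeManifest(comp, path)
  expect_identical(nrow(utils::read.csv(path)), 12L)
})

test_that("two 128-pixel-wide members side by side give the expected canvas", {
  members <- lapply(1:2, function(i) .memberImage(paste0("m", i), n = 8L))
  comp <- assembleComposite(members)
  expect_identical(ncol(comp), 128L)
  expect_identical(max(SummarizedExperiment::colData(comp)$col), 15L)
})

test_that("members with differing peak tables are rejected", {
  a <- .memberImage("a")
  b <- .memberImage("b", nPeaks = 5L)
  expect_error(assembleComposite(list(a, b)), "identical peak table")
})
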