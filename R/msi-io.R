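## imzML 1.1 reading/writing (XML descriptor + external .ibd binary) and
## composite-image assembly. Supports continuous and processed binary
## modes, 32/64-bit float and int arrays, no compression.

.IMZML_DTYPES <- c("MS:1000521" = "float32", "MS:1000523" = "float64",
                   "MS:1000519" = "int32")

.dtypeSize <- c(float32 = 4L, float64 = 8L, int32 = 4L)

.readArray <- function(con, offset, n, dtype) {
  seek(con, where = offset, origin = "start")
  what <- if (dtype %in% c("float32", "float64")) "double" else "integer"
  readBin(con, what = what, n = n, size = .dtypeSize[[dtype]],
          endian = "little")
}

#' Read an imzML mass spectrometry imaging file
#'
#' Parses an imzML descriptor plus its `.ibd` binary companion into a
#' [SpectralImageCube-class]. Both continuous-mode (shared m/z axis) and
#' processed-mode (per-pixel m/z axis) files are accepted; polarity and
#' pixel positions are preserved. Positions are converted from imzML's
#' 1-based (x, y) to the cube's 0-based (row, col) convention.
#'
#' @param path Path to the `.imzML` file; the `.ibd` companion must sit
#'   next to it.
#' @param layout Optional [TileLayout-class]; inferred as a single tile
#'   covering the position range when omitted.
#' @param sampleId,condition Labels applied to all pixels.
#' @return A [SpectralImageCube-class].
#' @export
readImzML <- function(path, layout = NULL, sampleId = NULL,
                      condition = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  ibd <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd, path)) ibd <- paste0(path, ".ibd")
  if (!file.exists(ibd))
    stop("imzML format error: missing .ibd companion for ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("imzML format error: malformed XML in ", path, ": ",
         conditionMessage(e)))
  xml2::xml_ns_strip(doc)

  ## binary mode + referenceable param groups -> array roles and dtypes
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  groupInfo <- list()
  for (g in groups) {
    acc <- xml2::xml_attr(xml2::xml_find_all(g, ".//cvParam"), "accession")
    role <- if ("MS:1000514" %in% acc) "mz"
            else if ("MS:1000515" %in% acc) "intensity" else NA
    dt <- .IMZML_DTYPES[intersect(acc, names(.IMZML_DTYPES))]
    groupInfo[[xml2::xml_attr(g, "id")]] <-
      list(role = role, dtype = if (length(dt)) dt[[1]] else "float64")
  }

  specNodes <- xml2::xml_find_all(doc, ".//run//spectrum")
  if (!length(specNodes)) stop("imzML format error: no spectra in ", path)
  con <- file(ibd, "rb")
  on.exit(close(con))
  n <- length(specNodes)
  coords <- matrix(0L, n, 2L, dimnames = list(NULL, c("row", "col")))
  spectra <- vector("list", n)
  polarity <- "negative"
  for (i in seq_len(n)) {
    sn <- specNodes[[i]]
    acc <- xml2::xml_attr(xml2::xml_find_all(sn, "./cvParam"), "accession")
    if ("MS:1000130" %in% acc) polarity <- "positive"
    x <- as.integer(xml2::xml_attr(xml2::xml_find_first(
      sn, ".//scan/cvParam[@accession='IMS:1000050']"), "value"))
    y <- as.integer(xml2::xml_attr(xml2::xml_find_first(
      sn, ".//scan/cvParam[@accession='IMS:1000051']"), "value"))
    if (is.na(x) || is.na(y))
      stop("imzML format error: spectrum ", i, " lacks pixel position")
    coords[i, ] <- c(y - 1L, x - 1L)
    arrays <- list()
    for (bda in xml2::xml_find_all(sn, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "./referenceableParamGroupRef"), "ref")
      info <- groupInfo[[ref]]
      cv <- xml2::xml_find_all(bda, "./cvParam")
      accs <- xml2::xml_attr(cv, "accession")
      vals <- xml2::xml_attr(cv, "value")
      if (is.null(info) || is.na(info$role)) {
        role <- if ("MS:1000514" %in% accs) "mz"
                else if ("MS:1000515" %in% accs) "intensity" else next
        dt <- .IMZML_DTYPES[intersect(accs, names(.IMZML_DTYPES))]
        info <- list(role = role,
                     dtype = if (length(dt)) dt[[1]] else "float64")
      }
      len <- as.numeric(vals[match("IMS:1000103", accs)])
      off <- as.numeric(vals[match("IMS:1000102", accs)])
      if (is.na(len) || is.na(off))
        stop("imzML format error: spectrum ", i,
             " lacks external offset/length")
      arrays[[info$role]] <- .readArray(con, off, len, info$dtype)
    }
    if (is.null(arrays$mz) || is.null(arrays$intensity))
      stop("imzML format error: spectrum ", i, " lacks m/z or intensity")
    if (any(arrays$intensity < 0))
      stop("imzML format error: spectrum ", i, " has negative intensity")
    spectra[[i]] <- list(mz = arrays$mz, intensity = arrays$intensity)
  }
  if (is.null(layout)) {
    layout <- TileLayout(tileEdgeUm = max(coords) + 1,
                         rasterPx = max(max(coords) + 1L, 2L))
  }
  if (is.null(sampleId))
    sampleId <- sub("\\.imzml$", "", basename(path), ignore.case = TRUE)
  SpectralImageCube(layout, coords, spectra, sampleId = sampleId,
                    condition = condition, polarity = polarity)
}

.uuidBytes <- function() as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)

.uuidText <- function(bytes) {
  h <- format(bytes)
  paste0("{", paste0(h[1:4], collapse = ""), "-",
         paste0(h[5:6], collapse = ""), "-", paste0(h[7:8], collapse = ""),
         "-", paste0(h[9:10], collapse = ""), "-",
         paste0(h[11:16], collapse = ""), "}")
}

.writeArray <- function(con, x, dtype) {
  writeBin(as.numeric(x), con, size = .dtypeSize[[dtype]],
           endian = "little")
}

#' Write a cube as imzML
#'
#' Writes a [SpectralImageCube-class] as a processed-mode imzML file
#' (per-pixel m/z axes, which also represents continuous data exactly)
#' with an external `.ibd` binary companion. Default encodings are
#' 64-bit float m/z and 32-bit float intensity.
#'
#' @param cube A [SpectralImageCube-class] with at least one pixel.
#' @param path Output `.imzML` path; the `.ibd` is written alongside.
#' @param mzDtype,intensityDtype `"float64"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
writeImzML <- function(cube, path, mzDtype = "float64",
                       intensityDtype = "float32") {
  n <- nPixels(cube)
  if (n == 0L) stop("no pixels: refusing to write an empty imzML file")
  stopifnot(mzDtype %in% c("float32", "float64"),
            intensityDtype %in% c("float32", "float64"))
  ibd <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd, path)) ibd <- paste0(path, ".ibd")
  uuid <- .uuidBytes()
  con <- file(ibd, "wb")
  writeBin(uuid, con)
  offset <- 16
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- cube@spectra[[i]]
    len <- length(sp$mz)
    mzBytes <- len * .dtypeSize[[mzDtype]]
    intBytes <- len * .dtypeSize[[intensityDtype]]
    .writeArray(con, sp$mz, mzDtype)
    .writeArray(con, sp$intensity, intensityDtype)
    meta[[i]] <- list(len = len, mzOff = offset, mzBytes = mzBytes,
                      intOff = offset + mzBytes, intBytes = intBytes)
    offset <- offset + mzBytes + intBytes
  }
  close(con)

  dtypeParam <- function(dt) {
    acc <- names(.IMZML_DTYPES)[match(dt, .IMZML_DTYPES)]
    nm <- c(float32 = "32-bit float", float64 = "64-bit float",
            int32 = "32-bit integer", int64 = "64-bit integer")[[dt]]
    sprintf('<cvParam cvRef="MS" accession="%s" name="%s" value=""/>',
            acc, nm)
  }
  polAcc <- if (cube@polarity == "negative")
    'accession="MS:1000129" name="negative scan"'
  else 'accession="MS:1000130" name="positive scan"'
  specXml <- vapply(seq_len(n), function(i) {
    m <- meta[[i]]
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, m$len),
      sprintf('<cvParam cvRef="MS" %s value=""/>', polAcc),
      '<scanList count="1"><scan>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
              cube@coords[i, "col"] + 1L),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
              cube@coords[i, "row"] + 1L),
      '</scan></scanList><binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', m$len),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>', m$mzBytes),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>', m$mzOff),
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', m$len),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>', m$intBytes),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>', m$intOff),
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>',
            .uuidText(uuid)),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    dtypeParam(mzDtype),
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
    dtypeParam(intensityDtype),
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<softwareList count="1"><software id="simsLipids" version="0.99.0"/></softwareList>',
    '<scanSettingsList count="1"><scanSettings id="scan1">',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>',
            max(cube@coords[, "col"]) + 1L),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>',
            max(cube@coords[, "row"]) + 1L),
    '</scanSettings></scanSettingsList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="simsLipids"/>',
    '</dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="export">', n),
    paste0(specXml, collapse = ""),
    '</spectrumList></run></mzML>\n')
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

#' Physical pixel size of a tile raster
#'
#' The edge length of one pixel given the tile edge length and the pixel
#' raster per tile edge. A 900 um tile rastered at 128 x 128 pixels gives
#' 7.03125 um — quoted as 7 um at instrument precision.
#'
#' @param tileEdgeUm Tile edge length, micrometers (> 0).
#' @param rasterPx Pixels per tile edge (> 0).
#' @return List with `um` (exact) and `nearestUm` (nearest integer).
#' @examples
#' pixelSizeUm(900, 128)  # 7.03125 um, nearest 7
#' @export
pixelSizeUm <- function(tileEdgeUm, rasterPx) {
  if (tileEdgeUm <= 0 || rasterPx <= 0)
    stop("tileEdgeUm and rasterPx must be positive")
  um <- tileEdgeUm / rasterPx
  list(um = um, nearestUm = as.integer(round(um)))
}

#' Assemble per-sample feature images into one composite image
#'
#' Places member [FeatureImage-class]s on a shared canvas (row-packed
#' grid in member order) so that multivariate analysis can run over all
#' samples at once. All members must share an identical peak table. The
#' composite `colData` keeps each pixel's sample of origin and local
#' coordinates, giving an exact reverse map from canvas pixel to
#' (sample, local pixel).
#'
#' @param members List of [FeatureImage-class] objects.
#' @param nrowGrid Number of grid rows for member placement; default 1
#'   (side by side).
#' @return A composite [FeatureImage-class]; `metadata()` carries the
#'   member manifest (sampleId, condition, canvas offsets).
#' @export
assembleComposite <- function(members, nrowGrid = 1L) {
  stopifnot(length(members) >= 1L)
  ref <- peaks(members[[1]])
  for (i in seq_along(members)[-1]) {
    pi2 <- peaks(members[[i]])
    if (nrow(pi2) != nrow(ref) ||
        any(abs(pi2$mzCenter - ref$mzCenter) > 1e-9)) {
      bad <- if (nrow(pi2) == nrow(ref))
        paste(sprintf("%.4f", ref$mzCenter[abs(pi2$mzCenter - ref$mzCenter)
                                           > 1e-9]), collapse = ", ")
      else sprintf("%d vs %d centroids", nrow(ref), nrow(pi2))
      stop("members must share an identical peak table; member ", i,
           " differs: ", bad)
    }
  }
  nrowGrid <- as.integer(nrowGrid)
  ncolGrid <- as.integer(ceiling(length(members) / nrowGrid))
  tileRows <- vapply(members, function(m)
    max(colData(m)$row) + 1L, integer(1))
  tileCols <- vapply(members, function(m)
    max(colData(m)$col) + 1L, integer(1))
  cellRows <- max(tileRows); cellCols <- max(tileCols)
  counts <- NULL; cd <- NULL
  manifest <- data.frame(sampleId = character(), condition = character(),
                         rowOffset = integer(), colOffset = integer())
  for (i in seq_along(members)) {
    m <- members[[i]]
    gr <- (i - 1L) %/% ncolGrid
    gc <- (i - 1L) %% ncolGrid
    cdm <- colData(m)
    cdm$memberRow <- cdm$row
    cdm$memberCol <- cdm$col
    cdm$row <- as.integer(cdm$row + gr * cellRows)
    cdm$col <- as.integer(cdm$col + gc * cellCols)
    counts <- cbind(counts, assay(m, "intensity"))
    cd <- rbind(cd, cdm)
    manifest <- rbind(manifest, data.frame(
      sampleId = unique(cdm$sampleId)[1],
      condition = unique(cdm$condition)[1],
      rowOffset = gr * cellRows, colOffset = gc * cellCols))
  }
  stage <- unique(vapply(members, normStage, character(1)))
  if (length(stage) != 1L)
    stop("members are at different normalization stages")
  layout <- TileLayout(
    tileEdgeUm = members[[1]]@layout@tileEdgeUm,
    rasterPx = members[[1]]@layout@rasterPx,
    mosaicRows = nrowGrid * (cellRows %/% members[[1]]@layout@rasterPx +
                               (cellRows %% members[[1]]@layout@rasterPx > 0)),
    mosaicCols = ncolGrid * (cellCols %/% members[[1]]@layout@rasterPx +
                               (cellCols %% members[[1]]@layout@rasterPx > 0)))
  fi <- FeatureImage(counts, PeakTable(ref), cd, layout, normStage = stage)
  metadata(fi)$members <- manifest
  fi
}

#' Write the composite member manifest as CSV
#' @param composite A composite [FeatureImage-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeCompositeManifest <- function(composite, path) {
  man <- metadata(composite)$members
  if (is.null(man)) stop("image carries no composite manifest")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}
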