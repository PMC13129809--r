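#' @include AllClasses.R utils.R
NULL

#' Construct a SpectraDataset
#'
#' @param coords integer matrix n x 2 of 0-based (row, col) pixel grid
#'   coordinates.
#' @param spectra list of two-column (mz, intensity) matrices, one per
#'   pixel.
#' @param mzRange numeric(2) acquisition mass range in Da.
#' @param pixelSize pixel edge length in micrometres (metadata).
#' @return a \linkS4class{SpectraDataset}.
#' @export
SpectraDataset <- function(coords, spectra, mzRange, pixelSize = 20) {
  coords <- matrix(as.integer(coords), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  spectra <- lapply(spectra, function(sp) {
    sp <- matrix(as.numeric(sp), ncol = 2L,
                 dimnames = list(NULL, c("mz", "intensity")))
    sp[order(sp[, 1]), , drop = FALSE]
  })
  new("SpectraDataset", coords = coords, spectra = spectra,
      mzRange = as.numeric(mzRange), pixelSize = pixelSize)
}

# cv accessions used in the imzML documents we read and write
.IMS_X <- "IMS:1000050"; .IMS_Y <- "IMS:1000051"
.IMS_OFFSET <- "IMS:1000102"; .IMS_LENGTH <- "IMS:1000103"
.MS_MZ_ARRAY <- "MS:1000514"; .MS_INT_ARRAY <- "MS:1000515"
.MS_F32 <- "MS:1000521"; .MS_F64 <- "MS:1000523"
.MS_SW_LO <- "MS:1000501"; .MS_SW_HI <- "MS:1000500"

#' Write a SpectraDataset as imzML (+ ibd)
#'
#' Writes a processed-mode imzML file: each pixel carries its own m/z
#' and intensity arrays (64-bit floats) in the binary .ibd companion.
#' Scan windows record the dataset mass range so it survives a
#' round-trip.
#'
#' @param ds a \linkS4class{SpectraDataset}.
#' @param path output path ending in \code{.imzML}; the \code{.ibd}
#'   companion is written alongside.
#' @return \code{path}, invisibly.
#' @export
writeImzML <- function(ds, path) {
  stopifnot(is(ds, "SpectraDataset"))
  ibdPath <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibdPath, path)) ibdPath <- paste0(path, ".ibd")
  uuid <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  con <- file(ibdPath, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16
  n <- nrow(ds@coords)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- ds@spectra[[i]]
    k <- nrow(sp)
    mzOff <- offset
    writeBin(as.numeric(sp[, 1]), con, size = 8L, endian = "little")
    offset <- offset + 8 * k
    intOff <- offset
    writeBin(as.numeric(sp[, 2]), con, size = 8L, endian = "little")
    offset <- offset + 8 * k
    entries[[i]] <- list(k = k, mzOff = mzOff, intOff = intOff,
                         x = ds@coords[i, 2] + 1L, y = ds@coords[i, 1] + 1L)
  }
  cv <- function(acc, name, value = NULL) {
    v <- if (is.null(value)) "" else
      sprintf(' value="%s"', format(value, scientific = FALSE, trim = TRUE))
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>',
            sub(":.*", "", acc), acc, name, v)
  }
  specXml <- vapply(seq_len(n), function(i) {
    e <- entries[[i]]
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, e$k),
      '<scanList count="1"><scan>',
      cv(.IMS_X, "position x", e$x), cv(.IMS_Y, "position y", e$y),
      '<scanWindowList count="1"><scanWindow>',
      cv(.MS_SW_LO, "scan window lower limit", ds@mzRange[1]),
      cv(.MS_SW_HI, "scan window upper limit", ds@mzRange[2]),
      "</scanWindow></scanWindowList></scan></scanList>",
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      cv(.IMS_LENGTH, "external array length", e$k),
      cv(.IMS_OFFSET, "external offset", e$mzOff),
      "<binary/></binaryDataArray>",
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      cv(.IMS_LENGTH, "external array length", e$k),
      cv(.IMS_OFFSET, "external offset", e$intOff),
      "<binary/></binaryDataArray>",
      "</binaryDataArrayList></spectrum>")
  }, "")
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    "<fileDescription><fileContent>",
    cv("IMS:1000031", "processed"),
    cv("IMS:1000080", "universally unique identifier",
       paste(sprintf("%02x", as.integer(uuid)), collapse = "")),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv(.MS_MZ_ARRAY, "m/z array"), cv(.MS_F64, "64-bit float"),
    cv("IMS:1000101", "external data", "true"),
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    cv(.MS_INT_ARRAY, "intensity array"), cv(.MS_F64, "64-bit float"),
    cv("IMS:1000101", "external data", "true"),
    "</referenceableParamGroup></referenceableParamGroupList>",
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    cv("IMS:1000042", "max count of pixels x", max(ds@coords[, 2]) + 1L),
    cv("IMS:1000043", "max count of pixels y", max(ds@coords[, 1]) + 1L),
    "</scanSettings></scanSettingsList>",
    '<run id="run1"><spectrumList count="', n, '">',
    paste(specXml, collapse = ""),
    "</spectrumList></run></mzML>")
  writeLines(doc, path)
  invisible(path)
}

.readIbdArray <- function(con, offset, length, size) {
  seek(con, where = offset, origin = "start")
  readBin(con, what = "numeric", n = length, size = size,
          endian = "little")
}

#' Read an imzML file into a SpectraDataset
#'
#' Supports processed- and continuous-mode imzML with 32- or 64-bit
#' float arrays stored externally in the .ibd companion. Pixel
#' positions must be unique; the mass range is taken from the first
#' scan window when present, otherwise from the data extremes.
#'
#' @param path path to the .imzML file; the .ibd companion must sit
#'   alongside (case-insensitive extension).
#' @return a \linkS4class{SpectraDataset}.
#' @export
readImzML <- function(path) {
  if (!file.exists(path)) stop("imzML file not found: ", path)
  ibd <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd)) {
    alt <- paste0(tools::file_path_sans_ext(path), ".ibd")
    if (file.exists(alt)) ibd <- alt
    else stop("missing binary companion (.ibd) for ", path)
  }
  x <- xml2::read_xml(path)
  xml2::xml_ns_strip(x)
  # data type per referenceable group (fallback: 64-bit)
  groupSize <- function(g) {
    accs <- xml2::xml_attr(xml2::xml_find_all(g, ".//cvParam"), "accession")
    if (.MS_F32 %in% accs) 4L else 8L
  }
  groups <- xml2::xml_find_all(x, ".//referenceableParamGroup")
  gsize <- vapply(groups, groupSize, 0L)
  gkind <- vapply(groups, function(g) {
    accs <- xml2::xml_attr(xml2::xml_find_all(g, ".//cvParam"), "accession")
    if (.MS_MZ_ARRAY %in% accs) "mz"
    else if (.MS_INT_ARRAY %in% accs) "intensity" else "other"
  }, "")
  names(gsize) <- names(gkind) <- xml2::xml_attr(groups, "id")

  specs <- xml2::xml_find_all(x, ".//spectrum")
  if (!length(specs)) stop("no spectra found in ", path)
  cvVal <- function(node, acc) {
    p <- xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']", acc))
    if (inherits(p, "xml_missing")) NA_real_
    else as.numeric(xml2::xml_attr(p, "value"))
  }
  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  n <- length(specs)
  coords <- matrix(0L, n, 2L)
  spectra <- vector("list", n)
  swLo <- NA_real_; swHi <- NA_real_
  for (i in seq_len(n)) {
    s <- specs[[i]]
    px <- cvVal(s, .IMS_X); py <- cvVal(s, .IMS_Y)
    if (is.na(px) || is.na(py))
      stop("spectrum ", i, " lacks pixel position cvParams")
    coords[i, ] <- c(as.integer(py) - 1L, as.integer(px) - 1L)
    if (is.na(swLo)) {
      swLo <- cvVal(s, .MS_SW_LO); swHi <- cvVal(s, .MS_SW_HI)
    }
    arrs <- xml2::xml_find_all(s, ".//binaryDataArray")
    mzv <- NULL; iv <- NULL
    for (a in arrs) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(a, ".//referenceableParamGroupRef"), "ref")
      accs <- xml2::xml_attr(xml2::xml_find_all(a, ".//cvParam"), "accession")
      kind <- if (!is.na(ref) && ref %in% names(gkind)) gkind[[ref]]
        else if (.MS_MZ_ARRAY %in% accs) "mz"
        else if (.MS_INT_ARRAY %in% accs) "intensity" else "other"
      size <- if (!is.na(ref) && ref %in% names(gsize)) gsize[[ref]]
        else if (.MS_F32 %in% accs) 4L else 8L
      off <- cvVal(a, .IMS_OFFSET); len <- cvVal(a, .IMS_LENGTH)
      if (is.na(off) || is.na(len))
        stop("spectrum ", i, " has a binary array without external offset/length")
      vals <- .readIbdArray(con, off, len, size)
      if (kind == "mz") mzv <- vals
      if (kind == "intensity") iv <- vals
    }
    if (is.null(mzv) || is.null(iv) || length(mzv) != length(iv))
      stop("spectrum ", i, " has inconsistent m/z and intensity arrays")
    spectra[[i]] <- cbind(mz = mzv, intensity = iv)
  }
  dup <- anyDuplicated(coords)
  if (dup)
    stop(sprintf(
      "pixel coordinates do not form a grid: position (row=%d, col=%d) of spectrum %d is listed more than once",
      coords[dup, 1], coords[dup, 2], dup))
  if (is.na(swLo) || is.na(swHi)) {
    allMz <- unlist(lapply(spectra, function(sp) sp[, 1]))
    if (!length(allMz)) stop("dataset has no peaks and no scan window metadata")
    swLo <- min(allMz); swHi <- max(allMz)
  }
  SpectraDataset(coords, spectra, c(swLo, swHi))
}
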