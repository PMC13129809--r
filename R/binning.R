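#' @include AllClasses.R utils.R
NULL

#' Quantize sparse spectra onto a fixed m/z bin grid
#'
#' Bins every peak within the dataset mass range to the single nearest
#' bin center, summing intensities. The grid is anchored at the lower
#' end of the mass range: centers are \code{mz_min + k / bins_per_mz}.
#' A peak exactly midway between two centers goes to the lower-index
#' bin. Peaks outside the range are dropped and counted in the cube
#' metadata (\code{droppedPeaks}). Twenty bins per m/z give the 0.05 Da
#' grid used for quantitative work; five give the coarser 0.2 Da
#' visualization grid.
#'
#' @param ds a \linkS4class{SpectraDataset}.
#' @param binsPerMz integer >= 1, number of bins per 1 Da.
#' @return a raw (un-normalized) \linkS4class{BinnedCube}.
#' @export
binSpectra <- function(ds, binsPerMz = 20L) {
  stopifnot(is(ds, "SpectraDataset"))
  if (length(ds@spectra) == 0L) stop("empty dataset: nothing to bin")
  if (!is.numeric(binsPerMz) || length(binsPerMz) != 1L || binsPerMz < 1)
    stop("binsPerMz must be a positive integer")
  binsPerMz <- as.integer(binsPerMz)
  bw <- 1 / binsPerMz
  mzMin <- ds@mzRange[1]; mzMax <- ds@mzRange[2]
  nb <- as.integer(round((mzMax - mzMin) * binsPerMz)) + 1L
  centers <- mzMin + (seq_len(nb) - 1L) * bw
  n <- length(ds@spectra)
  mat <- matrix(0, nrow = nb, ncol = n)
  dropped <- 0L
  for (i in seq_len(n)) {
    sp <- ds@spectra[[i]]
    if (!nrow(sp)) next
    inRange <- sp[, 1] >= mzMin & sp[, 1] <= mzMax
    dropped <- dropped + sum(!inRange)
    sp <- sp[inRange, , drop = FALSE]
    if (!nrow(sp)) next
    # nearest center; exact midpoints resolve to the lower-index bin
    # (tiny epsilon absorbs floating-point error in the tie position)
    idx <- as.integer(ceiling((sp[, 1] - mzMin) * binsPerMz - 0.5 - 1e-9)) + 1L
    idx[idx < 1L] <- 1L; idx[idx > nb] <- nb
    acc <- rowsum(sp[, 2], idx)
    mat[as.integer(rownames(acc)), i] <- acc[, 1]
  }
  if (dropped > 0L)
    message(dropped, " peak(s) outside the mass range were dropped")
  dims <- c(max(ds@coords[, 1]) + 1L, max(ds@coords[, 2]) + 1L)
  se <- SummarizedExperiment(
    assays = list(intensity = mat),
    rowData = DataFrame(mz = centers),
    colData = DataFrame(row = ds@coords[, 1], col = ds@coords[, 2]),
    metadata = list(binsPerMz = binsPerMz, binWidth = bw,
                    normalized = "raw", dims = dims,
                    mzRange = ds@mzRange, zeroTic = colSums(mat) == 0,
                    droppedPeaks = dropped))
  new("BinnedCube", se)
}

#' Total-ion-current normalization
#'
#' Divides each pixel's bin vector by its total so pixels become
#' comparable. Pixels with zero total signal stay all-zero and are
#' recorded in the \code{zeroTic} metadata mask rather than dropped.
#'
#' @param cube a raw \linkS4class{BinnedCube}.
#' @return the cube with \code{normalized = "TIC"}.
#' @export
ticNormalize <- function(cube) {
  stopifnot(is(cube, "BinnedCube"))
  if (identical(metadata(cube)$normalized, "TIC"))
    stop("cube is already TIC-normalized")
  a <- assay(cube, "intensity")
  tot <- colSums(a)
  zero <- tot == 0
  if (any(zero))
    warning(sum(zero), " pixel(s) with zero total ion current left as zeros")
  tot[zero] <- 1
  assay(cube, "intensity") <- sweep(a, 2L, tot, "/")
  metadata(cube)$normalized <- "TIC"
  metadata(cube)$zeroTic <- zero
  validObject(cube)
  cube
}

#' Extract one bin's intensities as an image matrix
#'
#' @param cube a \linkS4class{BinnedCube}.
#' @param mz m/z (Da) of the requested bin; the nearest bin center is
#'   used.
#' @return an H x W numeric matrix.
#' @export
cubeImage <- function(cube, mz) {
  stopifnot(is(cube, "BinnedCube"))
  ctr <- binCenters(cube)
  bin <- which.min(abs(ctr - mz))
  dims <- imageDims(cube)
  img <- matrix(0, dims[1], dims[2])
  img[pixelIndex(cbind(colData(cube)$row, colData(cube)$col), dims)] <-
    assay(cube, "intensity")[bin, ]
  img
}

#' Save / load the internal binned-cube container
#'
#' The cube travels as an R-native serialized object with a JSON
#' metadata sidecar for external inspection; imzML is the interchange
#' format for raw spectra.
#'
#' @param cube a \linkS4class{BinnedCube}.
#' @param path output path (conventionally \code{.rds}).
#' @return \code{path} (save) or the \linkS4class{BinnedCube} (load).
#' @export
saveCube <- function(cube, path) {
  stopifnot(is(cube, "BinnedCube"))
  saveRDS(cube, path)
  md <- metadata(cube)
  jsonlite::write_json(
    list(binsPerMz = md$binsPerMz, binWidth = md$binWidth,
         normalized = md$normalized, dims = md$dims, mzRange = md$mzRange,
         nBins = nrow(cube), nPixels = ncol(cube),
         droppedPeaks = md$droppedPeaks),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveCube
#' @export
readCube <- function(path) {
  cube <- readRDS(path)
  stopifnot(is(cube, "BinnedCube"))
  validObject(cube)
  cube
}

#' Assemble a labeled pixel feature table
#'
#' Joins a binned cube (or a feature matrix of refined-peak images)
#' with a rasterized label mask into the flat pixels-by-features table
#' the classifiers and selection procedures consume. All-zero feature
#' columns are dropped; categories with fewer labeled pixels than
#' \code{minPixels} are dropped with a warning.
#'
#' @param cube a \linkS4class{BinnedCube}.
#' @param mask a \linkS4class{LabelMask} matching the cube's image
#'   dimensions.
#' @param minPixels minimum pixels per retained category (default 20).
#' @param dropEmptyFeatures drop all-zero columns (default TRUE).
#' @param minTotalFraction keep only features whose summed intensity is
#'   at least this fraction of the strongest feature's total (default 0,
#'   no filtering); a standard peak filter separating structured signal
#'   from the scattered noise floor.
#' @param maxFeatures keep at most this many features, the most intense
#'   by summed intensity (default NULL, no cap).
#' @param includeBackground keep background pixels as their own
#'   category (default TRUE).
#' @return a \linkS4class{PixelTable}.
#' @export
pixelTable <- function(cube, mask, minPixels = 20L,
                       dropEmptyFeatures = TRUE,
                       minTotalFraction = 0, maxFeatures = NULL,
                       includeBackground = TRUE) {
  stopifnot(is(cube, "BinnedCube"), is(mask, "LabelMask"))
  dims <- imageDims(cube)
  if (!all(dims == dim(mask@labels)))
    stop("cube and mask dimensions differ")
  lin <- pixelIndex(cbind(colData(cube)$row, colData(cube)$col), dims)
  lab <- mask@labels[lin]
  catOf <- mask@indexTable$category[match(lab, mask@indexTable$index)]
  keep <- rep(TRUE, length(lab))
  if (!includeBackground)
    keep <- lab != mask@backgroundIndex
  X <- t(assay(cube, "intensity")[, keep, drop = FALSE])
  y <- factor(catOf[keep])
  cnt <- table(y)
  small <- names(cnt)[cnt < minPixels]
  if (length(small)) {
    warning("dropping categories below ", minPixels, " pixels: ",
            paste(small, collapse = ", "))
    sel <- !(y %in% small)
    X <- X[sel, , drop = FALSE]
    y <- droplevels(y[sel])
  }
  fmz <- binCenters(cube)
  tot <- colSums(X)
  keepF <- rep(TRUE, ncol(X))
  if (dropEmptyFeatures) keepF <- keepF & tot > 0
  if (minTotalFraction > 0) keepF <- keepF & tot >= minTotalFraction * max(tot)
  if (!is.null(maxFeatures) && sum(keepF) > maxFeatures) {
    ord <- order(tot, decreasing = TRUE)
    ord <- ord[keepF[ord]][seq_len(maxFeatures)]
    keepF <- seq_along(keepF) %in% ord
  }
  X <- X[, keepF, drop = FALSE]
  fmz <- fmz[keepF]
  new("PixelTable", X = X, y = y, featureMz = as.numeric(fmz))
}
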