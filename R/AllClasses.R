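#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' SpectraDataset: per-pixel sparse MSI spectra
#'
#' Holds one sparse centroided spectrum per image pixel, as acquired
#' (before any binning). Each spectrum is a two-column matrix of
#' (m/z in Da, intensity in arbitrary counts).
#'
#' @slot coords integer matrix, n_pixels x 2 (row, col), 0-based grid
#'   coordinates; rows unique.
#' @slot spectra list of numeric matrices with columns \code{mz},
#'   \code{intensity}; one entry per pixel, possibly zero-row.
#' @slot mzRange numeric(2), acquisition mass range (Da), min < max.
#' @slot pixelSize numeric(1), pixel edge length in micrometres
#'   (metadata only).
#' @exportClass SpectraDataset
setClass("SpectraDataset",
  representation(
    coords = "matrix",
    spectra = "list",
    mzRange = "numeric",
    pixelSize = "numeric"
  ),
  prototype(pixelSize = 20)
)

setValidity("SpectraDataset", function(object) {
  msg <- character()
  if (ncol(object@coords) != 2L)
    msg <- c(msg, "coords must have two columns (row, col)")
  if (nrow(object@coords) != length(object@spectra))
    msg <- c(msg, "one spectrum required per pixel")
  if (anyDuplicated(object@coords))
    msg <- c(msg, sprintf("duplicate pixel coordinate at row %d",
                          anyDuplicated(object@coords)))
  if (length(object@mzRange) != 2L || !all(is.finite(object@mzRange)) ||
      object@mzRange[1] >= object@mzRange[2])
    msg <- c(msg, "mzRange must be finite with mz_min < mz_max")
  for (i in seq_along(object@spectra)) {
    sp <- object@spectra[[i]]
    if (!is.matrix(sp) || ncol(sp) != 2L) {
      msg <- c(msg, sprintf("spectrum %d is not a 2-column matrix", i))
      break
    }
    if (nrow(sp) > 0L) {
      if (!all(is.finite(sp)) || any(sp[, 1] <= 0)) {
        msg <- c(msg, sprintf("spectrum %d has non-finite or non-positive m/z", i))
        break
      }
      if (any(sp[, 2] < 0)) {
        msg <- c(msg, sprintf("spectrum %d has negative intensity", i))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' BinnedCube: fixed-bin intensity cube
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{intensity}
#' (n_bins x n_pixels), rowData column \code{mz} (bin centers, Da) and
#' colData columns \code{row}, \code{col}. Metadata records
#' \code{binsPerMz}, \code{binWidth} (= 1/binsPerMz, Da),
#' \code{normalized} ("raw" or "TIC"), the image \code{dims} (H, W),
#' the logical \code{zeroTic} mask of pixels with zero total signal and
#' the count of \code{droppedPeaks} outside the mass range.
#'
#' @exportClass BinnedCube
setClass("BinnedCube", contains = "SummarizedExperiment")

setValidity("BinnedCube", function(object) {
  msg <- character()
  md <- metadata(object)
  need <- c("binsPerMz", "binWidth", "normalized", "dims", "mzRange")
  miss <- setdiff(need, names(md))
  if (length(miss))
    return(sprintf("missing metadata: %s", paste(miss, collapse = ", ")))
  ctr <- rowData(object)$mz
  if (is.null(ctr)) return("rowData must contain bin centers 'mz'")
  if (length(ctr) > 1L) {
    d <- diff(ctr)
    if (any(d <= 0) || max(abs(d - md$binWidth)) > 1e-9)
      msg <- c(msg, "bin centers must increase with constant spacing binWidth")
  }
  nb <- round(diff(md$mzRange) * md$binsPerMz) + 1L
  if (length(ctr) != nb)
    msg <- c(msg, "n_bins must equal round((mz_max - mz_min) * binsPerMz) + 1")
  if (abs(md$binWidth - 1 / md$binsPerMz) > 1e-12)
    msg <- c(msg, "binWidth must equal 1/binsPerMz")
  a <- assay(object, "intensity")
  if (any(a < 0)) msg <- c(msg, "intensities must be non-negative")
  if (!md$normalized %in% c("raw", "TIC"))
    msg <- c(msg, "normalized must be 'raw' or 'TIC'")
  if (identical(md$normalized, "TIC")) {
    tot <- colSums(a)
    bad <- abs(tot - 1) > 1e-6 & tot > 0
    if (any(bad))
      msg <- c(msg, "TIC-normalized pixels with signal must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' AnnotationSet: labeled polygon regions
#'
#' @slot polygons list; each element a list with \code{vertices}
#'   (numeric matrix, >= 3 rows, columns x, y in pixel coordinates) and
#'   \code{label} (nonempty string).
#' @slot categoryMap data.frame with columns \code{label}, \code{gross},
#'   \code{category}, \code{sub} (integer or NA).
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(polygons = "list", categoryMap = "data.frame")
)

setValidity("AnnotationSet", function(object) {
  msg <- character()
  for (i in seq_along(object@polygons)) {
    p <- object@polygons[[i]]
    if (!is.matrix(p$vertices) || nrow(p$vertices) < 3L)
      msg <- c(msg, sprintf("polygon %d has fewer than 3 vertices", i))
    if (is.null(p$label) || !nzchar(p$label))
      msg <- c(msg, sprintf("polygon %d has an empty label", i))
  }
  labs <- unique(vapply(object@polygons, `[[`, "", "label"))
  unresolved <- setdiff(labs, object@categoryMap$label)
  if (length(unresolved))
    msg <- c(msg, sprintf("labels without gross-region mapping: %s",
                          paste(unresolved, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' LabelMask: rasterized per-pixel category labels
#'
#' @slot labels integer matrix (H x W) of category indices.
#' @slot indexTable data.frame with columns \code{index},
#'   \code{category}, \code{gross}; includes the background row.
#' @slot backgroundIndex integer index of the background ("BG") category.
#' @exportClass LabelMask
setClass("LabelMask",
  representation(labels = "matrix", indexTable = "data.frame",
                 backgroundIndex = "integer")
)

setValidity("LabelMask", function(object) {
  msg <- character()
  if (!all(object@labels %in% object@indexTable$index))
    msg <- c(msg, "every pixel label must be a known category index")
  if (!object@backgroundIndex %in% object@indexTable$index)
    msg <- c(msg, "background index missing from index table")
  if (length(msg)) msg else TRUE
})

#' MzSampleSet: raw m/z observations around a candidate
#'
#' @slot candidateMz numeric(1), Da.
#' @slot samples numeric matrix with columns \code{mz}, \code{intensity}.
#' @slot halfWindow numeric(1), Da.
#' @exportClass MzSampleSet
setClass("MzSampleSet",
  representation(candidateMz = "numeric", samples = "matrix",
                 halfWindow = "numeric")
)

setValidity("MzSampleSet", function(object) {
  msg <- character()
  if (nrow(object@samples)) {
    if (any(abs(object@samples[, 1] - object@candidateMz) >
            object@halfWindow + 1e-12))
      msg <- c(msg, "all samples must lie within candidate +/- halfWindow")
    if (any(object@samples[, 2] <= 0))
      msg <- c(msg, "sample intensities must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' RefinedPeak: Gaussian-mixture refined m/z centers
#'
#' @slot candidateMz numeric(1), the fixed-bin candidate (Da).
#' @slot components data.frame with columns \code{mean}, \code{sigma},
#'   \code{weight}; all fitted components, weights summing to 1.
#' @slot retainedCenters numeric, sorted means of components with weight
#'   >= the discard threshold.
#' @slot capturedFraction numeric(1), fraction of window intensity within
#'   retained-center windows.
#' @exportClass RefinedPeak
setClass("RefinedPeak",
  representation(candidateMz = "numeric", components = "data.frame",
                 retainedCenters = "numeric", capturedFraction = "numeric")
)

setValidity("RefinedPeak", function(object) {
  msg <- character()
  if (nrow(object@components) &&
      abs(sum(object@components$weight) - 1) > 1e-6)
    msg <- c(msg, "component weights must sum to 1 before discarding")
  if (is.unsorted(object@retainedCenters))
    msg <- c(msg, "retained centers must be sorted ascending")
  if (length(msg)) msg else TRUE
})

#' PixelTable: labeled feature matrix for modeling
#'
#' @slot X numeric matrix, n_pixels x n_features.
#' @slot y factor of category labels, length n_pixels.
#' @slot featureMz numeric, m/z (Da) per feature column.
#' @exportClass PixelTable
setClass("PixelTable",
  representation(X = "matrix", y = "factor", featureMz = "numeric")
)

setValidity("PixelTable", function(object) {
  msg <- character()
  if (!all(is.finite(object@X)))
    msg <- c(msg, "feature matrix contains non-finite entries")
  if (nrow(object@X) != length(object@y))
    msg <- c(msg, "X rows and labels must match")
  if (length(object@featureMz) != ncol(object@X))
    msg <- c(msg, "one featureMz per column required")
  if (length(msg)) msg else TRUE
})

#' BayesModel: variational posterior of a Bayesian logistic classifier
#'
#' Mean-field Gaussian posterior over multinomial-logistic weights.
#'
#' @slot weightMean,weightSd numeric K x D matrices (classes x features).
#' @slot biasMean,biasSd numeric length-K vectors.
#' @slot classes character, category labels in weight row order.
#' @slot center,scale numeric length-D standardization applied to inputs.
#' @slot priorSd numeric(1), prior std of each weight.
#' @slot seed integer training seed.
#' @exportClass BayesModel
setClass("BayesModel",
  representation(weightMean = "matrix", weightSd = "matrix",
                 biasMean = "numeric", biasSd = "numeric",
                 classes = "character", center = "numeric",
                 scale = "numeric", priorSd = "numeric", seed = "integer")
)

setValidity("BayesModel", function(object) {
  msg <- character()
  if (any(object@weightSd <= 0) || any(object@biasSd <= 0))
    msg <- c(msg, "posterior stds must be positive")
  if (nrow(object@weightMean) != length(object@classes))
    msg <- c(msg, "one weight row per class required")
  if (length(msg)) msg else TRUE
})

#' EnsembleConfusion: per-model soft confusion and worst-case pair scores
#'
#' @slot perModel list; per model a list with K x K matrices \code{mean}
#'   and \code{sd} (moments over posterior draws of the soft confusion).
#' @slot pairScore numeric K x K, max over models of mean + 2*sd.
#' @slot classes character.
#' @slot nModels,nPosteriorSamples integers.
#' @exportClass EnsembleConfusion
setClass("EnsembleConfusion",
  representation(perModel = "list", pairScore = "matrix",
                 classes = "character", nModels = "integer",
                 nPosteriorSamples = "integer")
)

setValidity("EnsembleConfusion", function(object) {
  msg <- character()
  for (m in object@perModel) {
    rs <- rowSums(m$mean)
    ok <- is.na(rs) | abs(rs - 1) <= 1e-6
    if (!all(ok))
      msg <- c(msg, "each confusion mean row must sum to 1 (or be NA-flagged)")
  }
  if (any(object@pairScore < 0, na.rm = TRUE))
    msg <- c(msg, "pair scores must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CategoryProfile: per-category mean feature intensities
#'
#' @slot profile numeric K x D matrix of mean intensities.
#' @slot categories character, row labels.
#' @slot featureMz numeric per column.
#' @slot normalization "TIC" or "raw".
#' @exportClass CategoryProfile
setClass("CategoryProfile",
  representation(profile = "matrix", categories = "character",
                 featureMz = "numeric", normalization = "character")
)

setValidity("CategoryProfile", function(object) {
  msg <- character()
  if (nrow(object@profile) != length(object@categories))
    msg <- c(msg, "one profile row per category required")
  if (!all(is.finite(object@profile)))
    msg <- c(msg, "profile rows must be finite")
  if (length(msg)) msg else TRUE
})

#' AtlasGraph: the computational atlas graph
#'
#' Category nodes at 2-D embedding coordinates, sized by degree, joined
#' by confusion-weighted edges labeled intra- or inter-gross-region.
#'
#' @slot nodes data.frame: \code{category}, \code{gross}, \code{x},
#'   \code{y}, \code{degree}, \code{size}.
#' @slot edges data.frame: \code{from}, \code{to}, \code{weight},
#'   \code{kind} ("intra" or "inter").
#' @slot edgeThreshold numeric(1).
#' @slot seed integer embedding seed.
#' @exportClass AtlasGraph
setClass("AtlasGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 edgeThreshold = "numeric", seed = "integer")
)

setValidity("AtlasGraph", function(object) {
  msg <- character()
  if (nrow(object@edges)) {
    if (any(object@edges$weight < object@edgeThreshold - 1e-12))
      msg <- c(msg, "all edges must have weight >= edgeThreshold")
    if (!all(object@edges$kind %in% c("intra", "inter")))
      msg <- c(msg, "edge kind must be 'intra' or 'inter'")
    same <- object@nodes$gross[match(object@edges$from, object@nodes$category)] ==
            object@nodes$gross[match(object@edges$to, object@nodes$category)]
    if (!all((object@edges$kind == "intra") == same))
      msg <- c(msg, "edge kind must match the gross-region rule")
  }
  if (length(msg)) msg else TRUE
})

#' StabilityResult: noise-calibrated stability selection output
#'
#' @slot selected named list: per category, integer indices of retained
#'   features.
#' @slot frequency numeric K x D matrix of selection frequencies.
#' @slot noiseThresholds numeric matrix (models x categories) of the
#'   per-model max |noise weight| thresholds.
#' @slot retainFreq numeric(1).
#' @slot featureMz numeric per feature.
#' @exportClass StabilityResult
setClass("StabilityResult",
  representation(selected = "list", frequency = "matrix",
                 noiseThresholds = "matrix", retainFreq = "numeric",
                 featureMz = "numeric")
)

setValidity("StabilityResult", function(object) {
  msg <- character()
  if (any(object@frequency < 0 | object@frequency > 1, na.rm = TRUE))
    msg <- c(msg, "selection frequencies must lie in [0, 1]")
  for (cat in names(object@selected)) {
    idx <- object@selected[[cat]]
    if (length(idx) &&
        any(object@frequency[cat, idx] < object@retainFreq - 1e-12))
      msg <- c(msg, "selected features must meet the retention frequency")
  }
  if (length(msg)) msg else TRUE
})

#' MzAssociationTable: pairwise-AUC association scores
#'
#' @slot table data.frame: \code{mz}, \code{category}, \code{score},
#'   \code{round} (1 or 2), \code{rank}.
#' @slot topPerCategory named list of per-category m/z vectors.
#' @slot k,top integers: round-1 prune size and reported list length.
#' @exportClass MzAssociationTable
setClass("MzAssociationTable",
  representation(table = "data.frame", topPerCategory = "list",
                 k = "integer", top = "integer")
)

setValidity("MzAssociationTable", function(object) {
  if (nrow(object@table) && any(object@table$score < 0))
    return("association scores must be non-negative")
  TRUE
})
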