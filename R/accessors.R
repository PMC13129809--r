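#' @include AllClasses.R
NULL

#' Accessors for msiatlas classes
#'
#' Small accessor functions used in place of direct slot access.
#'
#' @param x an msiatlas object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
pixelCoords <- function(x) {
  stopifnot(is(x, "SpectraDataset"))
  x@coords
}

#' @rdname accessors
#' @export
spectraList <- function(x) {
  stopifnot(is(x, "SpectraDataset"))
  x@spectra
}

#' @rdname accessors
#' @export
mzRange <- function(x) {
  if (is(x, "SpectraDataset")) return(x@mzRange)
  if (is(x, "BinnedCube")) return(metadata(x)$mzRange)
  stop("no mzRange for class ", class(x))
}

#' @rdname accessors
#' @export
binCenters <- function(x) {
  stopifnot(is(x, "BinnedCube"))
  rowData(x)$mz
}

#' @rdname accessors
#' @export
binWidth <- function(x) {
  stopifnot(is(x, "BinnedCube"))
  metadata(x)$binWidth
}

#' @rdname accessors
#' @export
imageDims <- function(x) {
  if (is(x, "BinnedCube")) return(metadata(x)$dims)
  if (is(x, "LabelMask")) return(dim(x@labels))
  stop("no image dimensions for class ", class(x))
}

#' @rdname accessors
#' @export
normalizationState <- function(x) {
  stopifnot(is(x, "BinnedCube"))
  metadata(x)$normalized
}

#' @rdname accessors
#' @export
zeroTicMask <- function(x) {
  stopifnot(is(x, "BinnedCube"))
  metadata(x)$zeroTic
}

#' @rdname accessors
#' @export
labelMatrix <- function(x) {
  stopifnot(is(x, "LabelMask"))
  x@labels
}

#' @rdname accessors
#' @export
indexTable <- function(x) {
  stopifnot(is(x, "LabelMask"))
  x@indexTable
}

#' @rdname accessors
#' @export
polygonList <- function(x) {
  stopifnot(is(x, "AnnotationSet"))
  x@polygons
}

#' @rdname accessors
#' @export
categoryMap <- function(x) {
  stopifnot(is(x, "AnnotationSet"))
  x@categoryMap
}

#' @rdname accessors
#' @export
retainedCenters <- function(x) {
  stopifnot(is(x, "RefinedPeak"))
  x@retainedCenters
}

#' @rdname accessors
#' @export
peakComponents <- function(x) {
  stopifnot(is(x, "RefinedPeak"))
  x@components
}

#' @rdname accessors
#' @export
mzSamples <- function(x) {
  stopifnot(is(x, "MzSampleSet"))
  x@samples
}

#' @rdname accessors
#' @export
pairScore <- function(x) {
  stopifnot(is(x, "EnsembleConfusion"))
  x@pairScore
}

#' @rdname accessors
#' @export
modelConfusions <- function(x) {
  stopifnot(is(x, "EnsembleConfusion"))
  x@perModel
}

#' @rdname accessors
#' @export
atlasNodes <- function(x) {
  stopifnot(is(x, "AtlasGraph"))
  x@nodes
}

#' @rdname accessors
#' @export
atlasEdges <- function(x) {
  stopifnot(is(x, "AtlasGraph"))
  x@edges
}

#' @rdname accessors
#' @export
profileMatrix <- function(x) {
  stopifnot(is(x, "CategoryProfile"))
  x@profile
}

#' @rdname accessors
#' @export
selectedFeatures <- function(x) {
  stopifnot(is(x, "StabilityResult"))
  x@selected
}

#' @rdname accessors
#' @export
selectionFrequency <- function(x) {
  stopifnot(is(x, "StabilityResult"))
  x@frequency
}

#' @rdname accessors
#' @export
associationTable <- function(x) {
  stopifnot(is(x, "MzAssociationTable"))
  x@table
}

#' @rdname accessors
#' @export
pixelFeatures <- function(x) {
  stopifnot(is(x, "PixelTable"))
  x@X
}

#' @rdname accessors
#' @export
pixelLabels <- function(x) {
  stopifnot(is(x, "PixelTable"))
  x@y
}

#' @rdname accessors
#' @export
featureMz <- function(x) {
  if (is(x, "PixelTable")) return(x@featureMz)
  if (is(x, "CategoryProfile")) return(x@featureMz)
  if (is(x, "StabilityResult")) return(x@featureMz)
  stop("no featureMz for class ", class(x))
}

setMethod("show", "SpectraDataset", function(object) {
  cat(sprintf("SpectraDataset: %d pixels, m/z %.4g-%.4g Da, %.3g peaks/pixel\n",
              nrow(object@coords), object@mzRange[1], object@mzRange[2],
              mean(vapply(object@spectra, nrow, 0L))))
})

setMethod("show", "BinnedCube", function(object) {
  md <- metadata(object)
  cat(sprintf(
    "BinnedCube: %d x %d pixels, %d bins (%.3g Da at %d bins/mz), %s\n",
    md$dims[1], md$dims[2], nrow(object), md$binWidth, md$binsPerMz,
    md$normalized))
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d polygons, %d labels, grosses: %s\n",
              length(object@polygons), length(unique(object@categoryMap$label)),
              paste(sort(unique(object@categoryMap$gross)), collapse = " ")))
})

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask: %d x %d, %d categories (incl. background)\n",
              nrow(object@labels), ncol(object@labels),
              nrow(object@indexTable)))
})

setMethod("show", "RefinedPeak", function(object) {
  cat(sprintf(
    "RefinedPeak @ %.4f: %d fitted, %d retained [%s], captured %.3f\n",
    object@candidateMz, nrow(object@components),
    length(object@retainedCenters),
    paste(sprintf("%.4f", object@retainedCenters), collapse = ", "),
    object@capturedFraction))
})

setMethod("show", "BayesModel", function(object) {
  cat(sprintf("BayesModel: %d classes x %d features, prior sd %.3g, seed %d\n",
              nrow(object@weightMean), ncol(object@weightMean),
              object@priorSd, object@seed))
})

setMethod("show", "EnsembleConfusion", function(object) {
  cat(sprintf(
    "EnsembleConfusion: %d models x %d draws over %d categories; max pair score %.3f\n",
    object@nModels, object@nPosteriorSamples, length(object@classes),
    max(object@pairScore[upper.tri(object@pairScore)], na.rm = TRUE)))
})

setMethod("show", "AtlasGraph", function(object) {
  cat(sprintf("AtlasGraph: %d nodes, %d edges (%d intra / %d inter), threshold %.4g\n",
              nrow(object@nodes), nrow(object@edges),
              sum(object@edges$kind == "intra"),
              sum(object@edges$kind == "inter"), object@edgeThreshold))
})

setMethod("show", "PixelTable", function(object) {
  cat(sprintf("PixelTable: %d pixels x %d features, %d categories\n",
              nrow(object@X), ncol(object@X), nlevels(object@y)))
})

setMethod("show", "StabilityResult", function(object) {
  cat(sprintf("StabilityResult: %d categories, retainFreq %.2f, %s selected\n",
              length(object@selected), object@retainFreq,
              paste(vapply(object@selected, length, 0L), collapse = "/")))
})

setMethod("show", "MzAssociationTable", function(object) {
  cat(sprintf("MzAssociationTable: %d rows, k=%d, top=%d\n",
              nrow(object@table), object@k, object@top))
})
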