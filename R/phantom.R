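#' @include AllClasses.R annotations.R imzml.R
NULL

#' PhantomSpec: configuration of a synthetic MSI phantom
#'
#' Describes a region-structured synthetic MSI experiment: polygonal
#' category layout, per-category spectral signatures, optional spots
#' that blend a remote category's signature into a host region
#' (plaque-like lesions), Gaussian mass error, and a uniform-m/z
#' Poisson noise floor.
#'
#' @slot shape integer(2) image (H, W).
#' @slot polygons list of \code{list(vertices, label)} in annotation
#'   order (later polygons take precedence).
#' @slot signatures named list: category -> data.frame(mz, abundance,
#'   cv). Abundance is the LogNormal mean intensity; cv its
#'   coefficient of variation.
#' @slot spots list of \code{list(center = c(row, col), radius, mix)}
#'   where \code{mix} is a named convex weight vector over categories.
#' @slot massSigma Gaussian mass-error sd (Da).
#' @slot baselineRate Poisson mean of uniform-m/z noise peaks per pixel.
#' @slot baselineIntensity mean intensity of noise peaks.
#' @slot mzRange numeric(2) acquisition range (Da).
#' @slot seed integer generation seed.
#' @slot markers named list: category -> exclusive marker m/z values.
#' @slot duplicatePairs list of character(2) planted duplicates.
#' @slot sharedFeatures list of \code{list(mz, categories, abundances)}.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(shape = "integer", polygons = "list",
                 signatures = "list", spots = "list",
                 massSigma = "numeric", baselineRate = "numeric",
                 baselineIntensity = "numeric", mzRange = "numeric",
                 seed = "integer", markers = "list",
                 duplicatePairs = "list", sharedFeatures = "list")
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  for (s in object@signatures) {
    if (any(s$abundance <= 0)) msg <- c(msg, "abundances must be positive")
    if (any(s$mz <= object@mzRange[1] | s$mz >= object@mzRange[2]))
      msg <- c(msg, "signature m/z must lie inside mzRange")
  }
  if (object@massSigma < 0) msg <- c(msg, "massSigma must be >= 0")
  for (sp in object@spots) {
    if (abs(sum(sp$mix) - 1) > 1e-9)
      msg <- c(msg, "spot mixtures must sum to 1")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' PhantomTruth: ground truth of a generated phantom
#'
#' @slot mask the rasterized \linkS4class{LabelMask}.
#' @slot expected matrix categories x planted features of exact
#'   expected mean intensity per pixel of that category.
#' @slot featureMz numeric, true m/z of the planted features (columns
#'   of \code{expected}).
#' @slot markers,duplicatePairs,sharedFeatures copied from the
#'   generating \linkS4class{PhantomSpec}.
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(mask = "LabelMask", expected = "matrix",
                 featureMz = "numeric", markers = "list",
                 duplicatePairs = "list", sharedFeatures = "list")
)

#' @rdname PhantomSpec-class
#' @param ... slots passed through; see the class documentation.
#' @export
phantomSpec <- function(shape, polygons, signatures, spots = list(),
                        massSigma = 0.002, baselineRate = 3,
                        baselineIntensity = 2, mzRange = c(700, 800),
                        seed = 1L, markers = list(),
                        duplicatePairs = list(), sharedFeatures = list()) {
  new("PhantomSpec", shape = as.integer(shape), polygons = polygons,
      signatures = signatures, spots = spots, massSigma = massSigma,
      baselineRate = baselineRate, baselineIntensity = baselineIntensity,
      mzRange = as.numeric(mzRange), seed = as.integer(seed),
      markers = markers, duplicatePairs = duplicatePairs,
      sharedFeatures = sharedFeatures)
}

# Rectangle polygon helper (inclusive pixel bounds, 0-based)
.rectPoly <- function(r0, r1, c0, c1, label) {
  list(vertices = cbind(x = c(c0, c1, c1, c0), y = c(r0, r0, r1, r1)),
       label = label)
}

# Regular 16-gon approximating a circle
.circlePoly <- function(center, radius, label) {
  th <- seq(0, 2 * pi, length.out = 17L)[-17L]
  list(vertices = cbind(x = center[2] + radius * cos(th),
                        y = center[1] + radius * sin(th)),
       label = label)
}

# Tile categories into a margin-padded grid of rectangles
.gridLayout <- function(shape, names, margin = 3L, gap = 3L) {
  n <- length(names)
  nr <- max(1L, floor(sqrt(n)))
  nc <- ceiling(n / nr)
  hAvail <- shape[1] - 2 * margin - (nr - 1) * gap
  wAvail <- shape[2] - 2 * margin - (nc - 1) * gap
  hh <- floor(hAvail / nr); ww <- floor(wAvail / nc)
  polys <- list()
  for (i in seq_len(n)) {
    r <- (i - 1L) %/% nc; cc <- (i - 1L) %% nc
    r0 <- margin + r * (hh + gap); c0 <- margin + cc * (ww + gap)
    polys[[i]] <- .rectPoly(r0, r0 + hh - 1L, c0, c0 + ww - 1L, names[i])
  }
  polys
}

# LogNormal parameterized by mean and coefficient of variation
.rlnormMeanCv <- function(n, mean, cv) {
  if (all(cv <= 0)) return(rep(mean, length.out = max(n, length(mean))))
  s2 <- log(1 + cv^2)
  out <- stats::rlnorm(max(n, length(mean)),
                       meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
  ifelse(rep(cv <= 0, length.out = length(out)),
         rep(mean, length.out = length(out)), out)
}

#' Generate a synthetic MSI phantom
#'
#' For every pixel, each feature of its category's signature (blended
#' with remote signatures inside spots) contributes one peak with
#' LogNormal intensity matching the configured (mean, cv) and observed
#' m/z drawn Normal(true m/z, massSigma); Poisson(baselineRate)
#' uniform-m/z low-intensity noise peaks are added. Deterministic
#' under the PhantomSpec seed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{dataset} (\linkS4class{SpectraDataset}),
#'   \code{annotations} (\linkS4class{AnnotationSet}) and \code{truth}
#'   (\linkS4class{PhantomTruth}).
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  ann <- AnnotationSet(spec@polygons)
  mask <- rasterizeAnnotations(ann, spec@shape)
  H <- spec@shape[1]; W <- spec@shape[2]

  allMz <- sort(unique(unlist(lapply(spec@signatures, `[[`, "mz"))))
  sigMat <- sapply(spec@signatures, function(s) {
    v <- stats::setNames(rep(0, length(allMz)), format(allMz))
    v[format(s$mz)] <- s$abundance
    v
  })  # features x categories (matrix)
  cvMat <- sapply(spec@signatures, function(s) {
    v <- stats::setNames(rep(0, length(allMz)), format(allMz))
    v[format(s$mz)] <- s$cv
    v
  })

  # per-pixel mean abundance: category signature, overridden inside spots
  catNames <- colnames(sigMat)
  labs <- mask@labels
  idxTab <- mask@indexTable
  pixelCat <- matrix(idxTab$category[match(labs, idxTab$index)], H, W)
  meanAb <- function(r, c) {
    for (sp in spec@spots) {
      if ((r - sp$center[1])^2 + (c - sp$center[2])^2 <= sp$radius^2) {
        m <- rep(0, length(allMz))
        cvv <- rep(0, length(allMz))
        for (cn in names(sp$mix)) {
          m <- m + sp$mix[[cn]] * sigMat[, cn]
          cvv <- pmax(cvv, cvMat[, cn])
        }
        return(list(mean = m, cv = cvv))
      }
    }
    cn <- pixelCat[r + 1L, c + 1L]
    if (cn %in% catNames)
      list(mean = sigMat[, cn], cv = cvMat[, cn])
    else
      list(mean = rep(0, length(allMz)), cv = rep(0, length(allMz)))
  }

  set.seed(spec@seed)
  coords <- cbind(row = rep(seq_len(H) - 1L, times = W),
                  col = rep(seq_len(W) - 1L, each = H))
  nPix <- nrow(coords)
  spectra <- vector("list", nPix)
  expSum <- matrix(0, nrow(idxTab), length(allMz),
                   dimnames = list(idxTab$category, format(allMz)))
  expN <- stats::setNames(rep(0L, nrow(idxTab)), idxTab$category)
  for (p in seq_len(nPix)) {
    r <- coords[p, 1]; cc <- coords[p, 2]
    ab <- meanAb(r, cc)
    on <- which(ab$mean > 0)
    mzs <- numeric(0); ints <- numeric(0)
    if (length(on)) {
      ints <- .rlnormMeanCv(length(on), ab$mean[on], ab$cv[on])
      mzs <- allMz[on] +
        if (spec@massSigma > 0) stats::rnorm(length(on), 0, spec@massSigma)
        else 0
    }
    nNoise <- stats::rpois(1L, spec@baselineRate)
    if (nNoise > 0L) {
      mzs <- c(mzs, stats::runif(nNoise, spec@mzRange[1], spec@mzRange[2]))
      ints <- c(ints, stats::rexp(nNoise, 1 / spec@baselineIntensity))
    }
    spectra[[p]] <- cbind(mz = mzs, intensity = ints)
    cn <- pixelCat[r + 1L, cc + 1L]
    expSum[cn, ] <- expSum[cn, ] + ab$mean
    expN[cn] <- expN[cn] + 1L
  }
  expected <- expSum / pmax(expN, 1L)
  ds <- SpectraDataset(coords, spectra, spec@mzRange)
  truth <- new("PhantomTruth", mask = mask, expected = expected,
               featureMz = allMz, markers = spec@markers,
               duplicatePairs = spec@duplicatePairs,
               sharedFeatures = spec@sharedFeatures)
  list(dataset = ds, annotations = ann, truth = truth)
}

#' Standard phantom presets
#'
#' Named \linkS4class{PhantomSpec} presets used throughout the test
#' suite:
#' \describe{
#'   \item{separable8}{8 categories over 3 gross regions plus
#'     background; one exclusive high-abundance marker per category,
#'     gross-region-shared features, and two tissue-wide features.}
#'   \item{duplicates}{separable8 plus a ninth category whose signature
#'     duplicates CNUcp exactly (confusion / atlas tests).}
#'   \item{index}{separable8 plus one feature shared along a planted
#'     CTXL2 - CNUcp - BSTsn chain with graded abundance (index-lipid
#'     behavior).}
#'   \item{plaque}{separable8 plus circular plaque-like PLQ spots inside
#'     CTXL2 blending host signal; the PLQ signature shares three
#'     features with the remote donor WMcc and one with the host.}
#'   \item{twin_peaks}{one tissue category carrying two peaks 0.015 Da
#'     apart (700.100 / 700.115, abundance ratio 7:3) with 0.002 Da
#'     mass error, for mixture refinement tests.}
#' }
#'
#' @param seed integer generation seed stored in every preset.
#' @return named list of \linkS4class{PhantomSpec} objects.
#' @export
standardFixtures <- function(seed = 1L) {
  cats8 <- c("CTXL2", "CTXL4", "CTXL6", "CNUcp",
             "CNUgpe", "WMcc", "WMfi", "BSTsn")
  grossOf <- function(x) vapply(x, function(l) parseCategory(l)$gross, "")
  sig <- function(mz, abundance, cv = 0.25)
    data.frame(mz = mz, abundance = abundance, cv = cv)
  markerMz <- stats::setNames(750.1 + 2 * (seq_along(cats8) - 1L), cats8)
  grossMz <- c(CTX = 710.5, CNU = 720.5, WM = 730.5, BST = 740.5)
  baseSignatures <- function() {
    sigs <- lapply(cats8, function(cn) {
      rbind(sig(c(705.5, 706.5), 30),            # tissue-wide
            sig(grossMz[[grossOf(cn)]], 40),     # gross-region-shared
            sig(markerMz[[cn]], 60))             # exclusive marker
    })
    names(sigs) <- cats8
    sigs
  }
  mkSpec <- function(names, signatures, ...) {
    phantomSpec(shape = c(48L, 48L),
                polygons = .gridLayout(c(48L, 48L), names),
                signatures = signatures,
                markers = as.list(markerMz[intersect(names(markerMz),
                                                     names(signatures))]),
                seed = seed, ...)
  }

  separable8 <- mkSpec(cats8, baseSignatures())

  dupSigs <- baseSignatures()
  dupSigs$CNUcpx <- dupSigs$CNUcp
  duplicates <- mkSpec(c(cats8, "CNUcpx"), dupSigs,
                       duplicatePairs = list(c("CNUcp", "CNUcpx")))

  idxSigs <- baseSignatures()
  chain <- c(CTXL2 = 50, CNUcp = 35, BSTsn = 20)
  for (cn in names(chain))
    idxSigs[[cn]] <- rbind(idxSigs[[cn]], sig(770.3, chain[[cn]]))
  index <- mkSpec(cats8, idxSigs,
                  sharedFeatures = list(list(mz = 770.3,
                                             categories = names(chain),
                                             abundances = unname(chain))))

  plqSigs <- baseSignatures()
  donorMz <- c(772.3, 774.3, 776.3)
  plqSigs$WMcc <- rbind(plqSigs$WMcc, sig(donorMz, 45))
  plqSigs$CTXL2 <- rbind(plqSigs$CTXL2, sig(778.3, 45))
  plqSigs$PLQ <- rbind(sig(780.2, 60),      # exclusive plaque marker
                       sig(donorMz, 45),    # shared with remote donor WMcc
                       sig(778.3, 45))      # shared with host CTXL2
  spotCenters <- list(c(8, 6), c(13, 9), c(18, 6), c(10, 11), c(16, 11))
  plaquePolys <- c(.gridLayout(c(48L, 48L), cats8),
                   lapply(spotCenters, .circlePoly, radius = 2.5,
                          label = "PLQ"))
  plaque <- phantomSpec(
    shape = c(48L, 48L), polygons = plaquePolys, signatures = plqSigs,
    spots = lapply(spotCenters, function(ctr)
      list(center = ctr, radius = 2.5, mix = c(PLQ = 0.6, CTXL2 = 0.4))),
    markers = c(as.list(markerMz), list(PLQ = 780.2)),
    sharedFeatures = list(
      list(mz = donorMz, categories = c("PLQ", "WMcc"), abundances = 45),
      list(mz = 778.3, categories = c("PLQ", "CTXL2"), abundances = 45)),
    seed = seed)

  twinPeaks <- phantomSpec(
    shape = c(24L, 24L),
    polygons = list(.rectPoly(2L, 21L, 2L, 21L, "CTXL2")),
    signatures = list(CTXL2 = sig(c(700.100, 700.115), c(70, 30))),
    massSigma = 0.002, baselineRate = 0.5, mzRange = c(700, 701),
    markers = list(CTXL2 = c(700.100, 700.115)), seed = seed)

  list(separable8 = separable8, duplicates = duplicates, index = index,
       plaque = plaque, twin_peaks = twinPeaks)
}

#' Simulate an m/z sample set from a planted Gaussian mixture
#'
#' Draws intensity-carrying m/z observations from a mixture of normal
#' mass-error components, for mixture-refinement validation.
#'
#' @param means,sigmas,weights mixture parameters (weights sum to 1).
#' @param n number of samples.
#' @param candidateMz nominal fixed-bin candidate (defaults to the
#'   weighted mean of the component means).
#' @param halfWindow window half-width (Da).
#' @param meanIntensity,intensityCv LogNormal intensity model.
#' @param seed RNG seed.
#' @return an \linkS4class{MzSampleSet}.
#' @export
simulateMzSamples <- function(means, sigmas, weights, n = 5000L,
                              candidateMz = sum(weights * means),
                              halfWindow = 0.01, meanIntensity = 50,
                              intensityCv = 0.5, seed = 1L) {
  stopifnot(length(means) == length(weights),
            abs(sum(weights) - 1) < 1e-9)
  if (length(sigmas) == 1L) sigmas <- rep(sigmas, length(means))
  set.seed(seed)
  comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
  mz <- stats::rnorm(n, means[comp], sigmas[comp])
  int <- .rlnormMeanCv(n, meanIntensity, intensityCv)
  keep <- abs(mz - candidateMz) <= halfWindow
  new("MzSampleSet", candidateMz = candidateMz,
      samples = cbind(mz = mz[keep], intensity = int[keep]),
      halfWindow = halfWindow)
}
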