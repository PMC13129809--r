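#' @include AllClasses.R utils.R bayes.R binning.R
NULL

#' Per-category mean feature profiles
#'
#' Row i is the mean feature vector over pixels labeled i — the
#' "average spectrum" node representation of the atlas.
#'
#' @param cube a \linkS4class{BinnedCube} (TIC-normalized or raw).
#' @param mask a matching \linkS4class{LabelMask}.
#' @param features optional integer bin indices to keep.
#' @param includeBackground include the background category (default
#'   TRUE).
#' @return a \linkS4class{CategoryProfile}; categories without pixels
#'   are excluded with a warning.
#' @export
categoryProfiles <- function(cube, mask, features = NULL,
                             includeBackground = TRUE) {
  stopifnot(is(cube, "BinnedCube"), is(mask, "LabelMask"))
  dims <- imageDims(cube)
  lin <- pixelIndex(cbind(colData(cube)$row, colData(cube)$col), dims)
  lab <- mask@labels[lin]
  catOf <- mask@indexTable$category[match(lab, mask@indexTable$index)]
  A <- assay(cube, "intensity")
  if (!is.null(features)) A <- A[features, , drop = FALSE]
  cats <- mask@indexTable$category
  if (!includeBackground)
    cats <- setdiff(cats, mask@indexTable$category[
      mask@indexTable$index == mask@backgroundIndex])
  have <- cats[cats %in% catOf]
  if (length(have) < length(cats))
    warning("categories without pixels excluded: ",
            paste(setdiff(cats, have), collapse = ", "))
  prof <- t(vapply(have, function(cn)
    rowMeans(A[, catOf == cn, drop = FALSE]), numeric(nrow(A))))
  fmz <- if (is.null(features)) binCenters(cube) else binCenters(cube)[features]
  new("CategoryProfile", profile = prof, categories = have,
      featureMz = as.numeric(fmz),
      normalization = metadata(cube)$normalized)
}

# Cosine distance matrix between rows
.cosineDist <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  S <- (M / nrm) %*% t(M / nrm)
  d <- 1 - pmin(pmax(S, -1), 1)
  d[d < 0] <- 0
  stats::as.dist(d)
}

# Deterministic 2-D embedding of profile rows: classical MDS of cosine
# distances, with a seeded sub-resolution jitter so coincident rows
# (planted duplicates) stay distinct but adjacent.
.embed2d <- function(M, seed, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  if (nrow(M) < 3L) stop("embedding needs at least 3 categories")
  d <- if (metric == "cosine") .cosineDist(M) else stats::dist(M)
  xy <- stats::cmdscale(d, k = 2L)
  if (ncol(xy) < 2L) xy <- cbind(xy, 0)
  span <- max(max(xy[, 1]) - min(xy[, 1]), max(xy[, 2]) - min(xy[, 2]), 1e-6)
  set.seed(seed)
  xy + matrix(stats::rnorm(length(xy), 0, span * 1e-4), nrow(xy), 2L)
}

.makeAtlas <- function(M, categories, conf, grossMap, edgeThreshold,
                       seed, sMin, sScale, metric) {
  if (!setequal(categories, conf@classes))
    stop("profile and confusion category sets differ")
  M <- M[match(conf@classes, categories), , drop = FALSE]
  categories <- conf@classes
  sym <- symmetrizedPairScore(conf)
  K <- length(categories)
  off <- sym[upper.tri(sym)]
  if (is.null(edgeThreshold))
    edgeThreshold <- as.numeric(stats::quantile(off, 0.9, na.rm = TRUE))
  xy <- .embed2d(M, seed, metric)
  ij <- which(upper.tri(sym) & sym >= edgeThreshold, arr.ind = TRUE)
  gross <- unname(grossMap[categories])
  edges <- data.frame(
    from = categories[ij[, 1]], to = categories[ij[, 2]],
    weight = sym[ij],
    kind = ifelse(gross[ij[, 1]] == gross[ij[, 2]], "intra", "inter"),
    stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight), , drop = FALSE]
  rownames(edges) <- NULL
  degree <- vapply(categories, function(cn)
    sum(edges$from == cn) + sum(edges$to == cn), 0L)
  nodes <- data.frame(
    category = categories, gross = gross,
    x = xy[, 1], y = xy[, 2], degree = degree,
    size = sMin + sScale * degree, stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  new("AtlasGraph", nodes = nodes, edges = edges,
      edgeThreshold = edgeThreshold, seed = as.integer(seed))
}

#' Build the computational atlas graph from category profiles
#'
#' Nodes are categories placed by a 2-D embedding (classical
#' multidimensional scaling of cosine distances between mean-spectrum
#' profiles; spectra are compositional, so cosine is the default
#' metric). Edges join pairs whose symmetrized worst-case confusion
#' score reaches \code{edgeThreshold} (default: the 90th percentile of
#' off-diagonal pair scores); edges within a gross region are "intra",
#' across regions "inter". Node size grows linearly with degree.
#'
#' @param profiles a \linkS4class{CategoryProfile}.
#' @param conf an \linkS4class{EnsembleConfusion} over the same
#'   categories.
#' @param grossMap named character vector category -> gross region.
#' @param edgeThreshold absolute edge threshold; NULL for the
#'   percentile default.
#' @param seed embedding seed.
#' @param sMin,sScale node-size map \code{size = sMin + sScale *
#'   degree}.
#' @param metric "cosine" (default) or "euclidean".
#' @return an \linkS4class{AtlasGraph}.
#' @export
buildAtlas <- function(profiles, conf, grossMap, edgeThreshold = NULL,
                       seed = 1L, sMin = 1, sScale = 1,
                       metric = "cosine") {
  stopifnot(is(profiles, "CategoryProfile"), is(conf, "EnsembleConfusion"))
  .makeAtlas(profiles@profile, profiles@categories, conf, grossMap,
             edgeThreshold, seed, sMin, sScale, metric)
}

#' Model-explanation atlas
#'
#' Same construction as \code{\link{buildAtlas}} with per-category
#' posterior-mean weight vectors (averaged over the ensemble's models)
#' in place of mean-spectrum profiles, showing how the classifiers
#' internally arrange the categories.
#'
#' @param models list of \linkS4class{BayesModel} objects sharing one
#'   class set.
#' @param conf an \linkS4class{EnsembleConfusion}.
#' @param grossMap named character vector category -> gross region.
#' @param edgeThreshold,seed,sMin,sScale,metric as in
#'   \code{\link{buildAtlas}}.
#' @return an \linkS4class{AtlasGraph}.
#' @export
modelAtlas <- function(models, conf, grossMap, edgeThreshold = NULL,
                       seed = 1L, sMin = 1, sScale = 1,
                       metric = "cosine") {
  stopifnot(length(models) >= 1L, is(conf, "EnsembleConfusion"))
  classes <- models[[1]]@classes
  W <- Reduce(`+`, lapply(models, function(m) m@weightMean)) /
    length(models)
  .makeAtlas(W, classes, conf, grossMap, edgeThreshold, seed, sMin,
             sScale, metric)
}

#' Flag likely annotation problems
#'
#' Category pairs that sit close in the embedding (below the
#' \code{distanceQuantile} of all node-pair distances) while connected
#' by a strong edge (above the \code{weightQuantile} of edge weights)
#' are candidate duplicated or ambiguous annotations, ranked by edge
#' weight.
#'
#' @param g an \linkS4class{AtlasGraph} with >= 1 edge.
#' @param distanceQuantile quantile of node-pair distances (default
#'   0.25).
#' @param weightQuantile quantile of edge weights (default 0.75).
#' @return data.frame of flagged pairs: \code{from}, \code{to},
#'   \code{weight}, \code{distance}; empty when nothing qualifies.
#' @export
flagAnnotationIssues <- function(g, distanceQuantile = 0.25,
                                 weightQuantile = 0.75) {
  stopifnot(is(g, "AtlasGraph"))
  if (!nrow(g@edges))
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), distance = numeric()))
  xy <- as.matrix(g@nodes[, c("x", "y")])
  rownames(xy) <- g@nodes$category
  allD <- stats::dist(xy)
  dThr <- stats::quantile(allD, distanceQuantile)
  wThr <- stats::quantile(g@edges$weight, weightQuantile)
  ed <- g@edges
  ed$distance <- sqrt(rowSums((xy[ed$from, , drop = FALSE] -
                               xy[ed$to, , drop = FALSE])^2))
  out <- ed[ed$distance <= dThr & ed$weight >= wThr, , drop = FALSE]
  out <- out[order(-out$weight), c("from", "to", "weight", "distance")]
  rownames(out) <- NULL
  out
}

#' Majority-vote pixel segmentation
#'
#' Per pixel, each model votes with the argmax of its posterior-mean
#' prediction; ties break toward the class with the highest mean
#' predicted probability.
#'
#' @param models list of \linkS4class{BayesModel} objects.
#' @param X feature matrix.
#' @return character vector of predicted categories.
#' @export
majorityVote <- function(models, X) {
  classes <- models[[1]]@classes
  K <- length(classes)
  votes <- matrix(0L, nrow(X), K)
  meanP <- 0
  for (m in models) {
    P <- .forward(m, .standardize(m, X), draw = FALSE)
    meanP <- meanP + P / length(models)
    amax <- max.col(P, ties.method = "first")
    votes[cbind(seq_len(nrow(X)), amax)] <- votes[cbind(seq_len(nrow(X)), amax)] + 1L
  }
  top <- apply(votes, 1L, max)
  pick <- vapply(seq_len(nrow(X)), function(i) {
    tied <- which(votes[i, ] == top[i])
    if (length(tied) == 1L) tied else tied[which.max(meanP[i, tied])]
  }, 0L)
  classes[pick]
}

#' Compare cohorts on predicted-category raw profiles
#'
#' Segments every cube by ensemble majority vote (so categories absent
#' from a scan's annotations still get profiles), then averages raw
#' (non-TIC) spectra per predicted category within each cohort, and
#' tabulates per-(category, feature) differences between the first two
#' cohorts.
#'
#' @param cohorts named list (>= 2) of lists of raw
#'   \linkS4class{BinnedCube} objects.
#' @param models list of trained \linkS4class{BayesModel} objects (the
#'   segmentation ensemble).
#' @param featureMz m/z values of the model's feature columns (to
#'   locate them among the cube bins).
#' @return list: \code{profiles} (named list of
#'   \linkS4class{CategoryProfile}, raw scale), \code{difference}
#'   (matrix, first cohort minus second; rows NA-flagged when a
#'   category is predicted in only one cohort), \code{undefined}
#'   (those category names).
#' @export
cohortCompare <- function(cohorts, models, featureMz) {
  stopifnot(length(cohorts) >= 2L, length(models) >= 1L)
  classes <- models[[1]]@classes
  perCohort <- lapply(cohorts, function(cubes) {
    sumRaw <- NULL; cnt <- stats::setNames(rep(0L, length(classes)), classes)
    for (cube in cubes) {
      stopifnot(is(cube, "BinnedCube"))
      if (!identical(metadata(cube)$normalized, "raw"))
        stop("cohort cubes must be raw (non-TIC)")
      fIdx <- match(round(featureMz, 6), round(binCenters(cube), 6))
      if (anyNA(fIdx)) stop("model features not found among cube bins")
      ticCube <- ticNormalize(cube)
      X <- t(assay(ticCube, "intensity")[fIdx, , drop = FALSE])
      pred <- majorityVote(models, X)
      raw <- t(assay(cube, "intensity")[fIdx, , drop = FALSE])
      if (is.null(sumRaw))
        sumRaw <- matrix(0, length(classes), ncol(raw),
                         dimnames = list(classes, NULL))
      for (cl in unique(pred)) {
        sel <- pred == cl
        sumRaw[cl, ] <- sumRaw[cl, ] + colSums(raw[sel, , drop = FALSE])
        cnt[cl] <- cnt[cl] + sum(sel)
      }
    }
    prof <- sumRaw / pmax(cnt, 1L)
    prof[cnt == 0L, ] <- NA_real_
    list(profile = prof, counts = cnt)
  })
  profiles <- lapply(perCohort, function(pc)
    new("CategoryProfile",
        profile = ifelse(is.na(pc$profile), 0, pc$profile),
        categories = classes, featureMz = as.numeric(featureMz),
        normalization = "raw"))
  p1 <- perCohort[[1]]$profile; p2 <- perCohort[[2]]$profile
  diffM <- p1 - p2
  undefined <- classes[perCohort[[1]]$counts == 0L |
                       perCohort[[2]]$counts == 0L]
  if (length(undefined))
    warning("categories predicted in only one cohort: ",
            paste(undefined, collapse = ", "))
  list(profiles = profiles, difference = diffM, undefined = undefined)
}

#' Write / read an atlas graph as JSON
#'
#' @param g an \linkS4class{AtlasGraph}.
#' @param path output path.
#' @return \code{path} (write) or an \linkS4class{AtlasGraph} (read).
#' @export
writeAtlasGraph <- function(g, path) {
  stopifnot(is(g, "AtlasGraph"))
  jsonlite::write_json(
    list(nodes = g@nodes, edges = g@edges,
         edgeThreshold = g@edgeThreshold, seed = g@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAtlasGraph
#' @export
readAtlasGraph <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as.data.frame(j$edges)
  if (!nrow(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), kind = character())
  new("AtlasGraph", nodes = as.data.frame(j$nodes), edges = edges,
      edgeThreshold = j$edgeThreshold, seed = as.integer(j$seed))
}

#' Write an atlas graph as GraphML
#'
#' @param g an \linkS4class{AtlasGraph}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAtlasGraphML <- function(g, path) {
  stopifnot(is(g, "AtlasGraph"))
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  keys <- paste0(
    '<key id="gross" for="node" attr.name="gross" attr.type="string"/>',
    '<key id="x" for="node" attr.name="x" attr.type="double"/>',
    '<key id="y" for="node" attr.name="y" attr.type="double"/>',
    '<key id="size" for="node" attr.name="size" attr.type="double"/>',
    '<key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '<key id="kind" for="edge" attr.name="kind" attr.type="string"/>')
  nodes <- apply(g@nodes, 1L, function(r) sprintf(
    '<node id="%s"><data key="gross">%s</data><data key="x">%s</data><data key="y">%s</data><data key="size">%s</data></node>',
    esc(r[["category"]]), esc(r[["gross"]]), r[["x"]], r[["y"]], r[["size"]]))
  edges <- if (nrow(g@edges)) apply(g@edges, 1L, function(r) sprintf(
    '<edge source="%s" target="%s"><data key="weight">%s</data><data key="kind">%s</data></edge>',
    esc(r[["from"]]), esc(r[["to"]]), r[["weight"]], r[["kind"]]))
    else character()
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">', keys,
    '<graph id="atlas" edgedefault="undirected">',
    paste(nodes, collapse = ""), paste(edges, collapse = ""),
    "</graph></graphml>"), path)
  invisible(path)
}
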