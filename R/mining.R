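#' @include AllClasses.R utils.R
NULL

#' Rank-based AUC with a rank-sum p-value
#'
#' AUC = P(random a > random b) + 0.5 P(tie), computed from ranks.
#' The two-sided p-value comes from the Wilcoxon rank-sum null: exact
#' enumeration when both groups have at most 10 untied values, else a
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b nonempty numeric vectors (the two groups).
#' @return list with \code{auc} and \code{p}.
#' @export
pairwiseAUC <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (!n1 || !n2) stop("both groups must be nonempty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n2)
  hasTies <- anyDuplicated(c(a, b)) > 0L
  if (!hasTies && n1 <= 10L && n2 <= 10L) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 stats::pwilcox(n1 * n2 - U, n1, n2))
    p <- min(p, 1)
  } else {
    N <- n1 + n2
    ties <- table(c(a, b))
    tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tieCorr)
    mu <- n1 * n2 / 2
    if (sigma2 <= 0) return(list(auc = auc, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc = auc, p = p)
}

# Ridge one-vs-rest logistic regression by iteratively reweighted
# least squares (exact Newton steps, L2 penalty on the slopes,
# intercept unpenalized). Returns the (1 + D) x K coefficient matrix,
# intercept first.
.ridgeLogregOVR <- function(Xs, Y, lambda, maxIter = 25L, tol = 1e-5) {
  Xa <- cbind(1, Xs)
  D1 <- ncol(Xa)
  pen <- c(1e-10, rep(lambda, D1 - 1L))
  vapply(seq_len(ncol(Y)), function(k) {
    y <- Y[, k]
    b <- numeric(D1)
    for (it in seq_len(maxIter)) {
      eta <- drop(Xa %*% b)
      p <- stats::plogis(eta)
      w <- pmax(p * (1 - p), 1e-6)
      H <- crossprod(Xa * sqrt(w))
      diag(H) <- diag(H) + pen
      bn <- drop(solve(H, crossprod(Xa, w * eta + (y - p))))
      delta <- max(abs(bn - b))
      b <- bn
      if (delta < tol) break
    }
    b
  }, numeric(D1))
}

#' Noise-calibrated stability selection of category markers
#'
#' Trains \code{nModels} regularized one-vs-rest logistic models, each
#' on a random row subsample augmented with \code{nNoise} noise
#' columns (randomly chosen real feature columns, independently
#' row-permuted). Per model and category, the selection threshold is
#' the maximum absolute weight over the noise columns; real features
#' with positive weight above it are marked. Features marked in at
#' least \code{retainFreq} of the (valid) models are retained.
#'
#' @param t a \linkS4class{PixelTable}.
#' @param nModels number of models (default 200).
#' @param subsample row subsampling fraction (default 0.5).
#' @param nNoise number of permuted noise columns (default 50; must
#'   not exceed the feature count).
#' @param retainFreq retention frequency threshold (default 0.8).
#' @param seed base seed; per-model RNG derives from (seed, model).
#' @param lambda ridge penalty passed to the inner fits, scaled by the
#'   subsample size (default 1).
#' @return a \linkS4class{StabilityResult}.
#' @export
stabilitySelect <- function(t, nModels = 200L, subsample = 0.5,
                            nNoise = 50L, retainFreq = 0.8, seed = 1L,
                            lambda = 1.0) {
  stopifnot(is(t, "PixelTable"))
  D <- ncol(t@X)
  if (nNoise > D) stop("nNoise must not exceed the number of features")
  if (nModels < 1L) stop("nModels must be >= 1")
  cats <- levels(t@y)
  K <- length(cats)
  n <- nrow(t@X)
  marks <- matrix(0, K, D, dimnames = list(cats, NULL))
  denom <- stats::setNames(rep(0L, K), cats)
  thresholds <- matrix(NA_real_, nModels, K,
                       dimnames = list(NULL, cats))
  for (mIdx in seq_len(nModels)) {
    set.seed(deriveSeed(seed, mIdx))
    rows <- sample.int(n, max(2L, floor(n * subsample)))
    Xm <- t@X[rows, , drop = FALSE]
    ym <- t@y[rows]
    if (nNoise > 0L) {
      src <- sample.int(D, nNoise, replace = TRUE)
      noise <- vapply(src, function(j)
        Xm[sample.int(nrow(Xm)), j], numeric(nrow(Xm)))
      Xm <- cbind(Xm, noise)
    }
    ctr <- colMeans(Xm)
    scl <- apply(Xm, 2L, stats::sd); scl[scl == 0] <- 1
    Xs <- sweep(sweep(Xm, 2L, ctr), 2L, scl, "/")
    counts <- table(factor(ym, levels = cats))
    valid <- cats[counts >= 2L & (length(ym) - counts) >= 2L]
    if (length(valid) < length(cats))
      message(sprintf("model %d skipped for '%s' (too few pixels)", mIdx,
                      paste(setdiff(cats, valid), collapse = "', '")))
    if (!length(valid)) next
    Y <- vapply(valid, function(cat) as.numeric(ym == cat),
                numeric(length(ym)))
    B <- .ridgeLogregOVR(Xs, Y, lambda)
    for (ci in seq_along(valid)) {
      cat <- valid[ci]
      wts <- B[-1L, ci]
      thr <- if (nNoise > 0L) max(abs(wts[(D + 1L):(D + nNoise)])) else 0
      thresholds[mIdx, cat] <- thr
      marks[cat, ] <- marks[cat, ] + as.numeric(wts[seq_len(D)] > thr)
      denom[cat] <- denom[cat] + 1L
    }
  }
  freq <- marks / pmax(denom, 1L)
  freq[denom == 0L, ] <- NA_real_
  selected <- lapply(cats, function(cat) {
    f <- freq[cat, ]
    which(!is.na(f) & f >= retainFreq)
  })
  names(selected) <- cats
  new("StabilityResult", selected = selected, frequency = freq,
      noiseThresholds = thresholds, retainFreq = retainFreq,
      featureMz = t@featureMz)
}

#' Pairwise-AUC association scores for every (m/z, category)
#'
#' Round 1 scores every category i for every feature by summing, over
#' the other categories j, the AUC of category-i values against
#' category-j values, restricted to comparisons with p below
#' \code{pThreshold}. Round 2 keeps, per feature, the \code{k}
#' highest-scoring round-1 categories and recomputes the score within
#' that set, removing the influence of irrelevant categories. Reported
#' per feature are the \code{top} round-2 categories; the per-category
#' association lists contain features for which the category's round-2
#' rank is at most \code{assocRank}.
#'
#' @param t a \linkS4class{PixelTable} with >= 2 categories.
#' @param pThreshold p-value gate (default 0.05, uncorrected; set
#'   \code{bhCorrect = TRUE} for a Benjamini-Hochberg gate per
#'   feature).
#' @param k round-1 prune size (default 20).
#' @param top number of reported categories per feature (default 10).
#' @param assocRank rank cutoff for per-category association lists
#'   (default 2).
#' @param capPerCategory maximum pixels per category (uniform
#'   subsample, seeded; default 2000).
#' @param seed seed for the per-category cap.
#' @param bhCorrect apply Benjamini-Hochberg to the per-feature pair
#'   p-values before gating (default FALSE).
#' @return an \linkS4class{MzAssociationTable}.
#' @export
mpaucScores <- function(t, pThreshold = 0.05, k = 20L, top = 10L,
                        assocRank = 2L, capPerCategory = 2000L,
                        seed = 1L, bhCorrect = FALSE) {
  stopifnot(is(t, "PixelTable"))
  cats <- levels(t@y)
  K <- length(cats)
  if (K < 2L) stop("at least two categories are required")
  groups <- lapply(cats, function(cl) which(t@y == cl))
  set.seed(seed)
  groups <- lapply(groups, function(g)
    if (length(g) > capPerCategory) sort(sample(g, capPerCategory)) else g)
  names(groups) <- cats
  D <- ncol(t@X)
  rows <- list(); rn <- 0L
  assoc <- stats::setNames(vector("list", K), cats)
  for (f in seq_len(D)) {
    vals <- lapply(groups, function(g) t@X[g, f])
    aucM <- matrix(NA_real_, K, K); pM <- matrix(NA_real_, K, K)
    for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
      r <- pairwiseAUC(vals[[i]], vals[[j]])
      aucM[i, j] <- r$auc; aucM[j, i] <- 1 - r$auc
      pM[i, j] <- pM[j, i] <- r$p
    }
    if (bhCorrect) {
      up <- upper.tri(pM)
      pM[up] <- stats::p.adjust(pM[up], "BH")
      pM[lower.tri(pM)] <- t(pM)[lower.tri(pM)]
    }
    scoreWithin <- function(members) {
      vapply(members, function(i) {
        js <- setdiff(members, i)
        ok <- js[pM[i, js] < pThreshold]
        if (!length(ok)) 0 else sum(aucM[i, ok])
      }, 0)
    }
    s1 <- scoreWithin(seq_len(K))
    ord1 <- order(s1, decreasing = TRUE)
    for (rk in seq_len(min(top, K))) {
      rn <- rn + 1L
      rows[[rn]] <- data.frame(
        mz = t@featureMz[f], feature = f, category = cats[ord1[rk]],
        score = s1[ord1[rk]], round = 1L, rank = rk)
    }
    keepSet <- ord1[seq_len(min(k, K))]
    s2 <- scoreWithin(keepSet)
    ord2 <- order(s2, decreasing = TRUE)
    nRep <- min(top, length(keepSet))
    for (rk in seq_len(nRep)) {
      ci <- keepSet[ord2[rk]]
      rn <- rn + 1L
      rows[[rn]] <- data.frame(
        mz = t@featureMz[f], feature = f, category = cats[ci],
        score = s2[ord2[rk]], round = 2L, rank = rk)
      if (rk <= assocRank && s2[ord2[rk]] > 0)
        assoc[[cats[ci]]] <- c(assoc[[cats[ci]]], t@featureMz[f])
    }
  }
  tab <- if (rn) do.call(rbind, rows) else
    data.frame(mz = numeric(), feature = integer(), category = character(),
               score = numeric(), round = integer(), rank = integer())
  assoc <- lapply(assoc, function(v) if (is.null(v)) numeric(0) else v)
  new("MzAssociationTable", table = tab, topPerCategory = assoc,
      k = as.integer(k), top = as.integer(top))
}

# Per-category m/z sets from either association container.
.categorySets <- function(assoc) {
  if (is(assoc, "MzAssociationTable")) return(assoc@topPerCategory)
  if (is(assoc, "StabilityResult"))
    return(lapply(assoc@selected, function(idx) assoc@featureMz[idx]))
  stop("assoc must be an MzAssociationTable or StabilityResult")
}

#' Count categories sharing a focal category's features
#'
#' For each other category, the number of the focal category's
#' associated m/z values that are also associated with it. When a
#' gross-region map is supplied, per-gross feature-set unions are
#' attached (attribute \code{"grossSets"}) for Venn-style set
#' summaries.
#'
#' @param assoc an \linkS4class{MzAssociationTable} or
#'   \linkS4class{StabilityResult}.
#' @param focal focal category name with >= 1 associated feature.
#' @param grossMap optional named character vector category -> gross
#'   region.
#' @return named numeric vector of sharing counts (decreasing), with
#'   attributes \code{"focalFeatures"} and optionally
#'   \code{"grossSets"}.
#' @export
sharedFeatureSummary <- function(assoc, focal, grossMap = NULL) {
  sets <- .categorySets(assoc)
  if (!focal %in% names(sets)) stop("unknown focal category: ", focal)
  fset <- sets[[focal]]
  if (!length(fset)) stop("focal category has no associated features")
  others <- setdiff(names(sets), focal)
  counts <- vapply(others, function(cn)
    length(intersect(fset, sets[[cn]])), 0L)
  counts <- sort(counts, decreasing = TRUE)
  attr(counts, "focalFeatures") <- fset
  if (!is.null(grossMap)) {
    grosses <- unique(grossMap[names(sets)])
    gs <- lapply(grosses, function(g)
      sort(unique(unlist(sets[names(sets)[grossMap[names(sets)] == g]]))))
    names(gs) <- grosses
    attr(counts, "grossSets") <- gs
  }
  counts
}

# Proton mass (Da) for [M-H]- adduct adjustment
.PROTON_MASS <- 1.00728

#' Putative annotation by accurate-mass matching
#'
#' Matches query m/z values against a local reference table of neutral
#' monoisotopic masses, assuming the [M-H]- adduct (reference mass
#' minus one proton), within a mass tolerance. All matches within
#' tolerance are reported; queries with several matches are flagged
#' ambiguous.
#'
#' @param mzList numeric query m/z values (Da).
#' @param reference data.frame with columns \code{name},
#'   \code{monoisotopic_mz} and \code{class}.
#' @param tolerance mass tolerance in Da (default 0.01).
#' @param adduct only \code{"[M-H]-"} is supported.
#' @return data.frame with one row per (query, match): \code{mz},
#'   \code{name}, \code{reference_mz} (adduct-adjusted), \code{delta},
#'   \code{class}, \code{ambiguous}; unmatched queries get an NA match
#'   row.
#' @export
annotateMz <- function(mzList, reference, tolerance = 0.01,
                       adduct = "[M-H]-") {
  if (is.null(reference) || !nrow(reference))
    stop("a local reference table is required")
  stopifnot(all(c("name", "monoisotopic_mz", "class") %in% names(reference)))
  if (!identical(adduct, "[M-H]-"))
    stop("only the [M-H]- adduct is supported")
  adductMz <- reference$monoisotopic_mz - .PROTON_MASS
  out <- lapply(mzList, function(q) {
    d <- q - adductMz
    hit <- which(abs(d) <= tolerance)
    if (!length(hit))
      return(data.frame(mz = q, name = NA_character_,
                        reference_mz = NA_real_, delta = NA_real_,
                        class = NA_character_, ambiguous = FALSE))
    data.frame(mz = q, name = reference$name[hit],
               reference_mz = adductMz[hit], delta = d[hit],
               class = reference$class[hit],
               ambiguous = length(hit) > 1L)
  })
  do.call(rbind, out)
}
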