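#' @include AllClasses.R utils.R
NULL

#' Collect raw m/z observations around a candidate
#'
#' Stage 1 of the high-precision refinement workflow: instead of
#' building an image, gather every raw (m/z, intensity) pair within
#' candidate +/- halfWindow across all pixels. The result is
#' order-independent (sorted by m/z).
#'
#' @param ds a \linkS4class{SpectraDataset}.
#' @param candidateMz fixed-bin candidate (Da), inside the dataset mass
#'   range.
#' @param halfWindow half-width of the collection window (Da), default
#'   0.01.
#' @return an \linkS4class{MzSampleSet}; empty (with a warning) when
#'   no peaks fall in the window.
#' @export
collectMzSamples <- function(ds, candidateMz, halfWindow = 0.01) {
  stopifnot(is(ds, "SpectraDataset"))
  if (candidateMz < ds@mzRange[1] || candidateMz > ds@mzRange[2])
    stop("candidate m/z outside the dataset mass range")
  pieces <- lapply(ds@spectra, function(sp) {
    if (!nrow(sp)) return(NULL)
    sel <- abs(sp[, 1] - candidateMz) <= halfWindow & sp[, 2] > 0
    if (!any(sel)) return(NULL)
    sp[sel, , drop = FALSE]
  })
  samples <- do.call(rbind, pieces)
  if (is.null(samples) || !nrow(samples)) {
    warning(sprintf("no peaks within %.4f +/- %.4f", candidateMz, halfWindow))
    samples <- matrix(numeric(0), 0L, 2L,
                      dimnames = list(NULL, c("mz", "intensity")))
  } else {
    samples <- samples[order(samples[, 1]), , drop = FALSE]
  }
  new("MzSampleSet", candidateMz = candidateMz, samples = samples,
      halfWindow = halfWindow)
}

# Intensity-weighted EM for a 1-D Gaussian mixture. Case weights w sum
# to 1; variance floored to avoid component collapse.
.weightedGmmEM <- function(x, w, K, varFloor = 1e-8, maxIter = 300L,
                           tol = 1e-8, init = NULL) {
  n <- length(x)
  if (is.null(init)) {
    # weighted-quantile initialization (deterministic)
    o <- order(x)
    cw <- cumsum(w[o])
    q <- (seq_len(K) - 0.5) / K
    mu <- x[o][pmin(findInterval(q, cw) + 1L, n)]
    s2 <- rep(max(sum(w * (x - sum(w * x))^2) / K^2, varFloor), K)
    pi_ <- rep(1 / K, K)
  } else {
    mu <- init$mu; s2 <- init$s2; pi_ <- init$pi
  }
  ll <- -Inf
  logd <- matrix(0, n, K)
  for (it in seq_len(maxIter)) {
    for (k in seq_len(K))
      logd[, k] <- -0.5 * (x - mu[k])^2 / s2[k] - 0.5 * log(s2[k]) -
        0.918938533204673 + log(pi_[k])
    lse <- rowLogSumExp(logd)
    newLL <- sum(w * lse)
    r <- exp(logd - lse)
    Nk <- colSums(w * r)
    Nk <- pmax(Nk, 1e-300)
    pi_ <- Nk / sum(Nk)
    mu <- colSums(w * r * x) / Nk
    s2 <- vapply(seq_len(K), function(k)
      max(sum(w * r[, k] * (x - mu[k])^2) / Nk[k], varFloor), 0)
    if (is.finite(newLL) && abs(newLL - ll) < tol * (1 + abs(newLL))) {
      ll <- newLL; break
    }
    ll <- newLL
  }
  list(mu = mu, s2 = s2, pi = pi_, loglik = ll)
}

#' Fit a Gaussian mixture to an m/z sample set
#'
#' Stage 2 of the refinement workflow: an intensity-weighted
#' expectation-maximization mixture fit on the recorded m/z
#' distribution. Components carrying less than \code{minWeight} of the
#' mixture are discarded; the retained component means are the refined
#' m/z centers. When fewer distinct m/z values than components exist,
#' the component count is reduced accordingly. The best of one
#' deterministic quantile initialization and \code{restarts} seeded
#' random initializations (by weighted log-likelihood) is kept, so the
#' result is reproducible given the seed.
#'
#' @param s an \linkS4class{MzSampleSet} with at least one sample.
#' @param nComponents mixture size (default 3).
#' @param minWeight discard threshold on mixture weight (default 0.05).
#' @param seed integer RNG seed for the random restarts.
#' @param discardBy "weight" discards by mixture weight;
#'   "assigned" by the fraction of intensity-weighted samples whose
#'   maximum-responsibility assignment is the component.
#' @param restarts number of random restarts beyond the deterministic
#'   initialization (default 2).
#' @return a \linkS4class{RefinedPeak}.
#' @export
fitPeakGMM <- function(s, nComponents = 3L, minWeight = 0.05, seed = 1L,
                       discardBy = c("weight", "assigned"), restarts = 2L) {
  stopifnot(is(s, "MzSampleSet"))
  discardBy <- match.arg(discardBy)
  x <- s@samples[, 1]; w0 <- s@samples[, 2]
  if (!length(x)) stop("empty sample set: nothing to fit")
  w <- w0 / sum(w0)
  K <- min(as.integer(nComponents), length(unique(x)))
  fits <- list(.weightedGmmEM(x, w, K))
  if (K > 1L && restarts > 0L) {
    for (rix in seq_len(restarts)) {
      set.seed(deriveSeed(seed, rix))
      mu0 <- sample(x, K, prob = w)
      init <- list(mu = mu0,
                   s2 = rep(max(stats::var(x) / K, 1e-8), K),
                   pi = rep(1 / K, K))
      fits[[rix + 1L]] <- .weightedGmmEM(x, w, K, init = init)
    }
  }
  lls <- vapply(fits, `[[`, 0, "loglik")
  if (all(!is.finite(lls))) stop("mixture fit failed to converge to a finite likelihood")
  fit <- fits[[which.max(lls)]]
  ord <- order(fit$mu)
  comp <- data.frame(mean = fit$mu[ord], sigma = sqrt(fit$s2[ord]),
                     weight = fit$pi[ord])
  discardStat <- comp$weight
  if (discardBy == "assigned") {
    logd <- vapply(seq_len(K), function(k)
      stats::dnorm(x, comp$mean[k], comp$sigma[k], log = TRUE) +
        log(comp$weight[k]), numeric(length(x)))
    hard <- max.col(logd)
    discardStat <- vapply(seq_len(K), function(k) sum(w[hard == k]), 0)
  }
  keep <- discardStat >= minWeight
  if (!any(keep)) keep[which.max(discardStat)] <- TRUE
  centers <- sort(comp$mean[keep])
  within <- vapply(x, function(v) any(abs(v - centers) <= s@halfWindow),
                   logical(1))
  captured <- if (sum(w0) > 0) sum(w0[within]) / sum(w0) else NA_real_
  new("RefinedPeak", candidateMz = s@candidateMz, components = comp,
      retainedCenters = centers, capturedFraction = captured)
}

#' Re-extract per-center intensity images
#'
#' Stage 3: for each refined center, per pixel, sum raw intensities
#' within center +/- halfWindow. Overlapping center windows are
#' permitted; the pairwise overlap fraction is attached as the
#' \code{"overlapFraction"} attribute.
#'
#' @param ds a \linkS4class{SpectraDataset}.
#' @param centers nonempty numeric vector of refined m/z centers (Da).
#' @param halfWindow extraction half-width (Da), default 0.01.
#' @return named list of H x W intensity matrices, one per center.
#' @export
reextractRefinedImages <- function(ds, centers, halfWindow = 0.01) {
  stopifnot(is(ds, "SpectraDataset"))
  if (!length(centers)) stop("centers must be nonempty")
  centers <- sort(centers)
  dims <- c(max(ds@coords[, 1]) + 1L, max(ds@coords[, 2]) + 1L)
  imgs <- lapply(centers, function(ctr) {
    img <- matrix(0, dims[1], dims[2])
    vals <- vapply(ds@spectra, function(sp) {
      if (!nrow(sp)) return(0)
      sum(sp[abs(sp[, 1] - ctr) <= halfWindow, 2])
    }, 0)
    img[pixelIndex(ds@coords, dims)] <- vals
    img
  })
  names(imgs) <- format(centers)
  overlap <- 0
  if (length(centers) > 1L) {
    gaps <- diff(centers)
    overlap <- sum(pmax(2 * halfWindow - gaps, 0)) /
      (length(centers) * 2 * halfWindow)
    if (overlap > 0)
      message(sprintf("center windows overlap (fraction %.3f)", overlap))
  }
  attr(imgs, "overlapFraction") <- overlap
  imgs
}

#' Verify refined m/z centers against the raw data
#'
#' Stage 4: per retained center, the intensity-weighted mean and sd of
#' the contributing raw m/z values, plus the fraction of window
#' intensity captured by the retained windows.
#'
#' @param ds a \linkS4class{SpectraDataset}.
#' @param peak a \linkS4class{RefinedPeak} with >= 1 retained center.
#' @param halfWindow verification half-width (Da), default 0.01.
#' @return data.frame with columns \code{center}, \code{weightedMean},
#'   \code{weightedSd}, \code{n}, \code{empty}; the capture fraction is
#'   the \code{"capturedFraction"} attribute.
#' @export
verifyRefinement <- function(ds, peak, halfWindow = 0.01) {
  stopifnot(is(ds, "SpectraDataset"), is(peak, "RefinedPeak"))
  if (!length(peak@retainedCenters)) stop("peak has no retained centers")
  collectHw <- max(abs(peak@retainedCenters - peak@candidateMz)) + halfWindow
  all_ <- collectMzSamples(ds, peak@candidateMz, halfWindow = collectHw)
  sm <- all_@samples
  rows <- lapply(peak@retainedCenters, function(ctr) {
    sel <- abs(sm[, 1] - ctr) <= halfWindow
    if (!any(sel))
      return(data.frame(center = ctr, weightedMean = NA_real_,
                        weightedSd = NA_real_, n = 0L, empty = TRUE))
    mom <- weightedMoments(sm[sel, 1], sm[sel, 2])
    data.frame(center = ctr, weightedMean = mom[["mean"]],
               weightedSd = mom[["sd"]], n = sum(sel), empty = FALSE)
  })
  out <- do.call(rbind, rows)
  inAny <- vapply(sm[, 1], function(v)
    any(abs(v - peak@retainedCenters) <= halfWindow), logical(1))
  attr(out, "capturedFraction") <-
    if (nrow(sm)) sum(sm[inAny, 2]) / sum(sm[, 2]) else NA_real_
  out
}
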