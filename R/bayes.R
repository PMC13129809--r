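#' @include AllClasses.R utils.R
NULL

# One Adam update; state carries first/second moments and step count.
.adamStep <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$x <- state$x + lr * mhat / (sqrt(vhat) + eps)
  state
}

.newAdam <- function(x) list(x = x, m = x * 0, v = x * 0, t = 0L)

.viFit <- function(X, Y, priorSd, steps, lr, seed) {
  n <- nrow(X); D <- ncol(X); K <- ncol(Y)
  set.seed(seed)
  stW <- .newAdam(matrix(0, K, D))
  stLW <- .newAdam(matrix(log(0.1), K, D))
  stB <- .newAdam(numeric(K))
  stLB <- .newAdam(rep(log(0.1), K))
  ok <- TRUE
  for (it in seq_len(steps)) {
    sW <- exp(stLW$x); sB <- exp(stLB$x)
    epsW <- matrix(stats::rnorm(K * D), K, D)
    epsB <- stats::rnorm(K)
    W <- stW$x + sW * epsW
    b <- stB$x + sB * epsB
    logits <- X %*% t(W) + matrix(b, n, K, byrow = TRUE)
    P <- rowSoftmax(logits)
    if (!all(is.finite(P))) { ok <- FALSE; break }
    R <- Y - P                       # d loglik / d logits
    gW <- t(R) %*% X                 # K x D
    gB <- colSums(R)
    # KL gradients (mean-field Gaussian vs N(0, priorSd^2))
    gMuW <- gW - stW$x / priorSd^2
    gLsW <- gW * epsW * sW - (sW^2 / priorSd^2 - 1)
    gMuB <- gB - stB$x / priorSd^2
    gLsB <- gB * epsB * sB - (sB^2 / priorSd^2 - 1)
    stW <- .adamStep(stW, gMuW, lr)
    stLW <- .adamStep(stLW, gLsW, lr)
    stB <- .adamStep(stB, gMuB, lr)
    stLB <- .adamStep(stLB, gLsB, lr)
  }
  list(ok = ok, Wmu = stW$x, Wsd = exp(stLW$x), bmu = stB$x,
       bsd = exp(stLB$x))
}

#' Train a variational Bayesian multinomial logistic classifier
#'
#' Fits a mean-field Gaussian variational posterior over the weights
#' and biases of a multinomial logistic model by stochastic
#' maximization of the evidence lower bound (reparameterized
#' single-draw gradients, Adam). Each weight carries an independent
#' Gaussian prior with mean 0 and std \code{priorSd}. Features are
#' z-scored internally; the standardization is stored in the model and
#' applied automatically at prediction time.
#'
#' @param t a \linkS4class{PixelTable} with >= 2 classes.
#' @param priorSd prior std of each weight (default 1).
#' @param steps optimizer steps (default 400).
#' @param lr Adam learning rate (default 0.05).
#' @param seed integer seed; identical seed and data give identical
#'   posteriors.
#' @param balanced subsample every class to the minority count before
#'   fitting (default FALSE).
#' @return a \linkS4class{BayesModel}.
#' @export
trainBayesLogReg <- function(t, priorSd = 1.0, steps = 400L, lr = 0.05,
                             seed = 1L, balanced = FALSE) {
  stopifnot(is(t, "PixelTable"))
  y <- droplevels(t@y)
  if (nlevels(y) < 2L) stop("at least two classes are required")
  X <- t@X
  if (balanced) {
    set.seed(deriveSeed(seed, 999L))
    m <- min(table(y))
    keep <- unlist(lapply(levels(y), function(l)
      sample(which(y == l), m)))
    X <- X[keep, , drop = FALSE]; y <- droplevels(y[keep])
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  K <- nlevels(y)
  Y <- matrix(0, nrow(Xs), K)
  Y[cbind(seq_len(nrow(Xs)), as.integer(y))] <- 1
  fit <- .viFit(Xs, Y, priorSd, as.integer(steps), lr, seed)
  if (!fit$ok) {
    fit <- .viFit(Xs, Y, priorSd, as.integer(steps), lr / 5, seed)
    if (!fit$ok) stop("variational fit diverged (non-finite loss) even at reduced learning rate")
  }
  new("BayesModel", weightMean = fit$Wmu, weightSd = fit$Wsd,
      biasMean = fit$bmu, biasSd = fit$bsd, classes = levels(y),
      center = ctr, scale = scl, priorSd = priorSd,
      seed = as.integer(seed))
}

# n x K softmax probabilities for one posterior draw (or the mean when
# draw = FALSE).
.forward <- function(m, Xs, draw = TRUE) {
  K <- nrow(m@weightMean); D <- ncol(m@weightMean)
  if (draw) {
    W <- m@weightMean + m@weightSd * matrix(stats::rnorm(K * D), K, D)
    b <- m@biasMean + m@biasSd * stats::rnorm(K)
  } else {
    W <- m@weightMean; b <- m@biasMean
  }
  rowSoftmax(Xs %*% t(W) + matrix(b, nrow(Xs), K, byrow = TRUE))
}

.standardize <- function(m, X) {
  if (ncol(X) != ncol(m@weightMean))
    stop(sprintf("feature mismatch: model expects %d features, got %d",
                 ncol(m@weightMean), ncol(X)))
  sweep(sweep(X, 2L, m@center), 2L, m@scale, "/")
}

#' Posterior-averaged class probabilities
#'
#' Averages softmax outputs over \code{nSamples} posterior weight
#' draws; rows sum to 1.
#'
#' @param m a \linkS4class{BayesModel}.
#' @param X numeric matrix with the model's feature count.
#' @param nSamples posterior draws (default 100).
#' @param seed RNG seed for the draws.
#' @return n x K probability matrix with class column names.
#' @export
predictProba <- function(m, X, nSamples = 100L, seed = 1L) {
  stopifnot(is(m, "BayesModel"))
  Xs <- .standardize(m, X)
  set.seed(seed)
  acc <- 0
  for (s in seq_len(nSamples)) acc <- acc + .forward(m, Xs)
  P <- acc / nSamples
  colnames(P) <- m@classes
  P
}

# Per-draw soft confusions: running mean and sd over draws.
.confusionMoments <- function(m, t, nSamples, seed) {
  Xs <- .standardize(m, t@X)
  y <- as.character(t@y)
  K <- length(m@classes)
  groups <- lapply(m@classes, function(cl) which(y == cl))
  set.seed(seed)
  s1 <- matrix(0, K, K); s2 <- matrix(0, K, K)
  for (s in seq_len(nSamples)) {
    P <- .forward(m, Xs)
    cm <- t(vapply(groups, function(g) {
      if (!length(g)) return(rep(NA_real_, K))
      colMeans(P[g, , drop = FALSE])
    }, numeric(K)))
    s1 <- s1 + cm; s2 <- s2 + cm^2
  }
  mean_ <- s1 / nSamples
  sd_ <- sqrt(pmax(s2 / nSamples - mean_^2, 0))
  dimnames(mean_) <- dimnames(sd_) <- list(m@classes, m@classes)
  absent <- !vapply(groups, length, 0L)
  if (any(absent))
    warning("classes absent from the table; confusion rows flagged NA: ",
            paste(m@classes[absent], collapse = ", "))
  list(mean = mean_, sd = sd_)
}

#' Soft confusion matrix of a Bayesian classifier
#'
#' Entry (i, j) is the mean, over pixels with true label i, of the
#' posterior-averaged predicted probability of label j; rows sum to 1.
#' Classes absent from the table give NA rows with a warning.
#'
#' @param m a \linkS4class{BayesModel}.
#' @param t a labeled \linkS4class{PixelTable}.
#' @param nSamples posterior draws (default 100).
#' @param seed RNG seed.
#' @return K x K row-stochastic matrix.
#' @export
softConfusion <- function(m, t, nSamples = 100L, seed = 1L) {
  stopifnot(is(m, "BayesModel"), is(t, "PixelTable"))
  .confusionMoments(m, t, nSamples, seed)$mean
}

#' Ensemble confusion and worst-case pair scores
#'
#' Trains \code{nModels} independently seeded Bayesian classifiers,
#' computes each model's soft confusion mean and std over posterior
#' draws, and scores every ordered category pair by the maximum over
#' models of mean + 2*std — a conservative, worst-case estimate of
#' label ambiguity.
#'
#' @param t a \linkS4class{PixelTable}.
#' @param nModels ensemble size (default 10).
#' @param nSamples posterior draws per model (default 100).
#' @param seed base seed; per-model seeds are derived from it.
#' @param models optional list of pre-trained \linkS4class{BayesModel}
#'   objects (overrides training).
#' @param ... passed to \code{\link{trainBayesLogReg}}.
#' @return an \linkS4class{EnsembleConfusion}.
#' @export
ensembleConfusion <- function(t, nModels = 10L, nSamples = 100L,
                              seed = 1L, models = NULL, ...) {
  stopifnot(is(t, "PixelTable"))
  if (is.null(models)) {
    if (nModels < 1L) stop("nModels must be >= 1")
    models <- lapply(seq_len(nModels), function(i)
      trainBayesLogReg(t, seed = deriveSeed(seed, i), ...))
  }
  nModels <- length(models)
  perModel <- lapply(seq_along(models), function(i)
    .confusionMoments(models[[i]], t, nSamples,
                      seed = deriveSeed(seed, 10000L + i)))
  classes <- models[[1]]@classes
  K <- length(classes)
  score <- matrix(-Inf, K, K, dimnames = list(classes, classes))
  for (pm in perModel) score <- pmax(score, pm$mean + 2 * pm$sd)
  new("EnsembleConfusion", perModel = perModel, pairScore = score,
      classes = classes, nModels = as.integer(nModels),
      nPosteriorSamples = as.integer(nSamples))
}

#' Symmetrized worst-case pair score
#'
#' max(pairScore[i, j], pairScore[j, i]) as used for atlas edges.
#'
#' @param ec an \linkS4class{EnsembleConfusion}.
#' @return symmetric K x K matrix.
#' @export
symmetrizedPairScore <- function(ec) {
  stopifnot(is(ec, "EnsembleConfusion"))
  pmax(ec@pairScore, t(ec@pairScore))
}
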