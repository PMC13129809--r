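test_that("separable blobs are classified near-perfectly by the posterior mean", {
  tab <- blobTable(n = 400L, K = 2L, muScale = 4)
  m <- trainBayesLogReg(tab, seed = 3L)
  P <- predictProba(m, pixelFeatures(tab), nSamples = 50L, seed = 1L)
  acc <- mean(m@classes[max.col(P)] == as.character(pixelLabels(tab)))
  expect_gte(acc, 0.99)
  # posterior-mean weights correlate with maximum-likelihood weights
  y01 <- as.integer(pixelLabels(tab)) - 1L
  Xs <- scale(pixelFeatures(tab))
  ml <- suppressWarnings(glm(y01 ~ Xs, family = binomial()))
  viDiff <- m@weightMean[2, ] - m@weightMean[1, ]
  expect_gte(abs(cor(viDiff, coef(ml)[-1])), 0.9)
})

test_that("a tight prior pulls weights to zero and predictions to uniform", {
  tab <- blobTable(n = 200L, K = 2L, muScale = 4)
  m <- trainBayesLogReg(tab, priorSd = 1e-3, steps = 400L, lr = 0.01,
                        seed = 5L)
  mWide <- trainBayesLogReg(tab, priorSd = 1.0, seed = 5L)
  expect_lt(max(abs(m@weightMean)), 0.05)
  expect_lt(max(abs(m@weightMean)), 0.05 * max(abs(mWide@weightMean)))
  P <- predictProba(m, pixelFeatures(tab), nSamples = 100L, seed = 2L)
  expect_lt(max(abs(P - 0.5)), 0.05)
})

test_that("training is deterministic and validates inputs", {
  tab <- blobTable(n = 120L, K = 3L, muScale = 3)
  a <- trainBayesLogReg(tab, seed = 9L, steps = 150L)
  b <- trainBayesLogReg(tab, seed = 9L, steps = 150L)
  expect_identical(a@weightMean, b@weightMean)
  expect_identical(a@weightSd, b@weightSd)
  expect_identical(a@biasMean, b@biasMean)
  oneClass <- new("PixelTable", X = pixelFeatures(tab),
                  y = factor(rep("A", nrow(pixelFeatures(tab)))),
                  featureMz = featureMz(tab))
  expect_error(trainBayesLogReg(oneClass), "two classes")
})

test_that("posterior-averaged probabilities are row-stochastic and converge", {
  tab <- blobTable(n = 150L, K = 3L, muScale = 2)
  m <- trainBayesLogReg(tab, seed = 4L, steps = 200L)
  X <- pixelFeatures(tab)[1:20, ]
  P <- predictProba(m, X, nSamples = 25L, seed = 1L)
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  expect_error(predictProba(m, X[, 1:3]), "feature mismatch")
  # Monte-Carlo convergence: estimator spread shrinks ~ 1/sqrt(n);
  # probe an ambiguous point so posterior draws actually disagree
  mu12 <- (colMeans(pixelFeatures(tab)[pixelLabels(tab) == "1", ]) +
           colMeans(pixelFeatures(tab)[pixelLabels(tab) == "2", ])) / 2
  Xamb <- matrix(mu12, 1)
  spread <- function(ns) {
    reps <- vapply(1:25, function(s)
      predictProba(m, Xamb, nSamples = ns, seed = s)[1, 1], 0)
    sd(reps)
  }
  s1 <- spread(1L); s64 <- spread(64L)
  expect_lt(s64, s1 / 4)
  # zero-variance posterior reduces to the deterministic softmax
  m0 <- m
  m0@weightSd[] <- 1e-12
  m0@biasSd[] <- 1e-12
  Pdet <- predictProba(m0, X, nSamples = 5L, seed = 3L)
  W <- m0@weightMean
  Xs <- sweep(sweep(X, 2, m0@center), 2, m0@scale, "/")
  logits <- Xs %*% t(W) + matrix(m0@biasMean, nrow(Xs), length(m0@classes),
                                 byrow = TRUE)
  ref <- exp(logits - apply(logits, 1, max))
  ref <- ref / rowSums(ref)
  expect_equal(unname(Pdet), unname(ref), tolerance = 1e-6)
})

test_that("soft confusion approaches identity for separable data and 0.5 for twins", {
  tab <- blobTable(n = 300L, K = 3L, muScale = 4)
  m <- trainBayesLogReg(tab, seed = 6L)
  cm <- softConfusion(m, tab, nSamples = 50L, seed = 2L)
  expect_true(all(abs(rowSums(cm) - 1) < 1e-6))
  expect_true(all(diag(cm) > 0.9))
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] < 0.05))
  # two categories with identical feature distributions split ~ 50/50
  set.seed(8)
  n <- 400L
  X <- matrix(rnorm(n * 6), n, 6)
  X[1:200, 1] <- X[1:200, 1] + 5   # AB block separated from C
  y <- factor(c(rep(c("A", "B"), 100), rep("C", 200)))
  twin <- new("PixelTable", X = X, y = y, featureMz = 1:6)
  mt <- trainBayesLogReg(twin, seed = 2L)
  cmt <- softConfusion(mt, twin, nSamples = 50L, seed = 1L)
  expect_true(all(abs(cmt[c("A", "B"), c("A", "B")] - 0.5) < 0.05))
})

test_that("ensemble pair scores reduce correctly and dominate per-model means", {
  tab <- blobTable(n = 200L, K = 3L, muScale = 3)
  m <- trainBayesLogReg(tab, seed = 12L, steps = 200L)
  m0 <- m
  m0@weightSd[] <- 1e-12
  m0@biasSd[] <- 1e-12
  ec0 <- ensembleConfusion(tab, nSamples = 20L, seed = 1L,
                           models = list(m0))
  cm <- softConfusion(m0, tab, nSamples = 20L, seed = 1L)
  expect_equal(unname(pairScore(ec0)), unname(cm), tolerance = 1e-6)
  ec <- ensembleConfusion(tab, nModels = 3L, nSamples = 30L, seed = 2L,
                          steps = 200L)
  for (pm in modelConfusions(ec))
    expect_true(all(pairScore(ec) >= pm$mean - 1e-12))
  sym <- symmetrizedPairScore(ec)
  expect_true(all(abs(sym - t(sym)) < 1e-12))
})

test_that("duplicated categories attract the highest pair scores across seeds", {
  tab <- miningTableFixture("duplicates")
  for (seed in 1:2) {
    ec <- ensembleConfusion(tab, nModels = 2L, nSamples = 30L,
                            seed = seed, steps = 250L)
    sym <- symmetrizedPairScore(ec)
    diag(sym) <- -Inf
    mx <- which(sym == max(sym), arr.ind = TRUE)[1, ]
    expect_setequal(rownames(sym)[mx], c("CNUcp", "CNUcpx"))
  }
})

test_that("pair scores order planted similarity (ensemble ordering property)", {
  # 5 categories on a similarity gradient: means interpolate between a
  # shared template and category-specific directions
  set.seed(14)
  K <- 5L; D <- 12L; nPer <- 70L
  alpha <- c(0, 0.25, 0.5, 0.75, 1)   # fraction of shared template
  shared <- c(rep(3, 4), rep(0, D - 4))
  mu <- t(vapply(seq_len(K), function(k) {
    own <- rep(0, D); own[4 + k] <- 3
    alpha[k] * shared + (1 - alpha[k]) * own * 2
  }, numeric(D)))
  y <- factor(rep(paste0("C", seq_len(K)), each = nPer))
  X <- mu[as.integer(y), ] + matrix(rnorm(K * nPer * D, 0, 1.6),
                                    K * nPer, D)
  tab <- new("PixelTable", X = X, y = y, featureMz = 1:D)
  ec <- ensembleConfusion(tab, nModels = 3L, nSamples = 30L, seed = 3L,
                          steps = 250L)
  sym <- symmetrizedPairScore(ec)
  plantedSim <- -as.matrix(dist(mu))          # closer means = more similar
  ut <- upper.tri(sym)
  expect_gte(cor(sym[ut], plantedSim[ut], method = "spearman"), 0.8)
})
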