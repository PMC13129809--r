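test_that("rank-based AUC equals the exhaustive pair-count oracle", {
  set.seed(51)
  for (rep in 1:50) {
    a <- round(rnorm(30), sample(0:2, 1))   # occasional ties
    b <- round(rnorm(30), sample(0:2, 1))
    r <- pairwiseAUC(a, b)
    brute <- mean(outer(a, b, ">") + 0.5 * outer(a, b, "=="))
    expect_identical(r$auc, brute)
  }
  expect_equal(pairwiseAUC(c(3, 4, 5), c(0, 1, 2))$auc, 1)
  x <- c(1.5, 2.5, 9)
  expect_equal(pairwiseAUC(x, x)$auc, 0.5)
  expect_error(pairwiseAUC(numeric(0), 1:3), "nonempty")
})

test_that("AUC p-values track wilcox.test for large and small samples", {
  set.seed(52)
  # large-sample normal approximation with ties
  a <- round(rnorm(40, 0.3), 1); b <- round(rnorm(35), 1)
  p <- pairwiseAUC(a, b)$p
  pw <- suppressWarnings(wilcox.test(a, b)$p.value)
  expect_equal(p, pw, tolerance = 0.02)
  # small untied samples use exact enumeration
  a2 <- c(0.1, 0.9, 1.7, 2.2); b2 <- c(0.4, 1.1, 1.3)
  expect_equal(pairwiseAUC(a2, b2)$p,
               wilcox.test(a2, b2, exact = TRUE)$p.value)
})

test_that("the IRLS ridge solver matches glmnet coefficients", {
  skip_if_not_installed("glmnet")
  set.seed(53)
  n <- 300L; D <- 20L
  X <- scale(matrix(rnorm(n * D), n, D))
  y <- rbinom(n, 1, plogis(X[, 1] * 2 - X[, 2]))
  lam <- 0.7
  B <- msiatlas:::.ridgeLogregOVR(X, cbind(y), lam)
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = lam / n, standardize = FALSE,
                      thresh = 1e-12, intercept = TRUE)
  cg <- as.numeric(coef(g, s = lam / n))
  expect_gt(cor(B[-1, 1], cg[-1]), 0.9999)
  expect_lt(max(abs(B[-1, 1] - cg[-1])), 1e-3)
})

test_that("stability selection recovers exclusive markers and respects the boundary", {
  tab <- markerTable(K = 4L, nPer = 60L, nNull = 30L, fold = 8)
  for (seed in 1:2) {
    st <- stabilitySelect(tab, nModels = 50L, nNoise = 10L, seed = seed)
    sel <- selectedFeatures(st)
    for (k in 1:4) {
      expect_true(k %in% sel[[paste0("C", k)]])
      expect_gte(selectionFrequency(st)[paste0("C", k), k], 0.8)
    }
  }
  # retention boundary: frequency >= retainFreq keeps, below drops
  st <- stabilitySelect(tab, nModels = 50L, nNoise = 10L, seed = 1L)
  fr <- selectionFrequency(st)
  for (cat in rownames(fr)) {
    keep <- selectedFeatures(st)[[cat]]
    expect_true(all(fr[cat, keep] >= 0.8))
    expect_true(all(fr[cat, setdiff(seq_len(ncol(fr)), keep)] < 0.8))
  }
})

test_that("pure-noise tables yield (almost) no retentions", {
  set.seed(54)
  falseRet <- numeric(6)
  for (s in seq_along(falseRet)) {
    n <- 160L; D <- 25L
    X <- matrix(rnorm(n * D), n, D)
    y <- factor(rep(c("A", "B", "C", "D"), each = 40L))
    tab <- new("PixelTable", X = X, y = y, featureMz = seq_len(D))
    st <- stabilitySelect(tab, nModels = 40L, nNoise = 10L, seed = s)
    falseRet[s] <- mean(lengths(selectedFeatures(st)))
  }
  expect_lte(mean(falseRet), 0.1)
})

test_that("with no noise columns the rule degenerates to positive-weight frequency", {
  tab <- markerTable(K = 3L, nPer = 40L, nNull = 10L, fold = 6)
  st <- stabilitySelect(tab, nModels = 25L, nNoise = 0L, seed = 2L)
  expect_true(all(is.na(st@noiseThresholds) | st@noiseThresholds == 0))
  # markers still recovered; frequencies are fractions of models with
  # positive marker weight, which is 1 for strong markers
  for (k in 1:3)
    expect_gte(selectionFrequency(st)[paste0("C", k), k], 0.8)
})

test_that("mPAUC ranks planted markers first and handles shared features", {
  ph <- phantomFixture("separable8")
  tab <- miningTableFixture("separable8")
  mp <- mpaucScores(tab, seed = 1L)
  tb <- associationTable(mp)
  for (cn in names(ph$truth@markers)) {
    f <- which.min(abs(featureMz(tab) - ph$truth@markers[[cn]]))
    top <- tb[tb$feature == f & tb$round == 2L & tb$rank == 1L, ]
    expect_equal(top$category, cn)
  }
  # identically distributed feature scores zero everywhere
  nullTab <- new("PixelTable",
                 X = cbind(rep(1.25, nrow(pixelFeatures(tab)))),
                 y = pixelLabels(tab), featureMz = 999)
  mpNull <- mpaucScores(nullTab, seed = 1L)
  expect_true(all(associationTable(mpNull)$score == 0))
  # feature planted equally in two categories: both in the round-1 top-k
  phIdx <- phantomFixture("index")
  tabIdx <- miningTableFixture("index")
  f770 <- which.min(abs(featureMz(tabIdx) - 770.3))
  expect_lt(abs(featureMz(tabIdx)[f770] - 770.3), 0.05)
  mpIdx <- mpaucScores(tabIdx, k = 3L, seed = 1L)
  tbIdx <- associationTable(mpIdx)
  r2cats <- tbIdx$category[tbIdx$feature == f770 & tbIdx$round == 2L]
  expect_true(all(c("CTXL2", "CNUcp") %in% r2cats))
})

test_that("round 2 only rescores categories that survived round 1", {
  tab <- miningTableFixture("separable8")
  mp <- mpaucScores(tab, k = 3L, seed = 1L)
  tb <- associationTable(mp)
  for (f in unique(tb$feature)) {
    r1 <- tb[tb$feature == f & tb$round == 1L, ]
    r2 <- tb[tb$feature == f & tb$round == 2L, ]
    topk <- r1$category[order(-r1$score)][1:3]
    expect_true(all(r2$category %in% topk))
  }
})

test_that("shared-feature summaries count planted sharing symmetrically", {
  tab <- miningTableFixture("plaque")
  mp <- mpaucScores(tab, seed = 1L)
  counts <- sharedFeatureSummary(mp, "PLQ")
  expect_equal(names(counts)[1], "WMcc")
  expect_gte(counts[["WMcc"]], 2L)
  expect_gt(counts[["WMcc"]], counts[["CTXL2"]])
  # symmetry of the intersection count
  countsW <- sharedFeatureSummary(mp, "WMcc")
  expect_equal(countsW[["PLQ"]], counts[["WMcc"]])
  expect_error(sharedFeatureSummary(mp, "nope"), "unknown")
  # gross-region set summary for Venn-style reporting
  it <- indexTable(phantomFixture("plaque")$truth@mask)
  gm <- setNames(it$gross, it$category)
  cg <- sharedFeatureSummary(mp, "PLQ", grossMap = gm)
  expect_true(!is.null(attr(cg, "grossSets")))
  expect_true("WM" %in% names(attr(cg, "grossSets")))
})

test_that("selection methods diverge on shared features but agree on exclusives", {
  # a feature strong in the focal category but stronger elsewhere can be
  # retained by stability selection while mPAUC ranks the other category
  # higher; the intersection keeps only exclusive features
  set.seed(55)
  nPer <- 80L
  y <- factor(rep(c("F", "G", "H"), each = nPer))
  X <- matrix(rexp(3 * nPer * 6), 3 * nPer, 6)
  X[y == "F", 1] <- X[y == "F", 1] + 8    # exclusive to F
  X[y == "F", 2] <- X[y == "F", 2] + 8    # shared, stronger in G
  X[y == "G", 2] <- X[y == "G", 2] + 12
  X[y == "G", 3] <- X[y == "G", 3] + 8    # exclusive to G
  X[y == "H", 4] <- X[y == "H", 4] + 8
  tab <- new("PixelTable", X = X, y = y, featureMz = 1:6)
  st <- stabilitySelect(tab, nModels = 60L, nNoise = 3L, seed = 3L)
  mp <- mpaucScores(tab, assocRank = 1L, seed = 3L)
  # stability keeps the shared feature 2 for F (still predictive)
  expect_true(2L %in% selectedFeatures(st)$F)
  # mPAUC rank-1 for feature 2 is G, not F
  tb <- associationTable(mp)
  expect_equal(tb$category[tb$feature == 2L & tb$round == 2L &
                           tb$rank == 1L], "G")
  # intersection of both methods for F holds only F-exclusive features
  stF <- featureMz(st)[selectedFeatures(st)$F]
  mpF <- mp@topPerCategory$F
  expect_equal(intersect(stF, mpF), 1)
})

test_that("putative annotation matches within tolerance and flags ambiguity", {
  ref <- data.frame(
    name = c("PI 38:4", "PS 40:6", "twinA", "twinB"),
    monoisotopic_mz = c(886.5572, 834.5261, 800.5100, 800.5140),
    class = c("PI", "PS", "PC", "PC"))
  # exact adduct mass gives delta 0
  q <- 886.5572 - 1.00728
  out <- annotateMz(q, ref)
  expect_equal(out$name, "PI 38:4")
  expect_equal(out$delta, 0)
  expect_false(out$ambiguous)
  # 0.011 Da away: no match
  out2 <- annotateMz(q + 0.011, ref)
  expect_true(is.na(out2$name))
  # query between two references 0.004 Da apart: both reported, ambiguous
  q3 <- (800.5100 + 800.5140) / 2 - 1.00728
  out3 <- annotateMz(q3, ref)
  expect_equal(nrow(out3), 2L)
  expect_true(all(out3$ambiguous))
  expect_true(all(abs(out3$delta) <= 0.01))
  expect_error(annotateMz(700, ref[0, ]), "reference")
  # the bundled synthetic reference table works through the same path
  bundled <- read.csv(system.file("extdata",
                                  "synthetic_lipid_reference.csv",
                                  package = "msiatlas"))
  hit <- annotateMz(767.5465 - 1.00728, bundled)
  expect_equal(hit$name, "synthetic PE 38:4")
  expect_equal(hit$class, "PE")
})
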