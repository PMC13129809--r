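suppressMessages(library(SummarizedExperiment))

# Memoized phantom fixtures: each preset is generated once per test run.
.fixtureCache <- new.env(parent = emptyenv())

phantomFixture <- function(preset, seed = 1L) {
  key <- paste0(preset, "_", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generatePhantom(standardFixtures(seed)[[preset]])
  .fixtureCache[[key]]
}

ticCubeFixture <- function(preset, seed = 1L, binsPerMz = 20L) {
  key <- paste0("cube_", preset, "_", seed, "_", binsPerMz)
  if (is.null(.fixtureCache[[key]])) {
    ph <- phantomFixture(preset, seed)
    .fixtureCache[[key]] <-
      suppressWarnings(ticNormalize(binSpectra(ph$dataset, binsPerMz)))
  }
  .fixtureCache[[key]]
}

miningTableFixture <- function(preset, seed = 1L) {
  key <- paste0("tab_", preset, "_", seed)
  if (is.null(.fixtureCache[[key]])) {
    ph <- phantomFixture(preset, seed)
    .fixtureCache[[key]] <- pixelTable(
      ticCubeFixture(preset, seed), ph$truth@mask,
      maxFeatures = 60L, includeBackground = FALSE)
  }
  .fixtureCache[[key]]
}

# Small handmade SpectraDataset
tinyDataset <- function() {
  SpectraDataset(
    coords = rbind(c(0, 0), c(0, 1)),
    spectra = list(cbind(c(500.02, 500.03), c(10, 5)),
                   cbind(720.4, 3)),
    mzRange = c(300, 1350))
}

# Gaussian blob PixelTable: K classes, informative means muScale apart
blobTable <- function(n = 400L, K = 2L, D = 10L, muScale = 4,
                      seed = 11L) {
  set.seed(seed)
  y <- factor(rep(seq_len(K), length.out = n))
  mu <- matrix(0, K, D)
  for (k in seq_len(K)) mu[k, k] <- muScale
  X <- mu[as.integer(y), ] + matrix(rnorm(n * D), n, D)
  new("PixelTable", X = X, y = y, featureMz = 700 + seq_len(D))
}

# Marker phantom feature table: one exclusive strong marker per
# category plus null features (scaled-down stability example).
markerTable <- function(K = 4L, nPer = 60L, nNull = 30L, fold = 8,
                        seed = 5L) {
  set.seed(seed)
  n <- K * nPer
  y <- factor(rep(paste0("C", seq_len(K)), each = nPer))
  D <- K + nNull
  X <- matrix(rexp(n * D, rate = 1), n, D)
  for (k in seq_len(K))
    X[as.integer(y) == k, k] <- X[as.integer(y) == k, k] + fold
  new("PixelTable", X = X, y = y, featureMz = 800 + seq_len(D) * 0.1)
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
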