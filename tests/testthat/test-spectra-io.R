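test_that("nearest-bin quantization puts peaks in the right bins", {
  ds <- tinyDataset()
  cube <- binSpectra(ds, 20L)
  expect_equal(binWidth(cube), 0.05)
  expect_equal(nrow(cube), round((1350 - 300) * 20) + 1)
  ctr <- binCenters(cube)
  # 500.02 is nearer 500.00 than 500.05
  b500 <- which(abs(ctr - 500.00) < 1e-9)
  b50005 <- which(abs(ctr - 500.05) < 1e-9)
  A <- assay(cube, "intensity")
  expect_equal(unname(A[b500, 1]), 10)
  expect_equal(unname(A[b50005, 1]), 5)
  # empty-ish pixel: single peak lands in one bin, everything else zero
  expect_equal(sum(A[, 2] > 0), 1L)
  # exact midpoint resolves to the lower-index bin
  dsMid <- SpectraDataset(rbind(c(0, 0)), list(cbind(500.025, 7)),
                          c(300, 1350))
  Am <- assay(binSpectra(dsMid, 20L), "intensity")
  expect_equal(unname(Am[b500, 1]), 7)
  expect_equal(unname(Am[b50005, 1]), 0)
})

test_that("binning conserves in-range intensity and matches an argmin oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 12L
    coords <- cbind(rep(0:3, 3), rep(0:2, each = 4))
    spectra <- lapply(seq_len(n), function(i) {
      k <- rpois(1, 8)
      cbind(runif(k, 290, 1360), rexp(k, 1 / 10))
    })
    ds <- SpectraDataset(coords, spectra, c(300, 1350))
    cube <- suppressMessages(binSpectra(ds, 20L))
    inRange <- sum(vapply(spectraList(ds), function(sp)
      sum(sp[sp[, 1] >= 300 & sp[, 1] <= 1350, 2]), 0))
    expect_lt(abs(sum(assay(cube, "intensity")) - inRange),
              1e-9 * max(inRange, 1))
    # independent argmin-over-centers oracle
    ctr <- binCenters(cube)
    oracle <- matrix(0, nrow(cube), ncol(cube))
    for (i in seq_len(n)) {
      sp <- spectraList(ds)[[i]]
      for (r in seq_len(nrow(sp))) {
        if (sp[r, 1] < 300 || sp[r, 1] > 1350) next
        b <- which.min(abs(ctr - sp[r, 1]))
        oracle[b, i] <- oracle[b, i] + sp[r, 2]
      }
    }
    expect_equal(unname(assay(cube, "intensity")), oracle)
  }
})

test_that("TIC normalization makes nonzero pixels sum to one and flags zero pixels", {
  ds <- SpectraDataset(
    rbind(c(0, 0), c(0, 1), c(1, 0)),
    list(cbind(c(400.0, 500.0, 600.0), c(2, 2, 4)),
         matrix(numeric(0), 0, 2),
         cbind(700.0, 5)),
    c(300, 1350))
  cube <- binSpectra(ds, 20L)
  expect_warning(ticNormalize(cube), "zero total ion current")
  tic <- suppressWarnings(ticNormalize(cube))
  A <- assay(tic, "intensity")
  expect_equal(sort(A[A[, 1] > 0, 1]), c(0.25, 0.25, 0.5))
  expect_equal(sum(A[, 2]), 0)
  expect_equal(zeroTicMask(tic), c(FALSE, TRUE, FALSE))
  tots <- colSums(A)
  expect_true(all(abs(tots[tots > 0] - 1) < 1e-12))
  expect_error(ticNormalize(tic), "already")
})

test_that("binSpectra rejects bad inputs", {
  ds <- tinyDataset()
  expect_error(binSpectra(ds, 0), "positive")
  empty <- new("SpectraDataset",
               coords = matrix(integer(0), 0, 2), spectra = list(),
               mzRange = c(300, 1350), pixelSize = 20)
  expect_error(binSpectra(empty, 20), "empty")
})

test_that("imzML round-trips a dataset written by the package", {
  ds <- tinyDataset()
  path <- file.path(withr::local_tempdir(), "tiny.imzML")
  writeImzML(ds, path)
  back <- readImzML(path)
  expect_equal(pixelCoords(back), pixelCoords(ds))
  expect_equal(spectraList(back), spectraList(ds))
  expect_equal(mzRange(back), mzRange(ds))
})

test_that("imzML reader rejects duplicate pixel positions and missing ibd", {
  ds <- tinyDataset()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "dup.imzML")
  writeImzML(ds, path)
  xml <- readLines(path)
  # duplicate the second pixel's position onto the first
  xml <- sub('name="position x" value="2"', 'name="position x" value="1"',
             xml)
  writeLines(xml, path)
  expect_error(readImzML(path), "listed more than once")
  path2 <- file.path(dir, "orphan.imzML")
  writeImzML(ds, path2)
  unlink(sub("imzML$", "ibd", path2))
  expect_error(readImzML(path2), "companion")
})

test_that("a phantom written as imzML reads back with generator truth", {
  ph <- phantomFixture("twin_peaks")
  path <- file.path(withr::local_tempdir(), "phantom.imzML")
  writeImzML(ph$dataset, path)
  back <- readImzML(path)
  expect_equal(length(spectraList(back)), 24L * 24L)
  expect_equal(mzRange(back), c(700, 701))
  expect_equal(spectraList(back), spectraList(ph$dataset))
})

test_that("the package reader agrees with an independent imzML writer", {
  dir <- withr::local_tempdir()
  py <- file.path(dir, "write.py")
  out <- file.path(dir, "ref.imzML")
  writeLines(c(
    "from pyimzml.ImzMLWriter import ImzMLWriter",
    sprintf("w = ImzMLWriter(%s, mode='processed')", deparse(out)),
    "w.addSpectrum([500.25, 600.5], [3.0, 7.0], (1, 1, 1))",
    "w.addSpectrum([510.75], [2.5], (2, 1, 1))",
    "w.close()"), py)
  status <- system2("python", py, stdout = TRUE, stderr = TRUE)
  ds <- readImzML(out)
  expect_equal(nrow(pixelCoords(ds)), 2L)
  sp <- spectraList(ds)
  expect_equal(unname(sp[[1]][, "mz"]), c(500.25, 600.5),
               tolerance = 1e-9)
  expect_equal(unname(sp[[1]][, "intensity"]), c(3, 7), tolerance = 1e-6)
  expect_equal(unname(sp[[2]][, "mz"]), 510.75, tolerance = 1e-9)
  # x -> col, y -> row, 0-based
  expect_equal(unname(pixelCoords(ds)), rbind(c(0L, 0L), c(0L, 1L)))
})

test_that("the internal cube container round-trips losslessly", {
  cube <- ticCubeFixture("twin_peaks")
  path <- file.path(withr::local_tempdir(), "cube.rds")
  saveCube(cube, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- readCube(path)
  expect_identical(assay(back, "intensity"), assay(cube, "intensity"))
  expect_identical(binCenters(back), binCenters(cube))
  expect_identical(S4Vectors::metadata(back)$normalized, "TIC")
})

test_that("pixelTable filters features and small categories as documented", {
  ph <- phantomFixture("separable8")
  cube <- ticCubeFixture("separable8")
  tab <- pixelTable(cube, ph$truth@mask, maxFeatures = 25L)
  expect_equal(ncol(pixelFeatures(tab)), 25L)
  expect_true(all(colSums(pixelFeatures(tab)) > 0))
  tabNoBg <- pixelTable(cube, ph$truth@mask, includeBackground = FALSE)
  expect_false("BG" %in% levels(pixelLabels(tabNoBg)))
  expect_warning(
    pixelTable(cube, ph$truth@mask, minPixels = 1000L),
    "dropping categories")
})
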