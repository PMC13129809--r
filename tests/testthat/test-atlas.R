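test_that("category profiles equal brute-force per-label means", {
  ph <- phantomFixture("twin_peaks")
  cube <- ticCubeFixture("twin_peaks")
  prof <- suppressWarnings(categoryProfiles(cube, ph$truth@mask))
  A <- assay(cube, "intensity")
  lab <- labelMatrix(ph$truth@mask)
  it <- indexTable(ph$truth@mask)
  coords <- cbind(colData(cube)$row, colData(cube)$col)
  catOf <- it$category[match(lab[cbind(coords[, 1] + 1L, coords[, 2] + 1L)],
                             it$index)]
  for (cn in prof@categories) {
    oracle <- rowMeans(A[, catOf == cn, drop = FALSE])
    expect_equal(unname(profileMatrix(prof)[prof@categories == cn, ]),
                 unname(oracle))
  }
  # TIC rows sum to at most 1 (zero-TIC pixels pull below)
  expect_true(all(rowSums(profileMatrix(prof)) <= 1 + 1e-9))
})

test_that("atlas edges respect threshold, gross rule and node sizing", {
  tab <- miningTableFixture("duplicates")
  ph <- phantomFixture("duplicates")
  ec <- ensembleConfusion(tab, nModels = 2L, nSamples = 25L, seed = 7L,
                          steps = 250L)
  cube <- ticCubeFixture("duplicates")
  prof0 <- suppressWarnings(
    categoryProfiles(cube, ph$truth@mask, includeBackground = FALSE))
  keep <- match(ec@classes, prof0@categories)
  prof <- new("CategoryProfile",
              profile = profileMatrix(prof0)[keep, , drop = FALSE],
              categories = ec@classes, featureMz = prof0@featureMz,
              normalization = prof0@normalization)
  it <- indexTable(ph$truth@mask)
  gm <- setNames(it$gross, it$category)
  g <- buildAtlas(prof, ec, gm, seed = 5L)
  expect_s4_class(g, "AtlasGraph")
  ed <- atlasEdges(g)
  expect_true(all(ed$weight >= g@edgeThreshold))
  nd <- atlasNodes(g)
  same <- gm[ed$from] == gm[ed$to]
  expect_equal(unname(ed$kind == "intra"), unname(same))
  expect_equal(nd$size, 1 + nd$degree)
  # planted duplicates are connected and the edge is intra-gross
  dup <- ed[(ed$from == "CNUcp" & ed$to == "CNUcpx") |
            (ed$from == "CNUcpx" & ed$to == "CNUcp"), ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$kind, "intra")
  # edge kinds partition the edges
  expect_equal(sum(ed$kind == "intra") + sum(ed$kind == "inter"), nrow(ed))
  # threshold above the maximum score removes all edges
  gNone <- buildAtlas(prof, ec, gm, edgeThreshold = 2, seed = 5L)
  expect_equal(nrow(atlasEdges(gNone)), 0L)
  expect_true(all(atlasNodes(gNone)$size == 1))
  # identical inputs give identical graphs
  g2 <- buildAtlas(prof, ec, gm, seed = 5L)
  expect_identical(atlasNodes(g), atlasNodes(g2))
  expect_identical(atlasEdges(g), atlasEdges(g2))
  # mismatched category sets error
  profBad <- new("CategoryProfile",
                 profile = profileMatrix(prof)[1:5, ],
                 categories = prof@categories[1:5],
                 featureMz = prof@featureMz, normalization = "TIC")
  expect_error(buildAtlas(profBad, ec, gm), "differ")

  # flagging: the duplicate pair ranks first
  fl <- flagAnnotationIssues(g)
  expect_gt(nrow(fl), 0L)
  expect_setequal(unlist(fl[1, c("from", "to")]), c("CNUcp", "CNUcpx"))
  # flags are a subset of edges
  key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to))
  expect_true(all(key(fl) %in% key(ed)))
  expect_equal(nrow(flagAnnotationIssues(gNone)), 0L)

  # model atlas shares the node set and puts duplicates close
  models <- lapply(1:3, function(i)
    trainBayesLogReg(tab, seed = i, steps = 400L))
  gm2 <- modelAtlas(models, ec, gm, seed = 5L)
  expect_setequal(atlasNodes(gm2)$category, atlasNodes(g)$category)
  # duplicate weight vectors are closer (cosine) than to any third category
  W <- Reduce(`+`, lapply(models, function(m) m@weightMean)) /
    length(models)
  rownames(W) <- models[[1]]@classes
  Wn <- W / sqrt(rowSums(W^2))
  cosd <- 1 - Wn %*% t(Wn)
  third <- setdiff(rownames(W), c("CNUcp", "CNUcpx"))
  expect_lt(cosd["CNUcp", "CNUcpx"],
            min(cosd[c("CNUcp", "CNUcpx"), third]))
  # and their embedding distance sits among the smallest pairwise ones
  xy <- as.matrix(atlasNodes(gm2)[, c("x", "y")])
  rownames(xy) <- atlasNodes(gm2)$category
  dm <- as.matrix(dist(xy))
  dupDist <- dm["CNUcp", "CNUcpx"]
  expect_lte(mean(dm[upper.tri(dm)] <= dupDist), 0.3)
  gm3 <- modelAtlas(models, ec, gm, seed = 5L)
  expect_identical(atlasNodes(gm2), atlasNodes(gm3))
})

test_that("within-gross embedding distances undercut between-gross distances", {
  ph <- phantomFixture("separable8")
  cube <- ticCubeFixture("separable8")
  prof <- suppressWarnings(
    categoryProfiles(cube, ph$truth@mask, includeBackground = FALSE))
  it <- indexTable(ph$truth@mask)
  gm <- setNames(it$gross, it$category)
  for (seed in 1:5) {
    xy <- msiatlas:::.embed2d(profileMatrix(prof), seed)
    rownames(xy) <- prof@categories
    dm <- as.matrix(dist(xy))
    gr <- gm[prof@categories]
    same <- outer(gr, gr, "==") & upper.tri(dm)
    diff_ <- outer(gr, gr, "!=") & upper.tri(dm)
    expect_lt(mean(dm[same]), mean(dm[diff_]))
  }
})

test_that("cohort comparison recovers planted abundance differences", {
  fx <- standardFixtures(3L)
  specA <- fx$separable8
  phA <- generatePhantom(specA)
  # cohort B: one feature's abundance doubled in one category
  specB <- specA
  sig <- specB@signatures$WMcc
  sig$abundance[sig$mz == 760.1] <- sig$abundance[sig$mz == 760.1] * 2
  specB@signatures$WMcc <- sig
  specB@seed <- 17L
  phB <- generatePhantom(specB)
  cubeA <- binSpectra(phA$dataset, 20L)
  cubeB <- binSpectra(phB$dataset, 20L)
  tabA <- pixelTable(suppressWarnings(ticNormalize(cubeA)),
                     phA$truth@mask, maxFeatures = 40L)
  models <- lapply(1:3, function(i)
    trainBayesLogReg(tabA, seed = i, steps = 250L))
  res <- suppressWarnings(cohortCompare(
    list(B = list(cubeB), A = list(cubeA)),
    models, featureMz(tabA)))
  d <- res$difference
  f760 <- which.min(abs(featureMz(tabA) - 760.1))
  expect_equal(unname(which(d == max(d, na.rm = TRUE), arr.ind = TRUE)[1, ]),
               c(which(rownames(d) == "WMcc"), f760))
  # null comparison: same generator, different seeds, differences small
  specC <- specA; specC@seed <- 23L
  phC <- generatePhantom(specC)
  cubeC <- binSpectra(phC$dataset, 20L)
  resNull <- suppressWarnings(cohortCompare(
    list(A = list(cubeA), C = list(cubeC)), models, featureMz(tabA)))
  sel <- !is.na(resNull$difference)
  rel <- abs(resNull$difference[sel]) /
    pmax(abs(res$profiles$A@profile[sel]), 1)
  expect_lt(median(rel), 0.2)
  # majority vote with one model equals that model's argmax
  X1 <- pixelFeatures(tabA)[1:50, ]
  mv <- majorityVote(models[1], X1)
  P <- predictProba(models[[1]], X1, nSamples = 1L, seed = 1L)
  m0 <- models[[1]]; m0@weightSd[] <- 1e-12; m0@biasSd[] <- 1e-12
  Pd <- predictProba(m0, X1, nSamples = 1L, seed = 1L)
  expect_equal(mv, m0@classes[max.col(Pd)])
})

test_that("atlas graphs serialize to JSON and GraphML and back", {
  nodes <- data.frame(category = c("CTXa", "CTXb", "WMc"),
                      gross = c("CTX", "CTX", "WM"),
                      x = c(0, 1, 3), y = c(0, 0.5, 2),
                      degree = c(1L, 1L, 0L), size = c(2, 2, 1))
  edges <- data.frame(from = "CTXa", to = "CTXb", weight = 0.5,
                      kind = "intra")
  g <- new("AtlasGraph", nodes = nodes, edges = edges,
           edgeThreshold = 0.3, seed = 1L)
  dir <- withr::local_tempdir()
  writeAtlasGraph(g, file.path(dir, "g.json"))
  back <- readAtlasGraph(file.path(dir, "g.json"))
  expect_equal(atlasNodes(back), nodes)
  expect_equal(atlasEdges(back), edges)
  writeAtlasGraphML(g, file.path(dir, "g.graphml"))
  x <- xml2::read_xml(file.path(dir, "g.graphml"))
  xml2::xml_ns_strip(x)
  expect_length(xml2::xml_find_all(x, ".//node"), 3L)
  expect_length(xml2::xml_find_all(x, ".//edge"), 1L)
})
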