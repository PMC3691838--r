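test_that("scene generation is deterministic and leaves the RNG alone", {
  set.seed(123); before <- .Random.seed
  s1 <- generateScene(seed = 42, nTrees = 3, extentUm = 200)
  expect_identical(.Random.seed, before)
  s2 <- generateScene(seed = 42, nTrees = 3, extentUm = 200)
  expect_identical(s1@fibers, s2@fibers)
  expect_identical(graphEdges(s1), graphEdges(s2))
  i1 <- renderScene(s1, 192); i2 <- renderScene(s2, 192)
  expect_identical(intensities(i1), intensities(i2))
  s3 <- generateScene(seed = 43, nTrees = 3, extentUm = 200)
  expect_false(identical(graphEdges(s1), graphEdges(s3)))
})

test_that("degenerate scene parameters are caught and the empty scene is all zero", {
  expect_error(generateScene(nTrees = -1), "nTrees")
  expect_error(generateScene(branchProb = 1.5), "probability")
  expect_error(generateScene(extentUm = 0), "positive")

  empty <- generateScene(nTrees = 0, seed = 1)
  tm <- as.data.frame(truthMetrics(empty))
  expect_true(all(tm[, 1:9] == 0))
  img <- renderScene(empty, 64)
  np <- empty@noiseParams
  expect_true(all(abs(intensities(img) - np$background) <
                    5 * (np$additiveSd + 1e-9) + 1))
  quiet <- empty
  quiet@noiseParams <- list(background = 0.15, additiveSd = 0,
                            speckleSd = 0, blurSigmaPx = 0)
  expect_equal(unique(as.vector(intensities(renderScene(quiet, 64)))), 0.15)
})

test_that("a single straight fibre yields the forced border-to-border topology", {
  sc <- generateScene(nTrees = 1, branchProb = 0, tortuosity = 0, seed = 5)
  n <- graphNodes(sc); e <- graphEdges(sc)
  expect_equal(nrow(e), 1)
  expect_equal(sum(n$kind == "branch"), 0)
  expect_true(all(n$kind %in% c("border", "endpoint")))
  expect_gte(sum(n$kind == "border"), 1)  # entry is always on the border
})

test_that("truth total length equals direct summation over the stored polylines", {
  sc <- generateScene(nTrees = 5, branchProb = 0.02, seed = 7)
  direct <- sum(vapply(sc@fibers, function(f) {
    p <- f$points
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1)))
  tm <- truthMetrics(sc)
  expect_equal(tm@totalFibreLengthUm, direct, tolerance = 1e-12)
  expect_equal(sum(graphEdges(sc)$lengthUm), direct, tolerance = 1e-12)
})

test_that("truth density identity NFD x area = total length holds exactly", {
  for (s in c(2, 9, 31)) {
    tm <- truthMetrics(generateScene(seed = s, nTrees = 4, extentUm = 300))
    expect_equal(tm@nerveFibreDensity * tm@areaMm2,
                 tm@totalFibreLengthUm / 1000, tolerance = 1e-12)
  }
})

test_that("noiseless render puts the brightest pixels on the centerline", {
  sc <- makeStraightScene()
  img <- intensities(renderScene(sc, 384, noiseless = TRUE))
  peakRows <- apply(img[, 50:334], 2, which.max)
  # centerline y = 200 um -> row 192/193 at 384 px
  expect_true(all(abs(peakRows - 192.5) <= 1.5))
})

test_that("Y-scene truth metrics give the forced counts", {
  tm <- as.data.frame(truthMetrics(makeYScene()))
  expect_equal(tm$total_fibre_length_um, 300)
  expect_equal(tm$single_nerve_fibres, 3)
  expect_equal(tm$branches, 1)
  expect_equal(tm$nerve_fibre_components, 1)
  expect_equal(tm$connectivity_points, 0)
  expect_equal(tm$average_single_fibre_length_um, 100)
})

test_that("truth tables round-trip to delimited text", {
  sc <- generateScene(seed = 3, nTrees = 2, extentUm = 200)
  d <- withr::local_tempdir()
  paths <- writeTruthTables(sc, d)
  expect_true(all(file.exists(paths)))
  nodes <- read.csv(paths[1])
  expect_equal(nrow(nodes), nrow(graphNodes(sc)))
})
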