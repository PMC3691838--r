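test_that("empty inputs give all-zero metrics", {
  blank <- FiberMask(matrix(FALSE, 96, 96), 100, 100)
  m <- as.data.frame(quantifyImage(blank, snpConfig(maskPassthrough = TRUE)))
  expect_true(all(m[, 1:9] == 0))
  expect_equal(m$area_mm2, 0.01)
})

test_that("the worked example reproduces the printed density", {
  # total fibre length 1578 um in a 400 x 400 um field
  expect_equal(roundHalfAway(fibreDensity(1578, 0.16), 3), 9.863)
  expect_equal(fibreDensity(400, 0.16), 2.5)
})

test_that("the density identity holds to 1e-12 and the length ratio is bounded", {
  for (s in c(2, 14)) {
    sc <- generateScene(seed = s, nTrees = 3, extentUm = 250)
    m <- quantifyImage(rasterizeTruthMask(sc, 240),
                       snpConfig(maskPassthrough = TRUE))
    expect_equal(m@nerveFibreDensity * m@areaMm2,
                 m@totalFibreLengthUm / 1000, tolerance = 1e-12)
    ps <- 250 / 240
    ratio <- m@totalFibreLengthUm / m@skeletonPixels
    expect_gte(ratio, ps * 0.999)
    expect_lte(ratio, ps * sqrt(2) * 1.001)
    expect_lte(m@skeletonPixels, m@componentPixels)
  }
})

test_that("normalisation to 1 mm^2 scales counts, keeps intensive values, rejects repeats", {
  raw <- SNPMetrics(componentPixels = 1000, nerveFibreComponents = 4,
                    skeletonPixels = 300, singleNerveFibres = 19,
                    totalFibreLengthUm = 1578,
                    averageSingleFibreLengthUm = 1578 / 19,
                    nerveFibreDensity = fibreDensity(1578, 0.16),
                    connectivityPoints = 6, branches = 8, areaMm2 = 0.16)
  nm <- normalizePerMm2(raw)
  expect_equal(nm@singleNerveFibres, 118.75)   # 19 fibres in 0.16 mm^2
  expect_equal(nm@nerveFibreDensity, raw@nerveFibreDensity)
  expect_equal(nm@averageSingleFibreLengthUm, raw@averageSingleFibreLengthUm)
  expect_equal(nm@totalFibreLengthUm, 1578 / 0.16)
  expect_true(nm@normalised)
  expect_error(normalizePerMm2(nm), "already")

  unit <- raw; unit@areaMm2 <- 1
  n1 <- normalizePerMm2(unit)
  expect_equal(n1@singleNerveFibres, unit@singleNerveFibres)
})

test_that("Y-scene quantification matches the forced topology exactly", {
  sc <- makeYScene()
  m <- as.data.frame(quantifyImage(rasterizeTruthMask(sc),
                                   snpConfig(maskPassthrough = TRUE,
                                             pruneUm = 0)))
  expect_equal(m$single_nerve_fibres, 3)
  expect_equal(m$branches, 1)
  expect_equal(m$nerve_fibre_components, 1)
  expect_equal(m$connectivity_points, 0)
})

test_that("quantifyImage is deterministic and reporting rounds to 3 dp half away", {
  sc <- generateScene(seed = 6, nTrees = 2, extentUm = 200)
  img <- renderScene(sc, 192)
  m1 <- as.data.frame(quantifyImage(img))
  m2 <- as.data.frame(quantifyImage(img))
  expect_identical(m1, m2)
  r <- reportMetrics(quantifyImage(img))
  expect_equal(r$nerve_fibre_density_mm_per_mm2,
               roundHalfAway(m1$nerve_fibre_density_mm_per_mm2, 3))

  f <- withr::local_tempfile(fileext = ".csv")
  writeMetricsTable(quantifyImage(img), f, ids = "scene6")
  tab <- read.csv(f)
  expect_true(all(c("image", "component_pixels", "branches") %in%
                  names(tab)))
})

test_that("geometry mismatches between mask and graph are rejected", {
  sc <- generateScene(seed = 6, nTrees = 2, extentUm = 200)
  mask <- rasterizeTruthMask(sc, 192)
  g <- buildGraph(skeletonize(mask))
  wrong <- FiberMask(maskMatrix(mask), widthUm = 100, heightUm = 100)
  expect_error(computeMetrics(wrong, g), "mismatch")
})
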