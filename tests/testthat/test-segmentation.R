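test_that("contrast normalisation removes additive offsets and flags constants", {
  const <- ConfocalImage(matrix(0.4, 64, 64), 64, 64)
  out <- normalizeContrast(const)
  expect_identical(intensities(out), intensities(const))
  expect_equal(out@metadata$contrast_flag, "constant")

  sc <- generateScene(seed = 4, nTrees = 2, extentUm = 150)
  img <- renderScene(sc, 144)
  shifted <- img
  shifted@intensities <- intensities(img) + 0.07  # no clipping: max < 1 - 0.07
  shifted@intensities <- pmin(shifted@intensities, 1)
  n1 <- normalizeContrast(img); n2 <- normalizeContrast(shifted)
  expect_equal(intensities(n1), intensities(n2), tolerance = 1e-10)

  # oracle: medians compared through the ground-truth mask
  tm <- maskMatrix(rasterizeTruthMask(sc, 144))
  v <- intensities(n1)
  expect_gt(median(v[tm]), median(v[!tm]))
})

test_that("ridge enhancement is zero on constants, peaks on the fibre row, and is 90-degree invariant", {
  expect_true(all(enhanceRidges(matrix(0.3, 48, 48)) == 0))

  sc <- makeStraightScene()
  img <- intensities(renderScene(sc, 192, noiseless = TRUE))
  resp <- enhanceRidges(img)
  expect_true(all(resp >= 0 & resp <= 1))
  # oracle: row-mean scan; centerline at 200 um -> row ~96 of 192
  expect_true(abs(which.max(rowMeans(resp)) - 96.5) <= 1.5)

  rot <- t(img)[ncol(img):1, ]
  back <- t(enhanceRidges(rot)[nrow(img):1, ])
  expect_lt(max(abs(resp - back)), 1e-6)
  expect_error(enhanceRidges(img, scalesPx = numeric(0)), "scalesPx")
  expect_error(enhanceRidges(img, scalesPx = 0.2), "scalesPx")
})

test_that("segmentation pipeline handles blank input, recovers components, and validates config", {
  blank <- ConfocalImage(matrix(0, 96, 96), 100, 100)
  expect_equal(sum(maskMatrix(segmentFibers(blank))), 0)

  one <- generateScene(seed = 5, nTrees = 1, branchProb = 0)
  mask <- segmentFibers(renderScene(one, 384, noiseless = TRUE))
  lab <- labelComponents(maskMatrix(mask))
  expect_equal(max(lab), max(labelComponents(
    maskMatrix(rasterizeTruthMask(one, 384)))))

  expect_error(snpConfig(hysteresisLow = 0.3, hysteresisHigh = 0.2), "<")
  expect_error(snpConfig(minComponentPx = -1), ">= 0")
})

test_that("component pixel count of a noisy render stays within 30% of truth", {
  sc <- generateScene(seed = 7)
  seg <- segmentFibers(renderScene(sc), snpConfig())
  truthPx <- sum(maskMatrix(rasterizeTruthMask(sc)))
  expect_lt(abs(sum(maskMatrix(seg)) - truthPx) / truthPx, 0.30)
})

test_that("raising the high hysteresis threshold never grows the mask", {
  sc <- generateScene(seed = 8, nTrees = 3, extentUm = 200)
  img <- renderScene(sc, 192)
  sizes <- vapply(c(0.15, 0.25, 0.4, 0.6), function(h)
    sum(maskMatrix(segmentFibers(img, snpConfig(hysteresisHigh = h)))),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("small components are removed and mask pass-through is the identity", {
  sc <- generateScene(seed = 9, nTrees = 3, extentUm = 200)
  cfg <- snpConfig(minComponentPx = 30)
  seg <- segmentFibers(renderScene(sc, 192), cfg)
  sz <- tabulate(labelComponents(maskMatrix(seg)))
  expect_true(all(sz[sz > 0] >= 30))

  tm <- rasterizeTruthMask(sc, 192)
  expect_identical(
    maskMatrix(segmentFibers(tm, snpConfig(maskPassthrough = TRUE))),
    maskMatrix(tm))
  expect_error(segmentFibers(tm, snpConfig()), "maskPassthrough")
})

test_that("pipeline configuration round-trips through its text format", {
  cfg <- snpConfig(scalesPx = c(1, 2.5), hysteresisLow = 0.07,
                   hysteresisHigh = 0.3, minComponentPx = 12,
                   pruneUm = 3.5, normalize = TRUE)
  f <- withr::local_tempfile(fileext = ".cfg")
  writeConfig(cfg, f)
  expect_identical(readConfig(f), cfg)
  expect_error(readConfig({writeLines("bogus=1", f); f}), "unknown")
})
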