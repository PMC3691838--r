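test_that("PNG round trip is bit-exact for 8-bit data and geometry is derived", {
  m <- matrix(sample(0:255, 64 * 48, replace = TRUE) / 255, 48, 64)
  img <- ConfocalImage(m, widthUm = 64, heightUm = 48)
  f <- withr::local_tempfile(fileext = ".png")
  writeConfocalImage(img, f)
  back <- readConfocalImage(f, widthUm = 64, heightUm = 48)
  expect_identical(intensities(back), m)
  expect_equal(pixelSizeUm(back), 1)

  ref <- ConfocalImage(matrix(0, 384, 384))
  expect_equal(pixelSizeUm(ref), 400 / 384, tolerance = 1e-12)
  expect_equal(round(pixelSizeUm(ref), 4), 1.0417)
})

test_that("16-bit TIFF reads rescaled to [0,1] and RGB converts to luminance", {
  m <- matrix(seq(0, 1, length.out = 32 * 32), 32, 32)
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(m, f, bits.per.sample = 16L)
  img <- readConfocalImage(f, 32, 32)
  expect_equal(max(intensities(img)), 1, tolerance = 1e-4)

  rgb <- array(0, c(16, 16, 3)); rgb[, , 2] <- 1   # pure green
  f2 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgb, f2)
  lum <- readConfocalImage(f2, 16, 16)
  expect_equal(unique(as.vector(intensities(lum))), 0.7152, tolerance = 1e-4)
})

test_that("invalid raster inputs are rejected", {
  expect_error(readConfocalImage("no/such/file.png"), "not found")
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), f)
  expect_error(readConfocalImage(f, widthUm = -1), "positive")
  expect_error(ConfocalImage(matrix(0, 10, 20), widthUm = 400,
                             heightUm = 400),
               "square")
})

test_that("sidecar files parse key=value geometry", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# geometry", "width_um=400", "height_um = 400",
               "interslice_um=2"), f)
  sc <- readSidecar(f)
  expect_equal(sc$width_um, 400)
  expect_equal(sc$interslice_um, 2)
})

test_that("volume stacks round-trip through multi-page TIFF and slice selection works", {
  blank <- matrix(0.1, 96, 96)
  sc <- generateScene(seed = 11, nTrees = 2, extentUm = 100)
  fib <- intensities(renderScene(sc, 96))
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(blank, blank, fib), f, bits.per.sample = 8L)
  stack <- readVolumeStack(f, widthUm = 100, heightUm = 100)
  expect_s4_class(stack, "VolumeStack")
  expect_length(stack@slices, 3)

  # oracle: exhaustive per-slice mean ridge response
  resp <- vapply(stack@slices, function(s) mean(enhanceRidges(s)),
                 numeric(1))
  expect_identical(which.max(resp), 3L)
  sel <- selectSNPSlice(stack)
  expect_identical(intensities(sel), intensities(stack@slices[[3]]))

  # index strategy is deterministic and independent of content
  expect_identical(intensities(selectSNPSlice(stack, "index", k = 2)),
                   intensities(stack@slices[[2]]))
  expect_error(selectSNPSlice(stack, "index", k = 4), "range")

  # ties break to the lowest index
  same <- VolumeStack(list(stack@slices[[1]], stack@slices[[1]],
                           stack@slices[[1]]))
  expect_identical(intensities(selectSNPSlice(same)),
                   intensities(stack@slices[[1]]))
  expect_error(selectSNPSlice(VolumeStack(list())), "empty")
})
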