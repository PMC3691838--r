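#' Read a confocal image from PNG or TIFF
#'
#' Reads a single-plane grayscale raster and attaches its physical extent.
#' Multi-channel images are converted to luminance (Rec. 709 weights);
#' intensities are represented as floating values in [0, 1] (8- and 16-bit
#' integer data map their nominal maximum to 1; the readers do this
#' natively). Physical extent is supplied by the caller or a sidecar file
#' (see \code{\link{readSidecar}}), not parsed from vendor headers; the
#' default is the 400 x 400 um reference field of view.
#'
#' @param path file path (.png, .tif/.tiff).
#' @param widthUm,heightUm physical extent in um.
#' @return a \code{\link{ConfocalImage}}.
#' @export
readConfocalImage <- function(path, widthUm = 400, heightUm = 400) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (widthUm <= 0 || heightUm <= 0) stop("physical extent must be positive")
  a <- readRaster(path)
  if (length(a) == 0L || any(dim(a)[1:2] == 0L)) stop("zero-sized image")
  ConfocalImage(toLuminance(a), widthUm, heightUm,
                metadata = list(source = path))
}

readRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext))
}

toLuminance <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  nch <- dim(a)[3]
  if (nch >= 3L)
    0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
  else a[, , 1]
}

#' Write a confocal image to PNG or TIFF
#'
#' 8-bit output; a write-then-read round trip of 8-bit data is bit-exact.
#'
#' @param image a ConfocalImage.
#' @param path destination (.png or .tif/.tiff).
#' @return \code{path}, invisibly.
#' @export
writeConfocalImage <- function(image, path) {
  stopifnot(is(image, "ConfocalImage"))
  m <- pmin(pmax(image@intensities, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop("unsupported raster format: .", ext))
  invisible(path)
}

#' Read a z-stack from a multi-page TIFF
#'
#' @param path multi-page TIFF file.
#' @param widthUm,heightUm per-slice extent, um.
#' @param intersliceUm slice spacing, um (reference acquisition: 2 um).
#' @param depthOffsetUm depth of the first slice, um.
#' @return a \code{\link{VolumeStack}}.
#' @export
readVolumeStack <- function(path, widthUm = 400, heightUm = 400,
                            intersliceUm = 2, depthOffsetUm = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  slices <- lapply(pages, function(a)
    ConfocalImage(toLuminance(a), widthUm, heightUm))
  VolumeStack(slices, intersliceUm = intersliceUm,
              depthOffsetUm = depthOffsetUm)
}

#' Read a key=value sidecar file with image geometry
#'
#' Recognised keys: \code{width_um}, \code{height_um}, \code{interslice_um};
#' lines starting with \code{#} are ignored.
#'
#' @param path text file of \code{key=value} lines.
#' @return named list of numeric values.
#' @export
readSidecar <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed sidecar line: ", ln[bad][1])
  out <- lapply(kv, function(x) as.numeric(trimws(x[2])))
  names(out) <- vapply(kv, function(x) trimws(x[1]), character(1))
  out
}

#' Select the subbasal-nerve-plexus slice from a volume stack
#'
#' The acquisition scans through the SNP layer; the slice actually lying in
#' the plexus must be chosen from the stack. The default strategy picks the
#' slice with the highest mean curvilinear-ridge response (the segmentation
#' module's multi-scale Hessian enhancer at its default scales), i.e. the
#' plane with the most fibre-like signal; ties break to the lowest index.
#' \code{strategy = "index"} selects slice \code{k} directly.
#'
#' @param stack a VolumeStack.
#' @param strategy "max_ridge_response" (default) or "index".
#' @param k 1-based slice index when \code{strategy = "index"}.
#' @param scalesPx ridge-enhancement scales (px) for the default strategy.
#' @return the selected \code{ConfocalImage}.
#' @export
selectSNPSlice <- function(stack, strategy = c("max_ridge_response", "index"),
                           k = NULL, scalesPx = c(1, 2, 3)) {
  stopifnot(is(stack, "VolumeStack"))
  if (length(stack@slices) == 0L) stop("empty stack")
  strategy <- match.arg(strategy)
  if (strategy == "index") {
    if (is.null(k) || k < 1L || k > length(stack@slices))
      stop("slice index out of range")
    return(stack@slices[[k]])
  }
  score <- vapply(stack@slices, function(s)
    mean(enhanceRidges(s, scalesPx = scalesPx)), numeric(1))
  stack@slices[[which.max(score)]]  # which.max: first max, lowest index
}
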