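#' @import methods
NULL

#' ConfocalImage: a 2-D confocal micrograph with physical geometry
#'
#' Grayscale intensity grid (values in [0, 1]) together with its physical
#' extent in micrometres. The reference in vivo confocal geometry is
#' 384 x 384 pixels covering 400 x 400 um, i.e. a pixel size of
#' 400/384 ~ 1.0417 um. Pixels are assumed square; the validity method
#' enforces agreement of the horizontal and vertical pixel sizes to 1e-9
#' relative.
#'
#' @slot intensities numeric matrix, rows = image rows (y), cols = x.
#' @slot widthUm,heightUm physical extent in micrometres.
#' @slot metadata list of free-form provenance entries (source file,
#'   rescaling applied, preprocessing flags).
#' @exportClass ConfocalImage
setClass("ConfocalImage",
  representation(intensities = "matrix", widthUm = "numeric",
                 heightUm = "numeric", metadata = "list"),
  prototype(metadata = list()))

setValidity("ConfocalImage", function(object) {
  m <- object@intensities
  if (!is.numeric(m) || length(dim(m)) != 2L)
    return("intensities must be a 2-D numeric matrix")
  if (nrow(m) < 1L || ncol(m) < 1L) return("zero-sized image")
  if (length(object@widthUm) != 1L || length(object@heightUm) != 1L ||
      !is.finite(object@widthUm) || !is.finite(object@heightUm) ||
      object@widthUm <= 0 || object@heightUm <= 0)
    return("physical extent must be a single positive value per axis")
  psx <- object@widthUm / ncol(m)
  psy <- object@heightUm / nrow(m)
  if (abs(psx - psy) > 1e-9 * max(psx, psy))
    return("pixels must be square: width_um/ncol must equal height_um/nrow")
  TRUE
})

#' Construct a ConfocalImage
#'
#' @param intensities numeric matrix of grayscale values; values outside
#'   [0, 1] are linearly rescaled so the maximum maps to 1 (8-bit 0-255 and
#'   16-bit 0-65535 integer data are divided by their nominal maximum).
#' @param widthUm,heightUm physical extent in um (default 400 x 400, the
#'   reference field of view).
#' @param metadata optional list of provenance entries.
#' @return a \code{ConfocalImage}.
#' @examples
#' img <- ConfocalImage(matrix(0, 100, 100), 100, 100)
#' pixelSizeUm(img)  # 1
#' @export
ConfocalImage <- function(intensities, widthUm = 400, heightUm = 400,
                          metadata = list()) {
  storage.mode(intensities) <- "double"
  mx <- suppressWarnings(max(intensities, na.rm = TRUE))
  if (is.finite(mx) && mx > 1) {
    div <- if (mx <= 255) 255 else if (mx <= 65535) 65535 else mx
    intensities <- intensities / div
    metadata$rescaled_by <- div
  }
  new("ConfocalImage", intensities = intensities, widthUm = widthUm,
      heightUm = heightUm, metadata = metadata)
}

#' VolumeStack: an ordered z-stack of confocal slices
#'
#' All slices share one geometry; the reference acquisition is 30 slices at
#' a constant 2 um interslice distance (60 um depth).
#'
#' @slot slices list of \code{ConfocalImage} with identical geometry.
#' @slot intersliceUm slice spacing in um (> 0).
#' @slot depthOffsetUm depth of the first slice in um.
#' @exportClass VolumeStack
setClass("VolumeStack",
  representation(slices = "list", intersliceUm = "numeric",
                 depthOffsetUm = "numeric"),
  prototype(intersliceUm = 2, depthOffsetUm = 0))

setValidity("VolumeStack", function(object) {
  if (length(object@intersliceUm) != 1L || object@intersliceUm <= 0)
    return("intersliceUm must be a single positive value")
  if (length(object@slices) == 0L) return(TRUE)
  if (!all(vapply(object@slices, is, logical(1), "ConfocalImage")))
    return("slices must all be ConfocalImage objects")
  d <- vapply(object@slices, function(s)
    c(dim(s@intensities), s@widthUm, s@heightUm), numeric(4))
  if (any(apply(d, 1, function(x) diff(range(x)) > 0)))
    return("all slices must share identical dimensions and extent")
  TRUE
})

#' @rdname VolumeStack-class
#' @param slices list of ConfocalImage.
#' @param intersliceUm slice spacing, um.
#' @param depthOffsetUm depth of the first slice, um.
#' @export
VolumeStack <- function(slices, intersliceUm = 2, depthOffsetUm = 0) {
  new("VolumeStack", slices = slices, intersliceUm = intersliceUm,
      depthOffsetUm = depthOffsetUm)
}

#' FiberMask: binary segmentation of nerve-fibre pixels
#'
#' @slot mask logical matrix, TRUE on fibre ("component") pixels.
#' @slot widthUm,heightUm physical extent inherited from the source image.
#' @exportClass FiberMask
setClass("FiberMask",
  representation(mask = "matrix", widthUm = "numeric", heightUm = "numeric"))

setValidity("FiberMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@widthUm <= 0 || object@heightUm <= 0)
    return("physical extent must be positive")
  psx <- object@widthUm / ncol(object@mask)
  psy <- object@heightUm / nrow(object@mask)
  if (abs(psx - psy) > 1e-9 * max(psx, psy))
    return("pixels must be square")
  TRUE
})

#' @rdname FiberMask-class
#' @param mask logical (or 0/1) matrix.
#' @param widthUm,heightUm physical extent in um.
#' @export
FiberMask <- function(mask, widthUm = 400, heightUm = 400) {
  mode(mask) <- "logical"
  new("FiberMask", mask = mask, widthUm = widthUm, heightUm = heightUm)
}

#' SkeletonMask: one-pixel-wide medial axis of a fibre mask
#'
#' Subclass of \code{FiberMask} whose mask is a topology-preserving
#' thinning result (no 2 x 2 block of foreground pixels).
#' @exportClass SkeletonMask
setClass("SkeletonMask", contains = "FiberMask")

#' SkeletonGraph: node/edge representation of the medial-axis network
#'
#' Nodes are skeleton pixels classified by 8-neighbour count: endpoints
#' (1 neighbour), branch points (clusters of pixels with >= 3 neighbours,
#' merged), border nodes (degree-1 pixels on the outermost image row or
#' column) and anchors (artificial degree-2 nodes breaking isolated
#' cycles). Edges are traced pixel chains between nodes; chain-code length
#' counts an orthogonal step as one pixel size and a diagonal step as
#' sqrt(2) pixel sizes.
#'
#' @slot nodes data.frame: id, row, col, kind, degree, component.
#' @slot edges data.frame: id, from, to, steps, lengthUm, component.
#' @slot chains list of integer matrices (row, col) giving each edge's full
#'   pixel path, node pixels included.
#' @slot nodePixels list of integer matrices (row, col): the skeleton
#'   pixels belonging to each node (one pixel for endpoints/anchors, the
#'   merged cluster for branch nodes).
#' @slot skeletonPixels total number of skeleton pixels.
#' @slot nComponents number of connected components of the skeleton.
#' @slot pixelSizeUm pixel size in um.
#' @slot dim skeleton dimensions (rows, cols).
#' @exportClass SkeletonGraph
setClass("SkeletonGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 chains = "list", nodePixels = "list",
                 skeletonPixels = "integer", nComponents = "integer",
                 pixelSizeUm = "numeric", dim = "integer"))

setValidity("SkeletonGraph", function(object) {
  kinds <- c("endpoint", "branch", "border", "anchor")
  if (nrow(object@nodes) && !all(object@nodes$kind %in% kinds))
    return(sprintf("node kind must be one of: %s",
                   paste(kinds, collapse = ", ")))
  if (nrow(object@edges) != length(object@chains))
    return("one pixel chain per edge required")
  TRUE
})

#' SNPMetrics: the nine morphometric parameters of an SNP image
#'
#' Raw per-image values, or values normalised to an area of 1 mm^2
#' (\code{normalised = TRUE}: counts and total length scaled by
#' 1/area; density and average single-fibre length are intensive and
#' unchanged).
#'
#' @slot componentPixels number of pixels identified as nerve fibres.
#' @slot nerveFibreComponents number of separate nerve fibre networks.
#' @slot skeletonPixels number of medial-axis pixels.
#' @slot singleNerveFibres number of nerve segments between branches and
#'   nerve ends (graph edges).
#' @slot totalFibreLengthUm length of all nerve fibres in the image, um.
#' @slot averageSingleFibreLengthUm mean length of a single fibre, um.
#' @slot nerveFibreDensity total length per area, mm/mm^2.
#' @slot connectivityPoints fibres entering or leaving the image area.
#' @slot branches number of branch points.
#' @slot areaMm2 analysed image area, mm^2.
#' @slot normalised logical flag.
#' @exportClass SNPMetrics
setClass("SNPMetrics",
  representation(componentPixels = "numeric", nerveFibreComponents = "numeric",
                 skeletonPixels = "numeric", singleNerveFibres = "numeric",
                 totalFibreLengthUm = "numeric",
                 averageSingleFibreLengthUm = "numeric",
                 nerveFibreDensity = "numeric", connectivityPoints = "numeric",
                 branches = "numeric", areaMm2 = "numeric",
                 normalised = "logical"),
  prototype(normalised = FALSE))

setValidity("SNPMetrics", function(object) {
  v <- c(object@componentPixels, object@nerveFibreComponents,
         object@skeletonPixels, object@singleNerveFibres,
         object@totalFibreLengthUm, object@averageSingleFibreLengthUm,
         object@nerveFibreDensity, object@connectivityPoints,
         object@branches)
  if (any(!is.finite(v)) || any(v < 0)) return("metrics must be >= 0")
  if (object@areaMm2 <= 0) return("areaMm2 must be positive")
  if (object@skeletonPixels > object@componentPixels)
    return("skeleton pixels cannot exceed component pixels")
  TRUE
})

#' SceneTruth: a synthetic fibre scene with exact ground truth
#'
#' Generative model of an SNP image: branching, gently tortuous fibre trees
#' entering at the image border, stored as sub-pixel polylines, together
#' with the exact topological graph they induce (border entries, branch
#' points, fibre ends) and rendering noise parameters.
#'
#' @slot fibers list, one element per truth edge: \code{points} (n x 2
#'   matrix of x, y in um), \code{widthUm}, \code{peakIntensity},
#'   \code{tree} (tree id).
#' @slot nodes data.frame of truth nodes: id, x, y, kind, tree.
#' @slot edges data.frame of truth edges: id, from, to, lengthUm, tree.
#' @slot extentUm scene side length, um.
#' @slot seed integer seed the scene was generated from.
#' @slot noiseParams list: background, additiveSd, speckleSd, blurSigmaPx.
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(fibers = "list", nodes = "data.frame", edges = "data.frame",
                 extentUm = "numeric", seed = "integer",
                 noiseParams = "list"))

setValidity("SceneTruth", function(object) {
  if (object@extentUm <= 0) return("extentUm must be positive")
  if (length(object@fibers) != nrow(object@edges))
    return("one polyline per truth edge required")
  for (f in object@fibers) {
    p <- f$points
    if (nrow(p) < 2L) return("each fibre polyline needs >= 2 points")
    if (any(p < -1e-9) || any(p > object@extentUm + 1e-9))
      return("centerlines must lie within the scene extent")
    if (f$widthUm <= 0) return("fibre width must be positive")
  }
  TRUE
})
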