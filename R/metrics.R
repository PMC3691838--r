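#' Construct an SNPMetrics object
#'
#' @param componentPixels,nerveFibreComponents,skeletonPixels,singleNerveFibres,totalFibreLengthUm,averageSingleFibreLengthUm,nerveFibreDensity,connectivityPoints,branches the nine morphometric parameters.
#' @param areaMm2 analysed area in mm^2.
#' @param normalised logical; TRUE if counts/length are per 1 mm^2.
#' @return an \code{\link{SNPMetrics}}.
#' @export
SNPMetrics <- function(componentPixels = 0, nerveFibreComponents = 0,
                       skeletonPixels = 0, singleNerveFibres = 0,
                       totalFibreLengthUm = 0,
                       averageSingleFibreLengthUm = 0,
                       nerveFibreDensity = 0, connectivityPoints = 0,
                       branches = 0, areaMm2 = 0.16, normalised = FALSE) {
  new("SNPMetrics", componentPixels = componentPixels,
      nerveFibreComponents = nerveFibreComponents,
      skeletonPixels = skeletonPixels,
      singleNerveFibres = singleNerveFibres,
      totalFibreLengthUm = totalFibreLengthUm,
      averageSingleFibreLengthUm = averageSingleFibreLengthUm,
      nerveFibreDensity = nerveFibreDensity,
      connectivityPoints = connectivityPoints, branches = branches,
      areaMm2 = areaMm2, normalised = normalised)
}

#' Nerve fibre density from total length and area
#'
#' NFD = (total length in mm) / (area in mm^2); the identity
#' \code{fibreDensity(L, A) * A == L / 1000} is exact.
#'
#' @param totalFibreLengthUm total fibre length, um.
#' @param areaMm2 image area, mm^2 (> 0).
#' @return density in mm/mm^2.
#' @export
fibreDensity <- function(totalFibreLengthUm, areaMm2) {
  if (any(areaMm2 <= 0)) stop("areaMm2 must be positive")
  (totalFibreLengthUm / 1000) / areaMm2
}

canonicalMetricNames <- c(
  "component_pixels", "nerve_fibre_components", "skeleton_pixels",
  "single_nerve_fibres", "total_fibre_length_um",
  "average_single_fibre_length_um", "nerve_fibre_density_mm_per_mm2",
  "connectivity_points", "branches")

#' @describeIn SNPMetrics one-row data.frame with canonical column names
#'   (plus \code{area_mm2} and \code{normalised}).
#' @param x an SNPMetrics object.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.SNPMetrics <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  df <- data.frame(
    x@componentPixels, x@nerveFibreComponents, x@skeletonPixels,
    x@singleNerveFibres, x@totalFibreLengthUm,
    x@averageSingleFibreLengthUm, x@nerveFibreDensity,
    x@connectivityPoints, x@branches, x@areaMm2, x@normalised)
  names(df) <- c(canonicalMetricNames, "area_mm2", "normalised")
  df
}

#' Compute the nine morphometric parameters from mask and graph
#'
#' Component pixels = foreground pixels of the fibre mask; nerve fibre
#' components = connected networks of the medial axis; skeleton pixels =
#' medial-axis pixels; single nerve fibres = graph edges (nerve segments
#' between branches and nerve ends); total fibre length = sum of
#' chain-code edge lengths; average single-fibre length = total / single
#' fibres (0 when there are none); nerve fibre density =
#' (total length in mm) / area in mm^2 — an exact identity on every
#' output; connectivity points = border nodes (fibres entering or leaving
#' the image area); branches = branch nodes.
#'
#' @param mask the \code{\link{FiberMask}} the skeleton was derived from.
#' @param graph the \code{\link{SkeletonGraph}}.
#' @return a raw (un-normalised) \code{\link{SNPMetrics}}.
#' @export
computeMetrics <- function(mask, graph) {
  stopifnot(is(mask, "FiberMask"), is(graph, "SkeletonGraph"))
  if (!all(dim(maskMatrix(mask)) == graph@dim))
    stop("geometry mismatch between mask and graph")
  if (abs(pixelSizeUm(mask) - graph@pixelSizeUm) >
      1e-9 * graph@pixelSizeUm)
    stop("geometry mismatch between mask and graph")
  area <- areaMm2(mask)
  nEdge <- nrow(graph@edges)
  totalUm <- if (nEdge) sum(graph@edges$lengthUm) else 0
  SNPMetrics(
    componentPixels = sum(maskMatrix(mask)),
    nerveFibreComponents = graph@nComponents,
    skeletonPixels = graph@skeletonPixels,
    singleNerveFibres = nEdge,
    totalFibreLengthUm = totalUm,
    averageSingleFibreLengthUm = if (nEdge) totalUm / nEdge else 0,
    nerveFibreDensity = fibreDensity(totalUm, area),
    connectivityPoints = sum(graph@nodes$kind == "border"),
    branches = sum(graph@nodes$kind == "branch"),
    areaMm2 = area, normalised = FALSE)
}

#' Normalise metrics to an area of 1 mm^2
#'
#' Counts and total fibre length are scaled by 1 / area; nerve fibre
#' density and average single-fibre length are intensive and unchanged.
#' Double normalisation is an error.
#'
#' @param metrics a raw \code{\link{SNPMetrics}}.
#' @return the normalised \code{SNPMetrics}.
#' @export
normalizePerMm2 <- function(metrics) {
  stopifnot(is(metrics, "SNPMetrics"))
  if (metrics@normalised) stop("metrics already normalised")
  if (metrics@areaMm2 <= 0) stop("areaMm2 must be positive")
  f <- 1 / metrics@areaMm2
  SNPMetrics(
    componentPixels = metrics@componentPixels * f,
    nerveFibreComponents = metrics@nerveFibreComponents * f,
    skeletonPixels = metrics@skeletonPixels * f,
    singleNerveFibres = metrics@singleNerveFibres * f,
    totalFibreLengthUm = metrics@totalFibreLengthUm * f,
    averageSingleFibreLengthUm = metrics@averageSingleFibreLengthUm,
    nerveFibreDensity = metrics@nerveFibreDensity,
    connectivityPoints = metrics@connectivityPoints * f,
    branches = metrics@branches * f,
    areaMm2 = metrics@areaMm2, normalised = TRUE)
}

#' Quantify an SNP image end to end
#'
#' Full pipeline: segmentation (skipped for a \code{FiberMask} input in
#' pass-through mode), skeletonisation, medial-axis graph extraction with
#' spur pruning, and metric computation; optionally normalised to 1 mm^2
#' (\code{config$normalize}). Deterministic for a fixed configuration.
#'
#' @param x a \code{\link{ConfocalImage}} or (with
#'   \code{config$maskPassthrough}) a \code{\link{FiberMask}}.
#' @param config an \code{\link{snpConfig}}.
#' @return an \code{\link{SNPMetrics}}.
#' @export
quantifyImage <- function(x, config = snpConfig()) {
  mask <- segmentFibers(x, config)
  graph <- buildGraph(skeletonize(mask), pruneUm = config$pruneUm)
  m <- computeMetrics(mask, graph)
  if (isTRUE(config$normalize)) m <- normalizePerMm2(m)
  m
}

#' Report metrics with the study's rounding conventions
#'
#' Lengths and densities are rounded to 3 decimal places, half away from
#' zero; counts are left exact.
#'
#' @param metrics an SNPMetrics object.
#' @return one-row data.frame with canonical column names.
#' @export
reportMetrics <- function(metrics) {
  df <- as.data.frame(metrics)
  for (nm in c("total_fibre_length_um", "average_single_fibre_length_um",
               "nerve_fibre_density_mm_per_mm2"))
    df[[nm]] <- roundHalfAway(df[[nm]], 3)
  df
}

#' Write metrics rows as delimited text
#'
#' @param metrics an SNPMetrics or list of them.
#' @param path destination CSV.
#' @param ids optional row identifiers (e.g. file names).
#' @return invisibly, the data.frame written.
#' @export
writeMetricsTable <- function(metrics, path, ids = NULL) {
  if (is(metrics, "SNPMetrics")) metrics <- list(metrics)
  df <- do.call(rbind, lapply(metrics, reportMetrics))
  if (!is.null(ids)) df <- cbind(data.frame(image = ids), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
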