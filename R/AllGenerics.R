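#' @include AllClasses.R
NULL

#' Pixel size in micrometres
#' @param x a ConfocalImage, FiberMask or SkeletonGraph.
#' @return pixel edge length in um.
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' @rdname pixelSizeUm
setMethod("pixelSizeUm", "ConfocalImage", function(x)
  x@widthUm / ncol(x@intensities))

#' @rdname pixelSizeUm
setMethod("pixelSizeUm", "FiberMask", function(x) x@widthUm / ncol(x@mask))

#' @rdname pixelSizeUm
setMethod("pixelSizeUm", "SkeletonGraph", function(x) x@pixelSizeUm)

#' Intensity matrix of a confocal image
#' @param x a ConfocalImage.
#' @return numeric matrix in [0, 1].
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname intensities
setMethod("intensities", "ConfocalImage", function(x) x@intensities)

#' Binary mask matrix
#' @param x a FiberMask or SkeletonMask.
#' @return logical matrix.
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname maskMatrix
setMethod("maskMatrix", "FiberMask", function(x) x@mask)

#' Image area in mm^2
#' @param x an object with physical extent.
#' @return area in mm^2.
#' @export
setGeneric("areaMm2", function(x) standardGeneric("areaMm2"))

#' @rdname areaMm2
setMethod("areaMm2", "ConfocalImage", function(x)
  x@widthUm * x@heightUm / 1e6)

#' @rdname areaMm2
setMethod("areaMm2", "FiberMask", function(x) x@widthUm * x@heightUm / 1e6)

#' @rdname areaMm2
setMethod("areaMm2", "SNPMetrics", function(x) x@areaMm2)

#' Nodes of a skeleton or truth graph
#' @param x a SkeletonGraph or SceneTruth.
#' @return data.frame of nodes.
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname graphNodes
setMethod("graphNodes", "SkeletonGraph", function(x) x@nodes)

#' @rdname graphNodes
setMethod("graphNodes", "SceneTruth", function(x) x@nodes)

#' Edges of a skeleton or truth graph
#' @param x a SkeletonGraph or SceneTruth.
#' @return data.frame of edges.
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname graphEdges
setMethod("graphEdges", "SkeletonGraph", function(x) x@edges)

#' @rdname graphEdges
setMethod("graphEdges", "SceneTruth", function(x) x@edges)

setMethod("show", "ConfocalImage", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("ConfocalImage: %d x %d px, %.1f x %.1f um (%.4f um/px)\n",
              d[1], d[2], object@heightUm, object@widthUm,
              pixelSizeUm(object)))
  cat(sprintf("  intensity range [%.3f, %.3f]\n",
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "VolumeStack", function(object) {
  cat(sprintf("VolumeStack: %d slices, interslice %.1f um, depth offset %.1f um\n",
              length(object@slices), object@intersliceUm,
              object@depthOffsetUm))
})

setMethod("show", "FiberMask", function(object) {
  cat(sprintf("%s: %d x %d px, %d foreground pixels\n",
              class(object), nrow(object@mask), ncol(object@mask),
              sum(object@mask)))
})

setMethod("show", "SkeletonGraph", function(object) {
  tab <- table(factor(object@nodes$kind,
                      c("endpoint", "branch", "border", "anchor")))
  cat(sprintf(
    "SkeletonGraph: %d nodes (%d endpoint, %d branch, %d border, %d anchor)\n",
    nrow(object@nodes), tab["endpoint"], tab["branch"], tab["border"],
    tab["anchor"]))
  cat(sprintf("  %d edges, %d components, %d skeleton px, total %.1f um\n",
              nrow(object@edges), object@nComponents, object@skeletonPixels,
              sum(object@edges$lengthUm)))
})

setMethod("show", "SNPMetrics", function(object) {
  cat(sprintf("SNPMetrics (%s, area %.4f mm^2)\n",
              if (object@normalised) "normalised to 1 mm^2" else "raw",
              object@areaMm2))
  df <- as.data.frame(object)
  print(df, row.names = FALSE)
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf(
    "SceneTruth: %d fibre segments in %g x %g um (seed %d)\n",
    length(object@fibers), object@extentUm, object@extentUm, object@seed))
  cat(sprintf("  truth nodes: %d, edges: %d, total length %.1f um\n",
              nrow(object@nodes), nrow(object@edges),
              sum(object@edges$lengthUm)))
})
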