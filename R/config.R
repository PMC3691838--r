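#' Quantification pipeline configuration
#'
#' All tunable parameters of the segmentation / skeletonisation /
#' quantification pipeline, with their defaults. The segmentation chain is
#' the standard curvilinear-detection stack (background top-hat,
#' multi-scale Hessian ridge enhancement, hysteresis thresholding,
#' small-object removal); every stage is exposed here.
#'
#' @param scalesPx ridge-enhancement scales in pixels (default 1, 2, 3 —
#'   bracketing the 1-4 px apparent width of subbasal fibres).
#' @param hysteresisLow,hysteresisHigh hysteresis thresholds on the [0, 1]
#'   ridge response; \code{low < high} required (defaults 0.10 / 0.25).
#' @param minComponentPx connected components (8-connectivity) smaller than
#'   this are discarded (default 30 px).
#' @param tophatRadiusPx structuring-disc radius of the background top-hat
#'   (default 8 px).
#' @param pruneUm skeleton spurs from an endpoint shorter than this are
#'   removed once (default 5 um; 0 disables pruning).
#' @param maskPassthrough if TRUE, a supplied binary mask bypasses
#'   segmentation entirely (used to test downstream stages independently
#'   of segmentation quality).
#' @param normalize if TRUE, \code{\link{quantifyImage}} returns metrics
#'   normalised to 1 mm^2.
#' @return a list of class \code{snpConfig}.
#' @export
snpConfig <- function(scalesPx = c(1, 2, 3), hysteresisLow = 0.10,
                      hysteresisHigh = 0.25, minComponentPx = 30,
                      tophatRadiusPx = 8, pruneUm = 5,
                      maskPassthrough = FALSE, normalize = FALSE) {
  if (length(scalesPx) == 0L || any(scalesPx < 0.5))
    stop("scalesPx must be non-empty with every scale >= 0.5 px")
  if (hysteresisLow >= hysteresisHigh)
    stop("hysteresisLow must be < hysteresisHigh")
  if (minComponentPx < 0) stop("minComponentPx must be >= 0")
  if (pruneUm < 0) stop("pruneUm must be >= 0")
  structure(list(scalesPx = scalesPx, hysteresisLow = hysteresisLow,
                 hysteresisHigh = hysteresisHigh,
                 minComponentPx = minComponentPx,
                 tophatRadiusPx = tophatRadiusPx, pruneUm = pruneUm,
                 maskPassthrough = maskPassthrough, normalize = normalize),
            class = "snpConfig")
}

#' Write a pipeline configuration to a text file
#'
#' \code{key=value} lines; \code{scalesPx} is comma-separated. The
#' round trip \code{readConfig(writeConfig(cfg, f))} is lossless.
#'
#' @param config an \code{snpConfig}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
writeConfig <- function(config, path) {
  stopifnot(inherits(config, "snpConfig"))
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    paste(format(v, digits = 15, scientific = FALSE, trim = TRUE),
          collapse = ",")
  }
  writeLines(paste0(names(config), "=", vapply(config, fmt, character(1))),
             path)
  invisible(path)
}

#' Read a pipeline configuration from a text file
#'
#' @param path file written by \code{\link{writeConfig}} (unknown keys are
#'   rejected; missing keys take their defaults).
#' @return an \code{snpConfig}.
#' @export
readConfig <- function(path) {
  kv <- readSidecarText(path)
  defaults <- snpConfig()
  unknown <- setdiff(names(kv), names(defaults))
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  args <- lapply(names(kv), function(k) {
    v <- kv[[k]]
    if (is.logical(defaults[[k]])) return(identical(tolower(v), "true"))
    as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
  })
  names(args) <- names(kv)
  do.call(snpConfig, args)
}

readSidecarText <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  out <- lapply(kv, function(x) trimws(x[2]))
  names(out) <- vapply(kv, function(x) trimws(x[1]), character(1))
  out
}
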