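#' Background subtraction and contrast normalisation
#'
#' Morphological white top-hat (disc structuring element) removes the
#' slowly varying background, then intensities are contrast-stretched to
#' [0, 1] between their 1st and 99th percentiles. An additive constant
#' offset is removed exactly by the top-hat, so illumination offsets do not
#' affect downstream thresholds. A constant input is returned unchanged
#' with \code{metadata$contrast_flag = "constant"}.
#'
#' @param image a \code{\link{ConfocalImage}}.
#' @param tophatRadiusPx structuring-disc radius in px (default 8).
#' @return a \code{ConfocalImage} with normalised intensities.
#' @export
normalizeContrast <- function(image, tophatRadiusPx = 8) {
  stopifnot(is(image, "ConfocalImage"))
  m <- image@intensities
  if (diff(range(m)) == 0) {
    image@metadata$contrast_flag <- "constant"
    return(image)
  }
  brush <- EBImage::makeBrush(2L * as.integer(tophatRadiusPx) + 1L, "disc")
  th <- EBImage::whiteTopHat(m, brush)
  q <- stats::quantile(th, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) {
    image@metadata$contrast_flag <- "degenerate"
    return(image)
  }
  image@intensities <- pmin(pmax((th - q[1]) / (q[2] - q[1]), 0), 1)
  image@metadata$contrast_flag <- "ok"
  image
}

# separable Gaussian-derivative convolutions of the Hessian, one scale
hessianAtScale <- function(m, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  x <- -h:h
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -x / sigma^2 * g                    # first derivative
  g2 <- (x^2 - sigma^2) / sigma^4 * g       # second derivative
  g2 <- g2 - sum(g2) / length(g2)           # exact zero response to constants
  conv <- function(k) EBImage::filter2(m, k, boundary = "replicate")
  list(xx = conv(outer(g, g2)),             # d^2/dcol^2
       yy = conv(outer(g2, g)),             # d^2/drow^2
       xy = conv(outer(g1, g1)))
}

#' Multi-scale Hessian ridge enhancement
#'
#' Tubularity (vesselness) response for bright curvilinear structures:
#' at each scale the Gaussian-smoothed Hessian is diagonalised; pixels
#' whose dominant eigenvalue is negative (bright ridge) score
#' \eqn{\exp(-R_b^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2c^2))} with blobness
#' \eqn{R_b = \lambda_{lo}/\lambda_{hi}}, structureness
#' \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}}, \eqn{\beta = 0.5} and
#' \eqn{c} set to half the maximal \eqn{S} over all scales. Second
#' derivatives are scale-normalised linearly (\eqn{\gamma = 1}), weighting
#' the octaves toward the 1-4 px width of subbasal fibres. The per-pixel
#' maximum over scales is returned; the response lies in [0, 1] and a
#' constant image maps to all zeros.
#'
#' @param image a ConfocalImage (or plain numeric matrix).
#' @param scalesPx Gaussian scales in pixels, each >= 0.5.
#' @return numeric matrix in [0, 1], same dimension as the input.
#' @export
enhanceRidges <- function(image, scalesPx = c(1, 2, 3)) {
  if (length(scalesPx) == 0L || any(scalesPx < 0.5))
    stop("scalesPx must be non-empty with every scale >= 0.5 px")
  m <- if (is(image, "ConfocalImage")) image@intensities else image
  beta <- 0.5
  eig <- lapply(scalesPx, function(s) {
    H <- hessianAtScale(m, s)
    # linear (gamma = 1) scale normalisation: subbasal fibres are 1-4 px
    # wide, so the octaves are weighted toward the fine scales and the
    # response support stays close to the true fibre width (quadratic
    # weighting halos thin ridges with the coarse-scale skirt)
    xx <- s * H$xx; yy <- s * H$yy; xy <- s * H$xy
    mean2 <- (xx + yy) / 2
    disc <- sqrt(((xx - yy) / 2)^2 + xy^2)
    list(la = mean2 + disc, lb = mean2 - disc)
  })
  # one structureness scale c across all analysis scales, so weak broad
  # responses at large scales are not inflated relative to the fine ones
  smax <- max(vapply(eig, function(e) max(e$la^2 + e$lb^2), numeric(1)))
  cs <- 0.5 * sqrt(smax)
  out <- matrix(0, nrow(m), ncol(m))
  if (cs <= 1e-10) return(out)   # flat image: numerically zero structure
  for (e in eig) {
    hi <- ifelse(abs(e$la) >= abs(e$lb), e$la, e$lb)
    lo <- ifelse(abs(e$la) >= abs(e$lb), e$lb, e$la)
    s2 <- e$la^2 + e$lb^2
    rb2 <- ifelse(hi != 0, (lo / hi)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cs^2)))
    v[hi >= 0] <- 0
    out <- pmax(out, v)
  }
  out
}

# hysteresis: keep weak-threshold components containing a strong pixel
hysteresisThreshold <- function(resp, low, high) {
  weak <- resp >= low
  strong <- resp >= high
  if (!any(strong)) return(matrix(FALSE, nrow(resp), ncol(resp)))
  lab <- labelComponents(weak, connectivity = 8)
  keep <- unique(lab[strong])
  matrix(lab %in% keep[keep > 0L], nrow(resp), ncol(resp))
}

# drop 8-connected components smaller than minPx
removeSmallComponents <- function(mask, minPx) {
  if (minPx <= 1L || !any(mask)) return(mask)
  lab <- labelComponents(mask, connectivity = 8)
  sz <- tabulate(lab)
  keep <- which(sz >= minPx)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Segment nerve-fibre pixels
#'
#' Stage 1 of the quantification pipeline: contrast normalisation,
#' multi-scale Hessian ridge enhancement, hysteresis thresholding and
#' removal of small connected components (8-connectivity) yield the binary
#' fibre ("component pixel") mask. With \code{config$maskPassthrough} a
#' \code{\link{FiberMask}} input is returned unchanged, so all downstream
#' stages can be exercised independently of segmentation quality.
#'
#' @param image a \code{\link{ConfocalImage}} (or a \code{FiberMask} in
#'   pass-through mode).
#' @param config an \code{\link{snpConfig}}.
#' @return a \code{\link{FiberMask}}.
#' @export
segmentFibers <- function(image, config = snpConfig()) {
  stopifnot(inherits(config, "snpConfig"))
  if (is(image, "FiberMask")) {
    if (!isTRUE(config$maskPassthrough))
      stop("FiberMask input requires config$maskPassthrough = TRUE")
    return(image)
  }
  stopifnot(is(image, "ConfocalImage"))
  norm <- normalizeContrast(image, config$tophatRadiusPx)
  resp <- enhanceRidges(norm, config$scalesPx)
  mask <- hysteresisThreshold(resp, config$hysteresisLow,
                              config$hysteresisHigh)
  mask <- removeSmallComponents(mask, config$minComponentPx)
  FiberMask(mask, image@widthUm, image@heightUm)
}
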