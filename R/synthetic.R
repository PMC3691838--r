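#' Default rendering noise parameters
#'
#' Chosen to visually approximate in vivo confocal SNP images: background
#' offset 0.15, additive Gaussian noise sd 0.05, multiplicative speckle sd
#' 0.2, Gaussian blur sigma 0.8 px.
#'
#' @return named list of noise parameters.
#' @export
defaultNoiseParams <- function()
  list(background = 0.15, additiveSd = 0.05, speckleSd = 0.2,
       blurSigmaPx = 0.8)

#' Construct a SceneTruth
#'
#' @param fibers list of truth-edge polylines; each element a list with
#'   \code{points} (n x 2 matrix of x, y in um), \code{widthUm},
#'   \code{peakIntensity}, \code{tree}.
#' @param nodes data.frame: id, x, y, kind ("border", "branch",
#'   "endpoint"), tree.
#' @param edges data.frame: id, from, to, lengthUm, tree.
#' @param extentUm scene side length in um.
#' @param seed integer seed.
#' @param noiseParams list as \code{\link{defaultNoiseParams}}.
#' @return a \code{\link{SceneTruth-class}} object.
#' @export
SceneTruth <- function(fibers, nodes, edges, extentUm = 400, seed = 1L,
                       noiseParams = defaultNoiseParams()) {
  new("SceneTruth", fibers = fibers, nodes = nodes, edges = edges,
      extentUm = extentUm, seed = as.integer(seed),
      noiseParams = noiseParams)
}

polylineLength <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                    p[-nrow(p), , drop = FALSE])^2)))
}

emptyTruthNodes <- function()
  data.frame(id = integer(), x = numeric(), y = numeric(),
             kind = character(), tree = integer())

emptyTruthEdges <- function()
  data.frame(id = integer(), from = integer(), to = integer(),
             lengthUm = numeric(), tree = integer())

#' Generate a synthetic subbasal-nerve-plexus scene
#'
#' Emulates SNP geometry as seen in confocal images: hyperreflective,
#' gently tortuous fibres that enter the field at the border, propagate as
#' correlated random walks with bounded curvature, and branch at random.
#' Each fibre tree keeps a minimum separation from all other structures,
#' so the generative topology (border entries, branch points, fibre ends)
#' is exactly the topology a perfect quantification would recover — the
#' scene carries its own oracle. Generation is deterministic for a fixed
#' seed and leaves the caller's RNG state untouched.
#'
#' Defaults emulate a healthy (pre-irradiation) image at the reference
#' geometry: about five trees in a 400 x 400 um field with ~1 branch per
#' 100 um give a nerve fibre density near 15 mm/mm^2.
#'
#' @param nTrees number of fibre trees (>= 0).
#' @param branchProb per-step (1 um) branch probability in [0, 1].
#' @param tortuosity sd of the per-step heading change, radians (0 =
#'   straight).
#' @param extentUm scene side length, um.
#' @param seed integer seed.
#' @param widthUm fibre stroke width (default 2 px at the 384 px / 400 um
#'   reference geometry).
#' @param intensityRange range of per-tree peak intensities.
#' @param minSepUm minimum separation between distinct structures, um.
#' @param stepUm growth step, um (sub-pixel at the reference geometry).
#' @param maxSteps maximum steps per fibre segment chain.
#' @param noiseParams rendering noise, see \code{\link{defaultNoiseParams}}.
#' @return a \code{\link{SceneTruth-class}} object.
#' @export
generateScene <- function(nTrees = 5, branchProb = 0.01, tortuosity = 0.03,
                          extentUm = 400, seed = 1L,
                          widthUm = 2 * 400 / 384,
                          intensityRange = c(0.6, 1.0), minSepUm = 6,
                          stepUm = 1, maxSteps = 600,
                          noiseParams = defaultNoiseParams()) {
  if (nTrees < 0) stop("nTrees must be >= 0")
  if (branchProb < 0 || branchProb > 1)
    stop("branchProb must be a probability")
  if (extentUm <= 0) stop("extentUm must be positive")
  withSeed(as.integer(seed),
           growScene(nTrees, branchProb, tortuosity, extentUm,
                     as.integer(seed), widthUm, intensityRange, minSepUm,
                     stepUm, maxSteps, noiseParams))
}

growScene <- function(nTrees, branchProb, tortuosity, extentUm, seed,
                      widthUm, intensityRange, minSepUm, stepUm, maxSteps,
                      noiseParams) {
  nodes <- list(); edges <- list(); fibers <- list()
  ptsX <- numeric(0); ptsY <- numeric(0); ptsTree <- integer(0)
  ptsTip <- logical(0)   # committed interior fibre tips: never approached
  nid <- 0L; eid <- 0L
  branchAngle <- 40 * pi / 180

  addNode <- function(x, y, kind, tree) {
    nid <<- nid + 1L
    nodes[[nid]] <<- data.frame(id = nid, x = x, y = y, kind = kind,
                                tree = tree)
    nid
  }
  collides <- function(x, y, tree, startXY, chainStartIdx) {
    np <- length(ptsX)
    if (np == 0L) return(FALSE)
    d2 <- (ptsX - x)^2 + (ptsY - y)^2
    near <- d2 < minSepUm^2
    if (!any(near)) return(FALSE)
    # exempt (i) points of the same tree around the chain's start node —
    # the parent fibre legitimately passes there — and (ii) the chain's
    # own trailing points (closer along the arc than the separation)
    ds2 <- (ptsX - startXY[1])^2 + (ptsY - startXY[2])^2
    recent <- ceiling(minSepUm / stepUm) + 2L
    idx <- seq_len(np)
    exempt <- (ptsTree == tree & ds2 < (2 * minSepUm)^2 & !ptsTip) |
      idx > max(chainStartIdx, np - recent)
    any(near & !exempt)
  }
  clearAhead <- function(x, y, heading, tree, startXY, chainStartIdx,
                         nAhead = 4) {
    for (s in seq_len(nAhead)) {
      px <- x + s * stepUm * cos(heading)
      py <- y + s * stepUm * sin(heading)
      if (px < 0 || px > extentUm || py < 0 || py > extentUm) return(TRUE)
      if (collides(px, py, tree, startXY, chainStartIdx)) return(FALSE)
    }
    TRUE
  }
  clipToBorder <- function(p0, p1) {
    # intersection of segment p0 -> p1 with the square border
    t <- 1
    if (p1[1] < 0) t <- min(t, (0 - p0[1]) / (p1[1] - p0[1]))
    if (p1[1] > extentUm) t <- min(t, (extentUm - p0[1]) / (p1[1] - p0[1]))
    if (p1[2] < 0) t <- min(t, (0 - p0[2]) / (p1[2] - p0[2]))
    if (p1[2] > extentUm) t <- min(t, (extentUm - p0[2]) / (p1[2] - p0[2]))
    p0 + t * (p1 - p0)
  }

  for (tree in seq_len(nTrees)) {
    entry <- NULL
    for (try in 1:50) {     # place the entry on a border, clear of others
      side <- sample.int(4L, 1L)
      u <- runif(1, 0.1, 0.9) * extentUm
      p <- switch(side, c(u, 0), c(extentUm, u), c(u, extentUm), c(0, u))
      normal <- switch(side, pi / 2, pi, 3 * pi / 2, 0)
      h <- normal + runif(1, -0.35, 0.35)
      if (!collides(p[1], p[2], tree, p, length(ptsX)) &&
          clearAhead(p[1], p[2], h, tree, p, length(ptsX))) {
        entry <- list(p = p, h = h); break
      }
    }
    if (is.null(entry)) next
    intensity <- runif(1, intensityRange[1], intensityRange[2])
    rootId <- addNode(entry$p[1], entry$p[2], "border", tree)
    queue <- list(list(startId = rootId, start = entry$p, heading = entry$h))
    while (length(queue)) {
      st <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      pts <- matrix(st$start, 1L)
      heading <- st$heading
      chainStart <- length(ptsX)
      endKind <- "endpoint"; splitHere <- FALSE
      borderDist <- function(p) min(p, extentUm - p)
      for (step in seq_len(maxSteps)) {
        heading <- heading + rnorm(1, 0, tortuosity)
        last <- pts[nrow(pts), ]
        cand <- last + stepUm * c(cos(heading), sin(heading))
        if (any(cand < 0) || any(cand > extentUm)) {
          hit <- clipToBorder(last, cand)
          # only near-perpendicular exits cross the field edge: a grazing
          # exit leaves a wedge whose medial axis is not resolvable at
          # pixel scale, so such fibres stop short of the border instead
          d <- c(cos(heading), sin(heading))
          outward <- max(abs(d[1]) * (hit[1] < 1e-9 || hit[1] > extentUm - 1e-9),
                         abs(d[2]) * (hit[2] < 1e-9 || hit[2] > extentUm - 1e-9))
          if (outward >= cos(50 * pi / 180)) {
            pts <- rbind(pts, hit)
            ptsX <- c(ptsX, hit[1]); ptsY <- c(ptsY, hit[2])
            ptsTree <- c(ptsTree, tree); ptsTip <- c(ptsTip, FALSE)
            endKind <- "border"
          }
          break
        }
        if (collides(cand[1], cand[2], tree, st$start, chainStart)) break
        pts <- rbind(pts, cand)
        ptsX <- c(ptsX, cand[1]); ptsY <- c(ptsY, cand[2])
        ptsTree <- c(ptsTree, tree); ptsTip <- c(ptsTip, FALSE)
        # a new chain must run ~12 um before it may branch, and junctions
        # stay clear of the field edge: junctions closer than ~10 px to
        # each other or to the border rasterise into blobs that no
        # medial-axis analysis can resolve
        if (step >= 12 && runif(1) < branchProb &&
            min(borderDist(cand[1]), borderDist(cand[2])) > 15) {
          sgn <- sample(c(-1, 1), 1L)
          hBranch <- heading + sgn * (branchAngle + rnorm(1, 0, 0.09))
          if (clearAhead(cand[1], cand[2], heading, tree, st$start,
                         chainStart, nAhead = 10) &&
              clearAhead(cand[1], cand[2], hBranch, tree, st$start,
                         chainStart, nAhead = 10)) {
            endKind <- "branch"; splitHere <- TRUE
            branchHeading <- hBranch
            break
          }
        }
      }
      if (endKind == "endpoint") {
        # an interior fibre end must be resolvable: keep it clear of the
        # border band (it would read as a border crossing) and at least
        # 5 um from every other stroke (closer tips fuse with the
        # neighbouring fibre at mask level); trim back until clear
        while (nrow(pts) >= 2L) {
          p <- pts[nrow(pts), ]
          clearBorder <- min(borderDist(p[1]), borderDist(p[2])) >= 6.5
          clearOthers <- chainStart == 0L ||
            min((ptsX[seq_len(chainStart)] - p[1])^2 +
                (ptsY[seq_len(chainStart)] - p[2])^2) >= 25
          if (clearBorder && clearOthers) break
          pts <- pts[-nrow(pts), , drop = FALSE]
          n <- length(ptsX)
          ptsX <- ptsX[-n]; ptsY <- ptsY[-n]
          ptsTree <- ptsTree[-n]; ptsTip <- ptsTip[-n]
        }
      }
      if (nrow(pts) < 2L) {
        # immediate dead end (rare): degenerate chain, drop it; the start
        # node keeps its other incident edges
        next
      }
      if (endKind == "endpoint" && length(ptsX) > chainStart)
        ptsTip[length(ptsX)] <- TRUE
      endId <- addNode(pts[nrow(pts), 1], pts[nrow(pts), 2], endKind, tree)
      eid <- eid + 1L
      edges[[eid]] <- data.frame(id = eid, from = st$startId, to = endId,
                                 lengthUm = polylineLength(pts), tree = tree)
      fibers[[eid]] <- list(points = pts, widthUm = widthUm,
                            peakIntensity = intensity, tree = tree)
      if (splitHere) {
        p <- pts[nrow(pts), ]
        queue[[length(queue) + 1L]] <-
          list(startId = endId, start = p, heading = heading)
        queue[[length(queue) + 1L]] <-
          list(startId = endId, start = p, heading = branchHeading)
      }
    }
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes) else emptyTruthNodes()
  edges <- if (length(edges)) do.call(rbind, edges) else emptyTruthEdges()
  # a dropped child chain can leave its branch node with degree 2: splice
  # the two remaining edges through it into one continuous fibre segment
  if (nrow(edges) && nrow(nodes)) {
    repeat {
      deg <- tabulate(c(edges$from, edges$to), nrow(nodes))
      cand <- which(nodes$kind == "branch" & deg == 2L)
      if (!length(cand)) break
      n <- cand[1L]
      ei <- which(edges$from == n | edges$to == n)
      e1 <- ei[1L]; e2 <- ei[2L]
      p1 <- fibers[[e1]]$points
      if (edges$from[e1] == n) {
        p1 <- p1[nrow(p1):1, , drop = FALSE]; a <- edges$to[e1]
      } else a <- edges$from[e1]
      p2 <- fibers[[e2]]$points
      if (edges$to[e2] == n) {
        p2 <- p2[nrow(p2):1, , drop = FALSE]; b <- edges$from[e2]
      } else b <- edges$to[e2]
      edges$from[e1] <- a; edges$to[e1] <- b
      edges$lengthUm[e1] <- edges$lengthUm[e1] + edges$lengthUm[e2]
      fibers[[e1]]$points <- rbind(p1, p2[-1L, , drop = FALSE])
      edges <- edges[-e2, , drop = FALSE]; fibers <- fibers[-e2]
      nodes$kind[n] <- "unused"  # now degree 0; dropped below
    }
  }
  # drop orphaned nodes; a branch left with one edge is a plain fibre end
  if (nrow(nodes)) {
    deg <- tabulate(c(edges$from, edges$to), nrow(nodes))
    nodes$kind[nodes$kind == "branch" & deg == 1L] <- "endpoint"
    keep <- deg > 0L
    if (!all(keep)) {
      remap <- integer(nrow(nodes)); remap[which(keep)] <- seq_len(sum(keep))
      nodes <- nodes[keep, , drop = FALSE]
      nodes$id <- remap[nodes$id]
      if (nrow(edges)) {
        edges$from <- remap[edges$from]; edges$to <- remap[edges$to]
      }
      rownames(nodes) <- NULL
    }
    if (nrow(edges)) { edges$id <- seq_len(nrow(edges)); rownames(edges) <- NULL }
  }
  SceneTruth(fibers, nodes, edges, extentUm, seed, noiseParams)
}

# digitize the polylines of a scene onto a pixel grid; returns a list with
# the centerline logical matrix and per-edge pixel index lists
digitizeCenterlines <- function(scene, pixelsPerSide) {
  n <- as.integer(pixelsPerSide)
  ps <- scene@extentUm / n
  cl <- matrix(FALSE, n, n)
  perEdge <- vector("list", length(scene@fibers))
  for (i in seq_along(scene@fibers)) {
    p <- scene@fibers[[i]]$points
    # resample finely so no pixel along the path is skipped
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    keep <- c(TRUE, seg > 0)
    p <- p[keep, , drop = FALSE]
    if (nrow(p) < 2L) { perEdge[[i]] <- integer(0); next }
    d <- c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] -
                                   p[-nrow(p), , drop = FALSE])^2))))
    s <- seq(0, d[length(d)], by = ps / 3)
    x <- stats::approx(d, p[, 1], xout = s)$y
    y <- stats::approx(d, p[, 2], xout = s)$y
    col <- pmin(pmax(floor(x / ps) + 1L, 1L), n)
    row <- pmin(pmax(floor(y / ps) + 1L, 1L), n)
    idx <- unique((col - 1L) * n + row)
    cl[idx] <- TRUE
    perEdge[[i]] <- idx
  }
  list(centerline = cl, perEdge = perEdge, pixelSizeUm = ps)
}

#' Rasterise the noiseless ground-truth fibre mask of a scene
#'
#' Pixels within half the stroke width of any centerline are foreground.
#'
#' @param scene a SceneTruth.
#' @param pixelsPerSide image side in pixels (default 384).
#' @return a \code{\link{FiberMask}}.
#' @export
rasterizeTruthMask <- function(scene, pixelsPerSide = 384) {
  stopifnot(is(scene, "SceneTruth"))
  dig <- digitizeCenterlines(scene, pixelsPerSide)
  n <- as.integer(pixelsPerSide)
  mask <- matrix(FALSE, n, n)
  if (any(dig$centerline)) {
    d <- EBImage::distmap(1 - dig$centerline)
    w <- max(vapply(scene@fibers, function(f) f$widthUm, numeric(1)), 0)
    mask <- as.matrix(d) <= w / (2 * dig$pixelSizeUm) + 1e-9
  }
  FiberMask(mask, scene@extentUm, scene@extentUm)
}

#' Render a scene to a confocal-like image
#'
#' Each fibre is drawn as a Gaussian-profile stroke (full width at half
#' maximum equal to its stroke width) at its peak intensity; the frame is
#' then blurred, modulated by multiplicative speckle, offset by the
#' background level and perturbed by additive Gaussian noise, all per the
#' scene's noise parameters. Deterministic for a fixed scene seed; pass
#' \code{noiseless = TRUE} to skip speckle/additive noise/background.
#'
#' @param scene a SceneTruth.
#' @param pixelsPerSide image side in pixels (>= 32, default 384).
#' @param noiseless render without noise or background.
#' @return a \code{\link{ConfocalImage}}.
#' @export
renderScene <- function(scene, pixelsPerSide = 384, noiseless = FALSE) {
  stopifnot(is(scene, "SceneTruth"))
  if (pixelsPerSide < 32) stop("pixelsPerSide must be >= 32")
  n <- as.integer(pixelsPerSide)
  dig <- digitizeCenterlines(scene, n)
  img <- matrix(0, n, n)
  for (i in seq_along(scene@fibers)) {
    idx <- dig$perEdge[[i]]
    if (length(idx) == 0L) next
    f <- scene@fibers[[i]]
    cl <- matrix(FALSE, n, n); cl[idx] <- TRUE
    d <- as.matrix(EBImage::distmap(1 - cl))
    sigmaPx <- (f$widthUm / dig$pixelSizeUm) / 2.355  # FWHM = stroke width
    img <- pmax(img, f$peakIntensity * exp(-d^2 / (2 * sigmaPx^2)))
  }
  np <- scene@noiseParams
  if (np$blurSigmaPx > 0 && any(img > 0))
    img <- as.matrix(EBImage::gblur(img, sigma = np$blurSigmaPx))
  if (!noiseless) {
    img <- withSeed(scene@seed + 1000003L, {
      sp <- img * (1 + matrix(rnorm(n * n, 0, np$speckleSd), n, n))
      sp + np$background + matrix(rnorm(n * n, 0, np$additiveSd), n, n)
    })
  }
  ConfocalImage(pmin(pmax(img, 0), 1), scene@extentUm, scene@extentUm,
                metadata = list(seed = scene@seed, noiseless = noiseless))
}

#' Ground-truth morphometry of a synthetic scene
#'
#' Computes the nine morphometric parameters analytically from the
#' generative truth: lengths from the stored polylines, counts from the
#' truth topology, and the two pixel counts from rasterisation of the
#' noiseless mask and digitized centerline. The density/length identity
#' NFD x area = total length holds exactly.
#'
#' @param scene a SceneTruth.
#' @param pixelsPerSide raster used for the pixel-count parameters.
#' @return a raw \code{\link{SNPMetrics}}.
#' @export
truthMetrics <- function(scene, pixelsPerSide = 384) {
  stopifnot(is(scene, "SceneTruth"))
  area <- scene@extentUm^2 / 1e6
  if (length(scene@fibers) == 0L)
    return(SNPMetrics(areaMm2 = area))
  dig <- digitizeCenterlines(scene, pixelsPerSide)
  totalUm <- sum(scene@edges$lengthUm)
  nEdge <- nrow(scene@edges)
  SNPMetrics(
    componentPixels = sum(maskMatrix(rasterizeTruthMask(scene,
                                                        pixelsPerSide))),
    nerveFibreComponents = length(unique(scene@edges$tree)),
    skeletonPixels = sum(dig$centerline),
    singleNerveFibres = nEdge,
    totalFibreLengthUm = totalUm,
    averageSingleFibreLengthUm = totalUm / nEdge,
    nerveFibreDensity = (totalUm / 1000) / area,
    connectivityPoints = sum(scene@nodes$kind == "border"),
    branches = sum(scene@nodes$kind == "branch"),
    areaMm2 = area, normalised = FALSE)
}

#' Write the ground truth of a scene as delimited tables
#'
#' @param scene a SceneTruth.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written (nodes, edges, metrics CSVs).
#' @export
writeTruthTables <- function(scene, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("nodes", "edges", "metrics"),
                                 ".csv"))
  utils::write.csv(scene@nodes, paths[1], row.names = FALSE)
  utils::write.csv(scene@edges, paths[2], row.names = FALSE)
  utils::write.csv(reportMetrics(truthMetrics(scene)), paths[3],
                   row.names = FALSE)
  invisible(paths)
}
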