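# 8-neighbour matrices of m in the order p2..p9 = N, NE, E, SE, S, SW, W, NW
# (value of the neighbour, placed at the centre pixel; off-image = FALSE)
neighborStack <- function(m) {
  list(p2 = shiftMat(m,  1,  0), p3 = shiftMat(m,  1, -1),
       p4 = shiftMat(m,  0, -1), p5 = shiftMat(m, -1, -1),
       p6 = shiftMat(m, -1,  0), p7 = shiftMat(m, -1,  1),
       p8 = shiftMat(m,  0,  1), p9 = shiftMat(m,  1,  1))
}

neighborCount <- function(m) {
  n <- neighborStack(m)
  Reduce(`+`, lapply(n, function(x) x * 1L))
}

# one Guo-Hall sub-iteration; returns the deletion mask
guoHallDelete <- function(m, oddIter) {
  n <- neighborStack(m)
  C <- (!n$p2 & (n$p3 | n$p4)) + (!n$p4 & (n$p5 | n$p6)) +
       (!n$p6 & (n$p7 | n$p8)) + (!n$p8 & (n$p9 | n$p2))
  N1 <- (n$p9 | n$p2) + (n$p3 | n$p4) + (n$p5 | n$p6) + (n$p7 | n$p8)
  N2 <- (n$p2 | n$p3) + (n$p4 | n$p5) + (n$p6 | n$p7) + (n$p8 | n$p9)
  Nm <- pmin(N1, N2)
  mm <- if (oddIter) (n$p6 | n$p7 | !n$p9) & n$p8
        else         (n$p2 | n$p3 | !n$p5) & n$p4
  m & C == 1 & Nm >= 2 & Nm <= 3 & !mm
}

# Hilditch crossing number: 0->1 transitions in the cyclic 8-neighbour ring
crossingNumber <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  at <- function(rr, cc)
    rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && m[rr, cc]
  ring <- c(at(r - 1, c), at(r - 1, c + 1), at(r, c + 1), at(r + 1, c + 1),
            at(r + 1, c), at(r + 1, c - 1), at(r, c - 1), at(r - 1, c - 1))
  sum(!ring & c(ring[-1], ring[1]))
}

# remove residual 2x2 foreground blocks by deleting simple pixels
dissolveSquares <- function(m) {
  repeat {
    blk <- m & shiftMat(m, -1, 0) & shiftMat(m, 0, -1) & shiftMat(m, -1, -1)
    idx <- which(blk)
    if (length(idx) == 0L) return(m)
    removed <- FALSE
    nr <- nrow(m)
    for (i in idx) {
      r0 <- ((i - 1L) %% nr) + 1L; c0 <- ((i - 1L) %/% nr) + 1L
      for (d in list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))) {
        r <- r0 + d[1L]; c <- c0 + d[2L]
        if (!m[r, c]) next
        if (crossingNumber(m, r, c) == 1L) {  # simple pixel: safe to delete
          m[r, c] <- FALSE
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (!removed) return(m)  # nothing deletable without topology change
  }
}

#' Skeletonise a fibre mask to its medial axis
#'
#' Topology-preserving Guo-Hall two-subiteration thinning reduces the
#' binary fibre mask to its one-pixel-wide medial axis: the skeleton is a
#' subset of the mask, has the same number of 8-connected components, and
#' contains no 2 x 2 block of foreground pixels (residual blocks left by
#' the parallel thinning are dissolved by deleting simple pixels).
#'
#' @param mask a \code{\link{FiberMask}} (or logical matrix).
#' @return a \code{\link{SkeletonMask}} (logical matrix input gives a
#'   logical matrix back).
#' @export
skeletonize <- function(mask) {
  plain <- is.matrix(mask)
  m <- if (plain) mask != 0 else maskMatrix(mask)
  repeat {
    changed <- FALSE
    for (oddIter in c(TRUE, FALSE)) {
      del <- guoHallDelete(m, oddIter)
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m <- dissolveSquares(m)
  if (plain) return(m)
  new("SkeletonMask", mask = m, widthUm = mask@widthUm,
      heightUm = mask@heightUm)
}
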