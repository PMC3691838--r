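#' Round half away from zero
#'
#' Deterministic commercial rounding used for all reported quantities
#' (base \code{round} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' roundHalfAway(0.5)       # 1, not 0
#' roundHalfAway(9.8625, 3) # 9.863
#' @export
roundHalfAway <- function(x, digits = 0) {
  p <- 10^digits
  # the 1e-9 guard absorbs binary representation error in exact halves
  # (e.g. 9.8625 * 1000 stored as 9862.4999...)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Label connected components of a binary matrix
#'
#' 8-connected (default) or 4-connected component labelling. Labels are
#' positive integers in raster order of each component's first pixel;
#' background is 0.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same dimension with component labels.
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  idx <- which(m)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))                 # S, E
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))  # SE, NE
  ei <- integer(0); ej <- integer(0)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  for (o in offs) {
    r2 <- rr + o[1L]; c2 <- cc + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- m[nb]
    ei <- c(ei, vid[idx[ok][hit]])
    ej <- c(ej, vid[nb[hit]])
  }
  g <- igraph::make_graph(rbind(ei, ej), n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel in raster order of first occurrence
  first <- !duplicated(memb)
  remap <- integer(max(memb))
  remap[memb[first]] <- seq_len(sum(first))
  lab[idx] <- remap[memb]
  lab
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards (no global random state is disturbed).
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# shift a matrix by (dr, dc), filling vacated cells with `fill`
shiftMat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}
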