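# Fixtures built in code: small deterministic scenes and hand-made masks.

# Y-shaped truth scene: three 100-um arms meeting at the centre of a
# 400 x 400 um field (one border entry is deliberately absent: all three
# arm ends are interior endpoints).
makeYScene <- function() {
  cx <- 200; cy <- 200
  arm <- function(angle) {
    s <- seq(0, 100, by = 1)
    cbind(cx + s * cos(angle), cy + s * sin(angle))
  }
  fib <- lapply(c(pi / 2, pi + pi / 6, -pi / 6), function(a)
    list(points = arm(a), widthUm = 2 * 400 / 384, peakIntensity = 0.9,
         tree = 1L))
  nodes <- data.frame(
    id = 1:4,
    x = c(cx, fib[[1]]$points[101, 1], fib[[2]]$points[101, 1],
          fib[[3]]$points[101, 1]),
    y = c(cy, fib[[1]]$points[101, 2], fib[[2]]$points[101, 2],
          fib[[3]]$points[101, 2]),
    kind = c("branch", "endpoint", "endpoint", "endpoint"),
    tree = 1L)
  edges <- data.frame(id = 1:3, from = 1L, to = 2:4,
                      lengthUm = c(100, 100, 100), tree = 1L)
  SceneTruth(fib, nodes, edges, extentUm = 400, seed = 99L)
}

# single straight border-to-border horizontal fibre across 400 um
makeStraightScene <- function() {
  pts <- cbind(seq(0, 400, by = 1), 200)
  fib <- list(list(points = pts, widthUm = 2 * 400 / 384,
                   peakIntensity = 1, tree = 1L))
  nodes <- data.frame(id = 1:2, x = c(0, 400), y = 200,
                      kind = "border", tree = 1L)
  edges <- data.frame(id = 1L, from = 1L, to = 2L, lengthUm = 400,
                      tree = 1L)
  SceneTruth(fib, nodes, edges, extentUm = 400, seed = 7L)
}

emptyScene <- function()
  SceneTruth(list(), cornealSNP:::emptyTruthNodes(),
             cornealSNP:::emptyTruthEdges(), extentUm = 400, seed = 1L)

# skeleton-grade mask: horizontal 1-px line with a short vertical spur
lineWithSpurMask <- function() {
  m <- matrix(FALSE, 60, 60)
  m[30, 5:55] <- TRUE
  m[29:26, 31] <- TRUE   # 4-px spur, 4 um at 1 um pixels
  new("SkeletonMask", mask = m, widthUm = 60, heightUm = 60)
}
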