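test_that("thinning produces a one-pixel-wide subset with preserved topology", {
  expect_equal(sum(skeletonize(matrix(FALSE, 20, 20))), 0)

  # 3-px-wide bar spans the image -> single 1-px line on the middle row
  bar <- matrix(FALSE, 30, 30); bar[14:16, ] <- TRUE
  sk <- skeletonize(bar)
  expect_true(all(which(sk, arr.ind = TRUE)[, 1] == 15))

  for (s in c(1, 12, 33)) {
    sc <- generateScene(seed = s, nTrees = 3, extentUm = 200)
    m <- maskMatrix(rasterizeTruthMask(sc, 192))
    sk <- skeletonize(m)
    expect_true(all(m[sk]))                                     # subset
    no22 <- !any(sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
                 sk[-nrow(sk), -1] & sk[-1, -1])
    expect_true(no22)                                           # 1-px wide
    expect_equal(max(labelComponents(sk)), max(labelComponents(m)))
  }
})

test_that("straight and diagonal chains get exact chain-code lengths", {
  m <- matrix(FALSE, 120, 120); m[60, 11:110] <- TRUE
  g <- buildGraph(new("SkeletonMask", mask = m, widthUm = 120,
                      heightUm = 120), pruneUm = 0)
  expect_equal(nrow(graphEdges(g)), 1)
  expect_equal(graphEdges(g)$lengthUm, 99)
  expect_equal(sort(graphNodes(g)$kind), c("endpoint", "endpoint"))

  d <- matrix(FALSE, 120, 120); d[cbind(11:110, 11:110)] <- TRUE
  gd <- buildGraph(new("SkeletonMask", mask = d, widthUm = 120,
                       heightUm = 120), pruneUm = 0)
  expect_equal(graphEdges(gd)$lengthUm, 99 * sqrt(2), tolerance = 1e-12)
})

test_that("a Y-skeleton gives one branch node, three endpoints, three edges", {
  m <- matrix(FALSE, 60, 60)
  m[30, 10:30] <- TRUE
  m[cbind(30 - 1:20, 30 + 1:20)] <- TRUE
  m[cbind(30 + 1:20, 30 + 1:20)] <- TRUE
  g <- buildGraph(new("SkeletonMask", mask = m, widthUm = 60,
                      heightUm = 60), pruneUm = 0)
  k <- table(graphNodes(g)$kind)
  expect_equal(unname(k["branch"]), 1)
  expect_equal(unname(k["endpoint"]), 3)
  expect_equal(nrow(graphEdges(g)), 3)
})

test_that("isolated cycles get one anchor node and a self-loop edge", {
  m <- matrix(FALSE, 40, 40)
  th <- seq(0, 2 * pi, length.out = 200)
  m[cbind(round(20 + 10 * sin(th)), round(20 + 10 * cos(th)))] <- TRUE
  g <- buildGraph(skeletonize(new("FiberMask", mask = m, widthUm = 40,
                                  heightUm = 40)), pruneUm = 0)
  expect_equal(graphNodes(g)$kind, "anchor")
  expect_equal(nrow(graphEdges(g)), 1)
  expect_equal(graphEdges(g)$from, graphEdges(g)$to)
})

test_that("pixel conservation and the handshake identity hold on generated scenes", {
  for (s in c(3, 18)) {
    sc <- generateScene(seed = s, nTrees = 3, extentUm = 250)
    g <- buildGraph(skeletonize(rasterizeTruthMask(sc, 240)), pruneUm = 0)
    px <- unique(rbind(do.call(rbind, g@chains),
                       do.call(rbind, g@nodePixels)))
    expect_equal(nrow(px), g@skeletonPixels)
    expect_equal(sum(graphNodes(g)$degree) / 2, nrow(graphEdges(g)))
    # chain-code bounds: every edge length within [steps, sqrt(2) steps] px
    e <- graphEdges(g)
    ps <- pixelSizeUm(g)
    expect_true(all(e$lengthUm >= e$steps * ps - 1e-9))
    expect_true(all(e$lengthUm <= e$steps * ps * sqrt(2) + 1e-9))
  }
})

test_that("spur pruning removes short endpoint twigs and re-derives the graph once", {
  sk <- lineWithSpurMask()
  g0 <- buildGraph(sk, pruneUm = 0)
  expect_equal(nrow(graphEdges(g0)), 3)
  expect_equal(sum(graphNodes(g0)$kind == "branch"), 1)
  g5 <- buildGraph(sk, pruneUm = 5)
  expect_equal(nrow(graphEdges(g5)), 1)
  expect_equal(sum(graphNodes(g5)$kind == "branch"), 0)
  # border-touching ends are never pruned
  expect_equal(sum(graphNodes(g5)$kind %in% c("endpoint", "border")), 2)
})

test_that("a 2x2 block is rejected as input and graph export writes tables", {
  m <- matrix(FALSE, 10, 10); m[4:5, 4:5] <- TRUE
  expect_error(buildGraph(new("SkeletonMask", mask = m, widthUm = 10,
                              heightUm = 10)), "one pixel")
  g <- buildGraph(lineWithSpurMask(), pruneUm = 0)
  nf <- withr::local_tempfile(fileext = ".csv")
  ef <- withr::local_tempfile(fileext = ".csv")
  writeGraphTables(g, nf, ef)
  expect_equal(nrow(read.csv(ef)), nrow(graphEdges(g)))
})
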