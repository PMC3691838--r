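# step cost between two 8-adjacent pixels, in pixel units
stepCost <- function(r1, c1, r2, c2)
  ifelse(r1 != r2 & c1 != c2, sqrt(2), 1)

# neighbour linear indices of pixel (r, c) that are foreground, in fixed order
fgNeighbors <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  rr <- r + dr; cc <- c + dc
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  ok[ok] <- m[cbind(rr[ok], cc[ok])]
  cbind(rr[ok], cc[ok])
}

# single pass of graph extraction from a 1-px skeleton (no pruning)
traceGraph <- function(sk, pixelSizeUm, borderBandPx = 2L) {
  nr <- nrow(sk); nc <- ncol(sk)
  nb <- neighborCount(sk)
  fgIdx <- which(sk)
  comp <- labelComponents(sk, connectivity = 8)
  nComp <- max(comp, 0L)

  isBranchPx <- sk & nb >= 3L
  isEndPx <- sk & nb <= 1L          # endpoints and isolated pixels
  isNodePx <- isBranchPx | isEndPx
  isChainPx <- sk & nb == 2L

  # node table: endpoints one per pixel, branch clusters merged to centroid
  nodeIdAt <- matrix(0L, nr, nc)
  nodes <- list(); nodePixels <- list(); nid <- 0L
  epIdx <- which(isEndPx)
  for (i in epIdx) {
    r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
    nid <- nid + 1L
    nodeIdAt[i] <- nid
    onBorder <- r <= borderBandPx || r > nr - borderBandPx ||
      c <= borderBandPx || c > nc - borderBandPx
    kind <- if (onBorder && nb[i] == 1L) "border" else "endpoint"
    nodes[[nid]] <- data.frame(id = nid, row = r, col = c, kind = kind,
                               component = comp[i])
    nodePixels[[nid]] <- cbind(r, c)
  }
  if (any(isBranchPx)) {
    bl <- labelComponents(isBranchPx, connectivity = 8)
    for (b in seq_len(max(bl))) {
      px <- which(bl == b)
      r <- ((px - 1L) %% nr) + 1L; c <- ((px - 1L) %/% nr) + 1L
      nid <- nid + 1L
      nodeIdAt[px] <- nid
      nodes[[nid]] <- data.frame(id = nid, row = mean(r), col = mean(c),
                                 kind = "branch", component = comp[px[1]])
      nodePixels[[nid]] <- cbind(r, c)
    }
  }

  edges <- list(); chains <- list(); eid <- 0L
  addEdge <- function(from, to, path) {
    eid <<- eid + 1L
    len <- if (nrow(path) < 2L) 0 else
      sum(stepCost(path[-nrow(path), 1], path[-nrow(path), 2],
                   path[-1, 1], path[-1, 2])) * pixelSizeUm
    edges[[eid]] <<- data.frame(id = eid, from = from, to = to,
                                steps = nrow(path) - 1L, lengthUm = len,
                                component = comp[path[1, 1], path[1, 2]])
    chains[[eid]] <<- path
  }

  visited <- matrix(FALSE, nr, nc)   # chain pixels consumed by a trace
  nodePxIdx <- which(isNodePx)
  # direct node-pixel adjacencies across different nodes (no chain between)
  for (i in nodePxIdx) {
    r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
    nbs <- fgNeighbors(sk, r, c)
    for (k in seq_len(nrow(nbs))) {
      j <- (nbs[k, 2] - 1L) * nr + nbs[k, 1]
      if (j <= i || !isNodePx[j]) next     # each unordered pair once
      if (nodeIdAt[i] == nodeIdAt[j]) next # internal to one branch cluster
      addEdge(nodeIdAt[i], nodeIdAt[j],
              rbind(c(r, c), nbs[k, , drop = FALSE]))
    }
  }
  # chains from node pixels
  for (i in nodePxIdx) {
    r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
    nbs <- fgNeighbors(sk, r, c)
    for (k in seq_len(nrow(nbs))) {
      j <- (nbs[k, 2] - 1L) * nr + nbs[k, 1]
      if (!isChainPx[j] || visited[j]) next
      path <- matrix(c(r, c), 1L)
      prevR <- r; prevC <- c
      curR <- nbs[k, 1]; curC <- nbs[k, 2]
      repeat {
        path <- rbind(path, c(curR, curC))
        if (isNodePx[curR + (curC - 1L) * nr]) break
        visited[curR, curC] <- TRUE
        nxt <- fgNeighbors(sk, curR, curC)
        nxt <- nxt[!(nxt[, 1] == prevR & nxt[, 2] == prevC), , drop = FALSE]
        # a chain pixel has exactly two neighbours; if both ends of a
        # 1-chain touch node pixels diagonally + orthogonally, prefer any
        prevR <- curR; prevC <- curC
        curR <- nxt[1, 1]; curC <- nxt[1, 2]
      }
      addEdge(nodeIdAt[r, c], nodeIdAt[curR, curC], path)
    }
  }
  # isolated cycles: components of chain pixels never reached from a node
  left <- which(isChainPx & !visited)
  while (length(left)) {
    i <- left[1]
    r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
    nid <- nid + 1L                    # artificial degree-2 anchor
    nodeIdAt[i] <- nid
    nodes[[nid]] <- data.frame(id = nid, row = r, col = c, kind = "anchor",
                               component = comp[i])
    nodePixels[[nid]] <- cbind(r, c)
    isNodePx[i] <- TRUE; isChainPx[i] <- FALSE
    nbs <- fgNeighbors(sk, r, c)
    path <- matrix(c(r, c), 1L)
    prevR <- r; prevC <- c
    curR <- nbs[1, 1]; curC <- nbs[1, 2]
    repeat {
      path <- rbind(path, c(curR, curC))
      if (curR == r && curC == c) break
      visited[curR, curC] <- TRUE
      nxt <- fgNeighbors(sk, curR, curC)
      nxt <- nxt[!(nxt[, 1] == prevR & nxt[, 2] == prevC), , drop = FALSE]
      prevR <- curR; prevC <- curC
      curR <- nxt[1, 1]; curC <- nxt[1, 2]
    }
    addEdge(nid, nid, path)
    left <- which(isChainPx & !visited)
  }

  nodes <- if (length(nodes)) do.call(rbind, nodes) else
    data.frame(id = integer(), row = numeric(), col = numeric(),
               kind = character(), component = integer())
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(id = integer(), from = integer(), to = integer(),
               steps = integer(), lengthUm = numeric(),
               component = integer())

  # junction consolidation: thinning can realise one anatomical junction
  # as two branch clusters joined by a 1-3 px chain; contract such chains
  # into a single branch node (their pixels become node pixels)
  repeat {
    cand <- which(edges$from != edges$to & edges$steps <= 3L &
                  nodes$kind[edges$from] == "branch" &
                  nodes$kind[edges$to] == "branch")
    if (!length(cand)) break
    e <- cand[1L]
    a <- edges$from[e]; b <- edges$to[e]
    path <- chains[[e]]
    interior <- if (nrow(path) > 2L)
      path[-c(1L, nrow(path)), , drop = FALSE] else NULL
    nodePixels[[a]] <- unique(rbind(nodePixels[[a]], nodePixels[[b]],
                                    interior))
    nodePixels[[b]] <- cbind(integer(0), integer(0))
    nodes$row[a] <- mean(nodePixels[[a]][, 1])
    nodes$col[a] <- mean(nodePixels[[a]][, 2])
    nodes$kind[b] <- "dead"
    edges <- edges[-e, , drop = FALSE]; chains <- chains[-e]
    edges$from[edges$from == b] <- a
    edges$to[edges$to == b] <- a
  }
  # pixel-scale self-loops on a branch node are junction artifacts
  # (thinning can leave a small hole where three strokes meet); absorb
  # them into the node
  if (nrow(edges)) {
    tiny <- which(edges$from == edges$to & edges$steps <= 6L &
                  nodes$kind[edges$from] == "branch")
    if (length(tiny)) {
      for (e in tiny) {
        path <- chains[[e]]
        interior <- if (nrow(path) > 2L)
          path[-c(1L, nrow(path)), , drop = FALSE] else NULL
        a <- edges$from[e]
        nodePixels[[a]] <- unique(rbind(nodePixels[[a]], interior))
      }
      edges <- edges[-tiny, , drop = FALSE]; chains <- chains[-tiny]
      if (nrow(edges)) edges$id <- seq_len(nrow(edges))
      rownames(edges) <- NULL
    }
  }
  # a branch node left with exactly two incident edges is no junction
  # (e.g. after a spur was consumed): splice its edges into one chain and
  # keep its pixels with the merged edge
  if (nrow(edges)) {
    repeat {
      deg <- tabulate(edges$from, nrow(nodes)) +
        tabulate(edges$to, nrow(nodes))
      cand <- which(nodes$kind == "branch" & deg == 2L)
      cand <- cand[vapply(cand, function(n) {
        ei <- which(edges$from == n | edges$to == n)
        length(ei) == 2L
      }, logical(1))]
      if (!length(cand)) break
      n <- cand[1L]
      ei <- which(edges$from == n | edges$to == n)
      e1 <- ei[1L]; e2 <- ei[2L]
      p1 <- chains[[e1]]
      if (edges$from[e1] == n) {
        p1 <- p1[nrow(p1):1, , drop = FALSE]; a <- edges$to[e1]
      } else a <- edges$from[e1]
      p2 <- chains[[e2]]
      if (edges$to[e2] == n) {
        p2 <- p2[nrow(p2):1, , drop = FALSE]; b <- edges$from[e2]
      } else b <- edges$to[e2]
      # p1 ends and p2 begins on (possibly different) pixels of cluster n
      A <- p1[nrow(p1), ]; B <- p2[1L, ]
      joinLen <- if (all(A == B)) 0 else
        stepCost(A[1], A[2], B[1], B[2]) * pixelSizeUm
      extra <- nodePixels[[n]]
      extra <- extra[!(paste(extra[, 1], extra[, 2]) %in%
                       paste(c(p1[, 1], p2[, 1]), c(p1[, 2], p2[, 2]))), ,
                     drop = FALSE]
      edges$from[e1] <- a; edges$to[e1] <- b
      edges$steps[e1] <- edges$steps[e1] + edges$steps[e2] +
        as.integer(joinLen > 0)
      edges$lengthUm[e1] <- edges$lengthUm[e1] + edges$lengthUm[e2] +
        joinLen
      chains[[e1]] <- rbind(p1, if (all(A == B)) p2[-1L, , drop = FALSE]
                            else p2, extra)
      nodePixels[[n]] <- cbind(integer(0), integer(0))
      nodes$kind[n] <- "dead"
      edges <- edges[-e2, , drop = FALSE]; chains <- chains[-e2]
    }
  }
  if (any(nodes$kind == "dead")) {
    keep <- nodes$kind != "dead"
    remap <- integer(nrow(nodes)); remap[which(keep)] <- seq_len(sum(keep))
    nodes <- nodes[keep, , drop = FALSE]
    nodePixels <- nodePixels[keep]
    nodes$id <- remap[nodes$id]
    if (nrow(edges)) {
      edges$from <- remap[edges$from]; edges$to <- remap[edges$to]
      edges$id <- seq_len(nrow(edges))
    }
    rownames(nodes) <- NULL; rownames(edges) <- NULL
  }

  deg <- integer(nrow(nodes))
  if (nrow(edges)) {
    t1 <- tabulate(edges$from, nrow(nodes))
    t2 <- tabulate(edges$to, nrow(nodes))
    deg <- t1 + t2                      # self-loops count twice
  }
  nodes$degree <- deg
  nodes <- nodes[, c("id", "row", "col", "kind", "degree", "component")]
  new("SkeletonGraph", nodes = nodes, edges = edges, chains = chains,
      nodePixels = nodePixels, skeletonPixels = length(fgIdx),
      nComponents = nComp, pixelSizeUm = pixelSizeUm, dim = c(nr, nc))
}

#' Build the medial-axis network graph of a skeleton
#'
#' Stage 2 of the quantification pipeline. Skeleton pixels are classified
#' by 8-neighbour count (1 neighbour: endpoint; >= 3: branch candidate;
#' adjacent branch candidates merge into a single branch node at their
#' centroid, since thinning otherwise inflates branch counts). Edges are
#' the pixel chains traced between nodes; isolated cycles receive one
#' artificial degree-2 anchor node. Edge length is chain-code length: an
#' orthogonal step counts one pixel size, a diagonal step sqrt(2) pixel
#' sizes. Degree-1 pixels on the outermost image row/column are border
#' nodes (fibres entering or leaving the image area).
#'
#' Spur pruning: edges incident to an (interior) endpoint shorter than
#' \code{pruneUm} are removed and the graph re-derived once — thinning
#' produces 1-3 px spurs that would otherwise inflate single-fibre counts.
#' Set \code{pruneUm = 0} to disable (as done in the synthetic
#' oracle-equivalence tests).
#'
#' The border band is \code{borderBandPx} = 2 pixels by default: thinning
#' necessarily retracts the blunt end of a stroke cut by the field edge by
#' about half the stroke width, so a medial-axis end within half a fibre
#' width of the boundary corresponds to a fibre crossing it.
#'
#' @param skeleton a \code{\link{SkeletonMask}}.
#' @param pruneUm spur-length threshold in um (default 5; 0 disables).
#' @param borderBandPx width in px of the boundary band within which a
#'   degree-1 node counts as a border node (default 2).
#' @return a \code{\link{SkeletonGraph}}.
#' @export
buildGraph <- function(skeleton, pruneUm = 5, borderBandPx = 2L) {
  stopifnot(is(skeleton, "SkeletonMask"))
  m <- maskMatrix(skeleton)
  if (any(m & shiftMat(m, -1, 0) & shiftMat(m, 0, -1) & shiftMat(m, -1, -1)))
    stop("skeleton is not one pixel wide (2x2 foreground block present)")
  ps <- pixelSizeUm(skeleton)
  g <- traceGraph(m, ps, borderBandPx)
  if (pruneUm <= 0 || nrow(g@edges) == 0L) return(g)
  epIds <- g@nodes$id[g@nodes$kind == "endpoint" & g@nodes$degree == 1L]
  spur <- g@edges$lengthUm < pruneUm &
    (g@edges$from %in% epIds | g@edges$to %in% epIds)
  if (!any(spur)) return(g)
  nr <- nrow(m)
  for (e in which(spur)) {
    path <- g@chains[[e]]
    ends <- c(g@edges$from[e], g@edges$to[e])
    # drop chain interior plus any endpoint-node end pixels; keep pixels of
    # surviving (non-endpoint) end nodes
    keepFirst <- !(ends[1] %in% epIds)
    keepLast <- !(ends[2] %in% epIds)
    rows <- seq_len(nrow(path))
    if (keepFirst) rows <- rows[-1]
    if (keepLast && length(rows)) rows <- rows[-length(rows)]
    if (length(rows)) m[path[rows, , drop = FALSE]] <- FALSE
  }
  traceGraph(m, ps, borderBandPx)
}

#' Export a skeleton graph as node and edge tables
#'
#' @param graph a SkeletonGraph.
#' @param nodePath,edgePath destination CSV paths.
#' @return invisibly, a list with the two data.frames written.
#' @export
writeGraphTables <- function(graph, nodePath, edgePath) {
  stopifnot(is(graph, "SkeletonGraph"))
  utils::write.csv(graph@nodes, nodePath, row.names = FALSE)
  utils::write.csv(graph@edges, edgePath, row.names = FALSE)
  invisible(list(nodes = graph@nodes, edges = graph@edges))
}
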