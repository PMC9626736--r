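# Quadric edge-collapse mesh decimation with nearest-source attribute transfer.
#
# Greedy multiple-choice variant: each round ranks all candidate edges by
# quadric error, collapses a lowest-cost independent set (no shared vertices),
# and repeats until the vertex budget is met. Boundary (basal-rim) vertices
# only merge along the boundary so the open base is preserved.

# symmetric 4x4 quadric per vertex, stored as n x 10:
# (q11,q12,q13,q14,q22,q23,q24,q33,q34,q44)
vertexQuadrics <- function(v, f) {
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  area <- nn / 2
  ok <- nn > 1e-12
  nx <- ifelse(ok, nx / nn, 0); ny <- ifelse(ok, ny / nn, 0); nz <- ifelse(ok, nz / nn, 0)
  d <- -(nx * p1[, 1] + ny * p1[, 2] + nz * p1[, 3])
  w <- area
  K <- cbind(nx * nx, nx * ny, nx * nz, nx * d,
             ny * ny, ny * nz, ny * d,
             nz * nz, nz * d, d * d) * w
  Q <- matrix(0, nrow(v), 10)
  for (j in 1:3) {
    agg <- rowsum(K, group = f[, j], reorder = FALSE)
    idx <- as.integer(rownames(agg))
    Q[idx, ] <- Q[idx, ] + agg
  }
  Q
}

# evaluate [x,1] Q [x,1]^T for rows of Q and matching rows of pts
quadricCost <- function(Q, pts) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  Q[, 1] * x^2 + 2 * Q[, 2] * x * y + 2 * Q[, 3] * x * z + 2 * Q[, 4] * x +
    Q[, 5] * y^2 + 2 * Q[, 6] * y * z + 2 * Q[, 7] * y +
    Q[, 8] * z^2 + 2 * Q[, 9] * z + Q[, 10]
}

# unique undirected edges and, as attribute, whether each is a boundary edge
meshEdges <- function(f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  uq <- !duplicated(key)
  edges <- cbind(pmin(e[uq, 1], e[uq, 2]), pmax(e[uq, 1], e[uq, 2]))
  boundary <- as.integer(cnt[key[uq]]) == 1L
  list(edges = edges, boundary = boundary)
}

#' Decimate an LV mesh to a target vertex count
#'
#' Reduces mesh resolution by quadric-error edge collapse, e.g. to obtain the
#' low-resolution (about 358-vertex) geometry from the high-resolution
#' (3648-vertex) one. After simplification, per-vertex attributes (perfusion,
#' segment labels) are resampled by nearest original vertex.
#'
#' @param mesh an [LVMesh-class].
#' @param targetVertexCount desired vertex count, between 4 and the current
#'   count. The result is within 2% of the target.
#' @return the decimated [LVMesh-class].
#' @examples
#' hi <- makeLVMesh(nVertices = 600, seed = 1)
#' lo <- decimateMesh(hi, 150)
#' nVertices(lo)
#' @export
decimateMesh <- function(mesh, targetVertexCount) {
  stopifnot(is(mesh, "LVMesh"))
  target <- as.integer(targetVertexCount)
  n0 <- nrow(mesh@vertices)
  if (target < 4L) stop("targetVertexCount must be at least 4")
  if (target > n0) stop("targetVertexCount exceeds current vertex count (", n0, ")")
  if (target == n0) return(mesh)

  v <- mesh@vertices
  f <- mesh@faces
  origV <- mesh@vertices
  Q <- vertexQuadrics(v, f)

  nv <- nrow(v)
  maxRounds <- 200L
  for (round in seq_len(maxRounds)) {
    if (nv <= target) break
    ed <- meshEdges(f)
    edges <- ed$edges
    bVert <- rep(FALSE, nrow(v))
    bVert[unique(as.vector(ed$edges[ed$boundary, , drop = FALSE]))] <- TRUE
    a <- edges[, 1]; b <- edges[, 2]

    # candidate collapse positions: endpoint a, endpoint b, midpoint;
    # boundary vertices may only move along the boundary
    aB <- bVert[a]; bB <- bVert[b]
    allow <- !(aB & bB) | ed$boundary       # interior-interior, mixed, or rim edge
    pa <- v[a, , drop = FALSE]
    pb <- v[b, , drop = FALSE]
    pm <- (pa + pb) / 2
    Qe <- Q[a, , drop = FALSE] + Q[b, , drop = FALSE]
    ca <- quadricCost(Qe, pa)
    cb <- quadricCost(Qe, pb)
    cm <- quadricCost(Qe, pm)
    # mixed boundary/interior: pin to the boundary endpoint
    ca[!aB & bB] <- Inf
    cb[aB & !bB] <- Inf
    cm[xor(aB, bB)] <- Inf
    best <- pmin(ca, cb, cm)
    pos <- pm
    useA <- ca <= cb & ca <= cm
    useB <- !useA & cb <= cm
    pos[useA, ] <- pa[useA, , drop = FALSE]
    pos[useB, ] <- pb[useB, , drop = FALSE]
    cost <- ifelse(allow, best, Inf)

    need <- nv - target
    ord <- order(cost)
    used <- rep(FALSE, nrow(v))
    selA <- integer(0); selB <- integer(0)
    selPos <- matrix(0, 0, 3)
    taken <- 0L
    for (k in ord) {
      if (taken >= need) break
      if (!is.finite(cost[k])) break
      i <- a[k]; j <- b[k]
      if (used[i] || used[j]) next
      used[i] <- TRUE; used[j] <- TRUE
      selA <- c(selA, i); selB <- c(selB, j)
      selPos <- rbind(selPos, pos[k, ])
      taken <- taken + 1L
    }
    if (taken == 0L) break

    # merge b into a, move a to the chosen position, add quadrics
    map <- seq_len(nrow(v))
    map[selB] <- selA
    v[selA, ] <- selPos
    Q[selA, ] <- Q[selA, , drop = FALSE] + Q[selB, , drop = FALSE]
    f <- matrix(map[f], ncol = 3)
    degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    f <- f[!degen, , drop = FALSE]
    fk <- apply(f, 1, function(r) paste(sort(r), collapse = "-"))
    f <- f[!duplicated(fk), , drop = FALSE]

    keep <- sort(unique(as.vector(f)))
    reindex <- integer(nrow(v))
    reindex[keep] <- seq_along(keep)
    v <- v[keep, , drop = FALSE]
    Q <- Q[keep, , drop = FALSE]
    f <- matrix(reindex[f], ncol = 3)
    nv <- nrow(v)
  }

  # nearest-original-vertex attribute transfer
  perf <- lab <- NULL
  if (!is.null(mesh@perfusion) || !is.null(mesh@segmentLabels)) {
    nn <- nearestNeighbor(v, origV)$index
    if (!is.null(mesh@perfusion)) perf <- mesh@perfusion[nn]
    if (!is.null(mesh@segmentLabels)) lab <- mesh@segmentLabels[nn]
  }
  storage.mode(f) <- "integer"
  LVMesh(v, f, apex = mesh@apex, baseCentroid = mesh@baseCentroid,
         longAxis = mesh@longAxis, perfusion = perf, segmentLabels = lab)
}
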