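# Core mesh representation and accessors.

#' Construct an LV endocardial mesh
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param apex numeric(3) apex position (mm).
#' @param baseCentroid numeric(3) centroid of the basal rim (mm).
#' @param longAxis numeric(3); normalised internally. If missing, taken as
#'   the unit vector from `baseCentroid` to `apex`.
#' @param perfusion optional per-vertex uptake fraction in [0, 1].
#' @param segmentLabels optional per-vertex AHA segment in 1..17.
#' @return an [LVMesh-class].
#' @examples
#' m <- makeLVMesh(nVertices = 400, seed = 1)
#' m
#' @export
LVMesh <- function(vertices, faces, apex, baseCentroid, longAxis = NULL,
                   perfusion = NULL, segmentLabels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (is.null(longAxis)) longAxis <- apex - baseCentroid
  nrm <- sqrt(sum(longAxis^2))
  if (nrm < 1e-9)
    stop("invalid geometry: apex and base centroid coincide (degenerate long axis)")
  longAxis <- longAxis / nrm
  if (!is.null(segmentLabels)) segmentLabels <- as.integer(segmentLabels)
  new("LVMesh", vertices = vertices, faces = faces, apex = as.numeric(apex),
      baseCentroid = as.numeric(baseCentroid), longAxis = as.numeric(longAxis),
      perfusion = perfusion, segmentLabels = segmentLabels)
}

#' @rdname nVertices
#' @export
setMethod("nVertices", "LVMesh", function(x) nrow(x@vertices))

#' @rdname mesh-accessors
#' @export
setMethod("vertices", "LVMesh", function(x) x@vertices)

#' @rdname mesh-accessors
#' @export
setMethod("faces", "LVMesh", function(x) x@faces)

#' @rdname mesh-accessors
#' @export
setMethod("perfusion", "LVMesh", function(x) x@perfusion)

#' @rdname mesh-accessors
#' @export
setMethod("perfusion<-", "LVMesh", function(x, value) {
  x@perfusion <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname mesh-accessors
#' @export
setMethod("segmentLabels", "LVMesh", function(x) x@segmentLabels)

#' @rdname mesh-accessors
#' @export
setMethod("segmentLabels<-", "LVMesh", function(x, value) {
  x@segmentLabels <- as.integer(value)
  validObject(x)
  x
})

setMethod("show", "LVMesh", function(object) {
  cat(sprintf("LVMesh: %d vertices, %d faces\n", nrow(object@vertices), nrow(object@faces)))
  cat(sprintf("  long axis length: %.1f mm\n",
              sqrt(sum((object@apex - object@baseCentroid)^2))))
  cat(sprintf("  perfusion: %s; segment labels: %s\n",
              if (is.null(object@perfusion)) "unset" else
                sprintf("[%.2f, %.2f]", min(object@perfusion), max(object@perfusion)),
              if (is.null(object@segmentLabels)) "unset" else
                sprintf("%d segments", length(unique(object@segmentLabels)))))
  invisible(object)
})

#' Total surface area of a triangle mesh
#'
#' @param mesh an [LVMesh-class].
#' @return area in mm^2.
#' @export
surfaceArea <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Is the mesh a single connected component?
#'
#' @param mesh an [LVMesh-class].
#' @return logical.
#' @export
isConnectedMesh <- function(mesh) {
  n <- nrow(mesh@vertices)
  if (n == 0L) return(TRUE)
  f <- mesh@faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  # union-find over edges
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  length(unique(roots)) == 1L
}

# axial fraction of each point: 0 at the base plane, 1 at the apex
axialFraction <- function(mesh, pts = mesh@vertices) {
  L <- sum((mesh@apex - mesh@baseCentroid) * mesh@longAxis)
  if (abs(L) < 1e-9)
    stop("invalid geometry: apex and base centroid coincide (degenerate long axis)")
  d <- sweep(pts, 2, mesh@baseCentroid)
  pmin(pmax(as.numeric(d %*% mesh@longAxis) / L, 0), 1)
}

# circumferential angle in [0, 2*pi) about the long axis, measured from the
# anterior reference, for each point
circumferentialAngle <- function(mesh, anteriorRef, pts = mesh@vertices) {
  ax <- mesh@longAxis
  e1 <- anteriorRef - sum(anteriorRef * ax) * ax
  n1 <- sqrt(sum(e1^2))
  if (n1 < 1e-9) stop("anterior reference is parallel to the long axis")
  e1 <- e1 / n1
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  d <- sweep(pts, 2, mesh@baseCentroid)
  ang <- atan2(as.numeric(d %*% e2), as.numeric(d %*% e1))
  ang %% (2 * pi)
}
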