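# Shared numeric helpers.

# nearest reference point for each query point (brute force, chunked to keep
# the distance block below ~32 MB)
nearestNeighbor <- function(query, ref) {
  query <- as.matrix(query)
  ref <- as.matrix(ref)
  m <- nrow(query)
  n <- nrow(ref)
  ref2 <- rowSums(ref^2)
  idx <- integer(m)
  d2 <- numeric(m)
  chunk <- max(1L, as.integer(4e6 / max(1L, n)))
  for (s in seq(1L, m, by = chunk)) {
    e <- min(m, s + chunk - 1L)
    qc <- query[s:e, , drop = FALSE]
    D <- matrix(ref2, e - s + 1L, n, byrow = TRUE) - 2 * qc %*% t(ref) + rowSums(qc^2)
    j <- max.col(-D, ties.method = "first")
    idx[s:e] <- j
    d2[s:e] <- D[cbind(seq_len(e - s + 1L), j)]
  }
  list(index = idx, distance = sqrt(pmax(d2, 0)))
}

unitVector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# cross product of two 3-vectors
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an axis
#'
#' Rodrigues' formula; convenience for constructing test transforms.
#'
#' @param axis 3-vector, normalised internally.
#' @param angle rotation angle in radians.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angle) {
  u <- unitVector(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
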