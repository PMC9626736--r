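# Synthetic LV endocardial geometry.

#' Generate a synthetic LV endocardial mesh
#'
#' Builds a truncated half-ellipsoid open at the base, triangulated as an
#' apex fan plus ring strips, emulating the SPECT-derived endocardial LV
#' surface at a chosen resolution (the study geometries had 358 or 3648
#' vertices). Vertices lie exactly on the ellipsoid; a seeded random phase
#' per ring breaks the azimuthal symmetry of the tessellation.
#'
#' @param nVertices target vertex count (>= 50); the result matches it
#'   exactly up to ring rounding (within 2%).
#' @param radiiMM three positive semi-axes in mm: the two short axes of the
#'   cavity and the base-to-apex long axis. Default `c(25, 25, 65)`, a
#'   typical dilated ischaemic LV cavity.
#' @param seed integer seed; a fixed seed gives a bit-identical mesh.
#' @return an [LVMesh-class] with apex `(0, 0, -c)`, base centroid at the
#'   origin and long axis `(0, 0, -1)`.
#' @examples
#' m <- makeLVMesh(nVertices = 358, seed = 1)
#' nVertices(m)
#' @export
makeLVMesh <- function(nVertices = 3648, radiiMM = c(25, 25, 65), seed = 1L) {
  if (nVertices < 50) stop("nVertices must be at least 50")
  if (length(radiiMM) != 3L || any(radiiMM <= 0)) stop("radiiMM must be three positive semi-axes")
  set.seed(seed)
  a <- radiiMM[1]; b <- radiiMM[2]; cc <- radiiMM[3]

  nRings <- max(3L, round(sqrt((nVertices - 1) * pi / 8)))
  theta <- seq_len(nRings) * (pi / 2) / nRings
  s <- sin(theta)
  m <- pmax(3L, round(s * (nVertices - 1) / sum(s)))
  # distribute the rounding remainder over the largest rings
  diff <- (nVertices - 1L) - sum(m)
  ord <- order(m, decreasing = TRUE)
  k <- 0L
  while (diff != 0L) {
    i <- ord[(k %% nRings) + 1L]
    step <- sign(diff)
    if (m[i] + step >= 3L) {
      m[i] <- m[i] + step
      diff <- diff - step
    }
    k <- k + 1L
  }

  verts <- matrix(0, 1L + sum(m), 3)
  verts[1, ] <- c(0, 0, -cc)                       # apex
  ringIdx <- vector("list", nRings)
  ringAng <- vector("list", nRings)
  nxt <- 2L
  for (i in seq_len(nRings)) {
    phase <- stats::runif(1, 0, 2 * pi / m[i])
    phi <- phase + 2 * pi * (seq_len(m[i]) - 1L) / m[i]
    idx <- nxt:(nxt + m[i] - 1L)
    verts[idx, ] <- cbind(a * s[i] * cos(phi), b * s[i] * sin(phi), -cc * cos(theta[i]))
    ringIdx[[i]] <- idx
    ringAng[[i]] <- phi %% (2 * pi)
    nxt <- nxt + m[i]
  }

  faces <- vector("list", nRings)
  # apex fan to the first ring
  r1 <- ringIdx[[1]]
  o1 <- order(ringAng[[1]])
  faces[[1]] <- cbind(1L, r1[o1], r1[o1][c(2:length(o1), 1L)])
  for (i in seq_len(nRings - 1L)) {
    oA <- order(ringAng[[i]]); oB <- order(ringAng[[i + 1L]])
    faces[[i + 1L]] <- stitchRings(ringIdx[[i]][oA], sort(ringAng[[i]]),
                                   ringIdx[[i + 1L]][oB], sort(ringAng[[i + 1L]]))
  }
  f <- do.call(rbind, faces)
  storage.mode(f) <- "integer"

  # orient all faces so normals point outward (along the implicit gradient)
  cen <- (verts[f[, 1], ] + verts[f[, 2], ] + verts[f[, 3], ]) / 3
  e1 <- verts[f[, 2], ] - verts[f[, 1], ]
  e2 <- verts[f[, 3], ] - verts[f[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  grad <- cbind(cen[, 1] / a^2, cen[, 2] / b^2, cen[, 3] / cc^2)
  flip <- rowSums(nrm * grad) < 0
  f[flip, ] <- f[flip, c(1, 3, 2)]

  LVMesh(verts, f, apex = c(0, 0, -cc), baseCentroid = c(0, 0, 0),
         longAxis = c(0, 0, -1))
}

# triangulate the band between two sorted rings by advancing whichever ring
# has the smaller next angle (angles ascending, wrap handled by +2*pi)
stitchRings <- function(idxA, angA, idxB, angB) {
  nA <- length(idxA); nB <- length(idxB)
  # start ring B at its angle closest to angA[1]
  rot <- which.min(pmin(abs(angB - angA[1]), 2 * pi - abs(angB - angA[1])))
  if (rot > 1L) {
    idxB <- idxB[c(rot:nB, 1:(rot - 1L))]
    angB <- angB[c(rot:nB, 1:(rot - 1L))]
    angB[angB < angB[1]] <- angB[angB < angB[1]] + 2 * pi
  }
  # express B on the same unwrapped branch as A (their starts are circularly
  # close but may sit on opposite sides of the 0/2*pi seam)
  delta <- angB[1] - angA[1]
  if (delta > pi) angB <- angB - 2 * pi
  if (delta < -pi) angB <- angB + 2 * pi
  nextA <- c(angA[-1], angA[1] + 2 * pi)
  nextB <- c(angB[-1], angB[1] + 2 * pi)
  faces <- matrix(0L, nA + nB, 3)
  i <- 1L; j <- 1L; ai <- 0L; bj <- 0L; cnt <- 0L
  while (ai < nA || bj < nB) {
    advanceA <- if (ai >= nA) FALSE else if (bj >= nB) TRUE else nextA[i] <= nextB[j]
    cnt <- cnt + 1L
    if (advanceA) {
      i2 <- if (i < nA) i + 1L else 1L
      faces[cnt, ] <- c(idxA[i], idxB[j], idxA[i2])
      i <- i2; ai <- ai + 1L
    } else {
      j2 <- if (j < nB) j + 1L else 1L
      faces[cnt, ] <- c(idxA[i], idxB[j], idxB[j2])
      j <- j2; bj <- bj + 1L
    }
  }
  faces[seq_len(cnt), , drop = FALSE]
}
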