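# Two-stage landmark registration: least-squares rigid (Kabsch) alignment on
# the primary fiducials, then a thin-plate-spline refinement interpolating
# the secondary fiducials. The fitted pipeline maps EAM-frame coordinates
# into the SPECT frame.

#' Least-squares rigid (Kabsch) fit from paired points
#'
#' Finds the proper rotation and translation minimising the sum of squared
#' distances between transformed source points and their targets (orthogonal
#' Procrustes with the determinant +1 constraint, via SVD). With three exact
#' pairs the residual is zero to machine precision. An optional similarity
#' mode additionally estimates a uniform scale.
#'
#' @param source n x 3 matrix of source points (EAM frame), or a
#'   [FiducialSet-class] whose primary pairs are used.
#' @param target n x 3 matrix of target points (SPECT frame); ignored when
#'   `source` is a [FiducialSet-class].
#' @param allowScale estimate a uniform scale (default FALSE: pure rigid,
#'   scale fixed at 1).
#' @return a [RigidTransform-class].
#' @examples
#' src <- matrix(rnorm(15), 5, 3)
#' R <- rotationAboutAxis(c(0, 0, 1), pi / 2)
#' tgt <- src %*% t(R) + matrix(c(10, 0, 0), 5, 3, byrow = TRUE)
#' fitRigid(src, tgt)
#' @export
fitRigid <- function(source, target = NULL, allowScale = FALSE) {
  if (is(source, "FiducialSet")) {
    keep <- source@role == "primary"
    target <- source@target[keep, , drop = FALSE]
    source <- source@source[keep, , drop = FALSE]
  }
  source <- as.matrix(source); target <- as.matrix(target)
  n <- nrow(source)
  if (n < 3L || nrow(target) != n)
    stop("at least 3 paired points are required for a rigid fit")
  cs <- colMeans(source); ct <- colMeans(target)
  X <- sweep(source, 2, cs); Y <- sweep(target, 2, ct)
  # degenerate configurations: coincident or collinear points
  sv <- svd(X)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate fiducial configuration: points are collinear or coincident")
  H <- crossprod(X, Y)
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  D <- diag(c(1, 1, d))
  R <- dec$v %*% D %*% t(dec$u)
  s <- 1
  if (allowScale) {
    varX <- sum(X^2)
    s <- sum(dec$d * c(1, 1, d)) / varX
    if (s <= 0) stop("degenerate configuration: non-positive scale estimate")
  }
  tr <- ct - s * as.numeric(R %*% cs)
  new("RigidTransform", rotation = R, translation = tr, scale = s)
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return the inverse [RigidTransform-class].
#' @export
invertRigid <- function(transform) {
  stopifnot(is(transform, "RigidTransform"))
  Rinv <- t(transform@rotation)
  new("RigidTransform", rotation = Rinv,
      translation = -as.numeric(Rinv %*% transform@translation) / transform@scale,
      scale = 1 / transform@scale)
}

#' Fit a 3D thin-plate-spline warp from paired control points
#'
#' Interpolating (stiffness 0) or smoothing (stiffness > 0) thin-plate
#' spline with the 3D biharmonic kernel U(r) = r. The bending-energy
#' minimisation spreads the spatial effect of each landmark smoothly, and
#' the affine part absorbs any global linear trend, so a purely affine
#' displacement is recovered with zero kernel weights.
#'
#' @param source k x 3 source-side control points (secondary fiducials after
#'   rigid alignment).
#' @param target k x 3 target points.
#' @param stiffness non-negative regulariser added to the kernel diagonal
#'   (mm); 0 gives exact interpolation of the control points.
#' @return a [TPSWarp-class].
#' @examples
#' src <- matrix(rnorm(30, sd = 20), 10, 3)
#' w <- fitTPS(src, src + 2)
#' max(abs(applyTransform(w, src) - (src + 2)))
#' @export
fitTPS <- function(source, target, stiffness = 0) {
  source <- as.matrix(source); target <- as.matrix(target)
  k <- nrow(source)
  if (k < 4L || nrow(target) != k)
    stop("at least 4 paired control points are required for a 3D TPS")
  if (stiffness < 0) stop("stiffness must be non-negative")
  sv <- svd(sweep(source, 2, colMeans(source)))$d
  if (sv[3] < 1e-7 * max(sv[1], 1) && stiffness == 0)
    stop("control points are coplanar: the interpolating TPS is ill-conditioned; ",
         "add stiffness > 0 or spread the secondary fiducials")
  K <- as.matrix(stats::dist(source))
  P <- cbind(1, source)
  L <- rbind(cbind(K + stiffness * diag(k), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(target, matrix(0, 4, 3))
  sol <- tryCatch(solve(L, rhs), error = function(e) {
    # coplanar control points with stiffness: one affine direction is
    # unidentifiable; take the minimal-norm (pseudoinverse) solution
    if (stiffness > 0) {
      dec <- svd(L)
      pos <- dec$d > max(dec$d) * 1e-12
      dec$v[, pos, drop = FALSE] %*%
        (crossprod(dec$u[, pos, drop = FALSE], rhs) / dec$d[pos])
    } else {
      stop("TPS system is singular: ", conditionMessage(e),
           " (consider adding stiffness)")
    }
  })
  W <- sol[seq_len(k), , drop = FALSE]
  A <- sol[k + 1:4, , drop = FALSE]
  new("TPSWarp", controlPoints = source, affine = A, weights = W,
      stiffness = stiffness)
}

#' Fit the full two-stage registration from a fiducial set
#'
#' Rigid stage on the primary pairs, then (when at least 4 secondary pairs
#' are available) a thin-plate-spline refinement fitted between the rigidly
#' aligned secondary sources and their targets.
#'
#' @param fiducials a [FiducialSet-class].
#' @param stiffness TPS regulariser, default 0 (exact interpolation).
#' @param allowScale passed to [fitRigid()].
#' @param useTPS set FALSE for a rigid-only registration.
#' @return a [RegistrationPipeline-class].
#' @examples
#' m <- labelSegments(makeLVMesh(nVertices = 500, seed = 1))
#' gt <- makeGroundTruth(m, seed = 2)
#' fid <- makeFiducials(m, gt, noiseSDMM = 0, seed = 3)
#' reg <- fitRegistration(fid)
#' fre(reg, fid)
#' @export
fitRegistration <- function(fiducials, stiffness = 0, allowScale = FALSE,
                            useTPS = TRUE) {
  stopifnot(is(fiducials, "FiducialSet"))
  rigid <- fitRigid(fiducials, allowScale = allowScale)
  tps <- NULL
  sec <- fiducials@role == "secondary"
  if (useTPS && sum(sec) >= 4L) {
    alignedSrc <- applyTransform(rigid, fiducials@source[sec, , drop = FALSE])
    tps <- fitTPS(alignedSrc, fiducials@target[sec, , drop = FALSE],
                  stiffness = stiffness)
  }
  new("RegistrationPipeline", rigid = rigid, tps = tps)
}

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "matrix"),
  function(transform, points) {
    out <- transform@scale * points %*% t(transform@rotation)
    sweep(out, 2, transform@translation, "+")
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("TPSWarp", "matrix"),
  function(transform, points) {
    cp <- transform@controlPoints
    # exact coordinate differences: the expanded-square shortcut loses ~1e-7
    # near control points, which would break exact interpolation
    U <- sqrt(outer(points[, 1], cp[, 1], "-")^2 +
              outer(points[, 2], cp[, 2], "-")^2 +
              outer(points[, 3], cp[, 3], "-")^2)
    cbind(1, points) %*% transform@affine + U %*% transform@weights
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RegistrationPipeline", "matrix"),
  function(transform, points) {
    out <- applyTransform(transform@rigid, points)
    if (!is.null(transform@tps)) out <- applyTransform(transform@tps, out)
    out
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("ANY", "numeric"),
  function(transform, points) {
    stopifnot(length(points) == 3L)
    as.numeric(applyTransform(transform, matrix(points, 1, 3)))
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("ANY", "EAMCloud"),
  function(transform, points) {
    new("EAMCloud", points = applyTransform(transform, points@points),
        voltage = points@voltage)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "LVMesh"),
  function(transform, points) {
    m <- points
    m@vertices <- applyTransform(transform, m@vertices)
    m@apex <- applyTransform(transform, m@apex)
    m@baseCentroid <- applyTransform(transform, m@baseCentroid)
    m@longAxis <- as.numeric(transform@rotation %*% m@longAxis)
    m
  })

#' Fiducial and target registration error
#'
#' Root-mean-square residual between transformed source points and their
#' targets. `fre()` evaluates the pairs used for fitting (fiducial
#' registration error); `tre()` is the same computation on held-out pairs
#' (target registration error) - in the synthetic setting the ground truth
#' makes TRE computable, which clinical impedance-field data did not permit.
#'
#' @param transform any transform accepted by [applyTransform()].
#' @param source n x 3 source points, or a [FiducialSet-class] (all pairs).
#' @param target n x 3 target points; ignored for a [FiducialSet-class].
#' @return RMS error in mm.
#' @export
fre <- function(transform, source, target = NULL) {
  if (is(source, "FiducialSet")) {
    target <- source@target
    source <- source@source
  }
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) == 0L) stop("no pairs supplied")
  mapped <- applyTransform(transform, source)
  sqrt(mean(rowSums((mapped - target)^2)))
}

#' @rdname fre
#' @export
tre <- fre

setMethod("show", "RigidTransform", function(object) {
  angle <- acos(pmin(pmax((sum(diag(object@rotation)) - 1) / 2, -1), 1))
  cat(sprintf("RigidTransform: rotation %.1f deg, translation (%.1f, %.1f, %.1f) mm, scale %.3f\n",
              angle * 180 / pi, object@translation[1], object@translation[2],
              object@translation[3], object@scale))
  invisible(object)
})

setMethod("show", "TPSWarp", function(object) {
  cat(sprintf("TPSWarp: %d control points, stiffness %g, max |weight| %.3g\n",
              nrow(object@controlPoints), object@stiffness,
              if (nrow(object@weights)) max(abs(object@weights)) else 0))
  invisible(object)
})

setMethod("show", "RegistrationPipeline", function(object) {
  cat("RegistrationPipeline (EAM -> SPECT):\n  ")
  show(object@rigid)
  if (is.null(object@tps)) cat("  no nonrigid stage\n") else { cat("  "); show(object@tps) }
  invisible(object)
})
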