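# Synthetic perfusion defects, ground-truth transforms, voltage clouds and
# paired fiducials - the desk-scale stand-in for one mapped subject.

#' Specification of a perfusion defect
#'
#' Describes one contiguous scar: which AHA segments form its core, the
#' residual tracer uptake inside the core, and the width of the smooth
#' border zone between scar and remote myocardium.
#'
#' @slot centerSegment AHA segment at the defect centre.
#' @slot extentSegments segments whose vertices form the scar core.
#' @slot severity uptake fraction in the core, in [0, 1); default 0.15.
#' @slot borderWidthMM transition-zone width in mm (> 0); default 8.
#' @seealso [scarSpec()], [makePerfusion()]
#' @export
setClass("ScarSpec",
  representation(centerSegment = "integer", extentSegments = "integer",
                 severity = "numeric", borderWidthMM = "numeric")
)

setValidity("ScarSpec", function(object) {
  msg <- character()
  if (object@centerSegment < 1L || object@centerSegment > 17L)
    msg <- c(msg, "centerSegment must be in 1..17")
  if (any(object@extentSegments < 1L | object@extentSegments > 17L))
    msg <- c(msg, "extentSegments must be in 1..17")
  if (object@severity < 0 || object@severity >= 1)
    msg <- c(msg, "severity must be in [0, 1)")
  if (object@borderWidthMM <= 0) msg <- c(msg, "borderWidthMM must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname ScarSpec-class
#' @param centerSegment,extentSegments,severity,borderWidthMM see slots.
#' @return a [ScarSpec-class].
#' @examples
#' scarSpec(4, territorySegments("inferior"))
#' @export
scarSpec <- function(centerSegment, extentSegments = centerSegment,
                     severity = 0.15, borderWidthMM = 8) {
  new("ScarSpec", centerSegment = as.integer(centerSegment),
      extentSegments = as.integer(extentSegments),
      severity = severity, borderWidthMM = borderWidthMM)
}

#' Paint a perfusion map with scar defects onto a mesh
#'
#' Remote myocardium gets uptake 1.0 (fraction of the subject maximum), scar
#' cores the defect severity, with a smooth monotone (smoothstep) transition
#' over the border width; Gaussian noise is added and values are clipped to
#' [0, 1].
#'
#' @param mesh a segment-labelled [LVMesh-class].
#' @param scars list of [ScarSpec-class] objects (may be empty).
#' @param noiseSD per-vertex Gaussian noise SD (>= 0), default 0.03.
#' @param seed integer seed.
#' @return the mesh with `perfusion` set.
#' @examples
#' m <- labelSegments(makeLVMesh(nVertices = 500, seed = 1))
#' m <- makePerfusion(m, list(scarSpec(4, territorySegments("inferior"))), seed = 1)
#' range(perfusion(m))
#' @export
makePerfusion <- function(mesh, scars = list(), noiseSD = 0.03, seed = 1L) {
  stopifnot(is(mesh, "LVMesh"))
  if (is.null(mesh@segmentLabels)) stop("mesh must be segment-labelled first")
  if (noiseSD < 0) stop("noiseSD must be non-negative")
  set.seed(seed)
  n <- nrow(mesh@vertices)
  u <- rep(1, n)
  for (sc in scars) {
    stopifnot(is(sc, "ScarSpec"))
    core <- mesh@segmentLabels %in% sc@extentSegments
    if (!any(core)) next
    ui <- rep(sc@severity, n)
    outside <- which(!core)
    if (length(outside)) {
      d <- nearestNeighbor(mesh@vertices[outside, , drop = FALSE],
                           mesh@vertices[core, , drop = FALSE])$distance
      s <- pmin(d / sc@borderWidthMM, 1)
      h <- s * s * (3 - 2 * s)                       # smoothstep
      ui[outside] <- sc@severity + (1 - sc@severity) * h
    }
    u <- pmin(u, ui)
  }
  if (noiseSD > 0) u <- u + stats::rnorm(n, 0, noiseSD)
  perfusion(mesh) <- pmin(pmax(u, 0), 1)
  mesh
}

#' Generate the ground-truth SPECT-to-EAM transform
#'
#' A random proper rigid transform (the frame offset between the mapping
#' system and the scanner) followed by a smooth nonrigid deformation built
#' from Gaussian radial bumps anchored near the LV surface, emulating
#' cardiac-motion and impedance-field distortion at a few millimetres'
#' magnitude.
#'
#' @param mesh the SPECT-frame [LVMesh-class] the subject is built on.
#' @param seed integer seed.
#' @param maxRotationDeg upper bound of the random rotation angle (default 25).
#' @param maxTranslationMM componentwise bound of the random translation
#'   (default 30).
#' @param nBumps number of Gaussian deformation bumps (default 3).
#' @param bumpAmplitudeMM amplitude range in mm, default `c(2, 5)`.
#' @param bumpSigmaMM Gaussian width in mm, default 20.
#' @return a [GroundTruth-class].
#' @export
makeGroundTruth <- function(mesh, seed = 1L, maxRotationDeg = 25,
                            maxTranslationMM = 30, nBumps = 3L,
                            bumpAmplitudeMM = c(2, 5), bumpSigmaMM = 20) {
  stopifnot(is(mesh, "LVMesh"))
  set.seed(seed)
  ax <- unitVector(stats::rnorm(3))
  angle <- stats::runif(1, 5, maxRotationDeg) * pi / 180
  R <- rotationAboutAxis(ax, angle)
  tr <- stats::runif(3, -maxTranslationMM, maxTranslationMM)
  rigid <- new("RigidTransform", rotation = R, translation = tr, scale = 1)
  vi <- sample.int(nrow(mesh@vertices), nBumps)
  centers <- applyTransform(rigid, mesh@vertices[vi, , drop = FALSE])
  amp <- stats::runif(nBumps, bumpAmplitudeMM[1], bumpAmplitudeMM[2])
  dirs <- matrix(stats::rnorm(3 * nBumps), nBumps, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  new("GroundTruth", rigid = rigid, deformCenters = centers,
      deformVectors = dirs * amp, deformSigma = bumpSigmaMM)
}

#' Map points through the ground-truth pipeline (SPECT frame to EAM frame)
#'
#' Applies the rigid part, then displaces each point by the sum of Gaussian
#' bumps.
#'
#' @param truth a [GroundTruth-class].
#' @param points n x 3 matrix (mm).
#' @return n x 3 matrix in the EAM frame.
#' @export
applyGroundTruth <- function(truth, points) {
  stopifnot(is(truth, "GroundTruth"))
  y <- applyTransform(truth@rigid, points)
  for (k in seq_len(nrow(truth@deformCenters))) {
    d2 <- rowSums(sweep(y, 2, truth@deformCenters[k, ])^2)
    w <- exp(-d2 / (2 * truth@deformSigma^2))
    y <- y + outer(w, truth@deformVectors[k, ])
  }
  y
}

# tissue class from local uptake, using the perfusion score bin edges:
# score 0 (< 0.30) = scar core, scores 1-2 = border zone, score 3 = healthy
tissueClassFromUptake <- function(u) {
  cls <- rep("healthy", length(u))
  cls[u < 0.70] <- "border"
  cls[u < 0.30] <- "scar"
  cls
}

#' Sample a synthetic EAM voltage cloud
#'
#' Samples points uniformly by surface area (emulating a roving-catheter
#' acquisition), assigns each a tissue class from the local interpolated
#' uptake, draws a bipolar voltage from a class-conditional log-normal model
#' (default medians 0.15 / 0.8 / 3.0 mV for scar / border / healthy, matching
#' the clinical <0.3 mV deep-scar and >1.5 mV healthy cutoffs), then maps the
#' cloud into the EAM frame through the ground-truth rigid transform and
#' deformation.
#'
#' @param mesh a segment-labelled [LVMesh-class] with perfusion set.
#' @param nPoints number of voltage points (>= 1); the study acquired on the
#'   order of 700 (conventional catheter) to 1800 (high-density catheter).
#' @param truth a [GroundTruth-class]; its point-level slots are filled in.
#' @param voltageParams list with `medianScar`, `medianBorder`,
#'   `medianHealthy` (mV) and `sdlog`.
#' @param seed integer seed.
#' @param radialJitterMM points are jittered along the face normal by up to
#'   this amount (default 1; use 0 for points exactly on the surface).
#' @return list with `cloud` ([EAMCloud-class], EAM frame) and `truth` (the
#'   input [GroundTruth-class] with per-point class and segment filled in).
#' @examples
#' m <- labelSegments(makeLVMesh(nVertices = 500, seed = 1))
#' m <- makePerfusion(m, seed = 1)
#' gt <- makeGroundTruth(m, seed = 1)
#' res <- makeEAMCloud(m, 200, gt, seed = 1)
#' res$cloud
#' @export
makeEAMCloud <- function(mesh, nPoints, truth,
                         voltageParams = list(medianScar = 0.15, medianBorder = 0.8,
                                              medianHealthy = 3.0, sdlog = 0.45),
                         seed = 1L, radialJitterMM = 1) {
  stopifnot(is(mesh, "LVMesh"), is(truth, "GroundTruth"))
  if (nPoints < 1) stop("nPoints must be at least 1")
  if (is.null(mesh@perfusion)) stop("mesh must carry perfusion values")
  if (is.null(mesh@segmentLabels)) stop("mesh must be segment-labelled")
  set.seed(seed)
  v <- mesh@vertices
  f <- mesh@faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(nrm^2)) / 2
  fi <- sample.int(nrow(f), nPoints, replace = TRUE, prob = area)
  r1 <- stats::runif(nPoints); r2 <- stats::runif(nPoints)
  s1 <- sqrt(r1)
  w1 <- 1 - s1; w2 <- s1 * (1 - r2); w3 <- s1 * r2
  pts <- w1 * v[f[fi, 1], ] + w2 * v[f[fi, 2], ] + w3 * v[f[fi, 3], ]
  if (radialJitterMM > 0) {
    un <- nrm[fi, , drop = FALSE] / sqrt(rowSums(nrm[fi, , drop = FALSE]^2))
    pts <- pts + un * stats::runif(nPoints, -radialJitterMM, radialJitterMM)
  }
  uptake <- w1 * mesh@perfusion[f[fi, 1]] + w2 * mesh@perfusion[f[fi, 2]] +
    w3 * mesh@perfusion[f[fi, 3]]
  cls <- tissueClassFromUptake(uptake)
  med <- c(scar = voltageParams$medianScar, border = voltageParams$medianBorder,
           healthy = voltageParams$medianHealthy)
  volt <- stats::rlnorm(nPoints, meanlog = log(med[cls]), sdlog = voltageParams$sdlog)
  seg <- mesh@segmentLabels[nearestNeighbor(pts, v)$index]

  eamPts <- applyGroundTruth(truth, pts)
  truth@pointClass <- cls
  truth@pointSegment <- as.integer(seg)
  list(cloud = new("EAMCloud", points = eamPts, voltage = as.numeric(volt)),
       truth = truth)
}

#' Generate paired registration fiducials
#'
#' Primary fiducials are placed at extra-LV anchor positions (synthetic
#' stand-ins for the right-ventricular lead tip, coronary sinus and aortic
#' arch); secondary fiducials sit on the LV surface at axially and
#' circumferentially spread positions. Each pair consists of the SPECT-frame
#' point and its image under the ground-truth transform plus isotropic
#' Gaussian noise on the EAM side.
#'
#' @param mesh the SPECT-frame [LVMesh-class].
#' @param truth a [GroundTruth-class].
#' @param nPrimary number of extra-LV primary pairs (>= 3; default 3).
#' @param nSecondary number of on-surface secondary pairs (default 11, for a
#'   total of 14, inside the study's 12-15 range).
#' @param noiseSDMM isotropic landmark-localisation noise SD in mm
#'   (default 2).
#' @param seed integer seed.
#' @return a [FiducialSet-class].
#' @export
makeFiducials <- function(mesh, truth, nPrimary = 3L, nSecondary = 11L,
                          noiseSDMM = 2, seed = 1L) {
  stopifnot(is(mesh, "LVMesh"), is(truth, "GroundTruth"))
  if (nPrimary < 3L) stop("nPrimary must be at least 3 (rigid fit underdetermined)")
  if (noiseSDMM < 0) stop("noiseSDMM must be non-negative")
  set.seed(seed)
  ax <- mesh@longAxis
  base <- mesh@baseCentroid
  L <- sum((mesh@apex - base) * ax)
  radial <- sweep(mesh@vertices, 2, base)
  radial <- radial - outer(as.numeric(radial %*% ax), ax)
  rmax <- max(sqrt(rowSums(radial^2)))
  e1 <- unitVector(c(1, 0, 0) - sum(c(1, 0, 0) * ax) * ax)
  e2 <- cross3(ax, e1)
  place <- function(t, angDeg, rFrac) {
    a <- angDeg * pi / 180
    base + t * L * ax + rFrac * rmax * (cos(a) * e1 + sin(a) * e2)
  }
  # extra-LV anchors: lead tip near the apex (septal), coronary sinus just
  # above the base (posterior), aortic arch well above the base (anterior),
  # RV apex as a fourth
  anchors <- rbind(place(0.95, 100, 1.4),
                   place(-0.05, 190, 1.2),
                   place(-0.50, 20, 0.8),
                   place(1.10, 120, 0.9))
  prim <- anchors[rep(seq_len(nrow(anchors)), length.out = nPrimary), , drop = FALSE]
  if (nPrimary > nrow(anchors))                    # perturb duplicated anchors
    prim <- prim + matrix(stats::rnorm(3 * nPrimary, 0, 3), nPrimary, 3)

  sec <- matrix(0, 0, 3)
  if (nSecondary > 0L) {
    grid <- expand.grid(t = c(0.25, 0.5, 0.75), ang = c(45, 135, 225, 315) * pi / 180)
    grid <- grid[seq_len(min(nSecondary, nrow(grid))), , drop = FALSE]
    tv <- axialFraction(mesh)
    av <- circumferentialAngle(mesh, c(1, 0, 0))
    pick <- integer(0)
    for (g in seq_len(nrow(grid))) {
      dAng <- pmin(abs(av - grid$ang[g]), 2 * pi - abs(av - grid$ang[g]))
      cost <- (tv - grid$t[g])^2 + (0.15 * dAng)^2
      cost[pick] <- Inf
      pick <- c(pick, which.min(cost))
    }
    extra <- nSecondary - nrow(grid)
    if (extra > 0L) pick <- c(pick, sample(setdiff(seq_len(nrow(mesh@vertices)), pick), extra))
    sec <- mesh@vertices[pick, , drop = FALSE]
  }

  tgt <- rbind(prim, sec)                          # SPECT frame
  src <- applyGroundTruth(truth, tgt)              # EAM frame
  if (noiseSDMM > 0)
    src <- src + matrix(stats::rnorm(length(src), 0, noiseSDMM), nrow(src), 3)
  role <- c(rep("primary", nrow(prim)), rep("secondary", nrow(sec)))
  nm <- c(sprintf("P%d", seq_len(nrow(prim))), sprintf("S%d", seq_len(nrow(sec))))
  new("FiducialSet", source = src, target = tgt, role = role, name = nm)
}

setMethod("show", "FiducialSet", function(object) {
  cat(sprintf("FiducialSet: %d pairs (%d primary, %d secondary)\n",
              length(object@name), sum(object@role == "primary"),
              sum(object@role == "secondary")))
  invisible(object)
})

setMethod("show", "EAMCloud", function(object) {
  cat(sprintf("EAMCloud: %d points, voltage %.2f-%.2f mV (median %.2f)\n",
              nrow(object@points), min(object@voltage), max(object@voltage),
              stats::median(object@voltage)))
  invisible(object)
})

#' @rdname nVertices
#' @export
setMethod("nPoints", "EAMCloud", function(x) nrow(x@points))

#' @rdname mesh-accessors
#' @export
setMethod("voltage", "EAMCloud", function(x) x@voltage)
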