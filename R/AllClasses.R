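#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Left-ventricular endocardial surface mesh
#'
#' Triangle mesh of the LV endocardium in millimetre coordinates, as derived
#' from gated SPECT/CT ("SPECT-endoLV") or produced by the synthetic
#' generator. Carries the anatomical frame (apex, base centroid, long axis)
#' required for AHA 17-segment labelling, and optional per-vertex attributes:
#' tracer uptake as a fraction of the subject maximum, and segment labels.
#'
#' Faces are stored 1-based (R convention); file writers emit 0-based indices
#' as the PLY/VTK formats require.
#'
#' @slot vertices numeric matrix, n x 3, coordinates in mm.
#' @slot faces integer matrix, m x 3, 1-based vertex indices, counter-clockwise
#'   seen from outside the mesh solid (outward normals).
#' @slot apex numeric(3), apex position in mm.
#' @slot baseCentroid numeric(3), centroid of the open basal rim in mm.
#' @slot longAxis numeric(3), unit vector pointing from base to apex.
#' @slot perfusion per-vertex uptake fraction in [0, 1], or NULL until set.
#' @slot segmentLabels per-vertex integer in 1..17, or NULL until computed.
#'
#' @seealso [makeLVMesh()], [labelSegments()], [decimateMesh()]
#' @export
setClass("LVMesh",
  representation(
    vertices = "matrix",
    faces = "matrix",
    apex = "numeric",
    baseCentroid = "numeric",
    longAxis = "numeric",
    perfusion = "numericOrNULL",
    segmentLabels = "integerOrNULL"
  ),
  prototype(perfusion = NULL, segmentLabels = NULL)
)

setValidity("LVMesh", function(object) {
  msg <- character()
  v <- object@vertices
  f <- object@faces
  if (ncol(v) != 3L || !is.numeric(v)) msg <- c(msg, "vertices must be an n x 3 numeric matrix")
  if (ncol(f) != 3L) msg <- c(msg, "faces must be an m x 3 matrix")
  if (anyNA(v) || any(!is.finite(v))) msg <- c(msg, "vertices must be finite")
  if (nrow(f) > 0L && (min(f) < 1L || max(f) > nrow(v)))
    msg <- c(msg, "face indices out of range")
  if (length(object@apex) != 3L) msg <- c(msg, "apex must be length 3")
  if (length(object@baseCentroid) != 3L) msg <- c(msg, "baseCentroid must be length 3")
  if (length(object@longAxis) != 3L) msg <- c(msg, "longAxis must be length 3")
  if (abs(sqrt(sum(object@longAxis^2)) - 1) > 1e-6)
    msg <- c(msg, "longAxis must have unit norm")
  if (!is.null(object@perfusion)) {
    if (length(object@perfusion) != nrow(v))
      msg <- c(msg, "perfusion must have one value per vertex")
    else if (any(object@perfusion < 0 | object@perfusion > 1))
      msg <- c(msg, "perfusion values must lie in [0, 1]")
  }
  if (!is.null(object@segmentLabels)) {
    if (length(object@segmentLabels) != nrow(v))
      msg <- c(msg, "segmentLabels must have one value per vertex")
    else if (anyNA(object@segmentLabels) ||
             any(object@segmentLabels < 1L | object@segmentLabels > 17L))
      msg <- c(msg, "segmentLabels must be integers in 1..17")
  }
  if (length(msg)) msg else TRUE
})

#' AHA 17-segment model parameters
#'
#' Parameters of the standard American Heart Association partition of the LV
#' into 6 basal, 6 mid-cavity and 4 apical segments plus an apical cap
#' (segment 17). Vertices are assigned by their axial fraction along the
#' base-to-apex axis and their circumferential angle measured from a declared
#' anterior reference direction, increasing towards the septum.
#'
#' @slot bandBounds two increasing fractions in (0,1) splitting
#'   basal / mid / apical along the axial extent (defaults 1/3, 2/3).
#' @slot apicalCapFraction fraction of the axial extent, measured from the
#'   apex, assigned to segment 17 (default 0.15).
#' @slot sectorEdges6 seven angle boundaries (radians) partitioning
#'   [0, 2*pi) into the 6 basal/mid sectors.
#' @slot sectorEdges4 five angle boundaries (radians) for the 4 apical sectors.
#' @slot anteriorRef numeric(3), direction whose projection perpendicular to
#'   the long axis defines circumferential angle zero (anterior wall).
#'
#' @seealso [segmentModel17()], [labelSegments()]
#' @export
setClass("SegmentModel17",
  representation(
    bandBounds = "numeric",
    apicalCapFraction = "numeric",
    sectorEdges6 = "numeric",
    sectorEdges4 = "numeric",
    anteriorRef = "numeric"
  )
)

setValidity("SegmentModel17", function(object) {
  msg <- character()
  b <- object@bandBounds
  if (length(b) != 2L || any(b <= 0) || any(b >= 1) || b[1] >= b[2])
    msg <- c(msg, "bandBounds must be two strictly increasing fractions in (0,1)")
  if (object@apicalCapFraction <= 0 || object@apicalCapFraction >= 1)
    msg <- c(msg, "apicalCapFraction must be in (0,1)")
  for (nm in c("sectorEdges6", "sectorEdges4")) {
    e <- slot(object, nm)
    k <- if (nm == "sectorEdges6") 7L else 5L
    if (length(e) != k || is.unsorted(e, strictly = TRUE) ||
        abs(e[1]) > 1e-9 || abs(e[k] - 2 * pi) > 1e-9)
      msg <- c(msg, sprintf("%s must be %d increasing edges spanning [0, 2*pi]", nm, k))
  }
  if (length(object@anteriorRef) != 3L || sum(object@anteriorRef^2) == 0)
    msg <- c(msg, "anteriorRef must be a nonzero 3-vector")
  if (length(msg)) msg else TRUE
})

#' Electroanatomical voltage point cloud
#'
#' Bipolar-voltage sampling points acquired by a roving catheter in the
#' mapping system's coordinate frame ("EAM-endoLV"), or the same points after
#' registration into the SPECT frame.
#'
#' @slot points numeric matrix, n x 3, coordinates in mm.
#' @slot voltage numeric(n), bipolar peak-to-peak amplitude in mV (>= 0).
#'
#' @seealso [makeEAMCloud()], [projectCloud()]
#' @export
setClass("EAMCloud",
  representation(points = "matrix", voltage = "numeric")
)

setValidity("EAMCloud", function(object) {
  msg <- character()
  if (ncol(object@points) != 3L) msg <- c(msg, "points must be n x 3")
  if (anyNA(object@points) || any(!is.finite(object@points)))
    msg <- c(msg, "point coordinates must be finite")
  if (length(object@voltage) != nrow(object@points))
    msg <- c(msg, "one voltage per point required")
  if (any(object@voltage < 0)) msg <- c(msg, "voltages must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Paired registration fiducials
#'
#' Landmarks identified in both coordinate frames. Primary fiducials sit on
#' fixed extra-LV anatomy (device lead tip, coronary sinus, aortic arch) and
#' anchor the rigid stage; secondary fiducials sit on the LV endocardial
#' surface and drive the nonrigid refinement. `source` holds the EAM-frame
#' position of each landmark and `target` its SPECT-frame mate; the fitted
#' registration maps EAM coordinates into the SPECT frame.
#'
#' @slot source numeric matrix, n x 3, EAM-frame positions (mm).
#' @slot target numeric matrix, n x 3, SPECT-frame positions (mm).
#' @slot role character(n), "primary" or "secondary".
#' @slot name character(n), unique landmark names.
#'
#' @seealso [makeFiducials()], [fitRigid()], [fitTPS()], [fitRegistration()]
#' @export
setClass("FiducialSet",
  representation(source = "matrix", target = "matrix",
                 role = "character", name = "character")
)

setValidity("FiducialSet", function(object) {
  msg <- character()
  n <- nrow(object@source)
  if (ncol(object@source) != 3L || ncol(object@target) != 3L)
    msg <- c(msg, "source and target must be n x 3 matrices")
  if (nrow(object@target) != n || length(object@role) != n || length(object@name) != n)
    msg <- c(msg, "source, target, role and name must agree in length")
  if (!all(object@role %in% c("primary", "secondary")))
    msg <- c(msg, "role must be 'primary' or 'secondary'")
  if (anyDuplicated(object@name)) msg <- c(msg, "fiducial names must be unique")
  if (length(msg)) msg else TRUE
})

#' Rigid (or similarity) spatial transform
#'
#' Proper rotation plus translation, with an optional uniform scale (fixed at
#' 1 for a pure rigid fit; impedance-based mapping fields can distort scale,
#' so a similarity mode is available behind a flag in [fitRigid()]).
#'
#' @slot rotation 3 x 3 proper orthogonal matrix (det +1).
#' @slot translation numeric(3), mm.
#' @slot scale positive scalar, default 1.
#'
#' @seealso [fitRigid()], [applyTransform()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric", scale = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0), scale = 1)
)

setValidity("RigidTransform", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      msg <- c(msg, "rotation must be orthogonal within 1e-8")
    if (abs(det(R) - 1) > 1e-8)
      msg <- c(msg, "rotation must be proper (det +1) within 1e-8")
  }
  if (length(object@translation) != 3L) msg <- c(msg, "translation must be length 3")
  if (length(object@scale) != 1L || object@scale <= 0) msg <- c(msg, "scale must be positive")
  if (length(msg)) msg else TRUE
})

#' Thin-plate-spline warp in 3D
#'
#' Landmark-interpolating nonrigid warp with the 3D biharmonic kernel
#' U(r) = r, an affine part, and one weight vector per control point. The
#' weights satisfy the standard TPS side conditions (they sum to zero
#' componentwise and are orthogonal to the control-point coordinates), which
#' is what gives the warp its evenly distributed spatial effect.
#'
#' @slot controlPoints k x 3 matrix of source-side control points (the
#'   rigidly aligned secondary fiducials).
#' @slot affine 4 x 3 matrix; first row intercept, rows 2-4 the linear map.
#' @slot weights k x 3 kernel weight matrix.
#' @slot stiffness non-negative regularisation used at fit time (0 =
#'   exact interpolation).
#'
#' @seealso [fitTPS()], [applyTransform()]
#' @export
setClass("TPSWarp",
  representation(controlPoints = "matrix", affine = "matrix",
                 weights = "matrix", stiffness = "numeric")
)

setValidity("TPSWarp", function(object) {
  msg <- character()
  k <- nrow(object@controlPoints)
  if (ncol(object@controlPoints) != 3L) msg <- c(msg, "controlPoints must be k x 3")
  if (!all(dim(object@affine) == c(4L, 3L))) msg <- c(msg, "affine must be 4 x 3")
  if (!all(dim(object@weights) == c(k, 3L))) msg <- c(msg, "weights must be k x 3")
  if (object@stiffness < 0) msg <- c(msg, "stiffness must be non-negative")
  if (k > 0) {
    P <- cbind(1, object@controlPoints)
    side <- crossprod(P, object@weights)
    scale <- max(1, max(abs(object@weights)) * max(1, max(abs(object@controlPoints))))
    if (max(abs(side)) / scale > 1e-6)
      msg <- c(msg, "TPS side conditions violated (t(P) %*% W != 0)")
  }
  if (length(msg)) msg else TRUE
})

setClassUnion("TPSWarpOrNULL", c("TPSWarp", "NULL"))

#' Two-stage registration pipeline
#'
#' Composition of the rigid stage (fitted on primary fiducials) and the
#' optional thin-plate-spline refinement (fitted on rigidly aligned secondary
#' fiducials). Applying the pipeline maps EAM-frame points into the SPECT
#' frame.
#'
#' @slot rigid the fitted [RigidTransform-class].
#' @slot tps the fitted [TPSWarp-class], or NULL for rigid-only registration.
#'
#' @seealso [fitRegistration()], [applyTransform()]
#' @export
setClass("RegistrationPipeline",
  representation(rigid = "RigidTransform", tps = "TPSWarpOrNULL"),
  prototype(tps = NULL)
)

#' Ground truth for synthetic subjects
#'
#' The known forward map from the SPECT frame into the EAM frame (a proper
#' rigid transform followed by a smooth sum-of-Gaussian-bumps deformation),
#' plus the true tissue class and AHA segment of every generated voltage
#' point. Enables parameter-recovery and target-registration-error checks
#' that clinical data cannot provide.
#'
#' @slot rigid SPECT-to-EAM [RigidTransform-class].
#' @slot deformCenters k x 3 bump centres in the EAM frame (mm).
#' @slot deformVectors k x 3 bump displacement vectors (direction times
#'   amplitude, mm).
#' @slot deformSigma Gaussian bump width in mm.
#' @slot pointClass character per generated point: "scar", "border", "healthy"
#'   (empty until a cloud is generated).
#' @slot pointSegment integer per generated point, AHA segment 1..17.
#'
#' @seealso [makeGroundTruth()], [makeEAMCloud()], [applyGroundTruth()]
#' @export
setClass("GroundTruth",
  representation(
    rigid = "RigidTransform",
    deformCenters = "matrix",
    deformVectors = "matrix",
    deformSigma = "numeric",
    pointClass = "character",
    pointSegment = "integer"
  ),
  prototype(pointClass = character(), pointSegment = integer())
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!isTRUE(validObject(object@rigid, test = TRUE))) msg <- c(msg, "invalid rigid part")
  if (ncol(object@deformCenters) != 3L || !all(dim(object@deformCenters) == dim(object@deformVectors)))
    msg <- c(msg, "deformCenters and deformVectors must be matching k x 3 matrices")
  if (length(object@deformSigma) != 1L || object@deformSigma <= 0)
    msg <- c(msg, "deformSigma must be a positive scalar")
  if (length(object@pointClass) != length(object@pointSegment))
    msg <- c(msg, "pointClass and pointSegment must agree in length")
  if (length(msg)) msg else TRUE
})

#' Result of projecting a voltage cloud onto a mesh
#'
#' Each point is assigned to its nearest mesh vertex if within the projection
#' range, otherwise dropped; each occupied vertex carries one voltage per the
#' combine rule. Because a vertex can carry at most one effective value, the
#' points lost to the geometry are `pointsTotal - verticesOccupied`, which is
#' how mesh resolution erodes the usable voltage map.
#'
#' @slot assignment data.frame with one row per point: `vertex` (1-based
#'   index, NA if out of range), `distance` (mm), `retained` (logical).
#' @slot vertexVoltage numeric, one value per mesh vertex, NA where no point
#'   landed.
#' @slot summary named list: `pointsTotal`, `pointsRetained`,
#'   `verticesOccupied`, `lossFraction`, and the same occupancy/loss figures
#'   restricted to points below `voltageCutMV` (`pointsLowVoltage`,
#'   `verticesOccupiedLowVoltage`, `lossFractionLowVoltage`), plus
#'   `maxProjectionDistanceMM`, `voltageCutMV`, `combine`.
#'
#' @seealso [projectCloud()], [resolutionImpact()]
#' @export
setClass("ProjectionResult",
  representation(assignment = "data.frame", vertexVoltage = "numeric", summary = "list")
)

setValidity("ProjectionResult", function(object) {
  msg <- character()
  s <- object@summary
  need <- c("pointsTotal", "pointsRetained", "verticesOccupied", "lossFraction")
  if (!all(need %in% names(s))) msg <- c(msg, "summary missing required fields")
  else {
    if (s$pointsRetained > s$pointsTotal) msg <- c(msg, "retained points exceed total")
    if (s$lossFraction < 0 || s$lossFraction > 1) msg <- c(msg, "lossFraction outside [0,1]")
  }
  if (length(msg)) msg else TRUE
})
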