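#' Apply a spatial transform to points
#'
#' Maps a set of 3D points (or the vertices of an [LVMesh-class], or the
#' points of an [EAMCloud-class]) through a [RigidTransform-class], a
#' [TPSWarp-class], or a [RegistrationPipeline-class] (rigid followed by TPS).
#'
#' @param transform the transform object.
#' @param points an n x 3 numeric matrix, a length-3 vector, an
#'   [LVMesh-class] or an [EAMCloud-class].
#' @return an object of the same kind as `points` with mapped coordinates.
#' @examples
#' rt <- new("RigidTransform", rotation = diag(3), translation = c(1, 0, 0), scale = 1)
#' applyTransform(rt, c(0, 0, 0))
#' @export
setGeneric("applyTransform", function(transform, points) standardGeneric("applyTransform"))

#' Number of vertices / points in an object
#' @param x an [LVMesh-class] or [EAMCloud-class].
#' @return integer count.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname nVertices
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' Accessors for mesh attributes
#'
#' `vertices()`, `faces()`, `perfusion()` and `segmentLabels()` read the
#' corresponding [LVMesh-class] slots; `perfusion<-` and `segmentLabels<-`
#' set them with validity checking.
#'
#' @param x an [LVMesh-class].
#' @param value replacement per-vertex attribute vector.
#' @return the requested component, or the updated mesh for setters.
#' @name mesh-accessors
NULL

#' @rdname mesh-accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname mesh-accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname mesh-accessors
#' @export
setGeneric("perfusion", function(x) standardGeneric("perfusion"))
#' @rdname mesh-accessors
#' @export
setGeneric("perfusion<-", function(x, value) standardGeneric("perfusion<-"))
#' @rdname mesh-accessors
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))
#' @rdname mesh-accessors
#' @export
setGeneric("segmentLabels<-", function(x, value) standardGeneric("segmentLabels<-"))

#' @rdname mesh-accessors
#' @export
setGeneric("voltage", function(x) standardGeneric("voltage"))
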