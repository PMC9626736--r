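# AHA 17-segment labelling of the LV endocardial surface.

#' Default AHA 17-segment model
#'
#' Builds the standard AHA partition: 6 basal, 6 mid-cavity and 4 apical
#' sectors plus the apical cap (segment 17). The axial extent below the base
#' is split in equal thirds (boundaries 1/3 and 2/3); the most apical 15% of
#' the axial extent forms the cap. Circumferential angle 0 marks the leading
#' edge of the anterior sector and increases towards the septum, so the
#' basal/mid order is anterior (1/7), anteroseptal (2/8), inferoseptal (3/9),
#' inferior (4/10), inferolateral (5/11), anterolateral (6/12), and the
#' apical order is anterior (13), septal (14), inferior (15), lateral (16).
#'
#' @param bandBounds two increasing fractions in (0,1); defaults `c(1/3, 2/3)`.
#' @param apicalCapFraction cap extent as a fraction of the axial length,
#'   default 0.15.
#' @param anteriorRef direction defining circumferential angle zero,
#'   default `c(1, 0, 0)`.
#' @return a [SegmentModel17-class].
#' @examples
#' segmentModel17()
#' @export
segmentModel17 <- function(bandBounds = c(1 / 3, 2 / 3), apicalCapFraction = 0.15,
                           anteriorRef = c(1, 0, 0)) {
  new("SegmentModel17",
      bandBounds = bandBounds,
      apicalCapFraction = apicalCapFraction,
      sectorEdges6 = seq(0, 2 * pi, length.out = 7),
      sectorEdges4 = seq(0, 2 * pi, length.out = 5),
      anteriorRef = as.numeric(anteriorRef))
}

setMethod("show", "SegmentModel17", function(object) {
  cat("SegmentModel17 (AHA): bands at",
      paste(signif(object@bandBounds, 3), collapse = ", "),
      "| apical cap", object@apicalCapFraction, "\n")
  invisible(object)
})

#' Assign AHA 17-segment labels to mesh vertices
#'
#' Labels every vertex by its position relative to the long axis: the axial
#' fraction (0 at the base plane, 1 at the apex) selects the basal, mid,
#' apical band or the apical cap, and the circumferential angle about the
#' axis selects the sector within the band. The 17 label sets partition the
#' vertex set.
#'
#' @param mesh an [LVMesh-class] with apex, base centroid and long axis set.
#' @param model a [SegmentModel17-class]; default [segmentModel17()].
#' @return the mesh with `segmentLabels` filled in.
#' @examples
#' m <- labelSegments(makeLVMesh(nVertices = 500, seed = 1))
#' table(segmentLabels(m))
#' @export
labelSegments <- function(mesh, model = segmentModel17()) {
  stopifnot(is(mesh, "LVMesh"), is(model, "SegmentModel17"))
  t <- axialFraction(mesh)
  ang <- circumferentialAngle(mesh, model@anteriorRef)
  capStart <- 1 - model@apicalCapFraction
  b <- model@bandBounds
  lab <- integer(length(t))
  cap <- t > capStart
  lab[cap] <- 17L
  basal <- !cap & t < b[1]
  mid <- !cap & t >= b[1] & t < b[2]
  apical <- !cap & t >= b[2]
  s6 <- findInterval(ang, model@sectorEdges6, rightmost.closed = TRUE)
  s6 <- pmin(pmax(s6, 1L), 6L)
  s4 <- findInterval(ang, model@sectorEdges4, rightmost.closed = TRUE)
  s4 <- pmin(pmax(s4, 1L), 4L)
  lab[basal] <- s6[basal]
  lab[mid] <- 6L + s6[mid]
  lab[apical] <- 12L + s4[apical]
  segmentLabels(mesh) <- lab
  mesh
}

#' Segments belonging to a named scar territory
#'
#' Convenience lookup used by the synthetic generator to place defects where
#' the study cohort had them: inferior infarcts span the inferior wall across
#' bands, anteroseptal defects the basal/mid septum, apical defects the four
#' apical segments and the cap.
#'
#' @param territory one of "inferior", "anteroseptal", "apical".
#' @return integer vector of AHA segment numbers.
#' @export
territorySegments <- function(territory = c("inferior", "anteroseptal", "apical")) {
  switch(match.arg(territory),
    inferior = c(4L, 10L, 15L),
    anteroseptal = c(2L, 3L, 8L, 9L),
    apical = c(13L, 14L, 15L, 16L, 17L))
}
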