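# Viability scoring: map voltages and uptake to ordinal 0-3 scores, average
# per AHA segment, flag heterogeneity (SD > mean), and impute or exclude
# segments without voltage data.

#' Map bipolar voltage to a 0-3 viability score
#'
#' Scores ascend with viability: below 0.3 mV is deep scar (score 0), above
#' 1.5 mV healthy myocardium (score 3), and the 0.3-1.5 mV border zone is
#' split evenly at 0.9 mV into scores 1 and 2. Bins are left-closed
#' (a value equal to an edge takes the higher score).
#'
#' @param v voltages in mV (>= 0).
#' @param bins the three ascending bin edges, default `c(0.3, 0.9, 1.5)`.
#' @return integer scores in 0..3.
#' @examples
#' voltageToScore(c(0.2, 0.9, 2.0))
#' @export
voltageToScore <- function(v, bins = c(0.3, 0.9, 1.5)) {
  if (any(v < 0)) stop("voltages must be non-negative")
  findInterval(v, bins)
}

#' Map perfusion uptake to a 0-3 viability score
#'
#' Uptake is expressed as a fraction of the subject maximum. Below 30% is a
#' severe defect (score 0), 30-50% score 1, 50-70% score 2, and at or above
#' 70% fully viable (score 3); 50% of maximum is the conventional SPECT
#' viability cut and sits at the score 1/2 centre of the scale. Bins are
#' left-closed.
#'
#' @param u uptake fractions in [0, 1].
#' @param bins the three ascending bin edges, default `c(0.30, 0.50, 0.70)`.
#' @return integer scores in 0..3.
#' @examples
#' perfusionToScore(c(0.15, 0.5, 1.0))
#' @export
perfusionToScore <- function(u, bins = c(0.30, 0.50, 0.70)) {
  if (any(u < 0 | u > 1)) stop("uptake fractions must lie in [0, 1]")
  findInterval(u, bins)
}

#' Per-segment viability score table
#'
#' Averages per-vertex scores within each AHA segment for both modalities:
#' perfusion scores over all vertices of the segment, voltage scores over the
#' vertices occupied by projected points. A segment is flagged heterogeneous
#' when its score standard deviation (sample SD, n-1 denominator; 0 for a
#' single value) exceeds its mean. Segments with no voltage data are left
#' with `n = 0` for [imputeOrExclude()] to resolve.
#'
#' @param mesh a segment-labelled [LVMesh-class] with perfusion set.
#' @param projection a [ProjectionResult-class] for this mesh.
#' @param subject optional subject identifier carried into the table.
#' @param voltageBins,perfusionBins score bin edges, see [voltageToScore()]
#'   and [perfusionToScore()].
#' @return data.frame with one row per segment x modality: `subject`,
#'   `segment`, `modality` ("perfusion"/"voltage"), `n`, `mean`, `sd`,
#'   `heterogeneous`, `imputed`, `excluded`.
#' @export
segmentScores <- function(mesh, projection, subject = 1L,
                          voltageBins = c(0.3, 0.9, 1.5),
                          perfusionBins = c(0.30, 0.50, 0.70)) {
  stopifnot(is(mesh, "LVMesh"), is(projection, "ProjectionResult"))
  if (is.null(mesh@segmentLabels)) stop("mesh must be segment-labelled")
  if (is.null(mesh@perfusion)) stop("mesh must carry perfusion values")
  if (length(projection@vertexVoltage) != nrow(mesh@vertices))
    stop("projection does not match this mesh")

  perfScore <- perfusionToScore(mesh@perfusion, perfusionBins)
  vv <- projection@vertexVoltage
  rows <- vector("list", 34L)
  k <- 0L
  for (seg in 1:17) {
    inSeg <- mesh@segmentLabels == seg
    for (mod in c("perfusion", "voltage")) {
      vals <- if (mod == "perfusion") {
        perfScore[inSeg]
      } else {
        voltageToScore(vv[inSeg & !is.na(vv)], voltageBins)
      }
      n <- length(vals)
      mu <- if (n > 0) mean(vals) else NA_real_
      sdv <- if (n > 1) stats::sd(vals) else if (n == 1) 0 else NA_real_
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject = subject, segment = seg, modality = mod, n = n,
        mean = mu, sd = sdv,
        heterogeneous = isTRUE(sdv > mu),
        imputed = FALSE, excluded = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Impute or exclude segments without voltage data
#'
#' Segments never reached by the catheter carry no voltage score. When their
#' perfusion mean shows viable tissue (at or above the viability threshold)
#' they are assigned a voltage score of 3 and flagged imputed; otherwise the
#' segment is excluded from the analysis denominator (its viability cannot be
#' confirmed by either modality alone), and the exclusion is flagged on both
#' modality rows.
#'
#' @param table a segment score table from [segmentScores()] (possibly
#'   row-bound across subjects).
#' @param viabilityThreshold score threshold defining "known to be healthy"
#'   on perfusion (typically the ROC-selected classification threshold).
#' @return the updated table.
#' @export
imputeOrExclude <- function(table, viabilityThreshold) {
  stopifnot(is.data.frame(table))
  key <- paste(table$subject, table$segment)
  for (k in unique(key)) {
    i <- which(key == k)
    iv <- i[table$modality[i] == "voltage"]
    ip <- i[table$modality[i] == "perfusion"]
    if (length(iv) != 1L || length(ip) != 1L) next
    if (table$n[iv] > 0L) next
    if (!is.na(table$mean[ip]) && table$mean[ip] >= viabilityThreshold) {
      table$mean[iv] <- 3
      table$sd[iv] <- 0
      table$heterogeneous[iv] <- FALSE
      table$imputed[iv] <- TRUE
    } else {
      table$excluded[i] <- TRUE
    }
  }
  table
}
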