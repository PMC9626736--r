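# Segment-level agreement between the two modalities: threshold
# classification into TP/TN/FN/FP, the derived metrics, and ROC-based
# selection of the shared viability threshold.

# wide per-(subject, segment) view of a score table, excluded segments dropped
scoreTableWide <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("subject", "segment", "modality", "mean", "excluded") %in% names(table)))
  tab <- table[!table$excluded, , drop = FALSE]
  p <- tab[tab$modality == "perfusion", c("subject", "segment", "mean")]
  v <- tab[tab$modality == "voltage", c("subject", "segment", "mean")]
  names(p)[3] <- "perfusion"
  names(v)[3] <- "voltage"
  w <- merge(p, v, by = c("subject", "segment"))
  w <- w[!is.na(w$perfusion) & !is.na(w$voltage), , drop = FALSE]
  w[order(w$subject, w$segment), , drop = FALSE]
}

#' Classify segments as viable / not viable by both modalities
#'
#' Each non-excluded segment falls in one of four categories at the given
#' score threshold: true positive (both modality means at or above the
#' threshold), true negative (both below), false negative (perfusion viable
#' but voltage not: voltage overestimates scar), false positive (voltage
#' viable but perfusion not). Perfusion is the reference ("gold standard")
#' modality. Segments are pooled across subjects.
#'
#' @param table a (possibly multi-subject) score table after
#'   [imputeOrExclude()].
#' @param threshold viability score threshold; a mean at or above it is
#'   viable.
#' @return list with `threshold`, `counts` (named TP/TN/FN/FP), `nTotal`,
#'   `metrics` (see [classificationMetrics()]), `perSegment` (the wide table
#'   with a `category` column) and `perSubject` (subject-level concordance
#'   in percent).
#' @export
classifySegments <- function(table, threshold) {
  w <- scoreTableWide(table)
  if (nrow(w) == 0L) stop("no classifiable segments (all excluded or missing)")
  pPos <- w$perfusion >= threshold
  vPos <- w$voltage >= threshold
  w$category <- ifelse(pPos & vPos, "TP",
                ifelse(!pPos & !vPos, "TN",
                ifelse(pPos & !vPos, "FN", "FP")))
  counts <- c(TP = sum(w$category == "TP"), TN = sum(w$category == "TN"),
              FN = sum(w$category == "FN"), FP = sum(w$category == "FP"))
  agree <- w$category %in% c("TP", "TN")
  perSubject <- data.frame(
    subject = unique(w$subject),
    concordance = 100 * as.numeric(tapply(agree, w$subject, mean)[as.character(unique(w$subject))]),
    nSegments = as.integer(table(w$subject)[as.character(unique(w$subject))])
  )
  list(threshold = threshold, counts = counts, nTotal = nrow(w),
       metrics = classificationMetrics(counts["TP"], counts["TN"],
                                       counts["FN"], counts["FP"]),
       perSegment = w, perSubject = perSubject)
}

#' Concordance, sensitivity, specificity, PPV and NPV from 2x2 counts
#'
#' Derives the five agreement metrics from the segment classification counts,
#' reported in percent: concordance = (TP+TN)/N, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN). A metric
#' with a zero denominator is returned as NA (undefined), never as 0.
#'
#' @param TP,TN,FN,FP non-negative segment counts.
#' @return named numeric vector (percent, full precision) with elements
#'   `concordance`, `sensitivity`, `specificity`, `ppv`, `npv`; round to one
#'   decimal for reporting.
#' @examples
#' round(classificationMetrics(87, 130, 55, 40), 1)
#' @export
classificationMetrics <- function(TP, TN, FN, FP) {
  TP <- as.numeric(TP)[1]; TN <- as.numeric(TN)[1]
  FN <- as.numeric(FN)[1]; FP <- as.numeric(FP)[1]
  n <- TP + TN + FN + FP
  if (n <= 0) stop("empty classification: no segments")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(concordance = ratio(TP + TN, n),
    sensitivity = ratio(TP, TP + FN),
    specificity = ratio(TN, TN + FP),
    ppv = ratio(TP, TP + FP),
    npv = ratio(TN, TN + FN))
}

#' ROC sweep over score thresholds and Youden-optimal selection
#'
#' A single shared threshold binarises both modality means (viable when the
#' mean is at or above it), as in the clinical scoring procedure. The sweep
#' runs over every observed score value; at each candidate the sensitivity
#' and specificity of the voltage classification against the perfusion
#' reference are recorded, and the chosen threshold maximises Youden's J
#' (ties resolved towards the smaller threshold). The AUC is computed by the
#' trapezoidal rule over the ROC curve of the continuous voltage means
#' against perfusion binarised at the chosen threshold.
#'
#' @param table a score table after [imputeOrExclude()].
#' @param threshold optional fixed operating threshold; when given, Youden
#'   selection is skipped and the AUC truth is perfusion binarised at this
#'   value (used when the classification threshold is set externally, and
#'   for permutation nulls where re-selecting per permutation would bias the
#'   AUC upward).
#' @return list with `thresholds`, `sensitivity`, `specificity`, `youdenJ`
#'   (sweep vectors), `threshold` (chosen or fixed), `auc`, and `curve`
#'   (data.frame `cut`, `tpr`, `fpr` of the AUC construction).
#' @export
rocSelect <- function(table, threshold = NULL) {
  w <- scoreTableWide(table)
  if (nrow(w) == 0L) stop("no classifiable segments")
  if (length(unique(w$voltage)) < 2L)
    stop("fewer than 2 distinct voltage means: ROC sweep is degenerate")
  grid <- sort(unique(c(w$perfusion, w$voltage)))
  sens <- spec <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    t <- grid[i]
    pPos <- w$perfusion >= t
    vPos <- w$voltage >= t
    if (any(pPos)) sens[i] <- sum(pPos & vPos) / sum(pPos)
    if (any(!pPos)) spec[i] <- sum(!pPos & !vPos) / sum(!pPos)
  }
  ok <- !is.na(sens) & !is.na(spec)
  if (!any(ok))
    stop("perfusion reference is single-class at every candidate threshold")
  J <- sens + spec - 1
  if (is.null(threshold)) {
    Jok <- ifelse(ok, J, -Inf)
    best <- which(Jok == max(Jok))[1]        # ties -> smaller threshold
    chosen <- grid[best]
  } else {
    chosen <- threshold
  }

  truth <- w$perfusion >= chosen
  if (!any(truth) || all(truth))
    stop("perfusion reference is single-class at the chosen threshold")
  cuts <- c(Inf, sort(unique(w$voltage), decreasing = TRUE), -Inf)
  tpr <- fpr <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    vPos <- w$voltage >= cuts[i]
    tpr[i] <- sum(vPos & truth) / sum(truth)
    fpr[i] <- sum(vPos & !truth) / sum(!truth)
  }
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)

  list(thresholds = grid, sensitivity = sens, specificity = spec,
       youdenJ = J, threshold = chosen, auc = auc,
       curve = data.frame(cut = cuts, tpr = tpr, fpr = fpr))
}
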