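# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# mid-sized labelled mesh with an inferior defect
fixtureMesh <- function() {
  if (is.null(.fixtures$mesh)) {
    m <- labelSegments(makeLVMesh(nVertices = 600, seed = 42))
    .fixtures$mesh <- makePerfusion(
      m, list(scarSpec(4, territorySegments("inferior"))), noiseSD = 0.02, seed = 42)
  }
  .fixtures$mesh
}

# full-resolution labelled mesh (no defect)
fixtureMeshHigh <- function() {
  if (is.null(.fixtures$meshHigh))
    .fixtures$meshHigh <- labelSegments(makeLVMesh(nVertices = 3648, seed = 42))
  .fixtures$meshHigh
}

# identity ground truth (no frame offset, no deformation)
identityTruth <- function() {
  new("GroundTruth",
      rigid = new("RigidTransform", rotation = diag(3),
                  translation = c(0, 0, 0), scale = 1),
      deformCenters = matrix(0, 1, 3), deformVectors = matrix(0, 1, 3),
      deformSigma = 20)
}

# assemble a long-format score table from per-segment modality means
makeScoreTable <- function(perfMeans, voltMeans, subject = 1L) {
  n <- length(perfMeans)
  rbind(
    data.frame(subject = subject, segment = seq_len(n), modality = "perfusion",
               n = 5L, mean = perfMeans, sd = 0, heterogeneous = FALSE,
               imputed = FALSE, excluded = FALSE),
    data.frame(subject = subject, segment = seq_len(n), modality = "voltage",
               n = 5L, mean = voltMeans, sd = 0, heterogeneous = FALSE,
               imputed = FALSE, excluded = FALSE)
  )
}

# brute-force oracle: recount categories segment by segment
bruteForceMetrics <- function(perfMeans, voltMeans, threshold) {
  cat <- character(length(perfMeans))
  for (i in seq_along(perfMeans)) {
    p <- perfMeans[i] >= threshold
    v <- voltMeans[i] >= threshold
    cat[i] <- if (p && v) "TP" else if (!p && !v) "TN" else if (p) "FN" else "FP"
  }
  n <- length(cat)
  counts <- c(TP = sum(cat == "TP"), TN = sum(cat == "TN"),
              FN = sum(cat == "FN"), FP = sum(cat == "FP"))
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(counts = counts,
       metrics = c(concordance = pct(counts[["TP"]] + counts[["TN"]], n),
                   sensitivity = pct(counts[["TP"]], counts[["TP"]] + counts[["FN"]]),
                   specificity = pct(counts[["TN"]], counts[["TN"]] + counts[["FP"]]),
                   ppv = pct(counts[["TP"]], counts[["TP"]] + counts[["FP"]]),
                   npv = pct(counts[["TN"]], counts[["TN"]] + counts[["FN"]])))
}
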