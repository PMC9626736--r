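test_that("voltage-to-score bins match the clinical cutoffs, left-closed", {
  expect_identical(voltageToScore(c(0.2, 0.29, 0.3, 0.89, 0.9, 1.49, 1.5, 2.0)),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(voltageToScore(-0.1), "non-negative")
  # monotone non-decreasing
  v <- sort(runif(100, 0, 3))
  expect_true(all(diff(voltageToScore(v)) >= 0))
})

test_that("perfusion-to-score bins are left-closed on the uptake scale", {
  expect_identical(perfusionToScore(c(0.15, 0.29, 0.30, 0.49, 0.50, 0.69, 0.70, 1.0)),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(perfusionToScore(1.2), "\\[0, 1\\]")
  u <- sort(runif(100))
  expect_true(all(diff(perfusionToScore(u)) >= 0))
})

test_that("segment averaging, sample SD and the heterogeneity rule", {
  # build a small mesh/projection where one segment holds known voltage scores
  m <- fixtureMesh()
  pr <- projectCloud(new("EAMCloud", points = vertices(m)[1:50, ],
                         voltage = rep(2, 50)), m)
  tab <- segmentScores(m, pr)
  expect_identical(nrow(tab), 34L)
  expect_true(all(tab$mean >= 0 & tab$mean <= 3, na.rm = TRUE))
  expect_true(all(tab$sd >= 0, na.rm = TRUE))
  # flags agree with the SD > mean rule wherever data exist
  has <- tab$n > 0
  expect_identical(tab$heterogeneous[has], (tab$sd > tab$mean)[has])

  # hand-checked aggregates (sample SD, n-1 denominator)
  expect_identical(mean(c(0, 3)), 1.5)
  expect_equal(sd(c(0, 3)), 2.1213, tolerance = 1e-4)
  expect_true(sd(c(0, 3)) > mean(c(0, 3)))        # [0,3] -> heterogeneous
  expect_false(sd(c(2, 2, 2, 2)) > mean(c(2, 2, 2, 2)))
  expect_false(sd(c(3, 3, 3)) > mean(c(3, 3, 3)))
})

test_that("segment means are bounded by contributing scores and constants-3 are homogeneous", {
  m <- fixtureMesh()
  gt <- identityTruth()
  cl <- makeEAMCloud(m, 400, gt, seed = 3, radialJitterMM = 0)$cloud
  pr <- projectCloud(cl, m)
  tab <- segmentScores(m, pr)
  volt <- tab[tab$modality == "voltage" & tab$n > 0, ]
  expect_true(all(volt$mean >= 0 & volt$mean <= 3))
  # heterogeneity requires at least one score < 3
  expect_true(all(volt$mean[volt$heterogeneous] < 3))
})

test_that("voltage-empty segments are imputed when perfusion-healthy, else excluded", {
  tab <- makeScoreTable(perfMeans = c(2.5, 1.0, 2.0), voltMeans = c(NA, NA, 1.4))
  tab$n[tab$modality == "voltage" & tab$segment %in% c(1, 2)] <- 0L
  out <- imputeOrExclude(tab, viabilityThreshold = 1.72)

  v1 <- out[out$modality == "voltage" & out$segment == 1, ]
  expect_identical(v1$mean, 3)          # healthy on perfusion -> score 3
  expect_true(v1$imputed)
  expect_false(v1$excluded)

  s2 <- out[out$segment == 2, ]
  expect_true(all(s2$excluded))         # not perfusion-healthy -> excluded

  v3 <- out[out$modality == "voltage" & out$segment == 3, ]
  expect_identical(v3$mean, 1.4)        # voltage present -> untouched
  expect_false(v3$imputed || v3$excluded)
})
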