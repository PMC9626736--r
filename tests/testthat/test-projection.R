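test_that("points map to nearest vertices; occupancy defines loss", {
  m <- fixtureMesh()
  v <- vertices(m)

  # a point coincident with a vertex is assigned there at distance 0
  cl <- new("EAMCloud", points = v[5, , drop = FALSE], voltage = 2)
  pr <- projectCloud(cl, m)
  expect_identical(pr@assignment$vertex, 5L)
  expect_identical(pr@assignment$distance, 0)
  expect_identical(pr@summary$lossFraction, 0)

  # two points competing for one vertex: one effective value, half lost
  p <- v[10, , drop = FALSE]
  cl2 <- new("EAMCloud", points = rbind(p, p + 0.01), voltage = c(0.2, 3))
  pr2 <- projectCloud(cl2, m, combine = "min")
  expect_identical(pr2@summary$verticesOccupied, 1L)
  expect_identical(pr2@summary$lossFraction, 0.5)
  expect_identical(pr2@vertexVoltage[10], 0.2)   # scar-conservative minimum
  prMean <- projectCloud(cl2, m, combine = "mean")
  expect_identical(prMean@vertexVoltage[10], 1.6)

  expect_error(projectCloud(new("EAMCloud", points = matrix(0, 0, 3),
                                voltage = numeric(0)), m), "empty")
})

test_that("projection is idempotent on vertex-coincident clouds", {
  m <- fixtureMesh()
  idx <- seq(1, nVertices(m), by = 7)
  cl <- new("EAMCloud", points = vertices(m)[idx, ], voltage = rep(1, length(idx)))
  pr <- projectCloud(cl, m)
  expect_identical(pr@assignment$vertex, as.integer(idx))
  expect_identical(pr@summary$lossFraction, 0)
})

test_that("out-of-range points are dropped and counted", {
  m <- fixtureMesh()
  far <- matrix(c(500, 500, 500), 1, 3)
  cl <- new("EAMCloud", points = rbind(vertices(m)[1, ], far), voltage = c(1, 1))
  pr <- projectCloud(cl, m, maxDistanceMM = 10)
  expect_identical(pr@summary$pointsRetained, 1L)
  expect_true(is.na(pr@assignment$vertex[2]))
  # force-assignment keeps every point
  prInf <- projectCloud(cl, m, maxDistanceMM = Inf)
  expect_identical(prInf@summary$pointsRetained, 2L)
})

test_that("point loss obeys the pigeonhole bound on a coarse mesh", {
  lo <- makeLVMesh(358, seed = 5)
  lo <- makePerfusion(labelSegments(lo), list(), noiseSD = 0, seed = 5)
  gt <- identityTruth()
  cl <- makeEAMCloud(lo, 700, gt, seed = 5, radialJitterMM = 0)$cloud
  pr <- projectCloud(cl, lo, maxDistanceMM = Inf)
  expect_gte(pr@summary$verticesOccupied, 1L)
  expect_lte(pr@summary$verticesOccupied, min(700L, nVertices(lo)))
  expect_gte(pr@summary$lossFraction, 1 - nVertices(lo) / 700)
})

test_that("resolution impact: no loss for spread points on a dense mesh, coarse loses more", {
  hi <- fixtureMeshHigh()
  hi <- makePerfusion(hi, list(), noiseSD = 0, seed = 1)
  lo <- decimateMesh(hi, 358)

  # spread cloud far sparser than the dense mesh: zero loss at high resolution
  idx <- seq(1, nVertices(hi), by = 12)
  spread <- new("EAMCloud", points = vertices(hi)[idx, ],
                voltage = rep(2, length(idx)))
  tab <- resolutionImpact(spread, hi, lo)
  expect_identical(tab$lossFraction[tab$mesh == "high" & tab$subset == "all"], 0)

  # identical meshes give identical loss fractions
  same <- resolutionImpact(spread, hi, hi)
  expect_identical(same$lossFraction[same$mesh == "high"],
                   same$lossFraction[same$mesh == "low"])

  # decreasing resolution never decreases loss (10 random clouds)
  gt <- identityTruth()
  for (s in 1:10) {
    cl <- makeEAMCloud(hi, 600, gt, seed = s, radialJitterMM = 0)$cloud
    t2 <- resolutionImpact(cl, hi, lo, maxDistanceMM = Inf)
    expect_gte(t2$lossFraction[t2$mesh == "low" & t2$subset == "all"],
               t2$lossFraction[t2$mesh == "high" & t2$subset == "all"])
  }
})
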