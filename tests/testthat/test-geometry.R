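test_that("segment labelling partitions the mesh into the 17 AHA segments", {
  m <- fixtureMeshHigh()
  lab <- segmentLabels(m)
  expect_length(lab, nVertices(m))
  counts <- table(factor(lab, levels = 1:17))
  expect_true(all(counts > 0))          # all 17 segments populated
  expect_identical(sum(counts), as.integer(nVertices(m)))  # no overlap possible

  # the vertex closest to the apex lies in the apical cap
  d <- rowSums(sweep(vertices(m), 2, m@apex)^2)
  expect_identical(lab[which.min(d)], 17L)
})

test_that("band and sector assignment follow axial fraction and angle", {
  m <- fixtureMeshHigh()
  lab <- segmentLabels(m)
  t <- vtfuse:::axialFraction(m)
  ang <- vtfuse:::circumferentialAngle(m, c(1, 0, 0))
  basal <- t < 1 / 3
  expect_true(all(lab[basal] %in% 1:6))
  # angle in the second 60-degree sector at 10% axial depth -> anteroseptal
  pick <- basal & t < 0.15 & ang >= pi / 3 & ang < 2 * pi / 3
  expect_true(any(pick))
  expect_true(all(lab[pick] == 2L))
})

test_that("labelling is equivariant under rigid motion of mesh and reference", {
  m <- fixtureMesh()
  R <- rotationAboutAxis(c(1, 2, 3), 0.7)
  rt <- new("RigidTransform", rotation = R, translation = c(12, -5, 30), scale = 1)
  moved <- applyTransform(rt, m)
  model <- segmentModel17(anteriorRef = as.numeric(R %*% c(1, 0, 0)))
  expect_identical(segmentLabels(labelSegments(moved, model)), segmentLabels(m))
})

test_that("degenerate long axis is rejected", {
  expect_error(LVMesh(matrix(rnorm(12), 4, 3), matrix(c(1, 2, 3), 1, 3),
                      apex = c(0, 0, 0), baseCentroid = c(0, 0, 0)),
               "degenerate")
})

test_that("decimation hits the target count and preserves shape", {
  m <- fixtureMeshHigh()
  expect_identical(decimateMesh(m, nVertices(m)), m)   # identity case
  expect_error(decimateMesh(m, nVertices(m) + 1), "exceeds")

  lo <- decimateMesh(m, 358)
  expect_gte(nVertices(lo), 351)
  expect_lte(nVertices(lo), 365)
  expect_true(isConnectedMesh(lo))
  expect_lt(abs(surfaceArea(lo) - surfaceArea(m)) / surfaceArea(m), 0.10)
})

test_that("decimation transfers attributes and is monotone in two steps", {
  m <- fixtureMesh()
  mid <- decimateMesh(m, 300)
  expect_true(all(perfusion(mid) >= 0 & perfusion(mid) <= 1))
  expect_true(all(segmentLabels(mid) %in% 1:17))
  lo <- decimateMesh(mid, 150)
  expect_lte(abs(nVertices(lo) - 150), ceiling(0.02 * 150))
  expect_true(isConnectedMesh(lo))
})
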