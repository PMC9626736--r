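test_that("mesh generation is seeded, exact in count, and on-surface", {
  m1 <- makeLVMesh(nVertices = 3648, seed = 1)
  m2 <- makeLVMesh(nVertices = 3648, seed = 1)
  expect_identical(vertices(m1), vertices(m2))   # bit-identical under one seed
  expect_identical(faces(m1), faces(m2))

  m <- makeLVMesh(nVertices = 358, seed = 7)
  expect_gte(nVertices(m), 351)
  expect_lte(nVertices(m), 365)
  expect_true(isConnectedMesh(m))

  # every vertex satisfies the half-ellipsoid implicit equation
  v <- vertices(makeLVMesh(500, radiiMM = c(25, 25, 65), seed = 3))
  resid <- (v[, 1] / 25)^2 + (v[, 2] / 25)^2 + (v[, 3] / 65)^2 - 1
  expect_lt(max(abs(resid)), 1e-10)
  expect_true(all(v[, 3] <= 1e-9))               # open at the base plane z = 0

  # manifold surface: every edge borders 1 or 2 faces, and edges on a single
  # face (the open boundary) lie on the basal rim
  f <- faces(makeLVMesh(500, radiiMM = c(25, 25, 65), seed = 3))
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  mult <- table(key)
  expect_true(all(mult <= 2))
  rim <- unique(as.integer(unlist(strsplit(names(mult)[mult == 1], " "))))
  expect_lt(max(abs(v[rim, 3])), 1e-9)

  expect_error(makeLVMesh(500, radiiMM = c(25, -1, 65)), "positive")
  expect_error(makeLVMesh(10), "at least 50")
})

test_that("perfusion painting: defect-free, scar depth, and monotone burden", {
  m <- labelSegments(makeLVMesh(600, seed = 42))
  clean <- makePerfusion(m, list(), noiseSD = 0, seed = 1)
  expect_true(all(perfusion(clean) == 1))

  scar <- makePerfusion(m, list(scarSpec(4, territorySegments("inferior"))),
                        noiseSD = 0.02, seed = 1)
  core <- segmentLabels(scar) %in% territorySegments("inferior")
  # core sits at the severity level up to the noise floor (min of ~100
  # N(0.15, 0.02) draws)
  expect_lt(abs(mean(perfusion(scar)[core]) - 0.15), 0.01)
  expect_gte(min(perfusion(scar)[core]), 0.15 - 4.5 * 0.02)
  expect_lte(min(perfusion(scar)[core]), 0.20)
  expect_lt(mean(perfusion(scar)), mean(perfusion(clean)))

  expect_error(makePerfusion(m, list(), noiseSD = -1), "non-negative")
  expect_error(makePerfusion(makeLVMesh(600, seed = 42), list()), "labelled")
})

test_that("voltage cloud: surface sampling, class-conditional voltages, count", {
  m <- fixtureMesh()
  gt0 <- identityTruth()
  res <- makeEAMCloud(m, 1804, gt0, seed = 1, radialJitterMM = 0)
  expect_identical(nPoints(res$cloud), 1804L)
  expect_length(res$truth@pointClass, 1804L)
  expect_true(all(res$truth@pointSegment %in% 1:17))

  # identity transform, no jitter: points lie on the mesh surface
  nn <- vtfuse:::nearestNeighbor(res$cloud@points, vertices(m))
  edge <- sqrt(surfaceArea(m) * 4 / nrow(faces(m)))   # typical edge scale
  expect_lt(max(nn$distance), edge)

  # healthy-only mesh: >= 90% of points above the 1.5 mV healthy cutoff
  healthy <- makePerfusion(labelSegments(makeLVMesh(600, seed = 42)),
                           list(), noiseSD = 0, seed = 1)
  fr <- vapply(1:10, function(s) {
    gt <- makeGroundTruth(healthy, seed = s)
    mean(voltage(makeEAMCloud(healthy, 500, gt, seed = s)$cloud) > 1.5)
  }, numeric(1))
  expect_gte(median(fr), 0.9)

  expect_error(makeEAMCloud(m, 0, gt0), "at least 1")
})

test_that("scar-fraction of low-voltage points grows with scar extent", {
  base <- labelSegments(makeLVMesh(600, seed = 42))
  fracBelow <- function(segs) {
    m <- makePerfusion(base, list(scarSpec(segs[1], segs)), noiseSD = 0, seed = 5)
    gt <- identityTruth()
    mean(voltage(makeEAMCloud(m, 800, gt, seed = 9)$cloud) < 0.3)
  }
  small <- fracBelow(4L)
  large <- fracBelow(territorySegments("inferior"))
  expect_gte(large, small)
})

test_that("fiducials: pairing, noise model, count range and spread", {
  m <- fixtureMesh()
  gt <- makeGroundTruth(m, seed = 2)
  fid <- makeFiducials(m, gt, noiseSDMM = 0, seed = 3)
  expect_gte(length(fid@name), 12L)
  expect_lte(length(fid@name), 15L)
  expect_identical(sum(fid@role == "primary"), 3L)

  # zero noise: EAM-side fiducial is exactly the truth image of its mate
  expect_lt(max(abs(fid@source - applyGroundTruth(gt, fid@target))), 1e-12)

  # secondary fiducials are spread out on the surface
  sec <- fid@target[fid@role == "secondary", ]
  expect_gt(min(dist(sec)), 10)

  expect_error(makeFiducials(m, gt, nPrimary = 2), "at least 3")
})

test_that("ground truth transform is a proper rotation with bounded bumps", {
  m <- fixtureMesh()
  gt <- makeGroundTruth(m, seed = 11)
  expect_lt(abs(det(gt@rigid@rotation) - 1), 1e-10)
  expect_lte(max(sqrt(rowSums(gt@deformVectors^2))), 5)   # amplitude cap, mm
})
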