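test_that("rigid fit recovers exact and constructed transforms", {
  set.seed(1)
  pts <- matrix(runif(18, -40, 40), 6, 3)
  idFit <- fitRigid(pts, pts)
  expect_lt(max(abs(idFit@rotation - diag(3))), 1e-12)
  expect_lt(max(abs(idFit@translation)), 1e-12)

  R <- rotationAboutAxis(c(0, 0, 1), pi / 2)
  tgt <- pts %*% t(R) + matrix(c(10, 0, 0), 6, 3, byrow = TRUE)
  fit <- fitRigid(pts, tgt)
  expect_lt(max(abs(fit@rotation - R)), 1e-9)
  expect_lt(max(abs(fit@translation - c(10, 0, 0))), 1e-9)
  expect_lt(fre(fit, pts, tgt), 1e-9)
})

test_that("rigid fit rejects degenerate configurations, never reflects", {
  line <- cbind(1:5, 1:5, 1:5) * 1.0
  expect_error(fitRigid(line, line + 1), "collinear|coincident")

  # a reflected target still yields a proper rotation (det +1)
  set.seed(2)
  src <- matrix(rnorm(15, sd = 20), 5, 3)
  tgt <- src %*% diag(c(1, 1, -1))
  fit <- fitRigid(src, tgt)
  expect_lt(abs(det(fit@rotation) - 1), 1e-10)
})

test_that("noisy rigid fit recovers rotation within 3 degrees (95th pct)", {
  angErr <- vapply(1:100, function(s) {
    set.seed(s)
    src <- matrix(runif(18, -50, 50), 6, 3)
    R <- rotationAboutAxis(rnorm(3), runif(1, 0, pi))
    tgt <- src %*% t(R) + rep(c(5, -3, 10), each = 6) + matrix(rnorm(18), 6, 3)
    fit <- fitRigid(src, tgt)
    Rd <- t(fit@rotation) %*% R
    acos(pmin(pmax((sum(diag(Rd)) - 1) / 2, -1), 1)) * 180 / pi
  }, numeric(1))
  expect_lt(quantile(angErr, 0.95), 3)
})

test_that("rigid fit is equivariant under pre-rotation of both point sets", {
  set.seed(3)
  src <- matrix(runif(24, -40, 40), 8, 3)
  R0 <- rotationAboutAxis(c(1, 1, 0), 0.9)
  tgt <- src %*% t(R0) + matrix(c(3, 4, 5), 8, 3, byrow = TRUE) +
    matrix(rnorm(24, 0, 0.5), 8, 3)
  fit1 <- fitRigid(src, tgt)
  Rp <- rotationAboutAxis(c(0, 1, 2), 1.3)
  fit2 <- fitRigid(src %*% t(Rp), tgt %*% t(Rp))
  expect_equal(fit2@rotation, Rp %*% fit1@rotation %*% t(Rp), tolerance = 1e-8)
  expect_equal(fre(fit1, src, tgt),
               fre(fit2, src %*% t(Rp), tgt %*% t(Rp)), tolerance = 1e-8)
})

test_that("TPS: identity, affine reproduction, interpolation, side conditions", {
  set.seed(4)
  src <- matrix(runif(36, -40, 40), 12, 3)

  idW <- fitTPS(src, src)
  expect_lt(max(abs(idW@weights)), 1e-8)
  expect_lt(max(abs(idW@affine - rbind(0, diag(3)))), 1e-8)
  probe <- matrix(runif(30, -60, 60), 10, 3)
  expect_lt(max(abs(applyTransform(idW, probe) - probe)), 1e-7)

  # affine displacement fields are absorbed entirely by the affine part
  A <- matrix(c(1.1, 0.1, 0, -0.05, 0.95, 0.02, 0.03, 0, 1.02), 3, 3)
  tgt <- src %*% t(A) + matrix(c(5, -2, 7), 12, 3, byrow = TRUE)
  affW <- fitTPS(src, tgt)
  expect_lt(max(abs(affW@weights)), 1e-8)

  # generic targets: exact interpolation at stiffness 0
  tgt2 <- src + matrix(rnorm(36, 0, 3), 12, 3)
  w <- fitTPS(src, tgt2)
  expect_lt(max(abs(applyTransform(w, src) - tgt2)), 1e-8)
  expect_lt(fre(w, src, tgt2), 1e-8)
  # side conditions
  P <- cbind(1, src)
  expect_lt(max(abs(crossprod(P, w@weights))), 1e-8)
})

test_that("coplanar control points are rejected at stiffness 0, usable with stiffness", {
  set.seed(5)
  flat <- cbind(runif(8, -30, 30), runif(8, -30, 30), 0)
  tgt <- flat + matrix(rnorm(24), 8, 3)
  expect_error(fitTPS(flat, tgt), "coplanar")
  expect_s4_class(fitTPS(flat, tgt, stiffness = 1), "TPSWarp")
})

test_that("transforms compose and invert cleanly", {
  rt <- new("RigidTransform", rotation = rotationAboutAxis(c(1, 0, 2), 0.6),
            translation = c(4, 5, -6), scale = 1)
  pts <- matrix(rnorm(30, sd = 25), 10, 3)
  back <- applyTransform(invertRigid(rt), applyTransform(rt, pts))
  expect_lt(max(abs(back - pts)), 1e-9)

  idT <- new("RigidTransform", rotation = diag(3), translation = c(0, 0, 0), scale = 1)
  expect_identical(applyTransform(idT, pts), pts)
})

test_that("full pipeline recovers ground-truth positions on noise-free fiducials", {
  # one subject at full mesh resolution (the acceptance check covers the
  # median over a cohort of such subjects)
  m <- labelSegments(makeLVMesh(3648, seed = 1))
  gt <- makeGroundTruth(m, seed = 101)
  fid <- makeFiducials(m, gt, noiseSDMM = 0, seed = 201)
  reg <- fitRegistration(fid)
  back <- applyTransform(reg, applyGroundTruth(gt, vertices(m)))
  expect_lt(mean(sqrt(rowSums((back - vertices(m))^2))), 0.5)
})

test_that("registration error grows with fiducial noise and TRE improves with more secondaries", {
  m <- fixtureMesh()
  meanErr <- function(noise) {
    errs <- vapply(1:5, function(s) {
      gt <- makeGroundTruth(m, seed = s + 20)
      fid <- makeFiducials(m, gt, noiseSDMM = noise, seed = s)
      reg <- fitRegistration(fid)
      back <- applyTransform(reg, applyGroundTruth(gt, vertices(m)))
      mean(sqrt(rowSums((back - vertices(m))^2)))
    }, numeric(1))
    median(errs)
  }
  errByNoise <- vapply(c(0, 1, 2, 4), meanErr, numeric(1))
  expect_true(all(diff(errByNoise) > 0))

  treFor <- function(nSec, s) {
    gt <- makeGroundTruth(m, seed = s + 50)
    set.seed(s + 999)
    ho <- vertices(m)[sample.int(nVertices(m), 100), ]
    fid <- makeFiducials(m, gt, nSecondary = nSec, noiseSDMM = 1, seed = s)
    tre(fitRegistration(fid), applyGroundTruth(gt, ho), ho)
  }
  tre4 <- median(vapply(1:20, function(s) treFor(4L, s), numeric(1)))
  tre12 <- median(vapply(1:20, function(s) treFor(12L, s), numeric(1)))
  expect_lte(tre12, tre4)
})

test_that("fre and tre are zero on exact correspondences and reject empty input", {
  rt <- new("RigidTransform", rotation = diag(3), translation = c(1, 2, 3), scale = 1)
  pts <- matrix(rnorm(15), 5, 3)
  expect_identical(fre(rt, pts, applyTransform(rt, pts)), 0)
  expect_error(fre(rt, matrix(0, 0, 3), matrix(0, 0, 3)), "no pairs")
})
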