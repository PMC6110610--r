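# Rod tracing, segment sampling, initial orientations, sub-volume
# extraction and consistency curation.

straightRod <- function(len, r = 100, phi = 0) {
  y <- seq(0, len, by = 8)
  list(rod_id = 1L, centriole_id = 1L,
       points = cbind(r * cos(phi * pi / 180), y - len / 2,
                      r * sin(phi * pi / 180)))
}

test_that("segment sampling follows arc length", {
  expect_equal(nrow(sampleSegments(straightRod(440), 24)), 18)
  expect_equal(nrow(sampleSegments(straightRod(176), 24)), 7)
  expect_equal(nrow(sampleSegments(straightRod(16), 24)), 0)
  s <- sampleSegments(straightRod(96), 24)
  expect_equal(s$s, c(12, 36, 60, 84))
  expect_equal(s$ty, rep(1, 4))
  expect_error(sampleSegments(straightRod(96), -2), "step")
})

test_that("initial orientations map z to the tangent and x outward", {
  # rod parallel to the axis at azimuth 0: known closed form
  eul <- segmentOrientation(c(100, 0, 0), c(0, 1, 0))
  R <- eulerToMatrix(eul[1], eul[2], eul[3])
  expect_equal(as.numeric(R %*% c(0, 0, 1)), c(0, 1, 0), tolerance = 1e-9)
  expect_equal(as.numeric(R %*% c(1, 0, 0)), c(1, 0, 0), tolerance = 1e-9)
  # rods 40 degrees apart differ by 40 degrees in the in-plane angle
  e1 <- segmentOrientation(c(100, 0, 0), c(0, 1, 0))
  e2 <- segmentOrientation(100 * c(cos(pi * 40 / 180), 0,
                                   sin(pi * 40 / 180)), c(0, 1, 0))
  R1 <- eulerToMatrix(e1[1], e1[2], e1[3])
  R2 <- eulerToMatrix(e2[1], e2[2], e2[3])
  expect_equal(centriotome:::rotationDistance(R1, R2), 40,
               tolerance = 1e-6)
  # composing with the inverse gives identity
  R2 <- eulerToMatrix(e2[1], e2[2], e2[3])
  expect_lt(max(abs(R2 %*% t(R2) - diag(3))), 1e-9)
  expect_error(segmentOrientation(c(0, 0, 0) + 1e-12, c(0, 1, 0)),
               "degenerate")
})

test_that("initial orientations match ground truth on unflattened models", {
  # the S2 preset has straight single-domain rods: recovery is exact
  m <- assembleCentriole(s2Preset(), seed = 1)
  gt <- groundTruth(m)
  rods <- traceRods(NULL, "from_truth", truth = gt)
  expect_length(rods, 9)
  p <- sampleParticles(rods, seed = 1)
  p <- p[order(p$rod_id, p$s_nm), ]
  gt <- gt[order(gt$rod_id, gt$s_nm), ]
  expect_equal(nrow(p), nrow(gt))
  err <- vapply(seq_len(nrow(p)), function(i)
    centriotome:::rotationDistance(
      eulerToMatrix(p$rot_deg[i], p$tilt_deg[i], p$psi_deg[i]),
      eulerToMatrix(gt$rot_deg[i], gt$tilt_deg[i], gt$psi_deg[i])), 0)
  expect_lt(max(err), 1)
  expect_lt(max(abs(p$x_nm - gt$x_nm)), 0.5)

  # CHO rods kink at the domain boundary (radius change); away from the
  # boundary recovery is equally exact
  mC <- assembleCentriole(choPreset(), seed = 1)
  gtC <- groundTruth(mC)
  pC <- sampleParticles(traceRods(NULL, "from_truth", truth = gtC),
                        seed = 1)
  expect_equal(nrow(pC), nrow(gtC))
  pC <- pC[order(pC$rod_id, pC$s_nm), ]
  gtC <- gtC[order(gtC$rod_id, gtC$s_nm), ]
  # the tangent window spans ~3 control points (72 nm); stay clear of it
  away <- abs(gtC$s_nm - 200) > 80
  errC <- vapply(which(away), function(i)
    centriotome:::rotationDistance(
      eulerToMatrix(pC$rot_deg[i], pC$tilt_deg[i], pC$psi_deg[i]),
      eulerToMatrix(gtC$rot_deg[i], gtC$tilt_deg[i], gtC$psi_deg[i])), 0)
  expect_lt(max(errC), 1)
})

test_that("auto tracing finds 9 rods in a noiseless tomogram", {
  m <- assembleCentriole(choPreset(), seed = 1)
  tomo <- reconstructWBP(projectTiltSeries(rasterize(m, 4,
                                                     c(96, 120, 96))))
  rods <- traceRods(tomo, "auto")
  expect_length(rods, 9)
  lens <- vapply(rods, function(r) diff(range(r$points[, 2])), 0)
  expect_true(all(lens > 400))
  # rod centre lines sit near the ground-truth blade centres
  gt <- groundTruth(m)
  gtr <- sqrt(gt$x_nm[1]^2 + gt$z_nm[1]^2)
  rr <- vapply(rods, function(r)
    mean(sqrt(r$points[, 1]^2 + r$points[, 3]^2)), 0)
  # the density centroid of a decorated blade sits near, not on, the
  # tubule-centroid line
  expect_lt(max(abs(rr - gtr)), 15)
  expect_error(traceRods(DensityVolume(array(0, c(16, 16, 16)), 4), "auto"),
               "rod-deficit")
})

test_that("sub-volume extraction inverts rotations", {
  set.seed(3)
  v <- DensityVolume(array(0, c(40, 40, 40)), 1)
  blobs <- data.frame(x = runif(15, -10, 10), y = runif(15, -10, 10),
                      z = runif(15, -10, 10), sigma = 2.5, mass = 1)
  v <- rasterize(blobs, 1, box = c(40, 40, 40))
  # identity orientation, centre of the box: exact crop
  sub <- extractSubvolume(v, c(0, 0, 0), c(0, 0, 0), 24)
  expect_equal(volData(sub), volData(v)[9:32, 9:32, 9:32],
               tolerance = 1e-9)
  # extract with R, then extract from the result with R^-1: the round
  # trip recovers the central crop within interpolation error
  eul <- c(25, 40, -30)
  mid <- extractSubvolume(v, c(0, 0, 0), eul, 40)
  back <- extractSubvolume(mid, c(0, 0, 0), c(-eul[3], -eul[2], -eul[1]),
                           20)
  crop <- extractSubvolume(v, c(0, 0, 0), c(0, 0, 0), 20)
  rms <- sqrt(mean((volData(back) - volData(crop))^2))
  expect_lt(rms, 0.06 * sd(volData(crop)))   # two trilinear passes
  expect_error(extractSubvolume(v, c(100, 0, 0), c(0, 0, 0), 16),
               "out-of-bounds")
})

test_that("consistency curation rejects only outliers", {
  m <- assembleCentriole(choPreset(), seed = 1)
  rods <- traceRods(NULL, "from_truth", truth = groundTruth(m))
  p <- sampleParticles(rods, seed = 1)
  res <- curateConsistency(p)
  expect_equal(nrow(res$rejected), 0)
  # one particle rotated 90 degrees is exactly the one rejected
  p2 <- p
  bad <- which(p2$rod_id == 3)[5]
  p2$psi_deg[bad] <- p2$psi_deg[bad] + 90
  res2 <- curateConsistency(p2)
  expect_equal(res2$rejected$particle_id, p2$particle_id[bad])
  # infinite thresholds reject nothing
  res3 <- curateConsistency(p2, maxAngleDev = Inf, maxShiftDev = Inf)
  expect_equal(nrow(res3$rejected), 0)
})
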