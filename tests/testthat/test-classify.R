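# Axial binning, proximal/distal splitting and masked classification.

test_that("axial binning partitions the particle set", {
  m <- assembleCentriole(choPreset(), seed = 1)
  rods <- traceRods(NULL, "from_truth", truth = groundTruth(m))
  p <- sampleParticles(rods, seed = 1)
  # bin populations from the step-24 sampling: 12+24k in [0,100) -> 4, etc.
  edges <- seq(0, 400, by = 100)
  counts <- table(cut(p$s_nm, edges, right = FALSE))
  expect_equal(sum(counts) + sum(p$s_nm >= 400), nrow(p))
  sim <- simulateSegments(fixtureBlade, 8, snr = Inf, box = 24,
                          voxelSize = 2, angSd = 0, shiftSd = 0, seed = 2)
  sim$particles$s_nm <- seq(12, by = 24, length.out = 8)
  avgs <- axialBinAverage(sim$particles, sim$subvols, c(0, 100, 200, 500),
                          voxelSize = 2)
  expect_length(avgs, 3)
  expect_equal(nParticles(avgs[[1]]), 4L)   # s = 12, 36, 60, 84
  expect_equal(nParticles(avgs[[2]]), 4L)
  expect_null(avgs[[3]])                    # no particles beyond 200 nm
  # a bin beyond the rod length is reported empty
  avgs2 <- axialBinAverage(sim$particles, sim$subvols, c(1000, 2000),
                          voxelSize = 2)
  expect_null(avgs2[[1]])
  # a single bin covering everything equals the global average
  all1 <- axialBinAverage(sim$particles, sim$subvols, c(0, 1e4),
                          voxelSize = 2)[[1]]
  glob <- averageParticles(sim$particles, sim$subvols, voxelSize = 2)
  expect_equal(volData(all1), volData(glob), tolerance = 1e-12)
  expect_error(axialBinAverage(sim$particles, sim$subvols, c(3, 2, 1)),
               "increasing")
})

test_that("proximal/distal split is a half-open partition at the boundary", {
  m <- assembleCentriole(choPreset(), seed = 1)
  rods <- traceRods(NULL, "from_truth", truth = groundTruth(m))
  p <- sampleParticles(rods, seed = 1)
  sp <- splitProximalDistal(p, 200)
  expect_equal(nrow(sp$proximal) + nrow(sp$distal), nrow(p))
  expect_equal(nrow(sp$proximal) / 9, 8)   # s = 12+24k < 200
  expect_equal(nrow(sp$distal) / 9, 10)
  # ground-truth domain labels agree exactly
  gt <- groundTruth(m)
  key <- paste(gt$rod_id, gt$s_nm)
  dom <- gt$domain[match(paste(sp$proximal$rod_id, sp$proximal$s_nm), key)]
  expect_true(all(dom == "proximal"))
  # boundary at 0+ puts everything distal
  expect_equal(nrow(splitProximalDistal(p, 1e-9)$proximal), 0)
})

test_that("masked classification separates partial-B blades", {
  sp <- bladeSpecForPreset(s2Preset(), "fly")
  bmFull <- buildBlade(sp, 24, tilt = 50, seed = 1)
  bmPart <- buildBlade(makePartialB(sp), 24, tilt = 50, seed = 1)
  nF <- 54L; nP <- 6L   # 10% partial-B
  simF <- simulateSegments(bmFull, nF, snr = 0.5, box = 40, voxelSize = 2,
                           angSd = 0, shiftSd = 0, seed = 3)
  simP <- simulateSegments(bmPart, nP, snr = 0.5, box = 40, voxelSize = 2,
                           angSd = 0, shiftSd = 0, seed = 4)
  particles <- rbind(simF$particles, simP$particles)
  particles$particle_id <- seq_len(nrow(particles))
  subvols <- c(simF$subvols, simP$subvols)
  truthLab <- rep(c(1L, 2L), c(nF, nP))
  # tight mask over the B03-B06 wall region
  lay <- bmFull
  angsB <- lay@pfAngles$B[3:6]
  wall <- t(vapply(angsB, function(a)
    lay@centers$B + 11.5 * c(cos(pi * a / 180), sin(pi * a / 180)),
    numeric(2)))
  d <- rep(40L, 3)
  cx <- (d - 1) / 2
  mask <- array(0, d)
  for (k in seq_len(nrow(wall))) {
    ix <- round(cx[1] + wall[k, 1] / 2) + 1
    iy <- round(cx[2] + wall[k, 2] / 2) + 1
    mask[(ix - 2):(ix + 2), (iy - 2):(iy + 2), ] <- 1
  }
  cm <- maskedClassify(particles, subvols, mask, k = 2, nRounds = 30,
                       seed = 7, voxelSize = 2, lowpass = 5)
  agree <- max(mean(cm$assignments == truthLab),
               mean(cm$assignments == 3L - truthLab))
  expect_gte(agree, 0.9)
  # the partial class has the lower masked density
  selMin <- selectClass(cm, mask, "min_mask_density")
  lab <- truthLab[selMin$particles]
  expect_gte(mean(lab == 2L), 0.9)
  # classification objective non-decreasing over rounds
  expect_true(all(diff(cm$report$meanCC) > -1e-6))
  # determinism under the seed
  cm2 <- maskedClassify(particles, subvols, mask, k = 2, nRounds = 30,
                        seed = 7, voxelSize = 2, lowpass = 5)
  expect_identical(cm$assignments, cm2$assignments)
  # k = 1: everything in one class
  cm1 <- maskedClassify(particles, subvols, mask, k = 1, voxelSize = 2)
  expect_true(all(cm1$assignments == 1L))
  expect_error(maskedClassify(particles, subvols, mask,
                              k = nrow(particles) + 1), "exceeds")
})

test_that("pinhead-masked classes separate proximal from distal blades", {
  nP <- 30L; nD <- 30L
  simP <- simulateSegments(fixtureBlade, nP, snr = 0.5, box = 40,
                           voxelSize = 2, angSd = 0, shiftSd = 0, seed = 8)
  simD <- simulateSegments(fixtureBladeDistal, nD, snr = 0.5, box = 40,
                           voxelSize = 2, angSd = 0, shiftSd = 0, seed = 9)
  particles <- rbind(simP$particles, simD$particles)
  particles$particle_id <- seq_len(nrow(particles))
  subvols <- c(simP$subvols, simD$subvols)
  mask <- decorationMask(fixtureBlade, "pinhead", rep(40L, 3), 2)
  cm <- maskedClassify(particles, subvols, mask, k = 2, nRounds = 30,
                       seed = 5, voxelSize = 2, lowpass = 5)
  truthLab <- rep(c(1L, 2L), c(nP, nD))
  agree <- max(mean(cm$assignments == truthLab),
               mean(cm$assignments == 3L - truthLab))
  expect_gte(agree, 0.85)
  # the pinhead-free (distal) class has the lower masked density
  sel <- selectClass(cm, mask, "min_mask_density")
  expect_gte(mean(truthLab[sel$particles] == 2L), 0.85)
})

test_that("degenerate duplicate particles collapse into one class", {
  sim <- simulateSegments(fixtureBlade, 1, snr = Inf, box = 24,
                          voxelSize = 2, angSd = 0, shiftSd = 0, seed = 5)
  particles <- sim$particles[c(1, 1), ]
  particles$particle_id <- 1:2
  particles$half_set <- 0:1
  mask <- array(1, rep(24, 3))
  expect_message(
    cm <- maskedClassify(particles, sim$subvols[c(1, 1)], mask, k = 2,
                         nRounds = 4, seed = 1, voxelSize = 2),
    "re-seeded")
  expect_equal(length(unique(cm$assignments)), 1L)
})

test_that("null classification is flagged low-confidence", {
  sim <- simulateSegments(fixtureBlade, 16, snr = 1, box = 32,
                          voxelSize = 2, angSd = 0, shiftSd = 0, seed = 6)
  mask <- cylMask(32, 13, 8)
  cm <- maskedClassify(sim$particles, sim$subvols, mask, k = 2,
                       nRounds = 10, seed = 2, voxelSize = 2)
  sel <- selectClass(cm, mask, "min_mask_density")
  expect_true(sel$lowConfidence)
})
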