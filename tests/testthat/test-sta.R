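# Subtomogram alignment and averaging: constrained CC vs the real-space
# oracle, pose recovery, wedge-weighted averaging, FSC, periodicity and
# protofilament counting.

test_that("constrained CC has its analytic fixed points", {
  set.seed(1)
  x <- array(rnorm(24^3), rep(24, 3))
  expect_equal(constrainedCC(x, x), 1, tolerance = 1e-6)
  expect_equal(constrainedCC(x, -x), -1, tolerance = 1e-6)
  expect_error(constrainedCC(x, array(0, rep(16, 3))), "unequal")
  w <- array(FALSE, rep(24, 3))
  expect_error(constrainedCC(x, x, wedgeA = w), "empty-overlap")
})

test_that("constrained CC equals the real-space wedge-filtered oracle", {
  # independent oracle: filter both volumes to the joint region in real
  # space and take the plain Pearson correlation
  for (seed in 1:20) {
    set.seed(seed)
    a <- array(rnorm(32^3), rep(32, 3))
    b <- array(rnorm(32^3), rep(32, 3))
    regA <- centriotome:::wedgeRegion(rep(32, 3), -60, 60)
    regB <- centriotome:::wedgeRegion(rep(32, 3), -50, 70,
                                      R = eulerToMatrix(20, 30, 10))
    reg <- regA & regB
    af <- Re(fft(fft(a) * reg, inverse = TRUE)) / length(a)
    bf <- Re(fft(fft(b) * reg, inverse = TRUE)) / length(b)
    oracle <- cor(as.numeric(af), as.numeric(bf))
    got <- constrainedCC(a, b, wedgeA = regA, wedgeB = regB)
    expect_equal(got, oracle, tolerance = 1e-3)
  }
})

test_that("grid search recovers a known misrotation", {
  bm <- fixtureBlade
  ref <- suppressWarnings(rasterize(bm, 1.5, box = rep(48, 3)))
  # noiseless segment misrotated by 4 degrees in psi
  sim <- simulateSegments(bm, 1, snr = Inf, box = 48, voxelSize = 1.5,
                          angSd = 0, shiftSd = 0, seed = 2)
  sv <- centriotome:::fftInv(fft(suppressWarnings(
    rasterize(buildBlade(bm@spec, 24, tilt = choP@bladeTiltProximal + 4,
                         seed = 1), 1.5, box = rep(48, 3)))@data) *
    centriotome:::wedgeRegion(rep(48, 3), -60, 60,
                              R = eulerToMatrix(sim$particles$rot_x,
                                                sim$particles$tilt_x,
                                                sim$particles$psi_x)))
  params <- AlignmentParams(angularRange = 8, angularStep = 2,
                            shiftRange = 0, lowpass = 4, nIterations = 1L)
  al <- alignParticle(sv, volData(ref), sim$particles[1, ], params,
                      voxelSize = 1.5, mask = cylMask(48, 21, 10))
  # a +4 degree in-plane rotation of the blade content must be recovered
  # within one 2-degree step
  Rfound <- eulerToMatrix(al$rot_deg, al$tilt_deg, al$psi_deg)
  Rtrue <- eulerToMatrix(sim$particles$rot_x, sim$particles$tilt_x,
                         sim$particles$psi_x) %*% eulerToMatrix(0, 0, 4)
  expect_lt(centriotome:::rotationDistance(Rfound, Rtrue), 2)

  # zero ranges: particle unchanged, score recorded
  p0 <- AlignmentParams(angularRange = 0, angularStep = 1, shiftRange = 0,
                        lowpass = 4, nIterations = 1L)
  al0 <- alignParticle(sim$subvols[[1]], volData(ref), sim$particles[1, ],
                       p0, voxelSize = 1.5)
  expect_equal(al0$psi_deg, sim$particles$psi_deg[1])
  expect_false(is.na(al0$score))
})

test_that("alignment recovers poses at SNR 0.5 for >= 90% of particles", {
  bm <- fixtureBlade
  sim <- simulateSegments(bm, 100, snr = 0.5, box = 48, voxelSize = 1.5,
                          angSd = 2, shiftSd = 1.5, seed = 11)
  ref <- suppressWarnings(rasterize(bm, 1.5, box = rep(48, 3)))
  params <- AlignmentParams(angularRange = 4, angularStep = 2,
                            shiftRange = 4, shiftStep = 1, lowpass = 4,
                            nIterations = 2L)
  res <- runAlignment(sim$particles, sim$subvols, params,
                      reference0 = volData(ref), voxelSize = 1.5,
                      mask = cylMask(48, 21, 10), goldStandard = FALSE)
  err <- angularError(res$particles)
  expect_gte(mean(err <= params@angularStep), 0.9)
  # refinement reduces the mean geodesic error below the injected one
  err0 <- angularError(sim$particles)
  expect_lt(mean(err), mean(err0))
  # per-iteration mean score non-decreasing (within tolerance)
  expect_gte(diff(res$meanScore), -1e-3)
})

test_that("wedge-weighted averaging is idempotent and fills coverage", {
  bm <- fixtureBlade
  sim <- simulateSegments(bm, 6, snr = Inf, box = 32, voxelSize = 2,
                          angSd = 0, shiftSd = 0, seed = 4)
  # identical aligned noiseless copies with a shared wedge: average equals
  # any copy up to the coverage-floor regions
  p <- sim$particles
  same <- sim$particles[rep(1, 6), ]
  same$half_set <- rep(c(0L, 1L), 3)
  avg <- averageParticles(same, sim$subvols[rep(1, 6)], voxelSize = 2)
  reg <- centriotome:::wedgeRegion(rep(32, 3), -60, 60,
    R = eulerToMatrix(same$rot_deg[1], same$tilt_deg[1], same$psi_deg[1]))
  a <- Re(fft(fft(volData(avg)) * reg, inverse = TRUE)) / 32^3
  b <- sim$subvols[[1]]
  expect_lt(sqrt(mean((a - b)^2)), 1e-3 * sd(b))

  # complementary wedges: union coverage strictly larger than either
  two <- sim$particles[1:2, ]
  avg2 <- averageParticles(two, sim$subvols[1:2], voxelSize = 2)
  covBoth <- wedgeCoverage(avg2) > 0
  r1 <- centriotome:::wedgeRegion(rep(32, 3), -60, 60,
    R = eulerToMatrix(two$rot_deg[1], two$tilt_deg[1], two$psi_deg[1]))
  expect_gt(sum(covBoth), sum(r1))

  # single particle: average equals that particle's wedge-filtered volume
  one <- averageParticles(sim$particles[1, ], sim$subvols[1],
                          voxelSize = 2)
  af <- Re(fft(fft(volData(one)) * r1, inverse = TRUE)) / 32^3
  expect_lt(sqrt(mean((af - sim$subvols[[1]])^2)), 1e-3 * sd(b))

  expect_error(averageParticles(sim$particles[0, ], list()), "empty-set")
})

test_that("averages of many noisy segments correlate with the truth", {
  bm <- fixtureBlade
  sim <- simulateSegments(bm, 200, snr = 0.25, box = 40, voxelSize = 2,
                          angSd = 0, shiftSd = 0, seed = 8)
  avg <- averageParticles(sim$particles, sim$subvols, voxelSize = 2)
  truth <- suppressWarnings(rasterize(bm, 2, box = rep(40, 3)))
  m <- cylMask(40, 17, 9)
  expect_gt(centriotome:::maskedNCC(volData(avg), volData(truth), m), 0.9)
})

test_that("FSC behaves at its analytic limits", {
  set.seed(5)
  a <- array(rnorm(32^3), rep(32, 3))
  fsc1 <- computeFSC(a, a)
  expect_true(all(fsc1@fsc > 1 - 1e-9))
  # independent white noise: |FSC| below 3/sqrt(n) in >= 95% of shells
  b <- array(rnorm(32^3), rep(32, 3))
  fsc0 <- computeFSC(a, b)
  expect_gte(mean(abs(fsc0@fsc) < 3 / sqrt(fsc0@nvox)), 0.95)
  # band-limited source: resolution at the band limit
  lp <- centriotome:::lowpassMask(rep(32, 3), 1, 4)
  af <- Re(fft(fft(a) * lp, inverse = TRUE)) / 32^3
  bf <- af + 0.05 * sd(af) * array(rnorm(32^3), rep(32, 3))
  fscB <- computeFSC(af, bf, voxelSize = 1)
  shellW <- 1 / 32
  expect_lte(resolutionAt(fscB, 0.143), 1 / (1 / 4 - shellW) + 1e-6)
  expect_gte(resolutionAt(fscB, 0.143), 3.0)
  expect_error(computeFSC(array(0, rep(4, 3)), array(0, rep(4, 3))),
               "box")
})

test_that("decoration periodicity detection recovers generator periods", {
  latA <- LatticeSpec(13, 12.5, seamBetween = c(9L, 10L), seamExtraGap = 5)
  A <- TubuleSpec("A", latA)
  bare <- buildBlade(BladeSpec(list(A)), 40, tilt = 0, seed = 1)
  tub <- rasterize(bare, 1.25, box = rep(48, 3))
  for (per in c(8, 16)) {
    dec <- DecorationSpec("probe", "A", c(9L, 10L),
                          offsets = c(-2.8, 0, 0), sigmas = 1.6,
                          masses = 2, axialPeriod = per)
    bmD <- buildBlade(BladeSpec(list(A), list(dec)), 40, tilt = 0,
                      seed = 1)
    avg <- rasterize(bmD, 1.25, box = rep(48, 3))
    expect_equal(decorationPeriodicity(avg, tub), per)
  }
  expect_error(decorationPeriodicity(tub, tub), "ambiguous-period")
})

test_that("protofilament counting matches the lattice on ideal maps", {
  ann <- bladeAnnuli(fixtureBlade)
  expect_equal(countProtofilaments(fixtureRef, ann$A$center,
                                   ann$A$annulus), 13L)
  expect_equal(countProtofilaments(fixtureRef, ann$B$center,
                                   ann$B$annulus, arc = ann$B$arc), 10L)
  expect_equal(countProtofilaments(fixtureRef, ann$C$center,
                                   ann$C$annulus, arc = ann$C$arc), 10L)
  # uniform density: zero peaks
  u <- DensityVolume(array(1, rep(32, 3)), 1.5)
  expect_equal(countProtofilaments(u, c(0, 0), c(5, 12)), 0L)
  expect_error(countProtofilaments(fixtureRef, c(0, 0), c(12, 9)),
               "annulus")
  # invariance under in-plane rotation of the average
  v <- volData(fixtureRef)
  rot <- centriotome:::.cppResample(v, dim(v),
                                    eulerToMatrix(0, 0, 35), c(0, 0, 0), 0)
  cen <- ann$A$center
  a <- -35 * pi / 180
  cenR <- c(cos(a) * cen[1] - sin(a) * cen[2],
            sin(a) * cen[1] + cos(a) * cen[2])
  expect_equal(countProtofilaments(DensityVolume(rot, 1.5), cenR,
                                   ann$A$annulus), 13L)
})
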