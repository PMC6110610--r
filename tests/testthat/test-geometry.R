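# Geometry: pose refit, ellipse fitting, flattening correction,
# symmetrization, diameter and blade-tilt measurement, composite rebuild.

test_that("direct least-squares ellipse fit recovers known conics", {
  th <- seq(0, 2 * pi, length.out = 10)[-10]
  # 9 points on an exact circle
  circ <- cbind(100 * cos(th), 100 * sin(th))
  f <- fitEllipse(circ)
  expect_equal(f@a, 100, tolerance = 1e-6)
  expect_equal(f@b, 100, tolerance = 1e-6)
  expect_equal(ellipticity(f), 0, tolerance = 1e-6)

  # noiseless ellipse: 1e-6 relative recovery of all parameters
  rotp <- function(p, deg) {
    a <- deg * pi / 180
    cbind(p[, 1] * cos(a) - p[, 2] * sin(a),
          p[, 1] * sin(a) + p[, 2] * cos(a))
  }
  th2 <- seq(0, 2 * pi, length.out = 41)[-41]
  ell <- sweep(rotp(cbind(110 * cos(th2), 90 * sin(th2)), 25), 2,
               c(13, -7), "+")
  f2 <- fitEllipse(ell)
  expect_equal(f2@a, 110, tolerance = 1e-6)
  expect_equal(f2@b, 90, tolerance = 1e-6)
  expect_equal(f2@center, c(13, -7), tolerance = 1e-5)
  expect_equal(f2@orientation, 25, tolerance = 1e-4)

  # noisy ellipse: ellipticity within 1 point of 100*(110-90)/110
  set.seed(9)
  noisy <- ell + matrix(rnorm(2 * nrow(ell), sd = 1), ncol = 2)
  expect_equal(ellipticity(fitEllipse(noisy)), 100 * 20 / 110,
               tolerance = 1 / (100 * 20 / 110))

  expect_error(fitEllipse(ell[1:5, ]), "fit-degenerate")
  line <- cbind(1:10, 2 * (1:10) + 3)
  expect_error(fitEllipse(line), "fit-degenerate")
})

refitFromTruth <- function(model) {
  rods <- traceRods(NULL, "from_truth", truth = groundTruth(model))
  refitPositions(sampleParticles(rods, seed = 1))
}

test_that("pose refit reproduces the cross-section geometry", {
  cs <- refitFromTruth(assembleCentriole(choPreset(), seed = 1))
  rodMeans <- t(vapply(split(seq_along(cs@rodId), cs@rodId), function(i)
    colMeans(cs@points[i, , drop = FALSE]), numeric(2)))
  # unflattened: rod means equidistant from the centroid within 2 nm
  # (per-domain radii differ, so use the proximal subset)
  m <- assembleCentriole(choPreset(), seed = 1)
  rods <- traceRods(NULL, "from_truth", truth = groundTruth(m))
  p <- sampleParticles(rods, seed = 1)
  csP <- refitPositions(p[p$s_nm < 200, ])
  rmP <- t(vapply(split(seq_len(sum(p$s_nm < 200)), p$rod_id[p$s_nm < 200]),
                  function(i) colMeans(csP@points[i, , drop = FALSE]),
                  numeric(2)))
  r <- sqrt(rowSums(rmP^2))
  expect_lt(max(abs(r - mean(r))), 2)

  # flattened e = 0.25: max/min rod-mean distance ratio ~ (1+e)^2 within 5%
  mF <- assembleCentriole(choPreset(), FlatteningSpec(0.25), seed = 1)
  rodsF <- traceRods(NULL, "from_truth", truth = groundTruth(mF))
  pF <- sampleParticles(rodsF, seed = 1)
  csF <- refitPositions(pF[pF$s_nm < 200, ])
  rmF <- t(vapply(split(seq_len(nrow(csF@points)),
                        csF@rodId), function(i)
    colMeans(csF@points[i, , drop = FALSE]), numeric(2)))
  rF <- sqrt(rowSums(rmF^2))
  expect_equal(max(rF) / min(rF), 1.5625, tolerance = 0.05)

  expect_error(refitPositions(pF[pF$rod_id <= 2, ]), "fit-degenerate")
})

test_that("flattening round trip restores the blade-centre circle", {
  for (e in c(0.1, 0.25, 0.5)) {
    m <- assembleCentriole(choPreset(), FlatteningSpec(e), seed = 1)
    rods <- traceRods(NULL, "from_truth", truth = groundTruth(m))
    p <- sampleParticles(rods, seed = 1)
    p <- p[p$s_nm < 200, ]
    cs <- refitPositions(p)
    rm <- t(vapply(split(seq_len(nrow(cs@points)), cs@rodId), function(i)
      colMeans(cs@points[i, , drop = FALSE]), numeric(2)))
    fit <- fitEllipse(rm)
    corr <- correctFlattening(rm, fit)
    r <- sqrt(rowSums(sweep(corr, 2, fit@center)^2))
    rmsd <- sqrt(mean((r - choPreset()@radiusProximal)^2))
    expect_lt(rmsd, 2)
  }
})

test_that("map ellipticity recovers the generator distortion", {
  bm <- fixtureBlade
  ann <- bladeAnnuli(bm)
  expect_lt(measureMapEllipticity(fixtureRef, ann$A$center, c(9.5, 16)), 2)
  bmE <- centriotome:::distortATubule(bm, 0.10)
  refE <- suppressWarnings(rasterize(bmE, 1.5, box = rep(48, 3)))
  expect_equal(measureMapEllipticity(refE, ann$A$center, c(9.5, 16)), 10,
               tolerance = 0.2)
  # annulus missing the wall
  expect_error(measureMapEllipticity(fixtureRef, ann$A$center, c(20, 23)),
               "fit-degenerate")
})

test_that("symmetrization reproduces the preset geometry", {
  p <- choPreset()
  bm <- fixtureBlade
  ens <- symmetrize(bm, SymmetryParams(p@radiusProximal,
                                       p@bladeTiltProximal, "proximal"))
  # exact 9-fold invariance of the point model
  b <- ens@blobs
  a <- 40 * pi / 180
  rx <- b$x * cos(a) - b$z * sin(a)
  rz <- b$x * sin(a) + b$z * cos(a)
  key <- function(x, y, z) sort(paste(round(x, 6), round(y, 6),
                                      round(z, 6)))
  expect_identical(key(b$x, b$y, b$z), key(rx, b$y, rz))
  # density invariance under 40-degree rotation, at the fidelity the
  # band limit allows
  v <- volData(ens@density)
  rot <- function(x, deg) {
    t2 <- deg * pi / 180
    Q <- matrix(c(cos(t2), 0, sin(t2), 0, 1, 0, -sin(t2), 0, cos(t2)),
                3, 3)
    centriotome:::.cppResample(x, dim(x), Q, c(0, 0, 0), 0)
  }
  expect_gt(cor(as.numeric(rot(v, 40)), as.numeric(rot(v, 80))), 0.98)

  # diameters at the calibrated presets
  expect_equal(measureDiameter(ens), 235, tolerance = 0.05)
  ensD <- symmetrize(fixtureBladeDistal,
                     SymmetryParams(p@radiusDistal, p@bladeTiltDistal,
                                    "distal"))
  expect_equal(measureDiameter(ensD), 220, tolerance = 0.05)
  ensS <- symmetrize(fixtureBladeFly,
                     SymmetryParams(s2P@radiusProximal,
                                    s2P@bladeTiltProximal, "fly"))
  expect_equal(measureDiameter(ensS), 210, tolerance = 0.05)

  # diameter is monotone in the generator radius
  dia <- vapply(c(100, 117.5, 130), function(r)
    measureDiameter(symmetrize(bm, SymmetryParams(r, 50, "proximal"))), 0)
  expect_true(all(diff(dia) > 0))

  # blade-tilt measurement and the inward tilt change
  tp <- measureBladeTilt(ens)
  td <- measureBladeTilt(ensD)
  expect_equal(tp, p@bladeTiltProximal, tolerance = 0.05)
  expect_equal(td - tp, 15, tolerance = 2 / 15)
  expect_equal(tiltChange(ens, ens), 0, tolerance = 1e-9)
  # fly vs CHO proximal: remarkably similar blade angles
  expect_lt(abs(measureBladeTilt(ensS) - tp), 5)
})

test_that("proximal linkages close in the symmetrized ensemble", {
  p <- choPreset()
  ens <- symmetrize(fixtureBlade,
                    SymmetryParams(p@radiusProximal, p@bladeTiltProximal,
                                   "proximal"))
  b <- ens@blobs
  # A-half terminus of blade 1 meets the C-half terminus of blade 2
  tA <- b[b$part == "ac_linker_a" & b$blade == 1, ]
  tC <- b[b$part == "ac_linker_c" & b$blade == 2, ]
  dmin <- min(sqrt(outer(tA$x, tC$x, "-")^2 + outer(tA$z, tC$z, "-")^2))
  expect_lt(dmin, 4)
  # distal A09 foot reaches the neighbour's C07/C08 wall
  ensD <- symmetrize(fixtureBladeDistal,
                     SymmetryParams(p@radiusDistal, p@bladeTiltDistal,
                                    "distal"))
  bd <- ensD@blobs
  foot <- bd[bd$part == "a09_foot" & bd$blade == 1, ]
  wall <- bd[bd$part %in% c("C07", "C08") & bd$blade == 2, ]
  dmin2 <- min(sqrt(outer(foot$x, wall$x, "-")^2 +
                    outer(foot$z, wall$z, "-")^2))
  expect_lt(dmin2, 4)
})

test_that("composite rebuild places class maps and reports runs", {
  sim <- simulateSegments(fixtureBlade, 6, snr = Inf, box = 24,
                          voxelSize = 2, angSd = 0, shiftSd = 0, seed = 3)
  p <- sim$particles
  p$x_nm <- runif(6, -20, 20)
  p$y_nm <- seq(-60, 60, length.out = 6)
  p$z_nm <- runif(6, -20, 20)
  p$s_nm <- p$y_nm + 72
  p$rod_id <- rep(1:2, each = 3)
  p$class_label <- c(1L, 1L, 1L, 2L, 2L, 2L)
  maps <- list(array(1, rep(24, 3)), array(2, rep(24, 3)))
  res <- rebuildComposite(p, maps, tomoDim = rep(48, 3), tomoVoxel = 4,
                          mapVoxel = 2)
  expect_s4_class(res$composite, "DensityVolume")
  expect_equal(nrow(res$runs), 2)
  expect_equal(res$runs$run, c(3, 3))       # whole-rod class runs
  expect_equal(res$runs$class, c(1L, 2L))
  p2 <- p
  p2$class_label[1] <- NA
  expect_error(rebuildComposite(p2, maps, rep(48, 3), 4), "unclassified")
  expect_error(rebuildComposite(p, maps[1], rep(48, 3), 4), "missing")
})
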