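# Model builder: lattices, tubules, blades, partial-B, assembly and
# flattening.

test_that("tubule lattices emit the right monomer blobs", {
  latA <- LatticeSpec(13, 12.5, seamBetween = c(9L, 10L), seamExtraGap = 5)
  A <- TubuleSpec("A", latA)
  expect_equal(nrow(buildTubule(A, 24)), 78)   # 13 pf x 3 dimers x 2 monomers

  # monomer count = n_present x 2 x floor(L/8), brute force over cases
  for (L in c(8, 20, 24, 40)) {
    for (np in c(5L, 10L)) {
      tb <- TubuleSpec("A", LatticeSpec(13, 12.5), presentPfs = 1:np)
      expect_equal(nrow(buildTubule(tb, L)), np * 2 * floor(L / 8))
    }
  }

  # 10-pf full circle: angular spacing exactly 36 degrees
  B <- TubuleSpec("A", LatticeSpec(10, 11.5))
  lay <- centriotome:::tubuleLayout(list(B))[["A"]]
  gaps <- diff(c(lay$pfAngles, lay$pfAngles[1] + 360))
  expect_equal(gaps, rep(36, 10))

  # seam gap exceeds every other gap by the configured extra
  layA <- centriotome:::tubuleLayout(list(TubuleSpec("A",
    LatticeSpec(13, 12.5, seamBetween = c(9L, 10L), seamExtraGap = 6))))$A
  g <- diff(c(layA$pfAngles, layA$pfAngles[1] + 360))
  expect_equal(which.max(g), 9L)
  expect_gt(min(g[9] - g[-9]), 5.99)

  expect_error(buildTubule(TubuleSpec("A", LatticeSpec(13, 12.5),
                                      presentPfs = c(1, 3, 5)), 24),
               "contiguous")
})

test_that("blades position shared walls and decorations correctly", {
  bm <- fixtureBlade
  lay <- centriotome:::tubuleLayout(bm@spec@tubules)
  # B junction pfs coincide with the A wall within 0.1 nm
  pB <- lay$B$center + lay$B$radius *
    c(cos(pi / 180 * lay$B$pfAngles[1]), sin(pi / 180 * lay$B$pfAngles[1]))
  dA <- sqrt(sum((pB - lay$A$center)^2))
  expect_lt(abs(dA - lay$A$radius), 0.1)

  # pinhead blobs adjacent to pf A03
  ph <- bm@blobs[bm@blobs$part == "pinhead", ]
  expect_gt(nrow(ph), 0)
  wallA03 <- centriotome:::wallPoint(bm, "A", 3L)
  dmin <- min(sqrt((ph$x - wallA03[1])^2 + (ph$y - wallA03[2])^2))
  expect_lt(dmin, 6)

  # zero occupancy -> bare tubules only
  sp0 <- bm@spec
  sp0@decorations <- lapply(sp0@decorations, function(d) {
    d@occupancy <- 0
    d
  })
  bm0 <- buildBlade(sp0, 24, tilt = 50, seed = 1)
  expect_true(all(grepl("^[ABC][0-9]", bm0@blobs$part)))

  # 8 nm period over a 24 nm blade -> 3 instances
  d8 <- DecorationSpec("probe", "A", 5L, offsets = c(5, 0, 0),
                       axialPeriod = 8)
  sp1 <- BladeSpec(bm@spec@tubules, list(d8))
  bm1 <- buildBlade(sp1, 24, tilt = 0, seed = 1)
  expect_equal(sum(bm1@blobs$part == "probe"), 3)

  # decoration anchored to an absent pf errors
  bad <- BladeSpec(list(TubuleSpec("A", LatticeSpec(13, 12.5),
                                   presentPfs = 1:6)),
                   list(DecorationSpec("x", "A", 10L, offsets = c(3, 0, 0))))
  expect_error(buildBlade(bad, 24), "absent")
})

test_that("partial-B blades keep two stubs on the same lattice circle", {
  sp <- bladeSpecForPreset(s2P, "fly")
  pb <- makePartialB(sp)
  labs <- vapply(pb@tubules, function(t) t@label, "")
  expect_equal(pb@tubules[[which(labs == "B")]]@presentPfs,
               as.integer(c(1, 2, 7, 8, 9, 10)))
  expect_true(pb@partialB)
  # idempotent
  expect_equal(makePartialB(pb)@tubules[[which(labs == "B")]]@presentPfs,
               pb@tubules[[which(labs == "B")]]@presentPfs)
  # stub curvature equals the complete-B curvature: same centre and radius
  bmF <- buildBlade(sp, 24, tilt = 50, seed = 1)
  bmP <- buildBlade(pb, 24, tilt = 50, seed = 1)
  expect_equal(bmF@centers$B, bmP@centers$B, tolerance = 1e-9)
  expect_error(makePartialB(BladeSpec(list(TubuleSpec("A",
    LatticeSpec(13, 12.5))))), "no B-tubule")
})

test_that("assembled centrioles have 9-fold ground truth", {
  m <- assembleCentriole(choP, seed = 1)
  gt <- groundTruth(m)
  expect_equal(length(unique(gt$rod_id)), 9)
  expect_equal(nrow(gt), 9 * 18)             # floor(440/24) segments per rod
  expect_equal(sort(unique(gt$domain)), c("distal", "proximal"))
  expect_equal(sum(gt$domain == "proximal") / 9, 8)  # s = 12+24k < 200

  # azimuth set invariant under 40-degree rotation
  az <- sort(unique(round(atan2(gt$z_nm, gt$x_nm) * 180 / pi +
                          1e-9) %% 360))
  azRot <- sort((az + 40) %% 360)
  expect_equal(az, azRot, tolerance = 1e-6)

  # s2: no C tubule, 9 rods
  m2 <- assembleCentriole(s2P, seed = 1)
  labs <- vapply(m2@blades[[1]]$segments$fly$blade@spec@tubules,
                 function(t) t@label, "")
  expect_equal(labs, c("A", "B"))
  expect_equal(length(unique(groundTruth(m2)$rod_id)), 9)

  expect_error(assembleCentriole(choP, FlatteningSpec(-0.1)),
               "factor")
})

test_that("flattening is an area-preserving rigid-blade remap", {
  e <- 0.25
  m <- assembleCentriole(choP, FlatteningSpec(e), seed = 1)
  gt <- groundTruth(m)
  # closed-form oracle: remap the 9 discrete azimuths of the unflattened
  # ring and compare the max/min distance ratio
  gt0 <- groundTruth(assembleCentriole(choP, seed = 1))
  for (d in c("proximal", "distal")) {
    r <- sqrt(gt$x_nm[gt$domain == d]^2 + gt$z_nm[gt$domain == d]^2)
    phi <- atan2(gt0$z_nm[gt0$domain == d], gt0$x_nm[gt0$domain == d])
    R0 <- sqrt(gt0$x_nm[gt0$domain == d]^2 + gt0$z_nm[gt0$domain == d]^2)
    oracle <- sqrt((R0 * cos(phi) * (1 + e))^2 +
                   (R0 * sin(phi) / (1 + e))^2)
    expect_equal(max(r) / min(r), max(oracle) / min(oracle),
                 tolerance = 1e-6)
    # area preservation of the blade-centre ellipse: a*b = R^2
    expect_equal(max(oracle) * min(oracle), max(R0) * min(R0),
                 tolerance = 0.005 * max(R0)^2)
  }
  # blade rigidity: inter-tubule distances unchanged by flattening
  b0 <- assembleCentriole(choP, seed = 1)@blades[[1]]$segments$proximal$blade
  b1 <- m@blades[[1]]$segments$proximal$blade
  c0 <- do.call(rbind, tubuleCenters(b0))
  c1 <- do.call(rbind, tubuleCenters(b1))
  expect_lt(max(abs(dist(c0) - dist(c1))), 1e-9)
})

test_that("ground-truth tables round-trip through TSV", {
  gt <- groundTruth(assembleCentriole(choP, seed = 1))
  f <- tempfile(fileext = ".tsv")
  writeGroundTruth(gt, f)
  gt2 <- readGroundTruth(f)
  expect_equal(gt2$x_nm, gt$x_nm, tolerance = 1e-9)
  expect_equal(gt2$domain, gt$domain)
})
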