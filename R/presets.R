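# Named centriole presets and their blade specifications. The CHO (hamster)
# centriole is a 440 nm 9-fold cylinder of triplet blades with a proximal
# (A13+B10+C10, pinhead, A-C linker, 4 MIPs) and a distal (partial C01-C08,
# L-shaped linker + A09 foot, no pinhead / canonical A-C linker / A11 MIP)
# domain split at 200 nm. The fly S2 centriole is a 176 nm doublet (A13+B10)
# cylinder with an elaborated pinhead, an A-A hinge linker and the seam MIP.
#
# Blade reference radii are calibrated (see calibrateBladeRadius) so that the
# 20%-of-max outer-envelope diameter convention of measureDiameter yields the
# nominal ensemble diameters: CHO proximal 235 nm, CHO distal 220 nm, S2
# 210 nm.

DEFAULT_TILT_PROXIMAL <- 50
DEFAULT_TILT_DISTAL <- 65   # proximal + 15 degrees inward
DEFAULT_TILT_FLY <- 50

#' CHO triplet centriole preset
#'
#' @param radiusProximal,radiusDistal blade reference radii, nm.
#' @param bladeTiltProximal,bladeTiltDistal blade tilt from the local
#'   tangent, degrees (inward positive); the distal tilt exceeds the
#'   proximal one by the 15 degree inward rotation.
#' @param length,domainBoundary axial extent and proximal/distal boundary, nm.
#' @return A [CentriolePreset-class].
#' @export
choPreset <- function(radiusProximal = 109.6, radiusDistal = 99.7,
                      bladeTiltProximal = DEFAULT_TILT_PROXIMAL,
                      bladeTiltDistal = DEFAULT_TILT_DISTAL,
                      length = 440, domainBoundary = 200) {
  new("CentriolePreset", name = "cho", nBlades = 9L,
      radiusProximal = radiusProximal, radiusDistal = radiusDistal,
      bladeTiltProximal = bladeTiltProximal, bladeTiltDistal = bladeTiltDistal,
      length = length, domainBoundary = domainBoundary)
}

#' Drosophila S2 doublet centriole preset
#'
#' @param radius blade reference radius, nm.
#' @param bladeTilt blade tilt, degrees (close to the CHO proximal tilt).
#' @param length axial extent, nm (176 = nearest dimer multiple to 175).
#' @return A [CentriolePreset-class].
#' @export
s2Preset <- function(radius = 96.0, bladeTilt = DEFAULT_TILT_FLY,
                     length = 176) {
  new("CentriolePreset", name = "s2", nBlades = 9L,
      radiusProximal = radius, radiusDistal = radius,
      bladeTiltProximal = bladeTilt, bladeTiltDistal = bladeTilt,
      length = length, domainBoundary = length)
}

#' Look up a preset by name
#' @param name "cho" or "s2".
#' @export
getPreset <- function(name) {
  switch(name, cho = choPreset(), s2 = s2Preset(),
         stop("unknown preset '", name, "'"))
}

#' Read a preset from a YAML config
#'
#' Presets are shipped as named configs under `inst/presets/` (cho.yaml,
#' s2.yaml); `readPresetConfig("cho")` reads the shipped file, or pass a
#' path to a custom config with the same keys.
#'
#' @param name preset name or path to a YAML file.
#' @return A [CentriolePreset-class].
#' @export
readPresetConfig <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("presets", paste0(name, ".yaml"), package = "centriotome")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown preset config '", name, "'")
  y <- yaml::read_yaml(path)
  new("CentriolePreset", name = y$name, nBlades = as.integer(y$n_blades),
      radiusProximal = y$radius_proximal_nm,
      radiusDistal = y$radius_distal_nm,
      bladeTiltProximal = y$blade_tilt_proximal_deg,
      bladeTiltDistal = y$blade_tilt_distal_deg,
      length = y$length_nm, domainBoundary = y$domain_boundary_nm)
}

# Bare tubule stack for one domain (no decorations).
bareTubules <- function(domain) {
  latA <- LatticeSpec(13, 12.5, seamBetween = c(9L, 10L), seamExtraGap = 5)
  latBC <- LatticeSpec(10, 11.5)
  A <- TubuleSpec("A", latA)
  B <- TubuleSpec("B", latBC, attachment = list(parent = "A", pfs = c(10L, 13L)))
  if (domain == "fly") return(list(A, B))
  C <- TubuleSpec("C", latBC, attachment = list(parent = "B", pfs = c(7L, 10L)))
  if (domain == "distal") C@presentPfs <- 1:8
  list(A, B, C)
}

# Global 2-D position of a canonical blade point for a blade at azimuth
# `phi` (degrees), reference radius r, unflattened.
bladeGlobal2D <- function(p, phi, r) {
  a <- deg2rad(phi)
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  r * c(cos(a), sin(a)) + as.numeric(Rm %*% p)
}

# Express a global 2-D point in the canonical frame of the blade at `phi`.
bladeLocal2D <- function(g, phi, r) {
  a <- deg2rad(phi)
  Rm <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)  # R(-phi)
  as.numeric(Rm %*% (g - r * c(cos(a), sin(a))))
}

# Anchor-local-frame offsets (radial-from-tubule-centre, CCW-perp, axial)
# for blobs at canonical 2-D positions `pts` relative to an anchor wall point.
localOffsets <- function(pts, wall, tubCenter) {
  u <- wall - tubCenter
  u <- u / sqrt(sum(u^2))
  w <- c(-u[2], u[1])
  t(apply(pts, 1, function(p) {
    d <- p - wall
    c(sum(d * u), sum(d * w), 0)
  }))
}

# Wall point of pf j of tubule `lab` in a canonical BladeModel.
wallPoint <- function(bm, lab, j) {
  tub <- bm@centers[[lab]]
  r <- bm@spec@tubules[[match(lab, vapply(bm@spec@tubules,
                                          function(t) t@label, ""))]]@lattice@tubuleRadius
  colMeans(do.call(rbind, lapply(j, function(jj)
    tub + r * unitVec(bm@pfAngles[[lab]][jj]))))
}

#' Blade specification for a preset domain
#'
#' Builds the full [BladeSpec-class] for one domain of a preset, including
#' the decorations whose geometry depends on the assembled 9-fold layout:
#' the two A-C linker halves (proximal; their termini meet midway between
#' one blade's A09 and the next blade's C08/C09), the distal A09 foot
#' (reaching the neighbour's C07/C08 wall) and the fly A-A hinge (reaching
#' the neighbour's pinhead).
#'
#' @param preset a [CentriolePreset-class].
#' @param domain "proximal", "distal" or "fly".
#' @param a11MipProximalOnly keep the A11-bound MIP in the proximal domain
#'   only (default), as reported for the distal/proximal MIP asymmetry.
#' @return A [BladeSpec-class].
#' @export
bladeSpecForPreset <- function(preset, domain, a11MipProximalOnly = TRUE) {
  tubs <- bareTubules(domain)
  r <- if (domain == "distal") preset@radiusDistal else preset@radiusProximal
  tilt <- switch(domain, proximal = preset@bladeTiltProximal,
                 distal = preset@bladeTiltDistal, fly = preset@bladeTiltProximal)
  bare <- buildBlade(BladeSpec(tubs, list(), domain = domain), 8, tilt = tilt)

  decs <- list()
  mip <- function(name, tub, pfs, period = 8, mass = 1.8)
    DecorationSpec(name, tub, pfs, offsets = c(-2.8, 0, 0), sigmas = 1.6,
                   masses = mass, axialPeriod = period)
  # lumenal MIPs
  decs$mip_a09a10 <- mip("mip_a09a10", "A", c(9L, 10L))
  if (domain != "fly") {
    decs$mip_b01b02 <- mip("mip_b01b02", "B", c(1L, 2L))
    if (domain == "proximal" || !a11MipProximalOnly)
      decs$mip_a11 <- mip("mip_a11", "A", 11L, period = 16)
    if (domain == "proximal")
      decs$mip_c01c02 <- mip("mip_c01c02", "C", c(1L, 2L))
    if (domain == "distal")  # partial C keeps C01/C02, MIP persists
      decs$mip_c01c02 <- mip("mip_c01c02", "C", c(1L, 2L))
  }

  phOffsets <- rbind(c(4, 0, 0), c(7.5, 1, 0))
  if (domain == "proximal")
    decs$pinhead <- DecorationSpec("pinhead", "A", 3L, offsets = phOffsets,
                                   sigmas = c(1.8, 1.8), masses = c(3, 3),
                                   axialPeriod = 8)
  if (domain == "fly")  # elaborated: extra lobe toward A04/A05
    decs$pinhead <- DecorationSpec("pinhead", "A", 3L,
                                   offsets = rbind(phOffsets, c(5.5, -3, 0)),
                                   sigmas = c(1.8, 1.8, 1.8),
                                   masses = c(3, 3, 2.5), axialPeriod = 8)

  chain <- function(name, tub, pfs, from, to, fracs, mass = 2, sigma = 1.7) {
    pts <- t(vapply(fracs, function(f) from + f * (to - from),
                    numeric(2)))
    DecorationSpec(name, tub, pfs,
                   offsets = localOffsets(pts, wallPoint(bare, tub, pfs),
                                          bare@centers[[tub]]),
                   sigmas = rep(sigma, length(fracs)),
                   masses = rep(mass, length(fracs)), axialPeriod = 8)
  }

  if (domain == "proximal") {
    # A-C linker: A09 of this blade to C08/C09 of the next (+40 deg) blade;
    # the two halves meet midway (termini 3 nm apart).
    a09 <- bladeGlobal2D(wallPoint(bare, "A", 9L), 0, r)
    c89n <- bladeGlobal2D(wallPoint(bare, "C", c(8L, 9L)), 40, r)
    gmid <- (a09 + c89n) / 2
    dirn <- (c89n - a09) / sqrt(sum((c89n - a09)^2))
    span <- sqrt(sum((c89n - a09)^2))
    fA <- c(0.45, (span / 2 - 1.5) / span)             # terminus 1.5 nm short
    toLoc0 <- function(g) bladeLocal2D(g, 0, r)
    ptsA <- t(vapply(fA, function(f) toLoc0(a09 + f * (c89n - a09)),
                     numeric(2)))
    decs$ac_linker_a <- DecorationSpec("ac_linker_a", "A", 9L,
      offsets = localOffsets(ptsA, wallPoint(bare, "A", 9L),
                             bare@centers[["A"]]),
      sigmas = c(1.7, 1.7), masses = c(2, 2), axialPeriod = 8)
    # C half, expressed in the canonical frame of the +40 blade
    toLoc40 <- function(g) bladeLocal2D(g, 40, r)
    fC <- c(0.45, (span / 2 - 1.5) / span)
    ptsC <- t(vapply(fC, function(f) toLoc40(c89n + f * (a09 - c89n)),
                     numeric(2)))
    decs$ac_linker_c <- DecorationSpec("ac_linker_c", "C", c(8L, 9L),
      offsets = localOffsets(ptsC, wallPoint(bare, "C", c(8L, 9L)),
                             bare@centers[["C"]]),
      sigmas = c(1.7, 1.7), masses = c(2, 2), axialPeriod = 8)
  }

  if (domain == "distal") {
    # L-shaped linker from the inner AB junction pointing into the lumen
    ab <- wallPoint(bare, "A", c(1L, 2L))
    decs$l_linker <- DecorationSpec("l_linker", "A", c(1L, 2L),
      offsets = rbind(c(3, 0, 0), c(5.5, 2.5, 0)), sigmas = c(1.7, 1.7),
      masses = c(2, 2), axialPeriod = 8)
    # A09 foot reaching the neighbour's persistent C07/C08 wall
    a09 <- bladeGlobal2D(wallPoint(bare, "A", 9L), 0, r)
    c78n <- bladeGlobal2D(wallPoint(bare, "C", c(7L, 8L)), 40, r)
    toLoc0 <- function(g) bladeLocal2D(g, 0, r)
    pts <- t(vapply(c(0.35, 0.7, 1), function(f)
      toLoc0(a09 + f * (c78n - a09)), numeric(2)))
    decs$a09_foot <- DecorationSpec("a09_foot", "A", 9L,
      offsets = localOffsets(pts, wallPoint(bare, "A", 9L),
                             bare@centers[["A"]]),
      sigmas = c(1.7, 1.7, 1.7), masses = c(2, 2, 2), axialPeriod = 8)
  }

  if (domain == "fly") {
    # A-A hinge: from the A05/A06 hinge toward the neighbour's pinhead
    a56 <- bladeGlobal2D(wallPoint(bare, "A", c(5L, 6L)), 0, r)
    phW <- wallPoint(bare, "A", 3L)
    phU <- (phW - bare@centers[["A"]]) /
      sqrt(sum((phW - bare@centers[["A"]])^2))
    phPos <- phW + 4 * phU    # first pinhead blob position, canonical
    phn <- bladeGlobal2D(phPos, 40, r)
    toLoc0 <- function(g) bladeLocal2D(g, 0, r)
    pts <- t(vapply(c(0.35, 0.7, 1), function(f)
      toLoc0(a56 + f * (phn - a56)), numeric(2)))
    decs$aa_hinge <- DecorationSpec("aa_hinge", "A", c(5L, 6L),
      offsets = localOffsets(pts, wallPoint(bare, "A", c(5L, 6L)),
                             bare@centers[["A"]]),
      sigmas = c(1.7, 1.7, 1.7), masses = c(2, 2, 2), axialPeriod = 8)
    # wishbone density on the outer A surface
    decs$wishbone <- DecorationSpec("wishbone", "A", c(7L, 8L),
      offsets = rbind(c(3.2, -1.5, 0), c(3.2, 1.5, 0), c(5.5, 0, 0)),
      sigmas = c(1.6, 1.6, 1.6), masses = c(1.5, 1.5, 1.5), axialPeriod = 8)
  }

  BladeSpec(tubs, unname(decs), domain = domain)
}
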