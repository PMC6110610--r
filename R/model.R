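# Parametric centriole model builder: protofilament lattices, blades with
# decorations, whole-centriole assembly with ice-sheet flattening.
#
# Frames. Blade (canonical/reference) frame: z = axial, x = outward radial at
# the blade's azimuth, y completes the right-handed set; the blade long axis
# (A-tubule centre -> outermost tubule centre) lies at 90 + tilt degrees from
# the x axis, i.e. at `tilt` degrees from the local circle tangent, positive
# tilt rotating the outer end toward the centriole axis. Model frame: the
# centriole axis is y (the tilt axis of the simulated tomogram); the
# cross-section plane is (x, z); the proximal end is at y = -length/2.

#' Blade density model
#'
#' The realized geometry of one blade: all Gaussian density blobs, the 2-D
#' cross-section centres and protofilament wall angles of its tubules.
#'
#' @slot spec the [BladeSpec-class] realized.
#' @slot length axial extent, nm.
#' @slot blobs data.frame (x, y, z, sigma, mass, part) in the blade frame;
#'   x/y are cross-section nm, z axial nm.
#' @slot centers named list of tubule cross-section centres (2-vectors, nm).
#' @slot pfAngles named list of protofilament wall angles (degrees, full
#'   lattice) per tubule.
#' @export
setClass("BladeModel",
  representation(spec = "BladeSpec", length = "numeric", blobs = "data.frame",
                 centers = "list", pfAngles = "list"))

#' @describeIn BladeModel-class named list of tubule cross-section centres.
#' @param x a BladeModel.
#' @export
setMethod("tubuleCenters", "BladeModel", function(x) x@centers)

setMethod("show", "BladeModel", function(object) {
  cat(sprintf("BladeModel (%s): tubules %s, %d blobs, length %g nm\n",
              object@spec@domain,
              paste(names(object@centers), collapse = "+"),
              nrow(object@blobs), object@length))
})

unitVec <- function(deg) c(cos(deg2rad(deg)), sin(deg2rad(deg)))

# Cross-section layout of the tubules of a blade: A is a full circle at the
# origin; B and C are incomplete circles whose two junction protofilaments
# coincide with the parent wall at the attachment protofilaments.
tubuleLayout <- function(tubules) {
  out <- list()
  for (tb in tubules) {
    lat <- tb@lattice
    n <- lat@nPf
    if (tb@label == "A") {
      gaps <- rep((360 - lat@seamExtraGap) / n, n)
      if (length(lat@seamBetween)) {
        # gap i lies between pf i and pf i+1 (cyclic)
        s <- sort(lat@seamBetween)
        gi <- if (s[1] == 1L && s[2] == n) n else s[1]
        gaps[gi] <- gaps[gi] + lat@seamExtraGap
      }
      ang <- 90 + cumsum(c(0, gaps[-n]))   # pf A01 starts at the top
      out[[tb@label]] <- list(center = c(0, 0), pfAngles = ang,
                              radius = lat@tubuleRadius, spec = tb)
    } else {
      at <- tb@attachment
      parent <- out[[at$parent]]
      if (is.null(parent)) stop("invalid-spec: attachment parent not built")
      pA <- parent$center +
        parent$radius * unitVec(parent$pfAngles[at$pfs[1]])
      pB <- parent$center +
        parent$radius * unitVec(parent$pfAngles[at$pfs[2]])
      mid <- (pA + pB) / 2
      half <- sqrt(sum((pB - pA)^2)) / 2
      r <- lat@tubuleRadius
      if (r <= half)
        stop("invalid-spec: tubule radius too small for attachment chord")
      outward <- mid - parent$center
      outward <- outward / sqrt(sum(outward^2))
      cen <- mid + sqrt(r^2 - half^2) * outward
      a1 <- rad2deg(atan2(pA[2] - cen[2], pA[1] - cen[1]))
      a2 <- rad2deg(atan2(pB[2] - cen[2], pB[1] - cen[1]))
      aP <- rad2deg(atan2(parent$center[2] - cen[2], parent$center[1] - cen[1]))
      # spread the pfs over the arc from a1 to a2 that avoids the parent
      ccw <- (a2 - a1) %% 360                 # arc a1 -> a2 going CCW
      inCCW <- ((aP - a1) %% 360) < ccw       # parent inside the CCW arc?
      span <- if (inCCW) ccw - 360 else ccw   # negative = go clockwise
      ang <- a1 + span * (seq_len(n) - 1) / (n - 1)
      out[[tb@label]] <- list(center = cen, pfAngles = ang, radius = r,
                              spec = tb)
    }
  }
  out
}

#' Build the density primitives of one tubule
#'
#' Emits one Gaussian blob per tubulin monomer: 2 monomers per 8 nm dimer
#' per protofilament, protofilaments at equal angular spacing except for an
#' enlarged gap at the seam, only the present protofilaments emitted. The
#' monomer count per protofilament is exactly 2 * floor(length / dimerRepeat).
#'
#' @param spec a [TubuleSpec-class].
#' @param length axial length, nm (must be at least one dimer repeat).
#' @param layout optional precomputed layout entry (internal use).
#' @return data.frame of blobs (x, y, z, sigma, mass, part), z in
#'   [-length/2, length/2).
#' @export
buildTubule <- function(spec, length, layout = NULL) {
  if (spec@lattice@nPf < 1L) stop("invalid-spec: nPf must be >= 1")
  if (!isContiguousCyclic(spec@presentPfs, spec@lattice@nPf))
    stop("invalid-spec: presentPfs not contiguous")
  if (length < spec@lattice@dimerRepeat)
    stop("invalid-spec: length shorter than one dimer repeat")
  if (is.null(layout)) layout <- tubuleLayout(list(spec))[[spec@label]]
  lat <- spec@lattice
  nd <- floor(length / lat@dimerRepeat)
  rows <- list()
  for (j in spec@presentPfs) {
    wall <- layout$center + layout$radius * unitVec(layout$pfAngles[j])
    rise <- ((j - 1) * lat@risePerPf) %% lat@dimerRepeat
    z <- -length / 2 + rep(lat@dimerRepeat * (seq_len(nd) - 1), each = 2) +
      c(0, lat@monomerOffset) + rise
    rows[[length(rows) + 1L]] <- data.frame(
      x = wall[1], y = wall[2], z = z, sigma = lat@blobSigma, mass = 1,
      part = sprintf("%s%02d", spec@label, j))
  }
  do.call(rbind, rows)
}

# Decoration blob positions for one blade layout; occupancy draws use the
# current RNG state.
decorationBlobs <- function(dec, layout, length) {
  tub <- layout[[dec@anchorTubule]]
  if (is.null(tub)) stop("invalid-spec: decoration anchored to absent tubule")
  present <- tub$spec@presentPfs
  if (!all(dec@anchorPfs %in% present))
    stop("invalid-spec: decoration anchored to absent protofilament")
  wall <- colMeans(do.call(rbind, lapply(dec@anchorPfs, function(j)
    tub$center + tub$radius * unitVec(tub$pfAngles[j]))))
  u <- wall - tub$center
  u <- u / sqrt(sum(u^2))          # outward radial from tubule centre
  w <- c(-u[2], u[1])              # CCW perpendicular
  z0 <- -length / 2 + dec@axialPeriod / 2
  zc <- seq(z0, length / 2 - 1e-9, by = dec@axialPeriod)
  keep <- stats::runif(length(zc)) <= dec@occupancy
  zc <- zc[keep]
  if (!length(zc)) return(NULL)
  rows <- lapply(zc, function(z) {
    data.frame(
      x = wall[1] + dec@offsets[, 1] * u[1] + dec@offsets[, 2] * w[1],
      y = wall[2] + dec@offsets[, 1] * u[2] + dec@offsets[, 2] * w[2],
      z = z + dec@offsets[, 3],
      sigma = dec@sigmas, mass = dec@masses, part = dec@name)
  })
  do.call(rbind, rows)
}

#' Build a blade density model
#'
#' Lays out the tubules (shared-wall protofilaments coincide with the parent
#' wall by construction), places the decorations at their anchors replicated
#' axially with their period and occupancy, and canonicalizes the frame: the
#' centroid of the tubule centres moves to the origin and the blade long axis
#' (A centre to outermost tubule centre) is rotated to `90 + tilt` degrees
#' from the +x axis.
#'
#' @param spec a [BladeSpec-class].
#' @param length axial extent, nm.
#' @param tilt blade tilt baked into the canonical frame, degrees from the
#'   local tangent (positive = outer end toward the axis).
#' @param seed optional integer seed for the decoration occupancy draws.
#' @return A [BladeModel-class].
#' @export
buildBlade <- function(spec, length, tilt = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layout <- tubuleLayout(spec@tubules)
  blobs <- do.call(rbind, lapply(spec@tubules, function(tb)
    buildTubule(tb, length, layout = layout[[tb@label]])))
  for (dec in spec@decorations) {
    db <- decorationBlobs(dec, layout, length)
    if (!is.null(db)) blobs <- rbind(blobs, db)
  }
  centers <- lapply(layout, `[[`, "center")
  # canonicalize: centroid at origin, long axis at 90 + tilt degrees
  cen <- colMeans(do.call(rbind, centers))
  last <- names(centers)[length(centers)]
  axisRaw <- if (length(centers) > 1L)
    rad2deg(atan2(centers[[last]][2] - centers[["A"]][2],
                  centers[[last]][1] - centers[["A"]][1]))
  else 90
  dAng <- (90 + tilt) - axisRaw
  Rm <- matrix(c(cos(deg2rad(dAng)), sin(deg2rad(dAng)),
                 -sin(deg2rad(dAng)), cos(deg2rad(dAng))), 2, 2)
  xy <- t(Rm %*% t(cbind(blobs$x - cen[1], blobs$y - cen[2])))
  blobs$x <- xy[, 1]
  blobs$y <- xy[, 2]
  centers <- lapply(centers, function(p) as.numeric(Rm %*% (p - cen)))
  pfAngles <- lapply(layout, function(l) l$pfAngles + dAng)
  new("BladeModel", spec = spec, length = length, blobs = blobs,
      centers = centers, pfAngles = pfAngles)
}

#' Remove protofilaments B03-B06 from a blade specification
#'
#' Produces the incomplete-B-tubule biogenesis intermediate: the B-tubule
#' keeps only protofilaments B01, B02 and B07-B10 (two stubs on the same
#' lattice circle, hence with the curvature of the complete B-tubule); all
#' other blade content is unchanged. Idempotent.
#'
#' @param blade a [BladeSpec-class] with a B-tubule.
#' @return the modified [BladeSpec-class] with `partialB = TRUE`.
#' @export
makePartialB <- function(blade) {
  labs <- vapply(blade@tubules, function(t) t@label, "")
  bi <- which(labs == "B")
  if (!length(bi)) stop("invalid-spec: blade has no B-tubule")
  tb <- blade@tubules[[bi]]
  tb@presentPfs <- as.integer(c(1, 2, 7, 8, 9, 10))
  blade@tubules[[bi]] <- tb
  # decorations anchored to removed pfs would be dangling; drop them
  keep <- vapply(blade@decorations, function(d)
    d@anchorTubule != "B" || all(d@anchorPfs %in% tb@presentPfs), TRUE)
  blade@decorations <- blade@decorations[keep]
  blade@partialB <- TRUE
  blade
}
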