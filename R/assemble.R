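# Whole-centriole assembly: 9 blades at 40 degree azimuths, domain switch at
# the proximal/distal boundary, area-preserving ice-sheet flattening of the
# blade-centre ring with rigid blades, and the ground-truth segment table.

# Area-preserving elliptical remap of a cross-section point: coordinates
# along the kept axis scale by (1+e), along the squash axis by 1/(1+e).
flattenPoint <- function(p, flattening) {
  e <- flattening@factor
  if (e == 0) return(p)
  sq <- flattening@squashAxis
  kp <- c(-sq[2], sq[1])
  u <- sum(p * kp)
  v <- sum(p * sq)
  u * (1 + e) * kp + v / (1 + e) * sq
}

# Direction remap (for re-tangenting blade orientations): transform, then
# normalize.
flattenDir <- function(d, flattening) {
  e <- flattening@factor
  if (e == 0) return(d)
  sq <- flattening@squashAxis
  kp <- c(-sq[2], sq[1])
  v <- sum(d * kp) * (1 + e) * kp + sum(d * sq) / (1 + e) * sq
  v / sqrt(sum(v^2))
}

# Rotation matrix (reference -> model) of a blade whose canonical x axis
# points at cross-section angle `alpha` degrees; reference z maps to model +y.
bladeRotation <- function(alpha) {
  a <- deg2rad(alpha)
  matrix(c(cos(a), 0, sin(a),
           sin(a), 0, -cos(a),
           0, 1, 0), 3, 3)
}

#' Assemble a 9-fold centriole model
#'
#' Places 9 blades at azimuths k * 40 degrees at the domain-appropriate
#' radius and tilt; for the CHO preset the blades switch from the proximal
#' to the distal blade specification at the domain boundary. Flattening
#' remaps the blade centres onto the area-preserving ellipse and
#' re-tangents the blade orientations to the ellipse while keeping each
#' blade rigid. The ground-truth table records rod id, axial position,
#' segment centre, ZYZ Euler angles, domain and partial-B flag at the
#' segment step.
#'
#' @param preset a [CentriolePreset-class] (see [choPreset()], [s2Preset()]).
#' @param flattening a [FlatteningSpec-class]; `FlatteningSpec(0)` for none.
#' @param seed integer seed controlling decoration occupancy draws.
#' @param segmentStep ground-truth axial sampling, nm (default 24).
#' @param partialBRods rod ids (1..9) whose blades carry the incomplete
#'   B-tubule (biogenesis intermediate).
#' @param aTubuleDistortion fractional A-tubule ellipticity baked into every
#'   blade (0 = circular; 0.1 reproduces the ~10% distortion preset).
#' @return A [CentrioleModel-class].
#' @export
assembleCentriole <- function(preset, flattening = FlatteningSpec(0), seed = 1,
                              segmentStep = 24, partialBRods = integer(0),
                              aTubuleDistortion = 0) {
  if (flattening@factor < 0) stop("invalid-spec: flattening factor < 0")
  domains <- if (preset@name == "s2") "fly" else c("proximal", "distal")
  L <- preset@length
  bnd <- preset@domainBoundary
  segLen <- if (preset@name == "s2") c(fly = L) else
    c(proximal = bnd, distal = L - bnd)
  specs <- lapply(stats::setNames(domains, domains), function(d)
    bladeSpecForPreset(preset, d))

  blades <- vector("list", 9L)
  truth <- list()
  for (k in 0:8) {
    phi <- k * 40
    segs <- list()
    for (d in domains) {
      sp <- specs[[d]]
      if ((k + 1L) %in% partialBRods) sp <- makePartialB(sp)
      tilt <- switch(d, proximal = preset@bladeTiltProximal,
                     distal = preset@bladeTiltDistal,
                     fly = preset@bladeTiltProximal)
      bm <- buildBlade(sp, segLen[[d]], tilt = tilt,
                       seed = subSeed(seed, 31L * k + match(d, domains)))
      if (aTubuleDistortion > 0) bm <- distortATubule(bm, aTubuleDistortion)
      r <- if (d == "distal") preset@radiusDistal else preset@radiusProximal
      c2 <- flattenPoint(r * unitVec(phi), flattening)
      tangent <- flattenDir(c(-sin(deg2rad(phi)), cos(deg2rad(phi))),
                            flattening)
      alpha <- rad2deg(atan2(tangent[2], tangent[1])) - 90
      yMid <- switch(d, proximal = -L / 2 + bnd / 2,
                     distal = bnd / 2, fly = 0)
      segs[[d]] <- list(domain = d, blade = bm, center2 = c2,
                        inPlane = alpha, yMid = yMid,
                        sRange = switch(d, proximal = c(0, bnd),
                                        distal = c(bnd, L), fly = c(0, L)))
    }
    blades[[k + 1L]] <- list(rod = k + 1L, azimuth = phi, segments = segs)

    s <- seq(segmentStep / 2, L - 1e-9, by = segmentStep)
    for (si in s) {
      d <- if (preset@name == "s2") "fly" else
        if (si < bnd) "proximal" else "distal"
      sg <- segs[[d]]
      eul <- matrixToEuler(bladeRotation(sg$inPlane))
      truth[[length(truth) + 1L]] <- data.frame(
        rod_id = k + 1L, s_nm = si,
        x_nm = sg$center2[1], y_nm = -L / 2 + si, z_nm = sg$center2[2],
        rot_deg = eul[["rot"]], tilt_deg = eul[["tilt"]],
        psi_deg = eul[["psi"]], domain = d,
        partial_b = (k + 1L) %in% partialBRods)
    }
  }
  new("CentrioleModel", blades = blades, preset = preset,
      flattening = flattening, groundTruth = do.call(rbind, truth))
}

#' Bake an elliptical distortion into the A-tubule of a blade model
#'
#' Remaps the A-tubule blobs (and its lumenal decorations) about the A
#' centre so the wall becomes an area-preserving ellipse with semi-axes
#' r/sqrt(1-eps) and r*sqrt(1-eps), i.e. ellipticity 100*eps percent;
#' eps = 0.1 is the ~10% distortion preset.
#'
#' @param bm a [BladeModel-class].
#' @param eps fractional ellipticity in [0, 1).
#' @return the distorted [BladeModel-class].
#' @export
distortATubule <- function(bm, eps) {
  sa <- 1 / sqrt(1 - eps)
  cen <- bm@centers[["A"]]
  isA <- grepl("^A[0-9]", bm@blobs$part) | grepl("^mip_a", bm@blobs$part)
  dx <- bm@blobs$x[isA] - cen[1]
  dy <- bm@blobs$y[isA] - cen[2]
  bm@blobs$x[isA] <- cen[1] + dx * sa
  bm@blobs$y[isA] <- cen[2] + dy / sa
  bm
}

#' All density blobs of a centriole model in the model frame
#'
#' @param model a [CentrioleModel-class].
#' @return data.frame (x, y, z, sigma, mass, part, rod, domain), nm; the
#'   centriole axis is y.
#' @export
modelBlobs <- function(model) {
  out <- list()
  for (bl in model@blades) {
    for (sg in bl$segments) {
      b <- sg$blade@blobs
      a <- deg2rad(sg$inPlane)
      gx <- sg$center2[1] + b$x * cos(a) - b$y * sin(a)
      gz <- sg$center2[2] + b$x * sin(a) + b$y * cos(a)
      out[[length(out) + 1L]] <- data.frame(
        x = gx, y = sg$yMid + b$z, z = gz, sigma = b$sigma, mass = b$mass,
        part = b$part, rod = bl$rod, domain = sg$domain)
    }
  }
  do.call(rbind, out)
}

#' Write / read the ground-truth segment table
#'
#' Tab-separated with the canonical header (rod_id, s_nm, x_nm, y_nm, z_nm,
#' rot_deg, tilt_deg, psi_deg, domain, partial_b).
#'
#' @param truth data.frame as produced by [assembleCentriole()].
#' @param path file path.
#' @export
writeGroundTruth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
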