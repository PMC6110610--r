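# Geometric reconstruction: refit of particle poses into cross-section
# point clouds, flattening quantification by direct least-squares ellipse
# fitting, 9-fold symmetrization from supplied geometry, and ensemble
# diameter / blade-tilt measurement.

#' Cross-section refit of particle poses
#'
#' @slot axis fitted centriole axis direction (unit 3-vector).
#' @slot center centroid of the particle centres, nm.
#' @slot points per-particle 2-D coordinates in the plane perpendicular to
#'   the axis, nm.
#' @slot rodId,s per-point rod id and axial position.
#' @slot inPlane per-point in-plane blade orientation, degrees.
#' @export
setClass("CrossSection",
  representation(axis = "numeric", center = "numeric", points = "matrix",
                 rodId = "integer", s = "numeric", inPlane = "numeric"))

setMethod("show", "CrossSection", function(object) {
  cat(sprintf("CrossSection: %d points from %d rods\n",
              nrow(object@points), length(unique(object@rodId))))
})

#' Symmetrized 9-fold ensemble
#'
#' @slot density the symmetrized [DensityVolume-class] (axis along y).
#' @slot params the [SymmetryParams-class] used.
#' @slot bladeMap the placed blade map (array, blade frame).
#' @slot nTubules number of tubules per blade (3 triplet, 2 doublet).
#' @export
setClass("EnsembleModel",
  representation(density = "DensityVolume", params = "SymmetryParams",
                 bladeMap = "array", nTubules = "integer",
                 blobs = "data.frame"))

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: 9-fold, radius %g nm, tilt %g deg\n",
              object@params@bladeRadius, object@params@bladeTilt))
})

#' Refit refined particle poses into a cross-section
#'
#' The axis is the first principal direction of the particle centres
#' (refined shifts applied); every centre is projected onto the
#' perpendicular plane, and the in-plane blade orientation is derived from
#' the refined Euler angles.
#'
#' @param particles particle data.frame spanning at least 3 rods and 9
#'   particles.
#' @return A [CrossSection-class].
#' @export
refitPositions <- function(particles) {
  if (nrow(particles) < 9L || length(unique(particles$rod_id)) < 3L)
    stop("fit-degenerate: need >= 9 particles spanning >= 3 rods")
  cen <- cbind(particles$x_nm + particles$sx_nm,
               particles$y_nm + particles$sy_nm,
               particles$z_nm + particles$sz_nm)
  # the axis is the mean of the per-rod principal directions (each rod is
  # an elongated line along the centriole axis); a global PCA would pick a
  # cross-section direction whenever the ring radius exceeds the sampled
  # axial extent
  dirs <- lapply(split(seq_len(nrow(cen)), particles$rod_id), function(i) {
    if (length(i) < 2L) return(NULL)
    d <- prcomp(cen[i, , drop = FALSE])
    v <- d$rotation[, 1]
    if (d$sdev[1] < 1e-9) return(NULL)
    v * sign(v[which.max(abs(v))])
  })
  dirs <- do.call(rbind, dirs[!vapply(dirs, is.null, TRUE)])
  if (is.null(dirs) || nrow(dirs) < 1L)
    stop("fit-degenerate: no axial spread")
  axis <- colMeans(dirs)
  axis <- axis / sqrt(sum(axis^2))
  mid <- colMeans(cen)
  # in-plane basis perpendicular to the axis (deterministic)
  seedv <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- seedv - sum(seedv * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  rel <- sweep(cen, 2, mid)
  pts <- cbind(rel %*% e1, rel %*% e2)
  inPl <- vapply(seq_len(nrow(particles)), function(i) {
    R <- eulerToMatrix(particles$rot_deg[i], particles$tilt_deg[i],
                       particles$psi_deg[i])
    bx <- R[, 1]   # image of the blade-frame x axis
    rad2deg(atan2(sum(bx * e2), sum(bx * e1)))
  }, 0)
  new("CrossSection", axis = as.numeric(axis), center = mid, points = pts,
      rodId = as.integer(particles$rod_id), s = particles$s_nm,
      inPlane = inPl)
}

#' Direct least-squares ellipse fit
#'
#' Fitzgibbon-style conic fit constrained to ellipses (numerically stable
#' 3x3 partition), on at least 6 non-collinear points.
#'
#' @param points n x 2 matrix of coordinates, nm.
#' @return An [EllipseFit-class].
#' @export
fitEllipse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 6L) stop("fit-degenerate: need >= 6 points")
  mu <- colMeans(points)
  sc <- mean(sqrt(rowSums(sweep(points, 2, mu)^2)))
  if (sc < 1e-12) stop("fit-degenerate: coincident points")
  x <- (points[, 1] - mu[1]) / sc
  y <- (points[, 2] - mu[2]) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("fit-degenerate: collinear or under-determined points"))
  M <- S1 + S2 %*% T
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 1e-12)
  if (!length(ok)) stop("fit-degenerate: no elliptical solution")
  a1 <- V[, ok[1]]
  coefs <- c(a1, as.numeric(T %*% a1))   # A B C D E F (scaled frame)
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; F <- coefs[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  F0 <- F + (D * cx + E * cy) / 2
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  ax <- sqrt(pmax(-F0 / eg$values, 0))
  if (any(!is.finite(ax)) || any(ax <= 0))
    stop("fit-degenerate: not an ellipse")
  ord <- order(ax, decreasing = TRUE)
  major <- eg$vectors[, ord[1]]
  new("EllipseFit",
      center = mu + sc * c(cx, cy),
      a = sc * ax[ord[1]], b = sc * ax[ord[2]],
      orientation = rad2deg(atan2(major[2], major[1])) %% 180)
}

#' Undo an area-preserving flattening using a fitted ellipse
#'
#' Maps points on the fitted ellipse back onto the equivalent-area circle
#' of radius sqrt(a b): coordinates along the major axis scale by
#' sqrt(ab)/a, along the minor axis by sqrt(ab)/b.
#'
#' @param points n x 2 matrix.
#' @param fit an [EllipseFit-class].
#' @return the corrected n x 2 matrix.
#' @export
correctFlattening <- function(points, fit) {
  R0 <- sqrt(fit@a * fit@b)
  th <- deg2rad(fit@orientation)
  u <- c(cos(th), sin(th))
  v <- c(-sin(th), cos(th))
  rel <- sweep(as.matrix(points), 2, fit@center)
  pu <- rel %*% u * (R0 / fit@a)
  pv <- rel %*% v * (R0 / fit@b)
  sweep(cbind(pu) %*% t(u) + cbind(pv) %*% t(v), 2, fit@center, "+")
}

#' A-tubule ellipticity of an average map
#'
#' Extracts the per-angle radial position of the wall-density maximum over
#' the central 24 nm, fits an ellipse to the wall points and returns the
#' ellipticity in percent, 100 (a - b) / a.
#'
#' @param average an [AverageMap-class] or [DensityVolume-class].
#' @param tubuleCenter 2-D tubule centre relative to the box centre, nm.
#' @param annulus c(r_lo, r_hi), nm, containing the wall.
#' @param axialWindow axial extent averaged, nm.
#' @param minDensity wall points weaker than this fraction of the
#'   cross-section maximum are discarded.
#' @return ellipticity, percent.
#' @export
measureMapEllipticity <- function(average, tubuleCenter, annulus,
                                  axialWindow = 24, minDensity = 0.3,
                                  trim = 2) {
  vox <- voxelSize(average)
  v <- asArray(average)
  d <- dim(v)
  nz <- round(axialWindow / vox / 2)
  zc <- (d[3] + 1) / 2
  zidx <- max(1, ceiling(zc - nz)):min(d[3], floor(zc + nz))
  m2 <- apply(v[, , zidx, drop = FALSE], c(1, 2), mean)
  cx <- (d[1] - 1) / 2 + tubuleCenter[1] / vox
  cy <- (d[2] - 1) / 2 + tubuleCenter[2] / vox
  rr <- seq(annulus[1], annulus[2], by = vox / 4)
  raw <- t(vapply(seq(0, 358, by = 2), function(a) {
    xs <- cx + rr * cos(deg2rad(a)) / vox
    ys <- cy + rr * sin(deg2rad(a)) / vox
    vals <- .cppSample(array(m2, c(d[1], d[2], 1)), cbind(xs, ys, 0),
                       min(m2))
    pk <- which.max(vals)
    # parabolic sub-sample refinement of the wall radius
    r0 <- rr[pk]
    if (pk > 1 && pk < length(rr)) {
      y0 <- vals[pk - 1]; y1 <- vals[pk]; y2 <- vals[pk + 1]
      dn <- y0 - 2 * y1 + y2
      if (dn < 0) r0 <- r0 + 0.5 * (y0 - y2) / dn * (rr[2] - rr[1])
    }
    c(a, r0, vals[pk])
  }, numeric(3)))
  # wall peaks vary severalfold (shared-wall junctions), so the density
  # cut is taken relative to the median per-angle peak, not the maximum;
  # an annulus that misses the wall entirely has no meaningful peaks
  if (median(raw[, 3]) < 0.1 * max(m2))
    stop("fit-degenerate: wall not found in annulus")
  ar <- raw[raw[, 3] >= minDensity * median(raw[, 3]), , drop = FALSE]
  if (nrow(ar) < 6L) stop("fit-degenerate: wall not found in annulus")
  # decorations (lumenal MIPs, external linkers) produce coherent radial
  # outliers at specific angles; keep points near the median wall radius
  keep <- abs(ar[, 2] - median(ar[, 2])) <= trim
  ar <- ar[keep, , drop = FALSE]
  if (nrow(ar) < 6L) stop("fit-degenerate: wall not found in annulus")
  xy <- cbind(tubuleCenter[1] + ar[, 2] * cos(deg2rad(ar[, 1])),
              tubuleCenter[2] + ar[, 2] * sin(deg2rad(ar[, 1])))
  ellipticity(fitEllipse(xy))
}

# Pairwise centre distances of the canonical tubule layout (triplet or
# doublet); used as the rigid-shape prior for the ring locator.
tubuleDistMatrix <- function(nTubules) {
  lay <- tubuleLayout(bareTubules(if (nTubules == 2L) "fly" else "proximal"))
  cen <- do.call(rbind, lapply(lay, `[[`, "center"))[seq_len(nTubules), ,
                                                     drop = FALSE]
  as.matrix(stats::dist(cen))
}

# Ring-matching tubule locator on a z-collapsed 2-D map: finds `n` tubule
# centres of the given wall radii by greedy circle-template matching,
# constraining each next centre by the rigid-shape pairwise distances of
# the canonical tubule layout (within +/- tol nm).
locateTubules <- function(m2, vox, radii, searchR = NULL, sector = NULL,
                          expectedDist = NULL, tol = 4) {
  d <- dim(m2)
  cx <- (d[1] - 1) / 2
  cy <- (d[2] - 1) / 2
  if (is.null(searchR)) searchR <- min(d) * vox / 2 - max(radii) - 2
  arr <- array(m2, c(d[1], d[2], 1))
  ringScore <- function(px, py, r) {
    a <- seq(0, 2 * pi, length.out = 37)[-37]
    mean(.cppSample(arr, cbind(px + r * cos(a) / vox, py + r * sin(a) / vox,
                               0), 0))
  }
  gs <- 1 / vox   # 1 nm search grid
  cand <- expand.grid(
    x = seq(cx - searchR / vox, cx + searchR / vox, by = gs),
    y = seq(cy - searchR / vox, cy + searchR / vox, by = gs))
  if (!is.null(sector)) {
    ang <- (rad2deg(atan2(cand$y - cy, cand$x - cx)) - sector[1]) %% 360
    keep <- ang <= (sector[2] - sector[1]) %% 360
    cand <- cand[keep, , drop = FALSE]
  }
  if (is.null(expectedDist) && length(radii) > 1L)
    expectedDist <- tubuleDistMatrix(length(radii))
  centers <- matrix(NA_real_, length(radii), 2)
  refine1d <- function(f0, f1, f2) {
    dn <- f0 - 2 * f1 + f2
    if (dn < 0) 0.5 * (f0 - f2) / dn else 0
  }
  for (ti in seq_along(radii)) {
    sc <- vapply(seq_len(nrow(cand)), function(i)
      ringScore(cand$x[i], cand$y[i], radii[ti]), 0)
    if (ti > 1L) {
      for (j in seq_len(ti - 1L)) {
        dd <- sqrt((cand$x - centers[j, 1])^2 +
                   (cand$y - centers[j, 2])^2) * vox
        sc[abs(dd - expectedDist[ti, j]) > tol] <- -Inf
      }
    }
    if (all(!is.finite(sc)))
      stop("fit-degenerate: tubule centres not found")
    best <- which.max(sc)
    bx <- cand$x[best]
    by <- cand$y[best]
    # parabolic sub-grid refinement of the ring-score peak
    dxs <- gs * refine1d(ringScore(bx - gs, by, radii[ti]), sc[best],
                         ringScore(bx + gs, by, radii[ti]))
    dys <- gs * refine1d(ringScore(bx, by - gs, radii[ti]), sc[best],
                         ringScore(bx, by + gs, radii[ti]))
    centers[ti, ] <- c(bx + dxs, by + dys)
  }
  # nm relative to the box centre
  sweep(centers, 2, c(cx, cy)) * vox
}

# Long-axis angle (degrees) of a blade map: the direction from the A
# centre to the outermost tubule centre of the z-collapsed map.
bladeMapAxisAngle <- function(map3, vox, nTubules) {
  d <- dim(map3)
  m2 <- apply(map3, c(1, 2), mean)
  radii <- c(12.5, rep(11.5, nTubules - 1))
  cen <- locateTubules(m2, vox, radii,
                       searchR = min(30, min(d[1], d[2]) * vox / 2 - 14))
  dvec <- cen[nTubules, ] - cen[1, ]
  rad2deg(atan2(dvec[2], dvec[1]))
}

#' Impose 9-fold symmetry on a blade average
#'
#' Places the blade map at nine azimuths k * 40 degrees at the supplied
#' blade radius, oriented so the blade long axis (measured from the map by
#' ring-matching the tubule centres) sits at the supplied blade tilt from
#' the local tangent, and sums the densities.
#'
#' @param bladeAverage an [AverageMap-class] or [DensityVolume-class] in
#'   the blade frame (z axial).
#' @param params a [SymmetryParams-class].
#' @param boxXZ cross-section box size of the output, voxels (defaults to
#'   a box containing the ensemble).
#' @param nTubules tubules per blade (3 = triplet, 2 = doublet).
#' @return An [EnsembleModel-class] (ensemble axis along y).
#' @export
symmetrize <- function(bladeAverage, params, boxXZ = NULL, nTubules = 3L,
                       blobVoxel = 2) {
  if (is(bladeAverage, "BladeModel"))
    return(symmetrizeBlobs(bladeAverage, params, boxXZ, blobVoxel))
  vox <- voxelSize(bladeAverage)
  b <- asArray(bladeAverage)
  d <- dim(b)
  need <- 2 * (params@bladeRadius + max(d[1], d[2]) * vox / 2 + 4) / vox
  if (is.null(boxXZ)) boxXZ <- 2L * ceiling(need / 2)
  if (boxXZ < need - 1e-9)
    stop("invalid-argument: blade larger than the requested box")
  theta <- bladeMapAxisAngle(b, vox, nTubules)
  ny <- d[3]
  outDim <- c(as.integer(boxXZ), as.integer(ny), as.integer(boxXZ))
  acc <- array(0, outDim)
  for (k in 0:8) {
    phi <- k * 40
    alpha <- phi + 90 + params@bladeTilt - theta
    ca <- cos(deg2rad(alpha)); sa <- sin(deg2rad(alpha))
    # blade -> ensemble: bx -> (ca, 0, sa), by -> (-sa, 0, ca), bz -> y
    Reb <- matrix(c(ca, 0, sa, -sa, 0, ca, 0, 1, 0), 3, 3)
    cenE <- params@bladeRadius * c(cos(deg2rad(phi)), 0,
                                   sin(deg2rad(phi))) / vox
    Q <- t(Reb)
    t0 <- -as.numeric(Q %*% cenE)
    acc <- acc + .cppResample(b, outDim, Q, t0, 0)
  }
  new("EnsembleModel", density = DensityVolume(acc, vox), params = params,
      bladeMap = b, nTubules = as.integer(nTubules), blobs = data.frame())
}

# Point-model branch of symmetrize: places the blade's blob set at the nine
# azimuths (exact rigid transforms, no resampling) and rasterizes the
# resulting ensemble; the blob table is kept on the EnsembleModel so the
# 9-fold symmetry of the construction is exact.
symmetrizeBlobs <- function(bm, params, boxXZ = NULL, voxel = 2) {
  cen <- bm@centers
  last <- names(cen)[length(cen)]
  theta <- rad2deg(atan2(cen[[last]][2] - cen[["A"]][2],
                         cen[[last]][1] - cen[["A"]][1]))
  b <- bm@blobs
  rows <- lapply(0:8, function(k) {
    phi <- k * 40
    alpha <- deg2rad(phi + 90 + params@bladeTilt - theta)
    gx <- params@bladeRadius * cos(deg2rad(phi)) +
      b$x * cos(alpha) - b$y * sin(alpha)
    gz <- params@bladeRadius * sin(deg2rad(phi)) +
      b$x * sin(alpha) + b$y * cos(alpha)
    data.frame(x = gx, y = b$z, z = gz, sigma = b$sigma, mass = b$mass,
               part = b$part, blade = k + 1L)
  })
  blobs <- do.call(rbind, rows)
  ext <- 2 * (max(sqrt(blobs$x^2 + blobs$z^2)) + 10)
  if (is.null(boxXZ)) boxXZ <- 2L * ceiling(ext / voxel / 2)
  ny <- 2L * ceiling((max(abs(blobs$y)) + 10) / voxel / 2)
  dens <- rasterize(blobs[, c("x", "y", "z", "sigma", "mass")], voxel,
                    box = c(boxXZ, ny, boxXZ))
  nT <- length(cen)
  new("EnsembleModel", density = dens, params = params,
      bladeMap = array(0, c(1, 1, 1)), nTubules = as.integer(nT),
      blobs = blobs)
}

#' Outer-envelope diameter of a symmetrized ensemble
#'
#' Thresholds the density at `thresholdFraction` of its maximum and
#' returns the maximum chord through the axis between above-threshold
#' voxels, averaged over azimuth.
#'
#' @param ensemble an [EnsembleModel-class] (or a [DensityVolume-class]
#'   with the axis along y).
#' @param thresholdFraction density threshold as a fraction of the
#'   maximum.
#' @return diameter, nm.
#' @export
measureDiameter <- function(ensemble, thresholdFraction = 0.2) {
  v <- if (is(ensemble, "EnsembleModel")) ensemble@density else ensemble
  vox <- voxelSize(v)
  a <- asArray(v)
  d <- dim(a)
  idx <- which(a > thresholdFraction * max(a), arr.ind = TRUE)
  if (!nrow(idx)) stop("invalid-argument: empty thresholded set")
  x <- (idx[, 1] - 1 - (d[1] - 1) / 2) * vox
  z <- (idx[, 3] - 1 - (d[3] - 1) / 2) * vox
  r <- sqrt(x^2 + z^2)
  az <- (rad2deg(atan2(z, x))) %% 360
  bin <- floor(az / 2)
  rmax <- tapply(r, bin, max)
  full <- rep(NA_real_, 180)
  full[as.integer(names(rmax)) + 1L] <- rmax
  opp <- c(full[91:180], full[1:90])
  chord <- full + opp
  mean(chord, na.rm = TRUE)
}

#' Blade tilt of an ensemble or cross-section
#'
#' For an ensemble: the blade long axis is re-measured from the
#' symmetrized density (ring-matching the tubule centres within the blade
#' sector at azimuth 0) and the tilt is its angle from the local tangent,
#' inward positive. For a cross-section paired with its domain average
#' map: per-particle tilt from the refined in-plane orientation, the
#' map-measured long-axis angle and the refit azimuth, averaged
#' circularly.
#'
#' @param x an [EnsembleModel-class], or a [CrossSection-class].
#' @param average domain [AverageMap-class] (cross-section method).
#' @param nTubules tubules per blade.
#' @return tilt, degrees (positive = outer end toward the axis).
#' @export
measureBladeTilt <- function(x, average = NULL, nTubules = 3L) {
  if (is(x, "EnsembleModel")) {
    v <- x@density
    vox <- voxelSize(v)
    m2 <- apply(asArray(v), c(1, 3), mean)
    # 9-fold folding: average the 9 rotated copies so quantization and
    # noise average out before locating the blade's tubule centres
    d2 <- dim(m2)
    arr <- array(m2, c(d2[1], d2[2], 1))
    fold <- m2
    for (k in 1:8) {
      a <- deg2rad(40 * k)
      Q <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
      fold <- fold + array(.cppResample(arr, c(d2, 1L), Q, c(0, 0, 0), 0),
                           d2)
    }
    m2 <- fold / 9
    radii <- c(12.5, rep(11.5, x@nTubules - 1))
    cen <- locateTubules(m2, vox, radii, sector = c(-25, 25))
    dvec <- cen[x@nTubules, ] - cen[1, ]
    axisAng <- rad2deg(atan2(dvec[2], dvec[1]))
    # tangent taken at the tubule centroid, the blade's reference point
    mid <- colMeans(cen)
    azim <- rad2deg(atan2(mid[2], mid[1]))
    tilt <- angleDiff(axisAng, azim + 90)
    if (tilt < -90) tilt <- tilt + 180
    if (tilt > 90) tilt <- tilt - 180
    return(tilt)
  }
  if (is.null(average))
    stop("invalid-argument: cross-section method needs the domain average")
  theta <- bladeMapAxisAngle(asArray(average), voxelSize(average), nTubules)
  az <- rad2deg(atan2(x@points[, 2], x@points[, 1]))
  tilts <- angleDiff(x@inPlane + theta, az + 90)
  tilts[tilts < -90] <- tilts[tilts < -90] + 180
  tilts[tilts > 90] <- tilts[tilts > 90] - 180
  mean(tilts)
}

#' Inward blade-tilt change between two ensembles
#'
#' @param proximal,distal [EnsembleModel-class] objects (or precomputed
#'   tilts in degrees).
#' @return distal tilt minus proximal tilt, degrees (inward positive).
#' @export
tiltChange <- function(proximal, distal) {
  tp <- if (is(proximal, "EnsembleModel")) measureBladeTilt(proximal)
        else proximal
  td <- if (is(distal, "EnsembleModel")) measureBladeTilt(distal)
        else distal
  td - tp
}

#' Rebuild a composite centriole from class-labelled particles
#'
#' Resamples each particle's class map into tomogram coordinates at its
#' refined pose, averaging overlaps, and reports per-rod statistics of
#' consecutive same-class runs.
#'
#' @param particles classified particle data.frame.
#' @param classMaps list of class maps (arrays or volumes), indexed by
#'   class label.
#' @param tomoDim tomogram dimensions, voxels.
#' @param tomoVoxel tomogram voxel size, nm.
#' @param mapVoxel class-map voxel size, nm.
#' @return list(composite = [DensityVolume-class], runs = per-rod class-run
#'   data.frame).
#' @export
rebuildComposite <- function(particles, classMaps, tomoDim, tomoVoxel,
                             mapVoxel = tomoVoxel) {
  if (any(is.na(particles$class_label)))
    stop("invalid-argument: unclassified particle present")
  if (max(particles$class_label) > length(classMaps) ||
      any(vapply(classMaps[unique(particles$class_label)], is.null, TRUE)))
    stop("invalid-argument: missing class map")
  tomoDim <- as.integer(tomoDim)
  acc <- array(0, tomoDim)
  wt <- array(0, tomoDim)
  d1 <- dim(asArray(classMaps[[1]]))
  half <- ceiling(sqrt(sum((d1 * mapVoxel)^2)) / 2 / tomoVoxel)
  boxOut <- rep(2L * half + 1L, 3L)
  ones <- array(1, d1)
  for (i in seq_len(nrow(particles))) {
    R <- eulerToMatrix(particles$rot_deg[i], particles$tilt_deg[i],
                       particles$psi_deg[i])
    m <- asArray(classMaps[[particles$class_label[i]]])
    cen <- c(particles$x_nm[i] + particles$sx_nm[i],
             particles$y_nm[i] + particles$sy_nm[i],
             particles$z_nm[i] + particles$sz_nm[i])
    cenVox <- cen / tomoVoxel + (tomoDim - 1) / 2    # 0-based
    base <- round(cenVox)
    frac <- cenVox - base
    Q <- t(R) * (tomoVoxel / mapVoxel)
    t0 <- -as.numeric(Q %*% frac)
    sub <- .cppResample(m, boxOut, Q, t0, 0)
    subw <- .cppResample(ones, boxOut, Q, t0, 0)
    i0 <- base - half + 1L     # 1-based tomogram index of sub (1,1,1)
    lo <- pmax(i0, 1L)
    hi <- pmin(i0 + boxOut - 1L, tomoDim)
    if (any(lo > hi)) next
    slo <- lo - i0 + 1L
    shi <- hi - i0 + 1L
    acc[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      acc[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
      sub[slo[1]:shi[1], slo[2]:shi[2], slo[3]:shi[3]]
    wt[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      wt[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
      subw[slo[1]:shi[1], slo[2]:shi[2], slo[3]:shi[3]]
    }
  comp <- acc / pmax(wt, 1e-6)
  runs <- do.call(rbind, lapply(split(particles, particles$rod_id),
    function(pr) {
      pr <- pr[order(pr$s_nm), ]
      r <- rle(pr$class_label)
      data.frame(rod_id = pr$rod_id[1], class = r$values, run = r$lengths)
    }))
  rownames(runs) <- NULL
  list(composite = DensityVolume(comp, tomoVoxel), runs = runs)
}

#' Calibrate a preset blade radius against a target ensemble diameter
#'
#' Fixed-point iteration: builds the domain blade, symmetrizes a thin slab
#' of the rasterized blob model at the current radius, measures the
#' 20%-of-max outer-envelope diameter, and nudges the radius by half the
#' diameter error. Used once, at design time, to set the preset radii.
#'
#' @param preset a [CentriolePreset-class].
#' @param domain "proximal", "distal" or "fly".
#' @param targetDiameter nm.
#' @param iterations fixed-point iterations.
#' @param voxelSize rasterization voxel, nm.
#' @return the calibrated radius, nm.
#' @export
calibrateBladeRadius <- function(preset, domain, targetDiameter,
                                 iterations = 4, voxelSize = 2) {
  r <- if (domain == "distal") preset@radiusDistal else preset@radiusProximal
  tilt <- if (domain == "distal") preset@bladeTiltDistal
          else preset@bladeTiltProximal
  for (it in seq_len(iterations)) {
    if (domain == "distal") preset@radiusDistal <- r
    else preset@radiusProximal <- r
    sp <- bladeSpecForPreset(preset, domain)
    bm <- buildBlade(sp, 40, tilt = tilt, seed = 1)
    nxy <- 2L * ceiling((max(abs(c(bm@blobs$x, bm@blobs$y))) + 8) / voxelSize)
    vol <- rasterize(bm, voxelSize,
                     box = c(nxy, nxy, 2L * ceiling(28 / voxelSize)))
    ens <- symmetrize(vol, SymmetryParams(r, tilt, domain),
                      nTubules = if (domain == "fly") 2L else 3L)
    D <- measureDiameter(ens)
    r <- r + (targetDiameter - D) / 2
  }
  r
}
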