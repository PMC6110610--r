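# Rod tracing and sub-volume extraction: trace the nine microtubule rods of
# a centriole tomogram, sample 24 nm segments along each rod with
# geometry-derived initial orientations, extract disc sub-volumes, and the
# angular/translational consistency curation filter.

#' Trace the nine microtubule rods in a tomogram
#'
#' Auto mode: low-pass filter to 8 nm, threshold at mean + 2 SD, label
#' connected components, keep the 9 longest sufficiently elongated ones and
#' fit a polyline (per-slice density centroid along the centriole axis) to
#' each. From-truth mode rebuilds the rods exactly from a ground-truth
#' table.
#'
#' @param tomogram a [DensityVolume-class]; the centriole axis is assumed
#'   along y (the tilt axis).
#' @param mode "auto" or "from_truth".
#' @param truth ground-truth table (required for from_truth).
#' @param lowpass tracing low-pass, nm.
#' @param thresholdSD threshold in SDs above the mean.
#' @return list of rods; each rod is a list(rod_id, centriole_id, points)
#'   with points an n x 3 matrix of nm control points ordered along y.
#' @export
traceRods <- function(tomogram, mode = c("auto", "from_truth"), truth = NULL,
                      lowpass = 8, thresholdSD = 2) {
  mode <- match.arg(mode)
  if (mode == "from_truth") {
    if (is.null(truth)) stop("from_truth mode needs a truth table")
    return(lapply(split(truth, truth$rod_id), function(tr) {
      tr <- tr[order(tr$y_nm), ]
      pts <- cbind(tr$x_nm, tr$y_nm, tr$z_nm)
      # truth rows are segment centres; extend to the physical rod ends
      n <- nrow(pts)
      if (n >= 2L) {
        pts <- rbind(pts[1, ] - (pts[2, ] - pts[1, ]) / 2,
                     pts,
                     pts[n, ] + (pts[n, ] - pts[n - 1, ]) / 2)
      }
      list(rod_id = tr$rod_id[1], centriole_id = 1L, points = pts)
    }))
  }
  v <- tomogram@data
  if (all(v == v[1])) stop("rod-deficit: found 0 rods (empty volume)")
  d <- dim(v)
  vox <- tomogram@voxelSize
  # Fourier low-pass to `lowpass` nm
  lp <- lowpassMask(d, vox, lowpass)
  vf <- Re(fft(fft(v) * lp, inverse = TRUE)) / prod(d)
  thr <- mean(vf) + thresholdSD * sd(as.numeric(vf))
  lab <- .cppLabel3D(vf > thr)
  tab <- tabulate(lab)
  comps <- order(tab, decreasing = TRUE)
  rods <- list()
  for (ci in comps) {
    if (tab[ci] < 20) break
    idx <- which(lab == ci, arr.ind = TRUE)
    yext <- (max(idx[, 2]) - min(idx[, 2])) * vox
    xext <- max(max(idx[, 1]) - min(idx[, 1]),
                max(idx[, 3]) - min(idx[, 3])) * vox
    if (yext < 3 * vox || yext < 1.2 * xext) next   # not elongated along y
    # per-y-slice density-weighted centroid
    w <- vf[idx]
    ys <- sort(unique(idx[, 2]))
    pts <- t(vapply(ys, function(j) {
      s <- idx[, 2] == j
      c(sum(idx[s, 1] * w[s]) / sum(w[s]), j,
        sum(idx[s, 3] * w[s]) / sum(w[s]))
    }, numeric(3)))
    ptsNm <- sweep(pts - 1, 2, (d - 1) / 2, "-") * vox
    rods[[length(rods) + 1L]] <- list(rod_id = length(rods) + 1L,
                                      centriole_id = 1L, points = ptsNm)
  }
  if (length(rods) < 9L)
    stop(sprintf("rod-deficit: found %d rods", length(rods)))
  lens <- vapply(rods, function(r) diff(range(r$points[, 2])), 0)
  rods <- rods[order(lens, decreasing = TRUE)[1:9]]
  # stable ordering by azimuth of the mean cross-section position
  az <- vapply(rods, function(r)
    atan2(mean(r$points[, 3]), mean(r$points[, 1])), 0)
  rods <- rods[order(az)]
  for (i in 1:9) rods[[i]]$rod_id <- i
  rods
}

#' Sample segment centres along a rod
#'
#' Arc-length parameterized sampling every `step` nm starting at
#' s = step / 2; the tangent is the normalized local derivative.
#'
#' @param rod a rod as returned by [traceRods()].
#' @param step segment step, nm (24 = 3 tubulin heterodimers).
#' @return data.frame (s, x, y, z, tx, ty, tz); zero rows if the rod is
#'   shorter than one step.
#' @export
sampleSegments <- function(rod, step = 24) {
  if (step <= 0) stop("invalid-argument: step must be > 0")
  p <- rod$points
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  s <- seq(step / 2, total, by = step)
  s <- s[s + step / 2 <= total + 1e-9]
  if (!length(s)) return(data.frame(s = numeric(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0),
                                    tx = numeric(0), ty = numeric(0),
                                    tz = numeric(0)))
  out <- t(vapply(s, function(si) {
    i <- max(which(arc <= si + 1e-9))
    i <- min(i, nrow(p) - 1)
    f <- (si - arc[i]) / max(seg[i], 1e-12)
    cen <- p[i, ] + f * (p[i + 1, ] - p[i, ])
    # tangent from a window of neighbouring control points
    i0 <- max(1, i - 1); i1 <- min(nrow(p), i + 2)
    tg <- p[i1, ] - p[i0, ]
    tg <- tg / sqrt(sum(tg^2))
    c(cen, tg)
  }, numeric(6)))
  data.frame(s = s, x = out[, 1], y = out[, 2], z = out[, 3],
             tx = out[, 4], ty = out[, 5], tz = out[, 6])
}

#' Geometry-derived initial orientation for one segment
#'
#' The reference z axis maps to the rod tangent and the reference x axis to
#' the outward radial direction from the centriole axis; returns intrinsic
#' ZYZ Euler angles in [-180, 180).
#'
#' @param center segment centre, nm.
#' @param tangent rod tangent (unit 3-vector).
#' @param axisPoint,axisDir a point on and the direction of the centriole
#'   axis.
#' @return named numeric (rot, tilt, psi), degrees.
#' @export
segmentOrientation <- function(center, tangent, axisPoint = c(0, 0, 0),
                               axisDir = c(0, 1, 0)) {
  tangent <- tangent / sqrt(sum(tangent^2))
  axisDir <- axisDir / sqrt(sum(axisDir^2))
  foot <- axisPoint + sum((center - axisPoint) * axisDir) * axisDir
  radial <- center - foot
  radial <- radial - sum(radial * tangent) * tangent
  nr <- sqrt(sum(radial^2))
  if (nr < 1e-9) stop("orientation-degenerate: tangent parallel to radial")
  radial <- radial / nr
  yv <- c(tangent[2] * radial[3] - tangent[3] * radial[2],
          tangent[3] * radial[1] - tangent[1] * radial[3],
          tangent[1] * radial[2] - tangent[2] * radial[1])
  R <- cbind(radial, yv, tangent)
  matrixToEuler(R)
}

#' Initial orientations for all segments of a rod
#'
#' @param rod a rod (see [traceRods()]).
#' @param step segment step, nm.
#' @param axisPoint,axisDir the centriole axis.
#' @return data.frame of segments with Euler angles appended.
#' @export
initialOrientations <- function(rod, step = 24, axisPoint = c(0, 0, 0),
                                axisDir = c(0, 1, 0)) {
  segs <- sampleSegments(rod, step)
  if (!nrow(segs)) return(cbind(segs, rot_deg = numeric(0),
                                tilt_deg = numeric(0), psi_deg = numeric(0)))
  eul <- t(vapply(seq_len(nrow(segs)), function(i)
    segmentOrientation(c(segs$x[i], segs$y[i], segs$z[i]),
                       c(segs$tx[i], segs$ty[i], segs$tz[i]),
                       axisPoint, axisDir), numeric(3)))
  segs$rot_deg <- eul[, 1]
  segs$tilt_deg <- eul[, 2]
  segs$psi_deg <- eul[, 3]
  segs
}

#' Build the particle table for a set of rods
#'
#' Samples segments along every rod, attaches geometry-derived initial
#' orientations, assigns alternating half-sets after a seeded shuffle, and
#' initializes shifts, scores and class labels.
#'
#' @param rods list of rods.
#' @param step segment step, nm.
#' @param seed seed for the half-set shuffle.
#' @return particle data.frame.
#' @export
sampleParticles <- function(rods, step = 24, seed = 1) {
  rows <- list()
  for (rod in rods) {
    segs <- initialOrientations(rod, step)
    if (!nrow(segs)) next
    rows[[length(rows) + 1L]] <- data.frame(
      centriole_id = rod$centriole_id, rod_id = rod$rod_id, s_nm = segs$s,
      x_nm = segs$x, y_nm = segs$y, z_nm = segs$z,
      rot_deg = segs$rot_deg, tilt_deg = segs$tilt_deg,
      psi_deg = segs$psi_deg)
  }
  p <- do.call(rbind, rows)
  p <- cbind(particle_id = seq_len(nrow(p)), p,
             sx_nm = 0, sy_nm = 0, sz_nm = 0, score = NA_real_,
             class_label = NA_integer_, half_set = 0L)
  set.seed(seed)
  ord <- sample(nrow(p))
  p$half_set[ord] <- rep_len(c(0L, 1L), nrow(p))
  # extraction pose: frozen copy of the initial orientation
  p$rot_x <- p$rot_deg
  p$tilt_x <- p$tilt_deg
  p$psi_x <- p$psi_deg
  rownames(p) <- NULL
  p
}

#' Extract a sub-volume at a particle pose
#'
#' Resamples the tomogram by trilinear interpolation into the particle
#' frame: the rotation is applied so the rod axis becomes the sub-volume z
#' axis. Out-of-bounds voxels are filled with the tomogram mean.
#'
#' @param tomogram a [DensityVolume-class].
#' @param center particle centre, nm (model frame).
#' @param euler (rot, tilt, psi) ZYZ degrees, reference -> tomogram.
#' @param box output box size (scalar or length 3), voxels.
#' @param voxelSize output voxel size, nm (default: tomogram voxel size).
#' @return A [DensityVolume-class] sub-volume.
#' @export
extractSubvolume <- function(tomogram, center, euler, box,
                             voxelSize = tomogram@voxelSize) {
  box <- as.integer(if (length(box) == 1L) rep(box, 3L) else box)
  d <- dim(tomogram@data)
  vin <- tomogram@voxelSize
  cenVox <- (center - tomogram@origin) / vin        # 0-based voxel coords
  if (any(cenVox < 0) || any(cenVox > d - 1))
    stop("out-of-bounds: center outside volume")
  R <- eulerToMatrix(euler[1], euler[2], euler[3])
  Q <- R * (voxelSize / vin)
  t <- cenVox - (d - 1) / 2
  arr <- .cppResample(tomogram@data, box, Q, t, mean(tomogram@data))
  DensityVolume(arr, voxelSize)
}

#' Angular/translational consistency curation
#'
#' Per rod, computes the circular median of each Euler angle and the median
#' shift, and rejects particles deviating beyond the thresholds.
#'
#' @param particles particle data.frame.
#' @param maxAngleDev maximum per-angle circular deviation, degrees.
#' @param maxShiftDev maximum per-axis shift deviation, nm.
#' @return list(kept, rejected, counts).
#' @export
curateConsistency <- function(particles, maxAngleDev = 15, maxShiftDev = 6) {
  keep <- logical(nrow(particles))
  for (rid in unique(particles$rod_id)) {
    i <- which(particles$rod_id == rid)
    medR <- circularMedian(particles$rot_deg[i])
    medT <- circularMedian(particles$tilt_deg[i])
    medP <- circularMedian(particles$psi_deg[i])
    medS <- c(median(particles$sx_nm[i]), median(particles$sy_nm[i]),
              median(particles$sz_nm[i]))
    devA <- pmax(abs(angleDiff(particles$rot_deg[i], medR)),
                 abs(angleDiff(particles$tilt_deg[i], medT)),
                 abs(angleDiff(particles$psi_deg[i], medP)))
    devS <- pmax(abs(particles$sx_nm[i] - medS[1]),
                 abs(particles$sy_nm[i] - medS[2]),
                 abs(particles$sz_nm[i] - medS[3]))
    keep[i] <- devA <= maxAngleDev & devS <= maxShiftDev
  }
  list(kept = particles[keep, , drop = FALSE],
       rejected = particles[!keep, , drop = FALSE],
       counts = c(kept = sum(keep), rejected = sum(!keep)))
}
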