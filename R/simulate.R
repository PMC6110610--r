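# Desk-scale segment simulator: generates wedge-filtered, noisy sub-volume
# segments of a blade directly in the particle frame, with known pose
# perturbations, bypassing the full tomogram for unit-scale studies.

#' Simulate extracted blade segments
#'
#' Each segment emulates the result of extracting a sub-volume at a
#' geometry-derived initial orientation from a +/-60 degree tomogram: the
#' blade is rasterized at a small random pose error (the deviation of the
#' truth from the initial orientation), white Gaussian noise is added at
#' the stated SNR (variance ratio within the signal support), and the
#' volume is band-limited to the particle's missing-wedge region, whose
#' orientation follows the segment's rod azimuth (a random multiple of 40
#' degrees).
#'
#' @param blade a [BladeModel-class] (z axial).
#' @param n number of segments.
#' @param snr signal-to-noise variance ratio; Inf for noiseless.
#' @param thetaRange tilt range, degrees.
#' @param box box size, voxels.
#' @param voxelSize voxel size, nm.
#' @param angSd SD of the per-angle truth-vs-initial Euler error, degrees
#'   (truncated at 2 SD).
#' @param shiftSd SD of the per-axis truth shift, nm (truncated at 2 SD).
#' @param seed integer seed.
#' @return list(subvols, particles, voxelSize, thetaRange); the particle
#'   table carries the initial pose (rot_deg/... = rot_x/...) and the truth
#'   in rot_true/tilt_true/psi_true and sx_true/sy_true/sz_true.
#' @export
simulateSegments <- function(blade, n, snr = 0.5, thetaRange = c(-60, 60),
                             box = 48, voxelSize = 1.5, angSd = 2,
                             shiftSd = 1.5, seed = 1) {
  set.seed(seed)
  box <- as.integer(if (length(box) == 1L) rep(box, 3L) else box)
  blobs <- blade@blobs
  P <- as.matrix(blobs[, c("x", "y", "z")])
  subvols <- vector("list", n)
  rows <- vector("list", n)
  rtrunc <- function(k, sd) {
    x <- rnorm(k, sd = sd)
    pmin(pmax(x, -2 * sd), 2 * sd)
  }
  origin <- -(box - 1) / 2 * voxelSize
  for (i in seq_len(n)) {
    rodIdx <- sample.int(9L, 1L)
    phi <- (rodIdx - 1L) * 40
    RX <- bladeRotation(phi)
    dAng <- rtrunc(3, angSd)
    tErr <- rtrunc(3, shiftSd)
    dR <- eulerToMatrix(dAng[1], dAng[2], dAng[3])
    Ptrans <- t(dR %*% t(P)) + matrix(tErr, nrow(P), 3, byrow = TRUE)
    clean <- .cppBlobRaster(box, voxelSize, origin, Ptrans, blobs$sigma,
                            blobs$mass)
    if (is.finite(snr)) {
      supp <- abs(clean) > 0.05 * max(abs(clean))
      vs <- if (any(supp)) var(clean[supp]) else 1
      clean <- clean + rnorm(length(clean), sd = sqrt(vs / snr))
    }
    reg <- wedgeRegion(box, thetaRange[1], thetaRange[2], R = RX)
    subvols[[i]] <- fftInv(fft(clean) * reg)
    eulX <- matrixToEuler(RX)
    eulT <- matrixToEuler(RX %*% dR)
    sTom <- as.numeric(RX %*% tErr)
    rows[[i]] <- data.frame(
      particle_id = i, centriole_id = 1L, rod_id = rodIdx,
      s_nm = 12 + 24 * ((i - 1) %/% 9),
      x_nm = 0, y_nm = 0, z_nm = 0,
      rot_deg = eulX[["rot"]], tilt_deg = eulX[["tilt"]],
      psi_deg = eulX[["psi"]],
      sx_nm = 0, sy_nm = 0, sz_nm = 0, score = NA_real_,
      class_label = NA_integer_, half_set = 0L,
      rot_x = eulX[["rot"]], tilt_x = eulX[["tilt"]], psi_x = eulX[["psi"]],
      rot_true = eulT[["rot"]], tilt_true = eulT[["tilt"]],
      psi_true = eulT[["psi"]],
      sx_true = sTom[1], sy_true = sTom[2], sz_true = sTom[3])
  }
  particles <- do.call(rbind, rows)
  ord <- sample(n)
  particles$half_set[ord] <- rep_len(c(0L, 1L), n)
  list(subvols = subvols, particles = particles, voxelSize = voxelSize,
       thetaRange = thetaRange)
}

#' Angular recovery error of aligned segments
#'
#' Geodesic rotation distance between each particle's refined pose and its
#' simulated truth.
#'
#' @param particles particle table from [simulateSegments()], after
#'   alignment.
#' @return numeric vector of geodesic errors, degrees.
#' @export
angularError <- function(particles) {
  vapply(seq_len(nrow(particles)), function(i) {
    rotationDistance(
      eulerToMatrix(particles$rot_deg[i], particles$tilt_deg[i],
                    particles$psi_deg[i]),
      eulerToMatrix(particles$rot_true[i], particles$tilt_true[i],
                    particles$psi_true[i]))
  }, 0)
}
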