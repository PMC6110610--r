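# Tomographic simulation: analytic rasterization of Gaussian-blob models,
# single-axis tilt projection, additive white-Gaussian noise at a stated
# SNR, ramp-weighted back-projection, and Fourier missing-wedge masks.
# Convention: tilt axis = y (dim 2), beam = z (dim 3) at zero tilt,
# right-handed rotation about +y.

#' Rasterize a model to a density volume
#'
#' Each Gaussian blob is added analytically (evaluated out to 4 sigma); the
#' integrated density equals the summed blob masses for blobs well inside
#' the box.
#'
#' @param model a [CentrioleModel-class], [BladeModel-class], or a blob
#'   data.frame with columns x, y, z, sigma, mass (nm).
#' @param voxelSize voxel size, nm.
#' @param box integer box dimensions (nx, ny, nz); defaults to a box
#'   covering the model extent plus 4 sigma.
#' @return A [DensityVolume-class] centred on the model-frame origin.
#' @export
rasterize <- function(model, voxelSize, box = NULL) {
  if (voxelSize <= 0) stop("invalid-argument: voxelSize must be positive")
  blobs <- if (is(model, "CentrioleModel")) modelBlobs(model)
    else if (is(model, "BladeModel")) model@blobs   # blade frame: z axial
    else model
  if (is.null(box)) {
    ext <- 2 * (max(abs(c(blobs$x, blobs$y, blobs$z))) + 4 * max(blobs$sigma))
    box <- rep(2L * ceiling(ext / voxelSize / 2), 3L)
  }
  box <- as.integer(box)
  lim <- (box * voxelSize) / 2
  out <- abs(blobs$x) > lim[1] | abs(blobs$y) > lim[2] | abs(blobs$z) > lim[3]
  if (any(out))
    warning(sum(out), " blobs outside the box were clipped")
  origin <- -(box - 1) / 2 * voxelSize
  arr <- .cppBlobRaster(box, voxelSize, origin,
                        as.matrix(blobs[, c("x", "y", "z")]),
                        blobs$sigma, blobs$mass)
  new("DensityVolume", data = arr, voxelSize = voxelSize, origin = origin)
}

# Note: BladeModel blobs are (x, y cross-section, z axial); rasterize maps
# them into the volume frame as (x, z-axial -> y axis? no) -- see below.

#' Project a volume into a single-axis tilt series
#'
#' The image at tilt theta is the line integral along the beam after
#' rotating the volume by theta about the tilt (y) axis; interpolation is
#' bilinear in the rotation plane.
#'
#' @param volume a [DensityVolume-class].
#' @param angles tilt angles in degrees, strictly inside (-90, 90);
#'   default +60..-60 at 1 degree sampling (121 images).
#' @return A [TiltSeries-class].
#' @export
projectTiltSeries <- function(volume, angles = seq(60, -60, by = -1)) {
  if (!length(angles)) stop("invalid-argument: empty angle list")
  if (any(abs(angles) >= 90)) stop("invalid-argument: angles must be in (-90, 90)")
  img <- .cppProjectY(volume@data, as.numeric(angles), volume@voxelSize)
  new("TiltSeries", images = img, tiltAngles = as.numeric(angles),
      pixelSize = volume@voxelSize)
}

#' Add white Gaussian noise at a stated SNR
#'
#' Per-image additive white Gaussian noise scaled so that the variance of
#' the signal within the signal mask divided by the noise variance equals
#' `snr`. The signal mask is where |image| exceeds 5% of the image maximum
#' (or a user mask). Deterministic under `seed`.
#'
#' @param series a [TiltSeries-class].
#' @param snr signal-to-noise variance ratio (> 0).
#' @param seed integer seed.
#' @param signalMask optional logical array matching one image.
#' @return the noisy [TiltSeries-class].
#' @export
addNoise <- function(series, snr, seed = 1, signalMask = NULL) {
  if (snr <= 0) stop("invalid-argument: snr must be > 0")
  set.seed(seed)
  img <- series@images
  na <- dim(img)[3]
  for (a in seq_len(na)) {
    im <- img[, , a]
    m <- if (is.null(signalMask)) abs(im) > 0.05 * max(abs(im)) else signalMask
    vs <- if (any(m)) var(as.numeric(im[m])) else var(as.numeric(im))
    if (vs == 0) vs <- 1
    img[, , a] <- im + rnorm(length(im), sd = sqrt(vs / snr))
  }
  new("TiltSeries", images = img, tiltAngles = series@tiltAngles,
      pixelSize = series@pixelSize)
}

# Ramp-filter a projection stack along the u (dim 1) direction.
rampFilter <- function(images) {
  d <- dim(images)
  f <- abs(fftFreq(d[1], 1))
  for (a in seq_len(d[3])) {
    F <- mvfft(images[, , a])
    images[, , a] <- Re(mvfft(F * f, inverse = TRUE)) / d[1]
  }
  images
}

#' Reconstruct a tomogram by weighted back-projection
#'
#' Projections are ramp-filtered (exact |f| weighting along the direction
#' perpendicular to the tilt axis) and smeared back along their beam
#' directions. A noiseless point source reconstructs to a peak within one
#' voxel of its true position; with a +/-60 degree series the peak is
#' elongated along the beam axis (the missing wedge).
#'
#' @param series a [TiltSeries-class] (angles sorted, either direction).
#' @param boxZ beam-axis (z) depth of the reconstruction in voxels;
#'   defaults to the image x extent.
#' @return A [DensityVolume-class] tomogram.
#' @export
reconstructWBP <- function(series, boxZ = NULL) {
  d <- dim(series@images)
  if (d[3] < 1L) stop("invalid-argument: no images")
  if (is.unsorted(series@tiltAngles) &&
      is.unsorted(rev(series@tiltAngles)))
    stop("invalid-argument: angles must be sorted")
  if (is.null(boxZ)) boxZ <- d[1]
  filt <- rampFilter(series@images)
  arr <- .cppBackprojectY(filt, series@tiltAngles, as.integer(boxZ))
  arr <- arr / series@pixelSize   # undo the nm line-integral scaling
  DensityVolume(arr, series@pixelSize)
}

# Logical array of the Fourier region sampled by a single-axis scheme
# covering [thetaMin, thetaMax] degrees, optionally for content rotated by
# R (reference -> tomogram): a frequency f passes iff R f lies in the
# sampled region.
wedgeRegion <- function(dim, thetaMin = -60, thetaMax = 60, R = NULL) {
  g <- freqGrids(dim, 1)
  if (is.null(R)) {
    gx <- g$fx
    gz <- g$fz
  } else {
    gx <- R[1, 1] * g$fx + R[1, 2] * g$fy + R[1, 3] * g$fz
    gz <- R[3, 1] * g$fx + R[3, 2] * g$fy + R[3, 3] * g$fz
  }
  # the central section at tilt t samples f with fx sin t + fz cos t = 0,
  # i.e. t* = atan2(-fz, fx) folded to (-90, 90]
  a <- rad2deg(atan2(-gz, gx))
  a[a > 90] <- a[a > 90] - 180
  a[a <= -90] <- a[a <= -90] + 180
  m <- (a >= thetaMin & a <= thetaMax) | (gx == 0 & gz == 0)
  # enforce Friedel symmetry: on even grids the Nyquist planes alias +f_N
  # and -f_N onto one voxel, which can break m(f) = m(-f) for rotated or
  # asymmetric ranges; a self-aliased frequency passes only if both do
  ci <- lapply(dim, function(n) ((n - (seq_len(n) - 1L)) %% n) + 1L)
  m & m[ci[[1]], ci[[2]], ci[[3]]]
}

#' Fourier missing-wedge mask
#'
#' @param thetaMin,thetaMax tilt range, degrees (thetaMin < thetaMax);
#'   (-90, 90) gives the all-ones mask.
#' @param box integer box dimensions.
#' @return A [WedgeMask-class]; the logical array is Friedel-symmetric.
#' @export
wedgeMask <- function(thetaMin, thetaMax, box) {
  if (thetaMin >= thetaMax) stop("invalid-argument: thetaMin must be < thetaMax")
  box <- as.integer(box)
  if (length(box) == 1L) box <- rep(box, 3L)
  m <- wedgeRegion(box, thetaMin, thetaMax)
  new("WedgeMask", thetaMin = thetaMin, thetaMax = thetaMax, dim = box,
      mask = m)
}
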