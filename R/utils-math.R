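# Rotation and Fourier-grid helpers. Euler convention (used package-wide):
# intrinsic ZYZ (rot, tilt, psi) in degrees; eulerToMatrix(rot, tilt, psi) =
# Rz(rot) %*% Ry(tilt) %*% Rz(psi) maps reference-frame coordinates to
# tomogram-frame coordinates.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rotZ <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rotY <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' ZYZ Euler angles to rotation matrix
#'
#' Intrinsic ZYZ convention: the returned matrix maps reference-frame
#' coordinates to tomogram-frame coordinates.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
eulerToMatrix <- function(rot, tilt, psi) rotZ(rot) %*% rotY(tilt) %*% rotZ(psi)

#' Rotation matrix to ZYZ Euler angles
#'
#' Inverse of [eulerToMatrix()]; angles returned in [-180, 180). At the
#' gimbal singularity (tilt = 0 or 180) psi is set to 0.
#'
#' @param R 3x3 rotation matrix.
#' @return named numeric vector (rot, tilt, psi), degrees.
#' @export
matrixToEuler <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- acos(ct)
  if (abs(ct) > 1 - 1e-12) {
    # tilt ~ 0 or 180: rot and psi degenerate, fold into rot
    rot <- atan2(R[2, 1], R[1, 1])
    if (ct < 0) rot <- -rot
    psi <- 0
  } else {
    rot <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  }
  out <- rad2deg(c(rot = as.numeric(rot), tilt = as.numeric(tilt),
                   psi = as.numeric(psi)))
  ((out + 180) %% 360) - 180
}

# Geodesic angle (degrees) between two rotation matrices.
rotationDistance <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  rad2deg(acos(max(-1, min(1, (tr - 1) / 2))))
}

# Centred FFT frequency coordinates (cycles per nm) for one axis, in the
# standard unshifted FFT ordering.
fftFreq <- function(n, voxel) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n == 1L) k <- 0
  k[seq_len(n)] / (n * voxel)
}

# Arrays of the frequency component along each axis, unshifted ordering.
# Memoized per (dim, voxel): these grids are rebuilt for every particle in
# the alignment and averaging loops.
.gridCache <- new.env(parent = emptyenv())

freqGrids <- function(dim, voxel) {
  key <- paste(c(dim, voxel), collapse = "x")
  hit <- .gridCache[[key]]
  if (!is.null(hit)) return(hit)
  fx <- fftFreq(dim[1], voxel)
  fy <- fftFreq(dim[2], voxel)
  fz <- fftFreq(dim[3], voxel)
  out <- list(
    fx = array(rep(fx, times = dim[2] * dim[3]), dim),
    fy = array(rep(rep(fy, each = dim[1]), times = dim[3]), dim),
    fz = array(rep(fz, each = dim[1] * dim[2]), dim)
  )
  if (length(ls(.gridCache)) > 8L) rm(list = ls(.gridCache),
                                      envir = .gridCache)
  .gridCache[[key]] <- out
  out
}

# Radial spatial frequency magnitude array (1/nm).
freqRadius <- function(dim, voxel) {
  g <- freqGrids(dim, voxel)
  sqrt(g$fx^2 + g$fy^2 + g$fz^2)
}

# Logical low-pass mask keeping |f| <= 1/lowpassNm (lowpass in nm).
lowpassMask <- function(dim, voxel, lowpassNm) {
  if (is.null(lowpassNm) || !is.finite(lowpassNm) || lowpassNm <= 0)
    return(array(TRUE, dim))
  freqRadius(dim, voxel) <= 1 / lowpassNm
}

# Is the 1-based index set `p` contiguous on the cycle 1..n?
isContiguousCyclic <- function(p, n) {
  p <- sort(unique(as.integer(p)))
  if (length(p) == n) return(TRUE)
  inset <- logical(n)
  inset[p] <- TRUE
  # contiguous iff exactly one FALSE->TRUE transition around the cycle
  trans <- sum(!inset[c(n, 1:(n - 1))] & inset)
  trans == 1L
}

# Circular median of angles in degrees: the sample minimizing the summed
# circular distance to all others (ties broken by first occurrence).
circularMedian <- function(deg) {
  if (length(deg) == 1L) return(deg)
  d <- outer(deg, deg, function(a, b) {
    x <- abs(a - b) %% 360
    pmin(x, 360 - x)
  })
  deg[which.min(rowSums(d))]
}

# Minimal circular difference a - b folded to [-180, 180).
angleDiff <- function(a, b) ((a - b + 180) %% 360) - 180

# Normalized cross-correlation of two real arrays within a logical/soft mask.
maskedNCC <- function(a, b, mask = NULL) {
  if (is.null(mask)) mask <- array(1, dim(a))
  w <- as.numeric(mask)
  sw <- sum(w)
  am <- sum(a * w) / sw
  bm <- sum(b * w) / sw
  ac <- (a - am) * w
  bc <- (b - bm) * w
  den <- sqrt(sum(ac * (a - am)) * sum(bc * (b - bm)))
  if (den == 0) return(0)
  sum(ac * (b - bm)) / den
}

# Soft spherical mask (cosine edge) centred in the box; radius/edge in voxels.
softSphereMask <- function(dim, radius, edge = 3) {
  cx <- (dim - 1) / 2
  x <- array(rep(seq_len(dim[1]) - 1 - cx[1], times = dim[2] * dim[3]), dim)
  y <- array(rep(rep(seq_len(dim[2]) - 1 - cx[2], each = dim[1]),
                 times = dim[3]), dim)
  z <- array(rep(seq_len(dim[3]) - 1 - cx[3], each = dim[1] * dim[2]), dim)
  r <- sqrt(x^2 + y^2 + z^2)
  m <- array(0, dim)
  m[r <= radius] <- 1
  band <- r > radius & r < radius + edge
  m[band] <- 0.5 * (1 + cos(pi * (r[band] - radius) / edge))
  m
}

# Soft cylindrical mask along z (dim 3): radius in xy, half-height hz, voxels.
softCylMask <- function(dim, radius, hz, edge = 3) {
  cx <- (dim - 1) / 2
  x <- array(rep(seq_len(dim[1]) - 1 - cx[1], times = dim[2] * dim[3]), dim)
  y <- array(rep(rep(seq_len(dim[2]) - 1 - cx[2], each = dim[1]),
                 times = dim[3]), dim)
  z <- array(rep(abs(seq_len(dim[3]) - 1 - cx[3]), each = dim[1] * dim[2]), dim)
  r <- sqrt(x^2 + y^2)
  soft <- function(d, lim) {
    m <- array(0, dim)
    m[d <= lim] <- 1
    band <- d > lim & d < lim + edge
    m[band] <- 0.5 * (1 + cos(pi * (d[band] - lim) / edge))
    m
  }
  soft(r, radius) * soft(z, hz)
}

# Deterministic sub-seed derivation (keeps results < 2^31 and independent
# across stages).
subSeed <- function(seed, k) {
  s <- (as.numeric(seed) * 1103 + 7919 * as.numeric(k)) %% 2147483647
  as.integer(s)
}
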