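#' @import methods
#' @importFrom stats fft rnorm runif sd var median prcomp kmeans quantile mvfft
#' @importFrom utils read.delim write.table head tail
#' @useDynLib centriotome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Real-space density volume on a regular grid
#'
#' The basic 3-D container of the package: a scalar array with a physical
#' voxel size in nanometres and the nm position of the centre of voxel
#' (1,1,1) in the model frame. Axis convention throughout: x = dim 1,
#' y = dim 2 (the tilt axis), z = dim 3 (the beam axis).
#'
#' @slot data numeric 3-D array.
#' @slot voxelSize voxel edge length, nm.
#' @slot origin nm coordinates of the centre of the first voxel.
#' @export
setClass("DensityVolume",
  representation(data = "array", voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
    if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
      return("voxelSize must be a single positive number")
    if (length(object@origin) != 3L) return("origin must have length 3")
    if (!all(is.finite(object@data))) return("data must be finite")
    TRUE
  }
)

#' Construct a DensityVolume
#'
#' @param data 3-D numeric array.
#' @param voxelSize voxel size in nm.
#' @param origin nm position of the first voxel centre; defaults to a
#'   box centred on the model-frame origin.
#' @return A [DensityVolume-class] object.
#' @export
DensityVolume <- function(data, voxelSize, origin = NULL) {
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * voxelSize
  new("DensityVolume", data = data, voxelSize = voxelSize,
      origin = as.numeric(origin))
}

#' Single-axis tilt series
#'
#' A stack of projection images with their nominal tilt angles. The tilt
#' axis is the image y axis (dim 2); the beam runs along the volume z axis
#' at zero tilt.
#'
#' @slot images numeric array, nx x ny x n_angles.
#' @slot tiltAngles tilt angles in degrees, one per image.
#' @slot pixelSize pixel size, nm.
#' @export
setClass("TiltSeries",
  representation(images = "array", tiltAngles = "numeric",
                 pixelSize = "numeric"),
  validity = function(object) {
    d <- dim(object@images)
    if (length(d) != 3L) return("images must be a 3-D stack")
    if (d[3] != length(object@tiltAngles))
      return("one image per tilt angle required")
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    TRUE
  }
)

#' @export
TiltSeries <- function(images, tiltAngles, pixelSize) {
  new("TiltSeries", images = images, tiltAngles = as.numeric(tiltAngles),
      pixelSize = pixelSize)
}

#' Fourier-space missing-wedge mask
#'
#' Binary mask of the Fourier region sampled by a single-axis tilt scheme
#' covering [thetaMin, thetaMax] degrees; a frequency passes iff some tilt
#' in the range sampled the central section containing it.
#'
#' @slot thetaMin,thetaMax tilt range, degrees.
#' @slot dim box dimensions the mask was materialized for.
#' @slot mask logical array (Friedel-symmetric).
#' @export
setClass("WedgeMask",
  representation(thetaMin = "numeric", thetaMax = "numeric",
                 dim = "integer", mask = "array"),
  validity = function(object) {
    if (object@thetaMin >= object@thetaMax) return("thetaMin must be < thetaMax")
    TRUE
  }
)

#' Wedge-weighted sub-volume average
#'
#' Extends [DensityVolume-class] with half-set maps, the accumulated wedge
#' coverage, and the number of contributing particles.
#'
#' @slot nParticles number of particles averaged.
#' @slot halfA,halfB independently refined half-set maps.
#' @slot coverage accumulated Fourier wedge coverage (particles per voxel).
#' @export
setClass("AverageMap",
  contains = "DensityVolume",
  representation(nParticles = "integer", halfA = "array", halfB = "array",
                 coverage = "array")
)

#' Fourier shell correlation curve
#'
#' @slot freq shell centre spatial frequencies, 1/nm.
#' @slot fsc correlation per shell.
#' @slot nvox voxels per shell.
#' @export
setClass("FSCCurve",
  representation(freq = "numeric", fsc = "numeric", nvox = "numeric"),
  validity = function(object) {
    if (length(object@freq) != length(object@fsc)) return("length mismatch")
    TRUE
  }
)

#' Direct least-squares ellipse fit
#'
#' @slot center 2-D centre, nm.
#' @slot a,b semi-major and semi-minor axes, nm (a >= b).
#' @slot orientation major-axis angle, degrees.
#' @export
setClass("EllipseFit",
  representation(center = "numeric", a = "numeric", b = "numeric",
                 orientation = "numeric"),
  validity = function(object) {
    if (object@b <= 0 || object@a < object@b) return("need a >= b > 0")
    TRUE
  }
)

## ---- model specification classes -------------------------------------------

#' Protofilament lattice specification
#'
#' Geometry of one microtubule wall: protofilament count, wall-centre
#' radius, the 8 nm tubulin dimer repeat with its 4 nm monomer offset,
#' the helical rise per protofilament, an optional seam (an enlarged
#' angular gap between two adjacent protofilaments), and the Gaussian
#' width used for each tubulin monomer density blob.
#'
#' @export
setClass("LatticeSpec",
  representation(nPf = "integer", tubuleRadius = "numeric",
                 dimerRepeat = "numeric", monomerOffset = "numeric",
                 risePerPf = "numeric", seamBetween = "integer",
                 seamExtraGap = "numeric", blobSigma = "numeric"),
  prototype(dimerRepeat = 8, monomerOffset = 4, seamBetween = integer(0),
            seamExtraGap = 0, blobSigma = 1.2),
  validity = function(object) {
    if (object@nPf < 1L) return("nPf must be >= 1")
    if (object@dimerRepeat <= 0) return("dimerRepeat must be > 0")
    if (length(object@seamBetween)) {
      s <- object@seamBetween
      if (length(s) != 2L || any(s < 1L) || any(s > object@nPf))
        return("seamBetween must name two pf indices in 1..nPf")
      if ((s[2] - s[1]) %% object@nPf != 1L && (s[1] - s[2]) %% object@nPf != 1L)
        return("seamBetween must name adjacent protofilaments")
    }
    TRUE
  }
)

#' @export
LatticeSpec <- function(nPf, tubuleRadius, dimerRepeat = 8, monomerOffset = 4,
                        risePerPf = NULL, seamBetween = integer(0),
                        seamExtraGap = 0, blobSigma = 1.2) {
  if (is.null(risePerPf)) risePerPf <- 3 * monomerOffset / nPf
  new("LatticeSpec", nPf = as.integer(nPf), tubuleRadius = tubuleRadius,
      dimerRepeat = dimerRepeat, monomerOffset = monomerOffset,
      risePerPf = risePerPf, seamBetween = as.integer(seamBetween),
      seamExtraGap = seamExtraGap, blobSigma = blobSigma)
}

#' Tubule specification within a blade
#'
#' @slot label "A", "B" or "C".
#' @slot lattice the [LatticeSpec-class].
#' @slot attachment for B/C tubules: the parent label and the two parent
#'   protofilament indices bounding the shared wall.
#' @slot presentPfs protofilament subset present (contiguous in cyclic
#'   order), for partial tubules.
#' @export
setClass("TubuleSpec",
  representation(label = "character", lattice = "LatticeSpec",
                 attachment = "list", presentPfs = "integer"),
  validity = function(object) {
    if (!object@label %in% c("A", "B", "C")) return("label must be A, B or C")
    if (object@label == "A" && length(object@attachment))
      return("A tubule must not have an attachment")
    if (object@label != "A" && !length(object@attachment))
      return("B/C tubules need an attachment")
    p <- object@presentPfs
    if (!length(p)) return("presentPfs must be non-empty")
    if (any(p < 1L) || any(p > object@lattice@nPf))
      return("presentPfs out of range")
    if (!isContiguousCyclic(p, object@lattice@nPf))
      return("presentPfs must be contiguous in cyclic order")
    TRUE
  }
)

#' @export
TubuleSpec <- function(label, lattice, attachment = list(),
                       presentPfs = seq_len(lattice@nPf)) {
  new("TubuleSpec", label = label, lattice = lattice, attachment = attachment,
      presentPfs = as.integer(presentPfs))
}

#' Decoration specification
#'
#' A named accessory density (pinhead, linker half, MIP, ...) anchored to
#' one or more protofilaments of one tubule, built from 1-4 Gaussian blobs
#' placed at blade-frame offsets from the anchor, replicated axially at
#' `axialPeriod` nm with Bernoulli `occupancy`.
#'
#' @export
setClass("DecorationSpec",
  representation(name = "character", anchorTubule = "character",
                 anchorPfs = "integer", offsets = "matrix",
                 sigmas = "numeric", masses = "numeric",
                 axialPeriod = "numeric", occupancy = "numeric"),
  validity = function(object) {
    if (!object@axialPeriod %in% c(4, 8, 16, 24))
      return("axialPeriod must be one of 4, 8, 16, 24 nm")
    if (object@occupancy < 0 || object@occupancy > 1)
      return("occupancy must be in [0, 1]")
    if (nrow(object@offsets) != length(object@sigmas) ||
        nrow(object@offsets) != length(object@masses))
      return("offsets/sigmas/masses length mismatch")
    TRUE
  }
)

#' @export
DecorationSpec <- function(name, anchorTubule, anchorPfs, offsets,
                           sigmas = 1.5, masses = 1, axialPeriod = 8,
                           occupancy = 1) {
  offsets <- matrix(as.numeric(offsets), ncol = 3)
  k <- nrow(offsets)
  new("DecorationSpec", name = name, anchorTubule = anchorTubule,
      anchorPfs = as.integer(anchorPfs), offsets = offsets,
      sigmas = rep_len(sigmas, k), masses = rep_len(masses, k),
      axialPeriod = axialPeriod, occupancy = occupancy)
}

#' Blade specification
#'
#' One microtubule blade: its tubules (A, and optionally B and C, possibly
#' partial), decorations, the axial domain it belongs to, and whether its
#' B-tubule is the incomplete biogenesis intermediate.
#'
#' @export
setClass("BladeSpec",
  representation(tubules = "list", decorations = "list", domain = "character",
                 partialB = "logical"),
  prototype(partialB = FALSE),
  validity = function(object) {
    if (!object@domain %in% c("proximal", "distal", "fly"))
      return("domain must be proximal, distal or fly")
    labs <- vapply(object@tubules, function(t) t@label, "")
    if (labs[1] != "A") return("first tubule must be A")
    if (any(duplicated(labs))) return("duplicate tubule labels")
    TRUE
  }
)

#' @export
BladeSpec <- function(tubules, decorations = list(), domain = "proximal",
                      partialB = FALSE) {
  new("BladeSpec", tubules = tubules, decorations = decorations,
      domain = domain, partialB = partialB)
}

#' Whole-centriole preset
#'
#' Named geometry of a 9-fold centriole: blade reference radius and blade
#' tilt (angle between the blade long axis and the local circle tangent,
#' positive = outer end rotated toward the axis) per domain, total length,
#' and the proximal/distal domain boundary.
#'
#' @export
setClass("CentriolePreset",
  representation(name = "character", nBlades = "integer",
                 radiusProximal = "numeric", radiusDistal = "numeric",
                 bladeTiltProximal = "numeric", bladeTiltDistal = "numeric",
                 length = "numeric", domainBoundary = "numeric"),
  validity = function(object) {
    if (object@nBlades != 9L) return("nBlades must be 9")
    if (object@domainBoundary < 0 || object@domainBoundary > object@length)
      return("domainBoundary must lie in [0, length]")
    TRUE
  }
)

#' Ice-sheet flattening specification
#'
#' Area-preserving elliptical remap of the blade centres: a circle of
#' radius R becomes an ellipse with semi-axes R(1+e) and R/(1+e) (so the
#' max/min centre distance ratio is (1+e)^2 and the enclosed area is
#' preserved). Blades stay rigid; only centres and in-plane orientations
#' move.
#'
#' @export
setClass("FlatteningSpec",
  representation(factor = "numeric", squashAxis = "numeric"),
  prototype(factor = 0, squashAxis = c(0, 1)),
  validity = function(object) {
    if (object@factor < 0) return("flattening factor must be >= 0")
    TRUE
  }
)

#' @export
FlatteningSpec <- function(factor = 0, squashAxis = c(0, 1)) {
  sq <- as.numeric(squashAxis)
  sq <- sq / sqrt(sum(sq^2))
  new("FlatteningSpec", factor = factor, squashAxis = sq)
}

#' Assembled centriole model
#'
#' Nine rigid blades with their poses, the axis (model-frame y), total
#' length, and the ground-truth segment table used to seed and score the
#' downstream pipeline.
#'
#' @slot blades list of per-blade lists (spec, blob table, pose).
#' @slot preset the [CentriolePreset-class] used.
#' @slot flattening the [FlatteningSpec-class] applied.
#' @slot groundTruth data.frame: rod_id, s_nm, x/y/z_nm, rot/tilt/psi_deg,
#'   domain, partial_b.
#' @export
setClass("CentrioleModel",
  representation(blades = "list", preset = "CentriolePreset",
                 flattening = "FlatteningSpec", groundTruth = "data.frame"),
  validity = function(object) {
    if (length(object@blades) != 9L) return("a centriole has 9 blades")
    TRUE
  }
)

#' 9-fold symmetry parameters
#'
#' Externally supplied geometry used for symmetrization: blade reference
#' radius and blade tilt for one domain. Mirrors the use of published
#' geometry rather than estimating symmetry from flattened data.
#'
#' @export
setClass("SymmetryParams",
  representation(n = "integer", bladeRadius = "numeric", bladeTilt = "numeric",
                 domain = "character"),
  prototype(n = 9L),
  validity = function(object) {
    if (object@n != 9L) return("n must be 9")
    if (object@bladeRadius <= 0) return("bladeRadius must be > 0")
    TRUE
  }
)

#' @export
SymmetryParams <- function(bladeRadius, bladeTilt, domain = "proximal", n = 9L) {
  new("SymmetryParams", n = as.integer(n), bladeRadius = bladeRadius,
      bladeTilt = bladeTilt, domain = domain)
}

#' Alignment search parameters
#'
#' Local grid-search ranges and steps for the three ZYZ Euler offsets and
#' the translational search, the alignment low-pass (nm), the soft
#' real-space mask, and the iteration count. A zero range fixes the
#' corresponding parameter.
#'
#' @export
setClass("AlignmentParams",
  representation(angularRange = "numeric", angularStep = "numeric",
                 shiftRange = "numeric", shiftStep = "numeric",
                 lowpass = "numeric", nIterations = "integer"),
  prototype(angularRange = 8, angularStep = 2, shiftRange = 6, shiftStep = 1,
            lowpass = 2.5, nIterations = 2L),
  validity = function(object) {
    if (object@angularStep <= 0 || object@shiftStep <= 0)
      return("steps must be > 0")
    if (object@angularRange < 0 || object@shiftRange < 0)
      return("ranges must be >= 0 (0 fixes the parameter)")
    TRUE
  }
)

#' @export
AlignmentParams <- function(angularRange = 8, angularStep = 2, shiftRange = 6,
                            shiftStep = 1, lowpass = 2.5, nIterations = 2L) {
  new("AlignmentParams", angularRange = angularRange, angularStep = angularStep,
      shiftRange = shiftRange, shiftStep = shiftStep, lowpass = lowpass,
      nIterations = as.integer(nIterations))
}
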