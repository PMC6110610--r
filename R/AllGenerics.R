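#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))
#' @export
setGeneric("halfMaps", function(x) standardGeneric("halfMaps"))
#' @export
setGeneric("wedgeCoverage", function(x) standardGeneric("wedgeCoverage"))
#' @export
setGeneric("resolutionAt", function(x, threshold = 0.143)
  standardGeneric("resolutionAt"))
#' @export
setGeneric("ellipticity", function(x) standardGeneric("ellipticity"))
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @export
setGeneric("tubuleCenters", function(x) standardGeneric("tubuleCenters"))
#' @export
setGeneric("tiltAngles", function(x) standardGeneric("tiltAngles"))

## ---- accessors --------------------------------------------------------------

#' @describeIn DensityVolume-class the raw array.
#' @param x object.
#' @export
setMethod("volData", "DensityVolume", function(x) x@data)

#' @describeIn DensityVolume-class the voxel size in nm.
#' @export
setMethod("voxelSize", "DensityVolume", function(x) x@voxelSize)

#' @describeIn TiltSeries-class the pixel size in nm.
#' @export
setMethod("voxelSize", "TiltSeries", function(x) x@pixelSize)

#' @describeIn TiltSeries-class tilt angles in degrees.
#' @export
setMethod("tiltAngles", "TiltSeries", function(x) x@tiltAngles)

#' @describeIn AverageMap-class contributing particle count.
#' @export
setMethod("nParticles", "AverageMap", function(x) x@nParticles)

#' @describeIn AverageMap-class list of the two half-set maps.
#' @export
setMethod("halfMaps", "AverageMap", function(x) list(A = x@halfA, B = x@halfB))

#' @describeIn AverageMap-class accumulated Fourier wedge coverage.
#' @export
setMethod("wedgeCoverage", "AverageMap", function(x) x@coverage)

#' @describeIn FSCCurve-class resolution (nm) where the curve first crosses
#'   `threshold`, linearly interpolated between shells.
#' @param threshold FSC threshold (default 0.143, gold standard).
#' @export
setMethod("resolutionAt", "FSCCurve", function(x, threshold = 0.143) {
  f <- x@freq
  v <- x@fsc
  below <- which(v < threshold)
  below <- below[below > 1L]
  if (!length(below)) return(1 / f[length(f)])
  i <- below[1]
  # linear interpolation between shells i-1 and i
  f0 <- f[i - 1]; f1 <- f[i]; v0 <- v[i - 1]; v1 <- v[i]
  fc <- if (v0 == v1) f1 else f0 + (v0 - threshold) / (v0 - v1) * (f1 - f0)
  1 / fc
})

#' @describeIn EllipseFit-class ellipticity in percent, 100 (a - b) / a.
#' @export
setMethod("ellipticity", "EllipseFit", function(x) 100 * (x@a - x@b) / x@a)

#' @describeIn CentrioleModel-class the ground-truth segment table.
#' @export
setMethod("groundTruth", "CentrioleModel", function(x) x@groundTruth)

## ---- show methods -----------------------------------------------------------

setMethod("show", "DensityVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d voxels @ %.3g nm (%.3g x %.3g x %.3g nm)\n",
              class(object), d[1], d[2], d[3], object@voxelSize,
              d[1] * object@voxelSize, d[2] * object@voxelSize,
              d[3] * object@voxelSize))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n", min(object@data),
              max(object@data), mean(object@data)))
})

setMethod("show", "TiltSeries", function(object) {
  d <- dim(object@images)
  cat(sprintf("TiltSeries: %d images of %d x %d px @ %.3g nm, tilts %g..%g deg\n",
              d[3], d[1], d[2], object@pixelSize,
              object@tiltAngles[1], object@tiltAngles[d[3]]))
})

setMethod("show", "AverageMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("AverageMap: %d x %d x %d @ %.3g nm from %d particles\n",
              d[1], d[2], d[3], object@voxelSize, object@nParticles))
})

setMethod("show", "FSCCurve", function(object) {
  cat(sprintf("FSCCurve: %d shells, FSC(0.143) resolution %.2f nm\n",
              length(object@freq), resolutionAt(object)))
})

setMethod("show", "EllipseFit", function(object) {
  cat(sprintf(
    "EllipseFit: centre (%.2f, %.2f) nm, a = %.2f, b = %.2f nm, %.1f deg, ellipticity %.1f%%\n",
    object@center[1], object@center[2], object@a, object@b,
    object@orientation, ellipticity(object)))
})

setMethod("show", "CentrioleModel", function(object) {
  cat(sprintf(
    "CentrioleModel '%s': 9 blades, length %g nm, flattening e = %g, %d ground-truth segments\n",
    object@preset@name, object@preset@length, object@flattening@factor,
    nrow(object@groundTruth)))
})
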