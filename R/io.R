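# File formats: MRC (mode 2 float) volumes with the voxel size in the
# header cell dimensions (Angstrom = nm * 10), plain-text .tlt tilt-angle
# files, and particle tables as TSV or a STAR dialect with RELION-style
# column names.

#' Write a volume as MRC (mode 2, float32)
#'
#' @param volume a [DensityVolume-class] (or [AverageMap-class]).
#' @param path output file.
#' @export
writeMRC <- function(volume, path) {
  d <- dim(volume@data)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d[1], d[2], d[3], 2L)), con, size = 4)      # nx..mode
  writeBin(integer(3), con, size = 4)                                # nstart
  writeBin(as.integer(d), con, size = 4)                             # mx my mz
  writeBin(as.numeric(d) * volume@voxelSize * 10, con, size = 4)     # cella, A
  writeBin(rep(90, 3), con, size = 4)                                # cellb
  writeBin(1:3, con, size = 4)                                       # mapc/r/s
  writeBin(c(min(volume@data), max(volume@data), mean(volume@data)),
           con, size = 4)                                            # dmin..
  writeBin(integer(2), con, size = 4)                                # ispg, nsymbt
  writeBin(integer(25), con, size = 4)                               # extra
  writeBin(numeric(3), con, size = 4)                                # origin A
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)                   # machst LE
  writeBin(sd(as.numeric(volume@data)), con, size = 4)               # rms
  writeBin(0L, con, size = 4)                                        # nlabl
  writeBin(raw(800), con)                                            # labels
  writeBin(as.numeric(volume@data), con, size = 4)
  invisible(path)
}

#' Read an MRC volume (modes 0, 1, 2)
#'
#' @param path MRC file.
#' @return A [DensityVolume-class]; the voxel size is taken from the cell
#'   dimensions (Angstrom / 10).
#' @export
readMRC <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- readBin(con, "integer", 4, size = 4)
  d <- hd[1:3]
  mode <- hd[4]
  invisible(readBin(con, "integer", 3, size = 4))
  mxyz <- readBin(con, "integer", 3, size = 4)
  cella <- readBin(con, "numeric", 3, size = 4)
  invisible(readBin(con, "raw", 1024 - 52))
  vox <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] / 10 else 1
  n <- prod(d)
  arr <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE)),
    "2" = readBin(con, "numeric", n, size = 4),
    stop("unsupported MRC mode ", mode))
  DensityVolume(array(arr, d), vox)
}

#' Write / read tilt angles as a plain-text .tlt file
#'
#' One angle (degrees) per line.
#' @param angles numeric vector or a [TiltSeries-class].
#' @param path file path.
#' @export
writeTlt <- function(angles, path) {
  if (is(angles, "TiltSeries")) angles <- angles@tiltAngles
  writeLines(sprintf("%.2f", angles), path)
  invisible(path)
}

#' @rdname writeTlt
#' @export
readTlt <- function(path) as.numeric(readLines(path))

particleColumns <- c("particle_id", "centriole_id", "rod_id", "s_nm",
                     "x_nm", "y_nm", "z_nm", "rot_deg", "tilt_deg", "psi_deg",
                     "sx_nm", "sy_nm", "sz_nm", "score", "class_label",
                     "half_set")

#' Write / read a particle table as TSV
#'
#' @param particles particle data.frame (see [sampleParticles()]).
#' @param path file path.
#' @export
writeParticlesTSV <- function(particles, path) {
  write.table(particles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeParticlesTSV
#' @export
readParticlesTSV <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Write a particle table in the STAR dialect
#'
#' Columns rlnCoordinate{X,Y,Z} (nm), rlnAngle{Rot,Tilt,Psi} (degrees, ZYZ
#' intrinsic), rlnOrigin{X,Y,Z} (nm shifts), plus custom columns rodID,
#' sNm, classLabel, halfSet and scoreCC.
#'
#' @param particles particle data.frame.
#' @param path file path.
#' @export
writeParticlesSTAR <- function(particles, path) {
  cols <- c(rlnCoordinateX = "x_nm", rlnCoordinateY = "y_nm",
            rlnCoordinateZ = "z_nm", rlnAngleRot = "rot_deg",
            rlnAngleTilt = "tilt_deg", rlnAnglePsi = "psi_deg",
            rlnOriginX = "sx_nm", rlnOriginY = "sy_nm", rlnOriginZ = "sz_nm",
            rodID = "rod_id", sNm = "s_nm", classLabel = "class_label",
            halfSet = "half_set", scoreCC = "score")
  cols <- cols[cols %in% names(particles)]
  lines <- c("", "data_particles", "", "loop_",
             sprintf("_%s #%d", names(cols), seq_along(cols)))
  tab <- particles[, cols, drop = FALSE]
  body <- do.call(paste, c(lapply(tab, function(x)
    if (is.numeric(x)) sprintf("%.6g", x) else as.character(x)),
    sep = "\t"))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a STAR-dialect particle table
#'
#' @param path STAR file written by [writeParticlesSTAR()] (or any
#'   single-block loop_ STAR file with those column names).
#' @export
readParticlesSTAR <- function(path) {
  ln <- readLines(path)
  hdr <- grep("^_", ln)
  names <- sub("^_([^ #]+).*$", "\\1", ln[hdr])
  body <- ln[(max(hdr) + 1):length(ln)]
  body <- body[nzchar(trimws(body))]
  tab <- read.delim(text = body, header = FALSE, stringsAsFactors = FALSE)
  names(tab) <- names
  back <- c(rlnCoordinateX = "x_nm", rlnCoordinateY = "y_nm",
            rlnCoordinateZ = "z_nm", rlnAngleRot = "rot_deg",
            rlnAngleTilt = "tilt_deg", rlnAnglePsi = "psi_deg",
            rlnOriginX = "sx_nm", rlnOriginY = "sy_nm", rlnOriginZ = "sz_nm",
            rodID = "rod_id", sNm = "s_nm", classLabel = "class_label",
            halfSet = "half_set", scoreCC = "score")
  hit <- names(tab) %in% names(back)
  names(tab)[hit] <- back[names(tab)[hit]]
  tab
}

#' Write a Fourier shell correlation curve as two-column TSV
#'
#' @param fsc an [FSCCurve-class].
#' @param path file path.
#' @export
writeFSC <- function(fsc, path) {
  write.table(data.frame(freq_invnm = fsc@freq, fsc = fsc@fsc), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
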