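# Missing-wedge-aware subtomogram alignment and averaging.
#
# All scores are normalized cross-correlations computed on the Fourier
# region jointly sampled by both inputs (wedge intersection, optionally
# low-passed); averages are wedge-weighted Fourier sums divided by the
# accumulated coverage with a small-constant floor.

asArray <- function(x) if (is(x, "DensityVolume")) x@data else x

fftInv <- function(F) Re(fft(F, inverse = TRUE)) / length(F)

#' Missing-wedge-constrained cross-correlation
#'
#' Normalized correlation of two volumes computed in Fourier space
#' restricted to the intersection of their sampled wedges and an optional
#' low-pass, with both inputs mean-subtracted (zero frequency excluded)
#' and variance-normalized within that region. Equals the real-space
#' normalized correlation of wedge-filtered copies.
#'
#' @param a,b volumes (arrays or [DensityVolume-class]) of equal size.
#' @param wedgeA,wedgeB logical Fourier region arrays or
#'   [WedgeMask-class] objects (NULL = fully sampled).
#' @param mask optional soft real-space mask applied to both inputs.
#' @param lowpass optional low-pass, nm.
#' @param voxelSize voxel size, nm (needed when `lowpass` is set and the
#'   inputs are plain arrays).
#' @return correlation in [-1, 1].
#' @export
constrainedCC <- function(a, b, wedgeA = NULL, wedgeB = NULL, mask = NULL,
                          lowpass = NULL, voxelSize = NULL) {
  if (is(a, "DensityVolume") && is.null(voxelSize)) voxelSize <- a@voxelSize
  a <- asArray(a)
  b <- asArray(b)
  if (!identical(dim(a), dim(b))) stop("invalid-argument: unequal box sizes")
  reg <- array(TRUE, dim(a))
  grab <- function(w) if (is(w, "WedgeMask")) w@mask else w
  if (!is.null(wedgeA)) reg <- reg & grab(wedgeA)
  if (!is.null(wedgeB)) reg <- reg & grab(wedgeB)
  if (!is.null(lowpass)) {
    if (is.null(voxelSize)) voxelSize <- 1
    reg <- reg & lowpassMask(dim(a), voxelSize, lowpass)
  }
  reg[1, 1, 1] <- FALSE   # exclude DC: mean subtraction
  if (!any(reg)) stop("empty-overlap: no jointly sampled frequencies")
  if (!is.null(mask)) {
    a <- a * mask
    b <- b * mask
  }
  FA <- fft(a)[reg]
  FB <- fft(b)[reg]
  num <- sum(Re(Conj(FA) * FB))
  den <- sqrt(sum(Mod(FA)^2) * sum(Mod(FB)^2))
  if (den == 0) return(0)
  num / den
}

# Pearson-style score of a pre-centred volume `a` (sum(w * a) = 0) against
# `b` under weights w; saa = sum(w a^2), sw = sum(w). `aw` may carry the
# precomputed a * w to save a pass.
weightedScore <- function(a, b, w, saa, sw, aw = a * w) {
  s <- .cppScoreSums(aw, b, w)
  den <- saa * (s[3] - s[2]^2 / sw)
  if (den <= 0) return(0)
  s[1] / sqrt(den)
}

# Candidate Euler-offset grid ordered for deterministic tie-breaking:
# smallest total angular offset first, then lexicographic.
offsetGrid <- function(range, step) {
  if (range <= 0) return(matrix(0, 1, 3))
  v <- seq(-range, range, by = step)
  g <- as.matrix(expand.grid(dr = v, dt = v, dp = v))
  g <- g[order(abs(g[, 1]) + abs(g[, 2]) + abs(g[, 3]),
               g[, 1], g[, 2], g[, 3]), , drop = FALSE]
  g
}

#' Align particles to a reference by constrained local grid search
#'
#' For each particle the reference is band-limited to the particle's
#' sampled Fourier region (its rotated wedge intersected with the
#' alignment low-pass), then an exhaustive local grid search over the
#' three ZYZ Euler offsets maximizes the masked normalized correlation;
#' the translational offset is found at the best orientation by FFT
#' cross-correlation with parabolic sub-voxel refinement. Ties are broken
#' toward the smallest total angular offset, then lexicographically.
#'
#' @param particles particle data.frame (extraction pose in rot_x/tilt_x/
#'   psi_x, current pose in rot_deg/tilt_deg/psi_deg).
#' @param subvols list of sub-volume arrays (reference-frame extractions).
#' @param reference reference volume (array or [DensityVolume-class]); may
#'   be a list(A=, B=) of per-half-set references.
#' @param params an [AlignmentParams-class].
#' @param thetaRange tilt range of the acquisition, degrees.
#' @param voxelSize sub-volume voxel size, nm.
#' @param mask optional soft real-space mask.
#' @param inPlanePre optional c(range, step): coarse psi-only scan run
#'   before the local search (for data-derived starting references).
#' @return the particle table with refined poses, shifts and scores.
#' @export
alignParticles <- function(particles, subvols, reference, params,
                           thetaRange = c(-60, 60), voxelSize = 1,
                           mask = NULL, inPlanePre = NULL) {
  refs <- if (is.list(reference) && !is(reference, "DensityVolume"))
    lapply(reference, asArray) else list(all = asArray(reference))
  d <- dim(refs[[1]])
  Frefs <- lapply(refs, fft)
  lp <- lowpassMask(d, voxelSize, params@lowpass)
  w <- if (is.null(mask)) array(1, d) else mask
  sw <- sum(w)
  grid <- offsetGrid(params@angularRange, params@angularStep)
  shiftVox <- params@shiftRange / voxelSize

  for (i in seq_len(nrow(particles))) {
    RX <- eulerToMatrix(particles$rot_x[i], particles$tilt_x[i],
                        particles$psi_x[i])
    Rc <- eulerToMatrix(particles$rot_deg[i], particles$tilt_deg[i],
                        particles$psi_deg[i])
    dR0 <- crossprod(RX, Rc)
    reg <- wedgeRegion(d, thetaRange[1], thetaRange[2], R = RX) & lp
    Fref <- Frefs[[if (length(Frefs) > 1L)
      c("A", "B")[particles$half_set[i] + 1L] else 1L]]
    refF <- fftInv(Fref * reg)
    sv <- fftInv(fft(subvols[[i]]) * reg)
    svm <- sum(sv * w) / sw
    svc <- sv - svm
    # orientation search operates on content de-shifted by the current
    # translational estimate (zero on the first pass)
    shift0 <- as.numeric(crossprod(RX, c(particles$sx_nm[i],
                                         particles$sy_nm[i],
                                         particles$sz_nm[i]))) / voxelSize
    svo <- if (any(abs(shift0) > 0.05))
      .cppResample(svc, d, diag(3), shift0, 0) else svc
    saa <- sum(svo * svo * w)
    if (saa == 0) next
    svow <- svo * w

    cand <- grid
    if (!is.null(inPlanePre)) {
      pre <- seq(-inPlanePre[1], inPlanePre[1], by = inPlanePre[2])
      cand <- rbind(cbind(0, 0, pre[order(abs(pre), pre)]), grid)
    }
    best <- list(score = -Inf, dR = dR0, rb = NULL)
    for (ci in seq_len(nrow(cand))) {
      dR <- dR0 %*% eulerToMatrix(cand[ci, 1], cand[ci, 2], cand[ci, 3])
      rb <- .cppResample(refF, dim(refF), t(dR), c(0, 0, 0), 0)
      sc <- weightedScore(svo, rb, w, saa, sw, aw = svow)
      if (sc > best$score + 1e-12) best <- list(score = sc, dR = dR, rb = rb)
    }

    # translational search at the best orientation (absolute, within the
    # shift window around the current estimate)
    shift <- shift0
    if (params@shiftRange > 0) {
      rbw <- best$rb * w
      cc <- Re(fft(fft(svc * w) * Conj(fft(rbw - sum(rbw) / length(rbw))),
                   inverse = TRUE))
      off <- lapply(d, function(n) {
        k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[1:n]
      })
      allow <- array(FALSE, d)
      ax <- abs(off[[1]] - shift0[1]) <= shiftVox
      ay <- abs(off[[2]] - shift0[2]) <= shiftVox
      az <- abs(off[[3]] - shift0[3]) <= shiftVox
      allow[ax, ay, az] <- TRUE
      cc[!allow] <- -Inf
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      shift <- c(off[[1]][pk[1]], off[[2]][pk[2]], off[[3]][pk[3]])
      # parabolic sub-voxel refinement per axis
      for (ax3 in 1:3) {
        idx <- pk
        get <- function(delta) {
          j <- idx
          j[ax3] <- ((j[ax3] - 1 + delta) %% d[ax3]) + 1
          cc[j[1], j[2], j[3]]
        }
        y0 <- get(-1); y1 <- get(0); y2 <- get(1)
        if (is.finite(y0) && is.finite(y2)) {
          den <- y0 - 2 * y1 + y2
          if (den < 0) shift[ax3] <- shift[ax3] + 0.5 * (y0 - y2) / den
        }
      }
      # rescore with the shift applied
      rbs <- .cppResample(best$rb, d, diag(3), -shift, 0)
      saa2 <- sum(svc * svc * w)
      sc <- weightedScore(svc, rbs, w, saa2, sw)
      if (sc >= best$score - 0.02) best$score <- sc else shift <- shift0
    }

    Rnew <- RX %*% best$dR
    eul <- matrixToEuler(Rnew)
    stom <- RX %*% (shift * voxelSize)
    particles$rot_deg[i] <- eul[["rot"]]
    particles$tilt_deg[i] <- eul[["tilt"]]
    particles$psi_deg[i] <- eul[["psi"]]
    particles$sx_nm[i] <- stom[1]
    particles$sy_nm[i] <- stom[2]
    particles$sz_nm[i] <- stom[3]
    particles$score[i] <- best$score
  }
  particles
}

#' Refine one particle against a reference
#'
#' Convenience wrapper around [alignParticles()] for a single particle;
#' with zero search ranges the particle is returned unchanged with its
#' score recorded.
#'
#' @inheritParams alignParticles
#' @param subvol one sub-volume.
#' @param particle one-row particle data.frame.
#' @return the refined one-row particle data.frame.
#' @export
alignParticle <- function(subvol, reference, particle, params,
                          thetaRange = c(-60, 60), voxelSize = 1,
                          mask = NULL) {
  alignParticles(particle, list(subvol), reference, params,
                 thetaRange = thetaRange, voxelSize = voxelSize, mask = mask)
}

# Rotate a stored sub-volume (extracted at pose RX) into the reference
# frame of its refined pose R, applying the refined shift.
alignedSubvol <- function(sv, particle, voxelSize) {
  RX <- eulerToMatrix(particle$rot_x, particle$tilt_x, particle$psi_x)
  R <- eulerToMatrix(particle$rot_deg, particle$tilt_deg, particle$psi_deg)
  Q <- crossprod(RX, R)
  t <- crossprod(RX, c(particle$sx_nm, particle$sy_nm, particle$sz_nm)) /
    voxelSize
  .cppResample(sv, dim(sv), Q, as.numeric(t), mean(sv))
}

#' Wedge-weighted average of aligned particles
#'
#' Each sub-volume is rotated to the reference frame at its refined pose,
#' its Fourier transform accumulated, and the sum divided by the
#' accumulated rotated wedge coverage with a small-constant floor (1% of
#' the maximum coverage). Per-half-set maps are built from the half_set
#' labels.
#'
#' @param particles particle data.frame.
#' @param subvols list of sub-volume arrays.
#' @param thetaRange acquisition tilt range, degrees.
#' @param voxelSize sub-volume voxel size, nm.
#' @param coverageFloor floor as a fraction of the maximum coverage.
#' @return An [AverageMap-class].
#' @export
averageParticles <- function(particles, subvols, thetaRange = c(-60, 60),
                             voxelSize = 1, coverageFloor = 0.01) {
  n <- nrow(particles)
  if (n < 1L) stop("empty-set: no particles to average")
  d <- dim(subvols[[1]])
  num <- list(array(0 + 0i, d), array(0 + 0i, d))
  cov <- list(array(0, d), array(0, d))
  for (i in seq_len(n)) {
    al <- alignedSubvol(subvols[[i]], particles[i, ], voxelSize)
    R <- eulerToMatrix(particles$rot_deg[i], particles$tilt_deg[i],
                       particles$psi_deg[i])
    reg <- wedgeRegion(d, thetaRange[1], thetaRange[2], R = R)
    h <- particles$half_set[i] + 1L
    num[[h]] <- num[[h]] + fft(al) * reg
    cov[[h]] <- cov[[h]] + reg
  }
  divide <- function(nm, cv) {
    if (max(cv) == 0) return(array(0, d))
    fftInv(nm / pmax(cv, coverageFloor * max(cv)))
  }
  halfA <- divide(num[[1]], cov[[1]])
  halfB <- divide(num[[2]], cov[[2]])
  covAll <- cov[[1]] + cov[[2]]
  full <- divide(num[[1]] + num[[2]], covAll)
  new("AverageMap", data = full, voxelSize = voxelSize,
      origin = -(d - 1) / 2 * voxelSize, nParticles = as.integer(n),
      halfA = halfA, halfB = halfB, coverage = covAll)
}

#' Iterative alignment and averaging
#'
#' Alternates [alignParticles()] and [averageParticles()]; from the second
#' iteration on, the two half-sets are refined against their own half-maps
#' (gold standard). The starting reference is either supplied (e.g. a
#' rasterized ground-truth blade) or data-derived (the average at the
#' initial poses), in which case a coarse in-plane scan precedes the first
#' local search.
#'
#' @param particles particle data.frame.
#' @param subvols list of sub-volume arrays.
#' @param params an [AlignmentParams-class].
#' @param reference0 starting reference volume, or NULL for data-derived.
#' @param thetaRange acquisition tilt range, degrees.
#' @param voxelSize voxel size, nm.
#' @param mask optional soft real-space alignment mask.
#' @param inPlanePre coarse psi scan c(range, step) used when reference0
#'   is data-derived (or forced by the caller).
#' @return list(average = [AverageMap-class], particles = refined table,
#'   meanScore = per-iteration mean score).
#' @export
runAlignment <- function(particles, subvols, params, reference0 = NULL,
                         thetaRange = c(-60, 60), voxelSize = 1, mask = NULL,
                         inPlanePre = NULL, goldStandard = TRUE) {
  if (params@nIterations < 1L) stop("invalid-argument: nIterations >= 1")
  dataDerived <- is.null(reference0)
  if (dataDerived) {
    reference0 <- averageParticles(particles, subvols, thetaRange, voxelSize)
    if (is.null(inPlanePre)) inPlanePre <- c(180, 4)
  }
  ref <- reference0
  meanScore <- numeric(0)
  for (it in seq_len(params@nIterations)) {
    refArg <- if (goldStandard && it >= 2L && is(ref, "AverageMap"))
      list(A = ref@halfA, B = ref@halfB) else if (is(ref, "AverageMap"))
      ref@data else ref
    particles <- alignParticles(particles, subvols, refArg, params,
                                thetaRange = thetaRange,
                                voxelSize = voxelSize, mask = mask,
                                inPlanePre = if (it == 1L) inPlanePre)
    meanScore <- c(meanScore, mean(particles$score, na.rm = TRUE))
    ref <- averageParticles(particles, subvols, thetaRange, voxelSize)
  }
  list(average = ref, particles = particles, meanScore = meanScore)
}

#' Gold-standard Fourier shell correlation
#'
#' Shell-wise normalized correlation of two (masked) half-maps.
#'
#' @param halfA,halfB half-maps (arrays or volumes) of equal size.
#' @param mask optional soft real-space mask.
#' @param voxelSize voxel size, nm.
#' @return An [FSCCurve-class]; query with [resolutionAt()].
#' @export
computeFSC <- function(halfA, halfB, mask = NULL, voxelSize = 1) {
  a <- asArray(halfA)
  b <- asArray(halfB)
  if (!identical(dim(a), dim(b))) stop("invalid-argument: unequal boxes")
  d <- dim(a)
  if (min(d) < 8L) stop("invalid-argument: box too small for FSC")
  if (!is.null(mask)) {
    a <- a * mask
    b <- b * mask
  }
  FA <- fft(a)
  FB <- fft(b)
  fr <- freqRadius(d, voxelSize)
  dshell <- 1 / (min(d) * voxelSize)
  shell <- pmin(floor(fr / dshell), floor(min(d) / 2)) + 1L
  nS <- floor(min(d) / 2)
  num <- rowsum(Re(Conj(as.vector(FA)) * as.vector(FB)), as.vector(shell))
  pa <- rowsum(Mod(as.vector(FA))^2, as.vector(shell))
  pb <- rowsum(Mod(as.vector(FB))^2, as.vector(shell))
  cnt <- rowsum(rep(1, length(shell)), as.vector(shell))
  keep <- as.integer(rownames(num)) <= nS
  fsc <- as.numeric(num[keep] / sqrt(pa[keep] * pb[keep]))
  fsc[!is.finite(fsc)] <- 0
  new("FSCCurve", freq = (as.integer(rownames(num))[keep] - 0.5) * dshell,
      fsc = fsc, nvox = as.numeric(cnt[keep]))
}

#' Detect the axial period of a microtubule-binding decoration
#'
#' Subtracts the scaled tubulin-only model from an average built from
#' 5-heterodimer (40 nm) boxes, integrates the positive residual per axial
#' slice, and evaluates the (biased) autocorrelation of that profile at
#' the candidate periods; the candidate maximizing it is returned. The
#' biased normalization makes the fundamental period win over its
#' harmonics.
#'
#' @param average an [AverageMap-class] (or volume) from 40 nm boxes.
#' @param tubulinModel the decoration-free tubule density in the same
#'   frame (array or volume).
#' @param candidatePeriods candidate periods, nm.
#' @param voxelSize voxel size, nm.
#' @param margin axial margin excluded at both box ends, nm.
#' @param wallExclude radial band (nm from the tubule axis) excised from
#'   the residual - the tubule wall, whose subtraction residues carry the
#'   intrinsic 4 nm monomer period; NULL disables.
#' @return the winning period, nm.
#' @export
decorationPeriodicity <- function(average, tubulinModel,
                                  candidatePeriods = c(4, 8, 16, 24),
                                  voxelSize = NULL, margin = 2,
                                  wallExclude = c(10.4, 15.2)) {
  if (is(average, "DensityVolume") && is.null(voxelSize))
    voxelSize <- average@voxelSize
  a <- asArray(average)
  ref <- asArray(tubulinModel)
  beta <- sum(a * ref) / sum(ref * ref)
  res <- pmax(a - beta * ref, 0)
  # mask out the tubulin wall band: imperfect subtraction leaves residues
  # on the wall that carry the intrinsic 4 nm monomer period; decorations
  # sit off the wall (lumenal MIPs inward, appendages outward)
  if (!is.null(wallExclude)) {
    d0 <- dim(a)
    cx <- (d0[1] - 1) / 2
    cy <- (d0[2] - 1) / 2
    xs <- ((seq_len(d0[1]) - 1) - cx) * voxelSize
    ys <- ((seq_len(d0[2]) - 1) - cy) * voxelSize
    rr <- sqrt(outer(xs^2, ys^2, "+"))
    inBand <- rr >= wallExclude[1] & rr <= wallExclude[2]
    res[array(inBand, d0)] <- 0
  }
  d <- dim(a)
  mVox <- ceiling(margin / voxelSize)
  zidx <- (1 + mVox):(d[3] - mVox)
  p <- apply(res[, , zidx], 3, sum)
  p <- p - mean(p)
  if (sd(p) < 1e-9 * max(abs(asArray(average))))
    stop("ambiguous-period: no residual decoration density")
  z <- (zidx - 1) * voxelSize
  fine <- seq(min(z), max(z), by = 0.25)
  pf <- stats::approx(z, p, fine)$y
  score <- vapply(candidatePeriods, function(per) {
    lag <- round(per / 0.25)
    if (lag >= length(pf)) return(-Inf)
    n <- length(pf)
    sum(pf[1:(n - lag)] * pf[(lag + 1):n]) / n / stats::var(pf)
  }, 0)
  if (max(score) - min(score) < 1e-6)
    stop("ambiguous-period: all candidates tie")
  candidatePeriods[which.max(score)]
}

#' Count protofilaments on an annulus of an average map
#'
#' Averages the density over the central 24 nm axially, samples the
#' annulus as a function of angle (the maximum over radius per angle),
#' smooths circularly with a kernel narrower than half the expected peak
#' spacing, thresholds at mid-range and counts the above-threshold runs.
#'
#' @param average an [AverageMap-class] or [DensityVolume-class].
#' @param tubuleCenter 2-D centre of the tubule in the map cross-section,
#'   nm (relative to the box centre).
#' @param annulus c(r_lo, r_hi), nm, containing the tubule wall.
#' @param arc optional angular window c(lo, hi) degrees (for partial
#'   tubules); counting is then non-cyclic within the window.
#' @param smoothDeg circular Gaussian smoothing SD, degrees.
#' @param axialWindow axial extent averaged, nm.
#' @return integer protofilament count.
#' @export
countProtofilaments <- function(average, tubuleCenter, annulus, arc = NULL,
                                smoothDeg = 4, axialWindow = 24) {
  if (annulus[2] <= annulus[1]) stop("invalid-argument: empty annulus")
  vox <- voxelSize(average)
  v <- asArray(average)
  d <- dim(v)
  nz <- round(axialWindow / vox / 2)
  zc <- (d[3] + 1) / 2
  zidx <- max(1, ceiling(zc - nz)):min(d[3], floor(zc + nz))
  m2 <- apply(v[, , zidx, drop = FALSE], c(1, 2), mean)
  ang <- 0:359
  rr <- seq(annulus[1], annulus[2], by = vox / 3)
  cx <- (d[1] - 1) / 2 + tubuleCenter[1] / vox
  cy <- (d[2] - 1) / 2 + tubuleCenter[2] / vox
  prof <- vapply(ang, function(a) {
    xs <- cx + rr * cos(deg2rad(a)) / vox
    ys <- cy + rr * sin(deg2rad(a)) / vox
    vals <- .cppSample(array(m2, c(d[1], d[2], 1)),
                       cbind(xs, ys, 0), min(m2))
    max(vals)
  }, 0)
  # circular Gaussian smoothing
  k <- exp(-0.5 * (pmin(0:359, 360 - 0:359) / smoothDeg)^2)
  k <- k / sum(k)
  n <- 360L
  sm <- vapply(seq_len(n), function(i)
    sum(prof[((i - 1 + 0:(n - 1)) %% n) + 1] * k), 0)
  if (!is.null(arc)) {
    lo <- arc[1] %% 360
    hi <- arc[2] %% 360
    inArc <- if (lo <= hi) ang >= lo & ang <= hi else ang >= lo | ang <= hi
  } else inArc <- rep(TRUE, n)
  sel <- sm[inArc]
  if (max(sel) - min(sel) < 1e-6 * max(abs(sel), 1e-12)) return(0L)
  # peak = cyclic local maximum with sufficient prominence over its two
  # flanking minima; wall peak heights vary severalfold (shared-wall
  # junctions carry double density), so an absolute threshold is avoided
  prev <- sm[c(n, 1:(n - 1))]
  nxt <- sm[c(2:n, 1)]
  maxPos <- which(sm >= prev & sm > nxt)
  minPos <- which(sm <= prev & sm < nxt)
  if (!length(maxPos) || !length(minPos)) return(0L)
  scale <- quantile(sel, 0.95) - quantile(sel, 0.05)
  promOK <- vapply(maxPos, function(i) {
    lower <- minPos[minPos < i]
    upper <- minPos[minPos > i]
    left <- if (length(lower)) max(lower) else max(minPos)   # cyclic
    right <- if (length(upper)) min(upper) else min(minPos)
    sm[i] - max(sm[left], sm[right]) > 0.10 * scale
  }, TRUE)
  peakAng <- ang[maxPos[promOK & inArc[maxPos]]]
  if (!length(peakAng)) return(0L)
  # merge maxima closer than 8 degrees (flat-top duplicates)
  peakAng <- sort(peakAng)
  gaps <- diff(c(peakAng, peakAng[1] + 360))
  as.integer(sum(gaps >= 8))
}

#' Wall annuli and arcs of a blade model
#'
#' Geometry needed to count protofilaments per tubule on an average
#' aligned to this blade's frame: the tubule centre, a radial annulus
#' around the wall, and (for incomplete tubules) the angular window of the
#' present protofilaments.
#'
#' @param bm a [BladeModel-class].
#' @param halfWidth annulus half-width, nm.
#' @return named list per tubule: list(center, annulus, arc).
#' @export
bladeAnnuli <- function(bm, halfWidth = 2) {
  out <- list()
  for (tb in bm@spec@tubules) {
    lab <- tb@label
    r <- tb@lattice@tubuleRadius
    ann <- c(r - halfWidth, r + halfWidth)
    arc <- NULL
    full <- lab == "A" && length(tb@presentPfs) == tb@lattice@nPf
    if (!full) {
      a <- bm@pfAngles[[lab]][tb@presentPfs]
      # angles run monotonically along the pf ordering; pad half the
      # inter-pf spacing on each side
      spacing <- if (length(a) > 1L) abs(a[2] - a[1]) else
        360 / tb@lattice@nPf
      lo <- min(a[1], a[length(a)]) - spacing / 2
      hi <- max(a[1], a[length(a)]) + spacing / 2
      arc <- c(lo %% 360, (lo %% 360) + (hi - lo))
    }
    out[[lab]] <- list(center = bm@centers[[lab]], annulus = ann, arc = arc)
  }
  out
}
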