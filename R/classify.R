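# Axial binning, proximal/distal splitting and masked hard-assignment
# classification without alignment.

#' Axial-position block averages
#'
#' Groups particles by axial position into half-open bins [lo, hi) and
#' builds one wedge-weighted average per non-empty bin.
#'
#' @param particles particle data.frame (with s_nm).
#' @param subvols list of sub-volume arrays.
#' @param binEdges strictly increasing bin edges, nm.
#' @param thetaRange,voxelSize as in [averageParticles()].
#' @return list with one entry per bin: the [AverageMap-class], or NULL
#'   for an empty bin; names give the bin intervals.
#' @export
axialBinAverage <- function(particles, subvols, binEdges,
                            thetaRange = c(-60, 60), voxelSize = 1) {
  if (is.unsorted(binEdges, strictly = TRUE))
    stop("invalid-argument: bin edges must be strictly increasing")
  nb <- length(binEdges) - 1L
  out <- vector("list", nb)
  names(out) <- sprintf("[%g,%g)", binEdges[-(nb + 1L)], binEdges[-1])
  for (b in seq_len(nb)) {
    sel <- particles$s_nm >= binEdges[b] & particles$s_nm < binEdges[b + 1L]
    if (!any(sel)) next
    out[[b]] <- averageParticles(particles[sel, , drop = FALSE],
                                 subvols[sel], thetaRange, voxelSize)
  }
  out
}

#' Split particles at the proximal/distal boundary
#'
#' @param particles particle data.frame.
#' @param boundary axial boundary, nm (default 200); s < boundary is
#'   proximal, s >= boundary distal.
#' @return list(proximal, distal) particle data.frames.
#' @export
splitProximalDistal <- function(particles, boundary = 200) {
  prox <- particles$s_nm < boundary
  list(proximal = particles[prox, , drop = FALSE],
       distal = particles[!prox, , drop = FALSE])
}

# Wedge-filled masked voxel matrix for PCA initialization: missing-wedge
# Fourier voxels are replaced by the global-average values so the wedge
# orientation cannot drive the clustering.
wedgeFilledMatrix <- function(particles, subvols, mask, globalAvg,
                              thetaRange, voxelSize) {
  d <- dim(subvols[[1]])
  Fg <- fft(asArray(globalAvg))
  sel <- which(mask > 0.05)
  t(vapply(seq_len(nrow(particles)), function(i) {
    al <- alignedSubvol(subvols[[i]], particles[i, ], voxelSize)
    R <- eulerToMatrix(particles$rot_deg[i], particles$tilt_deg[i],
                       particles$psi_deg[i])
    reg <- wedgeRegion(d, thetaRange[1], thetaRange[2], R = R)
    filled <- fftInv(fft(al) * reg + Fg * !reg)
    (filled * mask)[sel]
  }, numeric(length(sel))))
}

#' Masked hard-assignment classification without alignment
#'
#' Initializes by k-means on the top principal components of wedge-filled
#' masked voxel vectors, then iterates rebuild-averages / reassign-each-
#' particle-to-the-class-maximizing-the-masked-constrained-CC for up to
#' `nRounds` rounds, stopping when the assignments no longer change. A
#' class that empties is re-seeded from the particle most dissimilar to
#' its current class average (logged in the report). Deterministic given
#' the seed.
#'
#' @param particles particle data.frame (orientations fixed).
#' @param subvols list of sub-volume arrays.
#' @param mask soft real-space mask over the region of interest.
#' @param k number of classes.
#' @param nRounds maximum reassignment rounds (default 100).
#' @param seed integer seed.
#' @param thetaRange,voxelSize acquisition and sampling parameters.
#' @param lowpass classification low-pass, nm.
#' @return list(k, assignments, averages, report, converged).
#' @export
maskedClassify <- function(particles, subvols, mask, k, nRounds = 100,
                           seed = 1, thetaRange = c(-60, 60), voxelSize = 1,
                           lowpass = NULL) {
  n <- nrow(particles)
  if (k < 1L) stop("invalid-argument: k must be >= 1")
  if (k > n) stop("invalid-argument: k exceeds particle count")
  d <- dim(subvols[[1]])
  if (k == 1L) {
    avg <- averageParticles(particles, subvols, thetaRange, voxelSize)
    return(list(k = 1L, assignments = rep(1L, n), averages = list(avg),
                report = data.frame(round = 0L, meanCC = NA_real_,
                                    sizes = n), converged = TRUE))
  }
  globalAvg <- averageParticles(particles, subvols, thetaRange, voxelSize)
  X <- wedgeFilledMatrix(particles, subvols, mask, globalAvg, thetaRange,
                         voxelSize)
  npc <- min(10L, n - 1L, ncol(X))
  pcs <- prcomp(X, center = TRUE, rank. = npc)$x
  set.seed(seed)
  assign <- tryCatch(kmeans(pcs, centers = k, nstart = 10)$cluster,
                     error = function(e) rep_len(seq_len(k), n))

  lp <- lowpassMask(d, voxelSize, lowpass)
  alignedF <- lapply(seq_len(n), function(i)
    fft(alignedSubvol(subvols[[i]], particles[i, ], voxelSize) * mask))
  regs <- lapply(seq_len(n), function(i) {
    R <- eulerToMatrix(particles$rot_deg[i], particles$tilt_deg[i],
                       particles$psi_deg[i])
    r <- wedgeRegion(d, thetaRange[1], thetaRange[2], R = R) & lp
    r[1, 1, 1] <- FALSE
    r
  })

  classAvg <- function(assign) {
    lapply(seq_len(k), function(cl) {
      sel <- which(assign == cl)
      if (!length(sel)) return(NULL)
      averageParticles(particles[sel, , drop = FALSE], subvols[sel],
                       thetaRange, voxelSize)
    })
  }
  report <- list()
  converged <- FALSE
  for (round in seq_len(nRounds)) {
    avgs <- classAvg(assign)
    reseeded <- FALSE
    for (cl in seq_len(k)) {
      if (!is.null(avgs[[cl]])) next
      # empty class: re-seed from the particle most dissimilar to its own
      # class average
      sc <- vapply(seq_len(n), function(i) {
        FB <- fft(asArray(avgs[[assign[i]]]) * mask)
        r <- regs[[i]]
        num <- sum(Re(Conj(alignedF[[i]][r]) * FB[r]))
        num / sqrt(sum(Mod(alignedF[[i]][r])^2) * sum(Mod(FB[r])^2))
      }, 0)
      worst <- which.min(sc)
      message("maskedClassify: class ", cl, " emptied; re-seeded from ",
              "particle ", worst)
      assign[worst] <- cl
      avgs <- classAvg(assign)
      reseeded <- TRUE
    }
    FBs <- lapply(avgs, function(a) fft(asArray(a) * mask))
    newAssign <- integer(n)
    ccBest <- numeric(n)
    for (i in seq_len(n)) {
      r <- regs[[i]]
      FA <- alignedF[[i]][r]
      na2 <- sum(Mod(FA)^2)
      sc <- vapply(seq_len(k), function(cl) {
        FB <- FBs[[cl]][r]
        sum(Re(Conj(FA) * FB)) / sqrt(na2 * sum(Mod(FB)^2))
      }, 0)
      newAssign[i] <- which.max(sc)
      ccBest[i] <- max(sc)
    }
    report[[round]] <- data.frame(round = round, meanCC = mean(ccBest),
                                  sizes = paste(tabulate(newAssign, k),
                                                collapse = "/"))
    if (!reseeded && identical(newAssign, assign)) {
      converged <- TRUE
      assign <- newAssign
      break
    }
    assign <- newAssign
  }
  list(k = as.integer(k), assignments = assign, averages = classAvg(assign),
       report = do.call(rbind, report), converged = converged)
}

#' Select the class with extreme masked density
#'
#' Picks the class whose average has the minimum (or maximum) mean density
#' within the mask - e.g. the incomplete-B-tubule class under a mask over
#' protofilaments B03-B06. When the class densities are indistinguishable
#' (within the between-class spread expected from noise) the selection is
#' flagged low-confidence.
#'
#' @param model result of [maskedClassify()].
#' @param mask the mask used for the density criterion.
#' @param criterion "min_mask_density" or "max_mask_density".
#' @return list(class, particles = indices, average, maskDensities,
#'   lowConfidence).
#' @export
selectClass <- function(model, mask,
                        criterion = c("min_mask_density",
                                      "max_mask_density")) {
  criterion <- match.arg(criterion)
  dens <- vapply(model$averages, function(a)
    if (is.null(a)) NA_real_ else
      sum(asArray(a) * mask) / sum(mask), 0)
  pick <- if (criterion == "min_mask_density") which.min(dens)
          else which.max(dens)
  spread <- diff(range(dens, na.rm = TRUE))
  scale <- max(abs(dens), na.rm = TRUE)
  lowConf <- is.finite(scale) && scale > 0 && spread < 0.1 * scale
  list(class = as.integer(pick),
       particles = which(model$assignments == pick),
       average = model$averages[[pick]], maskDensities = dens,
       lowConfidence = lowConf)
}
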