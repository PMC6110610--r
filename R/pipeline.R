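# End-to-end pipeline orchestration: simulate -> pick -> align -> classify
# -> geometry -> report, from a single config with named seeds.

#' Default run configuration
#'
#' @param preset preset name ("cho" or "s2").
#' @param flatten flattening factor e.
#' @param snr tilt-series signal-to-noise variance ratio.
#' @param seeds named integer seeds (model, noise, halves, classify).
#' @param segmentStep segment step, nm.
#' @param tomoVoxel tomogram voxel size, nm.
#' @param subvolBox sub-volume box, voxels (at tomoVoxel).
#' @param pickMode "from_truth" or "auto".
#' @param binEdges axial bin edges for block averages, nm.
#' @param alignParams an [AlignmentParams-class].
#' @param outDir output directory, or NULL to keep results in memory only.
#' @return a validated config list.
#' @export
pipelineConfig <- function(preset = "cho", flatten = 0, snr = 0.5,
                           seeds = list(model = 1L, noise = 2L,
                                        halves = 3L, classify = 4L),
                           segmentStep = 24, tomoVoxel = 2, subvolBox = 44,
                           pickMode = "from_truth",
                           binEdges = NULL,
                           alignParams = AlignmentParams(
                             angularRange = 4, angularStep = 2,
                             shiftRange = 4, shiftStep = 1, lowpass = 5,
                             nIterations = 2L),
                           outDir = NULL, length = NULL, classifyK = NULL) {
  if (!preset %in% c("cho", "s2"))
    stop("config error: unknown preset '", preset, "'")
  if (!all(c("model", "noise", "halves") %in% names(seeds)))
    stop("config error: seeds must name model, noise, halves")
  if (is.null(binEdges))
    binEdges <- if (preset == "cho") seq(0, 400, by = 100) else c(0, 88, 176)
  list(preset = preset, flatten = flatten, snr = snr,
       seeds = lapply(seeds, as.integer), segmentStep = segmentStep,
       tomoVoxel = tomoVoxel, subvolBox = subvolBox, pickMode = pickMode,
       binEdges = binEdges, alignParams = alignParams, outDir = outDir,
       length = length, classifyK = classifyK)
}

#' Soft spherical mask over a named decoration of a blade model
#'
#' Centres a soft sphere on the centroid of the decoration's blobs in the
#' blade frame - e.g. the pinhead region used for masked domain
#' classification.
#'
#' @param bm a [BladeModel-class] carrying the decoration.
#' @param part decoration name (e.g. "pinhead").
#' @param dim box dimensions, voxels.
#' @param voxelSize voxel size, nm.
#' @param radius mask radius, nm.
#' @return numeric array mask in [0, 1].
#' @export
decorationMask <- function(bm, part, dim, voxelSize, radius = 6) {
  b <- bm@blobs[bm@blobs$part == part, ]
  if (!nrow(b)) stop("invalid-argument: blade has no '", part, "' blobs")
  cen <- c(mean(b$x), mean(b$y), 0) / voxelSize
  m <- softSphereMask(dim, radius / voxelSize)
  .cppResample(m, as.integer(dim), diag(3), -cen, 0)
}

#' Read a run configuration from YAML (or JSON-style YAML)
#'
#' @param path config file.
#' @return config list (see [pipelineConfig()]).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  ap <- if (!is.null(y$align)) do.call(AlignmentParams, y$align)
        else AlignmentParams(angularRange = 4, angularStep = 2,
                             shiftRange = 4, shiftStep = 1, lowpass = 5,
                             nIterations = 2L)
  pipelineConfig(preset = y$preset %||% "cho",
                 flatten = y$flatten %||% 0,
                 snr = y$snr %||% 0.5,
                 seeds = y$seeds %||% list(model = 1L, noise = 2L,
                                           halves = 3L, classify = 4L),
                 segmentStep = y$segment_step %||% 24,
                 tomoVoxel = y$tomo_voxel %||% 2,
                 subvolBox = y$subvol_box %||% 44,
                 pickMode = y$pick_mode %||% "from_truth",
                 binEdges = y$bin_edges,
                 alignParams = ap,
                 outDir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Simulates a centriole tomogram at the configured preset, flattening and
#' SNR, traces rods and extracts segments, aligns and averages them
#' (ground-truth blade reference, independent half-sets), builds axial
#' block and proximal/distal domain averages, refits poses into a
#' cross-section, quantifies flattening by ellipse fit, symmetrizes each
#' domain with the preset geometry and measures ensemble diameter and
#' blade-tilt change. All randomness flows from the named seeds;
#' re-running a config reproduces the tables.
#'
#' @param config a config list from [pipelineConfig()] / [readRunConfig()].
#' @return a run-report list; intermediates are written under
#'   `config$outDir` when set.
#' @export
runPipeline <- function(config) {
  cfg <- config
  preset <- getPreset(cfg$preset)
  if (!is.null(cfg$length)) {   # desk-scale stub override
    preset@length <- cfg$length
    preset@domainBoundary <- min(preset@domainBoundary, cfg$length / 2)
  }
  out <- cfg$outDir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  persist <- function(obj, name, writer) {
    if (!is.null(out)) writer(obj, file.path(out, name))
    obj
  }

  ## simulate
  model <- assembleCentriole(preset, FlatteningSpec(cfg$flatten),
                             seed = cfg$seeds$model,
                             segmentStep = cfg$segmentStep)
  truth <- groundTruth(model)
  persist(truth, "ground_truth.tsv", writeGroundTruth)
  ext <- 2 * max(abs(c(truth$x_nm, truth$z_nm))) + 90
  nxz <- 2L * ceiling(ext / cfg$tomoVoxel / 2)
  ny <- 2L * ceiling((preset@length + 40) / cfg$tomoVoxel / 2)
  vol <- rasterize(model, cfg$tomoVoxel, box = c(nxz, ny, nxz))
  series <- projectTiltSeries(vol)
  if (is.finite(cfg$snr)) series <- addNoise(series, cfg$snr,
                                             seed = cfg$seeds$noise)
  tomo <- reconstructWBP(series)
  if (!is.null(out)) {
    writeMRC(tomo, file.path(out, "tomogram.mrc"))
    writeTlt(series, file.path(out, "angles.tlt"))
  }

  ## pick
  rods <- traceRods(tomo, mode = cfg$pickMode, truth = truth)
  particles <- sampleParticles(rods, step = cfg$segmentStep,
                               seed = cfg$seeds$halves)
  # axial position measured from the proximal end of the traced rod
  subvols <- lapply(seq_len(nrow(particles)), function(i)
    extractSubvolume(tomo,
                     c(particles$x_nm[i], particles$y_nm[i],
                       particles$z_nm[i]),
                     c(particles$rot_deg[i], particles$tilt_deg[i],
                       particles$psi_deg[i]),
                     box = cfg$subvolBox)@data)
  persist(particles, "particles_initial.tsv", writeParticlesTSV)

  ## align (reference: rasterized ground-truth blade of the first domain)
  domains <- if (cfg$preset == "s2") "fly" else c("proximal", "distal")
  bladeRef <- function(domain) {
    tilt <- if (domain == "distal") preset@bladeTiltDistal
            else preset@bladeTiltProximal
    bm <- buildBlade(bladeSpecForPreset(preset, domain), 48, tilt = tilt,
                     seed = cfg$seeds$model)
    # linker arms reaching toward the neighbouring blade fall outside the
    # single-blade reference box by construction
    suppressWarnings(rasterize(bm, cfg$tomoVoxel,
                               box = rep(cfg$subvolBox, 3)))
  }
  mask <- softCylMask(rep(cfg$subvolBox, 3),
                      radius = cfg$subvolBox / 2 - 2,
                      hz = cfg$segmentStep / cfg$tomoVoxel / 2 + 2)
  refs <- lapply(stats::setNames(domains, domains), bladeRef)
  aligned <- particles
  flatSlack <- 2 * atan(1 - 1 / (1 + cfg$flatten)^2) * 45 / atan(1) + 8
  run1 <- runAlignment(particles, subvols, cfg$alignParams,
                       reference0 = refs[[1]], voxelSize = cfg$tomoVoxel,
                       mask = mask, inPlanePre = c(ceiling(flatSlack), 3))
  aligned <- run1$particles
  globalAvg <- run1$average
  if (!is.null(out)) {
    writeMRC(globalAvg, file.path(out, "average_global.mrc"))
    writeParticlesTSV(aligned, file.path(out, "particles_refined.tsv"))
    writeParticlesSTAR(aligned, file.path(out, "particles_refined.star"))
  }
  fsc <- computeFSC(globalAvg@halfA, globalAvg@halfB, mask = mask,
                    voxelSize = cfg$tomoVoxel)
  if (!is.null(out)) writeFSC(fsc, file.path(out, "fsc_global.tsv"))

  ## axial block and domain averages
  binAvgs <- axialBinAverage(aligned, subvols, cfg$binEdges,
                             voxelSize = cfg$tomoVoxel)
  domSplit <- splitProximalDistal(aligned, boundary = preset@domainBoundary)
  domAvg <- list()
  domParts <- list()
  if (cfg$preset == "cho") {
    for (d in c("proximal", "distal")) {
      sel <- if (d == "proximal") aligned$s_nm < preset@domainBoundary
             else aligned$s_nm >= preset@domainBoundary
      p <- alignParticles(aligned[sel, , drop = FALSE], subvols[sel],
                          refs[[d]], cfg$alignParams,
                          voxelSize = cfg$tomoVoxel, mask = mask)
      domParts[[d]] <- p
      domAvg[[d]] <- averageParticles(p, subvols[sel],
                                      voxelSize = cfg$tomoVoxel)
      if (!is.null(out))
        writeMRC(domAvg[[d]], file.path(out, paste0("average_", d, ".mrc")))
    }
  } else {
    domParts$fly <- aligned
    domAvg$fly <- globalAvg
  }

  ## classify (optional): masked hard-assignment classes over the pinhead
  ## region, the discriminative decoration between the two domains
  classification <- NULL
  if (!is.null(cfg$classifyK)) {
    bmP <- buildBlade(bladeSpecForPreset(preset, domains[1]), 24,
                      tilt = preset@bladeTiltProximal,
                      seed = cfg$seeds$model)
    phMask <- decorationMask(bmP, "pinhead", rep(cfg$subvolBox, 3),
                             cfg$tomoVoxel)
    classification <- maskedClassify(aligned, subvols, phMask,
                                     k = cfg$classifyK,
                                     seed = cfg$seeds$classify %||% 4L,
                                     voxelSize = cfg$tomoVoxel,
                                     lowpass = cfg$alignParams@lowpass)
    aligned$class_label <- classification$assignments
    if (!is.null(out)) {
      write.table(classification$report,
                  file.path(out, "classification_report.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      writeParticlesTSV(aligned, file.path(out, "particles_classified.tsv"))
    }
  }

  ## geometry
  cs <- refitPositions(aligned)
  rodMeans <- t(vapply(split(seq_len(nrow(aligned)), aligned$rod_id),
                       function(i) colMeans(cs@points[i, , drop = FALSE]),
                       numeric(2)))
  flatFit <- fitEllipse(rodMeans)
  geom <- list(flattening = flatFit,
               ellipticity_percent = ellipticity(flatFit))
  ensembles <- list()
  nT <- if (cfg$preset == "s2") 2L else 3L
  for (d in names(domAvg)) {
    r <- if (d == "distal") preset@radiusDistal else preset@radiusProximal
    tl <- if (d == "distal") preset@bladeTiltDistal
          else preset@bladeTiltProximal
    ensembles[[d]] <- symmetrize(domAvg[[d]], SymmetryParams(r, tl, d),
                                 nTubules = nT)
    geom[[paste0("diameter_", d, "_nm")]] <- measureDiameter(ensembles[[d]])
    if (!is.null(out))
      writeMRC(ensembles[[d]]@density,
               file.path(out, paste0("ensemble_", d, ".mrc")))
  }
  if (cfg$preset == "cho") {
    geom$tilt_change_deg <- tiltChange(ensembles$proximal,
                                       ensembles$distal)
  } else {
    geom$tilt_fly_deg <- measureBladeTilt(ensembles$fly)
    # A-A linkage: nearest-neighbour gap between adjacent doublets in the
    # symmetrized ensemble (no C-tubule metrics for the doublet preset)
    geom$aa_linkage_gap_nm <- aaLinkageGap(ensembles$fly)
  }

  report <- list(
    version = as.character(utils::packageVersion("centriotome")),
    config = cfg[setdiff(names(cfg), "alignParams")],
    n_particles = nrow(aligned),
    n_rods = length(rods),
    mean_cc = run1$meanScore,
    fsc_resolution_nm = resolutionAt(fsc),
    bin_averages = names(binAvgs),
    bin_counts = vapply(binAvgs, function(a)
      if (is.null(a)) 0L else nParticles(a), 0L),
    n_proximal = nrow(domSplit$proximal), n_distal = nrow(domSplit$distal),
    class_sizes = if (!is.null(classification))
      tabulate(classification$assignments, cfg$classifyK),
    geometry = geom)
  out2 <- list(report = report, model = model, tomogram = tomo,
               particles = aligned, subvols = subvols,
               average = globalAvg, binAverages = binAvgs,
               domainAverages = domAvg, ensembles = ensembles,
               crossSection = cs, fsc = fsc,
               classification = classification)
  if (!is.null(out)) {
    rep2 <- report
    rep2$geometry <- geom[names(geom) != "flattening"]
    yaml::write_yaml(rep2, file.path(out, "report.yaml"))
  }
  out2
}

# Minimum gap between density of adjacent blades at the blade-tip radius:
# a crude A-A linkage closure metric for the doublet ensemble.
aaLinkageGap <- function(ensemble, thresholdFraction = 0.2) {
  v <- asArray(ensemble@density)
  vox <- voxelSize(ensemble@density)
  d <- dim(v)
  m2 <- apply(v, c(1, 3), mean)
  above <- which(m2 > thresholdFraction * max(m2), arr.ind = TRUE)
  x <- (above[, 1] - 1 - (d[1] - 1) / 2) * vox
  z <- (above[, 2] - 1 - (d[3] - 1) / 2) * vox
  az <- rad2deg(atan2(z, x)) %% 40   # fold to one 9-fold sector
  # widest empty azimuthal run in the fold = inter-blade gap angle
  h <- hist(az, breaks = seq(0, 40, by = 1), plot = FALSE)$counts
  r <- rle(h == 0)
  gapDeg <- if (any(r$values)) max(r$lengths[r$values]) else 0
  gapDeg * pi / 180 * ensemble@params@bladeRadius
}

#' Generate deterministic fixture bundles
#'
#' tiny: a 96 nm CHO stub model and simulated 24 nm segments for unit
#' tests (at most 40 particles); standard: full-length CHO and S2 models.
#'
#' @param scale "tiny" or "standard".
#' @param seed integer seed.
#' @return fixture list.
#' @export
makeFixtures <- function(scale = c("tiny", "standard"), seed = 1) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    preset <- choPreset(length = 96, domainBoundary = 48)
    model <- assembleCentriole(preset, seed = seed)
    bm <- buildBlade(bladeSpecForPreset(preset, "proximal"), 24,
                     tilt = preset@bladeTiltProximal, seed = seed)
    seg <- simulateSegments(bm, 12, snr = 1, box = 32, voxelSize = 2,
                            seed = seed)
    list(scale = scale, preset = preset, model = model, blade = bm,
         segments = seg)
  } else {
    list(scale = scale,
         cho = assembleCentriole(choPreset(), seed = seed),
         s2 = assembleCentriole(s2Preset(), seed = subSeed(seed, 2L)))
  }
}
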