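#' Run the full analysis pipeline on a synthetic experiment
#'
#' Simulates a compaction experiment, renders its kymograph, then runs
#' every analysis stage: tracking and classification, diffusion (MSD fit on
#' diffusive trajectories from the extended phase), bleaching-corrected
#' cluster stoichiometry at the post-compaction phase, both footprint
#' estimators (force-distance compaction at 25 pN and flow-box intensity),
#' and the rotation-coupled sliding model. Every numeric output carries its
#' units in its name, and the bundle records the seed and configuration, so
#' the same `(config, seed)` always reproduces the same bundle.
#'
#' @param config an [ExperimentConfig-class].
#' @param optics an [OpticsConfig-class].
#' @param cal a [Calibration-class]; defaults to the 1.5 photons/fluorophore
#'   single-dye calibration.
#' @param seed integer seed controlling all randomness in the run.
#' @param outputDir optional directory; when given, the bundle JSON and CSV
#'   tables are written there.
#' @param nFlowSegments number of bridged segments for the flow-image stage.
#' @param verbose log stage progress to stderr.
#' @return A named list (the result bundle): `meta`, `tracking`,
#'   `diffusion`, `clusters`, `footprints`, `rotationModel`.
#' @export
runPipeline <- function(config = experimentConfig(),
                        optics = opticsConfig(),
                        cal = calibration(1.5),
                        seed = 1L, outputDir = NULL,
                        nFlowSegments = 4L, verbose = TRUE) {
  say <- function(...) if (verbose) message("[KymoQuant] ", ...)
  t0 <- proc.time()[["elapsed"]]
  cfg <- config
  cfg@seed <- as.numeric(subSeed(seed, 1))

  say("simulate: compaction experiment (", cfg@nTetramers, " tetramers)")
  sim <- simulateCompactionExperiment(cfg, linePeriod = optics@linePeriod)
  truth <- sim$truth

  say("render: kymograph")
  kymo <- renderKymograph(truth, optics, seed = subSeed(seed, 2))

  say("track: extended phase")
  extLines <- which(truth@phase == "extended")
  kymoExt <- kymograph(kymo@counts[extLines, , drop = FALSE],
                       pixelSize = kymo@pixelSize,
                       linePeriod = kymo@linePeriod,
                       metadata = kymo@metadata)
  trajs <- trackKymograph(kymoExt, cal = cal)
  trajs <- lapply(trajs, classifyTrajectory)
  classes <- vapply(trajs, classification, character(1))
  stoich <- vapply(trajs, trajectoryStoichiometry, numeric(1), cal = cal)

  say("diffusion: MSD fit on ", sum(classes == "diffusive"),
      " diffusive trajectories")
  diffusive <- trajs[classes == "diffusive"]
  Dfits <- lapply(diffusive, function(tr) {
    ml <- min(10L, length(tr) - 2L)
    if (ml < 4) return(NULL)
    fitDiffusion(msdCurve(tr, maxLag = ml), fitRange = c(2, ml))
  })
  Dfits <- Filter(Negate(is.null), Dfits)
  Dvals <- vapply(Dfits, `[[`, numeric(1), "D")

  say("photometry: cluster sizes")
  postLines <- which(truth@phase == "post")
  tMeasure <- (postLines[min(length(postLines), 50L)] - 1L) * kymo@linePeriod
  clusterTable <- data.frame(position_um = numeric(0),
                             tetramers = numeric(0),
                             amplitude_photons = numeric(0))
  for (a in truth@clusterAnchors) {
    px <- round(a * 1000 / kymo@pixelSize)
    win <- seq.int(max(1, px - 10), min(ncol(kymo@counts), px + 10))
    est <- tryCatch(
      estimateClusterFromKymo(kymo, cal, tMeasure, fitWindow = win,
                              background = optics@backgroundRate),
      error = function(e) NULL)
    if (!is.null(est) && est$fit@converged)
      clusterTable <- rbind(clusterTable,
        data.frame(position_um = est$position, tetramers = est$tetramers,
                   amplitude_photons = est$amplitude))
  }

  say("footprint: force-distance at 25 pN")
  f <- truth@sequesteredPerDomain
  nBound <- sum(!is.na(truth@clusterId))
  nClusters <- max(1L, length(truth@clusterAnchors))
  seqLen_um <- 2 * f * nBound / 1000
  fdFree <- simulateForceDistance(cfg, 0, 0, forceNoiseSd = 0.05,
                                  seed = subSeed(seed, 3))
  fdComp <- simulateForceDistance(cfg, seqLen_um, nClusters,
                                  forceNoiseSd = 0.05,
                                  seed = subSeed(seed, 4))
  fpComp <- footprintFromCompaction(lengthAtForce(fdFree, 25),
                                    lengthAtForce(fdComp, 25),
                                    nClusters, max(1L, nBound),
                                    cfg@persistenceLength)

  say("footprint: flow boxes")
  segs <- data.frame(x0 = 800, x1 = 800 + 3000,
                     y = 1500 + 3000 * (seq_len(nFlowSegments) - 1))
  flow <- simulateFlowImage(segs, footprint = f, optics = optics,
                            seed = subSeed(seed, 5))
  d <- optics@pixelSize
  boxCols <- seq.int(round((800 + 500) / d), round((800 + 2500) / d))
  fpBox <- vapply(seq_len(nFlowSegments), function(i) {
    rowC <- round(segs$y[i] / d)
    res <- analyzeFlowBox(flow$image, optics, boxCols,
                          seq.int(rowC - 6L, rowC + 6L), bgOffset = 12L)
    res$footprint
  }, numeric(1))

  rot <- rotationCoupledD(rotationModelParams())
  trans <- translationalD(rotationModelParams())

  bundle <- list(
    meta = list(package = "KymoQuant",
                version = as.character(utils::packageVersion("KymoQuant")),
                seed = seed,
                nTetramers = as.integer(cfg@nTetramers),
                linePeriod_s = optics@linePeriod,
                pixelSize_nm = optics@pixelSize),
    tracking = list(nTrajectories = length(trajs),
                    nDiffusive = sum(classes == "diffusive"),
                    nStatic = sum(classes == "static"),
                    meanDyesPerTrajectory = if (length(stoich)) mean(stoich)
                                            else NA),
    diffusion = list(D_um2_s = if (length(Dvals)) mean(Dvals) else NA,
                     D_sd = if (length(Dvals) > 1) sd(Dvals) else NA,
                     nTrajectories = length(Dvals)),
    clusters = list(n = nrow(clusterTable),
                    meanTetramers = if (nrow(clusterTable))
                      mean(clusterTable$tetramers) else NA,
                    table = clusterTable),
    footprints = list(
      compaction_nm = fpComp$footprint,
      compactionValid = fpComp$valid,
      flowBox_nm = mean(fpBox, na.rm = TRUE),
      planted_nm = f),
    rotationModel = list(D_rotation_um2_s = rot$D,
                         D_translation_um2_s = trans$D,
                         ratio = trans$D / rot$D,
                         barrierForm = rot$barrierForm))

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    writeResultBundle(bundle, file.path(outputDir, "bundle.json"))
    utils::write.csv(clusterTable,
                     file.path(outputDir, "clusters.csv"),
                     row.names = FALSE)
    writeForceDistance(fdFree, file.path(outputDir, "fd_free.csv"))
    writeForceDistance(fdComp, file.path(outputDir, "fd_compacted.csv"))
    say("wrote bundle to ", outputDir)
  }
  say(sprintf("done in %.1f s", proc.time()[["elapsed"]] - t0))
  bundle
}
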