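#' @include AllGenerics.R
NULL

## Central S4 containers. Units are fixed project-wide: positions and
## bead separations in micrometres, optics lengths (pixel size, PSF width,
## footprints) in nanometres, time in seconds, force in piconewtons,
## intensity in photons.

#' Confocal optics and photophysics configuration
#'
#' Describes the imaging side of the experiment: pixel size along the scan
#' line, the Gaussian point-spread width, the photon yield of one fluorophore,
#' the excitation power, photobleaching kinetics and background.
#'
#' @slot pixelSize pixel size along the DNA axis, nm.
#' @slot psfSd standard deviation of the Gaussian emission profile, nm.
#' @slot photonsPerFluorPerLine expected peak amplitude contributed by one
#'   fluorophore to a single confocal scan line, photons.
#' @slot laserPower excitation power, microwatts.
#' @slot referencePower power at which `bleachRateAtReference` applies, uW.
#' @slot bleachRateAtReference per-fluorophore bleaching rate at the
#'   reference power, 1/s. The realized rate scales as
#'   `(laserPower/referencePower)^2` (two-photon bleaching), while photon
#'   emission scales linearly with power.
#' @slot backgroundRate expected background, photons/pixel/line.
#' @slot linePeriod time per confocal scan line, s.
#' @export
setClass("OpticsConfig", representation(
  pixelSize = "numeric",
  psfSd = "numeric",
  photonsPerFluorPerLine = "numeric",
  laserPower = "numeric",
  referencePower = "numeric",
  bleachRateAtReference = "numeric",
  backgroundRate = "numeric",
  linePeriod = "numeric"
))

setValidity("OpticsConfig", function(object) {
  msg <- character()
  for (sl in c("pixelSize", "psfSd", "photonsPerFluorPerLine", "laserPower",
               "referencePower", "linePeriod")) {
    v <- slot(object, sl)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", sl))
  }
  for (sl in c("bleachRateAtReference", "backgroundRate")) {
    v <- slot(object, sl)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("'%s' must be a single nonnegative number", sl))
  }
  if (length(msg) == 0L && object@psfSd < object@pixelSize / 4)
    msg <- c(msg, "psfSd must be >= pixelSize/4 (profile must be resolvable)")
  if (length(msg)) msg else TRUE
})

#' @param pixelSize,psfSd,photonsPerFluorPerLine,laserPower,referencePower,bleachRateAtReference,backgroundRate,linePeriod
#'   see the corresponding slots.
#' @return `opticsConfig()` returns an [OpticsConfig-class] object.
#' @rdname OpticsConfig-class
#' @examples
#' opt <- opticsConfig()
#' pixelSize(opt)
#' @export
opticsConfig <- function(pixelSize = 75, psfSd = 100,
                         photonsPerFluorPerLine = 1.5,
                         laserPower = 6.4, referencePower = 6.4,
                         bleachRateAtReference = 5e-5,
                         backgroundRate = 0.2, linePeriod = 0.02) {
  new("OpticsConfig", pixelSize = pixelSize, psfSd = psfSd,
      photonsPerFluorPerLine = photonsPerFluorPerLine,
      laserPower = laserPower, referencePower = referencePower,
      bleachRateAtReference = bleachRateAtReference,
      backgroundRate = backgroundRate, linePeriod = linePeriod)
}

#' @rdname OpticsConfig-class
#' @param object an `OpticsConfig`.
#' @export
setMethod("pixelSize", "OpticsConfig", function(object) object@pixelSize)

#' @rdname OpticsConfig-class
#' @export
setMethod("linePeriod", "OpticsConfig", function(object) object@linePeriod)

setMethod("show", "OpticsConfig", function(object) {
  cat("OpticsConfig\n",
      sprintf("  pixel %g nm | PSF sd %g nm | %g photons/fluor/line\n",
              object@pixelSize, object@psfSd, object@photonsPerFluorPerLine),
      sprintf("  power %g uW (ref %g) | bleach %g /s at ref | bg %g ph/px/line | line %g s\n",
              object@laserPower, object@referencePower,
              object@bleachRateAtReference, object@backgroundRate,
              object@linePeriod), sep = "")
})

#' Compaction-experiment configuration
#'
#' Parameters of the pulling protocol and of the simulated molecule
#' population. The default protocol is the one used in the compaction assay:
#' the tether is held extended at 16 um (5 pN), relaxed to 8 um at 0.6 um/s,
#' held ~5.5 s, and re-extended at the same speed.
#'
#' @slot contourLength DNA contour length, um (lambda DNA: 16.4).
#' @slot extendedSeparation,relaxedSeparation bead separations, um.
#' @slot pullSpeed trap speed during relaxation/re-extension, um/s.
#' @slot holdTime time spent at the relaxed separation, s.
#' @slot holdForce force at the extended separation, pN.
#' @slot diffusionConstant true 1D diffusion constant of sliding tetramers,
#'   um^2/s.
#' @slot nTetramers number of DNA-bound tetramers simulated.
#' @slot fluorsPerTetramer fluorescent labels per tetramer (4).
#' @slot clusterSizeMean,clusterSizeRange,clusterSizeSdLog parameters of the
#'   truncated-lognormal cluster-size distribution (tetramers per cluster).
#' @slot conversionProb probability that a diffusing tetramer joins a static
#'   cluster during the relaxation + hold phases.
#' @slot persistenceLength DNA persistence length, nm.
#' @slot extendedTime,postTime observation time before the pull and after
#'   re-extension, s.
#' @slot seed integer seed controlling all randomness (NA = leave RNG alone).
#' @export
setClass("ExperimentConfig", representation(
  contourLength = "numeric",
  extendedSeparation = "numeric",
  relaxedSeparation = "numeric",
  pullSpeed = "numeric",
  holdTime = "numeric",
  holdForce = "numeric",
  diffusionConstant = "numeric",
  nTetramers = "numeric",
  fluorsPerTetramer = "numeric",
  clusterSizeMean = "numeric",
  clusterSizeRange = "numeric",
  clusterSizeSdLog = "numeric",
  conversionProb = "numeric",
  persistenceLength = "numeric",
  extendedTime = "numeric",
  postTime = "numeric",
  seed = "numeric"
))

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (!(object@relaxedSeparation < object@extendedSeparation))
    msg <- c(msg, "relaxedSeparation must be < extendedSeparation")
  if (!(object@extendedSeparation <= object@contourLength))
    msg <- c(msg, "extendedSeparation must be <= contourLength")
  if (object@diffusionConstant < 0)
    msg <- c(msg, "diffusionConstant must be >= 0")
  if (object@nTetramers < 0 || object@nTetramers != round(object@nTetramers))
    msg <- c(msg, "nTetramers must be a nonnegative integer")
  if (object@fluorsPerTetramer < 1)
    msg <- c(msg, "fluorsPerTetramer must be >= 1")
  if (length(object@clusterSizeRange) != 2L ||
      object@clusterSizeRange[1] < 1 ||
      diff(object@clusterSizeRange) < 0)
    msg <- c(msg, "clusterSizeRange must be (min, max) with 1 <= min <= max")
  if (object@conversionProb < 0 || object@conversionProb > 1)
    msg <- c(msg, "conversionProb must lie in [0, 1]")
  for (sl in c("pullSpeed", "holdTime", "persistenceLength",
               "extendedTime", "postTime")) {
    if (slot(object, sl) < 0) msg <- c(msg, sprintf("'%s' must be >= 0", sl))
  }
  if (length(msg)) msg else TRUE
})

#' @param contourLength,extendedSeparation,relaxedSeparation,pullSpeed,holdTime,holdForce,diffusionConstant,nTetramers,fluorsPerTetramer,clusterSizeMean,clusterSizeRange,clusterSizeSdLog,conversionProb,persistenceLength,extendedTime,postTime,seed
#'   see the corresponding slots.
#' @return `experimentConfig()` returns an [ExperimentConfig-class] object.
#' @rdname ExperimentConfig-class
#' @export
experimentConfig <- function(contourLength = 16.4,
                             extendedSeparation = 16,
                             relaxedSeparation = 8,
                             pullSpeed = 0.6,
                             holdTime = 5.5,
                             holdForce = 5,
                             diffusionConstant = 0.16,
                             nTetramers = 300,
                             fluorsPerTetramer = 4,
                             clusterSizeMean = 67,
                             clusterSizeRange = c(20, 160),
                             clusterSizeSdLog = 0.45,
                             conversionProb = 0.9,
                             persistenceLength = 50,
                             extendedTime = 10,
                             postTime = 10,
                             seed = NA_real_) {
  new("ExperimentConfig", contourLength = contourLength,
      extendedSeparation = extendedSeparation,
      relaxedSeparation = relaxedSeparation, pullSpeed = pullSpeed,
      holdTime = holdTime, holdForce = holdForce,
      diffusionConstant = diffusionConstant, nTetramers = nTetramers,
      fluorsPerTetramer = fluorsPerTetramer,
      clusterSizeMean = clusterSizeMean, clusterSizeRange = clusterSizeRange,
      clusterSizeSdLog = clusterSizeSdLog, conversionProb = conversionProb,
      persistenceLength = persistenceLength, extendedTime = extendedTime,
      postTime = postTime, seed = seed)
}

setMethod("show", "ExperimentConfig", function(object) {
  cat("ExperimentConfig\n",
      sprintf("  contour %g um | %g -> %g -> %g um at %g um/s, hold %g s\n",
              object@contourLength, object@extendedSeparation,
              object@relaxedSeparation, object@extendedSeparation,
              object@pullSpeed, object@holdTime),
      sprintf("  %d tetramers (%g labels each), D = %g um^2/s, P(convert) = %g\n",
              as.integer(object@nTetramers), object@fluorsPerTetramer,
              object@diffusionConstant, object@conversionProb),
      sprintf("  clusters: mean %g, range [%g, %g] tetramers\n",
              object@clusterSizeMean, object@clusterSizeRange[1],
              object@clusterSizeRange[2]), sep = "")
})

#' Ground truth of a simulated experiment
#'
#' Everything the generator knows and the estimators must recover:
#' per-tetramer axial trajectories, cluster membership and anchor positions,
#' the bead-separation timeline, and (once a kymograph has been rendered)
#' per-fluorophore bleach times.
#'
#' @slot positions numeric matrix, scan lines x tetramers; axial position in
#'   um from the left bead.
#' @slot bleachTimes per-fluorophore bleach times, s; length
#'   `nTetramers * fluorsPerTetramer`, or length 0 before rendering.
#' @slot fluorTetramer integer map fluorophore -> tetramer column.
#' @slot clusterId integer per tetramer; NA for tetramers that stay diffusive.
#' @slot clusterAnchors anchor position of each cluster, um.
#' @slot separation bead separation at every scan line, um.
#' @slot phase factor-like character per line: `extended`, `relax`, `hold`,
#'   `reextend`, `post`.
#' @slot linePeriod s per line.
#' @slot sequesteredPerDomain nm of DNA contour sequestered per DNA-binding
#'   domain by each cluster member (the planted footprint).
#' @export
setClass("GroundTruth", representation(
  positions = "matrix",
  bleachTimes = "numeric",
  fluorTetramer = "integer",
  clusterId = "integer",
  clusterAnchors = "numeric",
  separation = "numeric",
  phase = "character",
  linePeriod = "numeric",
  sequesteredPerDomain = "numeric"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  n <- nrow(object@positions)
  if (length(object@separation) != n)
    msg <- c(msg, "separation must have one value per scan line")
  if (length(object@phase) != n)
    msg <- c(msg, "phase must have one value per scan line")
  if (n > 0 && ncol(object@positions) > 0) {
    tol <- 1e-9
    bad <- object@positions < -tol | object@positions > object@separation + tol
    if (any(bad))
      msg <- c(msg, "positions must lie within [0, separation] at every line")
  }
  if (length(object@bleachTimes) && any(object@bleachTimes < 0))
    msg <- c(msg, "bleach times must be nonnegative")
  if (length(object@bleachTimes) &&
      length(object@fluorTetramer) != length(object@bleachTimes))
    msg <- c(msg, "fluorTetramer must map every fluorophore")
  if (length(object@clusterId) != ncol(object@positions))
    msg <- c(msg, "clusterId must have one entry per tetramer")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  nc <- length(object@clusterAnchors)
  cat(sprintf("GroundTruth: %d tetramers, %d scan lines (%.3g s), %d clusters\n",
              ncol(object@positions), nrow(object@positions),
              nrow(object@positions) * object@linePeriod, nc))
})

#' @rdname GroundTruth-class
#' @param object a `GroundTruth`.
#' @export
setMethod("linePeriod", "GroundTruth", function(object) object@linePeriod)

#' Kymograph: photon counts from repeated confocal line scans
#'
#' Rows are scan lines (time ascending), columns are pixels along the DNA
#' axis from the left bead towards the right bead; values are photon counts.
#'
#' @slot counts integer-valued matrix of nonnegative photon counts.
#' @slot pixelSize nm per pixel.
#' @slot linePeriod s per scan line.
#' @slot metadata free-form list (seed, optics, realized bleach times, ...).
#' @export
setClass("Kymograph", representation(
  counts = "matrix",
  pixelSize = "numeric",
  linePeriod = "numeric",
  metadata = "list"
))

setValidity("Kymograph", function(object) {
  msg <- character()
  cts <- object@counts
  if (!is.numeric(cts))
    msg <- c(msg, "counts must be numeric")
  else {
    if (any(!is.finite(cts)) || any(cts < 0))
      msg <- c(msg, "counts must be finite and nonnegative")
    else if (any(cts != round(cts)))
      msg <- c(msg, "counts must be integer-valued photon counts")
  }
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number (nm)")
  if (length(object@linePeriod) != 1L || object@linePeriod <= 0)
    msg <- c(msg, "linePeriod must be a single positive number (s)")
  if (length(msg)) msg else TRUE
})

#' @param counts,pixelSize,linePeriod,metadata see the corresponding slots.
#' @return `kymograph()` returns a [Kymograph-class].
#' @rdname Kymograph-class
#' @export
kymograph <- function(counts, pixelSize = 75, linePeriod = 0.02,
                      metadata = list()) {
  new("Kymograph", counts = counts, pixelSize = pixelSize,
      linePeriod = linePeriod, metadata = metadata)
}

#' @rdname Kymograph-class
#' @param object a `Kymograph`.
#' @export
setMethod("counts", "Kymograph", function(object) object@counts)

#' @rdname Kymograph-class
#' @export
setMethod("pixelSize", "Kymograph", function(object) object@pixelSize)

#' @rdname Kymograph-class
#' @export
setMethod("linePeriod", "Kymograph", function(object) object@linePeriod)

#' @rdname Kymograph-class
#' @param x a `Kymograph`.
#' @export
setMethod("dim", "Kymograph", function(x) dim(x@counts))

setMethod("show", "Kymograph", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "Kymograph: %d scan lines x %d pixels | %g nm/px, %g s/line | total %.4g photons\n",
    d[1], d[2], object@pixelSize, object@linePeriod, sum(object@counts)))
})

#' Force-distance record of a tethered DNA molecule
#'
#' @slot distance end-to-end bead separations, um (ascending).
#' @slot force force at each separation, pN.
#' @slot label `"free"` or `"compacted"`.
#' @slot metadata list; for simulated curves holds the effective contour
#'   length and the planted sequestration.
#' @export
setClass("ForceDistanceCurve", representation(
  distance = "numeric",
  force = "numeric",
  label = "character",
  metadata = "list"
))

setValidity("ForceDistanceCurve", function(object) {
  msg <- character()
  if (length(object@distance) != length(object@force))
    msg <- c(msg, "distance and force must have equal length")
  if (any(object@distance <= 0))
    msg <- c(msg, "distances must be positive")
  if (any(object@force < 0))
    msg <- c(msg, "forces must be nonnegative")
  if (!object@label %in% c("free", "compacted"))
    msg <- c(msg, "label must be 'free' or 'compacted'")
  if (length(msg)) msg else TRUE
})

#' @param distance,force,label,metadata see the corresponding slots.
#' @return `forceDistanceCurve()` returns a [ForceDistanceCurve-class].
#' @rdname ForceDistanceCurve-class
#' @export
forceDistanceCurve <- function(distance, force, label = "free",
                               metadata = list()) {
  o <- order(distance)
  new("ForceDistanceCurve", distance = distance[o], force = force[o],
      label = label, metadata = metadata)
}

setMethod("show", "ForceDistanceCurve", function(object) {
  cat(sprintf("ForceDistanceCurve (%s): %d samples, %.3g-%.3g um, %.3g-%.3g pN\n",
              object@label, length(object@distance), min(object@distance),
              max(object@distance), min(object@force), max(object@force)))
})

#' @rdname ForceDistanceCurve-class
#' @param x a `ForceDistanceCurve`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "ForceDistanceCurve", function(x, ...) {
  data.frame(distance_um = x@distance, force_pN = x@force, label = x@label)
})

#' Single-fluorophore photometric calibration
#'
#' Holds the photon yield of a single fluorophore per confocal scan line, as
#' measured from photobleaching step sizes, and the derived per-tetramer
#' yield (exactly 4x, four labels per tetramer).
#'
#' @slot photonsPerFluor photons per scan line for one fluorophore.
#' @slot photonsPerTetramer exactly `4 * photonsPerFluor`.
#' @slot nSteps number of bleaching steps the calibration is based on.
#' @export
setClass("Calibration", representation(
  photonsPerFluor = "numeric",
  photonsPerTetramer = "numeric",
  nSteps = "integer"
))

setValidity("Calibration", function(object) {
  msg <- character()
  if (object@photonsPerFluor <= 0)
    msg <- c(msg, "photonsPerFluor must be positive")
  if (!identical(object@photonsPerTetramer, 4 * object@photonsPerFluor))
    msg <- c(msg, "photonsPerTetramer must equal 4 * photonsPerFluor exactly")
  if (length(msg)) msg else TRUE
})

#' @param photonsPerFluor photons/scan line for a single fluorophore.
#' @param nSteps number of bleaching steps used.
#' @return `calibration()` returns a [Calibration-class].
#' @rdname Calibration-class
#' @examples
#' cal <- calibration(1.5)
#' photonsPerTetramer(cal)  # 6.0
#' @export
calibration <- function(photonsPerFluor, nSteps = 0L) {
  new("Calibration", photonsPerFluor = photonsPerFluor,
      photonsPerTetramer = 4 * photonsPerFluor, nSteps = as.integer(nSteps))
}

#' @rdname Calibration-class
#' @param object a `Calibration`.
#' @export
setMethod("photonsPerFluor", "Calibration", function(object) object@photonsPerFluor)

#' @rdname Calibration-class
#' @export
setMethod("photonsPerTetramer", "Calibration",
          function(object) object@photonsPerTetramer)

setMethod("show", "Calibration", function(object) {
  cat(sprintf(
    "Calibration: %.4g photons/fluorophore/line, %.4g/tetramer (%d steps)\n",
    object@photonsPerFluor, object@photonsPerTetramer, object@nSteps))
})

#' Gaussian fit to one scan line (or an averaged band of lines)
#'
#' @slot amplitude peak amplitude above background, photons.
#' @slot center fitted peak position, um.
#' @slot width fitted Gaussian sd, nm.
#' @slot background fitted constant offset, photons/pixel.
#' @slot goodness residual standard error of the fit (Inf when the fit
#'   failed to converge).
#' @slot converged logical; failed fits are flagged, never silent.
#' @export
setClass("ScanlineFit", representation(
  amplitude = "numeric",
  center = "numeric",
  width = "numeric",
  background = "numeric",
  goodness = "numeric",
  converged = "logical"
))

setMethod("show", "ScanlineFit", function(object) {
  if (object@converged)
    cat(sprintf(
      "ScanlineFit: amp %.4g photons at %.4g um (sd %.3g nm, bg %.3g), rse %.3g\n",
      object@amplitude, object@center, object@width, object@background,
      object@goodness))
  else cat("ScanlineFit: NOT CONVERGED\n")
})

#' Single-particle trajectory on the DNA axis
#'
#' @slot time sample times, s (strictly increasing).
#' @slot position axial positions, um.
#' @slot amplitude fitted Gaussian amplitude at each sample, photons.
#' @slot classification `"diffusive"`, `"static"` or `"ambiguous"`.
#' @slot pixelSize nm, carried over from the source kymograph.
#' @export
setClass("Trajectory", representation(
  time = "numeric",
  position = "numeric",
  amplitude = "numeric",
  classification = "character",
  pixelSize = "numeric"
))

setValidity("Trajectory", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@position) != n || length(object@amplitude) != n)
    msg <- c(msg, "time, position and amplitude must have equal length")
  if (n > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (!object@classification %in% c("diffusive", "static", "ambiguous"))
    msg <- c(msg, "classification must be diffusive/static/ambiguous")
  if (length(msg)) msg else TRUE
})

#' @param time,position,amplitude,classification,pixelSize see slots.
#' @return `trajectory()` returns a [Trajectory-class].
#' @rdname Trajectory-class
#' @export
trajectory <- function(time, position, amplitude = rep(NA_real_, length(time)),
                       classification = "ambiguous", pixelSize = 75) {
  new("Trajectory", time = time, position = position, amplitude = amplitude,
      classification = classification, pixelSize = pixelSize)
}

#' @rdname Trajectory-class
#' @param object a `Trajectory`.
#' @export
setMethod("classification", "Trajectory", function(object) object@classification)

#' @rdname Trajectory-class
#' @export
setMethod("length", "Trajectory", function(x) length(x@time))

#' @rdname Trajectory-class
#' @param x a `Trajectory`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "Trajectory", function(x, ...) {
  data.frame(time_s = x@time, position_um = x@position,
             amplitude_photons = x@amplitude)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory (%s): %d samples over %.3g s, mean amp %.3g photons\n",
              object@classification, length(object@time),
              diff(range(object@time)),
              mean(object@amplitude, na.rm = TRUE)))
})
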