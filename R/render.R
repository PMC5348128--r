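#' Draw per-fluorophore photobleaching times
#'
#' Bleach times are exponential with rate
#' `bleachRateAtReference * (laserPower / referencePower)^2`: photobleaching
#' is driven by a two-photon process, so the rate scales quadratically with
#' excitation power, while photon emission scales linearly.
#'
#' @param nFluor number of fluorophores.
#' @param optics an [OpticsConfig-class].
#' @param seed RNG seed.
#' @return Bleach times in seconds (`Inf` when the rate is zero).
#' @export
drawBleachTimes <- function(nFluor, optics, seed = NA) {
  stopifnot(is(optics, "OpticsConfig"), nFluor >= 0)
  rate <- optics@bleachRateAtReference *
    (optics@laserPower / optics@referencePower)^2
  if (rate == 0) return(rep(Inf, nFluor))
  withSeed(seed, stats::rexp(nFluor, rate))
}

#' Render a kymograph from ground truth
#'
#' Each unbleached fluorophore contributes, on every scan line, a Gaussian
#' profile of sd `psfSd` centred on its axial position, with expected peak
#' amplitude `photonsPerFluorPerLine * (laserPower / referencePower)`
#' (emission is linear in power). Pixel values are Poisson draws of the
#' summed fluorophore signal plus the uniform background rate. Bleach times
#' are taken from the truth when present, otherwise drawn with
#' [drawBleachTimes()] (quadratic power scaling) and recorded in the
#' returned kymograph's metadata.
#'
#' @param truth a [GroundTruth-class].
#' @param optics an [OpticsConfig-class]; its `linePeriod` must match the
#'   truth's.
#' @param seed RNG seed (bleach times and photon noise).
#' @param nPixels number of pixels; default spans the largest bead
#'   separation.
#' @param noise set `FALSE` to return the rounded expected signal instead of
#'   Poisson draws (useful for noise-free checks).
#' @return A [Kymograph-class]; `metadata` carries the optics, seed and
#'   realized bleach times.
#' @export
renderKymograph <- function(truth, optics, seed = NA, nPixels = NULL,
                            noise = TRUE) {
  stopifnot(is(truth, "GroundTruth"), is(optics, "OpticsConfig"))
  if (abs(truth@linePeriod - optics@linePeriod) > 1e-12)
    stop("line period of the truth (", truth@linePeriod,
         " s) does not match the optics (", optics@linePeriod, " s)")
  d_um <- optics@pixelSize / 1000
  s_um <- optics@psfSd / 1000
  nLines <- nrow(truth@positions)
  nTet <- ncol(truth@positions)
  if (is.null(nPixels))
    nPixels <- as.integer(ceiling(max(truth@separation) / d_um))
  xpix <- (seq_len(nPixels) - 0.5) * d_um
  tline <- (seq_len(nLines) - 1L) * truth@linePeriod
  amp <- optics@photonsPerFluorPerLine *
    (optics@laserPower / optics@referencePower)
  fluorsPerTet <- if (nTet > 0) tabulate(truth@fluorTetramer, nTet) else integer(0)

  withSeed(seed, {
    bt <- truth@bleachTimes
    if (!length(bt) && nTet > 0)
      bt <- drawBleachTimes(sum(fluorsPerTet), optics)
    E <- matrix(optics@backgroundRate, nLines, nPixels)
    if (nTet > 0) {
      # alive label count per tetramer per line
      aliveCount <- matrix(0, nLines, nTet)
      for (tet in seq_len(nTet)) {
        bts <- bt[truth@fluorTetramer == tet]
        aliveCount[, tet] <- vapply(tline, function(t) sum(bts > t),
                                    numeric(1))
      }
      # group static tetramers sharing one anchor: one profile per group
      isStatic <- apply(truth@positions, 2L,
                        function(p) all(p == p[1]))
      if (any(isStatic)) {
        anchors <- truth@positions[1, isStatic]
        for (a in unique(anchors)) {
          cols <- which(isStatic)[anchors == a]
          profile <- amp * exp(-(xpix - a)^2 / (2 * s_um^2))
          tot <- if (length(cols) > 1L) rowSums(aliveCount[, cols, drop = FALSE])
                 else aliveCount[, cols]
          E <- E + outer(tot, profile)
        }
      }
      for (tet in which(!isStatic)) {
        G <- exp(-(outer(truth@positions[, tet], xpix, "-"))^2 /
                   (2 * s_um^2))
        E <- E + amp * aliveCount[, tet] * G
      }
    }
    cts <- if (noise) matrix(stats::rpois(length(E), E), nLines, nPixels)
           else round(E)
    kymograph(cts, pixelSize = optics@pixelSize,
              linePeriod = truth@linePeriod,
              metadata = list(optics = optics, seed = seed,
                              bleachTimes = bt))
  })
}

#' Simulate a flow-stretched bridged-DNA image
#'
#' Emulates the flow experiment in which parallel, flow-extended DNA
#' molecules are bridged by protein over micrometre-long segments. Each
#' bridged segment is populated with fluorophores at linear density
#' `4 / footprint` per nm (one tetramer per `footprint` nm of axis, four
#' labels each: in a bridged geometry the two DNA-binding domains of a
#' tetramer engage two parallel molecules at the same axial position).
#' Fluorophores are rendered as 2D Gaussians (sd `psfSd`) with peak
#' amplitude `photonsPerFluorPerLine`, and pixel values are Poisson draws of
#' signal plus background.
#'
#' @param segments data.frame with columns `x0`, `x1`, `y` (nm): horizontal
#'   bridged segments.
#' @param footprint planted footprint per DNA-binding domain, nm.
#' @param optics an [OpticsConfig-class].
#' @param imageSize `c(rows, cols)` in pixels; default fits the segments
#'   with a margin.
#' @param seed RNG seed.
#' @return List with `image` (photon-count matrix, rows = y), `fluors`
#'   (data.frame of planted positions), `footprint` and `pixelSize`.
#' @export
simulateFlowImage <- function(segments, footprint = 3.6, optics = opticsConfig(),
                              imageSize = NULL, seed = NA) {
  stopifnot(is.data.frame(segments) || nrow(segments) == 0,
            footprint > 0)
  d <- optics@pixelSize
  s <- optics@psfSd
  A <- optics@photonsPerFluorPerLine *
    (optics@laserPower / optics@referencePower)
  if (is.null(imageSize)) {
    if (nrow(segments)) {
      margin <- 10 * d
      wide <- ceiling((max(segments$x1) + margin) / d)
      high <- ceiling((max(segments$y) + 4 * margin) / d)
      imageSize <- c(high, wide)
    } else imageSize <- c(32L, 32L)
  }
  if (nrow(segments)) {
    if (any(segments$x0 < 0) || any(segments$x1 * 1 > imageSize[2] * d) ||
        any(segments$y < 0) || any(segments$y > imageSize[1] * d))
      stop("segments must lie within the image bounds")
  }
  xc <- (seq_len(imageSize[2]) - 0.5) * d
  yc <- (seq_len(imageSize[1]) - 0.5) * d
  withSeed(seed, {
    E <- matrix(optics@backgroundRate, imageSize[1], imageSize[2])
    fx <- numeric(0); fy <- numeric(0); fseg <- integer(0)
    if (nrow(segments)) {
      density <- 4 / footprint  # labels per nm of bridged axis
      for (i in seq_len(nrow(segments))) {
        len <- segments$x1[i] - segments$x0[i]
        stopifnot(len > 0)
        nF <- stats::rpois(1, len * density)
        if (nF == 0) next
        x <- stats::runif(nF, segments$x0[i], segments$x1[i])
        y <- rep(segments$y[i], nF)
        # separable rendering: all fluors of a segment share y
        colSig <- A * colSums(exp(-(outer(x, xc, "-"))^2 / (2 * s^2)))
        rowProf <- exp(-(yc - segments$y[i])^2 / (2 * s^2))
        E <- E + outer(rowProf, colSig)
        fx <- c(fx, x); fy <- c(fy, y); fseg <- c(fseg, rep(i, nF))
      }
    }
    img <- matrix(stats::rpois(length(E), E), nrow(E), ncol(E))
    list(image = img,
         fluors = data.frame(x_nm = fx, y_nm = fy, segment = fseg),
         footprint = footprint, pixelSize = d)
  })
}
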