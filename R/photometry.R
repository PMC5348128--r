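## Scan-line photometry: Gaussian fitting, photobleaching-step calibration,
## bleaching correction and cluster stoichiometry.

# Gaussian + constant least-squares fit of a 1D profile.
# x in um, y in photons; returns a ScanlineFit (width reported in nm).
gaussFitProfile <- function(x, y, sdPrior_um = 0.1) {
  n <- length(x)
  if (stats::sd(y) == 0) {
    return(new("ScanlineFit", amplitude = 0, center = mean(x),
               width = sdPrior_um * 1000, background = y[1],
               goodness = 0, converged = TRUE))
  }
  bg0 <- as.numeric(stats::quantile(y, 0.25))
  amp0 <- max(max(y) - bg0, 1e-3)
  c0 <- x[which.max(y)]
  px <- if (n > 1) min(diff(sort(x))) else sdPrior_um
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ bg + amp * exp(-(x - ctr)^2 / (2 * sdg^2)),
                      start = list(bg = bg0, amp = amp0, ctr = c0,
                                   sdg = sdPrior_um),
                      lower = c(bg = 0, amp = 0, ctr = min(x),
                                sdg = px / 4),
                      upper = c(bg = Inf, amp = Inf, ctr = max(x),
                                sdg = diff(range(x)) + px),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("ScanlineFit", amplitude = NA_real_, center = NA_real_,
               width = NA_real_, background = NA_real_, goodness = Inf,
               converged = FALSE))
  }
  cf <- coef(fit)
  new("ScanlineFit", amplitude = unname(cf["amp"]),
      center = unname(cf["ctr"]), width = unname(cf["sdg"]) * 1000,
      background = unname(cf["bg"]),
      goodness = sqrt(mean(resid(fit)^2)), converged = TRUE)
}

#' Fit a Gaussian-plus-constant profile to a scan line
#'
#' Least-squares fit of `bg + A * exp(-(x - c)^2 / (2 s^2))` to the photon
#' counts of one scan line (or to the average of a band of lines, the way a
#' stable cluster is photometered). Non-convergence is flagged via the
#' `goodness`/`converged` slots, never silent.
#'
#' @param kymo a [Kymograph-class].
#' @param row scan-line index, or a vector of indices whose counts are
#'   averaged before fitting.
#' @param window pixel indices to fit over (default: all; at least 5).
#' @return A [ScanlineFit-class]; amplitude in photons at the peak, center
#'   in um, width (sd) in nm.
#' @export
fitScanline <- function(kymo, row, window = NULL) {
  stopifnot(is(kymo, "Kymograph"))
  cts <- kymo@counts
  if (is.null(window)) window <- seq_len(ncol(cts))
  if (length(window) < 5) stop("fit window must span at least 5 pixels")
  if (any(window < 1) || any(window > ncol(cts)))
    stop("window outside the kymograph")
  if (any(row < 1) || any(row > nrow(cts)))
    stop("row outside the kymograph")
  y <- if (length(row) > 1L) colMeans(cts[row, window, drop = FALSE])
       else cts[row, window]
  x <- (window - 0.5) * kymo@pixelSize / 1000
  sdPrior <- if (!is.null(kymo@metadata$optics))
    kymo@metadata$optics@psfSd / 1000 else 0.1
  gaussFitProfile(x, y, sdPrior_um = sdPrior)
}

# Penalized least-squares changepoint segmentation (optimal partitioning)
# of a piecewise-constant signal. Returns segment boundaries and means.
segmentTrace <- function(x, penalty = NULL, minSegment = 5L) {
  n <- length(x)
  stopifnot(n >= 2 * minSegment)
  if (is.null(penalty)) {
    sigma2 <- (stats::mad(diff(x)) / sqrt(2))^2
    penalty <- max(2 * sigma2 * log(n), 1e-8)
  }
  cs <- cumsum(c(0, x))
  css <- cumsum(c(0, x^2))
  F <- rep(Inf, n + 1L)
  F[1L] <- -penalty
  cp <- integer(n + 1L)
  for (t in seq.int(minSegment, n)) {
    s <- 0:(t - minSegment)
    s <- s[s == 0L | s >= minSegment]
    len <- t - s
    cost <- F[s + 1L] + (css[t + 1L] - css[s + 1L] -
                           (cs[t + 1L] - cs[s + 1L])^2 / len) + penalty
    j <- which.min(cost)
    F[t + 1L] <- cost[j]
    cp[t + 1L] <- s[j]
  }
  # backtrack
  ends <- integer(0)
  t <- n
  while (t > 0L) {
    ends <- c(t, ends)
    t <- cp[t + 1L]
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  means <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
  data.frame(start = starts, end = ends, mean = means)
}

#' Detect photobleaching steps in an intensity trace
#'
#' Segments the trace into plateaus by penalized least-squares changepoint
#' detection (optimal partitioning with an SIC-type penalty
#' `2 * sigma^2 * log(n)`, sigma estimated from first differences), then
#' reports the decreases between consecutive plateaus. The segmentation is
#' deterministic given the trace.
#'
#' @param trace photon intensity per scan line (>= 20 lines).
#' @param linePeriod s per line (for the reported step times).
#' @param penalty segmentation penalty; default as above.
#' @param minSegment minimum plateau length, lines.
#' @return data.frame with one row per downward step: `line` (first line of
#'   the new plateau), `time` (s) and `size` (photons, positive). Zero rows
#'   when fewer than two plateaus are found.
#' @examples
#' detectBleachSteps(c(rep(6, 30), rep(4.5, 30)), linePeriod = 1)
#' @export
detectBleachSteps <- function(trace, linePeriod = 1, penalty = NULL,
                              minSegment = 5L) {
  if (length(trace) < 20) stop("trace must have at least 20 lines")
  seg <- segmentTrace(trace, penalty = penalty, minSegment = minSegment)
  if (nrow(seg) < 2)
    return(data.frame(line = integer(0), time = numeric(0),
                      size = numeric(0)))
  d <- diff(seg$mean)
  down <- which(d < 0)
  data.frame(line = seg$start[down + 1L],
             time = (seg$start[down + 1L] - 1L) * linePeriod,
             size = -d[down])
}

#' Photobleaching step sizes in Gaussian-amplitude units
#'
#' The calibration pipeline for single-fluorophore photometry: the summed
#' intensity trace of an immobile emitter is segmented into bleaching
#' plateaus, a Gaussian is fitted to the average profile of each plateau,
#' and the decreases in fitted amplitude between consecutive plateaus are
#' returned. These amplitude drops are the per-fluorophore photon yields.
#'
#' @param kymo a [Kymograph-class] containing one immobile emitter.
#' @param window pixel indices around the emitter (default all).
#' @param penalty,minSegment passed to the changepoint segmentation.
#' @return Numeric vector of amplitude step sizes (photons), one per
#'   detected bleaching step.
#' @export
bleachStepAmplitudes <- function(kymo, window = NULL, penalty = NULL,
                                 minSegment = 10L) {
  stopifnot(is(kymo, "Kymograph"))
  cts <- kymo@counts
  if (is.null(window)) window <- seq_len(ncol(cts))
  trace <- rowSums(cts[, window, drop = FALSE])
  seg <- segmentTrace(trace, penalty = penalty, minSegment = minSegment)
  if (nrow(seg) < 2) return(numeric(0))
  amps <- vapply(seq_len(nrow(seg)), function(i) {
    f <- fitScanline(kymo, row = seg$start[i]:seg$end[i], window = window)
    if (f@converged) f@amplitude else NA_real_
  }, numeric(1))
  d <- diff(amps)
  d <- d[!is.na(d)]
  -d[d < 0]
}

#' Calibrate the single-fluorophore photon yield
#'
#' The mean photobleaching step size, pooled over traces, gives the photon
#' yield of one fluorophore per scan line; the per-tetramer yield is exactly
#' four times that (four labels per tetramer).
#'
#' @param steps photobleaching step sizes in Gaussian-amplitude units
#'   (photons), pooled from one or more emitters.
#' @return A [Calibration-class].
#' @examples
#' calibrateSingleFluorophore(c(1.0, 2.0))  # 1.5 / 6.0
#' @export
calibrateSingleFluorophore <- function(steps) {
  steps <- steps[is.finite(steps)]
  if (length(steps) == 0) stop("no bleaching steps to calibrate from")
  if (length(steps) < 10)
    warning("calibration from fewer than 10 steps is unreliable")
  calibration(mean(steps), nSteps = length(steps))
}

#' Bleaching correction factor
#'
#' Ratio of the total photon count over the DNA at the start of the
#' kymograph to that at time `t`:
#' `I_total(0) / I_total(t)`. Totals are summed over the pixel band and
#' averaged over `band` scan lines at each endpoint to tame shot noise.
#' Assumes all intensity loss is photobleaching (no dissociation).
#'
#' @param kymo a [Kymograph-class].
#' @param t time at which the cluster is photometered, s.
#' @param band number of scan lines averaged at each endpoint.
#' @param window pixel indices spanning the DNA (default all).
#' @param background expected background in photons/pixel/line, subtracted
#'   from both totals.
#' @return Correction factor (unitless, 1 at `t = 0`).
#' @export
bleachCorrectionFactor <- function(kymo, t, band = 10L, window = NULL,
                                   background = 0) {
  stopifnot(is(kymo, "Kymograph"), t >= 0)
  cts <- kymo@counts
  if (is.null(window)) window <- seq_len(ncol(cts))
  nLines <- nrow(cts)
  r <- as.integer(round(t / kymo@linePeriod)) + 1L
  if (r > nLines) stop("t beyond the end of the kymograph")
  bandRows <- function(centerEnd) {
    i <- seq.int(max(1L, centerEnd - band + 1L), centerEnd)
    i
  }
  bandTotal <- function(rows) {
    mean(rowSums(cts[rows, window, drop = FALSE])) -
      background * length(window)
  }
  i0 <- bandTotal(seq.int(1L, min(band, nLines)))
  it <- bandTotal(bandRows(max(r, min(band, nLines))))
  if (t == 0) return(1.0)
  if (it <= 0) stop("total intensity at time t is not positive")
  i0 / it
}

#' Estimate cluster size in tetramers
#'
#' `tetramers = amplitude * correction / photonsPerTetramer`: the fitted
#' Gaussian amplitude of the cluster, corrected for photobleaching, divided
#' by the calibrated per-tetramer yield (6.0 photons for the 1.5
#' photons/fluorophore calibration).
#'
#' @param fit a [ScanlineFit-class] of the cluster profile.
#' @param cal a [Calibration-class].
#' @param corr bleaching correction factor (>= 1 in normal use).
#' @return List with `tetramers`, `amplitude`, `bleachCorrection`,
#'   `position` (um).
#' @examples
#' f <- new("ScanlineFit", amplitude = 402, center = 5, width = 100,
#'          background = 0, goodness = 0, converged = TRUE)
#' estimateClusterSize(f, calibration(1.5), 1)$tetramers  # 67
#' @export
estimateClusterSize <- function(fit, cal, corr = 1) {
  stopifnot(is(fit, "ScanlineFit"), is(cal, "Calibration"), corr > 0)
  if (!fit@converged)
    stop("cannot estimate cluster size from a non-converged fit")
  list(tetramers = fit@amplitude * corr / cal@photonsPerTetramer,
       amplitude = fit@amplitude, bleachCorrection = corr,
       position = fit@center)
}

#' Photometer one cluster in a kymograph
#'
#' Convenience wrapper: fits the cluster profile in a band of scan lines
#' around time `t`, computes the bleaching correction at `t`, and converts
#' to tetramers with [estimateClusterSize()].
#'
#' @inheritParams bleachCorrectionFactor
#' @param cal a [Calibration-class].
#' @param fitWindow pixel indices around the cluster for the Gaussian fit.
#' @return As [estimateClusterSize()], plus the `fit` and `corr` used.
#' @export
estimateClusterFromKymo <- function(kymo, cal, t, fitWindow = NULL,
                                    band = 10L, window = NULL,
                                    background = 0) {
  r <- as.integer(round(t / kymo@linePeriod)) + 1L
  rows <- seq.int(max(1L, r - band %/% 2L),
                  min(nrow(kymo@counts), r + band %/% 2L))
  fit <- fitScanline(kymo, row = rows, window = fitWindow)
  corr <- bleachCorrectionFactor(kymo, t, band = band, window = window,
                                 background = background)
  est <- estimateClusterSize(fit, cal, corr)
  c(est, list(fit = fit))
}

#' Estimate the photobleaching rate from a decaying kymograph
#'
#' Single-exponential least-squares fit `I(t) = I0 exp(-k t)` to the
#' integrated intensity per scan line.
#'
#' @param kymo a [Kymograph-class], or a numeric intensity trace (then
#'   supply `linePeriod`).
#' @param linePeriod s per line when `kymo` is a plain trace.
#' @param window pixel indices to integrate over (default all).
#' @param background photons/pixel/line subtracted before fitting.
#' @return List with `rate` (1/s), `se`, `converged`, and `wideConfidence`
#'   (TRUE when total decay over the trace is under 20%, where the rate is
#'   poorly constrained).
#' @export
estimateBleachRate <- function(kymo, linePeriod = NULL, window = NULL,
                               background = 0) {
  if (is(kymo, "Kymograph")) {
    cts <- kymo@counts
    if (is.null(window)) window <- seq_len(ncol(cts))
    trace <- rowSums(cts[, window, drop = FALSE]) -
      background * length(window)
    dt <- kymo@linePeriod
  } else {
    trace <- as.numeric(kymo)
    if (is.null(linePeriod))
      stop("linePeriod is required when passing a plain trace")
    dt <- linePeriod
  }
  n <- length(trace)
  stopifnot(n >= 3)
  t <- (seq_len(n) - 1) * dt
  pos <- pmax(trace, 1e-12)
  k0 <- max(0, -unname(coef(lm(log(pos) ~ t))[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(trace ~ I0 * exp(-k * t),
                      start = list(I0 = max(mean(head(trace, 10)), 1e-9),
                                   k = k0),
                      lower = c(I0 = 0, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(rate = k0, se = NA_real_, converged = FALSE,
                wideConfidence = TRUE))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  decay <- 1 - exp(-cf[["k"]] * max(t))
  list(rate = unname(cf[["k"]]), se = unname(se), converged = TRUE,
       wideConfidence = decay < 0.2)
}

#' Power-law exponent of the bleaching rate vs laser power
#'
#' Log-log regression slope of rate against excitation power. A slope of 2
#' indicates two-photon-mediated photobleaching (emission itself is linear
#' in power).
#'
#' @param rates bleaching rates, 1/s (positive).
#' @param powers laser powers, uW (>= 2 distinct values).
#' @return The fitted exponent.
#' @examples
#' fitPowerExponent(c(1, 4, 9), c(1, 2, 3))  # 2
#' @export
fitPowerExponent <- function(rates, powers) {
  stopifnot(length(rates) == length(powers))
  if (any(rates <= 0)) stop("rates must be positive for a log-log fit")
  if (length(unique(powers)) < 2)
    stop("at least two distinct power levels are required")
  unname(coef(lm(log(rates) ~ log(powers)))[2])
}
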