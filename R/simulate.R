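#' Simulate 1D Brownian sliding on a DNA tether
#'
#' Discrete Brownian path sampled at the confocal line period, with
#' per-step variance `2 * D * linePeriod` and specular reflection at the
#' tether ends (bound protein does not fall off at the beads).
#'
#' @param D 1D diffusion constant, um^2/s (>= 0; 0 gives a constant path).
#' @param tetherLength tether length, um.
#' @param duration trace duration, s.
#' @param linePeriod sampling interval, s.
#' @param x0 starting position, um; default uniform on the tether.
#' @param seed RNG seed.
#' @return Numeric vector of positions (um), one per scan line.
#' @examples
#' x <- simulateTrajectory(0.16, 16, 5, seed = 1)
#' var(diff(x))  # ~ 2 * 0.16 * 0.02
#' @export
simulateTrajectory <- function(D, tetherLength, duration, linePeriod = 0.02,
                               x0 = NULL, seed = NA) {
  if (D < 0) stop("diffusion constant must be nonnegative")
  stopifnot(tetherLength > 0, duration > 0, linePeriod > 0)
  n <- max(2L, as.integer(round(duration / linePeriod)))
  withSeed(seed, {
    if (is.null(x0)) x0 <- stats::runif(1, 0, tetherLength)
    if (D == 0) return(rep(x0, n))
    steps <- stats::rnorm(n - 1L, 0, sqrt(2 * D * linePeriod))
    reflectInto(x0 + cumsum(c(0, steps)) , tetherLength)
  })
}

#' Sample cluster sizes (tetramers per cluster)
#'
#' Truncated lognormal on `range`, with the log-scale location solved
#' numerically so that the truncated mean equals `mean`. The defaults
#' reproduce the observed cluster-size population: mean 67 tetramers,
#' individual clusters between 20 and 160.
#'
#' @param n number of clusters.
#' @param mean target mean cluster size, tetramers.
#' @param range `(min, max)` truncation bounds, tetramers.
#' @param sdlog lognormal shape parameter.
#' @param seed RNG seed.
#' @return Integer vector of cluster sizes.
#' @export
sampleClusterSizes <- function(n, mean = 67, range = c(20, 160),
                               sdlog = 0.45, seed = NA) {
  stopifnot(n >= 0, mean > range[1], mean < range[2])
  if (n == 0) return(integer(0))
  truncMean <- function(mu) {
    za <- (log(range[1]) - mu) / sdlog
    zb <- (log(range[2]) - mu) / sdlog
    num <- stats::pnorm(zb - sdlog) - stats::pnorm(za - sdlog)
    den <- stats::pnorm(zb) - stats::pnorm(za)
    exp(mu + sdlog^2 / 2) * num / den
  }
  mu <- stats::uniroot(function(m) truncMean(m) - mean,
                       lower = log(range[1]), upper = log(range[2]),
                       tol = 1e-10)$root
  withSeed(seed, {
    u <- stats::runif(n, stats::plnorm(range[1], mu, sdlog),
                      stats::plnorm(range[2], mu, sdlog))
    pmin(range[2], pmax(range[1], round(stats::qlnorm(u, mu, sdlog))))
  })
}

#' Simulate the DNA-compaction experiment
#'
#' Runs the full pulling protocol: an extended-observation phase (tether at
#' the extended separation, all tetramers sliding diffusively), relaxation
#' to the relaxed separation at the pull speed, a hold, re-extension, and a
#' final observation phase. During relaxation + hold each tetramer
#' independently converts, with probability `conversionProb`, into a member
#' of a static cluster; cluster sizes follow the configured
#' truncated-lognormal distribution and clusters are anchored at fixed
#' positions. Unconverted tetramers keep diffusing, reflected at the
#' (time-varying) bead positions.
#'
#' @param config an [ExperimentConfig-class].
#' @param linePeriod sampling interval, s (must match the optics used to
#'   render the kymograph later).
#' @param footprintPerDomain nm of DNA sequestered per DNA-binding domain by
#'   each cluster member; recorded in the truth for footprint round trips.
#' @return A list with elements `truth` ([GroundTruth-class]) and
#'   `separation` (data.frame of time and bead separation).
#' @export
simulateCompactionExperiment <- function(config, linePeriod = 0.02,
                                         footprintPerDomain = 2.7) {
  stopifnot(is(config, "ExperimentConfig"))
  dt <- linePeriod
  pullDur <- (config@extendedSeparation - config@relaxedSeparation) /
    config@pullSpeed
  durs <- c(extended = config@extendedTime, relax = pullDur,
            hold = config@holdTime, reextend = pullDur,
            post = config@postTime)
  nl <- pmax(1L, as.integer(round(durs / dt)))
  names(nl) <- names(durs)
  phase <- rep(names(durs), nl)
  n <- sum(nl)
  tm <- (seq_len(n) - 1L) * dt
  sep <- numeric(n)
  sep[phase == "extended"] <- config@extendedSeparation
  sep[phase == "relax"] <- config@extendedSeparation -
    config@pullSpeed * dt * seq_len(nl["relax"])
  sep[phase == "hold"] <- config@relaxedSeparation
  sep[phase == "reextend"] <- config@relaxedSeparation +
    config@pullSpeed * dt * seq_len(nl["reextend"])
  sep[phase == "post"] <- config@extendedSeparation
  sep <- pmin(sep, config@extendedSeparation)
  sep <- pmax(sep, config@relaxedSeparation)

  nTet <- as.integer(config@nTetramers)
  withSeed(config@seed, {
    converts <- stats::runif(nTet) < config@conversionProb
    convWindow <- which(phase %in% c("relax", "hold"))
    convLine <- rep(NA_integer_, nTet)
    convLine[converts] <- convWindow[sample.int(length(convWindow),
                                                sum(converts), replace = TRUE)]

    nConv <- sum(converts)
    clusterId <- rep(NA_integer_, nTet)
    anchors <- numeric(0)
    if (nConv > 0) {
      sizes <- integer(0)
      while (sum(sizes) < nConv)
        sizes <- c(sizes, sampleClusterSizes(1,
          mean = config@clusterSizeMean, range = config@clusterSizeRange,
          sdlog = config@clusterSizeSdLog))
      memb <- rep(seq_along(sizes), sizes)[seq_len(nConv)]
      clusterId[which(converts)[sample.int(nConv)]] <- memb
      anchors <- stats::runif(max(memb), 0.05, 0.95) *
        config@relaxedSeparation
    }

    pos <- matrix(NA_real_, n, nTet)
    if (nTet > 0) {
      pos[1, ] <- stats::runif(nTet, 0, sep[1])
      sdStep <- sqrt(2 * config@diffusionConstant * dt)
      for (i in seq_len(n - 1L) + 1L) {
        p <- pos[i - 1L, ] + stats::rnorm(nTet, 0, sdStep)
        p <- reflectInto(p, sep[i])
        frozen <- !is.na(convLine) & convLine <= i
        p[frozen] <- anchors[clusterId[frozen]]
        pos[i, ] <- p
      }
    }
    truth <- new("GroundTruth", positions = pos,
                 bleachTimes = numeric(0),
                 fluorTetramer = rep(seq_len(nTet),
                                     each = as.integer(config@fluorsPerTetramer)),
                 clusterId = clusterId, clusterAnchors = anchors,
                 separation = sep, phase = phase, linePeriod = dt,
                 sequesteredPerDomain = footprintPerDomain)
    list(truth = truth, separation = data.frame(time_s = tm,
                                                separation_um = sep))
  })
}

#' Ground truth for static clusters of known size
#'
#' Convenience builder for recovery tests: clusters of the given sizes sit
#' at fixed positions on a tether of constant separation for the whole
#' trace.
#'
#' @param sizes tetramers per cluster.
#' @param positions anchor positions, um (default: evenly spread).
#' @param duration trace duration, s.
#' @param separation bead separation, um.
#' @param linePeriod s per line.
#' @param fluorsPerTetramer labels per tetramer.
#' @param footprintPerDomain nm, recorded in the truth.
#' @return A [GroundTruth-class].
#' @export
staticClusterTruth <- function(sizes, positions = NULL, duration = 20,
                               separation = 16, linePeriod = 0.02,
                               fluorsPerTetramer = 4,
                               footprintPerDomain = 2.7) {
  stopifnot(all(sizes >= 1), duration > 0)
  k <- length(sizes)
  if (is.null(positions))
    positions <- separation * (seq_len(k)) / (k + 1)
  stopifnot(length(positions) == k, all(positions >= 0),
            all(positions <= separation))
  n <- max(2L, as.integer(round(duration / linePeriod)))
  nTet <- sum(sizes)
  clusterId <- rep(seq_len(k), sizes)
  pos <- matrix(rep(positions[clusterId], each = n), n, nTet)
  new("GroundTruth", positions = pos, bleachTimes = numeric(0),
      fluorTetramer = rep(seq_len(nTet), each = as.integer(fluorsPerTetramer)),
      clusterId = as.integer(clusterId), clusterAnchors = positions,
      separation = rep(separation, n), phase = rep("extended", n),
      linePeriod = linePeriod, sequesteredPerDomain = footprintPerDomain)
}
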