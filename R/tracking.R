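## Single-particle tracking on kymographs: per-line peak detection with
## sub-pixel Gaussian localization, nearest-neighbour linking.

# Detect peaks in one scan line: local maxima of the 3-point smoothed
# counts exceeding background + threshold, localized by a Gaussian fit in a
# window around the peak. Returns data.frame(position_um, amplitude).
detectPeaksLine <- function(kymo, row, threshold, halfWindow = 4L) {
  y <- kymo@counts[row, ]
  np <- length(y)
  sm <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  sm[c(1, np)] <- y[c(1, np)]
  bg <- stats::median(y)
  isMax <- sm >= c(-Inf, sm[-np]) & sm >= c(sm[-1], -Inf) &
    sm > bg + threshold
  idx <- which(as.logical(isMax))
  # collapse runs of adjacent candidate pixels to the strongest one
  if (length(idx) > 1) {
    grp <- cumsum(c(1, diff(idx) > halfWindow))
    idx <- vapply(split(idx, grp), function(ii) ii[which.max(y[ii])],
                  integer(1))
  }
  out <- lapply(idx, function(i) {
    win <- seq.int(max(1L, i - halfWindow), min(np, i + halfWindow))
    if (length(win) < 5) return(NULL)
    f <- fitScanline(kymo, row, window = win)
    if (!f@converged || f@amplitude <= 0) return(NULL)
    data.frame(position_um = f@center, amplitude = f@amplitude)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(position_um = numeric(0),
                               amplitude = numeric(0))
  else out
}

#' Track particles through a kymograph
#'
#' Per scan line, Gaussian peaks above `threshold` photons over the local
#' background are detected and localized at sub-pixel precision; detections
#' are linked across lines by nearest neighbour within `maxJump` pixels
#' (ties broken by smallest displacement, then larger amplitude). Each
#' detection is assigned to at most one trajectory; a trajectory survives
#' up to `maxGap` lines without a detection. Tracking is deterministic for
#' a fixed kymograph and parameters.
#'
#' @param kymo a [Kymograph-class].
#' @param threshold detection threshold, photons above local background;
#'   default `2 * photonsPerFluor` of `cal` (or 3.0 photons without one).
#' @param cal optional [Calibration-class] supplying the default threshold.
#' @param maxJump maximum linking displacement per line, pixels; across a
#'   gap of `g` missed lines the allowance grows as `maxJump * sqrt(g + 1)`
#'   (Brownian spread).
#' @param maxGap maximum number of consecutive missed lines.
#' @param minLength minimum trajectory length, lines; shorter tracks are
#'   dropped (diffusion analysis needs well-sampled tracks).
#' @return List of [Trajectory-class] objects.
#' @export
trackKymograph <- function(kymo, threshold = NULL, cal = NULL, maxJump = 3,
                           maxGap = 5L, minLength = 10L) {
  stopifnot(is(kymo, "Kymograph"))
  if (is.null(threshold))
    threshold <- if (!is.null(cal)) 2 * cal@photonsPerFluor else 3.0
  d_um <- kymo@pixelSize / 1000
  nLines <- nrow(kymo@counts)
  active <- list()   # each: list(time, pos, amp, lastLine)
  done <- list()
  for (r in seq_len(nLines)) {
    det <- detectPeaksLine(kymo, r, threshold)
    tnow <- (r - 1) * kymo@linePeriod
    assigned <- rep(FALSE, nrow(det))
    if (length(active) && nrow(det)) {
      lastPos <- vapply(active, function(a) tail(a$pos, 1), numeric(1))
      gap <- vapply(active, function(a) r - a$lastLine, numeric(1))
      # candidate pairs within the (gap-scaled) jump allowance, greedy by
      # displacement then amplitude
      cand <- expand.grid(traj = seq_along(active), det = seq_len(nrow(det)))
      cand$disp <- abs(lastPos[cand$traj] - det$position_um[cand$det])
      cand <- cand[cand$disp <= maxJump * d_um * sqrt(gap[cand$traj]), ,
                   drop = FALSE]
      cand <- cand[order(cand$disp, -det$amplitude[cand$det]), , drop = FALSE]
      usedT <- rep(FALSE, length(active))
      for (i in seq_len(nrow(cand))) {
        ti <- cand$traj[i]; di <- cand$det[i]
        if (usedT[ti] || assigned[di]) next
        usedT[ti] <- TRUE; assigned[di] <- TRUE
        a <- active[[ti]]
        a$time <- c(a$time, tnow)
        a$pos <- c(a$pos, det$position_um[di])
        a$amp <- c(a$amp, det$amplitude[di])
        a$lastLine <- r
        active[[ti]] <- a
      }
    }
    # retire stale trajectories
    if (length(active)) {
      stale <- vapply(active, function(a) r - a$lastLine > maxGap, logical(1))
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    # open new trajectories for unmatched detections
    for (di in which(!assigned)) {
      active[[length(active) + 1L]] <- list(time = tnow,
                                            pos = det$position_um[di],
                                            amp = det$amplitude[di],
                                            lastLine = r)
    }
  }
  done <- c(done, active)
  # gap closing: re-join fragments split by a single outsized Brownian jump
  # or a missed stretch; allowance is looser than per-line linking
  if (length(done) > 1) {
    done <- done[order(vapply(done, function(a) a$time[1], numeric(1)))]
    merged <- TRUE
    while (merged && length(done) > 1) {
      merged <- FALSE
      for (i in seq_along(done)) {
        ei <- tail(done[[i]]$time, 1)
        pi <- tail(done[[i]]$pos, 1)
        for (j in seq_along(done)) {
          if (i == j) next
          sj <- done[[j]]$time[1]
          g <- round((sj - ei) / kymo@linePeriod)
          if (g < 1 || g > maxGap + 1) next
          if (abs(done[[j]]$pos[1] - pi) >
              maxJump * d_um * (sqrt(g) + 1)) next
          done[[i]] <- list(time = c(done[[i]]$time, done[[j]]$time),
                            pos = c(done[[i]]$pos, done[[j]]$pos),
                            amp = c(done[[i]]$amp, done[[j]]$amp),
                            lastLine = done[[j]]$lastLine)
          done[[j]] <- NULL
          merged <- TRUE
          break
        }
        if (merged) break
      }
    }
  }
  done <- Filter(function(a) length(a$time) >= minLength, done)
  lapply(done, function(a)
    trajectory(a$time, a$pos, a$amp, pixelSize = kymo@pixelSize))
}

#' Classify a trajectory as static or diffusive
#'
#' A trajectory is `static` when its positional spread stays below
#' `threshold` pixels: the median over sliding windows of `window` samples
#' of the positional standard deviation is compared to
#' `threshold * pixelSize`. At the default line period (20 ms) and window,
#' a particle diffusing at ~0.16 um^2/s accumulates a window sd of ~2
#' pixels, well above the threshold, while a static cluster stays at its
#' localization noise (a fraction of a pixel). Trajectories shorter than 10
#' samples are `ambiguous`.
#'
#' @param traj a [Trajectory-class].
#' @param window sliding-window length, samples.
#' @param threshold positional-sd threshold, pixels.
#' @return The trajectory with its `classification` slot filled in.
#' @export
classifyTrajectory <- function(traj, window = 20L, threshold = 1.5) {
  stopifnot(is(traj, "Trajectory"))
  n <- length(traj@position)
  if (n < 10L) {
    traj@classification <- "ambiguous"
    return(traj)
  }
  w <- min(window, n)
  sds <- vapply(seq_len(n - w + 1L), function(i)
    stats::sd(traj@position[i:(i + w - 1L)]), numeric(1))
  lim <- threshold * traj@pixelSize / 1000
  traj@classification <- if (stats::median(sds) < lim) "static" else "diffusive"
  traj
}

#' Dye stoichiometry of a trajectory
#'
#' Mean scan-line Gaussian amplitude along the trajectory divided by the
#' calibrated single-fluorophore yield: the number of active dyes carried by
#' the diffusing particle (4 for a fully labelled tetramer; 5 photons /
#' 1.5 photons = 3.3 dyes).
#'
#' @param traj a [Trajectory-class].
#' @param cal a [Calibration-class].
#' @return Dye count (real-valued).
#' @export
trajectoryStoichiometry <- function(traj, cal) {
  stopifnot(is(traj, "Trajectory"), is(cal, "Calibration"))
  mean(traj@amplitude, na.rm = TRUE) / cal@photonsPerFluor
}
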