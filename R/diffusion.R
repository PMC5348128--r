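#' Time-averaged mean-squared displacement
#'
#' For each lag `k`, averages the squared displacement over all ordered
#' pairs of samples separated by `k` lines:
#' `MSD(k dt) = mean((x[i+k] - x[i])^2)`. Sampling must be uniform: all
#' sample times must fall on a common grid of spacing `dt`. Missed scan
#' lines inside a tracked trajectory are allowed (pairs spanning them use
#' whatever samples exist at both ends of the lag); genuinely non-uniform
#' time stamps are an error.
#'
#' @param traj a [Trajectory-class], or a numeric position vector (then
#'   supply `linePeriod`).
#' @param maxLag largest lag, in samples (needs at least `maxLag + 2`
#'   samples).
#' @param linePeriod s per sample when `traj` is a plain vector.
#' @return data.frame with columns `lag` (index), `tau` (s), `msd` (um^2)
#'   and `n` (pairs averaged), including the `lag = 0` row.
#' @examples
#' msdCurve(c(0, 1, 0, 1), maxLag = 2, linePeriod = 1)
#' @export
msdCurve <- function(traj, maxLag = NULL, linePeriod = NULL) {
  if (is(traj, "Trajectory")) {
    dts <- diff(traj@time)
    dt <- min(dts)
    gridIdx <- round((traj@time - traj@time[1]) / dt)
    if (any(abs(traj@time - traj@time[1] - gridIdx * dt) > 1e-6 * dt))
      stop("trajectory is not uniformly sampled; MSD lags are undefined")
    x <- rep(NA_real_, max(gridIdx) + 1L)
    x[gridIdx + 1L] <- traj@position
  } else {
    x <- as.numeric(traj)
    if (is.null(linePeriod))
      stop("linePeriod is required when passing a plain position vector")
    dt <- linePeriod
  }
  n <- length(x)
  nObs <- sum(!is.na(x))
  if (is.null(maxLag)) maxLag <- min(nObs - 2L, 50L)
  stopifnot(maxLag >= 1, nObs >= maxLag + 2)
  lags <- 0:maxLag
  stat <- vapply(seq_len(maxLag), function(k) {
    d2 <- (x[(k + 1):n] - x[1:(n - k)])^2
    c(mean(d2, na.rm = TRUE), sum(!is.na(d2)))
  }, numeric(2))
  data.frame(lag = lags, tau = lags * dt,
             msd = c(0, stat[1, ]), n = c(nObs, stat[2, ]))
}

#' Fit a diffusion constant to an MSD curve
#'
#' Weighted linear fit `MSD = 2 D tau + offset` over the lag range
#' `fitRange` (weights = number of pairs per lag). The offset absorbs
#' localization noise, which is why lag 1 is excluded by default.
#'
#' @param curve output of [msdCurve()].
#' @param fitRange `(first, last)` lag indices used in the fit (>= 3 lags).
#' @return List with `D` (um^2/s), `se`, `offset` (um^2) and `flag`
#'   (`"ok"` or `"negative-D"`).
#' @examples
#' fitDiffusion(data.frame(lag = 1:10, tau = 1:10, msd = 0.32 * (1:10),
#'                         n = 100))$D  # 0.16
#' @export
fitDiffusion <- function(curve, fitRange = c(2, 10)) {
  stopifnot(all(c("tau", "msd", "n") %in% names(curve)))
  sel <- curve$lag >= fitRange[1] & curve$lag <= fitRange[2]
  if (sum(sel) < 3) stop("need at least 3 lags in the fit range")
  fit <- lm(msd ~ tau, data = curve[sel, ], weights = curve$n[sel])
  D <- unname(coef(fit)[2]) / 2
  se <- summary(fit)$coefficients["tau", "Std. Error"] / 2
  res <- list(D = D, se = unname(se), offset = unname(coef(fit)[1]),
              flag = if (D < 0) "negative-D" else "ok")
  if (D < 0) warning("fitted diffusion constant is negative")
  res
}

#' Parameters of the rotation-coupled sliding model
#'
#' A protein tracking the DNA helix advances `b` (one helical turn, 3.4 nm)
#' per revolution; its centre follows a helical path of radius
#' `R_OC = R + R_DNA`. Sliding across a corrugated free-energy landscape
#' with mean barrier `epsilon` (in kBT) further slows diffusion.
#'
#' @slot b displacement per helical turn, nm.
#' @slot epsilon mean free-energy barrier, kBT units.
#' @slot R protein radius, nm.
#' @slot R_DNA DNA radius, nm.
#' @slot R_OC helical-path radius, nm; must equal `R + R_DNA`.
#' @slot eta solvent viscosity, Pa s.
#' @slot temperature K.
#' @export
setClass("RotationModelParams", representation(
  b = "numeric", epsilon = "numeric", R = "numeric", R_DNA = "numeric",
  R_OC = "numeric", eta = "numeric", temperature = "numeric"
))

setValidity("RotationModelParams", function(object) {
  msg <- character()
  for (sl in c("b", "R", "R_DNA", "R_OC", "eta", "temperature"))
    if (slot(object, sl) <= 0)
      msg <- c(msg, sprintf("'%s' must be positive", sl))
  if (object@epsilon < 0) msg <- c(msg, "epsilon must be nonnegative")
  if (abs(object@R_OC - (object@R + object@R_DNA)) > 1e-9)
    msg <- c(msg, "R_OC must equal R + R_DNA")
  if (length(msg)) msg else TRUE
})

#' @param b,epsilon,R,R_DNA,eta,temperature see the corresponding slots.
#' @return `rotationModelParams()` returns a [RotationModelParams-class].
#' @rdname RotationModelParams-class
#' @export
rotationModelParams <- function(b = 3.4, epsilon = 1.33, R = 10, R_DNA = 1,
                                eta = 1e-3, temperature = 298) {
  new("RotationModelParams", b = b, epsilon = epsilon, R = R,
      R_DNA = R_DNA, R_OC = R + R_DNA, eta = eta, temperature = temperature)
}

setMethod("show", "RotationModelParams", function(object) {
  cat(sprintf(
    "RotationModelParams: b %g nm, eps %g kBT, R %g nm, R_OC %g nm, eta %g Pa s, T %g K\n",
    object@b, object@epsilon, object@R, object@R_OC, object@eta,
    object@temperature))
})

barrierFactor <- function(p, barrier) {
  switch(barrier,
         exponential = exp(-p@epsilon),
         rough = exp(-p@epsilon^2),
         stop("unknown barrier form: ", barrier))
}

#' Rotation-coupled 1D diffusion constant
#'
#' Hydrodynamic model of a sphere sliding while tracking the DNA helix:
#' \deqn{D = \frac{k_B T}{\xi_t + (2\pi/b)^2 \xi_r}\, e^{-\epsilon},}
#' with translational friction \eqn{\xi_t = 6\pi\eta R} and rotational
#' friction about the helix axis
#' \eqn{\xi_r = 8\pi\eta R^3 + 6\pi\eta R\, R_{OC}^2}. The barrier factor
#' is `exp(-epsilon)` by default; the rough-landscape alternative
#' `exp(-epsilon^2)` is available via `barrier = "rough"`. The returned
#' record always states which form was used and also carries the
#' barrier-free value.
#'
#' @param p a [RotationModelParams-class].
#' @param barrier `"exponential"` or `"rough"`.
#' @return List with `D` (um^2/s), `D_noBarrier`, `barrierForm`.
#' @export
rotationCoupledD <- function(p, barrier = c("exponential", "rough")) {
  stopifnot(is(p, "RotationModelParams"))
  barrier <- match.arg(barrier)
  kBT <- 1.380649e-23 * p@temperature            # J
  R <- p@R * 1e-9; Roc <- p@R_OC * 1e-9; b <- p@b * 1e-9
  xi_t <- 6 * pi * p@eta * R                     # N s / m
  xi_r <- 8 * pi * p@eta * R^3 + 6 * pi * p@eta * R * Roc^2  # N s m
  D0 <- kBT / (xi_t + (2 * pi / b)^2 * xi_r) * 1e12  # um^2/s
  list(D = D0 * barrierFactor(p, barrier), D_noBarrier = D0,
       barrierForm = barrier)
}

#' Purely translational 1D diffusion constant
#'
#' `D = kBT / (6 pi eta R)` times the same barrier factor as
#' [rotationCoupledD()]; the ratio of the two measures how much helical
#' tracking slows sliding (the barrier cancels in the ratio).
#'
#' @inheritParams rotationCoupledD
#' @return List with `D` (um^2/s), `D_noBarrier`, `barrierForm` and
#'   `ratioToRotation` (D_trans / D_rot).
#' @export
translationalD <- function(p, barrier = c("exponential", "rough")) {
  stopifnot(is(p, "RotationModelParams"))
  barrier <- match.arg(barrier)
  kBT <- 1.380649e-23 * p@temperature
  D0 <- kBT / (6 * pi * p@eta * p@R * 1e-9) * 1e12
  rot <- rotationCoupledD(p, barrier)
  list(D = D0 * barrierFactor(p, barrier), D_noBarrier = D0,
       barrierForm = barrier, ratioToRotation = D0 / rot$D_noBarrier)
}
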