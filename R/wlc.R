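#' Worm-like-chain force-extension law
#'
#' Entropic elasticity of a semiflexible polymer via the standard
#' interpolation formula
#' \deqn{F(x) = \frac{k_B T}{P}\left[\frac{1}{4(1-x/L)^2} - \frac{1}{4} +
#'   \frac{x}{L}\right],}
#' with persistence length \eqn{P} and contour length \eqn{L}. Enthalpic
#' stretching is ignored, which is adequate below ~30 pN for dsDNA.
#'
#' @param extension end-to-end distance, um (vectorized).
#' @param contourLength contour length, um.
#' @param persistenceLength persistence length, nm (50 for dsDNA).
#' @param temperature K.
#' @return Force in pN; `Inf` where `extension >= contourLength`
#'   (out of model).
#' @examples
#' wlcForce(15.3, 16.4)       # ~5 pN for lambda DNA
#' @export
wlcForce <- function(extension, contourLength, persistenceLength = 50,
                     temperature = 298) {
  stopifnot(contourLength > 0, persistenceLength > 0)
  if (any(extension < 0)) stop("extension must be nonnegative")
  z <- extension / contourLength
  f <- ifelse(z >= 1, Inf,
              kBT_pN_nm(temperature) / persistenceLength *
                (1 / (4 * (1 - z)^2) - 1 / 4 + z))
  f
}

#' Inverse worm-like-chain: extension at a given force
#'
#' Numerically inverts [wlcForce()] (which is strictly increasing in
#' extension).
#'
#' @param force pN (vectorized, positive).
#' @inheritParams wlcForce
#' @return End-to-end distance, um.
#' @export
wlcExtension <- function(force, contourLength, persistenceLength = 50,
                         temperature = 298) {
  stopifnot(all(force > 0))
  vapply(force, function(f) {
    stats::uniroot(function(x)
      wlcForce(x, contourLength, persistenceLength, temperature) - f,
      lower = 0, upper = contourLength * (1 - 1e-9), tol = 1e-12)$root
  }, numeric(1))
}

#' Simulate a force-distance curve for free or compacted DNA
#'
#' Generates a worm-like-chain force-extension record. Protein-compacted DNA
#' is modelled by an effective contour length
#' `contourLength - sequesteredLength - nLoops * persistenceLength`: bound
#' tetramers sequester DNA inside bridged clusters, and each cluster
#' additionally holds one persistence length of DNA in the loop at its end.
#' At any distance the compacted force is therefore above the free-DNA
#' force.
#'
#' @param config an [ExperimentConfig-class]; supplies the contour length and
#'   persistence length.
#' @param sequesteredLength total contour length sequestered by bound
#'   protein, um.
#' @param nLoops number of bridged clusters, each consuming one persistence
#'   length of DNA.
#' @param distances optional sampling grid, um; default covers 20-98.5% of
#'   the effective contour.
#' @param forceNoiseSd Gaussian measurement noise on force, pN.
#' @param seed RNG seed for the noise.
#' @return A [ForceDistanceCurve-class]; its metadata records the effective
#'   contour length.
#' @examples
#' fd <- simulateForceDistance(experimentConfig())
#' lengthAtForce(fd, 5)   # near 16 um
#' @export
simulateForceDistance <- function(config, sequesteredLength = 0, nLoops = 0,
                                  distances = NULL, forceNoiseSd = 0,
                                  seed = NA) {
  stopifnot(is(config, "ExperimentConfig"))
  L <- config@contourLength
  P <- config@persistenceLength
  if (sequesteredLength >= L)
    stop("sequesteredLength must be smaller than the contour length")
  Leff <- L - sequesteredLength - nLoops * P / 1000
  if (Leff <= 0)
    stop("effective contour length is non-positive (over-sequestered)")
  if (is.null(distances))
    distances <- seq(0.2 * Leff, 0.985 * Leff, length.out = 400)
  if (any(distances >= Leff))
    stop("requested distance at or beyond the effective contour length ",
         "(out of the worm-like-chain model)")
  force <- wlcForce(distances, Leff, P)
  force <- withSeed(seed,
    pmax(0, force + stats::rnorm(length(force), 0, forceNoiseSd)))
  lab <- if (sequesteredLength > 0 || nLoops > 0) "compacted" else "free"
  forceDistanceCurve(distances, force, label = lab,
                     metadata = list(effectiveContour_um = Leff,
                                     sequestered_um = sequesteredLength,
                                     nLoops = nLoops))
}

#' Interpolated DNA length at a readout force
#'
#' Linear interpolation of the force-distance samples bracketing the readout
#' force (25 pN in the footprint analysis, high enough to strip weak
#' nonspecific interactions).
#'
#' @param fd a [ForceDistanceCurve-class].
#' @param force readout force, pN.
#' @return End-to-end distance at that force, um.
#' @export
lengthAtForce <- function(fd, force = 25) {
  stopifnot(is(fd, "ForceDistanceCurve"))
  f <- fd@force
  d <- fd@distance
  if (force < min(f) || force > max(f))
    stop(sprintf("readout force %g pN outside the recorded range [%g, %g]",
                 force, min(f), max(f)))
  stats::approx(f, d, xout = force, ties = mean)$y
}
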