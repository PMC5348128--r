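## Footprint estimators: force-distance compaction and flow-box intensity.

#' Footprint per DNA-binding domain from force-distance compaction
#'
#' \deqn{f = \frac{\Delta L - n_{clusters} P}{2 N_{tetramers}},}
#' where \eqn{\Delta L} is the length difference between free and
#' protein-bound DNA at the 25 pN readout, one persistence length \eqn{P}
#' per cluster accounts for the DNA loop closing each bridged cluster, and
#' the factor 2 counts the two DNA-binding domains of each tetramer.
#'
#' @param lengthFree,lengthBound end-to-end distances at the readout force,
#'   um.
#' @param nClusters number of clusters on the molecule (>= 1).
#' @param nTetramers total tetramers on the molecule (>= nClusters).
#' @param persistenceLength nm.
#' @return List with `footprint` (nm per DNA-binding domain), `deltaL`
#'   (nm) and `valid` (FALSE when the loop allowance consumes the whole
#'   compaction, giving a non-positive footprint).
#' @examples
#' footprintFromCompaction(16.0, 15.0, 2, 150)$footprint  # 3.0 nm
#' @export
footprintFromCompaction <- function(lengthFree, lengthBound, nClusters,
                                    nTetramers, persistenceLength = 50) {
  stopifnot(lengthFree > lengthBound, nClusters >= 1,
            nTetramers >= nClusters, persistenceLength > 0)
  deltaL <- (lengthFree - lengthBound) * 1000  # nm
  f <- (deltaL - nClusters * persistenceLength) / (2 * nTetramers)
  list(footprint = f, deltaL = deltaL, valid = f > 0)
}

#' Reference intensity of a single fluorophore in a 2D image
#'
#' Total photon count of one fluorophore integrated over the image:
#' `I_ref = A * 2 * pi * (s / d)^2` for a Gaussian of peak amplitude `A`
#' and sd `s` sampled at pixel size `d` (16.8 photons for A = 1.5,
#' s = 100 nm, d = 75 nm).
#'
#' @param A single-dye Gaussian amplitude, photons.
#' @param s Gaussian sd, nm.
#' @param d pixel size, nm.
#' @return I_ref in photons.
#' @examples
#' boxReferenceIntensity(1.5, 100, 75)  # 16.8
#' @export
boxReferenceIntensity <- function(A = 1.5, s = 100, d = 75) {
  stopifnot(A >= 0, s > 0, d > 0)
  A * 2 * pi * (s / d)^2
}

#' Footprint from a flow-box intensity measurement
#'
#' Tetramer count and footprint from the background-subtracted photon count
#' of a box drawn over a bridged DNA segment:
#' `N = (I_box - I_bg) / (4 I_ref)` (four labels per tetramer) and
#' `footprint = boxLength / N`.
#'
#' @param Ibox total photons in the box.
#' @param Ibg total photons in an equal-sized adjacent background box.
#' @param boxLength box length along the DNA, nm.
#' @param Iref single-fluorophore reference intensity
#'   ([boxReferenceIntensity()]).
#' @param labelsPerTetramer fluorescent labels per tetramer.
#' @return List with `N` (tetramers), `footprint` (nm) and `valid`
#'   (FALSE with `footprint = NA` when `Ibox <= Ibg`).
#' @examples
#' footprintFromBox(672, 0, 1000, 16.8)  # N = 10, footprint = 100 nm
#' @export
footprintFromBox <- function(Ibox, Ibg, boxLength, Iref,
                             labelsPerTetramer = 4) {
  stopifnot(Ibox >= 0, Ibg >= 0, boxLength > 0, Iref > 0)
  N <- (Ibox - Ibg) / (labelsPerTetramer * Iref)
  if (N <= 0)
    return(list(N = N, footprint = NA_real_, valid = FALSE))
  list(N = N, footprint = boxLength / N, valid = TRUE)
}

#' Measure a flow-image box and estimate the footprint
#'
#' Sums photon counts in a pixel box around a bridged segment and in an
#' equal box offset perpendicular to the DNA for background, then applies
#' [footprintFromBox()] with `I_ref` computed from the optics.
#'
#' @param image photon-count matrix (rows = y), as from
#'   [simulateFlowImage()].
#' @param optics the [OpticsConfig-class] the image was acquired with.
#' @param cols pixel columns of the box (along the DNA).
#' @param rows pixel rows of the box (across the DNA; should span several
#'   PSF widths).
#' @param bgOffset row offset of the background box, pixels.
#' @return As [footprintFromBox()], plus `Ibox`, `Ibg` and `boxLength`.
#' @export
analyzeFlowBox <- function(image, optics, cols, rows, bgOffset = 15L) {
  stopifnot(is.matrix(image), all(cols >= 1), all(cols <= ncol(image)),
            all(rows >= 1), all(rows <= nrow(image)))
  bgRows <- rows + bgOffset
  if (any(bgRows > nrow(image)) || any(bgRows < 1))
    stop("background box falls outside the image; reduce bgOffset")
  Ibox <- sum(image[rows, cols])
  Ibg <- sum(image[bgRows, cols])
  A <- optics@photonsPerFluorPerLine *
    (optics@laserPower / optics@referencePower)
  Iref <- boxReferenceIntensity(A, optics@psfSd, optics@pixelSize)
  res <- footprintFromBox(Ibox, Ibg, length(cols) * optics@pixelSize, Iref)
  c(res, list(Ibox = Ibox, Ibg = Ibg,
              boxLength = length(cols) * optics@pixelSize))
}
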