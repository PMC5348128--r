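---
title: "Quantifying DNA-compaction kymographs: models, estimators and design choices"
author: "KymoQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA-compaction kymographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KymoQuant)
```

## The experiment being modelled

A single lambda-DNA molecule (48.5 kbp, contour length 16.4 µm) is tethered
between two optically trapped beads inside a microfluidic flow cell.
Fluorescently labelled SYCP3 — a strut-like tetramer with DNA-binding
domains at both ends, carrying four Alexa555 labels — binds the DNA, and a
confocal spot is scanned repeatedly along the tether. Stacking these line
scans gives a *kymograph*: rows are scan lines (time), columns are pixels
along the DNA, values are photon counts. In the compaction protocol the
tether is held at 16 µm (5 pN), relaxed to 8 µm at 0.6 µm/s, held ~5.5 s,
and re-extended. On extended DNA the tetramers slide diffusively; after
relaxation most of them co-localise into static clusters, the signature of
DNA bridging.

Four quantities are extracted from such data, and this package implements
an estimator for each plus a synthetic generator that emulates the whole
experiment with known ground truth:

1. the photon yield of a single fluorophore per scan line (from
   photobleaching steps), which calibrates cluster stoichiometry;
2. the number of tetramers per static cluster (bleaching-corrected Gaussian
   photometry);
3. the 1D diffusion constant of sliding tetramers (MSD analysis), compared
   with a rotation-coupled sliding model;
4. the DNA-binding footprint per DNA-binding domain, by two independent
   routes: force-distance compaction at 25 pN, and intensity boxes on
   flow-stretched bridged DNA.

## The synthetic generator

`simulateCompactionExperiment()` runs the pulling protocol above.
Tetramers perform discrete Brownian motion with per-step variance
$2D\,\Delta t$ and specular reflection at the bead positions; during
relaxation and hold each tetramer independently converts to a static
cluster member with probability `conversionProb` (default 0.9 — in the
real experiment "the majority" of molecules convert; no kinetics are
published, so conversion is phenomenological). Cluster sizes are drawn
from a lognormal truncated to [20, 160] tetramers whose location parameter
is solved so the truncated mean equals 67, matching the reported
population (mean 67, observed range 20–160). The shape parameter
(`sdlog = 0.45`) is chosen so that the expected extreme values of a
~15-cluster sample land near the reported range; it is a modelling choice,
not a published value.

`renderKymograph()` turns ground truth into photon counts. Each unbleached
fluorophore contributes a Gaussian profile (sd `psfSd` = 100 nm, the
average fitted spot width) centred on its position, with peak amplitude
`photonsPerFluorPerLine` = 1.5 photons — the calibrated single-Alexa555
scan-line amplitude — sampled at 75 nm pixels. Pixel values are Poisson
draws of signal plus a uniform background (default 0.2 photons/pixel/line,
a typical confocal dark/buffer level; not a published value). Emission
scales *linearly* with laser power while the photobleaching rate scales
*quadratically* (`rate = bleachRateAtReference * (P/P_ref)^2`), following
the two-photon bleaching interpretation of the measured power dependence.
The measured factor-10 rate change between 2.9 and 6.4 µW actually exceeds
the quadratic prediction (~4.9x); the generator follows the quadratic law
and we note the discrepancy rather than resolve it. The line period is not
published; the default 20 ms is a typical confocal line rate and every
estimator takes the period as data.

`simulateForceDistance()` uses the standard worm-like-chain interpolation
formula with persistence length 50 nm, ignoring enthalpic stretching
(adequate below ~30 pN). Compacted DNA has effective contour
`L - sequestered - nClusters * P`: each bound tetramer sequesters twice
its per-domain footprint and each cluster holds one persistence length in
its terminal loop. `simulateFlowImage()` renders bridged segments at label
density `4 / footprint` per nm: in the bridged geometry one tetramer
engages two parallel DNA molecules at the same axial position, so it
occupies one footprint of axis length and carries four labels.

What the generator does *not* emulate: polymer dynamics of the relaxed
coil, trap-bead mechanics and force noise beyond a Gaussian error term,
protein unbinding (the bleaching-correction assumption is zero
dissociation, exactly as in the analysis), partial labelling (supported as
a parameter but off by default), and non-Gaussian PSF tails. Recovery
tests against this generator therefore validate the estimators'
arithmetic and their behaviour under shot noise — not instrument
systematics.

## Estimators and numerical choices

**Scan-line photometry.** `fitScanline()` fits
$bg + A e^{-(x-c)^2/2s^2}$ by Levenberg–Marquardt least squares
(`minpack.lm`), with moment-based starting values and box constraints
(nonnegative amplitude and background, width at least a quarter pixel).
Non-convergence is flagged (`goodness = Inf`), never silent; a constant
profile short-circuits to amplitude 0. Amplitudes are *peak* photons per
scan line, the unit in which the 1.5 photons/fluorophore and 6.0
photons/tetramer calibration is expressed.

**Step detection.** No published algorithm accompanies the bleaching-step
analysis, so `detectBleachSteps()` uses penalized least-squares
changepoint segmentation (optimal partitioning, SIC-type penalty
$2\hat\sigma^2\log n$ with $\hat\sigma$ from the MAD of first
differences, minimum plateau 5 lines; `bleachStepAmplitudes()` uses 10).
It is deterministic given the trace. Only *decreases* between consecutive
plateaus count as bleaching steps; each plateau's amplitude comes from a
Gaussian fit to its row-averaged profile, so step sizes are in calibration
units. For calibration simulations we set the cascade bleach rate so that
expected inter-bleach gaps (≥ 1/(4k)) are an order of magnitude longer
than the minimum plateau; when gaps approach the plateau resolution,
merged double-steps inflate the mean step size.

**Bleaching correction.** `bleachCorrectionFactor()` returns
$I_{total}(0)/I_{total}(t)$ summed over the DNA band. Unlike a
single-time-point readout it averages 10 lines at each endpoint to tame
shot noise; background can be subtracted when known. `t = 0` returns
exactly 1.

**Tracking.** Detection threshold defaults to twice the single-fluorophore
yield above local background; peaks are localized by a windowed Gaussian
fit (sub-pixel). Linking is nearest-neighbour with a 3 pixel/line jump
allowance — about 2.8 standard deviations of the Brownian step at
D = 0.16 µm²/s and 20 ms lines — growing as $\sqrt{g}$ across gaps of
$g$ missed lines (up to 5), with ties broken by smallest displacement and
then larger amplitude. A second pass re-joins fragments split by a single
outsized jump. Trajectories shorter than 10 lines are dropped from
analysis. These defaults are declared, not inferred from the original
tracking software, whose parameters are unpublished.

**Classification.** A trajectory is *static* when the median sliding-window
(20-sample) positional sd is below 1.5 pixels. At the default line period
a particle at 0.16 µm²/s accumulates ~2 pixels of window sd, while a
static cluster sits at its localization noise (well under a pixel), so
the rule separates the two regimes with margin.

**Diffusion.** `msdCurve()` is the time-averaged MSD over all ordered
pairs, tolerating missing lines on a uniform grid; `fitDiffusion()` fits
$\mathrm{MSD} = 2D\tau + c$ by weighted least squares over lags 2–10. Lag 1
is excluded because it is the most localization-noise-contaminated point;
the intercept absorbs the (static) localization error. The brute-force
pair enumeration serves as the test oracle.

**Rotation-coupled sliding.** `rotationCoupledD()` implements
$D = k_BT\,/\,[\xi_t + (2\pi/b)^2 \xi_r]\cdot e^{-\epsilon}$ with
$\xi_t = 6\pi\eta R$ and $\xi_r = 8\pi\eta R^3 + 6\pi\eta R R_{OC}^2$ —
the published form of the cited hydrodynamic model. Viscosity and
temperature are not stated in the source analysis; defaults are
$10^{-3}$ Pa·s and 298 K. The barrier factor is $e^{-\epsilon}$ by
default; the rough-landscape alternative $e^{-\epsilon^2}$ is available
as `barrier = "rough"`, and the output always states which form was used.
With the quoted parameter set (b = 3.4 nm, ε = 1.33 k~B~T, R = 10 nm,
R~OC~ = 11 nm) this form evaluates to ~0.0066 µm²/s — not the measured
0.16 µm²/s — and the translational/rotational ratio is ~870 rather than
~20. We deliberately report the computed value instead of adjusting
parameters to match: the exact algebraic form used in the original
calculation is not reproduced in the text, and transparency beats
agreement.

**Footprints.** `footprintFromCompaction()` is
$f = (\Delta L - n_{cl} P)/(2N_{tet})$ with the 25 pN readout obtained by
linear interpolation of the bracketing force-distance samples; a
non-positive result is returned with `valid = FALSE` rather than clipped.
`footprintFromBox()` is $N = (I_{box}-I_{bg})/(4 I_{ref})$,
$f = L_{box}/N$, with $I_{ref} = A\,2\pi(s/d)^2$ (16.8 photons at the
default optics). The factor 4 counts labels per tetramer and is kept
fixed; with partial labelling it would overestimate the footprint
proportionally. In flow-image analysis the measurement box should sit
inside a longer bridged segment, so that PSF spill-out at the box ends is
balanced by spill-in; the background box is offset perpendicular to the
DNA by several PSF widths. An "apparent footprint" computed on
non-bridged DNA by the same formula is a control, not a footprint: without
bridging the density assumption (one tetramer per footprint of axis) does
not hold.

## Problem sizes used in the tests

Recovery tests run at sizes chosen to keep the whole suite fast while
leaving comfortable Monte-Carlo margins: 10 bleach cascades of 3000 lines
for step calibration (~40 steps); 200 clusters of 1000 lines each for the
cluster-size population (sampling error of the truncated-lognormal mean
~2.2 tetramers); 8 trajectories of 875 lines at 0.16 µm²/s for diffusion;
3 force-distance molecule pairs and 13 flow boxes for the footprints.
These are the same routines a real analysis would call, only on smaller
populations than an instrument would collect.

## Known limitations

* Cluster formation is phenomenological; the generator cannot test
  bridging kinetics or cooperativity, only the photometry built on top.
* Tracking uses nearest-neighbour linking; crossing trajectories are not
  disambiguated, so crowded kymographs fragment into shorter tracks
  (their MSDs remain valid).
* The bleaching correction inherits the zero-dissociation assumption; if
  molecules unbind, cluster sizes are overestimated. This is documented,
  not validated.
* The rotation-coupled model is for a sphere; SYCP3 is a 20 nm strut.
  The computed model value is reported alongside measurements, never
  fitted.
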