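# KymoQuant

Quantitative analysis of single-molecule confocal kymographs from
optical-tweezers DNA-compaction assays, built around the experiment in
which fluorescently labelled SYCP3 — the strut-like tetramer of the
meiotic chromosome axis, with DNA-binding domains at both ends — slides
on, bridges and compacts a tethered lambda-DNA molecule.

The package is for single-molecule biophysicists who record kymographs
(repeated confocal line scans along a DNA tether; rows = time, columns =
pixels, values = photon counts), force-distance curves, and flow-cell
images, and want the complete quantification chain with a synthetic
generator to validate every step against known ground truth.

## What it computes

| quantity | estimator | core relation |
|---|---|---|
| single-fluorophore photon yield | photobleaching-step calibration | mean Gaussian-amplitude drop per step; tetramer yield = 4x |
| cluster stoichiometry | bleaching-corrected photometry | `tetramers = A * (I_tot,0 / I_tot,t) / 6.0` |
| 1D diffusion constant | time-averaged MSD | `MSD(tau) = 2 D tau + offset`, weighted fit over lags 2-10 |
| rotation-coupled sliding model | hydrodynamic sphere on a helix | `D = kBT / (6 pi eta R + (2 pi / b)^2 (8 pi eta R^3 + 6 pi eta R R_OC^2)) * exp(-eps)` |
| footprint (compaction route) | 25 pN force-distance readout | `f = (dL - n_clusters * P) / (2 N_tetramers)` |
| footprint (flow-box route) | box photometry on bridged DNA | `N = (I_box - I_bg) / (4 I_ref)`, `I_ref = A * 2 pi (s/d)^2`, `f = L_box / N` |

The synthetic generator emulates the full experiment: Brownian sliding
with reflecting bead boundaries, Poisson photon counting through a 100 nm
Gaussian profile at 75 nm pixels (1.5 photons/fluorophore/line),
exponential photobleaching with quadratic laser-power dependence,
worm-like-chain mechanics (persistence length 50 nm), the
16 um -> 8 um -> 16 um pulling protocol, and flow-stretched bridged-DNA
images.

## Worked example

```r
library(KymoQuant)

## calibration: 1.5 photons per dye per scan line, 6.0 per tetramer
cal <- calibration(1.5)

## render a static 67-tetramer cluster and photometer it back
truth <- staticClusterTruth(67, positions = 2, duration = 20, separation = 4)
kymo  <- renderKymograph(truth, opticsConfig(), seed = 7)
est   <- estimateClusterFromKymo(kymo, cal, t = 10, background = 0.2)

## a diffusing tetramer: MSD fit of a simulated trajectory
pos <- simulateTrajectory(0.16, 16, 17.5, seed = 1, x0 = 8)
fit <- fitDiffusion(msdCurve(pos, maxLag = 10, linePeriod = 0.02))

boxReferenceIntensity(1.5, 100, 75)        # single-dye 2D reference
footprintFromCompaction(16.0, 15.0, 2, 150)  # 25 pN footprint formula
```

Output from this session:

```
Kymograph: 1000 scan lines x 54 pixels | 75 nm/px, 0.02 s/line | total 1.354e+06 photons
cluster size: 66.6 tetramers (amplitude 397.3 photons, correction 1.0066)
D = 0.119 +/- 0.002 um^2/s
I_ref = 16.8 photons
compaction footprint = 3.0 nm
```

The cluster comes back at 66.6 of 67 planted tetramers (the Gaussian
amplitude 397 photons is divided by the 6.0 photons/tetramer calibration
and multiplied by the bleaching correction). The single 17.5 s trajectory
gives D = 0.119 µm²/s — individual trajectories scatter around the true
0.16 µm²/s; averaging several (as the estimators do) recovers the mean.
I_ref = 16.8 photons and the 3.0 nm footprint are the exact worked
arithmetic of the two footprint formulas.

`runPipeline()` chains every stage (simulate, render, track, classify,
photometry, diffusion, footprints) into a schema-validated JSON bundle;
`inst/scripts/run_pipeline.R` is a command-line wrapper. Kymographs read
and write as single-plane 16-bit grayscale TIFF or CSV with a YAML
metadata sidecar (`readKymograph()` / `writeKymograph()`).

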