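test_that("Brownian trajectory generator has the right step statistics", {
  # zero diffusion: constant path
  x0 <- simulateTrajectory(0, 16, 1, seed = 1)
  expect_true(all(x0 == x0[1]))

  # step variance matches 2 D dt within 5% at 10^4 steps
  x <- simulateTrajectory(0.16, 1e3, 200, linePeriod = 0.02, seed = 2,
                          x0 = 500)
  expect_gt(length(x), 9999)
  expect_equal(var(diff(x)), 2 * 0.16 * 0.02, tolerance = 0.05)

  # reproducible given the seed
  expect_identical(simulateTrajectory(0.16, 16, 2, seed = 7),
                   simulateTrajectory(0.16, 16, 2, seed = 7))
  expect_error(simulateTrajectory(-0.1, 16, 1), "nonnegative")
})

test_that("boundaries reflect: positions stay on the tether", {
  # violent diffusion on a short tether: every step proposes an excursion
  x <- simulateTrajectory(50, 0.5, 20, linePeriod = 0.02, seed = 3)
  expect_true(all(x >= 0 & x <= 0.5))
  # empirical MSD slope still matches at moderate D (5% at 1e5 steps)
  x <- simulateTrajectory(0.16, 1e3, 2000, linePeriod = 0.02, seed = 4,
                          x0 = 500)
  msd <- msdCurve(x[1:1e5], maxLag = 1, linePeriod = 0.02)
  expect_equal(msd$msd[2], 2 * 0.16 * 0.02, tolerance = 0.05)
})

test_that("compaction experiment honours the conversion probability", {
  base <- experimentConfig(nTetramers = 30, extendedTime = 1, postTime = 1,
                           holdTime = 1, seed = 11)
  none <- simulateCompactionExperiment(
    `slot<-`(base, "conversionProb", value = 0))
  expect_true(all(is.na(none$truth@clusterId)))
  all_ <- simulateCompactionExperiment(
    `slot<-`(base, "conversionProb", value = 1))
  expect_true(all(!is.na(all_$truth@clusterId)))
  # separation timeline follows the protocol
  sep <- all_$separation$separation_um
  expect_equal(max(sep), 16)
  expect_equal(min(sep), 8)
  expect_true(all(diff(sep) <= 0.6 * 0.02 + 1e-9))
})

test_that("cluster sizes follow the configured truncated distribution", {
  s <- sampleClusterSizes(4000, mean = 67, range = c(20, 160),
                          seed = 5)
  expect_true(all(s >= 20 & s <= 160))
  # configured mean recovered within sampling error (se ~ 0.5)
  expect_equal(mean(s), 67, tolerance = 0.03)
})

test_that("renderer conserves photons in expectation", {
  opt <- stableOptics(backgroundRate = 0.1)
  truth <- staticClusterTruth(1, positions = 2, duration = 100,
                              separation = 4, fluorsPerTetramer = 1)
  k <- renderKymograph(truth, opt, seed = 6)
  # time-average of Poisson counts matches the deterministic field
  expected <- 1.5 * exp(-(((1:54) - 0.5) * 0.075 - 2)^2 / (2 * 0.1^2)) + 0.1
  got <- colMeans(counts(k))
  expect_lt(max(abs(got - expected)), 4 * sqrt(max(expected) / nrow(counts(k))))
  expect_equal(sum(got), sum(expected), tolerance = 0.01)
})

test_that("renderer edge cases: no emitters, and noise-free rendering", {
  empty <- staticClusterTruth(1, positions = 1, duration = 0.5,
                              separation = 2)
  empty@positions <- empty@positions[, 0, drop = FALSE]
  empty@clusterId <- integer(0)
  empty@fluorTetramer <- integer(0)
  k0 <- renderKymograph(empty, stableOptics(backgroundRate = 0), seed = 1)
  expect_true(all(counts(k0) == 0))

  # noise-free single tetramer: Gaussian fit returns the planted amplitude
  kq <- renderKymograph(staticClusterTruth(1, positions = 2, duration = 0.5,
                                           separation = 4),
                        stableOptics(backgroundRate = 0), noise = FALSE)
  f <- fitScanline(kq, 1)
  expect_equal(f@amplitude, 6.0, tolerance = 1e-3)
  expect_equal(f@center, 2.0, tolerance = 1e-2)
})

test_that("single-fluorophore scan-line amplitude calibrates near 1.5 photons", {
  opt <- stableOptics(backgroundRate = 0.2)
  truth <- staticClusterTruth(1, positions = 2, duration = 40,
                              separation = 4, fluorsPerTetramer = 1)
  k <- renderKymograph(truth, opt, seed = 8)
  amps <- vapply(seq(1, 1901, by = 100), function(r)
    fitScanline(k, r:(r + 99))@amplitude, numeric(1))
  expect_equal(mean(amps), 1.5, tolerance = 0.1)
})

test_that("rendered bleaching decays at the configured rate", {
  opt <- opticsConfig(linePeriod = 0.5, bleachRateAtReference = 0.02,
                      backgroundRate = 0.1)
  truth <- staticClusterTruth(50, positions = 2, duration = 100,
                              separation = 4, linePeriod = 0.5)
  k <- renderKymograph(truth, opt, seed = 9)
  est <- estimateBleachRate(k, background = 0.1)
  expect_true(est$converged)
  expect_equal(est$rate, 0.02, tolerance = 0.15)
  # surviving fraction at t matches exp(-k t) within binomial error
  bt <- k@metadata$bleachTimes
  surv <- mean(bt > 50)
  p <- exp(-0.02 * 50)
  expect_lt(abs(surv - p), 4 * sqrt(p * (1 - p) / length(bt)))
})

test_that("bleach times scale quadratically with laser power", {
  o2 <- opticsConfig(laserPower = 12.8, bleachRateAtReference = 1e-3)
  bt <- drawBleachTimes(4000, o2, seed = 10)
  # doubled power -> 4x rate -> mean time 1/(4e-3)
  expect_equal(mean(bt), 250, tolerance = 0.1)
  expect_identical(drawBleachTimes(3, opticsConfig(bleachRateAtReference = 0)),
                   rep(Inf, 3))
})

test_that("worm-like chain behaves: monotone, lambda DNA near 16 um at 5 pN", {
  ext <- seq(1, 16.2, by = 0.1)
  f <- wlcForce(ext, 16.4)
  expect_true(all(diff(f) > 0))                     # increasing in extension
  expect_true(all(wlcForce(10, c(16.4)) > wlcForce(10, 18)))  # decreasing in L
  expect_equal(wlcExtension(5, 16.4), 16, tolerance = 0.05)
  expect_equal(wlcForce(wlcExtension(25, 16.4), 16.4), 25, tolerance = 1e-9)
  expect_identical(wlcForce(17, 16.4), Inf)
})

test_that("compacted force-distance curves sit above the free curve", {
  cfg <- experimentConfig()
  grid <- seq(4, 14, by = 0.5)
  free <- simulateForceDistance(cfg, distances = grid)
  expect_identical(free@label, "free")
  comp <- simulateForceDistance(cfg, sequesteredLength = 0.8, nLoops = 3,
                                distances = grid)
  expect_identical(comp@label, "compacted")
  expect_true(all(comp@force > free@force))
  # zero sequestration: identical to the free curve
  same <- simulateForceDistance(cfg, 0, 0, distances = grid)
  expect_equal(same@force, free@force)
  # out-of-model distances are refused
  expect_error(simulateForceDistance(cfg, distances = c(10, 16.41)),
               "out of the worm-like-chain")
})

test_that("flow images: empty input gives background only, density is linear", {
  opt <- opticsConfig()
  bgOnly <- simulateFlowImage(data.frame(x0 = numeric(0), x1 = numeric(0),
                                         y = numeric(0)),
                              optics = opt, seed = 12)
  expect_lt(abs(mean(bgOnly$image) - opt@backgroundRate),
            4 * sqrt(opt@backgroundRate / length(bgOnly$image)))
  expect_equal(nrow(bgOnly$fluors), 0)

  # doubling the label density (halving the planted footprint) halves the
  # recovered footprint
  segs <- data.frame(x0 = 800, x1 = 3800, y = 1500)
  cols <- seq.int(round(1300 / 75), round(3300 / 75))
  rec <- vapply(c(3.6, 1.8), function(fp) {
    fl <- simulateFlowImage(segs, footprint = fp, optics = opt, seed = 13)
    rc <- round(1500 / 75)
    analyzeFlowBox(fl$image, opt, cols, seq.int(rc - 6, rc + 6),
                   bgOffset = 12)$footprint
  }, numeric(1))
  expect_equal(rec[1] / rec[2], 2, tolerance = 0.1)
})

test_that("object validity catches bad inputs", {
  expect_error(kymograph(matrix(c(-1, 0, 1, 2), 2)), "nonnegative")
  expect_error(kymograph(matrix(c(0.5, 0, 1, 2), 2)), "integer")
  expect_error(opticsConfig(psfSd = 10), "resolvable")
  expect_error(experimentConfig(relaxedSeparation = 17), "relaxedSeparation")
  expect_error(trajectory(c(1, 1), c(0, 0)), "strictly increasing")
})
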