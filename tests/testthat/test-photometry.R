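test_that("scan-line Gaussian fit recovers exact and noisy amplitudes", {
  # exact noiseless Gaussian, amplitude 6.0 over background 1
  px <- 75 / 1000
  x <- (seq_len(41) - 0.5) * px
  y <- 1 + 6 * exp(-(x - 1.5)^2 / (2 * 0.1^2))
  k <- kymograph(matrix(round(y * 1000), 1), pixelSize = 75,
                 linePeriod = 0.02)
  # counts are integers; scale up so rounding is negligible
  f <- fitScanline(k, 1)
  expect_true(f@converged)
  expect_equal(f@amplitude / 1000, 6.0, tolerance = 1e-3)
  expect_equal(f@center, 1.5, tolerance = 1e-3)
  expect_equal(f@width, 100, tolerance = 1e-2)

  # flat background: amplitude ~ 0
  kf <- kymograph(matrix(5L, 20, 41), pixelSize = 75, linePeriod = 0.02)
  ff <- fitScanline(kf, 1)
  expect_equal(ff@amplitude, 0, tolerance = 1e-6)

  # Poisson-noised amplitude 402: mean over 100 scan lines within 2%
  truth <- staticClusterTruth(67, positions = 1.5, duration = 2,
                              separation = 3)
  kk <- renderKymograph(truth, stableOptics(backgroundRate = 0.2), seed = 21)
  amps <- vapply(1:100, function(r) fitScanline(kk, r)@amplitude, numeric(1))
  expect_equal(mean(amps), 402, tolerance = 0.02)

  expect_error(fitScanline(k, 1, window = 1:3), "at least 5")
  expect_error(fitScanline(k, 5), "row outside")
})

test_that("bleach-step detection finds plateau decreases", {
  # noiseless single drop 6.0 -> 4.5: one step of 1.5
  st <- detectBleachSteps(c(rep(6, 30), rep(4.5, 30)), linePeriod = 1)
  expect_equal(nrow(st), 1)
  expect_equal(st$size, 1.5)
  expect_equal(st$line, 31)

  # constant trace: no steps
  expect_equal(nrow(detectBleachSteps(rep(5, 40))), 0)
  # upward jumps are not bleaching steps
  expect_equal(nrow(detectBleachSteps(c(rep(2, 30), rep(5, 30)))), 0)
  expect_error(detectBleachSteps(rep(1, 10)), "at least 20")
})

test_that("bleach cascade photometry recovers ~1.5 photons per step", {
  opt <- opticsConfig(linePeriod = 0.05, bleachRateAtReference = 0.1,
                      backgroundRate = 0.2)
  steps <- c()
  for (i in 1:4) {
    truth <- staticClusterTruth(1, positions = 1.5, duration = 120,
                                separation = 3, linePeriod = 0.05)
    k <- renderKymograph(truth, opt, seed = 30 + i)
    steps <- c(steps, bleachStepAmplitudes(k))
  }
  expect_gt(length(steps), 8)
  expect_equal(mean(steps), 1.5, tolerance = 0.15)
})

test_that("calibration is the mean step size with an exact 4x tetramer yield", {
  cal <- suppressWarnings(calibrateSingleFluorophore(c(1.0, 2.0)))
  expect_identical(photonsPerFluor(cal), 1.5)
  expect_identical(photonsPerTetramer(cal), 6.0)
  cal2 <- suppressWarnings(calibrateSingleFluorophore(rep(1.5, 5)))
  expect_identical(photonsPerTetramer(cal2), 4 * photonsPerFluor(cal2))
  expect_error(calibrateSingleFluorophore(numeric(0)), "no bleaching steps")
  expect_warning(calibrateSingleFluorophore(c(1, 2)), "fewer than 10")
})

test_that("bleaching correction factor is the I_total ratio", {
  # identity at t = 0 for any kymograph
  truth <- staticClusterTruth(10, positions = 2, duration = 10,
                              separation = 4)
  k <- renderKymograph(truth, stableOptics(), seed = 41)
  expect_identical(bleachCorrectionFactor(k, 0), 1.0)

  # no bleaching, no noise: 1 at all times
  kq <- renderKymograph(truth, stableOptics(backgroundRate = 0),
                        noise = FALSE)
  expect_equal(bleachCorrectionFactor(kq, 5), 1.0, tolerance = 1e-3)

  # synthetic exponential decay: factor ~ exp(+k t)
  n <- 500; dt <- 0.02; kr <- 0.5
  decay <- exp(-kr * (seq_len(n) - 1) * dt)
  cts <- round(outer(decay, rep(1000, 20)))
  kd <- kymograph(cts, pixelSize = 75, linePeriod = dt)
  # band-averaged readout: compare to exp(k * (tbar_t - tbar_0)) with the
  # band mean times 3.91 s and 0.09 s
  expect_equal(bleachCorrectionFactor(kd, 4, band = 10),
               exp(kr * (3.91 - 0.09)), tolerance = 0.005)
  expect_error(bleachCorrectionFactor(kd, 100), "beyond the end")
})

test_that("cluster-size estimator is exact arithmetic on its inputs", {
  cal <- calibration(1.5)
  mkfit <- function(a) new("ScanlineFit", amplitude = a, center = 5,
                           width = 100, background = 0, goodness = 0,
                           converged = TRUE)
  expect_equal(estimateClusterSize(mkfit(6), cal, 1)$tetramers, 1)
  expect_equal(estimateClusterSize(mkfit(402), cal, 1)$tetramers, 67)
  expect_equal(estimateClusterSize(mkfit(201), cal, 2)$tetramers, 67)
  # exactly linear in amplitude and in the correction factor
  for (a in c(10, 50, 300)) for (corr in c(1, 1.5, 3)) {
    expect_identical(estimateClusterSize(mkfit(a), cal, corr)$tetramers,
                     a * corr / 6)
  }
  bad <- new("ScanlineFit", amplitude = NA_real_, center = NA_real_,
             width = NA_real_, background = NA_real_, goodness = Inf,
             converged = FALSE)
  expect_error(estimateClusterSize(bad, cal, 1), "non-converged")
})

test_that("cluster recovery end to end across the reported size range", {
  cal <- calibration(1.5)
  opt <- opticsConfig()
  for (S in c(20, 67, 160)) {
    est <- vapply(1:6, function(i) {
      truth <- staticClusterTruth(S, positions = 2, duration = 20,
                                  separation = 4)
      k <- renderKymograph(truth, opt, seed = 50 + 10 * S + i)
      estimateClusterFromKymo(k, cal, t = 10,
                              background = 0.2)$tetramers
    }, numeric(1))
    expect_equal(mean(est), S, tolerance = 0.1)
  }
})

test_that("bleach-rate estimation: exact, degenerate and noisy inputs", {
  tt <- seq(0, 40000, by = 400)
  # noiseless exponential at the reported rate
  est <- estimateBleachRate(1e4 * exp(-5e-5 * tt), linePeriod = 400)
  expect_equal(est$rate, 5e-5, tolerance = 1e-6)
  expect_false(est$wideConfidence)
  # constant trace: zero rate, flagged poorly constrained
  est0 <- estimateBleachRate(rep(500, 100), linePeriod = 1)
  expect_equal(est0$rate, 0)
  expect_true(est0$wideConfidence)
})

test_that("bleaching-rate power dependence fits a log-log exponent", {
  expect_equal(fitPowerExponent(c(1, 4, 9), c(1, 2, 3)), 2)
  expect_equal(fitPowerExponent(c(2, 4, 6), c(1, 2, 3)), 1)
  expect_error(fitPowerExponent(c(0, 1), c(1, 2)), "positive")
  expect_error(fitPowerExponent(c(1, 2), c(3, 3)), "distinct")

  # generator at three powers: recovered exponent ~ 2
  rates <- vapply(c(2.9, 4.5, 6.4), function(p) {
    opt <- opticsConfig(linePeriod = 0.5, laserPower = p,
                        bleachRateAtReference = 0.02, backgroundRate = 0.1)
    truth <- staticClusterTruth(60, positions = 2, duration = 300,
                                separation = 4, linePeriod = 0.5)
    k <- renderKymograph(truth, opt, seed = round(60 + p * 10))
    estimateBleachRate(k, background = 0.1)$rate
  }, numeric(1))
  expect_equal(fitPowerExponent(rates, c(2.9, 4.5, 6.4)), 2,
               tolerance = 0.1)
})
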