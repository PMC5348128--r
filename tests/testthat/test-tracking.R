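test_that("immobile noiseless emitters are tracked one-to-one", {
  opt <- stableOptics(backgroundRate = 0)
  k1 <- renderKymograph(staticClusterTruth(1, positions = 2, duration = 1,
                                           separation = 6),
                        opt, noise = FALSE)
  trs <- trackKymograph(k1, cal = calibration(1.5))
  expect_length(trs, 1)
  expect_equal(diff(range(trs[[1]]@position)), 0, tolerance = 1e-9)

  # two well-separated immobile emitters -> two trajectories
  k2 <- renderKymograph(staticClusterTruth(c(1, 1), positions = c(1.5, 4.5),
                                           duration = 1, separation = 6),
                        opt, noise = FALSE)
  trs2 <- trackKymograph(k2, cal = calibration(1.5))
  expect_length(trs2, 2)
  pos <- sort(vapply(trs2, function(t) t@position[1], numeric(1)))
  expect_equal(pos, c(1.5, 4.5), tolerance = 1e-2)
})

test_that("tracked positions equal the sub-pixel Gaussian centers", {
  # tracker localization must agree with a direct windowed Gaussian fit
  opt <- stableOptics(backgroundRate = 0)
  pos <- simulateTrajectory(0.05, 6, 0.6, seed = 71, x0 = 3)
  k <- renderKymograph(singleEmitterTruth(pos, separation = 6), opt,
                       noise = FALSE)
  tr <- trackKymograph(k, cal = calibration(1.5))[[1]]
  rows <- round(tr@time / linePeriod(k)) + 1
  direct <- vapply(seq_along(rows), function(i) {
    y <- counts(k)[rows[i], ]
    sm <- stats::filter(y, rep(1 / 3, 3), sides = 2)  # tracker's smoother
    px <- which.max(sm[-c(1, length(y))]) + 1L
    win <- seq.int(px - 4, px + 4)
    fitScanline(k, rows[i], window = win)@center
  }, numeric(1))
  expect_lt(max(abs(tr@position - direct)) / (pixelSize(k) / 1000), 1e-3)
})

test_that("a diffusing tetramer is recovered close to the generator truth", {
  opt <- stableOptics(backgroundRate = 0.2)
  pos <- simulateTrajectory(0.16, 16, 17.5, seed = 72, x0 = 8)
  k <- renderKymograph(singleEmitterTruth(pos), opt, seed = 73)
  trs <- trackKymograph(k, cal = calibration(1.5))
  expect_gt(length(trs), 0)
  tl <- trs[[which.max(vapply(trs, length, integer(1)))]]
  expect_gt(length(tl), 400)  # covers most of the 875-line trace
  idx <- round(tl@time / 0.02) + 1
  rms_px <- sqrt(mean((tl@position - pos[idx])^2)) / 0.075
  expect_lt(rms_px, 1)
})

test_that("tracking is deterministic and trajectories never share detections", {
  opt <- stableOptics(backgroundRate = 0.2)
  pos <- simulateTrajectory(0.16, 16, 6, seed = 74, x0 = 8)
  k <- renderKymograph(singleEmitterTruth(pos), opt, seed = 75)
  a <- trackKymograph(k, cal = calibration(1.5))
  b <- trackKymograph(k, cal = calibration(1.5))
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))
  # no (time, position) detection appears in two trajectories
  allDet <- do.call(rbind, lapply(a, as.data.frame))
  expect_identical(anyDuplicated(allDet[, c("time_s", "position_um")]), 0L)
})

test_that("classification separates static from diffusive motion", {
  static <- trajectory((0:99) * 0.02,
                       rep(5, 100) + rnorm(100, 0, 0.02),  # 0.3 px noise
                       rep(6, 100))
  expect_identical(classification(classifyTrajectory(static)), "static")

  brown <- trajectory((0:874) * 0.02,
                      simulateTrajectory(0.16, 16, 17.5, seed = 76, x0 = 8),
                      rep(6, 875))
  expect_identical(classification(classifyTrajectory(brown)), "diffusive")

  short <- trajectory((0:5) * 0.02, rep(1, 6), rep(6, 6))
  expect_identical(classification(classifyTrajectory(short)), "ambiguous")
})

test_that("conversion shows up as static trajectories after the hold", {
  cfg <- experimentConfig(nTetramers = 12, extendedTime = 4, postTime = 4,
                          holdTime = 1, conversionProb = 1, seed = 77)
  sim <- simulateCompactionExperiment(cfg)
  post <- sim$truth@phase == "post"
  postPos <- sim$truth@positions[post, ]
  # with conversion probability 1 every tetramer is frozen after the hold
  expect_true(all(apply(postPos, 2, function(p) diff(range(p))) == 0))
  ext <- sim$truth@phase == "extended"
  extSd <- apply(sim$truth@positions[ext, ], 2, sd)
  expect_true(all(extSd > 0))  # all diffusive before relaxation
})

test_that("trajectory stoichiometry divides amplitude by the dye yield", {
  cal <- calibration(1.5)
  mk <- function(a) trajectory((0:19) * 0.02, rep(1, 20), rep(a, 20))
  expect_equal(round(trajectoryStoichiometry(mk(5), cal), 1), 3.3)
  expect_equal(trajectoryStoichiometry(mk(6), cal), 4.0)
  expect_equal(trajectoryStoichiometry(mk(0), cal), 0)
})
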