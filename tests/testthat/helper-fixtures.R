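# Shared fixtures: all synthetic, built in code at test time.

# GroundTruth for a single mobile emitter following `pos` (um) on a tether
# of constant separation.
singleEmitterTruth <- function(pos, separation = 16, linePeriod = 0.02,
                               fluorsPerTetramer = 4) {
  n <- length(pos)
  new("GroundTruth", positions = matrix(pos, ncol = 1),
      bleachTimes = numeric(0),
      fluorTetramer = rep(1L, fluorsPerTetramer),
      clusterId = NA_integer_, clusterAnchors = numeric(0),
      separation = rep(separation, n), phase = rep("extended", n),
      linePeriod = linePeriod, sequesteredPerDomain = 2.7)
}

# O(n^2) brute-force time-averaged MSD over all ordered pairs: the
# independent oracle for msdCurve().
bruteMsd <- function(x, maxLag) {
  n <- length(x)
  vapply(seq_len(maxLag), function(k) {
    acc <- c()
    for (i in seq_len(n)) {
      j <- i + k
      if (j <= n && !is.na(x[i]) && !is.na(x[j]))
        acc <- c(acc, (x[j] - x[i])^2)
    }
    mean(acc)
  }, numeric(1))
}

# Optics with photobleaching off: stable emitters.
stableOptics <- function(...) {
  opticsConfig(bleachRateAtReference = 0, ...)
}
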