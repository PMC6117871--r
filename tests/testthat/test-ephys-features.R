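triangularTrace <- function(fs = 20000, base = -45, peak = 35,
                            slope = 100, at = 0.05, total = 0.1) {
  # symmetric triangular spike: closed-form amplitude and half-width
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  rise_t <- (peak - base) / slope / 1000    # s
  v <- rep(base, n)
  up <- t >= at & t < at + rise_t
  v[up] <- base + slope * 1000 * (t[up] - at)
  dn <- t >= at + rise_t & t < at + 2 * rise_t
  v[dn] <- peak - slope * 1000 * (t[dn] - at - rise_t)
  v
}

test_that("AP detection recovers the closed-form geometry of a triangular spike", {
  v <- triangularTrace()
  aps <- detectAPs(v, 20000)
  expect_equal(nrow(aps), 1L)
  expect_equal(aps$amplitude, 80, tolerance = 0.01)
  expect_equal(aps$threshold_v, -45, tolerance = 0.01)
  # width at half amplitude (-5 mV): 40 mV at 100 mV/ms on each side
  expect_equal(aps$half_width, 0.8, tolerance = 0.01)
  expect_identical(nrow(detectAPs(rep(-70, 2000), 20000)), 0L)
})

test_that("two planted spikes yield two events 50 ms apart", {
  v1 <- triangularTrace(at = 0.02, total = 0.12)
  v2 <- triangularTrace(at = 0.07, total = 0.12)
  v <- pmax(v1, v2)
  aps <- detectAPs(v, 20000)
  expect_equal(nrow(aps), 2L)
  expect_equal(diff(aps$peak_t) * 1000, 50, tolerance = 0.1)
})

test_that("a passive RC membrane is recovered within tight tolerances", {
  cfg <- traceSimConfig("passive", r_in = 100, tau = 0.020,
                        hyper_currents = c(-50, -20), noise_sd = 0.05)
  sim <- simulateSweeps(cfg, seed = 2, cell_id = "rc")
  f <- extractFeatures(sim$sweeps)
  expect_equal(unname(f["rin"]), 100, tolerance = 0.02)
  expect_equal(unname(f["tau_m"]), 20, tolerance = 0.1)
  expect_lt(abs(f["sag"]), 0.02)
  expect_equal(unname(f["rmp"]), -70, tolerance = 0.01)
  expect_true(all(c("rheobase", "ap_halfwidth") %in%
                    attr(f, "missing")))
})

test_that("planted rheobase on a 1 pA grid is recovered exactly", {
  cfg <- traceSimConfig("fast_spiking", rheobase = 120)
  sim <- simulateSweeps(cfg, seed = 4)
  f <- extractFeatures(sim$sweeps)
  expect_identical(unname(f["rheobase"]), 120)
  expect_identical(unname(sim$truth["rheobase"]), 120)
})

test_that("fast-spiking half-width is recovered within five percent", {
  cfg <- traceSimConfig("fast_spiking")
  for (s in 1:5) {
    sim <- simulateSweeps(cfg, seed = s)
    f <- extractFeatures(sim$sweeps)
    expect_lt(abs(f["ap_halfwidth"] - 0.35) / 0.35, 0.05)
  }
})

test_that("late-spiking cells fire with the planted delay at rheobase", {
  sim <- simulateSweeps(traceSimConfig("late_spiking"), seed = 6)
  f <- extractFeatures(sim$sweeps)
  expect_lt(abs(f["latency_first_spike"] - 150), 10)
})

test_that("quality exclusion applies the printed boundary semantics", {
  feats <- data.frame(cell_id = paste0("c", 1:5),
                      ap_halfwidth = c(2.0, 2.01, 0.4, NA, 0.4),
                      ap_amplitude = c(60, 60, 39.9, NA, 41))
  expect_warning(res <- excludeLowQuality(feats), "unmeasurable")
  expect_setequal(res$kept$cell_id, c("c1", "c4", "c5"))
  expect_setequal(res$excluded$cell_id, c("c2", "c3"))
  expect_match(res$excluded$reason[res$excluded$cell_id == "c2"],
               "half_width")
  expect_match(res$excluded$reason[res$excluded$cell_id == "c3"],
               "amplitude")
})

test_that("feature PCA respects symmetry and rank structure", {
  set.seed(61)
  n <- 60
  base <- rnorm(n)
  feats <- data.frame(cell_id = paste0("c", 1:n),
                      rmp = -70 + rnorm(n), rin = 100 + 30 * base,
                      mean_iei = 100 + 30 * base,
                      tau_m = 20 + rnorm(n), sag = runif(n, 0, 0.2))
  pc <- ephysPCA(feats)
  # two perfectly correlated parameters load PC1 equally in magnitude
  l <- pc$loadings[, 1]
  expect_equal(abs(l[["mean_iei"]]), abs(l[["rin"]]), tolerance = 1e-6)
  # rank-1 data: PC1 explains nearly everything
  r1 <- data.frame(cell_id = paste0("c", 1:n),
                   rmp = -70 + base, rin = 100 + base, tau_m = 20 - base)
  pc1 <- ephysPCA(r1)
  expect_gt(pc1$var_explained[1], 0.999)
  # invariance (up to sign) to parameter ordering
  pc2 <- ephysPCA(feats[, c("cell_id", "sag", "tau_m", "mean_iei",
                            "rin", "rmp")])
  expect_equal(abs(pc$scores[, 1]), abs(pc2$scores[, 1]),
               tolerance = 1e-8)
})

test_that("parameter-wise group tests find a planted shift and only it", {
  set.seed(62)
  nA <- 20; nB <- 25
  mk <- function(n, shift = 0)
    data.frame(rin = 100 + rnorm(n, 0, 10) + shift * 30,
               tau_m = 20 + rnorm(n), sag = runif(n, 0, 0.2),
               rmp = -70 + rnorm(n))
  feats <- cbind(cell_id = paste0("c", 1:(nA + nB)),
                 rbind(mk(nA, shift = 1), mk(nB)))
  res <- pairwiseCompare(feats, paste0("c", 1:nA),
                         paste0("c", nA + 1:nB))
  expect_lt(res$q[res$parameter == "rin"], 0.05)
  expect_true(all(res$q[res$parameter != "rin"] > 0.05))
  # identical groups: t = 0
  same <- cbind(cell_id = paste0("c", 1:12), rbind(mk(6), mk(6)))
  same[7:12, -1] <- same[1:6, -1]
  r0 <- pairwiseCompare(same, paste0("c", 1:6), paste0("c", 7:12))
  expect_true(all(abs(r0$t) < 1e-10))
})

test_that("hierarchical clustering separates simulated archetype groups", {
  fs <- lapply(1:6, function(s)
    simulateSweeps(traceSimConfig("fast_spiking"), seed = s,
                   cell_id = paste0("fs", s))$sweeps)
  rs <- lapply(1:6, function(s)
    simulateSweeps(traceSimConfig("regular"), seed = 10 + s,
                   cell_id = paste0("rs", s))$sweeps)
  feats <- extractFeatureTable(c(fs, rs))
  h <- hclusterEphys(feats)
  top2 <- cutree(h, 2)
  expect_equal(adjustedRand(top2, rep(c("FS", "RS"), each = 6)), 1)
  # duplicated cell merges with its twin at height zero
  f2 <- rbind(feats, feats[1, ])
  f2$cell_id[13] <- "dup"
  h2 <- hclusterEphys(f2)
  expect_equal(min(h2$height), 0, tolerance = 1e-12)
})

test_that("sweep sets round-trip through the on-disk CSV + manifest format", {
  sim <- simulateSweeps(traceSimConfig("regular"), seed = 8,
                        cell_id = "rt")
  dirp <- file.path(withr::local_tempdir(), "rt")
  writeSweepSet(sim$sweeps, dirp)
  back <- readSweepSet(dirp)
  expect_equal(back@currents, sim$sweeps@currents)
  expect_equal(back@fs, sim$sweeps@fs)
  expect_equal(back@voltages[[3]], sim$sweeps@voltages[[3]],
               tolerance = 1e-6)
  f1 <- extractFeatures(sim$sweeps)
  f2 <- extractFeatures(back)
  expect_equal(f1, f2, tolerance = 1e-4)
})
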