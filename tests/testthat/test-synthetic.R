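test_that("makeCohort produces the configured, reproducible cohort", {
  cfg <- generativeConfig(nHealthy = 18, nPD = 8, seed = 3)
  prof <- makeCohort(cfg)
  expect_length(prof, 26L)
  groups <- vapply(prof, function(p) p@group, "")
  expect_equal(sum(groups == "healthy"), 18L)
  expect_equal(sum(groups == "pd"), 8L)
  # healthy subjects have no tremor or dyskinesia by construction
  for (p in prof[groups == "healthy"]) {
    expect_equal(p@tremorAmplitude, 0)
    expect_equal(p@dyskinesiaAmplitude, 0)
  }
  # pd gait is slower and more irregular on average ranges
  for (p in prof[groups == "pd"]) {
    expect_lte(p@gaitFrequency, 1.8)
    expect_gte(p@gaitCycleJitter, 0.08)
  }
  # determinism and distinct subject seeds
  prof2 <- makeCohort(cfg)
  expect_equal(prof, prof2)
  expect_false(anyDuplicated(vapply(prof, function(p) p@seed, 1L)) > 0)
})

test_that("zero heterogeneity collapses subjects to the central parameters", {
  prof <- makeCohort(generativeConfig(nHealthy = 3, nPD = 0, seed = 5,
                                      subjectHeterogeneity = 0))
  freqs <- vapply(prof, function(p) p@gaitFrequency, 1)
  expect_equal(freqs, rep(1.9, 3))  # midpoint of the healthy range
  expect_equal(vapply(prof, function(p) p@tiltAngle, 1), rep(0, 3))
})

test_that("pdLikeHealthy draws the pd group from healthy distributions", {
  prof <- makeCohort(generativeConfig(nHealthy = 0, nPD = 6, seed = 5,
                                      pdLikeHealthy = TRUE))
  for (p in prof) {
    expect_equal(p@group, "pd")
    expect_equal(p@tremorAmplitude, 0)
    expect_gte(p@gaitFrequency, 1.6)
    expect_lte(p@gaitCycleJitter, 0.03)
  }
})

test_that("simulated bouts respect the sampling band and sensor range", {
  p <- makeCohort(generativeConfig(nHealthy = 0, nPD = 1, seed = 8))[[1]]
  rec <- simulateRecording(p, "walking", duration = 30)
  rate <- 1 / diff(rec@time)
  expect_true(all(rate >= 15 - 1e-9 & rate <= 25 + 1e-9))
  expect_true(all(abs(rec@accel) <= 2.8))
  expect_gte(max(rec@time), 30)
  # same seed, same bout -> identical signal
  rec2 <- simulateRecording(p, "walking", duration = 30)
  expect_identical(rec@accel, rec2@accel)
  expect_error(simulateRecording(p, "jogging", duration = 30), "unknown")
})

test_that("a phone on the table is nearly still; worn postures carry gravity", {
  prof <- makeCohort(generativeConfig(nHealthy = 1, nPD = 0, seed = 21,
                                      subjectHeterogeneity = 0))[[1]]
  off <- simulateRecording(prof, "not_wearing", duration = 30)
  expect_true(all(apply(off@accel, 2, sd) < 0.01))
  standing <- simulateRecording(prof, "standing", duration = 30)
  dom <- which.max(colMeans(abs(standing@accel)))
  expect_lt(abs(abs(mean(standing@accel[, dom])) - 1), 0.05)
  # oscillation power (variance about the gravity mean) is tiny when standing
  expect_lt(sum(apply(standing@accel, 2, var)), 0.005)
  # sitting rotates gravity away from the long axis toward the face normal
  sitting <- simulateRecording(prof, "sitting", duration = 30)
  expect_gt(abs(mean(sitting@accel[, 3])), abs(mean(sitting@accel[, 2])))
})

test_that("parkinsonian gait has a wider, lower spectral peak than healthy gait", {
  base <- makeCohort(generativeConfig(nHealthy = 2, nPD = 0, seed = 31,
                                      subjectHeterogeneity = 0))
  mk <- function(p, jitter) {
    p@gaitCycleJitter <- jitter
    rec <- resampleToUniform(simulateRecording(p, "walking", duration = 60))
    v <- rec@accel[, 2] - mean(rec@accel[, 2])
    pg <- Mod(fft(v))^2 / length(v)
    pg[seq_len(length(v) %/% 2)]
  }
  healthyPeak <- max(mk(base[[1]], 0.02))
  pdPeak <- max(mk(base[[1]], 0.15))
  expect_lt(pdPeak / healthyPeak, 1)
})

test_that("tremor appears while worn, strongest while holding, absent off-body", {
  cfg <- generativeConfig(nHealthy = 0, nPD = 1, seed = 13)
  p <- makeCohort(cfg)[[1]]
  p@tremorAmplitude <- 0.15
  p@dyskinesiaAmplitude <- 0
  bandPower <- function(activity) {
    rec <- resampleToUniform(simulateRecording(p, activity, duration = 30))
    v <- rec@accel[, 1] - mean(rec@accel[, 1])
    pg <- Mod(fft(v))^2 / length(v)
    hz <- (seq_along(v) - 1) * 20 / length(v)
    sum(pg[hz >= 3.5 & hz <= 6.5])
  }
  expect_gt(bandPower("holding"), bandPower("standing"))
  expect_gt(bandPower("standing"), 10 * bandPower("not_wearing"))
})

test_that("simulateStudy writes a deterministic full protocol", {
  cfg <- generativeConfig(nHealthy = 2, nPD = 1, boutSeconds = 30, seed = 17)
  dir <- withr::local_tempdir()
  study <- simulateStudy(cfg, dir = dir)
  expect_equal(nrow(study$manifest), 3L * length(cfg$activitySequence))
  # every subject performs each worn activity at least twice
  bouts <- table(study$manifest$subjectId, study$manifest$activity)
  for (act in c("walking", "holding", "standing", "sitting"))
    expect_true(all(bouts[, act] >= 2))
  expect_true(file.exists(file.path(dir, "recordings.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # byte-identical regeneration
  dir2 <- withr::local_tempdir()
  simulateStudy(cfg, dir = dir2)
  expect_identical(
    unname(tools::md5sum(file.path(dir, "recordings.csv"))),
    unname(tools::md5sum(file.path(dir2, "recordings.csv"))))
  # the raw CSV round-trips into the signals module
  recs <- readRecordings(file.path(dir, "recordings.csv"))
  expect_length(recs, nrow(study$manifest))
})

test_that("bouts shorter than 30 s are rejected by config and simulator", {
  expect_error(generativeConfig(boutSeconds = 20), "boutSeconds")
  p <- makeCohort(generativeConfig(nHealthy = 1, seed = 1))[[1]]
  expect_error(simulateRecording(p, "walking", duration = 10), "duration")
})
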