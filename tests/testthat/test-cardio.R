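# A tiny spectrum carrier for classification tests: one injected peak set
# over a valid grid.
specWithPeaks <- function(freqHz, power = rep(1, length(freqHz)),
                          significant = rep(TRUE, length(freqHz))) {
  spec <- computePeriodogram(rep(0, 64), fps = 30)
  spec@peaks <- data.frame(freq = freqHz, power = power,
                           significant = significant)
  spec
}

test_that("tile reference equals the brute-force per-tile temporal mean", {
  ## constant stack
  const <- FrameStack(array(7, dim = c(16, 16, 64)))
  expect_true(all(computeReference(const) == 7))
  ## alternating frames of 0 and 2
  fr <- array(rep(c(0, 2), each = 16 * 16, length.out = 16 * 16 * 64),
              dim = c(16, 16, 64))
  expect_true(all(computeReference(FrameStack(fr)) == 1))
  ## phantom vs direct loop oracle, including edge remainder tiles (20 px)
  ph <- makeHeartVideo(nFrames = 64, width = 20, height = 20, seed = 3)
  ref <- computeReference(ph$stack, tilePx = 8)
  f <- frames(ph$stack)
  oracle <- numeric(0)
  for (tc in list(1:8, 9:16, 17:20))   # column-major tile order
    for (tr in list(1:8, 9:16, 17:20))
      oracle <- c(oracle, mean(f[tr, tc, ]))
  ## match values as sets ordered by the internal tile indexing
  expect_equal(sort(as.numeric(ref)), sort(oracle))
})

test_that("motion signals behave on constant, impulse and sinusoid videos", {
  const <- FrameStack(array(5, dim = c(16, 16, 64)))
  sig <- computeMotionSignals(const)
  expect_true(all(edSignal(sig) == 0))
  expect_equal(ofAmplitude(sig), 0)
  ## single differing frame against an explicit constant reference
  f <- array(5, dim = c(16, 16, 64))
  f[, , 10] <- 9
  ref <- computeReference(const)
  sig <- computeMotionSignals(FrameStack(f), ref)
  expect_equal(which(edSignal(sig) != 0), 10L)
  ## one oscillating tile: ed is proportional to |sin|
  f2 <- array(10, dim = c(16, 16, 64))
  s <- sin(2 * pi * (4 / 64) * (0:63))  # integer cycles, zero mean
  for (k in 1:64) f2[1:8, 1:8, k] <- 10 + 3 * s[k]
  sig2 <- computeMotionSignals(FrameStack(f2))
  expect_equal(edSignal(sig2), 3 * abs(s), tolerance = 1e-12)
  ## geometry mismatch
  expect_error(
    computeMotionSignals(FrameStack(array(1, dim = c(8, 8, 64))), ref),
    "geometry")
})

test_that("drift quality control flags moved embryos and passes clean ones", {
  drift <- makeHeartVideo(fAtrial = 2.6, fVentricular = 2.6,
                          driftPxPerFrame = 0.05, seed = 21)
  expect_false(qualityControl(computeMotionSignals(drift$stack)))
  clean <- makeHeartVideo(fAtrial = 2.6, fVentricular = 2.6, seed = 22)
  expect_true(qualityControl(computeMotionSignals(clean$stack)))
  const <- FrameStack(array(4, dim = c(16, 16, 64)))
  expect_true(qualityControl(computeMotionSignals(const)))
})

test_that("periodogram localises a pure sinusoid to one padded bin", {
  t <- (0:511) / 30
  ed <- sin(2 * pi * 2.4 * t)
  spec <- computePeriodogram(ed, fps = 30, padFactor = 8)
  fhat <- freqs(spec)[which.max(specPower(spec))]
  expect_lt(abs(fhat - 2.4), 30 / (8 * 512))
  ## zero series
  z <- computePeriodogram(rep(0, 512), fps = 30)
  expect_true(all(specPower(z) == 0))
  expect_error(computePeriodogram(ed, fps = 30, bandHz = c(3, 3)),
               "empty")
})

test_that("white-noise series yields no significant peak in >=95% of seeds", {
  set.seed(123)
  pass <- 0
  for (s in 1:100) {
    spec <- detectSignificantPeaks(computePeriodogram(rnorm(512), fps = 30))
    pass <- pass + (sum(peaks(spec)$significant) == 0)
  }
  expect_gte(pass, 95)
})

test_that("peak significance separates control from 2:1 phantom spectra", {
  ctrl <- makeHeartVideo(fAtrial = 2.6, fVentricular = 2.6, seed = 31)
  spec <- detectSignificantPeaks(
    computePeriodogram(computeMotionSignals(ctrl$stack)))
  expect_equal(sum(peaks(spec)$significant), 1)
  arr <- makeHeartVideo(fAtrial = 2.6, fVentricular = 1.3, seed = 32)
  spec2 <- detectSignificantPeaks(
    computePeriodogram(computeMotionSignals(arr$stack)))
  sig <- peaks(spec2)[peaks(spec2)$significant, ]
  expect_gte(nrow(sig), 2)
  expect_equal(sort(sig$freq)[1:2], c(1.3, 2.6), tolerance = 0.02)
  ## all-zero spectrum
  empty <- detectSignificantPeaks(computePeriodogram(rep(0, 128), fps = 30))
  expect_equal(nrow(peaks(empty)), 0)
})

test_that("four-way classification applies its thresholds exactly", {
  cfg <- assayConfig()
  amp <- cfg@arrestAmplitude
  ## static phantom: OF below threshold -> arrest regardless of peaks
  r <- classifyCardio(specWithPeaks(2.6), ofAmplitude = amp / 2, cfg)
  expect_equal(category(r), "CARDIAC_ARREST")
  expect_equal(heartRateHz(r), 0)
  ## 2.40 Hz -> 36.0 beats/15 s, below the 36.5 cutoff
  r <- classifyCardio(specWithPeaks(2.40), ofAmplitude = 10 * amp, cfg)
  expect_equal(category(r), "BRADYCARDIA")
  expect_equal(beatsPer15s(r), 36.0)
  ## 2.60 Hz -> 39.0 -> no effect
  r <- classifyCardio(specWithPeaks(2.60), ofAmplitude = 10 * amp, cfg)
  expect_equal(category(r), "NO_EFFECT")
  expect_equal(beatsPer15s(r), 39.0)
  ## exactly at the boundary: 36.5 is not bradycardia (strict <)
  r <- classifyCardio(specWithPeaks(36.5 / 15), ofAmplitude = 10 * amp, cfg)
  expect_equal(category(r), "NO_EFFECT")
  ## two rhythms -> 2:1 arrhythmia, rate = first significant frequency
  r <- classifyCardio(specWithPeaks(c(1.3, 2.6)), ofAmplitude = 10 * amp, cfg)
  expect_equal(category(r), "ARRHYTHMIA_21")
  expect_equal(heartRateHz(r), 1.3)
  ## motion but no significant peak -> NO_CALL
  r <- classifyCardio(specWithPeaks(numeric(0)), ofAmplitude = 10 * amp, cfg)
  expect_equal(category(r), "NO_CALL")
})

test_that("circular time-shift preserves the category and the rate", {
  ph <- makeHeartVideo(fAtrial = 3.1, fVentricular = 3.1, seed = 6)
  r1 <- analyzeCardioVideo(ph$stack)
  f <- frames(ph$stack)
  shifted <- FrameStack(f[, , c(101:512, 1:100)], fps = 30)
  r2 <- analyzeCardioVideo(shifted)
  expect_identical(category(r2), category(r1))
  expect_lte(abs(heartRateHz(r2) - heartRateHz(r1)), 30 / (8 * 512))
})

test_that("intensity rescaling scales ed linearly and keeps the category", {
  ph <- makeHeartVideo(fAtrial = 3.1, fVentricular = 3.1, seed = 6)
  s1 <- computeMotionSignals(ph$stack)
  cfg <- assayConfig()
  for (k in c(0.5, 3)) {
    scaled <- FrameStack(frames(ph$stack) * k, fps = 30)
    s2 <- computeMotionSignals(scaled)
    expect_equal(edSignal(s2), k * edSignal(s1), tolerance = 1e-12)
    ## the arrest threshold is calibrated to the configured noise SD, which
    ## scales with the intensities; all spectral thresholds are relative
    cfgK <- assayConfig(arrestAmplitude = k * cfg@arrestAmplitude)
    expect_identical(category(analyzeCardioVideo(scaled, cfgK)), "NO_EFFECT")
  }
})

test_that("a constant video is classified as cardiac arrest", {
  const <- FrameStack(array(50, dim = c(32, 32, 64)))
  r <- analyzeCardioVideo(const)
  expect_identical(category(r), "CARDIAC_ARREST")
  expect_true(isAnalysable(r))
})
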