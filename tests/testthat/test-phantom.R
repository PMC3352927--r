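test_that("same seed gives bit-identical phantom outputs", {
  a <- makeHeartVideo(nFrames = 64, width = 24, height = 24, seed = 5)
  b <- makeHeartVideo(nFrames = 64, width = 24, height = 24, seed = 5)
  expect_identical(frames(a$stack), frames(b$stack))
  v1 <- makeVesselImage(nIsvs = 7, seed = 9, width = 256, height = 128)
  v2 <- makeVesselImage(nIsvs = 7, seed = 9, width = 256, height = 128)
  expect_identical(v1$image, v2$image)
  d1 <- makeDoseResponse(ic50 = 1, noiseSd = 3, seed = 4)
  d2 <- makeDoseResponse(ic50 = 1, noiseSd = 3, seed = 4)
  expect_identical(d1, d2)
})

test_that("heart phantom regimes carry the right ground truth", {
  expect_error(makeHeartVideo(fAtrial = 20), "fps/2")
  expect_equal(makeHeartVideo(fAtrial = 2.6, nFrames = 64)$truth$category,
               "NO_EFFECT")
  expect_equal(makeHeartVideo(fAtrial = 2.0, nFrames = 64)$truth$category,
               "BRADYCARDIA")
  expect_equal(
    makeHeartVideo(fAtrial = 2.6, fVentricular = 1.3,
                   nFrames = 64)$truth$category, "ARRHYTHMIA_21")
  arrest <- makeHeartVideo(amp = 0, nFrames = 64)
  expect_equal(arrest$truth$category, "CARDIAC_ARREST")
  expect_equal(arrest$truth$beatsPer15s, 0)
})

test_that("noiseless control phantom analyses to its stated rate", {
  ph <- makeHeartVideo(fAtrial = 2.6, fVentricular = 2.6, noiseSd = 0,
                       seed = 1)
  r <- analyzeCardioVideo(ph$stack)
  expect_equal(category(r), "NO_EFFECT")
  expect_equal(beatsPer15s(r), 39.0, tolerance = 0.005)
})

test_that("arrest phantom motion sits at the noise floor", {
  ph <- makeHeartVideo(amp = 0, seed = 3)
  sig <- computeMotionSignals(ph$stack)
  expect_lt(ofAmplitude(sig), assayConfig()@arrestAmplitude / 2)
})

test_that("2:1 phantom has spectral components at both chamber rates", {
  ph <- makeHeartVideo(fAtrial = 2.6, fVentricular = 1.3, seed = 4)
  spec <- computePeriodogram(computeMotionSignals(ph$stack))
  p <- specPower(spec)
  f <- freqs(spec)
  dom <- max(p)
  expect_gt(max(p[abs(f - 1.3) < 0.06]) / dom, 0.25)
  expect_gt(max(p[abs(f - 2.6) < 0.06]) / dom, 0.25)
})

test_that("vessel phantom geometric truth covers the stated cases", {
  ph <- makeVesselImage(nIsvs = 10, seed = 1)
  expect_equal(ph$truth$totalISVs, 10L)
  expect_equal(ph$truth$completeISVs, 10L)
  expect_equal(ph$truth$nEnclosedRegions, 9L)
  empty <- makeVesselImage(nIsvs = 0, seed = 1)
  expect_equal(empty$truth$totalISVs, 0L)
  expect_equal(empty$truth$nEnclosedRegions, 0L)
  gapped <- makeVesselImage(nIsvs = 10, dlavGaps = "all", seed = 1)
  expect_equal(gapped$truth$nEnclosedRegions, 0L)
  ## a gap between two complete ISVs opens exactly that cell
  g <- c(ph$truth$isvX[4] + 2, ph$truth$isvX[5] - 2)
  partial <- makeVesselImage(nIsvs = 10, dlavGaps = list(g), seed = 1)
  expect_equal(partial$truth$nEnclosedRegions, 8L)
})

test_that("dose-response generator obeys the 4PL identities", {
  ## midpoint identity at dose == ic50
  d <- makeDoseResponse(ic50 = 2, hill = 1.7, top = 80, bottom = 20,
                        doses = 2)
  expect_equal(d$response, 50)
  ## steep hill approaches a step between top and bottom
  d2 <- makeDoseResponse(ic50 = 1, hill = 200, top = 100, bottom = 0,
                         doses = c(0.5, 0.9, 1.1, 2))
  expect_equal(d2$response, c(100, 100, 0, 0), tolerance = 1e-6)
  ## a noiseless curve at a validated-compound IC50 is recovered by the fit
  d3 <- makeDoseResponse(ic50 = 0.035, hill = 1.2,
                         doses = 10^seq(-3.5, 0.5, length.out = 8))
  fit <- fit4PL(d3$dose, d3$response)
  expect_true(fit$converged)
  expect_lt(abs(fit$ic50 - 0.035), 1e-3)
})
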