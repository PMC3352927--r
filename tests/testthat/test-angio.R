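# Smaller-than-default phantom geometry keeps the flood-fill oracle fast;
# the pipeline itself is geometry-agnostic.
smallVessel <- function(...) makeVesselImage(..., width = 320, height = 160)

test_that("embryo segmentation recovers the body footprint", {
  ph <- makeVesselImage(nIsvs = 10, seed = 3)
  em <- segmentEmbryo(ph$image)
  iou <- sum(maskMatrix(em) & ph$truth$bodyMask) /
    sum(maskMatrix(em) | ph$truth$bodyMask)
  expect_gte(iou, 0.9)
  expect_gt(embryoLengthPx(em), 0)
  expect_error(segmentEmbryo(matrix(0, 50, 50)), "no embryo")
  ## largest-component rule
  img <- matrix(0, 100, 100)
  img[10:60, 10:60] <- 50
  img[80:85, 80:85] <- 50
  m <- maskMatrix(segmentEmbryo(img))
  expect_equal(sum(m[80:85, 80:85]), 0)
  expect_gt(sum(m[10:60, 10:60]), 2000)
})

test_that("head/tail split starts the ROI at the yolk bulge", {
  for (posFrac in c(0.3, 0.45)) {
    ph <- makeVesselImage(nIsvs = 8, yolkPositionFrac = posFrac, seed = 11)
    em <- splitHeadTail(segmentEmbryo(ph$image))
    expect_false(em@roiFallback)
    expect_lt(abs(roi(em)[3] - ph$truth$roiStartCol),
              0.05 * ph$truth$lengthPx)
  }
  ## degenerate symmetric rectangle -> posterior 60% fallback with warning
  rect <- matrix(0, 60, 200)
  rect[20:40, 10:190] <- 50
  expect_warning(em <- splitHeadTail(segmentEmbryo(rect)), "degenerate")
  expect_true(em@roiFallback)
  span <- roi(em)[4] - roi(em)[3] + 1
  expect_equal(span / (190 - 10 + 1), 0.6, tolerance = 0.05)
  ## bulge at the anterior edge -> ROI covers almost the whole trunk
  ph <- makeVesselImage(nIsvs = 8, yolkPositionFrac = 0.12, seed = 12)
  em <- splitHeadTail(segmentEmbryo(ph$image))
  expect_lt(roi(em)[3], ph$truth$isvX[1])
})

test_that("vessel-mask extraction finds the vessels and rejects noise", {
  ph <- makeVesselImage(nIsvs = 10, noiseSd = 0, seed = 8)
  em <- splitHeadTail(segmentEmbryo(ph$image))
  r <- roi(em)
  inRoi <- matrix(FALSE, nrow(ph$image), ncol(ph$image))
  inRoi[r[1]:r[2], r[3]:r[4]] <- TRUE
  truthRoi <- ph$truth$vesselMask & inRoi
  ## noiseless phantom: nearly all truth pixels, few spurious
  vm <- extractVesselMask(ph$image, em)
  expect_gte(sum(vm & truthRoi) / sum(truthRoi), 0.95)
  expect_lte(sum(vm & !ph$truth$vesselMask) / sum(vm), 0.05)
  ## idempotence: the ground-truth mask maps to itself
  vmId <- extractVesselMask(ph$truth$vesselMask + 0, em)
  expect_gte(sum(vmId & truthRoi) / sum(vmId | truthRoi), 0.98)
  ## background-noise-only ROI stays near-empty across seeds
  for (s in 1:5) {
    set.seed(400 + s)
    noise <- matrix(round(pmax(rnorm(128 * 256, 5, 6), 0)), 128, 256)
    vmN <- extractVesselMask(noise, c(20, 110, 20, 240))
    expect_lt(sum(vmN) / (91 * 221), 0.005)
  }
})

test_that("enclosed-area measurement matches the flood-fill oracle", {
  cfg <- assayConfig()
  ## full ladder: 10 complete rungs -> 9 cells
  ph <- smallVessel(nIsvs = 10, seed = 41)
  em <- splitHeadTail(segmentEmbryo(ph$image))
  vm <- extractVesselMask(ph$image, em)
  got <- measureEnclosedAreas(vm, em)
  r <- roi(em)
  oracle <- floodFillHoles(vm[r[1]:r[2], r[3]:r[4]],
                           minArea = cfg@minHoleAreaPx)
  expect_equal(got$nEnclosedRegions, 9L)
  expect_equal(got$nEnclosedRegions, oracle$nRegions)
  expect_equal(got$enclosedAreaPx, oracle$areaPx)
  ## DLAV deleted -> no enclosure
  ph2 <- smallVessel(nIsvs = 10, dlavGaps = "all", seed = 41)
  em2 <- splitHeadTail(segmentEmbryo(ph2$image))
  got2 <- measureEnclosedAreas(extractVesselMask(ph2$image, em2), em2)
  expect_equal(got2$nEnclosedRegions, 0L)
  expect_equal(got2$enclosedAreaPx, 0)
  ## 7 complete + 3 stubs -> 6 cells, oracle-checked
  ph3 <- smallVessel(nIsvs = 10,
                     completeFlags = c(rep(TRUE, 7), rep(FALSE, 3)),
                     seed = 42)
  em3 <- splitHeadTail(segmentEmbryo(ph3$image))
  vm3 <- extractVesselMask(ph3$image, em3)
  got3 <- measureEnclosedAreas(vm3, em3)
  r3 <- roi(em3)
  oracle3 <- floodFillHoles(vm3[r3[1]:r3[2], r3[3]:r3[4]],
                            minArea = cfg@minHoleAreaPx)
  expect_equal(got3$nEnclosedRegions, 6L)
  expect_equal(got3$enclosedAreaPx, oracle3$areaPx)
})

test_that("deleting one complete ISV removes exactly one enclosed region", {
  base <- smallVessel(nIsvs = 8, seed = 43)
  q0 <- quantifyVessels(base$image)
  expect_equal(nEnclosedRegions(q0), 7L)
  for (del in c(1, 4, 8)) {
    flags <- rep(TRUE, 8)
    flags[del] <- FALSE
    ph <- smallVessel(nIsvs = 8, completeFlags = flags, seed = 43)
    expect_equal(nEnclosedRegions(quantifyVessels(ph$image)), 6L,
                 info = paste("deleted ISV", del))
  }
})

test_that("ISV counting matches ground truth and flags missing rails", {
  ph <- makeVesselImage(nIsvs = 10, seed = 44)
  em <- splitHeadTail(segmentEmbryo(ph$image))
  vm <- extractVesselMask(ph$image, em)
  counts <- countISVs(vm, em)
  expect_true(counts$railsFound)
  expect_equal(counts$totalISVs, 10L)
  expect_equal(counts$completeISVs, 10L)
  ## empty mask -> rails not found
  none <- countISVs(matrix(FALSE, nrow(ph$image), ncol(ph$image)), em)
  expect_false(none$railsFound)
  expect_true(is.na(none$totalISVs))
  ## 7 of 10 reaching the DLAV
  ph2 <- makeVesselImage(nIsvs = 10,
                         completeFlags = c(rep(TRUE, 7), rep(FALSE, 3)),
                         seed = 45)
  q2 <- quantifyVessels(ph2$image)
  expect_equal(totalISVs(q2), 10L)
  expect_equal(completeISVs(q2), 7L)
})

test_that("quantification is invariant to intensity rescaling", {
  ph <- smallVessel(nIsvs = 9, seed = 46)
  q1 <- quantifyVessels(ph$image)
  q2 <- quantifyVessels(ph$image * 4)
  expect_equal(enclosedAreaPx(q2), enclosedAreaPx(q1))
  expect_equal(nEnclosedRegions(q2), nEnclosedRegions(q1))
  expect_equal(totalISVs(q2), totalISVs(q1))
})

test_that("mean enclosed area is non-increasing as complete ISVs drop", {
  means <- vapply(c(10, 7, 4, 2), function(k) {
    areas <- vapply(1:3, function(s) {
      flags <- rep(FALSE, 10)
      flags[seq_len(k)] <- TRUE
      ph <- smallVessel(nIsvs = 10, completeFlags = flags, seed = 50 + s)
      enclosedAreaPx(quantifyVessels(ph$image))
    }, numeric(1))
    mean(areas)
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})

test_that("inhibition calling needs 10 embryos and controls type I error", {
  set.seed(60)
  mkGroup <- function(shift = 0, n = 12)
    data.frame(enclosedAreaPx = rnorm(n, 5000 - shift, 400),
               nEnclosedRegions = 9L, totalISVs = 10L, completeISVs = 10L)
  expect_error(callInhibition(mkGroup(n = 5), mkGroup()), "at least 10")
  ## a strong effect is called
  res <- callInhibition(mkGroup(shift = 2500), mkGroup())
  expect_equal(res$category, "INHIBITED")
  ## treated == control distribution: called NOT_INHIBITED >=95/100 repeats
  notInhibited <- 0
  for (s in 1:100) {
    set.seed(600 + s)
    res <- callInhibition(mkGroup(), mkGroup())
    notInhibited <- notInhibited + (res$category == "NOT_INHIBITED")
  }
  expect_gte(notInhibited, 95)
})

test_that("treated phantoms with half the ISVs removed are called inhibited", {
  ctl <- lapply(1:10, function(s)
    quantifyVessels(smallVessel(nIsvs = 10, seed = 700 + s)$image))
  trt <- lapply(1:10, function(s) {
    flags <- rep(c(TRUE, FALSE), 5)
    quantifyVessels(smallVessel(nIsvs = 10, completeFlags = flags,
                                seed = 800 + s)$image)
  })
  res <- callInhibition(trt, ctl)
  expect_equal(res$category, "INHIBITED")
  expect_lt(res$summary$meanCompleteISVs[2], res$summary$meanCompleteISVs[1])
})
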