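#' @include AllClasses.R
NULL

## Raised-cosine contraction bump: one asymmetric pulse per cycle, active
## over the fraction `duty` of the cycle. `phase` may be a matrix (cycle
## fraction), which produces the peristaltic traveling wave.
.contractionBump <- function(f, t, duty, phase = 0) {
  ph <- (f * t + phase) %% 1
  ifelse(ph < duty, 0.5 - 0.5 * cos(2 * pi * ph / duty), 0)
}

#' Synthetic beating-heart video with ground truth
#'
#' Draws two soft-edged elliptical chambers (atrium left, ventricle right)
#' over a static fluorescent body. Chamber areas contract once per cycle at
#' `fAtrial` and `fVentricular` following an asymmetric raised-cosine pulse;
#' the contraction travels across each chamber as a peristaltic wave (phase
#' spread `waveSpread` cycles), which keeps the fundamental of the ED signal
#' at the true beat frequency. Gaussian pixel noise is added and intensities
#' are rounded to the integer camera grid. An optional whole-frame linear
#' drift emulates an embryo that moved during recording.
#'
#' Regimes: control `fAtrial == fVentricular` (ventricle-dominated,
#' `ampRatio` 2); 2:1 atrio-ventricular block `fAtrial == 2 * fVentricular`
#' with comparable, atrium-dominant amplitudes (`ampRatio` 0.7, the
#' atrium beats fully in an AV block); cardiac arrest
#' `amp = 0`. The ground truth is computed from the parameters, never from
#' the generated pixels.
#'
#' @param fAtrial,fVentricular chamber beat frequencies, Hz, in `[0, fps/2)`
#' @param amp overall motion amplitude (0 = arrest)
#' @param ampRatio ventricular / atrial motion amplitude
#' @param noiseSd pixel noise SD, intensity units
#' @param driftPxPerFrame whole-frame translation per frame, px
#' @param nFrames,fps video length and rate
#' @param width,height frame geometry, px
#' @param duty active fraction of the contraction cycle
#' @param waveSpread peristaltic phase spread across a chamber, cycles
#' @param seed RNG seed (same seed, same video, bit for bit)
#' @return list with `stack` (a [FrameStack-class]) and `truth` (list:
#'   `category`, `rateHz`, `beatsPer15s`, `fAtrial`, `fVentricular`,
#'   `drifted`)
#' @examples
#' ph <- makeHeartVideo(fAtrial = 2.6, fVentricular = 1.3, ampRatio = 1,
#'                      seed = 7)
#' ph$truth$category  # "ARRHYTHMIA_21"
#' @export
makeHeartVideo <- function(fAtrial = 2.6, fVentricular = fAtrial, amp = 1,
                           ampRatio = if (fAtrial == fVentricular) 2 else 0.7,
                           noiseSd = 8, driftPxPerFrame = 0,
                           nFrames = 512, fps = 30, width = 64, height = 64,
                           duty = 0.6, waveSpread = 0.3, seed = 1) {
  if (fAtrial < 0 || fAtrial >= fps / 2 || fVentricular < 0 ||
      fVentricular >= fps / 2)
    stop("chamber frequencies must lie in [0, fps/2)")
  stopifnot(noiseSd >= 0, nFrames >= 64)
  set.seed(seed)
  H <- height
  W <- width
  t <- seq_len(nFrames) / fps
  xg <- matrix(rep(seq_len(W), each = H), H, W)
  yg <- matrix(rep(seq_len(H), W), H, W)
  ## geometry scaled to the frame: atrium left of centre, ventricle right
  cxA <- 0.36 * W; cyA <- 0.5 * H; rxA <- 0.15 * W; ryA <- 0.12 * H
  cxV <- 0.66 * W; cyV <- 0.5 * H; rxV <- 0.19 * W; ryV <- 0.15 * H
  ampV <- amp                # ventricular motion amplitude
  ampA <- amp / ampRatio     # atrial amplitude relative to the ventricle
  phA <- waveSpread * (xg - cxA) / (2 * rxA)
  phV <- 0.3 + waveSpread * (xg - cxV) / (2 * rxV)
  soft <- 3  # soft chamber edge width, px
  depth <- 0.28  # maximal relative radius contraction
  fr <- array(0, dim = c(H, W, nFrames))
  for (k in seq_len(nFrames)) {
    dx <- driftPxPerFrame * (k - 1)
    dy <- 0.3 * driftPxPerFrame * (k - 1)
    dA <- sqrt(((xg - cxA - dx) / rxA)^2 + ((yg - cyA - dy) / ryA)^2)
    dV <- sqrt(((xg - cxV - dx) / rxV)^2 + ((yg - cyV - dy) / ryV)^2)
    dB <- ((xg - 0.52 * W - dx) / (0.4 * W))^2 +
          ((yg - 0.5 * H - dy) / (0.31 * H))^2
    sA <- if (ampA > 0) .contractionBump(fAtrial, t[k], duty, phA) else 0
    sV <- if (ampV > 0) .contractionBump(fVentricular, t[k], duty, phV) else 0
    rA <- 1 - depth * ampA * sA
    rV <- 1 - depth * ampV * sV
    covA <- pmin(1, pmax(0, (rA - dA) * rxA / soft + 0.5))
    covV <- pmin(1, pmax(0, (rV - dV) * rxV / soft + 0.5))
    img <- 30 + 40 * exp(-dB) + 300 * covA + 300 * covV
    if (noiseSd > 0) img <- img + stats::rnorm(H * W, 0, noiseSd)
    fr[, , k] <- round(pmax(img, 0))
  }
  category <- if (amp == 0) "CARDIAC_ARREST"
              else if (abs(fAtrial - 2 * fVentricular) < 1e-9 &&
                       fAtrial != fVentricular) "ARRHYTHMIA_21"
              else if (15 * fVentricular < 36.5) "BRADYCARDIA"
              else "NO_EFFECT"
  rate <- if (amp == 0) 0 else fVentricular
  list(stack = FrameStack(fr, fps = fps),
       truth = list(category = category, rateHz = rate,
                    beatsPer15s = 15 * rate, fAtrial = fAtrial,
                    fVentricular = fVentricular,
                    drifted = driftPxPerFrame != 0))
}

## Geometric layout of the vessel phantom, shared by the drawer and the
## ground-truth calculator. All coordinates in pixels, anterior left,
## dorsal up (row 1 is the dorsal-most row).
.vesselLayout <- function(width, height, nIsvs, yolkPositionFrac) {
  trunkTop <- round(0.23 * height)
  trunkBottom <- round(0.74 * height)
  headCx <- round(0.12 * width)
  headR <- round(0.17 * height)
  tailEnd <- width - round(0.04 * width)
  bodyStart <- headCx - headR
  len <- tailEnd - bodyStart
  yolkCx <- bodyStart + round(yolkPositionFrac * len)
  yolkRx <- round(0.07 * width)
  yolkBottom <- round(0.86 * height)
  yDlav <- round(0.31 * height)
  yDa <- round(0.59 * height)
  yPcv <- round(0.645 * height)
  isvX <- if (nIsvs > 0)
    round(seq(yolkCx + yolkRx + 0.03 * width, tailEnd - 0.03 * width,
              length.out = nIsvs)) else integer()
  list(trunkTop = trunkTop, trunkBottom = trunkBottom, headCx = headCx,
       headR = headR, tailEnd = tailEnd, bodyStart = bodyStart,
       length = len, yolkCx = yolkCx, yolkRx = yolkRx,
       yolkBottom = yolkBottom, yDlav = yDlav, yDa = yDa, yPcv = yPcv,
       isvX = isvX)
}

#' Synthetic trunk-vasculature image with ground truth
#'
#' Draws a faint embryo body (head blob, trunk band tapering toward the
#' tail, ventral yolk bulge) and a bright vessel skeleton: dorsal aorta (DA)
#' and posterior cardinal vein (PCV) as ventral horizontal rails, the dorsal
#' longitudinal anastomotic vessel (DLAV) as the dorsal rail (optionally
#' interrupted by gaps), and `nIsvs` vertical intersegmental vessels rising
#' from the DA; incomplete ISVs stop at mid-height. Gaussian noise is added
#' and intensities rounded.
#'
#' Ground truth (counts, enclosed regions, masks) is computed geometrically
#' from the parameters, never from the rendered pixels: an enclosed region
#' lies between two consecutive complete ISVs whose connecting DLAV stretch
#' has no gap.
#'
#' @param nIsvs number of intersegmental vessels
#' @param completeFlags logical, length `nIsvs`: does the ISV reach the DLAV
#' @param isvWidthPx ISV line width, px (>= 1)
#' @param dlavGaps list of `c(xStart, xEnd)` intervals (px) removed from the
#'   DLAV, or the string `"all"` to delete the DLAV entirely
#' @param yolkPositionFrac yolk-bulge centre as a fraction of embryo length
#' @param noiseSd pixel noise SD
#' @param width,height image geometry, px
#' @param seed RNG seed
#' @return list with `image` (numeric matrix), and `truth`: `vesselMask`,
#'   `bodyMask` (logical matrices), `totalISVs`, `completeISVs`,
#'   `nEnclosedRegions`, `isvX`, `roiStartCol`, `lengthPx`
#' @examples
#' ph <- makeVesselImage(nIsvs = 10, seed = 3)
#' ph$truth$nEnclosedRegions  # 9
#' @export
makeVesselImage <- function(nIsvs = 10,
                            completeFlags = rep(TRUE, nIsvs),
                            isvWidthPx = 3, dlavGaps = list(),
                            yolkPositionFrac = 0.3, noiseSd = 6,
                            width = 512, height = 256, seed = 1) {
  stopifnot(nIsvs >= 0, length(completeFlags) == nIsvs, isvWidthPx >= 1)
  set.seed(seed)
  L <- .vesselLayout(width, height, nIsvs, yolkPositionFrac)
  xg <- matrix(rep(seq_len(width), each = height), height, width)
  yg <- matrix(rep(seq_len(height), width), height, width)
  ## body: trunk band (tapering), head disk, yolk ellipse
  taper <- pmax(0, (xg - L$yolkCx) / (L$tailEnd - L$yolkCx))
  halfTrunk <- (L$trunkBottom - L$trunkTop) / 2
  midTrunk <- (L$trunkBottom + L$trunkTop) / 2
  body <- xg >= L$bodyStart & xg <= L$tailEnd &
    abs(yg - midTrunk) <= halfTrunk * (1 - 0.35 * taper)
  body <- body | ((xg - L$headCx)^2 + (yg - midTrunk)^2 <= L$headR^2)
  yolkRy <- (L$yolkBottom - midTrunk)
  body <- body | (((xg - L$yolkCx) / L$yolkRx)^2 +
                  ((yg - midTrunk) / yolkRy)^2 <= 1 & yg >= midTrunk)
  ## vessels
  vessel <- matrix(FALSE, height, width)
  railHalf <- 2L
  xVesselStart <- L$headCx + L$headR  # axial vessels start behind the head
  daRows <- (L$yDa - railHalf):(L$yDa + railHalf)
  pcvRows <- (L$yPcv - railHalf):(L$yPcv + railHalf)
  vessel[daRows, xVesselStart:L$tailEnd] <- TRUE
  vessel[pcvRows, xVesselStart:L$tailEnd] <- TRUE
  dlavCols <- rep(FALSE, width)
  if (!identical(dlavGaps, "all")) {
    dlavCols[xVesselStart:L$tailEnd] <- TRUE
    if (length(dlavGaps))
      for (g in dlavGaps)
        dlavCols[max(1, round(g[1])):min(width, round(g[2]))] <- FALSE
    vessel[(L$yDlav - railHalf):(L$yDlav + railHalf), dlavCols] <- TRUE
  }
  halfIsv <- (isvWidthPx - 1) / 2
  isvTopComplete <- L$yDlav
  isvTopIncomplete <- round(L$yDlav + 0.5 * (L$yDa - L$yDlav))
  for (i in seq_len(nIsvs)) {
    x0 <- max(1, round(L$isvX[i] - halfIsv))
    x1 <- min(width, round(L$isvX[i] + halfIsv))
    top <- if (completeFlags[i]) isvTopComplete else isvTopIncomplete
    vessel[top:L$yDa, x0:x1] <- TRUE
  }
  img <- 5 + 35 * body + 160 * vessel
  if (noiseSd > 0) img <- img + stats::rnorm(height * width, 0, noiseSd)
  img <- round(pmax(img, 0))
  ## geometric ground truth for the enclosed regions
  nRegions <- 0L
  cx <- L$isvX[completeFlags]
  if (length(cx) >= 2 && !identical(dlavGaps, "all")) {
    for (i in seq_len(length(cx) - 1)) {
      gapHit <- FALSE
      if (length(dlavGaps))
        for (g in dlavGaps)
          if (g[1] < cx[i + 1] && g[2] > cx[i]) gapHit <- TRUE
      if (!gapHit) nRegions <- nRegions + 1L
    }
  }
  list(image = img,
       truth = list(vesselMask = vessel, bodyMask = body | vessel,
                    totalISVs = as.integer(nIsvs),
                    completeISVs = as.integer(sum(completeFlags)),
                    nEnclosedRegions = nRegions,
                    isvX = L$isvX, roiStartCol = L$yolkCx,
                    lengthPx = L$length))
}

#' Synthetic sigmoidal dose-response data
#'
#' Variable-slope (four-parameter logistic) dose-response readings:
#' `response = bottom + (top - bottom) / (1 + (dose / ic50)^hill) + noise`.
#' At `dose == ic50` the noiseless response is the midpoint
#' `(top + bottom) / 2`.
#'
#' @param ic50 half-maximal concentration, uM
#' @param hill Hill slope (> 0 gives a response decreasing with dose)
#' @param top,bottom upper/lower asymptotes
#' @param doses dose vector, uM (> 0)
#' @param nPerDose replicates per dose
#' @param noiseSd Gaussian noise SD on the response
#' @param seed RNG seed
#' @return data.frame with columns `dose`, `response`
#' @export
makeDoseResponse <- function(ic50, hill = 1, top = 100, bottom = 0,
                             doses = 10^seq(-2, 2, length.out = 8),
                             nPerDose = 1, noiseSd = 0, seed = 1) {
  stopifnot(all(doses > 0), ic50 > 0)
  set.seed(seed)
  dose <- rep(doses, each = nPerDose)
  resp <- bottom + (top - bottom) / (1 + (dose / ic50)^hill)
  if (noiseSd > 0) resp <- resp + stats::rnorm(length(dose), 0, noiseSd)
  data.frame(dose = dose, response = resp)
}
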