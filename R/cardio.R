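#' @include AllClasses.R
NULL

## Tile index map for an H x W frame cut into tilePx x tilePx squares
## (remainder tiles at the right/bottom edges keep their smaller size).
.tileIndex <- function(H, W, tilePx) {
  tr <- ceiling(seq_len(H) / tilePx)
  tc <- ceiling(seq_len(W) / tilePx)
  nr <- max(tr)
  matrix(tr, H, W) + (rep(tc, each = H) - 1L) * nr
}

## nTiles x T matrix of per-tile mean intensities, one column per frame.
.tileMeans <- function(stack, tilePx) {
  fr <- frames(stack)
  d <- dim(fr)
  tid <- as.vector(.tileIndex(d[1], d[2], tilePx))
  counts <- tabulate(tid)
  dim(fr) <- c(d[1] * d[2], d[3])
  rowsum(fr, tid, reorder = TRUE) / counts
}

#' Reference field of a heart video
#'
#' The "homogeneous zones" reference: the video frame area is cut into square
#' tiles (default 8 x 8 px, remainder tiles at the edges) and the temporal
#' mean intensity of each tile over all frames is returned. Deterministic.
#'
#' @param stack a [FrameStack-class]
#' @param tilePx tile side in pixels
#' @return numeric vector of per-tile temporal means, with attributes
#'   `tilePx` and `dim` (the frame geometry) used for geometry checks
#' @export
computeReference <- function(stack, tilePx = 8) {
  stopifnot(is(stack, "FrameStack"))
  tm <- .tileMeans(stack, tilePx)
  ref <- rowMeans(tm)
  attr(ref, "tilePx") <- tilePx
  attr(ref, "frameDim") <- dim(frames(stack))[1:2]
  ref
}

#' ED and OF motion signals of a heart video
#'
#' For each frame the tile-mean intensity vector is compared with the
#' reference field: the ED signal is the Euclidean norm of the difference
#' (periodic under cardiac motion), the OF signal is the mean absolute
#' tile-brightness difference (a movement measure whose max-min amplitude
#' drops to the noise floor for a dead embryo).
#'
#' @param stack a [FrameStack-class]
#' @param reference a reference field from [computeReference()] (computed
#'   from the stack itself when omitted)
#' @return a [MotionSignals-class]
#' @export
computeMotionSignals <- function(stack, reference = NULL) {
  stopifnot(is(stack, "FrameStack"))
  if (is.null(reference)) reference <- computeReference(stack)
  tilePx <- attr(reference, "tilePx")
  if (is.null(tilePx)) tilePx <- 8
  fd <- attr(reference, "frameDim")
  if (!is.null(fd) && !all(fd == dim(frames(stack))[1:2]))
    stop("reference geometry does not match the frame stack")
  tm <- .tileMeans(stack, tilePx)
  if (nrow(tm) != length(reference))
    stop("reference geometry does not match the frame stack")
  dif <- tm - as.numeric(reference)
  ed <- sqrt(colSums(dif^2))
  of <- colMeans(abs(dif))
  new("MotionSignals", ed = ed, of = of,
      ofAmplitude = max(of) - min(of), fps = fps(stack))
}

#' Drift quality control
#'
#' Embryos that moved during video recording must be discarded: a drifting or
#' twitching embryo concentrates ED power at very low frequencies. The
#' fraction of (mean-removed) ED signal power below `lowFreqHz` is compared
#' with `driftThreshold`; the video is analysable when the fraction is below
#' the threshold.
#'
#' @param signals a [MotionSignals-class]
#' @param driftThreshold maximal tolerated low-frequency power fraction
#' @param lowFreqHz boundary of the drift band, Hz
#' @return logical: is the video analysable
#' @export
qualityControl <- function(signals, driftThreshold = 0.5, lowFreqHz = 0.3) {
  stopifnot(is(signals, "MotionSignals"))
  x <- edSignal(signals) - mean(edSignal(signals))
  if (all(x == 0)) return(TRUE)  # constant video: no drift, arrest downstream
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  fr <- (seq_len(n) - 1) * fps(signals) / n
  half <- fr <= fps(signals) / 2
  p <- p[half]
  fr <- fr[half]
  lowFrac <- sum(p[fr > 0 & fr < lowFreqHz]) / sum(p[fr > 0])
  lowFrac <= driftThreshold
}

#' Modified periodogram of the ED signal
#'
#' The DFT periodogram, modified to avoid undesired effects: the series is
#' mean-removed (suppresses the DC term), Hann-windowed (suppresses leakage
#' from drift residuals), zero-padded by `padFactor` (sub-bin frequency
#' resolution `fps / (padFactor * T)`), and power outside the physiological
#' band (default 0.5-8 Hz) is zeroed.
#'
#' @param ed numeric ED series (length >= 64) or a [MotionSignals-class]
#' @param fps sampling rate, frames per second (taken from `ed` when it is a
#'   `MotionSignals`)
#' @param bandHz analysed frequency interval, Hz
#' @param padFactor zero-padding factor, one of 1, 2, 4, 8
#' @return a [Spectrum-class]
#' @export
computePeriodogram <- function(ed, fps = 30, bandHz = c(0.5, 8),
                               padFactor = 8) {
  if (is(ed, "MotionSignals")) {
    fps <- fps(ed)
    ed <- edSignal(ed)
  }
  stopifnot(length(ed) >= 64, padFactor %in% c(1, 2, 4, 8))
  if (length(bandHz) != 2 || bandHz[1] >= bandHz[2])
    stop("empty frequency band")
  n <- length(ed)
  x <- ed - mean(ed)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  N <- padFactor * n
  p <- Mod(stats::fft(c(x * w, rep(0, N - n))))^2
  fr <- (seq_len(N) - 1) * fps / N
  half <- fr <= fps / 2
  p <- p[half]
  fr <- fr[half]
  p[fr < bandHz[1] | fr > bandHz[2]] <- 0
  new("Spectrum", freqs = fr, power = p, band = as.numeric(bandHz), fps = fps)
}

#' Significant spectral peaks
#'
#' Finds the significant frequencies of a modified periodogram. Local maxima
#' inside the band are candidate peaks; a peak is significant when its power
#' is at least `noiseMult` times the robust noise floor (the in-band median
#' divided by ln 2, the exponential-noise estimate) and at least `relThresh`
#' times the dominant in-band power. Candidate peaks at integer multiples
#' (within 3 percent relative) of the lowest significant frequency are pruned
#' as harmonics unless their power reaches `relThresh` times the dominant
#' power, so a genuine second rhythm at ratio 2 (the 2:1 arrhythmia
#' signature) survives. Peaks closer than `minSepHz` are merged (strongest
#' kept). The first significant frequency (the heart rate) is the lowest
#' surviving significant peak.
#'
#' @param spec a [Spectrum-class]
#' @param relThresh fraction of the dominant in-band power
#' @param noiseMult multiple of the in-band noise floor
#' @param minSepHz minimal separation between distinct peaks, Hz
#' @return the `Spectrum` with its `peaks` slot filled (columns `freq`,
#'   `power`, `significant`)
#' @export
detectSignificantPeaks <- function(spec, relThresh = 0.25, noiseMult = 12,
                                   minSepHz = 0.25) {
  stopifnot(is(spec, "Spectrum"))
  p <- spec@power
  fr <- spec@freqs
  inband <- fr >= spec@band[1] & fr <= spec@band[2]
  pb <- p[inband]
  fb <- fr[inband]
  empty <- function() {
    spec@peaks <- data.frame(freq = numeric(), power = numeric(),
                             significant = logical())
    spec
  }
  if (!length(pb) || all(pb == 0)) return(empty())
  noiseFloor <- stats::median(pb) / log(2)
  dominant <- max(pb)
  i <- which(diff(sign(diff(c(-Inf, pb, -Inf)))) < 0)  # local maxima
  keep <- pb[i] >= noiseMult * noiseFloor
  i <- i[keep]
  if (!length(i)) return(empty())
  ## merge peaks closer than minSepHz, keeping the strongest of each cluster
  o <- order(pb[i], decreasing = TRUE)
  sel <- integer()
  for (j in i[o])
    if (!length(sel) || all(abs(fb[j] - fb[sel]) >= minSepHz))
      sel <- c(sel, j)
  sel <- sort(sel)
  pk <- data.frame(freq = fb[sel], power = pb[sel])
  sig <- pk$power >= relThresh * dominant
  if (any(sig)) {
    f1 <- min(pk$freq[sig])
    ratio <- pk$freq / f1
    harmonic <- abs(ratio - round(ratio)) <= 0.03 * ratio & round(ratio) >= 2
    sig <- sig & (!harmonic | pk$power >= relThresh * dominant)
  }
  pk$significant <- sig
  spec@peaks <- pk
  spec
}

#' Four-way cardiotoxicity classification
#'
#' Classification logic of the cardio assay: the FFT evidence is consulted
#' only when the OF amplitude is above the cardiac-arrest threshold. A video
#' with OF amplitude below `arrestAmplitude` is `CARDIAC_ARREST` (rate 0);
#' otherwise two or more significant frequencies give `ARRHYTHMIA_21`;
#' otherwise a single significant frequency below the bradycardia cutoff
#' (36.5 beats per 15 s, the ROC-derived threshold) gives `BRADYCARDIA`, else
#' `NO_EFFECT`. A beating video without any significant peak is flagged
#' `NO_CALL` and excluded from group statistics.
#'
#' @param spec a [Spectrum-class] with peaks detected (see
#'   [detectSignificantPeaks()])
#' @param ofAmplitude OF amplitude of the video
#' @param config an [AssayConfig-class] carrying `arrestAmplitude` and
#'   `bradycardiaBeatsPer15s`
#' @param analysable quality-control flag to carry through
#' @return a [CardioResult-class]
#' @export
classifyCardio <- function(spec, ofAmplitude, config = assayConfig(),
                           analysable = TRUE) {
  stopifnot(is(spec, "Spectrum"))
  pk <- peaks(spec)
  sig <- pk[pk$significant, , drop = FALSE]
  nsig <- nrow(sig)
  if (ofAmplitude < config@arrestAmplitude) {
    return(new("CardioResult", category = "CARDIAC_ARREST", heartRateHz = 0,
               beatsPer15s = 0, nSignificantFreqs = 0L,
               ofAmplitude = ofAmplitude, analysable = analysable))
  }
  if (nsig == 0L) {
    return(new("CardioResult", category = "NO_CALL", heartRateHz = NA_real_,
               beatsPer15s = NA_real_, nSignificantFreqs = 0L,
               ofAmplitude = ofAmplitude, analysable = analysable))
  }
  rate <- min(sig$freq)  # first significant frequency
  beats15 <- 15 * rate
  cat <- if (nsig >= 2L) "ARRHYTHMIA_21"
         else if (beats15 < config@bradycardiaBeatsPer15s) "BRADYCARDIA"
         else "NO_EFFECT"
  new("CardioResult", category = cat, heartRateHz = rate,
      beatsPer15s = beats15, nSignificantFreqs = as.integer(nsig),
      ofAmplitude = ofAmplitude, analysable = analysable)
}

#' Full cardio pipeline for one video
#'
#' Reference field, motion signals, drift quality control, modified
#' periodogram, significant-peak detection and four-way classification for a
#' single heart video.
#'
#' @param stack a [FrameStack-class]
#' @param config an [AssayConfig-class]
#' @return a [CardioResult-class]
#' @examples
#' ph <- makeHeartVideo(fAtrial = 2.6, fVentricular = 2.6, seed = 1)
#' analyzeCardioVideo(ph$stack)
#' @export
analyzeCardioVideo <- function(stack, config = assayConfig()) {
  ref <- computeReference(stack, tilePx = config@tilePx)
  sig <- computeMotionSignals(stack, ref)
  ok <- qualityControl(sig, driftThreshold = config@driftThreshold,
                       lowFreqHz = config@driftBandHz)
  spec <- computePeriodogram(sig, bandHz = config@bandHz,
                             padFactor = config@padFactor)
  spec <- detectSignificantPeaks(spec, relThresh = config@relThresh,
                                 noiseMult = config@noiseMult,
                                 minSepHz = config@peakMinSepHz)
  classifyCardio(spec, ofAmplitude(sig), config, analysable = ok)
}
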