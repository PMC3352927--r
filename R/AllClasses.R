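#' @include AllGenerics.R
NULL

## ---- controlled vocabularies -------------------------------------------

#' Phenotype category codes
#'
#' Controlled vocabulary for the automatic phenotype calls. Cardio videos are
#' classified into four categories (plus the `NO_CALL` flag for videos whose
#' motion is above the cardiac-arrest threshold but where no significant
#' spectral peak was found; those embryos are excluded from group statistics).
#' Angiogenesis groups are classified as inhibited or not inhibited.
#'
#' @format Character vectors of allowed codes.
#' @export
CARDIO_CATEGORIES <- c("NO_EFFECT", "BRADYCARDIA", "ARRHYTHMIA_21",
                       "CARDIAC_ARREST", "NO_CALL")

#' @rdname CARDIO_CATEGORIES
#' @export
ANGIO_CATEGORIES <- c("INHIBITED", "NOT_INHIBITED")

## ---- FrameStack ---------------------------------------------------------

#' FrameStack: an ordered grayscale video
#'
#' Container for a heart video: a numeric `H x W x T` array of grayscale
#' intensities (frames along the third dimension, temporal order) together
#' with the frame rate. A cardiotoxicity recording is nominally 512 frames at
#' 30 frames per second; at least 64 frames are required for the spectral
#' analysis to be meaningful.
#'
#' @slot frames numeric array, `H x W x T`
#' @slot fps frames per second (> 0)
#' @slot bitDepth 8 or 16
#'
#' @export
setClass("FrameStack",
         representation(frames = "array", fps = "numeric",
                        bitDepth = "integer"),
         prototype(fps = 30, bitDepth = 16L))

setValidity("FrameStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L)
    return("'frames' must be an H x W x T array")
  if (d[3] < 64L)
    return(sprintf("need at least 64 frames, got %d", d[3]))
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    return("'fps' must be a single positive number")
  if (!object@bitDepth %in% c(8L, 16L))
    return("'bitDepth' must be 8 or 16")
  TRUE
})

#' Construct a FrameStack
#'
#' @param frames numeric `H x W x T` array
#' @param fps frames per second
#' @param bitDepth integer, 8 or 16
#' @return a [FrameStack-class] object
#' @export
FrameStack <- function(frames, fps = 30, bitDepth = 16L) {
  new("FrameStack", frames = frames, fps = as.numeric(fps),
      bitDepth = as.integer(bitDepth))
}

#' @rdname accessors
#' @export
setMethod("frames", "FrameStack", function(object) object@frames)

#' @rdname accessors
#' @export
setMethod("fps", "FrameStack", function(object) object@fps)

#' @rdname accessors
#' @export
setMethod("nFrames", "FrameStack", function(object) dim(object@frames)[3])

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d x %d px, %d frames @ %g fps (%d-bit)\n",
              d[1], d[2], d[3], object@fps, object@bitDepth))
})

## ---- MotionSignals ------------------------------------------------------

#' MotionSignals: per-frame motion measures of a heart video
#'
#' The Euclidean-distance (ED) signal is, for each frame, the Euclidean norm
#' of the difference between the frame's tile-mean intensity vector and a
#' reference vector (the temporal mean over homogeneous zones). The
#' optical-flow-style (OF) signal is the mean absolute tile-brightness
#' difference to the same reference; its max-min amplitude separates beating
#' hearts from cardiac arrest.
#'
#' @slot ed numeric length-T, non-negative
#' @slot of numeric length-T, non-negative
#' @slot ofAmplitude max(of) - min(of)
#' @slot fps frames per second of the source video
#' @export
setClass("MotionSignals",
         representation(ed = "numeric", of = "numeric",
                        ofAmplitude = "numeric", fps = "numeric"))

setValidity("MotionSignals", function(object) {
  if (length(object@ed) != length(object@of))
    return("'ed' and 'of' must have the same length")
  if (any(object@ed < -1e-9))
    return("'ed' must be non-negative")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("edSignal", "MotionSignals", function(object) object@ed)

#' @rdname accessors
#' @export
setMethod("ofSignal", "MotionSignals", function(object) object@of)

#' @rdname accessors
#' @export
setMethod("ofAmplitude", "MotionSignals", function(object) object@ofAmplitude)

#' @rdname accessors
#' @export
setMethod("fps", "MotionSignals", function(object) object@fps)

setMethod("show", "MotionSignals", function(object) {
  cat(sprintf("MotionSignals: %d samples @ %g fps, OF amplitude %.4g\n",
              length(object@ed), object@fps, object@ofAmplitude))
})

## ---- Spectrum -----------------------------------------------------------

#' Spectrum: modified periodogram of the ED signal
#'
#' One-sided periodogram of the mean-removed, Hann-windowed, zero-padded ED
#' signal with power outside the physiological band zeroed. `peaks` is filled
#' by [detectSignificantPeaks()].
#'
#' @slot freqs strictly increasing Hz grid (one-sided)
#' @slot power periodogram ordinates, zero outside `band`
#' @slot band analysed frequency interval, Hz
#' @slot fps sampling rate of the source signal
#' @slot peaks data.frame with columns `freq`, `power`, `significant`
#' @export
setClass("Spectrum",
         representation(freqs = "numeric", power = "numeric",
                        band = "numeric", fps = "numeric",
                        peaks = "data.frame"),
         prototype(peaks = data.frame(freq = numeric(), power = numeric(),
                                      significant = logical())))

setValidity("Spectrum", function(object) {
  if (length(object@freqs) != length(object@power))
    return("'freqs' and 'power' must have the same length")
  if (is.unsorted(object@freqs, strictly = TRUE))
    return("'freqs' must be strictly increasing")
  if (length(object@band) != 2L || object@band[1] >= object@band[2])
    return("'band' must be an interval c(lo, hi) with lo < hi")
  if (object@band[1] < 0 || object@band[2] > object@fps / 2 + 1e-9)
    return("'band' must lie within [0, fps/2]")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("freqs", "Spectrum", function(object) object@freqs)

#' @rdname accessors
#' @export
setMethod("specPower", "Spectrum", function(object) object@power)

#' @rdname accessors
#' @export
setMethod("peaks", "Spectrum", function(object) object@peaks)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d bins, band [%g, %g] Hz, %d peak(s) (%d significant)\n",
              length(object@freqs), object@band[1], object@band[2],
              nrow(object@peaks), sum(object@peaks$significant)))
})

## ---- CardioResult -------------------------------------------------------

#' CardioResult: per-embryo cardiotoxicity call
#'
#' The four-way call (no effect, bradycardia, 2:1 arrhythmia, cardiac arrest)
#' with its spectral evidence. Heart rate is reported both in Hz and in beats
#' per 15 s; the bradycardia cutoff (36.5) applies to the 15-s scale.
#' `analysable` is FALSE for videos rejected by the drift quality control.
#'
#' @slot category one of [CARDIO_CATEGORIES]
#' @slot heartRateHz first significant frequency, Hz (0 for arrest, NA for NO_CALL)
#' @slot beatsPer15s `heartRateHz * 15`
#' @slot nSignificantFreqs number of significant spectral peaks
#' @slot ofAmplitude OF amplitude of the video
#' @slot analysable logical quality-control flag
#' @export
setClass("CardioResult",
         representation(category = "character", heartRateHz = "numeric",
                        beatsPer15s = "numeric", nSignificantFreqs = "integer",
                        ofAmplitude = "numeric", analysable = "logical"))

setValidity("CardioResult", function(object) {
  if (!object@category %in% CARDIO_CATEGORIES)
    return(sprintf("unknown category '%s'", object@category))
  if (object@category == "ARRHYTHMIA_21" && object@nSignificantFreqs < 2L)
    return("ARRHYTHMIA_21 requires at least 2 significant frequencies")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("category", "CardioResult", function(object) object@category)

#' @rdname accessors
#' @export
setMethod("heartRateHz", "CardioResult", function(object) object@heartRateHz)

#' @rdname accessors
#' @export
setMethod("beatsPer15s", "CardioResult", function(object) object@beatsPer15s)

#' @rdname accessors
#' @export
setMethod("nSignificantFreqs", "CardioResult",
          function(object) object@nSignificantFreqs)

#' @rdname accessors
#' @export
setMethod("ofAmplitude", "CardioResult", function(object) object@ofAmplitude)

#' @rdname accessors
#' @export
setMethod("isAnalysable", "CardioResult", function(object) object@analysable)

setMethod("show", "CardioResult", function(object) {
  cat(sprintf("CardioResult: %s  rate %.3g Hz (%.1f beats/15s), %d sig. freq(s), OF amp %.3g%s\n",
              object@category, object@heartRateHz, object@beatsPer15s,
              object@nSignificantFreqs, object@ofAmplitude,
              if (object@analysable) "" else "  [not analysable]"))
})

## ---- EmbryoMask ---------------------------------------------------------

#' EmbryoMask: trunk segmentation of an angiogenesis image
#'
#' The largest connected foreground component of the thresholded fluorescence
#' image, its anterior-posterior extent in pixels, and the rectangular tail
#' region of interest (posterior to the yolk bulge) where intersegmental
#' vessels are quantified.
#'
#' @slot mask logical H x W matrix
#' @slot lengthPx embryo extent along the principal axis
#' @slot roi integer `c(row1, row2, col1, col2)` (inclusive, 1-based)
#' @slot roiFallback TRUE when the degenerate posterior-60\% fallback was used
#' @export
setClass("EmbryoMask",
         representation(mask = "matrix", lengthPx = "numeric",
                        roi = "integer", roiFallback = "logical"),
         prototype(roi = integer(), roiFallback = FALSE))

setValidity("EmbryoMask", function(object) {
  if (!is.logical(object@mask))
    return("'mask' must be a logical matrix")
  if (any(object@mask) && object@lengthPx <= 0)
    return("'lengthPx' must be > 0 for a non-empty mask")
  if (length(object@roi) == 4L) {
    d <- dim(object@mask)
    if (object@roi[1] < 1L || object@roi[3] < 1L ||
        object@roi[2] > d[1] || object@roi[4] > d[2] ||
        object@roi[1] > object@roi[2] || object@roi[3] > object@roi[4])
      return("'roi' must be a valid rectangle within the image")
  }
  TRUE
})

#' @rdname accessors
#' @export
setMethod("maskMatrix", "EmbryoMask", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("embryoLengthPx", "EmbryoMask", function(object) object@lengthPx)

#' @rdname accessors
#' @export
setMethod("roi", "EmbryoMask", function(object) object@roi)

setMethod("show", "EmbryoMask", function(object) {
  cat(sprintf("EmbryoMask: %d fg px, length %.0f px, ROI [%s]%s\n",
              sum(object@mask), object@lengthPx,
              paste(object@roi, collapse = ", "),
              if (object@roiFallback) " (fallback)" else ""))
})

## ---- VesselQuant --------------------------------------------------------

#' VesselQuant: per-embryo vessel quantification
#'
#' Enclosed-area measurement (pixels of regions bounded by the intersegmental
#' vessels, the DLAV and the dorsal aorta) plus total/complete intersegmental
#' vessel counts. Counts are NA with `railsFound = FALSE` when the axial
#' rails could not be located.
#'
#' @slot enclosedAreaPx summed area of enclosed regions
#' @slot nEnclosedRegions number of enclosed regions
#' @slot totalISVs total ISV count (NA if rails not found)
#' @slot completeISVs ISVs reaching the DLAV (NA if rails not found)
#' @slot railsFound were the DLAV and DA/PCV bands located
#' @slot embryoLengthPx embryo length carried over from segmentation
#' @export
setClass("VesselQuant",
         representation(enclosedAreaPx = "numeric",
                        nEnclosedRegions = "integer",
                        totalISVs = "integer", completeISVs = "integer",
                        railsFound = "logical", embryoLengthPx = "numeric"),
         prototype(embryoLengthPx = NA_real_))

setValidity("VesselQuant", function(object) {
  if (!is.na(object@totalISVs) && !is.na(object@completeISVs) &&
      (object@completeISVs < 0L || object@completeISVs > object@totalISVs))
    return("need 0 <= completeISVs <= totalISVs")
  if (object@nEnclosedRegions == 0L && object@enclosedAreaPx != 0)
    return("enclosedAreaPx must be 0 when there are no enclosed regions")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("enclosedAreaPx", "VesselQuant", function(object) object@enclosedAreaPx)

#' @rdname accessors
#' @export
setMethod("nEnclosedRegions", "VesselQuant", function(object) object@nEnclosedRegions)

#' @rdname accessors
#' @export
setMethod("totalISVs", "VesselQuant", function(object) object@totalISVs)

#' @rdname accessors
#' @export
setMethod("completeISVs", "VesselQuant", function(object) object@completeISVs)

#' @rdname accessors
#' @export
setMethod("railsFound", "VesselQuant", function(object) object@railsFound)

#' @rdname accessors
#' @export
setMethod("embryoLengthPx", "VesselQuant", function(object) object@embryoLengthPx)

setMethod("show", "VesselQuant", function(object) {
  cat(sprintf("VesselQuant: %d enclosed region(s), %.0f px area, ISVs %s/%s (complete/total)%s\n",
              object@nEnclosedRegions, object@enclosedAreaPx,
              ifelse(is.na(object@completeISVs), "NA", object@completeISVs),
              ifelse(is.na(object@totalISVs), "NA", object@totalISVs),
              if (object@railsFound) "" else "  [rails not found]"))
})

## ---- GroupComparison ----------------------------------------------------

#' GroupComparison: one statistical group test
#'
#' @slot statistic test statistic
#' @slot pValue p value
#' @slot adjustedP multiplicity-adjusted p (NA when not applicable)
#' @slot testName which test produced this comparison
#' @slot estimate effect estimate (difference of means where defined)
#' @export
setClass("GroupComparison",
         representation(statistic = "numeric", pValue = "numeric",
                        adjustedP = "numeric", testName = "character",
                        estimate = "numeric"),
         prototype(adjustedP = NA_real_, estimate = NA_real_))

setValidity("GroupComparison", function(object) {
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("'pValue' must be in [0, 1]")
  if (!is.na(object@adjustedP) && object@adjustedP < object@pValue - 1e-9)
    return("'adjustedP' must be >= pValue")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("pValue", "GroupComparison", function(object) object@pValue)

#' @rdname accessors
#' @export
setMethod("adjustedP", "GroupComparison", function(object) object@adjustedP)

#' @rdname accessors
#' @export
setMethod("testStatistic", "GroupComparison", function(object) object@statistic)

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison [%s]: statistic %.4g, p %.4g%s\n",
              object@testName, object@statistic, object@pValue,
              if (is.na(object@adjustedP)) ""
              else sprintf(", adjusted p %.4g", object@adjustedP)))
})
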