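#' @include AllClasses.R
NULL

#' AssayConfig: all tunables of the two assay pipelines
#'
#' Every analysis parameter has a default; a config round-trips unchanged
#' through [writeAssayConfig()] / [readAssayConfig()] and every result file
#' carries [configHash()] so that re-running with a changed threshold is
#' visible in the run manifest.
#'
#' @slot tilePx cardio homogeneous-zone tile side, px
#' @slot bandHz analysed frequency band, Hz (physiological embryo range)
#' @slot padFactor periodogram zero-padding factor
#' @slot noiseMult peak significance: multiple of the spectral noise floor
#' @slot relThresh peak significance: fraction of the dominant power
#' @slot peakMinSepHz minimal separation of distinct spectral peaks, Hz
#' @slot driftThreshold QC: maximal low-frequency ED power fraction
#' @slot driftBandHz QC: drift band upper boundary, Hz
#' @slot arrestAmplitude OF amplitude below which a video is cardiac arrest
#' @slot arrestNoiseMult calibration factor of [calibrateArrestAmplitude()]
#' @slot bradycardiaBeatsPer15s bradycardia cutoff on the beats/15 s scale
#' @slot segClosePx closing size after embryo thresholding, px
#' @slot tophatPx top-hat (background subtraction) box size for vessels, px
#' @slot vesselClosePx closing size of the vessel mask, px
#' @slot railMinFrac minimal horizontal-run fraction for an axial rail
#' @slot completeFrac ISV completeness cutoff, fraction of rail separation
#' @slot totalFrac ISV counting cutoff, fraction of rail separation
#' @slot minHoleAreaPx minimal area of a counted enclosed region, px
#' @slot anteriorLeft TRUE when the embryo head is on the left
#' @slot alpha significance level of the group statistics
#' @slot seed base seed of seeded operations
#' @export
setClass("AssayConfig",
         representation(tilePx = "numeric", bandHz = "numeric",
                        padFactor = "numeric", noiseMult = "numeric",
                        relThresh = "numeric", peakMinSepHz = "numeric",
                        driftThreshold = "numeric", driftBandHz = "numeric",
                        arrestAmplitude = "numeric",
                        arrestNoiseMult = "numeric",
                        bradycardiaBeatsPer15s = "numeric",
                        segClosePx = "numeric", tophatPx = "numeric",
                        vesselClosePx = "numeric", railMinFrac = "numeric",
                        completeFrac = "numeric", totalFrac = "numeric",
                        minHoleAreaPx = "numeric", anteriorLeft = "logical",
                        alpha = "numeric", seed = "numeric"))

setValidity("AssayConfig", function(object) {
  if (length(object@bandHz) != 2 || object@bandHz[1] >= object@bandHz[2])
    return("'bandHz' must be an interval c(lo, hi) with lo < hi")
  if (!object@padFactor %in% c(1, 2, 4, 8))
    return("'padFactor' must be one of 1, 2, 4, 8")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("'alpha' must be in (0, 1)")
  TRUE
})

#' Calibrate the cardiac-arrest OF amplitude threshold
#'
#' The arrest threshold is `mult` times the OF amplitude of a pure-noise
#' video (no cardiac motion) at the stated pixel noise level: tile means of
#' an `nTiles`-tile, `nFrames`-frame noise stack are simulated with a fixed
#' internal seed and the max-min amplitude of the mean-absolute-deviation
#' signal is scaled by `mult`.
#'
#' @param noiseSd pixel intensity noise SD the assay is configured for
#' @param tilePx tile side, px
#' @param nTiles number of tiles of the nominal video geometry
#' @param nFrames nominal frames per video
#' @param mult safety multiple over the noise-floor amplitude
#' @return the threshold, intensity units
#' @export
calibrateArrestAmplitude <- function(noiseSd = 8, tilePx = 8, nTiles = 64,
                                     nFrames = 512, mult = 5) {
  if (noiseSd == 0) return(mult * .Machine$double.eps)
  withSeed(20120515, {
    tm <- matrix(stats::rnorm(nTiles * nFrames, 0, noiseSd / tilePx),
                 nTiles, nFrames)
    of <- colMeans(abs(tm - rowMeans(tm)))
    mult * (max(of) - min(of))
  })
}

#' Build an assay configuration
#'
#' All arguments default to the package's validated settings; see
#' [AssayConfig-class] for their meaning. The default arrest threshold is
#' calibrated for the default phantom noise level (SD 8) on the nominal
#' 64 x 64 px, 512-frame geometry.
#'
#' @param tilePx,bandHz,padFactor,noiseMult,relThresh,peakMinSepHz see class
#' @param driftThreshold,driftBandHz,arrestAmplitude,arrestNoiseMult see class
#' @param bradycardiaBeatsPer15s,segClosePx,tophatPx,vesselClosePx see class
#' @param railMinFrac,completeFrac,totalFrac,minHoleAreaPx,anteriorLeft see class
#' @param alpha,seed see class
#' @return an [AssayConfig-class]
#' @export
assayConfig <- function(tilePx = 8, bandHz = c(0.5, 8), padFactor = 8,
                        noiseMult = 12, relThresh = 0.25, peakMinSepHz = 0.25,
                        driftThreshold = 0.5, driftBandHz = 0.3,
                        arrestAmplitude = NULL, arrestNoiseMult = 5,
                        bradycardiaBeatsPer15s = 36.5,
                        segClosePx = 5, tophatPx = 11, vesselClosePx = 3,
                        railMinFrac = 0.3, completeFrac = 0.9,
                        totalFrac = 0.2, minHoleAreaPx = 9,
                        anteriorLeft = TRUE, alpha = 0.05, seed = 1) {
  if (is.null(arrestAmplitude))
    arrestAmplitude <- calibrateArrestAmplitude(mult = arrestNoiseMult)
  new("AssayConfig", tilePx = tilePx, bandHz = as.numeric(bandHz),
      padFactor = padFactor, noiseMult = noiseMult, relThresh = relThresh,
      peakMinSepHz = peakMinSepHz, driftThreshold = driftThreshold,
      driftBandHz = driftBandHz, arrestAmplitude = arrestAmplitude,
      arrestNoiseMult = arrestNoiseMult,
      bradycardiaBeatsPer15s = bradycardiaBeatsPer15s,
      segClosePx = segClosePx, tophatPx = tophatPx,
      vesselClosePx = vesselClosePx, railMinFrac = railMinFrac,
      completeFrac = completeFrac, totalFrac = totalFrac,
      minHoleAreaPx = minHoleAreaPx, anteriorLeft = anteriorLeft,
      alpha = alpha, seed = seed)
}

setMethod("show", "AssayConfig", function(object) {
  cat("AssayConfig (hash", configHash(object), ")\n")
  for (nm in slotNames(object))
    cat(sprintf("  %-22s %s\n", nm,
                paste(slot(object, nm), collapse = ",")))
})

#' Write / read an assay configuration as a plain-text key-value file
#'
#' `key = value` lines, one per parameter; vector values comma-separated.
#' The round trip `readAssayConfig(writeAssayConfig(cfg, f))` reproduces the
#' configuration exactly.
#'
#' @param config an [AssayConfig-class]
#' @param path file path
#' @return `writeAssayConfig` returns `path` invisibly; `readAssayConfig`
#'   returns an [AssayConfig-class]
#' @export
writeAssayConfig <- function(config, path) {
  stopifnot(is(config, "AssayConfig"))
  lines <- vapply(slotNames(config), function(nm) {
    v <- slot(config, nm)
    fmt <- if (is.logical(v)) as.character(v)
           else formatC(v, digits = 17, format = "g")
    sprintf("%s = %s", nm, paste(fmt, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeAssayConfig
#' @export
readAssayConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- assayConfig()
  for (item in kv) {
    key <- trimws(item[1])
    val <- trimws(paste(item[-1], collapse = "="))
    if (!key %in% slotNames(cfg)) stop("unknown config key '", key, "'")
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- if (is.logical(slot(cfg, key))) as.logical(parts)
              else as.numeric(parts)
    slot(cfg, key) <- parsed
  }
  validObject(cfg)
  cfg
}

#' Hash of an assay configuration
#'
#' Polynomial rolling hash (mod 2^31 - 1) of the canonical key-value
#' serialisation; stamped into every result file so that runs with different
#' thresholds are distinguishable.
#'
#' @param config an [AssayConfig-class]
#' @return 8-character hex string
#' @export
configHash <- function(config) {
  stopifnot(is(config, "AssayConfig"))
  s <- paste(vapply(slotNames(config), function(nm) {
    v <- slot(config, nm)
    fmt <- if (is.logical(v)) as.character(v)
           else formatC(v, digits = 17, format = "g")
    paste(nm, paste(fmt, collapse = ","), sep = "=")
  }, character(1)), collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state around a seeded computation, so
#' that internally seeded operations (Monte-Carlo Dunnett, threshold
#' calibration) do not disturb user-level reproducibility.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
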