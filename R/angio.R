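#' @include AllClasses.R
NULL

.runsOfTrue <- function(x) {
  ## start/end indices of maximal TRUE runs
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Segment the embryo from a trunk fluorescence image
#'
#' Automatic histogram (Otsu) threshold, morphological closing, and largest
#' connected foreground component. The threshold is computed on
#' log-intensities: fluorescence images are trimodal (background, faint
#' body, bright vessels) over a wide dynamic range, and the log compresses
#' the vessel mode so that the threshold falls between background and body
#' instead of between body and vessels. The embryo length is the extent of
#' the mask along its principal axis.
#'
#' @param image numeric matrix (single-channel, any bit depth)
#' @param config an [AssayConfig-class]
#' @return an [EmbryoMask-class] (without ROI; see [splitHeadTail()])
#' @export
segmentEmbryo <- function(image, config = assayConfig()) {
  stopifnot(is.matrix(image))
  lg <- log1p(pmax(boxMeanFilter(image, 5), 0))
  thr <- otsuThreshold(lg)
  bw <- lg > thr
  if (!any(bw)) stop("no embryo detected")
  bw <- closeBox(bw + 0, config@segClosePx) > 0.5
  lab <- labelComponents(bw, 8)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes)) stop("no embryo detected")
  mask <- lab == which.max(sizes)
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  cc <- stats::cov(idx)
  ev <- eigen(cc, symmetric = TRUE)$vectors[, 1]
  proj <- (idx[, 1] - ctr[1]) * ev[1] + (idx[, 2] - ctr[2]) * ev[2]
  new("EmbryoMask", mask = mask, lengthPx = diff(range(proj)) + 1,
      roi = integer(), roiFallback = FALSE)
}

#' Locate the tail region of interest
#'
#' Computes the column-wise thickness profile of the embryo mask along the
#' anterior-posterior axis. The trunk ROI (where intersegmental vessels are
#' counted) starts immediately posterior to the global thickness maximum
#' (the largest bulge of the yolk) and extends to the posterior tip. When
#' the profile is degenerate (flat or monotone, no recognisable bulge) the
#' ROI falls back to the posterior 60 percent of the embryo length and a
#' warning is raised.
#'
#' @param emask an [EmbryoMask-class] from [segmentEmbryo()]
#' @param config an [AssayConfig-class]; `anteriorLeft` selects the axis
#'   orientation
#' @return the `EmbryoMask` with its `roi` slot set
#'   (`c(row1, row2, col1, col2)`)
#' @export
splitHeadTail <- function(emask, config = assayConfig()) {
  stopifnot(is(emask, "EmbryoMask"))
  mask <- maskMatrix(emask)
  if (!any(mask)) stop("empty embryo mask")
  if (!config@anteriorLeft) mask <- mask[, rev(seq_len(ncol(mask)))]
  thick <- colSums(mask)
  cols <- which(thick > 0)
  prof <- thick[cols]
  k <- min(9L, length(prof))
  sm <- stats::filter(prof, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- prof[is.na(sm)]
  sm <- as.numeric(sm)
  ## no recognisable bulge: peak prominence over the typical thickness
  flat <- (max(sm) - stats::median(sm)) / stats::median(sm) < 0.1
  monotone <- all(diff(sm) >= -1e-9) || all(diff(sm) <= 1e-9)
  if (flat || monotone) {
    warning("degenerate thickness profile; falling back to posterior 60% ROI")
    startCol <- cols[1] + round(0.4 * (length(cols) - 1))
    fallback <- TRUE
  } else {
    startCol <- cols[which.max(sm)] + 1L
    fallback <- FALSE
  }
  endCol <- cols[length(cols)]
  if (startCol >= endCol) startCol <- cols[1]
  rows <- which(rowSums(mask[, startCol:endCol, drop = FALSE]) > 0)
  margin <- 2L
  r1 <- max(1L, min(rows) - margin)
  r2 <- min(nrow(mask), max(rows) + margin)
  if (!config@anteriorLeft) {
    w <- ncol(mask)
    tmp <- startCol
    startCol <- w - endCol + 1L
    endCol <- w - tmp + 1L
  }
  emask@roi <- as.integer(c(r1, r2, startCol, endCol))
  emask@roiFallback <- fallback
  validObject(emask)
  emask
}

#' Extract the vessel mask inside the ROI
#'
#' Within the tail ROI: white top-hat background subtraction (removes the
#' diffuse body fluorescence), automatic threshold, thin-object closing, and
#' removal of fluorescent areas that should not be quantified - components
#' not connected to the axial vessels (kept components must span at least
#' half the ROI width, which the DA/PCV and DLAV rails do and to which all
#' genuine ISVs connect).
#'
#' @param image numeric matrix (the full image)
#' @param roi integer `c(row1, row2, col1, col2)` or an [EmbryoMask-class]
#' @param config an [AssayConfig-class]
#' @return logical matrix of the image size; TRUE = vessel (empty outside
#'   the ROI)
#' @export
extractVesselMask <- function(image, roi, config = assayConfig()) {
  if (is(roi, "EmbryoMask")) roi <- roi(roi)
  stopifnot(length(roi) == 4)
  crop <- image[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  th <- topHat(crop, config@tophatPx)
  ## Otsu splits even a pure-noise crop, so the threshold is floored at a
  ## robust estimate of the top-hat noise ceiling (median + 6 MAD)
  noiseCeil <- stats::median(th) + 6 * stats::mad(th)
  bw <- th > max(otsuThreshold(th), noiseCeil)
  bw <- closeBox(bw + 0, config@vesselClosePx) > 0.5
  lab <- labelComponents(bw, 8)
  keepMask <- matrix(FALSE, nrow(bw), ncol(bw))
  if (max(lab) > 0) {
    cols <- col(lab)[lab > 0]
    labs <- lab[lab > 0]
    widths <- tapply(cols, labs, function(x) diff(range(x)) + 1L)
    keep <- as.integer(names(widths))[widths >= 0.5 * ncol(bw)]
    if (length(keep)) keepMask <- matrix(lab %in% keep, nrow(bw), ncol(bw))
  }
  out <- matrix(FALSE, nrow(image), ncol(image))
  out[roi[1]:roi[2], roi[3]:roi[4]] <- keepMask
  out
}

#' Measure the areas enclosed by the vessel network
#'
#' Enclosed regions are the topological holes of the vessel mask inside the
#' ROI: background components (4-connectivity) completely surrounded by
#' vessel pixels. Components touching the ROI border are open and therefore
#' excluded - when vessels are incomplete or the DLAV is absent no enclosed
#' area exists and nothing is measured. Holes smaller than `minHoleAreaPx`
#' (pinholes from pixel noise) are ignored.
#'
#' @param vesselMask logical matrix from [extractVesselMask()] (or any
#'   boolean mask)
#' @param roi integer `c(row1, row2, col1, col2)` or an [EmbryoMask-class]
#' @param config an [AssayConfig-class]
#' @return list with `enclosedAreaPx` and `nEnclosedRegions`
#' @export
measureEnclosedAreas <- function(vesselMask, roi, config = assayConfig()) {
  if (is(roi, "EmbryoMask")) roi <- roi(roi)
  crop <- vesselMask[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  lab <- labelComponents(!crop, 4)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  if (max(lab) == 0)
    return(list(enclosedAreaPx = 0, nEnclosedRegions = 0L))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  holeIds <- setdiff(which(sizes >= config@minHoleAreaPx), border)
  list(enclosedAreaPx = sum(sizes[holeIds]),
       nEnclosedRegions = length(holeIds))
}

## Locate the axial rails (DLAV band, DA/PCV band) in a ROI crop.
.findRails <- function(crop, railMinFrac) {
  rs <- rowSums(crop)
  railRows <- rs >= railMinFrac * ncol(crop)
  if (!any(railRows)) return(NULL)
  bands <- .runsOfTrue(railRows)
  if (nrow(bands) < 2) return(NULL)
  dlav <- bands[1, ]
  ventral <- bands[2, ]
  ## the DLAV must sit well above the DA; two adjacent ventral bands
  ## (DA + PCV with a missing DLAV) are not a valid rail pair
  if (ventral["start"] - dlav["end"] < 0.2 * nrow(crop)) return(NULL)
  list(dlavEnd = unname(dlav["end"]), daStart = unname(ventral["start"]),
       railSep = unname(ventral["start"] - dlav["end"] - 1L))
}

#' Count total and complete intersegmental vessels
#'
#' Locates the axial rails as horizontal-run maxima (the dorsal band is the
#' DLAV, the ventral band the DA/PCV), removes them, and counts the
#' remaining vertical components between the rails: candidates at least
#' `totalFrac` of the rail separation tall are ISVs; candidates spanning at
#' least `completeFrac` of the separation and touching the DLAV band are
#' complete ISVs (they reached the dorsal side and formed the DLAV). When
#' the rails cannot be located the counts are reported missing
#' (`railsFound = FALSE`).
#'
#' @param vesselMask logical matrix
#' @param roi integer `c(row1, row2, col1, col2)` or an [EmbryoMask-class]
#' @param config an [AssayConfig-class]
#' @return list with `totalISVs`, `completeISVs` (NA when flagged) and
#'   `railsFound`
#' @export
countISVs <- function(vesselMask, roi, config = assayConfig()) {
  if (is(roi, "EmbryoMask")) roi <- roi(roi)
  crop <- vesselMask[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  rails <- .findRails(crop, config@railMinFrac)
  if (is.null(rails))
    return(list(totalISVs = NA_integer_, completeISVs = NA_integer_,
                railsFound = FALSE))
  rows <- (rails$dlavEnd + 1L):(rails$daStart - 1L)
  inter <- crop[rows, , drop = FALSE]
  lab <- labelComponents(inter, 8)
  if (max(lab) == 0)
    return(list(totalISVs = 0L, completeISVs = 0L, railsFound = TRUE))
  rr <- row(lab)[lab > 0]
  ll <- lab[lab > 0]
  top <- tapply(rr, ll, min)
  bottom <- tapply(rr, ll, max)
  height <- bottom - top + 1L
  isTotal <- height >= config@totalFrac * rails$railSep
  isComplete <- height >= config@completeFrac * rails$railSep & top <= 2L
  list(totalISVs = as.integer(sum(isTotal)),
       completeISVs = as.integer(sum(isComplete & isTotal)),
       railsFound = TRUE)
}

#' Full vessel quantification of one image
#'
#' Segmentation, head/tail split, vessel-mask extraction, enclosed-area
#' measurement and ISV counting for a single trunk fluorescence image.
#'
#' @param image numeric matrix
#' @param config an [AssayConfig-class]
#' @return a [VesselQuant-class]
#' @examples
#' ph <- makeVesselImage(nIsvs = 10, seed = 2)
#' quantifyVessels(ph$image)
#' @export
quantifyVessels <- function(image, config = assayConfig()) {
  emask <- splitHeadTail(segmentEmbryo(image, config), config)
  vm <- extractVesselMask(image, emask, config)
  areas <- measureEnclosedAreas(vm, emask, config)
  counts <- countISVs(vm, emask, config)
  new("VesselQuant",
      enclosedAreaPx = areas$enclosedAreaPx,
      nEnclosedRegions = as.integer(areas$nEnclosedRegions),
      totalISVs = counts$totalISVs, completeISVs = counts$completeISVs,
      railsFound = counts$railsFound,
      embryoLengthPx = embryoLengthPx(emask))
}

.quantToDF <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("enclosedAreaPx" %in% names(x))
    return(x)
  }
  if (is(x, "VesselQuant")) x <- list(x)
  stopifnot(is.list(x), all(vapply(x, is, logical(1), "VesselQuant")))
  data.frame(
    enclosedAreaPx = vapply(x, enclosedAreaPx, numeric(1)),
    nEnclosedRegions = vapply(x, nEnclosedRegions, integer(1)),
    totalISVs = vapply(x, totalISVs, integer(1)),
    completeISVs = vapply(x, completeISVs, integer(1)))
}

#' Call angiogenesis inhibition for a treated group
#'
#' Compares the enclosed-area mean of a treated group with the vehicle
#' control (one-way ANOVA with Dunnett adjustment against the control) and
#' calls `INHIBITED` when the adjusted p value is below `alpha` with the
#' treated mean below the control mean. The total/complete ISV count
#' summaries are attached as the deeper analysis that accompanies a
#' significant call. Both groups must contain at least 10 analysable
#' embryos.
#'
#' @param treated,control groups of [VesselQuant-class] objects (list), or
#'   data frames with an `enclosedAreaPx` column
#' @param alpha significance level
#' @param config an [AssayConfig-class] (used when `alpha` is missing)
#' @return list with `category` (one of [ANGIO_CATEGORIES]), `comparison`
#'   (a [GroupComparison-class]), and `summary` (group means)
#' @export
callInhibition <- function(treated, control, alpha = config@alpha,
                           config = assayConfig()) {
  trt <- .quantToDF(treated)
  ctl <- .quantToDF(control)
  if (nrow(trt) < 10 || nrow(ctl) < 10)
    stop("need at least 10 analysable embryos per group")
  res <- anovaDunnett(list(control = ctl$enclosedAreaPx,
                           treated = trt$enclosedAreaPx),
                      controlIndex = 1, alpha = alpha)
  cmp <- res$comparisons[[1]]
  inhibited <- !is.na(adjustedP(cmp)) && adjustedP(cmp) < alpha &&
    mean(trt$enclosedAreaPx) < mean(ctl$enclosedAreaPx)
  meanOrNA <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  list(category = if (inhibited) "INHIBITED" else "NOT_INHIBITED",
       comparison = cmp,
       summary = data.frame(
         group = c("control", "treated"),
         meanEnclosedArea = c(mean(ctl$enclosedAreaPx),
                              mean(trt$enclosedAreaPx)),
         meanTotalISVs = c(meanOrNA(ctl$totalISVs), meanOrNA(trt$totalISVs)),
         meanCompleteISVs = c(meanOrNA(ctl$completeISVs),
                              meanOrNA(trt$completeISVs))))
}
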