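#' @include AllClasses.R
NULL

#' Connected-component labelling
#'
#' Labels connected foreground components of a logical matrix. Vessels use
#' 8-connectivity and holes 4-connectivity (the standard complementary
#' pairing).
#'
#' @param mask logical matrix
#' @param connectivity 4 or 8
#' @return integer matrix of component labels, 0 = background
#' @export
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  storage.mode(mask) <- "logical"
  .cpp_label(mask, as.integer(connectivity))
}

#' Grayscale box morphology
#'
#' Erosion, dilation, opening, closing and white top-hat with a rectangular
#' (box) structuring element of odd side `size` (or `c(sizeRows, sizeCols)`).
#' Binary masks can be passed as 0/1 matrices.
#'
#' @param img numeric matrix
#' @param size odd box side length, scalar or length-2 (rows, cols)
#' @return numeric matrix of the same dimension
#' @name morphology
NULL

.boxHalf <- function(size) {
  size <- as.integer(rep(size, length.out = 2L))
  if (any(size < 1L) || any(size %% 2L == 0L))
    stop("structuring element sides must be odd and >= 1")
  (size - 1L) %/% 2L
}

#' @rdname morphology
#' @export
erodeBox <- function(img, size) {
  h <- .boxHalf(size)
  .cpp_box_minmax(img, h[1], h[2], 0L)
}

#' @rdname morphology
#' @export
dilateBox <- function(img, size) {
  h <- .boxHalf(size)
  .cpp_box_minmax(img, h[1], h[2], 1L)
}

#' @rdname morphology
#' @export
openBox <- function(img, size) dilateBox(erodeBox(img, size), size)

#' @rdname morphology
#' @export
closeBox <- function(img, size) erodeBox(dilateBox(img, size), size)

#' @rdname morphology
#' @export
topHat <- function(img, size) img - openBox(img, size)

#' Box mean filter
#'
#' Local mean smoothing with a square window (integral-image
#' implementation, edge-normalised). Used to suppress pixel noise before
#' thresholding.
#'
#' @param img numeric matrix
#' @param size odd window side
#' @return smoothed matrix of the same dimension
#' @export
boxMeanFilter <- function(img, size) {
  h <- .boxHalf(size)[1]
  H <- nrow(img)
  W <- ncol(img)
  ## integral image with a zero border
  int <- matrix(0, H + 1, W + 1)
  int[-1, -1] <- t(apply(apply(img, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(H) - h, 1)
  r2 <- pmin(seq_len(H) + h, H)
  c1 <- pmax(seq_len(W) - h, 1)
  c2 <- pmin(seq_len(W) + h, W)
  s <- int[r2 + 1, c2 + 1, drop = FALSE] - int[r1, c2 + 1, drop = FALSE] -
    int[r2 + 1, c1, drop = FALSE] + int[r1, c1, drop = FALSE]
  area <- outer(r2 - r1 + 1, c2 - c1 + 1)
  s / area
}

#' Otsu threshold
#'
#' Histogram-based automatic global threshold maximising the between-class
#' variance.
#'
#' @param x numeric vector or matrix of intensities
#' @param nbins number of histogram bins
#' @return the threshold value; foreground is `x > threshold`
#' @export
otsuThreshold <- function(x, nbins = 256) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE),
                           nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  wTot <- w[nbins]
  mTot <- m[nbins]
  w1 <- w[-nbins]
  m1 <- m[-nbins]
  valid <- w1 > 0 & w1 < wTot
  bc <- rep(-Inf, nbins - 1L)
  bc[valid] <- (mTot * w1[valid] - wTot * m1[valid])^2 /
    (w1[valid] * (wTot - w1[valid]))
  mids[which.max(bc)]
}
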