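#' @include AllClasses.R
NULL

## Minimal baseline TIFF support (uncompressed, single-channel grayscale,
## 8/16-bit, multi-page). No TIFF reader is available in the installed R
## stack, so the subset of the format the platform uses is implemented here.

.u16raw <- function(v) {
  v <- as.integer(v)
  as.raw(as.vector(rbind(v %% 256L, (v %/% 256L) %% 256L)))
}

.u32raw <- function(v) {
  v <- as.numeric(v)
  as.raw(as.vector(rbind(v %% 256, (v %/% 256) %% 256,
                         (v %/% 65536) %% 256, (v %/% 16777216) %% 256)))
}

.ifdEntry <- function(tag, type, count, value) {
  ## value is already the 4-byte field content (raw)
  c(.u16raw(tag), .u16raw(type), .u32raw(count), value)
}

.shortValue <- function(v) c(.u16raw(v), as.raw(c(0, 0)))

#' Write a grayscale multi-page TIFF
#'
#' Baseline little-endian uncompressed TIFF, one strip per page. Intensities
#' are clamped to the bit-depth range and rounded.
#'
#' @param pages a numeric matrix (single page) or list of matrices (equal
#'   geometry) or an `H x W x T` array
#' @param path output file
#' @param bitDepth 8 or 16
#' @return `path`, invisibly
#' @export
writeTIFF <- function(pages, path, bitDepth = 16L) {
  if (is.matrix(pages)) pages <- list(pages)
  if (is.array(pages) && length(dim(pages)) == 3)
    pages <- lapply(seq_len(dim(pages)[3]), function(k) pages[, , k])
  stopifnot(bitDepth %in% c(8L, 16L), length(pages) >= 1)
  H <- nrow(pages[[1]])
  W <- ncol(pages[[1]])
  bytes <- bitDepth / 8
  maxVal <- 2^bitDepth - 1
  nIFD <- 9L
  ifdSize <- 2L + nIFD * 12L + 4L
  dataSize <- H * W * bytes
  pad <- dataSize %% 2
  pageSize <- ifdSize + dataSize + pad
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), .u16raw(42), .u32raw(8)), con)
  offset <- 8
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    if (nrow(m) != H || ncol(m) != W)
      stop("all pages must have the same geometry")
    dataOffset <- offset + ifdSize
    nextIFD <- if (i < length(pages)) offset + pageSize else 0
    ifd <- c(
      .u16raw(nIFD),
      .ifdEntry(256, 4, 1, .u32raw(W)),
      .ifdEntry(257, 4, 1, .u32raw(H)),
      .ifdEntry(258, 3, 1, .shortValue(bitDepth)),
      .ifdEntry(259, 3, 1, .shortValue(1)),        # no compression
      .ifdEntry(262, 3, 1, .shortValue(1)),        # BlackIsZero
      .ifdEntry(273, 4, 1, .u32raw(dataOffset)),
      .ifdEntry(277, 3, 1, .shortValue(1)),
      .ifdEntry(278, 4, 1, .u32raw(H)),
      .ifdEntry(279, 4, 1, .u32raw(dataSize)),
      .u32raw(nextIFD))
    v <- as.vector(t(round(pmin(pmax(m, 0), maxVal))))  # row-major
    pix <- if (bitDepth == 8L) as.raw(as.integer(v)) else .u16raw(v)
    if (pad) pix <- c(pix, as.raw(0))
    writeBin(c(ifd, pix), con)
    offset <- offset + pageSize
  }
  invisible(path)
}

.rd16 <- function(buf, pos, le) {
  a <- as.integer(buf[pos])
  b <- as.integer(buf[pos + 1])
  if (le) a + 256L * b else 256L * a + b
}

.rd32 <- function(buf, pos, le) {
  v <- as.numeric(as.integer(buf[pos + 0:3]))
  if (le) sum(v * c(1, 256, 65536, 16777216))
  else sum(v * c(16777216, 65536, 256, 1))
}

.readIFDValue <- function(buf, entryPos, le) {
  type <- .rd16(buf, entryPos + 2, le)
  count <- .rd32(buf, entryPos + 4, le)
  size <- c(1, 1, 2, 4)[type]  # BYTE/ASCII/SHORT/LONG
  if (is.na(size)) return(NULL)
  total <- size * count
  pos <- if (total <= 4) entryPos + 8 else .rd32(buf, entryPos + 8, le) + 1
  if (size == 2) vapply(seq_len(count), function(k)
    .rd16(buf, pos + 2 * (k - 1), le), numeric(1))
  else if (size == 4) vapply(seq_len(count), function(k)
    .rd32(buf, pos + 4 * (k - 1), le), numeric(1))
  else as.numeric(as.integer(buf[pos + seq_len(count) - 1]))
}

#' Read a grayscale multi-page TIFF
#'
#' Reads uncompressed single-channel baseline TIFF files (either byte
#' order, 8 or 16 bit, any strip layout).
#'
#' @param path TIFF file
#' @return list of numeric matrices (one per page), with attribute
#'   `bitDepth`
#' @export
readTIFF <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 8) stop("not a TIFF file: ", path)
  le <- buf[1] == as.raw(0x49) && buf[2] == as.raw(0x49)
  be <- buf[1] == as.raw(0x4d) && buf[2] == as.raw(0x4d)
  if (!le && !be) stop("unreadable format (not a TIFF): ", path)
  if (.rd16(buf, 3, le) != 42) stop("unreadable format (not a TIFF): ", path)
  ifdOffset <- .rd32(buf, 5, le)
  pages <- list()
  bits <- 16
  while (ifdOffset != 0) {
    p <- ifdOffset + 1
    n <- .rd16(buf, p, le)
    tags <- list()
    for (e in seq_len(n)) {
      ep <- p + 2 + (e - 1) * 12
      tag <- .rd16(buf, ep, le)
      tags[[as.character(tag)]] <- .readIFDValue(buf, ep, le)
    }
    W <- tags[["256"]]
    H <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 8 else tags[["258"]][1]
    comp <- if (is.null(tags[["259"]])) 1 else tags[["259"]]
    if (comp != 1) stop("unreadable codec (compressed TIFF): ", path)
    if (!bits %in% c(8, 16)) stop("unsupported bit depth in ", path)
    offs <- tags[["273"]]
    counts <- tags[["279"]]
    if (is.null(counts)) counts <- H * W * bits / 8
    pix <- unlist(lapply(seq_along(offs), function(s) {
      bytes <- buf[offs[s] + seq_len(counts[s])]
      if (bits == 8) as.numeric(as.integer(bytes))
      else {
        v <- as.integer(bytes)
        i <- seq(1, length(v), by = 2)
        if (le) v[i] + 256 * v[i + 1] else 256 * v[i] + v[i + 1]
      }
    }))
    if (length(pix) != H * W) stop("corrupt TIFF page in ", path)
    pages[[length(pages) + 1]] <- matrix(pix, nrow = H, ncol = W,
                                         byrow = TRUE)
    ifdOffset <- .rd32(buf, p + 2 + n * 12, le)
  }
  attr(pages, "bitDepth") <- as.integer(bits)
  pages
}

#' Read a heart video into a FrameStack
#'
#' Multi-page TIFF, pages in temporal order. The frame rate is taken from a
#' `<path>.json` sidecar (written by [writeFrameStack()]) when present, from
#' the `fps` argument otherwise, defaulting to 30.
#'
#' @param path multi-page TIFF
#' @param fps frame rate override
#' @return a [FrameStack-class]
#' @export
readFrameStack <- function(path, fps = NULL) {
  if (grepl("\\.avi$", path, ignore.case = TRUE))
    stop("unreadable codec: AVI input is not supported for ", path,
         "; convert to multi-page TIFF")
  pages <- readTIFF(path)
  dims <- vapply(pages, dim, integer(2))
  if (length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1)
    stop("mixed frame sizes in ", path)
  if (length(pages) < 64)
    stop(sprintf("%s has %d frame(s); at least 64 are required", path,
                 length(pages)))
  sidecar <- paste0(path, ".json")
  if (is.null(fps))
    fps <- if (file.exists(sidecar))
      jsonlite::fromJSON(sidecar)$fps else 30
  fr <- array(unlist(pages), dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                                     length(pages)))
  FrameStack(fr, fps = fps, bitDepth = attr(pages, "bitDepth"))
}

#' Write a FrameStack to a multi-page TIFF (plus fps sidecar)
#'
#' @param stack a [FrameStack-class]
#' @param path output TIFF path; the frame rate goes to `<path>.json`
#' @return `path`, invisibly
#' @export
writeFrameStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  writeTIFF(frames(stack), path, bitDepth = stack@bitDepth)
  jsonlite::write_json(list(fps = fps(stack), nFrames = nFrames(stack)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read / write a single grayscale image
#'
#' Single-page convenience wrappers around [readTIFF()] / [writeTIFF()] for
#' the angiogenesis images.
#'
#' @param path TIFF file
#' @param image numeric matrix
#' @param bitDepth 8 or 16
#' @return `readGrayImage`: a numeric matrix; `writeGrayImage`: `path`
#' @export
readGrayImage <- function(path) {
  readTIFF(path)[[1]]
}

#' @rdname readGrayImage
#' @export
writeGrayImage <- function(image, path, bitDepth = 16L) {
  writeTIFF(image, path, bitDepth = bitDepth)
  invisible(path)
}
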