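# Minimal multi-page 32-bit floating-point TIFF codec (baseline,
# uncompressed, little-endian, SampleFormat = IEEE float). No TIFF package
# is available in the offline R stack, and the format contract (one page per
# B-scan, bit-exact float32 round trip) is part of this package's I/O
# surface, so the few tags needed are written and parsed here directly.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L,
               sample_format = 339L)

#' Write a list of matrices as a multi-page 32-bit float TIFF
#'
#' @param pages List of numeric matrices (all the same size); each page is
#'   stored as one uncompressed strip of IEEE float32 scanlines.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_f32 <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  wle <- function(x, size) writeBin(as.integer(x), con, size = size,
                                    endian = "little")
  writeBin(charToRaw("II"), con); wle(42, 2)
  data_bytes <- 4 * w * h
  n_entries <- 10L
  ifd_bytes <- 2 + n_entries * 12 + 4
  # layout per page: [pixel data][IFD]; header points at page 1's IFD
  page_start <- function(k) 8 + (k - 1) * (data_bytes + ifd_bytes)
  wle(page_start(1) + data_bytes, 4)
  entry <- function(tag, type, count, value) {
    wle(tag, 2); wle(type, 2); wle(count, 4)
    if (type == 3) { wle(value, 2); wle(0, 2) } else wle(value, 4)
  }
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    stopifnot(nrow(pg) == h, ncol(pg) == w)
    writeBin(as.numeric(t(pg)), con, size = 4, endian = "little")
    wle(n_entries, 2)
    entry(TIFF_TAGS[["width"]], 3, 1, w)
    entry(TIFF_TAGS[["length"]], 3, 1, h)
    entry(TIFF_TAGS[["bits"]], 3, 1, 32)
    entry(TIFF_TAGS[["compression"]], 3, 1, 1)
    entry(TIFF_TAGS[["photometric"]], 3, 1, 1)
    entry(TIFF_TAGS[["strip_offsets"]], 4, 1, page_start(k))
    entry(TIFF_TAGS[["spp"]], 3, 1, 1)
    entry(TIFF_TAGS[["rows_per_strip"]], 3, 1, h)
    entry(TIFF_TAGS[["strip_bytes"]], 4, 1, data_bytes)
    entry(TIFF_TAGS[["sample_format"]], 3, 1, 3)
    wle(if (k < length(pages)) page_start(k + 1) + data_bytes else 0, 4)
  }
  invisible(path)
}

#' Read a multi-page 32-bit float TIFF written by [write_tiff_f32()]
#'
#' Parses little-endian baseline TIFF IFDs; only uncompressed single-sample
#' IEEE float32 pages are supported.
#'
#' @param path File path.
#' @return List of numeric matrices, one per page.
#' @export
read_tiff_f32 <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u <- function(off, size)  # unsigned little-endian integer at byte offset
    sum(as.integer(raw[(off + 1):(off + size)]) * 256^(0:(size - 1)))
  if (rawToChar(raw[1:2]) != "II" || u(2, 2) != 42)
    stop("not a little-endian TIFF file")
  ifd <- u(4, 4)
  pages <- list()
  while (ifd != 0) {
    n <- u(ifd, 2)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u(off, 2); type <- u(off + 2, 2)
      val <- u(off + 8, if (type == 3) 2 else 4)
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    if (g(TIFF_TAGS[["compression"]], 1) != 1 ||
        g(TIFF_TAGS[["bits"]], 1) != 32 ||
        g(TIFF_TAGS[["sample_format"]], 1) != 3 ||
        g(TIFF_TAGS[["spp"]], 1) != 1)
      stop("unsupported TIFF variant (need uncompressed float32, 1 sample)")
    w <- g(TIFF_TAGS[["width"]]); h <- g(TIFF_TAGS[["length"]])
    so <- g(TIFF_TAGS[["strip_offsets"]])
    sb <- g(TIFF_TAGS[["strip_bytes"]])
    vals <- readBin(raw[(so + 1):(so + sb)], "numeric", n = w * h,
                    size = 4, endian = "little")
    pages[[length(pages) + 1]] <- matrix(vals, nrow = h, ncol = w,
                                         byrow = TRUE)
    ifd <- u(ifd + 2 + n * 12, 4)
  }
  pages
}
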