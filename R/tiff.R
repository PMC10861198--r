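# Minimal baseline TIFF I/O (little-endian, uncompressed, grayscale).
#
# The package writes 16-bit unsigned images (rendered scenes, label images)
# and 32-bit float planes (orientation fields), and reads back the same
# baseline subset: Compression = 1, PhotometricInterpretation = 0/1,
# SamplesPerPixel = 1, one or more strips, chained IFDs for multi-plane
# files. This is deliberately a small codec, not a general TIFF library.

u16le <- function(v) {
  v <- as.integer(round(v))
  as.raw(rbind(v %% 256L, v %/% 256L))
}
u32le <- function(v) {
  v <- as.double(v)
  as.raw(rbind(v %% 256, (v %/% 256) %% 256,
               (v %/% 65536) %% 256, (v %/% 16777216) %% 256))
}

tiff_entry <- function(tag, type, count, value) {
  # value must already fit in 4 bytes (all entries here do)
  val <- switch(as.character(type),
    "3" = c(u16le(value), as.raw(c(0, 0))[seq_len(4 - 2 * length(value))]),
    "4" = u32le(value))
  c(u16le(tag), u16le(type), u32le(count), val)
}

#' Write a grayscale image (or image stack) as baseline TIFF
#'
#' @param img a numeric matrix, or a list of matrices of equal size written
#'   as one multi-plane (multi-IFD) file.
#' @param path output file path.
#' @param bits 16 (unsigned integer, values clamped to 0..65535 and rounded)
#'   or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, bits = 16L) {
  if (is.matrix(img)) img <- list(img)
  stopifnot(length(img) >= 1L, all(vapply(img, is.matrix, TRUE)))
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), u16le(42L), u32le(8L)), con)
  offset <- 8
  n_planes <- length(img)
  for (p in seq_len(n_planes)) {
    m <- img[[p]]
    nr <- nrow(m); nc <- ncol(m)
    n_entries <- 9L
    ifd_size <- 2 + n_entries * 12 + 4
    data_off <- offset + ifd_size
    n_bytes <- nr * nc * (bits / 8)
    next_ifd <- if (p < n_planes) data_off + n_bytes else 0
    entries <- c(
      tiff_entry(256L, 3L, 1L, nc),                    # ImageWidth
      tiff_entry(257L, 3L, 1L, nr),                    # ImageLength
      tiff_entry(258L, 3L, 1L, bits),                  # BitsPerSample
      tiff_entry(259L, 3L, 1L, 1L),                    # Compression: none
      tiff_entry(262L, 3L, 1L, 1L),                    # Photometric: BlackIsZero
      tiff_entry(273L, 4L, 1L, data_off),              # StripOffsets
      tiff_entry(277L, 3L, 1L, 1L),                    # SamplesPerPixel
      tiff_entry(279L, 4L, 1L, n_bytes),               # StripByteCounts
      tiff_entry(339L, 3L, 1L, if (bits == 32L) 3L else 1L) # SampleFormat
    )
    writeBin(c(u16le(n_entries), entries, u32le(next_ifd)), con)
    # pixel data, row-major (TIFF scanlines) = transpose of R's column-major
    v <- as.vector(t(m))
    if (bits == 16L) {
      writeBin(u16le(pmin(pmax(round(v), 0), 65535)), con)
    } else {
      writeBin(as.numeric(v), con, size = 4L, endian = "little")
    }
    offset <- data_off + n_bytes
  }
  invisible(path)
}

read_u <- function(raw, pos, n_bytes) {
  # little-endian unsigned integer from raw vector (1-based pos)
  sum(as.double(raw[pos:(pos + n_bytes - 1)]) * 256^(0:(n_bytes - 1)))
}

#' Read a baseline grayscale TIFF written by [write_tiff()]
#'
#' Supports uncompressed, little-endian, single-sample images with 8/16-bit
#' unsigned or 32-bit float pixels; multi-IFD files return a list.
#'
#' @param path file path.
#' @return a numeric matrix, or a list of matrices if the file has several
#'   planes.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (!(raw[1] == 0x49 && raw[2] == 0x49))
    stop("only little-endian TIFF is supported")
  if (read_u(raw, 3, 2) != 42) stop("not a TIFF file")
  ifd_off <- read_u(raw, 5, 4)
  planes <- list()
  while (ifd_off != 0) {
    n <- read_u(raw, ifd_off + 1, 2)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 3 + (i - 1) * 12
      tag <- read_u(raw, e, 2)
      type <- read_u(raw, e + 2, 2)
      count <- read_u(raw, e + 4, 4)
      val <- if (type == 3 && count == 1) read_u(raw, e + 8, 2)
             else read_u(raw, e + 8, 4)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = val, entry_pos = e)
    }
    gettag <- function(id, default = NULL) {
      t <- tags[[as.character(id)]]
      if (is.null(t)) default else t$value
    }
    if (gettag(259, 1) != 1) stop("compressed TIFF is not supported")
    nc_img <- gettag(256); nr_img <- gettag(257)
    bits <- gettag(258, 8)
    fmt <- gettag(339, 1)
    # strip offsets/counts may be inline (count 1) or stored as an array
    strip_tag <- tags[["273"]]
    cnt_tag <- tags[["279"]]
    read_arr <- function(t) {
      if (t$count == 1) return(t$value)
      off <- t$value
      size <- if (t$type == 3) 2 else 4
      vapply(seq_len(t$count),
             function(k) read_u(raw, off + 1 + (k - 1) * size, size), 0)
    }
    offs <- read_arr(strip_tag)
    cnts <- read_arr(cnt_tag)
    bytes <- unlist(lapply(seq_along(offs), function(k)
      raw[(offs[k] + 1):(offs[k] + cnts[k])]))
    v <- if (fmt == 3 && bits == 32) {
      readBin(bytes, "numeric", n = nr_img * nc_img, size = 4L,
              endian = "little")
    } else if (bits == 16) {
      readBin(bytes, "integer", n = nr_img * nc_img, size = 2L,
              signed = FALSE, endian = "little")
    } else if (bits == 8) {
      as.integer(bytes)
    } else stop("unsupported bit depth: ", bits)
    planes[[length(planes) + 1L]] <- matrix(as.numeric(v), nrow = nr_img,
                                            ncol = nc_img, byrow = TRUE)
    ifd_off <- read_u(raw, ifd_off + 3 + n * 12, 4)
  }
  if (length(planes) == 1L) planes[[1L]] else planes
}
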