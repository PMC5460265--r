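#' Read a single-channel baseline TIFF image
#'
#' Minimal reader for the files this package writes and for comparable
#' single-channel microscopy exports: uncompressed baseline TIFF, grayscale,
#' 8- or 16-bit, little- or big-endian, strip-organized. Pixel size in
#' micrometres per pixel is recovered from the X resolution tag (written as
#' pixels per centimetre) or taken from \code{pixel_size} when the file has
#' no resolution metadata.
#'
#' @param path Path to the TIFF file.
#' @param pixel_size Optional micrometres-per-pixel override; required when
#'   the file carries no resolution tag.
#' @return An integer matrix (rows = image rows, top row first) with
#'   attributes \code{pixel_size} (µm/px) and \code{bits} (8 or 16).
#' @export
read_tiff <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  bo <- rawToChar(raw[1:2])
  endian <- if (bo == "II") "little" else if (bo == "MM") "big" else
    stop("not a TIFF file (bad byte-order mark): ", path)
  rd <- function(off, n, size, signed = TRUE)
    readBin(raw[(off + 1):(off + n * size)], "integer", n = n, size = size,
            endian = endian, signed = signed)
  if (rd(2, 1, 2, signed = FALSE) != 42L) stop("not a TIFF file (bad magic)")
  ifd_off <- rd(4, 1, 4)
  n_entries <- rd(ifd_off, 1, 2, signed = FALSE)
  tags <- list()
  for (i in seq_len(n_entries)) {
    base <- ifd_off + 2 + (i - 1) * 12
    tag <- rd(base, 1, 2, signed = FALSE)
    type <- rd(base + 2, 1, 2, signed = FALSE)
    count <- rd(base + 4, 1, 4)
    val <- switch(as.character(type),
      "3" = {  # SHORT: up to 2 fit inline
        if (count <= 2) rd(base + 8, count, 2, signed = FALSE)
        else rd(rd(base + 8, 1, 4), count, 2, signed = FALSE)
      },
      "4" = {  # LONG
        if (count <= 1) rd(base + 8, count, 4)
        else rd(rd(base + 8, 1, 4), count, 4)
      },
      "5" = {  # RATIONAL: numerator/denominator pairs at offset
        off <- rd(base + 8, 1, 4)
        v <- rd(off, 2 * count, 4)
        v[seq(1, 2 * count, 2)] / v[seq(2, 2 * count, 2)]
      },
      NULL)
    if (!is.null(val)) tags[[as.character(tag)]] <- val
  }
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop("TIFF missing required tag ", tag)
    v
  }
  width <- need(256); height <- need(257)
  bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
  if (!bits %in% c(8L, 16L)) stop("unsupported bit depth: ", bits)
  if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
    stop("compressed TIFF not supported (compression = ", tags[["259"]], ")")
  spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]]
  if (spp != 1L)
    stop("multi-channel TIFF not supported (", spp,
         " samples per pixel); export a single channel")
  offs <- need(273)
  counts <- if (is.null(tags[["279"]])) (width * height * bits / 8) else tags[["279"]]
  bytes_per <- bits / 8
  px <- unlist(lapply(seq_along(offs), function(k)
    rd(offs[k], counts[k] / bytes_per, bytes_per, signed = FALSE)))
  if (length(px) != width * height) stop("TIFF pixel data truncated")
  m <- matrix(as.integer(px), nrow = height, ncol = width, byrow = TRUE)
  ps <- pixel_size
  if (is.null(ps)) {
    xres <- tags[["282"]]
    unit <- if (is.null(tags[["296"]])) 2 else tags[["296"]]
    if (is.null(xres))
      stop("TIFF has no resolution tag; supply pixel_size explicitly")
    per_cm <- switch(as.character(unit), "3" = xres, "2" = xres / 2.54,
                     stop("resolution unit ", unit, " without pixel_size override"))
    ps <- 1e4 / per_cm
  }
  structure(m, pixel_size = ps, bits = as.integer(bits))
}

#' Write a single-channel 16-bit baseline TIFF image
#'
#' Writes an uncompressed little-endian grayscale TIFF with the pixel size
#' encoded in the resolution tags (pixels per centimetre), so a round trip
#' through \code{\link{read_tiff}} is bit-identical.
#'
#' @param img Integer or numeric matrix; values are clamped to [0, 65535]
#'   and rounded.
#' @param path Output path.
#' @param pixel_size Micrometres per pixel; defaults to the matrix's
#'   \code{pixel_size} attribute.
#' @return \code{path}, invisibly.
#' @export
write_tiff <- function(img, path, pixel_size = attr(img, "pixel_size")) {
  if (is.null(pixel_size)) stop("pixel_size required (attribute or argument)")
  stopifnot(is.matrix(img))
  v <- round(as.numeric(img))
  v[v < 0] <- 0; v[v > 65535] <- 65535
  nr <- nrow(img); nc <- ncol(img)
  data_bytes <- nr * nc * 2L
  # layout: header(8) | pixel data | xres(8) | yres(8) | IFD
  data_off <- 8L
  xres_off <- data_off + data_bytes
  yres_off <- xres_off + 8L
  ifd_off <- yres_off + 8L
  res_num <- round(1e7 / pixel_size)  # pixels per cm, denominator 1000
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL)
  w2(42L); w4(ifd_off)
  # pixel data, row-major from the top row
  writeBin(as.integer(t(matrix(v, nr, nc))), con, size = 2, endian = "little")
  w4(c(res_num, 1000L))  # XResolution
  w4(c(res_num, 1000L))  # YResolution
  entry <- function(tag, type, count, value) { w2(c(tag, type)); w4(c(count, value)) }
  short_val <- function(x) x  # little-endian: low 2 bytes of the 4-byte slot
  w2(12L)  # entry count
  entry(256L, 4L, 1L, nc)                 # ImageWidth
  entry(257L, 4L, 1L, nr)                 # ImageLength
  entry(258L, 3L, 1L, short_val(16L))     # BitsPerSample
  entry(259L, 3L, 1L, short_val(1L))      # Compression: none
  entry(262L, 3L, 1L, short_val(1L))      # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_off)           # StripOffsets
  entry(277L, 3L, 1L, short_val(1L))      # SamplesPerPixel
  entry(278L, 4L, 1L, nr)                 # RowsPerStrip
  entry(279L, 4L, 1L, data_bytes)         # StripByteCounts
  entry(282L, 5L, 1L, xres_off)           # XResolution
  entry(283L, 5L, 1L, yres_off)           # YResolution
  entry(296L, 3L, 1L, short_val(3L))      # ResolutionUnit: cm
  w4(0L)  # next IFD
  invisible(path)
}
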