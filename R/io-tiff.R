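# TIFF input/output.
#
# Reading goes through tiff::readTIFF (as.is = TRUE keeps integer samples
# bit-exact).  Writing is a minimal little-endian, uncompressed, single-strip
# TIFF writer: r-tiff's writeTIFF cannot embed resolution tags, and carrying
# the physical pixel size inside the file is non-negotiable for this pipeline
# (silent unit errors are the classic correlative-imaging failure mode).
# The writer emits XResolution/YResolution in pixels-per-centimetre
# (ResolutionUnit = 3) and supports uint8/uint16/float32 grayscale and
# uint8 RGB, single- or multi-page.

TIFF_EXT <- c("tif", "tiff")
MRC_EXT  <- c("mrc", "rec", "map", "st")

#' @noRd
file_ext_lower <- function(path) tolower(tools::file_ext(path))

#' @noRd
tiff_pixel_size_nm <- function(info) {
  xres <- attr(info, "x.resolution")
  unit <- attr(info, "resolution.unit")
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NULL)
  if (is.null(unit)) unit <- "inch"  # TIFF default ResolutionUnit = 2
  unit_nm <- switch(as.character(unit), cm = 1e7, inch = 2.54e7, NULL)
  if (is.null(unit_nm)) return(NULL)
  unit_nm / xres
}

# ---- writer -----------------------------------------------------------------

#' @noRd
uint16_to_int <- function(v) {
  v <- as.integer(round(v))
  ifelse(v > 32767L, v - 65536L, v)
}

#' @noRd
tiff_rational <- function(x) {
  # best uint32/uint32 approximation with a fixed denominator
  den <- max(1, min(10000, floor(4294967295 / max(x, 1e-9))))
  c(round(x * den), den)
}

# Serialize one page: returns list(data = raw pixel strip, ifd_builder = fn).
#' @noRd
tiff_encode_pixels <- function(m, dtype) {
  if (length(dim(m)) == 3L) {            # RGB, [row, col, 3]
    v <- as.vector(aperm(m, c(3, 2, 1))) # interleaved RGB, row-major
    return(writeBin(as.raw(pmin(pmax(round(v * 255), 0), 255)), raw()))
  }
  v <- as.vector(t(m))                   # row-major
  con <- raw()
  switch(dtype,
    uint8   = as.raw(pmin(pmax(round(v), 0), 255)),
    uint16  = writeBin(uint16_to_int(v), con, size = 2, endian = "little"),
    float32 = writeBin(as.numeric(v), con, size = 4, endian = "little"),
    stop_clxm("clxm_input_error", "unsupported TIFF dtype: ", dtype)
  )
}

#' Write a TIFF file with embedded pixel-size metadata
#'
#' Minimal uncompressed writer used by [write_plane()]; exposed for testing.
#' `pages` is a list of numeric matrices (grayscale) or `[row, col, 3]`
#' arrays in `[0, 1]` (RGB, written as uint8).
#'
#' @param pages list of matrices / RGB arrays.
#' @param path output file path.
#' @param pixel_size_nm physical pixel pitch (nm) stored in the resolution
#'   tags, or `NULL` to omit them.
#' @param dtype `"uint8"`, `"uint16"` or `"float32"` (grayscale pages only).
#' @keywords internal
#' @export
write_tiff_raw <- function(pages, path, pixel_size_nm = NULL, dtype = "float32") {
  stopifnot(is.list(pages), length(pages) >= 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w4u <- function(x) {                    # unsigned 32-bit via two shorts
    x <- as.numeric(x)
    w2(x %% 65536); w2((x %/% 65536) %% 65536)
  }

  rgb <- vapply(pages, function(p) length(dim(p)) == 3L, logical(1))
  if (any(rgb) && !all(rgb))
    stop_clxm("clxm_input_error", "cannot mix grayscale and RGB pages")
  rgb <- rgb[1]
  bps <- if (rgb) 8L else switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  spp <- if (rgb) 3L else 1L
  sample_format <- if (!rgb && dtype == "float32") 3L else 1L
  has_res <- !is.null(pixel_size_nm)

  blobs <- lapply(pages, tiff_encode_pixels, dtype = dtype)
  n_tags <- 10L + (if (has_res) 3L else 0L)
  ifd_size <- 2L + 12L * n_tags + 4L
  extra_size <- (if (has_res) 16L else 0L) + (if (rgb) 6L else 0L)

  # layout: 8-byte header | per page: [pixel strip | extra values | IFD]
  offset <- 8L
  strip_off <- extra_off <- ifd_off <- integer(length(pages))
  for (i in seq_along(pages)) {
    strip_off[i] <- offset
    extra_off[i] <- offset + length(blobs[[i]])
    ifd_off[i]   <- extra_off[i] + extra_size
    offset       <- ifd_off[i] + ifd_size
  }

  writeBin(charToRaw("II"), con); w2(42L); w4(ifd_off[1])
  ppcm <- if (has_res) tiff_rational(1e7 / pixel_size_nm) else NULL

  for (i in seq_along(pages)) {
    m <- pages[[i]]
    nr <- dim(m)[1]; nc <- dim(m)[2]
    writeBin(blobs[[i]], con)
    if (has_res) { w4u(ppcm[1]); w4u(ppcm[2]); w4u(ppcm[1]); w4u(ppcm[2]) }
    if (rgb) w2(c(8L, 8L, 8L))

    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count)
      if (type == 3L && count == 1L) { w2(value); w2(0L) } else w4(value)
    }
    res_off <- extra_off[i]
    bps_off <- extra_off[i] + (if (has_res) 16L else 0L)
    w2(n_tags)
    entry(256L, 4L, 1L, nc)                         # ImageWidth
    entry(257L, 4L, 1L, nr)                         # ImageLength
    if (rgb) entry(258L, 3L, 3L, bps_off) else entry(258L, 3L, 1L, bps)
    entry(259L, 3L, 1L, 1L)                         # Compression: none
    entry(262L, 3L, 1L, if (rgb) 2L else 1L)        # Photometric
    entry(273L, 4L, 1L, strip_off[i])               # StripOffsets
    entry(277L, 3L, 1L, spp)                        # SamplesPerPixel
    entry(278L, 4L, 1L, nr)                         # RowsPerStrip
    entry(279L, 4L, 1L, length(blobs[[i]]))         # StripByteCounts
    if (has_res) {
      entry(282L, 5L, 1L, res_off)                  # XResolution
      entry(283L, 5L, 1L, res_off + 8L)             # YResolution
      entry(296L, 3L, 1L, 3L)                       # ResolutionUnit: cm
    }
    entry(339L, 3L, 1L, sample_format)              # SampleFormat
    w4(if (i < length(pages)) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

#' @noRd
read_tiff_pages <- function(path) {
  # as.is = TRUE keeps integer samples bit-exact but is rejected for float
  # pages, which are already returned natively
  tryCatch(
    tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
             error = function(e) {
               if (grepl("as.is", conditionMessage(e), fixed = TRUE))
                 tiff::readTIFF(path, all = TRUE, info = TRUE)
               else stop(e)
             }),
    error = function(e)
      stop_clxm("clxm_format_error", "cannot read TIFF '", path,
                "': ", conditionMessage(e)))
}

# Convert one readTIFF page (EBImage-free) to a [row, col] matrix.
# readTIFF returns [row, col] already (optionally with a channel dim).
#' @noRd
tiff_page_matrix <- function(p) {
  if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse channels for analysis
  attributes(p) <- list(dim = dim(p))      # drop reader metadata attributes
  p
}
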