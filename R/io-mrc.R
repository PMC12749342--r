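# Minimal MRC2014 reader/writer (little-endian).
#
# Header fields follow the MRC2014 convention: cell dimensions (cella) are
# stored in Angstrom, so the physical pixel size is cella/mx Angstrom/px and
# is converted to nm on read.  Modes supported: 0 (int8), 1 (int16),
# 2 (float32), 6 (uint16).

#' @noRd
mrc_read_header <- function(con, path) {
  ints <- readBin(con, integer(), n = 10, size = 4, endian = "little")
  if (length(ints) < 10)
    stop_clxm("clxm_format_error", "truncated MRC header in '", path, "'")
  cell <- readBin(con, numeric(), n = 6, size = 4, endian = "little")
  maps <- readBin(con, integer(), n = 3, size = 4, endian = "little")
  dstats <- readBin(con, numeric(), n = 3, size = 4, endian = "little")
  ispg <- readBin(con, integer(), n = 2, size = 4, endian = "little")
  seek(con, 1024)
  list(nx = ints[1], ny = ints[2], nz = ints[3], mode = ints[4],
       mx = ints[8], my = ints[9], mz = ints[10],
       cella = cell[1:3], nsymbt = ispg[2])
}

#' @noRd
mrc_pixel_size_nm <- function(h) {
  if (h$mx <= 0 || h$cella[1] <= 0) return(NULL)
  (h$cella[1] / h$mx) / 10  # Angstrom -> nm
}

#' @noRd
mrc_read_data <- function(con, h, path) {
  if (h$nsymbt > 0) seek(con, 1024 + h$nsymbt)
  n <- h$nx * h$ny * h$nz
  v <- switch(as.character(h$mode),
    `0` = readBin(con, integer(), n = n, size = 1, signed = TRUE),
    `1` = readBin(con, integer(), n = n, size = 2, signed = TRUE,
                  endian = "little"),
    `2` = readBin(con, numeric(), n = n, size = 4, endian = "little"),
    `6` = readBin(con, integer(), n = n, size = 2, signed = FALSE,
                  endian = "little"),
    stop_clxm("clxm_format_error", "unsupported MRC mode ", h$mode,
              " in '", path, "'"))
  if (length(v) < n)
    stop_clxm("clxm_format_error", "truncated MRC data in '", path, "'")
  # nx (columns) is the fastest axis: each section is read column-fastest
  slices <- vector("list", h$nz)
  per <- h$nx * h$ny
  for (k in seq_len(h$nz)) {
    sec <- v[((k - 1) * per + 1):(k * per)]
    slices[[k]] <- matrix(sec, nrow = h$ny, ncol = h$nx, byrow = TRUE)
  }
  slices
}

#' @noRd
mrc_write <- function(slices, path, pixel_size_nm, dtype = "float32") {
  mode <- switch(dtype, int8 = 0L, int16 = 1L, float32 = 2L, uint16 = 6L,
                 stop_clxm("clxm_input_error", "unsupported MRC dtype: ", dtype))
  nz <- length(slices)
  nr <- nrow(slices[[1]]); nc <- ncol(slices[[1]])
  all_v <- unlist(lapply(slices, function(m) as.vector(t(m))))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nc, nr, nz, mode, 0, 0, 0, nc, nr, nz))
  wf(c(nc, nr, nz) * pixel_size_nm * 10)       # cella in Angstrom
  wf(c(90, 90, 90))                             # cellb
  wi(c(1, 2, 3))                                # mapc, mapr, maps
  wf(c(min(all_v), max(all_v), mean(all_v)))    # dmin, dmax, dmean
  wi(c(0, 0))                                   # ispg, nsymbt
  writeBin(raw(100), con)                       # extra
  wf(c(0, 0, 0))                                # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(all_v))                          # rms
  wi(1)                                         # nlabl
  lab <- charToRaw(sprintf("%-80s", "clxmreg"))
  writeBin(c(lab, raw(800 - length(lab))), con)
  if (mode == 2L) wf(all_v)
  else if (mode == 1L) writeBin(as.integer(round(all_v)), con, size = 2,
                                endian = "little")
  else if (mode == 6L) writeBin(uint16_to_int(all_v), con, size = 2,
                                endian = "little")
  else writeBin(as.integer(round(all_v)), con, size = 1)
  invisible(path)
}
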