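#' Image containers with physical pixel size
#'
#' `image_plane()` wraps a 2D intensity matrix together with its physical
#' pixel pitch in nanometres and a modality tag; it is the currency of every
#' pipeline stage.  `image_stack()` holds an ordered list of identically
#' shaped planes (tomographic z-slices or tilt frames).
#'
#' Matrix layout is `[row, col]`; positions are `(x, y)` with `x` = column
#' index and `y` = row index, 0-based, physical nm = index * `pixel_size_nm`
#' at pixel centres.
#'
#' @param pixels numeric matrix of intensities (finite everywhere).
#' @param pixel_size_nm physical pixel pitch in nm/px (isotropic, > 0).
#' @param modality one of `"FM"`, `"SXT"`, `"SYNTH"`, `"OTHER"`.
#' @return an object of class `image_plane`.
#' @examples
#' img <- image_plane(matrix(runif(64 * 64), 64), pixel_size_nm = 29, modality = "SXT")
#' dim(img$pixels)
#' @export
image_plane <- function(pixels, pixel_size_nm, modality = c("OTHER", "FM", "SXT", "SYNTH")) {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_clxm("clxm_input_error", "pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_clxm("clxm_input_error", "pixels must have at least one row and column")
  if (!all(is.finite(pixels)))
    stop_clxm("clxm_input_error", "pixels must be finite everywhere")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop_clxm("clxm_input_error", "pixel_size_nm must be a single positive number")
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm), modality = modality),
    class = "image_plane"
  )
}

#' @rdname image_plane
#' @param slices list of `image_plane` objects sharing shape and pixel size.
#' @param axis_meaning `"Z_SLICES"` or `"TILT_FRAMES"`.
#' @param tilt_angles_deg optional numeric vector, one angle per slice.
#' @export
image_stack <- function(slices, axis_meaning = c("Z_SLICES", "TILT_FRAMES"),
                        tilt_angles_deg = NULL) {
  axis_meaning <- match.arg(axis_meaning)
  if (!is.list(slices) || length(slices) < 1L)
    stop_clxm("clxm_input_error", "slices must be a nonempty list of image_plane objects")
  if (!all(vapply(slices, inherits, logical(1), "image_plane")))
    stop_clxm("clxm_input_error", "every slice must be an image_plane")
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_clxm("clxm_format_error", "all slices must share the same shape")
  px <- vapply(slices, function(s) s$pixel_size_nm, numeric(1))
  if (any(abs(px - px[1]) > 1e-9))
    stop_clxm("clxm_format_error", "all slices must share the same pixel_size_nm")
  if (!is.null(tilt_angles_deg) && length(tilt_angles_deg) != length(slices))
    stop_clxm("clxm_input_error", "tilt_angles_deg length must equal the slice count")
  structure(
    list(slices = slices, axis_meaning = axis_meaning,
         tilt_angles_deg = tilt_angles_deg),
    class = "image_stack"
  )
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d px, %.4g nm/px, modality %s, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm, x$modality,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices[[1]]$pixels)
  cat(sprintf("<image_stack> %d slices of %d x %d px, %.4g nm/px, axis %s\n",
              length(x$slices), d[1], d[2], x$slices[[1]]$pixel_size_nm, x$axis_meaning))
  invisible(x)
}
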