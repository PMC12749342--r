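#' Read a single 2D image with physical pixel-size metadata
#'
#' Supported formats are single-page TIFF (resolution tags in cm or inch) and
#' 2D MRC2014 (cell dimensions in Angstrom).  If the file carries no usable
#' pixel size, `pixel_size_nm` must be given explicitly; the function never
#' guesses a scale.
#'
#' @param path path to a `.tif`/`.tiff` or `.mrc`/`.rec`/`.map` file.
#' @param pixel_size_nm optional override for the physical pixel pitch (nm).
#' @param modality modality tag attached to the result.
#' @return an [image_plane()].
#' @seealso [write_plane()], [read_stack()]
#' @export
read_plane <- function(path, pixel_size_nm = NULL, modality = "OTHER") {
  if (!file.exists(path))
    stop_clxm("clxm_input_error", "file not found: '", path, "'")
  ext <- file_ext_lower(path)
  if (ext %in% TIFF_EXT) {
    pages <- read_tiff_pages(path)
    if (length(pages) != 1L)
      stop_clxm("clxm_format_error", "'", path, "' has ", length(pages),
                " pages; use read_stack()")
    px <- tiff_pixel_size_nm(pages[[1]])
    m <- tiff_page_matrix(pages[[1]])
  } else if (ext %in% MRC_EXT) {
    con <- file(path, "rb"); on.exit(close(con))
    h <- mrc_read_header(con, path)
    if (h$nz != 1L)
      stop_clxm("clxm_format_error", "'", path, "' has ", h$nz,
                " sections; use read_stack()")
    px <- mrc_pixel_size_nm(h)
    m <- mrc_read_data(con, h, path)[[1]]
  } else {
    stop_clxm("clxm_format_error", "unsupported image format: '", path, "'")
  }
  if (!is.null(pixel_size_nm)) px <- pixel_size_nm
  if (is.null(px))
    stop_clxm("clxm_metadata_error", "'", path,
              "' carries no pixel size; pass pixel_size_nm explicitly")
  image_plane(m, pixel_size_nm = px, modality = modality)
}

#' Read a multi-page TIFF or 3D MRC as an image stack
#'
#' @inheritParams read_plane
#' @param axis_meaning `"Z_SLICES"` or `"TILT_FRAMES"`.
#' @param tilt_angles_deg optional per-slice tilt angles.
#' @return an [image_stack()] with slice order preserved.
#' @export
read_stack <- function(path, pixel_size_nm = NULL, modality = "OTHER",
                       axis_meaning = "Z_SLICES", tilt_angles_deg = NULL) {
  if (!file.exists(path))
    stop_clxm("clxm_input_error", "file not found: '", path, "'")
  ext <- file_ext_lower(path)
  if (ext %in% TIFF_EXT) {
    pages <- read_tiff_pages(path)
    px <- tiff_pixel_size_nm(pages[[1]])
    mats <- lapply(pages, tiff_page_matrix)
    dims <- vapply(mats, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop_clxm("clxm_format_error", "'", path, "' has pages of differing shapes")
  } else if (ext %in% MRC_EXT) {
    con <- file(path, "rb"); on.exit(close(con))
    h <- mrc_read_header(con, path)
    px <- mrc_pixel_size_nm(h)
    mats <- mrc_read_data(con, h, path)
  } else {
    stop_clxm("clxm_format_error", "unsupported image format: '", path, "'")
  }
  if (!is.null(pixel_size_nm)) px <- pixel_size_nm
  if (is.null(px))
    stop_clxm("clxm_metadata_error", "'", path,
              "' carries no pixel size; pass pixel_size_nm explicitly")
  image_stack(lapply(mats, image_plane, pixel_size_nm = px, modality = modality),
              axis_meaning = axis_meaning, tilt_angles_deg = tilt_angles_deg)
}

#' Write an image plane (or stack) with pixel-size metadata
#'
#' TIFF output embeds XResolution/YResolution tags (pixels per cm); MRC
#' output stores the pixel size in the MRC2014 cell dimensions (Angstrom).
#' Integer dtypes round-trip bit-exactly.
#'
#' @param img an [image_plane()] (or [image_stack()] for `write_stack`).
#' @param path output path; format chosen by extension (TIFF or MRC).
#' @param dtype `"uint8"`, `"uint16"` or `"float32"`.
#' @export
write_plane <- function(img, path, dtype = "float32") {
  stopifnot(inherits(img, "image_plane"))
  write_pages(list(img$pixels), path, img$pixel_size_nm, dtype)
  invisible(path)
}

#' @rdname write_plane
#' @param stack an [image_stack()].
#' @export
write_stack <- function(stack, path, dtype = "float32") {
  stopifnot(inherits(stack, "image_stack"))
  write_pages(lapply(stack$slices, function(s) s$pixels), path,
              stack$slices[[1]]$pixel_size_nm, dtype)
  invisible(path)
}

#' @noRd
write_pages <- function(mats, path, pixel_size_nm, dtype) {
  if (!dir.exists(dirname(path)))
    stop_clxm("clxm_input_error", "parent directory does not exist: '",
              dirname(path), "'")
  ext <- file_ext_lower(path)
  if (ext %in% TIFF_EXT) {
    write_tiff_raw(mats, path, pixel_size_nm = pixel_size_nm, dtype = dtype)
  } else if (ext %in% MRC_EXT) {
    mrc_write(mats, path, pixel_size_nm = pixel_size_nm, dtype = dtype)
  } else {
    stop_clxm("clxm_format_error", "unsupported output format: '", path, "'")
  }
}

#' Write a rectangular table as CSV with a header row
#'
#' @param t a data.frame with unique column names.
#' @param path output `.csv` path.
#' @export
write_table <- function(t, path) {
  stopifnot(is.data.frame(t))
  if (anyDuplicated(names(t)))
    stop_clxm("clxm_input_error", "table headers must be unique")
  utils::write.csv(t, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a registration transform as JSON
#'
#' The JSON records the full linear form, the named parameters when present,
#' the optional thin-plate-spline warp, and the coordinate convention string.
#'
#' @param a an `affine2d` transform.
#' @param w optional `tps_warp` model.
#' @param path output `.json` path.
#' @export
write_transform <- function(a, w = NULL, path) {
  stopifnot(inherits(a, "affine2d"))
  obj <- list(
    convention = a$convention,
    affine = list(M = a$M, b = a$b, params = a$params)
  )
  if (!is.null(w)) {
    stopifnot(inherits(w, "tps_warp"))
    obj$warp <- list(kernel = "U(r) = r^2 log r", lambda = w$lambda,
                     coord_scale = w$scale %||% 1,
                     control_nm = w$ctrl, weights = w$w, affine_part = w$a)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_mat <- function(x) { x <- as.matrix(x); storage.mode(x) <- "double"; x }
  a <- new_affine(num_mat(obj$affine$M), as.numeric(obj$affine$b),
                  params = obj$affine$params)
  w <- NULL
  if (!is.null(obj$warp)) {
    w <- structure(list(ctrl = num_mat(obj$warp$control_nm),
                        w = num_mat(obj$warp$weights),
                        a = num_mat(obj$warp$affine_part),
                        scale = obj$warp$coord_scale %||% 1,
                        lambda = obj$warp$lambda),
                   class = "tps_warp")
  }
  list(affine = a, warp = w)
}
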