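#' Preprocessing parameters
#'
#' @param gaussian_sigma_px Gaussian smoothing sigma in pixels (0 disables).
#' @param clahe_clip_limit CLAHE contrast limit (multiplicative, as in
#'   adaptive histogram equalization with clipping; higher = stronger).
#' @param clahe_tile_px CLAHE tile edge length in pixels (>= 8).
#' @param gaussian_enabled,clahe_enabled per-step switches.
#' @return list of class `preprocess_params`.
#' @export
preprocess_params <- function(gaussian_sigma_px = 2, clahe_clip_limit = 2,
                              clahe_tile_px = 64, gaussian_enabled = TRUE,
                              clahe_enabled = TRUE) {
  stopifnot(gaussian_sigma_px >= 0, clahe_clip_limit > 0, clahe_tile_px >= 8)
  structure(as.list(environment()), class = "preprocess_params")
}

#' Gaussian + CLAHE preprocessing
#'
#' Gaussian smoothing reduces noise; contrast-limited adaptive histogram
#' equalization (CLAHE) then enhances local contrast so faint droplets
#' survive a global threshold.  The output is min-max rescaled to `[0, 1]`
#' (a constant input maps to all zeros) and keeps shape and pixel size.
#'
#' @param img an [image_plane()].
#' @param p a [preprocess_params()] list.
#' @return an [image_plane()] in `[0, 1]`.
#' @export
preprocess <- function(img, p = preprocess_params()) {
  stopifnot(inherits(img, "image_plane"))
  m <- img$pixels
  if (p$gaussian_enabled && p$gaussian_sigma_px > 0)
    m <- from_eb(EBImage::gblur(as_eb(m), sigma = p$gaussian_sigma_px))
  m <- norm01(m)
  if (p$clahe_enabled && diff(range(m)) > 0) {
    nx <- max(1L, round(ncol(m) / p$clahe_tile_px))
    ny <- max(1L, round(nrow(m) / p$clahe_tile_px))
    # clahe needs dimensions divisible by the tile counts: pad by edge
    # replication, equalize, crop back
    nr0 <- nrow(m); nc0 <- ncol(m)
    nr1 <- ceiling(nr0 / ny) * ny; nc1 <- ceiling(nc0 / nx) * nx
    mp <- m[c(seq_len(nr0), rep(nr0, nr1 - nr0)),
            c(seq_len(nc0), rep(nc0, nc1 - nc0)), drop = FALSE]
    mp <- from_eb(EBImage::clahe(as_eb(mp), nx = nx, ny = ny,
                                 limit = p$clahe_clip_limit))
    m <- norm01(mp[seq_len(nr0), seq_len(nc0), drop = FALSE])
  }
  image_plane(m, img$pixel_size_nm, img$modality)
}

#' Project an image stack to a single plane
#'
#' Pixelwise reduction across slices; the minimum-intensity projection is
#' the standard way to collapse an absorption-contrast stack so that dark
#' droplets remain detectable in 2D.
#'
#' @param stack an [image_stack()].
#' @param mode `"min"`, `"mean"` or `"max"`.
#' @return an [image_plane()] with the stack's shape and pixel size.
#' @export
project_stack <- function(stack, mode = c("min", "mean", "max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "image_stack"))
  mats <- lapply(stack$slices, function(s) s$pixels)
  out <- switch(mode,
    min  = Reduce(pmin, mats),
    max  = Reduce(pmax, mats),
    mean = Reduce(`+`, mats) / length(mats))
  image_plane(out, stack$slices[[1]]$pixel_size_nm,
              stack$slices[[1]]$modality)
}

#' Convert transmission intensities to optical density
#'
#' Absorption contrast follows the Beer-Lambert law; optical density is
#' `-ln(I / I0)`, with the ratio clipped below at `eps` so zero-transmission
#' pixels stay finite.
#'
#' @param img an [image_plane()] of transmission intensities (>= 0).
#' @param i0 flat-field (unattenuated) intensity (> 0).
#' @param eps lower clip for the transmission ratio.
#' @return an [image_plane()] of optical densities, with an
#'   `attr(, "units") == "optical_density"` marker.
#' @export
transmission_to_od <- function(img, i0, eps = 1e-6) {
  stopifnot(inherits(img, "image_plane"))
  if (!is.numeric(i0) || length(i0) != 1L || i0 <= 0)
    stop_clxm("clxm_input_error", "i0 must be a single positive intensity")
  if (any(img$pixels < 0))
    stop_clxm("clxm_input_error", "transmission intensities must be >= 0")
  od <- -log(pmax(img$pixels / i0, eps))
  out <- image_plane(od, img$pixel_size_nm, img$modality)
  attr(out, "units") <- "optical_density"
  out
}
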