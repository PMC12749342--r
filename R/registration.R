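# End-to-end registration: rescale -> preprocess/segment -> phase
# cross-correlation -> cost-driven affine refinement -> thin-plate-spline
# residual warp -> overlay.

#' Rescale a moving image to the reference pixel size
#'
#' Bilinear interpolation under the pixel-centre convention; the physical
#' field of view is preserved within one output pixel and intensities are
#' not renormalized.
#'
#' @param mov an [image_plane()].
#' @param ref_pixel_nm target pixel size (nm/px, > 0).
#' @return an [image_plane()] with `pixel_size_nm = ref_pixel_nm`.
#' @export
rescale_to_reference <- function(mov, ref_pixel_nm) {
  stopifnot(inherits(mov, "image_plane"), ref_pixel_nm > 0)
  if (abs(mov$pixel_size_nm - ref_pixel_nm) < 1e-12) return(mov)
  r <- ref_pixel_nm / mov$pixel_size_nm
  nr_out <- max(1L, round(nrow(mov$pixels) / r))
  nc_out <- max(1L, round(ncol(mov$pixels) / r))
  rows <- (seq_len(nr_out) - 1) * r
  cols <- (seq_len(nc_out) - 1) * r
  out <- matrix(bilinear_sample(mov$pixels,
                                rep(rows, times = nc_out),
                                rep(cols, each = nr_out)),
                nr_out, nc_out)
  image_plane(out, ref_pixel_nm, mov$modality)
}

#' Map landmark points through the registration transform
#'
#' Points are mapped forward by the affine, then shifted by the warp's
#' displacement field (evaluated at the affine-transformed positions).
#'
#' @param pts `centroid_set` or n x 2 matrix of nm positions.
#' @param a an `affine2d`.
#' @param w optional `tps_warp`.
#' @return a `centroid_set` of mapped positions.
#' @export
apply_to_points <- function(pts, a, w = NULL) {
  p <- as_points(pts)
  out <- apply_affine(a, p)
  if (!is.null(w)) out <- out + tps_displacement(w, out)
  centroid_set(out, modality = attr(pts, "modality") %||% "OTHER",
               provenance = "transformed")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a moving image into the reference frame
#'
#' Inverse mapping with bilinear interpolation: each output pixel position
#' is pulled back through the transform (the warp is inverted to first
#' order, adequate for the small local distortions it models) and sampled
#' from the moving image.  Positions falling outside the moving image map
#' to `fill`.
#'
#' @param img moving [image_plane()].
#' @param a `affine2d` (moving -> reference).
#' @param w optional `tps_warp` of residual displacements.
#' @param out_grid list with `dim = c(rows, cols)` and `pixel_size_nm`
#'   describing the reference grid; defaults to the input grid.
#' @param fill value for out-of-field pixels.
#' @return an [image_plane()] on the reference grid.
#' @export
apply_to_image <- function(img, a, w = NULL, out_grid = NULL, fill = 0) {
  stopifnot(inherits(img, "image_plane"))
  if (is.null(out_grid))
    out_grid <- list(dim = dim(img$pixels), pixel_size_nm = img$pixel_size_nm)
  nr <- out_grid$dim[1]; nc <- out_grid$dim[2]
  px <- out_grid$pixel_size_nm
  gx <- rep((seq_len(nc) - 1) * px, each = nr)
  gy <- rep((seq_len(nr) - 1) * px, times = nc)
  pts <- cbind(gx, gy)
  if (!is.null(w)) pts <- pts - tps_displacement(w, pts)
  src <- apply_affine(invert_affine(a), pts)
  row0 <- src[, 2] / img$pixel_size_nm
  col0 <- src[, 1] / img$pixel_size_nm
  vals <- bilinear_sample(img$pixels, row0, col0)
  oob <- row0 < -0.5 | row0 > nrow(img$pixels) - 0.5 |
         col0 < -0.5 | col0 > ncol(img$pixels) - 0.5
  vals[oob] <- fill
  image_plane(matrix(vals, nr, nc), px, img$modality)
}

#' Compose a red/blue correlative overlay
#'
#' Red carries the X-ray channel (contrast-inverted so absorbing droplets
#' render bright), blue the fluorescence channel, and green the pixelwise
#' minimum of the two so coincident signal renders white-ish.
#'
#' @param ref reference (SXT) [image_plane()].
#' @param warped_mov moving (FM) [image_plane()] already on the same grid.
#' @return an `overlay_rgb`: list with `rgb` (`rows x cols x 3` array of
#'   8-bit-quantized values in `[0, 1]`) and `pixel_size_nm`.
#' @export
compose_overlay <- function(ref, warped_mov) {
  stopifnot(inherits(ref, "image_plane"), inherits(warped_mov, "image_plane"))
  if (!identical(dim(ref$pixels), dim(warped_mov$pixels)) ||
      abs(ref$pixel_size_nm - warped_mov$pixel_size_nm) > 1e-9)
    stop_clxm("clxm_input_error", "overlay inputs must share grid and pixel size")
  red <- 1 - norm01(ref$pixels)
  blue <- norm01(warped_mov$pixels)
  green <- pmin(red, blue)
  q <- function(m) round(m * 255) / 255
  rgb <- array(0, c(nrow(red), ncol(red), 3))
  rgb[, , 1] <- q(red); rgb[, , 2] <- q(green); rgb[, , 3] <- q(blue)
  structure(list(rgb = rgb, pixel_size_nm = ref$pixel_size_nm),
            class = "overlay_rgb")
}

#' Parameters for the full registration pipeline
#'
#' @param preprocess_fm,preprocess_sxt [preprocess_params()] per modality.
#' @param min_radius_nm,max_radius_nm droplet size-filter bounds.
#' @param gate_nm landmark matching gate for the final pairing.
#' @param lambda thin-plate-spline regularization (0 = exact interpolation).
#' @param refine_opts options list passed to [refine_affine()].
#' @param warp_enabled fit the non-rigid stage (`TRUE`) or stop after the
#'   affine.
#' @return list of class `register_params`.
#' @export
register_params <- function(preprocess_fm = preprocess_params(),
                            preprocess_sxt = preprocess_params(),
                            min_radius_nm = 150, max_radius_nm = 1500,
                            gate_nm = 2000, lambda = 0,
                            refine_opts = list(), warp_enabled = TRUE) {
  structure(as.list(environment()), class = "register_params")
}

#' @noRd
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(
      class = unique(c(class(e), "clxm_error", "error", "condition")),
      list(message = paste0("[stage ", stage, "] ", conditionMessage(e)),
           call = conditionCall(e), stage = stage,
           best_so_far = e$best_so_far)))
  })
}

#' Register a correlative FM/SXT image pair end to end
#'
#' Executes the full workflow: rescale the moving image to the reference
#' pixel size, preprocess and segment droplets in both modalities, coarse
#' phase-correlation translation, cost-driven affine refinement, optional
#' thin-plate residual warp, and overlay composition.  All intermediates
#' are retained in the result.
#'
#' @param ref_img reference [image_plane()] (typically SXT, 29 nm/px).
#' @param mov_img moving [image_plane()] (typically FM, 120 nm/px).
#' @param params a [register_params()] list.
#' @return a `registration_result`: list with `coarse_shift_nm`, `affine`,
#'   `warp`, `pairs`, `residuals_before_nm`, `residuals_after_nm`,
#'   `ref_mask`, `mov_mask`, `ref_centroids`, `mov_centroids`,
#'   `warped_mov`, `overlay`, `stages`.
#' @export
register_pair <- function(ref_img, mov_img, params = register_params()) {
  stopifnot(inherits(ref_img, "image_plane"), inherits(mov_img, "image_plane"))
  mov_r <- with_stage("rescale",
    rescale_to_reference(mov_img, ref_img$pixel_size_nm))
  ref_mask <- with_stage("segment_ref",
    segment_droplets(ref_img, modality = ref_img$modality,
                     p = params$preprocess_sxt,
                     min_radius_nm = params$min_radius_nm,
                     max_radius_nm = params$max_radius_nm))
  mov_mask <- with_stage("segment_mov",
    segment_droplets(mov_r, modality = mov_r$modality,
                     p = params$preprocess_fm,
                     min_radius_nm = params$min_radius_nm,
                     max_radius_nm = params$max_radius_nm))
  coarse <- with_stage("pcc", coarse_align_pcc(ref_mask, mov_mask))
  ref_c <- centroids(ref_mask)
  mov_c <- centroids(mov_mask)
  aff <- with_stage("affine_refine",
    refine_affine(ref_c, mov_c, init = coarse, opts = params$refine_opts))
  pairs <- match_pairs(ref_c, mov_c, aff,
                       gate_nm = min(params$gate_nm,
                                     attr(aff, "gate_final_nm") %||% params$gate_nm))
  mov_t <- apply_to_points(mov_c, aff)
  warp <- NULL
  res_after <- rep(NA_real_, nrow(pairs))
  if (params$warp_enabled && nrow(pairs) >= 3) {
    warp <- with_stage("tps_warp",
      fit_warp(pairs, ref_c, mov_t, lambda = params$lambda))
    mt <- as_points(mov_t)[pairs$mov_index, , drop = FALSE]
    mw <- mt + tps_displacement(warp, mt)
    rp <- as_points(ref_c)[pairs$ref_index, , drop = FALSE]
    res_after <- sqrt(rowSums((mw - rp)^2))
  }
  warped <- with_stage("warp_image",
    apply_to_image(mov_r, aff, warp,
                   out_grid = list(dim = dim(ref_img$pixels),
                                   pixel_size_nm = ref_img$pixel_size_nm)))
  overlay <- with_stage("overlay", compose_overlay(ref_img, warped))
  structure(list(
    coarse_shift_nm = coarse, affine = aff, warp = warp, pairs = pairs,
    residuals_before_nm = pairs$distance_nm, residuals_after_nm = res_after,
    ref_mask = ref_mask, mov_mask = mov_mask,
    ref_centroids = ref_c, mov_centroids = mov_c,
    warped_mov = warped, overlay = overlay,
    stages = c("rescale", "segment", "pcc", "affine_refine", "tps_warp",
               "overlay")),
    class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %d pairs, coarse (%.0f, %.0f) nm, affine RMS %.1f nm%s\n",
              nrow(x$pairs), x$coarse_shift_nm[1], x$coarse_shift_nm[2],
              attr(x$affine, "rms_nm") %||% NA,
              if (is.null(x$warp)) "" else ", warp fitted"))
  invisible(x)
}
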