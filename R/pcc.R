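# Phase cross-correlation on binary droplet masks.  The two modalities have
# unrelated intensity contrast, so correlation runs on the segmentations,
# not the raw intensities; the peak is refined to subpixel by a quadratic
# fit on its 3x3 neighbourhood.

#' @noRd
good_fft_size <- function(n) {
  m <- n
  repeat {
    k <- m
    for (f in c(2, 3, 5)) while (k %% f == 0) k <- k / f
    if (k == 1) return(m)
    m <- m + 1
  }
}

#' @noRd
pad_to <- function(m, nr, nc) {
  out <- matrix(0, nr, nc)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

#' @noRd
mask_binary <- function(mask) {
  if (inherits(mask, "segmentation_mask")) return(mask$labels > 0L)
  if (inherits(mask, "image_plane")) return(mask$pixels > 0)
  mask > 0
}

# Core phase correlation between two pre-padded FFTs.
# Returns the (dx, dy) shift in pixels such that moving + shift ~ reference.
# The whitened spectrum is low-pass weighted (Gaussian, `lowpass_sigma_px`
# in real space): for sparse blob masks the phase at frequencies beyond the
# blob scale is noise-dominated and produces spurious peaks otherwise.
#' @noRd
pcc_core <- function(Fa, Fb, lowpass_sigma_px = 5) {
  R <- Fa * Conj(Fb)
  mag <- Mod(R)
  R <- R / pmax(mag, 1e-12)
  if (lowpass_sigma_px > 0) {
    nr0 <- nrow(R); nc0 <- ncol(R)
    kr <- c(0:(nr0 %/% 2), -rev(seq_len(nr0 - nr0 %/% 2 - 1))) / nr0
    kc <- c(0:(nc0 %/% 2), -rev(seq_len(nc0 - nc0 %/% 2 - 1))) / nc0
    W <- exp(-2 * pi^2 * lowpass_sigma_px^2 *
               outer(kr^2, kc^2, "+"))
    R <- R * W
  }
  r <- Re(fft(R, inverse = TRUE))
  nr <- nrow(r); nc <- ncol(r)
  peak <- arrayInd(which.max(r), dim(r))
  i <- peak[1]; j <- peak[2]
  # quadratic subpixel interpolation with wraparound, per axis
  sub1 <- function(vm, v0, vp) {
    den <- 2 * (2 * v0 - vm - vp)
    if (abs(den) < 1e-12) 0 else {
      d <- (vp - vm) / den
      max(min(d, 0.5), -0.5)
    }
  }
  wrap <- function(k, n) ((k - 1) %% n) + 1
  di <- sub1(r[wrap(i - 1, nr), j], r[i, j], r[wrap(i + 1, nr), j])
  dj <- sub1(r[i, wrap(j - 1, nc)], r[i, j], r[i, wrap(j + 1, nc)])
  dy <- (i - 1) + di; dx <- (j - 1) + dj
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  c(dx = dx, dy = dy)
}

#' Coarse translation alignment by phase cross-correlation
#'
#' Estimates the translation (in nm) that best superimposes the moving
#' droplet mask on the reference mask, in the sense `p_ref = p_mov + t`.
#'
#' @param ref_mask,mov_mask `segmentation_mask`s (or binary matrices /
#'   [image_plane()]s) sharing the same pixel size.
#' @param pixel_size_nm pixel size; taken from the masks when available.
#' @return named numeric `(dx_nm, dy_nm)`.
#' @export
coarse_align_pcc <- function(ref_mask, mov_mask, pixel_size_nm = NULL) {
  if (is.null(pixel_size_nm)) {
    px_r <- if (inherits(ref_mask, "segmentation_mask")) ref_mask$pixel_size_nm
            else if (inherits(ref_mask, "image_plane")) ref_mask$pixel_size_nm
            else NULL
    px_m <- if (inherits(mov_mask, "segmentation_mask")) mov_mask$pixel_size_nm
            else if (inherits(mov_mask, "image_plane")) mov_mask$pixel_size_nm
            else NULL
    if (is.null(px_r))
      stop_clxm("clxm_input_error", "pixel_size_nm required for bare matrices")
    if (!is.null(px_m) && abs(px_r - px_m) > 1e-9)
      stop_clxm("clxm_input_error", "masks must share pixel size")
    pixel_size_nm <- px_r
  }
  a <- mask_binary(ref_mask); b <- mask_binary(mov_mask)
  if (!any(a) || !any(b))
    stop_clxm("clxm_input_error", "phase correlation needs nonempty masks")
  nr <- good_fft_size(max(nrow(a), nrow(b)))
  nc <- good_fft_size(max(ncol(a), ncol(b)))
  d <- pcc_core(fft(pad_to(a + 0, nr, nc)), fft(pad_to(b + 0, nr, nc)))
  c(dx_nm = unname(d["dx"]) * pixel_size_nm,
    dy_nm = unname(d["dy"]) * pixel_size_nm)
}
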