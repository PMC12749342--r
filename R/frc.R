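# Fourier ring correlation resolution estimation.
#
# Two noise-independent realizations of the same field are correlated per
# spatial-frequency ring; resolution is read off where the curve first
# drops below a fixed threshold (0.25 by default) and reported as full
# pitch (one full period, 1/frequency).

#' Split a frame series into two noise-independent half-datasets
#'
#' Even-indexed frames (0-based) are summed into half A, odd-indexed into
#' half B, per tilt group (`tilt_angles_deg` when present, else the whole
#' stack is one group).  Conservation holds: A + B equals the sum of all
#' frames pixelwise.
#'
#' @param frames an [image_stack()] with an even number (>= 2) of frames
#'   per tilt position.
#' @return list of two [image_stack()]s (one summed frame per tilt group).
#' @export
split_frames <- function(frames) {
  stopifnot(inherits(frames, "image_stack"))
  angles <- frames$tilt_angles_deg
  groups <- if (is.null(angles)) list(seq_along(frames$slices))
            else split(seq_along(frames$slices), match(angles, unique(angles)))
  px <- frames$slices[[1]]$pixel_size_nm
  a_slices <- b_slices <- vector("list", length(groups))
  g_angles <- numeric(length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    if (length(idx) < 2L || length(idx) %% 2L != 0L)
      stop_clxm("clxm_split_error",
                "each tilt group needs an even frame count >= 2 (group ", g,
                " has ", length(idx), ")")
    even <- idx[seq_along(idx) %% 2L == 1L]  # 0-based even = 1st, 3rd, ...
    odd  <- idx[seq_along(idx) %% 2L == 0L]
    sum_of <- function(ii) Reduce(`+`, lapply(frames$slices[ii],
                                              function(s) s$pixels))
    a_slices[[g]] <- image_plane(sum_of(even), px, frames$slices[[1]]$modality)
    b_slices[[g]] <- image_plane(sum_of(odd), px, frames$slices[[1]]$modality)
    if (!is.null(angles)) g_angles[g] <- angles[idx[1]]
  }
  mk <- function(sl) image_stack(sl, axis_meaning = frames$axis_meaning,
                                 tilt_angles_deg = if (is.null(angles)) NULL
                                                   else g_angles)
  list(mk(a_slices), mk(b_slices))
}

#' Fourier ring correlation between two images
#'
#' `FRC(r) = Re{sum_ring Fa conj(Fb)} / sqrt(sum_ring |Fa|^2 sum_ring |Fb|^2)`
#' over concentric integer-radius frequency rings.  Images are mean-
#' subtracted, optionally Hann-windowed (default, suppresses edge leakage),
#' and zero-padded to a common square.  The DC ring is excluded; the curve
#' starts at ring 1.
#'
#' @param a,b [image_plane()]s of the same shape and pixel size.
#' @param ring_width_bins ring width in frequency bins (default 1).
#' @param window `"hann"` or `"none"`.
#' @return an `frc_curve`: data.frame with `ring_index`,
#'   `frequency_cyc_per_nm`, `frc`, `n_samples`, plus `pixel_size_nm` and
#'   `nyquist_cyc_per_nm` attributes.
#' @export
frc <- function(a, b, ring_width_bins = 1L, window = c("hann", "none")) {
  window <- match.arg(window)
  stopifnot(inherits(a, "image_plane"), inherits(b, "image_plane"))
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop_clxm("clxm_input_error", "FRC inputs must share shape")
  if (abs(a$pixel_size_nm - b$pixel_size_nm) > 1e-9)
    stop_clxm("clxm_input_error", "FRC inputs must share pixel size")
  px <- a$pixel_size_nm
  n <- max(dim(a$pixels))
  prep <- function(m) {
    m <- m - mean(m)
    if (window == "hann") {
      wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nrow(m)) - 1) / (nrow(m) - 1))
      wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ncol(m)) - 1) / (ncol(m) - 1))
      m <- m * outer(wr, wc)
    }
    pad_to(m, n, n)
  }
  Fa <- fft(prep(a$pixels)); Fb <- fft(prep(b$pixels))
  # integer frequency indices (cycles per field), centred at 0
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  if (n %% 2 == 0) k <- c(0:(n / 2 - 1), -(n / 2):-1)
  kr <- sqrt(outer(k^2, k^2, "+"))
  ring <- as.integer(round(kr / ring_width_bins))
  max_ring <- floor((n %/% 2) / ring_width_bins)
  num <- Re(Fa * Conj(Fb))
  pa <- Mod(Fa)^2; pb <- Mod(Fb)^2
  rim <- ring >= 1L & ring <= max_ring
  rv <- ring[rim]
  s_num <- tapply(num[rim], rv, sum)
  s_pa <- tapply(pa[rim], rv, sum)
  s_pb <- tapply(pb[rim], rv, sum)
  cnt <- tapply(rep(1, sum(rim)), rv, sum)
  idx <- as.integer(names(s_num))
  vals <- as.numeric(s_num) / sqrt(pmax(as.numeric(s_pa) * as.numeric(s_pb),
                                        .Machine$double.xmin))
  freq <- idx * ring_width_bins / (n * px)
  structure(data.frame(ring_index = idx, frequency_cyc_per_nm = freq,
                       frc = vals, n_samples = as.numeric(cnt)),
            pixel_size_nm = px, nyquist_cyc_per_nm = 1 / (2 * px),
            window = window,
            class = c("frc_curve", "data.frame"))
}

#' Read a resolution off an FRC curve at a fixed threshold
#'
#' The first downward crossing of the threshold is located by linear
#' interpolation between adjacent rings; resolution is reported as full
#' pitch (1/frequency).  A curve that never crosses is Nyquist-limited
#' (`full_pitch_nm = 2 * pixel_size`, `interpolated = FALSE`); a curve
#' already below threshold at the first ring is flagged degenerate.
#'
#' @param curve an `frc_curve` from [frc()].
#' @param threshold fixed FRC threshold (default 0.25, the convention
#'   matching previously published soft X-ray optical characterisation).
#' @return a `resolution_estimate`: list with `full_pitch_nm`,
#'   `crossing_frequency`, `threshold`, `interpolated`, `degenerate`.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.25) {
  stopifnot(inherits(curve, "frc_curve"), threshold > 0, threshold < 1)
  f <- curve$frequency_cyc_per_nm; v <- curve$frc
  px <- attr(curve, "pixel_size_nm")
  if (v[1] < threshold)
    return(structure(list(full_pitch_nm = NA_real_, crossing_frequency = NA_real_,
                          threshold = threshold, interpolated = FALSE,
                          degenerate = TRUE), class = "resolution_estimate"))
  below <- which(v < threshold)
  if (length(below) == 0)
    return(structure(list(full_pitch_nm = 2 * px,
                          crossing_frequency = 1 / (2 * px),
                          threshold = threshold, interpolated = FALSE,
                          degenerate = FALSE), class = "resolution_estimate"))
  i <- below[1]                       # first ring below; i-1 is above
  f_cross <- f[i - 1] + (f[i] - f[i - 1]) *
    (v[i - 1] - threshold) / (v[i - 1] - v[i])
  structure(list(full_pitch_nm = 1 / f_cross, crossing_frequency = f_cross,
                 threshold = threshold, interpolated = TRUE,
                 degenerate = FALSE), class = "resolution_estimate")
}

#' @export
print.resolution_estimate <- function(x, ...) {
  if (isTRUE(x$degenerate)) cat("<resolution_estimate> degenerate (below threshold at first ring)\n")
  else cat(sprintf("<resolution_estimate> full pitch %.1f nm at FRC threshold %.2f%s\n",
                   x$full_pitch_nm, x$threshold,
                   if (!x$interpolated) " (Nyquist-limited)" else ""))
  invisible(x)
}

#' FRC resolution versus distance from the focal plane
#'
#' Per-slice FRC resolution between two half-dataset reconstructions; the
#' focal slice is the slice of minimal full-pitch resolution and z-offsets
#' are reported relative to it.
#'
#' @param recon_a,recon_b paired half-dataset [image_stack()]s of the same
#'   geometry.
#' @param threshold FRC threshold (default 0.25).
#' @param slice_spacing_nm physical z-spacing between slices; defaults to
#'   the in-plane pixel size.
#' @return data.frame with `slice`, `z_offset_nm`, `full_pitch_nm`.
#' @export
depth_profile <- function(recon_a, recon_b, threshold = 0.25,
                          slice_spacing_nm = NULL) {
  stopifnot(inherits(recon_a, "image_stack"), inherits(recon_b, "image_stack"))
  if (length(recon_a$slices) != length(recon_b$slices))
    stop_clxm("clxm_input_error", "half-dataset stacks must have equal slice counts")
  if (is.null(slice_spacing_nm))
    slice_spacing_nm <- recon_a$slices[[1]]$pixel_size_nm
  fp <- vapply(seq_along(recon_a$slices), function(i) {
    est <- resolution_at_threshold(frc(recon_a$slices[[i]], recon_b$slices[[i]]),
                                   threshold)
    if (isTRUE(est$degenerate)) NA_real_ else est$full_pitch_nm
  }, numeric(1))
  focal <- which.min(fp)
  data.frame(slice = seq_along(fp),
             z_offset_nm = (seq_along(fp) - focal) * slice_spacing_nm,
             full_pitch_nm = fp)
}
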