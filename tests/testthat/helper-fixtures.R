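# Shared fixtures, all generated in code at test time.

# noise-free render parameters
quiet_params <- function(...) {
  render_params(fm_noise_sd = 0, sxt_noise_sd = 0, ...)
}

# a small, fast scene (15 x 15 um field, a handful of droplets)
small_scene <- function(n = 6, seed = 1, radius_range = c(300, 700)) {
  sample_scene(n, field_size_nm = c(15000, 15000),
               radius_range_nm = radius_range, min_sep_nm = 2000, seed = seed)
}

# circularly roll a matrix by (dr, dc)
roll_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dr) %% nr) + 1, ((seq_len(nc) - 1 - dc) %% nc) + 1]
}

# intensity-weighted centre of mass of a matrix, 0-based (x, y) pixels
weighted_centroid_px <- function(m) {
  w <- m - min(m)
  c(x = sum((col(m) - 1) * w) / sum(w),
    y = sum((row(m) - 1) * w) / sum(w))
}

# band-limited periodic image pair sharing signal up to ring `k_cut`,
# plus independent white noise; used by the FRC band-limit checks
banded_pair <- function(n = 128, k_cut = 30, noise_sd = 0.15,
                        pixel_nm = 29, seed = 11) {
  set.seed(seed)
  k <- c(0:(n / 2 - 1), -(n / 2):-1)
  kr <- sqrt(outer(k^2, k^2, "+"))
  F <- fft(matrix(rnorm(n * n), n))
  F[kr > k_cut] <- 0
  sig <- Re(fft(F, inverse = TRUE)) / n^2
  sig <- sig / sd(sig)
  list(a = image_plane(sig + matrix(rnorm(n * n, sd = noise_sd), n), pixel_nm),
       b = image_plane(sig + matrix(rnorm(n * n, sd = noise_sd), n), pixel_nm),
       k_cut = k_cut, n = n, pixel_nm = pixel_nm)
}

# centroid_set -> plain matrix
as_matrix_points <- function(cs) cbind(cs$x_nm, cs$y_nm)

# decompose the linear part M = R(theta) S(sx, sy)
decompose_rs <- function(M) {
  c(theta_deg = atan2(M[2, 1], M[1, 1]) * 180 / pi,
    sx = sqrt(M[1, 1]^2 + M[2, 1]^2),
    sy = sqrt(M[1, 2]^2 + M[2, 2]^2))
}

# segment a rendered pair the way the pipeline does (FM rescaled first)
segment_pair <- function(pair) {
  mov_r <- rescale_to_reference(pair$fm, pair$sxt$pixel_size_nm)
  list(ref = segment_droplets(pair$sxt, modality = "SXT"),
       mov = segment_droplets(mov_r, modality = "FM"))
}
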