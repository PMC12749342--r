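# Synthetic correlative FM/SXT scene generator.
#
# Emulates the imaging situation the registration pipeline is built for:
# a field of circular lipid droplets (radii a few hundred nm up to a micron)
# that appear as bright PSF-blurred blobs in epifluorescence (~120 nm/px)
# and as dark absorbing discs or rings in soft X-ray projections (~29 nm/px),
# related by a ground-truth affine transform plus a smooth local distortion.
# FM is the moving/distorted modality; SXT (the scene frame) is the fixed
# reference.

#' Sample a ground-truth droplet scene
#'
#' Droplet centres are drawn by rejection sampling: every droplet lies fully
#' inside the field with an `edge_margin_nm` clearance (so the blurred
#' fluorescence blob stays interior), pairwise centre separations respect
#' `min_sep_nm`, and droplet surfaces keep at least `min_gap_nm` of free
#' space (droplets are solid organelles and must not interpenetrate; the
#' gap also keeps blurred blobs separable).
#'
#' @param n_droplets number of droplets (>= 1).
#' @param field_size_nm numeric length-2 `(width, height)` of the field in nm.
#' @param radius_range_nm numeric length-2 `(min, max)` droplet radius in nm.
#' @param min_sep_nm minimum pairwise centre separation in nm.
#' @param seed integer RNG seed (scenes are deterministic given the seed).
#' @param edge_margin_nm extra clearance between droplet surface and field
#'   border.
#' @param min_gap_nm minimum surface-to-surface gap between droplets.
#' @param max_attempts rejection-sampling budget per droplet.
#' @return a `droplet_scene`: data.frame with columns `cx_nm`, `cy_nm`,
#'   `radius_nm`, plus `field_size_nm` and `seed` attributes.
#' @examples
#' sc <- sample_scene(5, c(20000, 20000), c(400, 800), min_sep_nm = 2500, seed = 1)
#' nrow(sc)
#' @export
sample_scene <- function(n_droplets, field_size_nm = c(30000, 30000),
                         radius_range_nm = c(200, 1000), min_sep_nm = 2000,
                         seed = 1, edge_margin_nm = 1000, min_gap_nm = 600,
                         max_attempts = 500L) {
  stopifnot(n_droplets >= 1, all(field_size_nm > 0),
            radius_range_nm[1] > 0, radius_range_nm[2] >= radius_range_nm[1])
  set.seed(derive_seed(seed, "scene"))
  cx <- cy <- r <- numeric(0)
  for (i in seq_len(n_droplets)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      ri <- stats::runif(1, radius_range_nm[1], radius_range_nm[2])
      inset <- ri + edge_margin_nm
      if (2 * inset >= min(field_size_nm))
        stop_clxm("clxm_packing_error",
                  "field too small for droplet radius plus edge margin")
      xi <- stats::runif(1, inset, field_size_nm[1] - inset)
      yi <- stats::runif(1, inset, field_size_nm[2] - inset)
      if (length(cx) == 0 ||
          all(sqrt((cx - xi)^2 + (cy - yi)^2) >=
              pmax(min_sep_nm, r + ri + min_gap_nm))) {
        cx <- c(cx, xi); cy <- c(cy, yi); r <- c(r, ri)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_clxm("clxm_packing_error",
                "could not place droplet ", i, " of ", n_droplets,
                " after ", max_attempts, " attempts; relax min_sep_nm or field size")
  }
  structure(data.frame(cx_nm = cx, cy_nm = cy, radius_nm = r),
            field_size_nm = as.numeric(field_size_nm), seed = seed,
            class = c("droplet_scene", "data.frame"))
}

#' Sample a ground-truth inter-modality transform
#'
#' The affine component maps the moving (FM) frame onto the reference (SXT)
#' frame — the quantity the registration pipeline estimates.  The local
#' distortion is a smooth thin-plate-spline displacement field from random
#' control points, rescaled so its maximum magnitude over the field equals
#' `warp_amp_nm` (0 disables it).
#'
#' @param field_size_nm field extent `(width, height)` in nm.
#' @param t_max_nm maximum |translation| per axis in nm.
#' @param theta_max_deg maximum |rotation| in degrees.
#' @param scale_range range for the anisotropic scale factors.
#' @param warp_amp_nm peak local-distortion magnitude in nm.
#' @param n_warp_ctrl number of distortion control points.
#' @param seed integer RNG seed.
#' @return list with `affine` (an `affine2d`, moving -> reference), `warp`
#'   (a `tps_warp` or `NULL`) and `warp_amp_nm`.
#' @export
sample_ground_truth <- function(field_size_nm = c(30000, 30000),
                                t_max_nm = 2000, theta_max_deg = 3,
                                scale_range = c(0.97, 1.03),
                                warp_amp_nm = 150, n_warp_ctrl = 8L,
                                seed = 1) {
  set.seed(derive_seed(seed, "ground_truth"))
  centre <- field_size_nm / 2
  aff <- affine_transform(
    tx_nm = stats::runif(1, -t_max_nm, t_max_nm),
    ty_nm = stats::runif(1, -t_max_nm, t_max_nm),
    theta_deg = stats::runif(1, -theta_max_deg, theta_max_deg),
    sx = stats::runif(1, scale_range[1], scale_range[2]),
    sy = stats::runif(1, scale_range[1], scale_range[2]),
    centre_nm = centre)
  warp <- NULL
  if (warp_amp_nm > 0) {
    ctrl <- cbind(stats::runif(n_warp_ctrl, 0, field_size_nm[1]),
                  stats::runif(n_warp_ctrl, 0, field_size_nm[2]))
    disp <- matrix(stats::runif(2 * n_warp_ctrl, -1, 1), ncol = 2) * warp_amp_nm
    warp <- tps_fit(ctrl, disp, lambda = 0)
    # rescale so the peak displacement over the field equals warp_amp_nm
    gx <- seq(0, field_size_nm[1], length.out = 40)
    gy <- seq(0, field_size_nm[2], length.out = 40)
    grid <- as.matrix(expand.grid(x = gx, y = gy))
    mags <- sqrt(rowSums(tps_displacement(warp, grid)^2))
    s <- warp_amp_nm / max(mags)
    warp$w <- warp$w * s
    warp$a <- warp$a * s
  }
  list(affine = aff, warp = warp, warp_amp_nm = warp_amp_nm)
}

#' Rendering parameters for the synthetic modalities
#'
#' Defaults encode the study conditions: FM sampled at 120 nm/px with a
#' 250 nm PSF sigma, SXT at 29 nm/px with ring-like droplet absorption, and
#' additive Gaussian noise sized so the faintest droplet has a
#' contrast-to-noise ratio of about 5.
#'
#' @param fm_pixel_nm,sxt_pixel_nm physical pixel pitches (nm/px).
#' @param fm_psf_sigma_nm Gaussian PSF sigma of the FM channel (nm).
#' @param sxt_ring render droplets as dark rims with a brighter core
#'   (`TRUE`, the characteristic SXT appearance) or as filled dark discs.
#' @param ring_width_nm rim width (FWHM of the rim absorption profile, nm).
#' @param ring_core niveau of core absorption relative to the rim (0..1).
#' @param fm_background,fm_amplitude FM background level and blob height.
#' @param sxt_background,sxt_absorption SXT background transmission and
#'   peak droplet absorption depth.
#' @param fm_noise_sd,sxt_noise_sd additive Gaussian noise sigmas.
#' @param supersample anti-aliasing factor (discs drawn on a `supersample`x
#'   finer grid, then box-averaged down).
#' @param seed integer RNG seed for the noise streams.
#' @return list of class `render_params`.
#' @export
render_params <- function(fm_pixel_nm = 120, sxt_pixel_nm = 29,
                          fm_psf_sigma_nm = 250, sxt_ring = TRUE,
                          ring_width_nm = 150, ring_core = 0.25,
                          fm_background = 0.1, fm_amplitude = 0.9,
                          sxt_background = 0.9, sxt_absorption = 0.5,
                          fm_noise_sd = 0.05, sxt_noise_sd = 0.1,
                          supersample = 4L, seed = 1) {
  stopifnot(fm_pixel_nm > 0, sxt_pixel_nm > 0, fm_psf_sigma_nm >= 0,
            fm_noise_sd >= 0, sxt_noise_sd >= 0, supersample >= 1)
  structure(as.list(environment()), class = "render_params")
}

# Draw discs onto a supersampled canvas and box-average down.
# profile(r2, R) returns the absorption/emission height at squared radius r2.
#' @noRd
render_discs <- function(centres, radii, field_size_nm, pixel_nm, ss, profile) {
  n_col <- max(1L, round(field_size_nm[1] / pixel_nm))
  n_row <- max(1L, round(field_size_nm[2] / pixel_nm))
  step <- pixel_nm / ss
  off <- -(ss - 1) / 2 * step   # ss-grid index m sits at m*step + off (nm)
  nc_ss <- n_col * ss; nr_ss <- n_row * ss
  canvas <- matrix(0, nr_ss, nc_ss)
  for (i in seq_len(nrow(centres))) {
    cx <- centres[i, 1]; cy <- centres[i, 2]; R <- radii[i]
    c_lo <- max(0, floor((cx - R - step - off) / step))
    c_hi <- min(nc_ss - 1, ceiling((cx + R + step - off) / step))
    r_lo <- max(0, floor((cy - R - step - off) / step))
    r_hi <- min(nr_ss - 1, ceiling((cy + R + step - off) / step))
    if (c_hi < c_lo || r_hi < r_lo) next  # fully outside the field
    cols <- c_lo:c_hi; rows <- r_lo:r_hi
    dx2 <- (cols * step + off - cx)^2
    dy2 <- (rows * step + off - cy)^2
    r2 <- outer(dy2, dx2, "+")
    sub <- canvas[rows + 1, cols + 1, drop = FALSE]
    canvas[rows + 1, cols + 1] <- pmax(sub, profile(r2, R))
  }
  if (ss > 1) canvas <- block_mean(canvas, ss)
  canvas
}

#' @noRd
block_mean <- function(m, ss) {
  nr <- nrow(m) %/% ss; nc <- ncol(m) %/% ss
  # average rows then columns
  m1 <- matrix(colMeans(matrix(m, nrow = ss)), nrow = nr, ncol = ncol(m))
  t(matrix(colMeans(matrix(t(m1), nrow = ss)), nrow = nc, ncol = nr))
}

#' Render the fluorescence (moving) modality of a scene
#'
#' Droplet centres are mapped from the reference frame into the FM frame
#' through the inverse of the ground-truth affine plus the local distortion,
#' drawn as discs, convolved with the Gaussian PSF, and sampled at
#' `fm_pixel_nm`; noise is applied last.
#'
#' @param scene a `droplet_scene` from [sample_scene()].
#' @param gt ground truth from [sample_ground_truth()] (identity affine and
#'   no warp if `NULL`).
#' @param p a [render_params()] list.
#' @return an [image_plane()] with modality `"FM"`.
#' @export
render_fm <- function(scene, gt = NULL, p = render_params()) {
  fs <- attr(scene, "field_size_nm")
  pts <- as.matrix(scene[, c("cx_nm", "cy_nm")])
  if (!is.null(gt)) {
    pos <- apply_affine(invert_affine(gt$affine), pts)
    if (!is.null(gt$warp)) pos <- pos + tps_displacement(gt$warp, pts)
  } else pos <- pts
  img <- render_discs(pos, scene$radius_nm, fs, p$fm_pixel_nm, p$supersample,
                      profile = function(r2, R) p$fm_amplitude * (r2 <= R^2))
  if (p$fm_psf_sigma_nm > 0) {
    sig_px <- p$fm_psf_sigma_nm / p$fm_pixel_nm
    img <- from_eb(EBImage::gblur(as_eb(img), sigma = sig_px))
  }
  img <- img + p$fm_background
  if (p$fm_noise_sd > 0) {
    set.seed(derive_seed(p$seed, "fm_noise"))
    img <- img + matrix(stats::rnorm(length(img), sd = p$fm_noise_sd),
                        nrow(img), ncol(img))
  }
  image_plane(img, pixel_size_nm = p$fm_pixel_nm, modality = "FM")
}

#' @noRd
sxt_profile <- function(p) {
  if (!p$sxt_ring)
    return(function(r2, R) p$sxt_absorption * (r2 <= R^2))
  function(r2, R) {
    r <- sqrt(r2)
    hw <- p$ring_width_nm / 2
    sig <- p$ring_width_nm / 2.355          # FWHM -> sigma
    rim <- exp(-((r - (R - hw))^2) / (2 * sig^2))
    p$sxt_absorption * pmax(p$ring_core * (r <= R), rim * (r <= R))
  }
}

#' Render the soft X-ray (reference) modality of a scene
#'
#' Droplets are darker than the background (absorption contrast), rendered
#' in the undistorted scene frame at `sxt_pixel_nm`, as filled discs or as
#' rings with a dark rim and brighter core per `p$sxt_ring`.
#'
#' @inheritParams render_fm
#' @return an [image_plane()] with modality `"SXT"`.
#' @export
render_sxt <- function(scene, p = render_params()) {
  fs <- attr(scene, "field_size_nm")
  pts <- as.matrix(scene[, c("cx_nm", "cy_nm")])
  absorb <- render_discs(pts, scene$radius_nm, fs, p$sxt_pixel_nm,
                         p$supersample, profile = sxt_profile(p))
  img <- p$sxt_background - absorb
  if (p$sxt_noise_sd > 0) {
    set.seed(derive_seed(p$seed, "sxt_noise"))
    img <- img + matrix(stats::rnorm(length(img), sd = p$sxt_noise_sd),
                        nrow(img), ncol(img))
  }
  image_plane(img, pixel_size_nm = p$sxt_pixel_nm, modality = "SXT")
}

#' @rdname render_sxt
#' @param n_slices number of z-slices; droplets are distributed round-robin
#'   across slices so a minimum-intensity projection recovers the 2D render
#'   (exactly so when noise-free).
#' @export
render_sxt_stack <- function(scene, p = render_params(), n_slices = 5L) {
  stopifnot(n_slices >= 1)
  fs <- attr(scene, "field_size_nm")
  pts <- as.matrix(scene[, c("cx_nm", "cy_nm")])
  prof <- sxt_profile(p)
  slices <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    idx <- which((seq_len(nrow(scene)) - 1L) %% n_slices == (k - 1L))
    absorb <- render_discs(pts[idx, , drop = FALSE], scene$radius_nm[idx],
                           fs, p$sxt_pixel_nm, p$supersample, profile = prof)
    img <- p$sxt_background - absorb
    if (p$sxt_noise_sd > 0) {
      set.seed(derive_seed(p$seed, paste0("sxt_slice_", k)))
      img <- img + matrix(stats::rnorm(length(img), sd = p$sxt_noise_sd),
                          nrow(img), ncol(img))
    }
    slices[[k]] <- image_plane(img, pixel_size_nm = p$sxt_pixel_nm,
                               modality = "SXT")
  }
  image_stack(slices, axis_meaning = "Z_SLICES")
}

#' Build two noise-independent realizations of the same image
#'
#' Mirrors the frame-splitting acquisition scheme: both images share `base`
#' and receive independent additive Gaussian noise streams.
#'
#' @param base an [image_plane()].
#' @param noise_sigma Gaussian noise sigma (>= 0).
#' @param seed integer seed (pair is reproducible).
#' @return list of two [image_plane()]s.
#' @export
make_frc_pair <- function(base, noise_sigma, seed = 1) {
  stopifnot(inherits(base, "image_plane"), noise_sigma >= 0)
  mk <- function(tag) {
    m <- base$pixels
    if (noise_sigma > 0) {
      set.seed(derive_seed(seed, tag))
      m <- m + matrix(stats::rnorm(length(m), sd = noise_sigma),
                      nrow(m), ncol(m))
    }
    image_plane(m, base$pixel_size_nm, base$modality)
  }
  list(mk("frc_half_a"), mk("frc_half_b"))
}

#' Plan a tilt series as an inclusive arithmetic progression
#'
#' A 1-degree step over a 120-degree range (-60..+60) yields 121 projection
#' angles; a 180-degree range (-90..+90) yields 181.
#'
#' @param min_deg,max_deg tilt range bounds (degrees), `max_deg > min_deg`.
#' @param step_deg step (degrees, > 0); the range must be divisible by it.
#' @return numeric vector of tilt angles, inclusive of both ends.
#' @examples
#' length(plan_tilt_series(-60, 60, 1))  # 121
#' @export
plan_tilt_series <- function(min_deg, max_deg, step_deg) {
  if (max_deg <= min_deg || step_deg <= 0)
    stop_clxm("clxm_input_error", "need max_deg > min_deg and step_deg > 0")
  n <- (max_deg - min_deg) / step_deg
  if (abs(n - round(n)) > 1e-9)
    stop_clxm("clxm_planning_error",
              "tilt range is not divisible by the step")
  min_deg + step_deg * (0:round(n))
}

#' Generate a complete synthetic correlative FM/SXT pair
#'
#' One call producing the default study conditions: 15 droplets with radii
#' 200-1000 nm in a 30 x 30 um field (>= 2 um separation), ground-truth
#' affine within |t| <= 2 um, |theta| <= 3 deg, scales 0.97-1.03, local
#' thin-plate distortion up to 150 nm, FM at 120 nm/px (250 nm PSF sigma),
#' SXT at 29 nm/px, default noise.
#'
#' @param seed integer seed driving scene, transform and noise.
#' @param n_droplets,field_size_nm,radius_range_nm,min_sep_nm scene geometry.
#' @param t_max_nm,theta_max_deg,scale_range,warp_amp_nm transform bounds.
#' @param params a [render_params()] list (its `seed` is overridden).
#' @return list with `scene`, `gt`, `fm`, `sxt`, `params`.
#' @export
simulate_pair <- function(seed = 1, n_droplets = 15L,
                          field_size_nm = c(30000, 30000),
                          radius_range_nm = c(200, 1000), min_sep_nm = 2000,
                          t_max_nm = 2000, theta_max_deg = 3,
                          scale_range = c(0.97, 1.03), warp_amp_nm = 150,
                          params = render_params()) {
  params$seed <- seed
  scene <- sample_scene(n_droplets, field_size_nm, radius_range_nm,
                        min_sep_nm, seed = seed)
  gt <- sample_ground_truth(field_size_nm, t_max_nm, theta_max_deg,
                            scale_range, warp_amp_nm, seed = seed)
  list(scene = scene, gt = gt,
       fm = render_fm(scene, gt, params),
       sxt = render_sxt(scene, params),
       params = params)
}
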