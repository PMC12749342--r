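# Fourier ring correlation, frame splitting, depth profiling, and FWHM
# line profiles.

test_that("frame splitting conserves signal and requires even counts", {
  px <- 29
  mk <- function(v) image_plane(matrix(v, 16, 16), px)
  st <- image_stack(lapply(c(3, 3, 3, 3), mk), axis_meaning = "TILT_FRAMES")
  halves <- split_frames(st)
  expect_equal(halves[[1]]$slices[[1]]$pixels, matrix(6, 16, 16))
  expect_equal(halves[[2]]$slices[[1]]$pixels, matrix(6, 16, 16))

  set.seed(4)
  frames <- lapply(1:8, function(k) mk(runif(256, 0, 2)))
  st2 <- image_stack(frames, axis_meaning = "TILT_FRAMES",
                     tilt_angles_deg = rep(c(-1, 1), each = 4))
  h2 <- split_frames(st2)
  expect_length(h2[[1]]$slices, 2)  # one summed frame per tilt
  total <- Reduce(`+`, lapply(frames, function(s) s$pixels))
  ab <- h2[[1]]$slices[[1]]$pixels + h2[[2]]$slices[[1]]$pixels +
        h2[[1]]$slices[[2]]$pixels + h2[[2]]$slices[[2]]$pixels
  expect_equal(ab, total, tolerance = 1e-12)

  st3 <- image_stack(frames[1:3], axis_meaning = "TILT_FRAMES")
  expect_error(split_frames(st3), class = "clxm_split_error")
})

test_that("FRC is 1 for self-correlation, symmetric, and near 0 for noise", {
  set.seed(10)
  a <- image_plane(matrix(rnorm(128^2), 128), 29)
  self <- frc(a, a)
  expect_lt(max(abs(self$frc - 1)), 1e-9)
  expect_equal(self$ring_index[1], 1L)  # DC ring excluded
  expect_true(all(diff(self$frequency_cyc_per_nm) > 0))
  expect_lte(max(self$frequency_cyc_per_nm), 1 / (2 * 29) + 1e-12)

  b <- image_plane(matrix(rnorm(128^2), 128), 29)
  expect_identical(frc(a, b)$frc, frc(b, a)$frc)
  noise <- frc(a, b)
  expect_lt(abs(mean(noise$frc)), 3 / sqrt(nrow(noise)))
  expect_true(all(abs(noise$frc) <= 1 + 1e-12))
  expect_error(frc(a, image_plane(matrix(1, 6, 6), 29)),
               class = "clxm_input_error")
})

test_that("FRC is invariant to a common affine intensity rescaling", {
  set.seed(12)
  bp <- banded_pair(seed = 12)
  c1 <- frc(bp$a, bp$b)
  a2 <- image_plane(3.7 * bp$a$pixels + 11, 29)
  b2 <- image_plane(3.7 * bp$b$pixels + 11, 29)
  c2 <- frc(a2, b2)
  expect_lt(max(abs(c1$frc - c2$frc)), 1e-9)
})

test_that("the 0.25 crossing interpolates between rings as full pitch", {
  # hand-built curve: 0.3 at 0.01 cyc/nm, 0.2 at 0.0125 =>
  # crossing at 0.01 + 0.0025 * (0.3 - 0.25)/(0.3 - 0.2) = 0.01125
  curve <- structure(
    data.frame(ring_index = 1:4,
               frequency_cyc_per_nm = c(0.0075, 0.01, 0.0125, 0.015),
               frc = c(0.8, 0.3, 0.2, 0.1), n_samples = c(8, 16, 24, 32)),
    pixel_size_nm = 29, nyquist_cyc_per_nm = 1 / 58,
    class = c("frc_curve", "data.frame"))
  est <- resolution_at_threshold(curve)
  expect_equal(est$threshold, 0.25)     # the convention's default
  expect_equal(est$crossing_frequency, 0.01125)
  expect_equal(est$full_pitch_nm, 1 / 0.01125, tolerance = 1e-9)
  expect_true(est$interpolated)

  # a curve pinned at 1 everywhere is Nyquist-limited
  a <- image_plane(matrix(rnorm(64^2), 64), 29)
  est2 <- resolution_at_threshold(frc(a, a))
  expect_false(est2$interpolated)
  expect_equal(est2$full_pitch_nm, 2 * 29)

  # already below threshold at the first ring: degenerate
  curve$frc <- c(0.1, 0.05, 0.02, 0.01)
  expect_true(resolution_at_threshold(curve)$degenerate)
})

test_that("the crossing estimator recovers a constructed band limit", {
  bp <- banded_pair(n = 128, k_cut = 30, noise_sd = 0.15, seed = 11)
  est <- resolution_at_threshold(frc(bp$a, bp$b, window = "none"))
  cross_ring <- est$crossing_frequency * bp$n * bp$pixel_nm
  expect_lt(abs(cross_ring - bp$k_cut), 1)  # within one ring width
})

test_that("depth profiles track focus through z-dependent blur", {
  set.seed(14)
  base <- banded_pair(n = 96, k_cut = 28, noise_sd = 0)$a$pixels
  sigmas <- c(0.8, 2, 4)
  mk_half <- function(tag) image_stack(lapply(seq_along(sigmas), function(i) {
    blur <- clxmreg:::from_eb(EBImage::gblur(clxmreg:::as_eb(base),
                                             sigma = sigmas[i]))
    image_plane(blur + matrix(rnorm(96^2, sd = 0.1), 96), 29)
  }))
  pa <- mk_half("a"); pb <- mk_half("b")
  prof <- depth_profile(pa, pb)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$z_offset_nm[which.min(prof$full_pitch_nm)], 0)
  expect_true(all(diff(prof$full_pitch_nm) >= 0))  # focal slice is first

  # identical stacks are Nyquist-flagged at every z
  same <- depth_profile(pa, pa)
  expect_true(all(same$full_pitch_nm == 2 * 29))
  one <- depth_profile(image_stack(pa$slices[1]), image_stack(pb$slices[1]))
  expect_equal(nrow(one), 1)
  expect_error(depth_profile(pa, image_stack(pb$slices[1:2])),
               class = "clxm_input_error")
})

test_that("FWHM matches closed forms and refuses undefined profiles", {
  # Gaussian peak, sigma 20 nm: FWHM = 2 sqrt(2 ln 2) * 20 = 47.096 nm
  xs <- seq(0, 200, by = 1)
  m <- matrix(rep(exp(-((xs - 100)^2) / (2 * 20^2)), each = 5), 5,
              byrow = FALSE)
  img <- image_plane(m, 1)
  prof <- line_profile(img, c(0, 2), c(200, 2), step_nm = 1)
  expect_equal(nrow(prof), 201)
  expect_lt(abs(fwhm(prof) - 2 * sqrt(2 * log(2)) * 20), 0.5)
  # finer sampling converges further
  prof_f <- line_profile(img, c(0, 2), c(200, 2), step_nm = 0.25)
  expect_lte(abs(fwhm(prof_f) - 2 * sqrt(2 * log(2)) * 20),
             abs(fwhm(prof) - 2 * sqrt(2 * log(2)) * 20) + 0.05)

  # rectangular dip of width 60 nm, within one sampling step
  v <- rep(1, 201); v[71:130] <- 0
  m2 <- matrix(rep(v, each = 5), 5)
  prof2 <- line_profile(image_plane(m2, 1), c(0, 2), c(200, 2), step_nm = 1)
  expect_lt(abs(fwhm(prof2, polarity = "dip") - 60), 1.5)
  # auto polarity picks the dip here
  expect_equal(fwhm(prof2, "auto"), fwhm(prof2, "dip"))

  ramp <- matrix(rep(seq(0, 1, length.out = 101), each = 5), 5)
  prof3 <- line_profile(image_plane(ramp, 1), c(0, 2), c(100, 2), step_nm = 1)
  expect_error(fwhm(prof3), class = "clxm_fwhm_undefined_error")
  expect_error(line_profile(img, c(-5, 0), c(10, 0), 1),
               class = "clxm_input_error")
})
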