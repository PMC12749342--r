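# Ground-truth scene sampling and the two modality renderers.

test_that("scene sampling honours geometry constraints deterministically", {
  sc <- sample_scene(15, c(30000, 30000), c(200, 1000), min_sep_nm = 2000,
                     seed = 1)
  expect_equal(nrow(sc), 15)
  expect_true(all(sc$radius_nm >= 200 & sc$radius_nm <= 1000))
  # fully inside the field
  expect_true(all(sc$cx_nm - sc$radius_nm >= 0 &
                  sc$cx_nm + sc$radius_nm <= 30000 &
                  sc$cy_nm - sc$radius_nm >= 0 &
                  sc$cy_nm + sc$radius_nm <= 30000))
  # all pairwise centre separations >= 2 um
  d <- as.matrix(dist(sc[, c("cx_nm", "cy_nm")]))
  expect_true(all(d[upper.tri(d)] >= 2000))
  # droplets are solid: no interpenetration
  rr <- outer(sc$radius_nm, sc$radius_nm, "+")
  expect_true(all(d[upper.tri(d)] >= rr[upper.tri(rr)]))
  # determinism
  expect_identical(sample_scene(15, seed = 5), sample_scene(15, seed = 5))

  one <- sample_scene(1, c(10000, 10000), c(500, 500), 500, seed = 7)
  expect_equal(nrow(one), 1)
  expect_equal(one$radius_nm, 500)

  expect_error(sample_scene(1000, c(5000, 5000), c(900, 1000), 2000),
               class = "clxm_packing_error")
})

test_that("renders are deterministic and place droplets where the scene says", {
  sc <- small_scene(n = 4, seed = 2)
  p <- render_params(seed = 9)
  expect_identical(render_fm(sc, NULL, p)$pixels, render_fm(sc, NULL, p)$pixels)
  expect_identical(render_sxt(sc, p)$pixels, render_sxt(sc, p)$pixels)

  # noise-free single droplet: global FM maximum within 1 px of the centre
  one <- sample_scene(1, c(10000, 10000), c(600, 600), 500, seed = 3)
  fm <- render_fm(one, NULL, quiet_params())
  peak <- arrayInd(which.max(fm$pixels), dim(fm$pixels))
  expect_lt(abs((peak[2] - 1) * 120 - one$cx_nm), 120)
  expect_lt(abs((peak[1] - 1) * 120 - one$cy_nm), 120)

  # psf -> 0: blob support equals the disc support within 1 px
  fm0 <- render_fm(one, NULL, quiet_params(fm_psf_sigma_nm = 0))
  half <- (max(fm0$pixels) + min(fm0$pixels)) / 2
  sup <- which(fm0$pixels > half, arr.ind = TRUE)
  r_est <- max(sqrt(((sup[, 2] - 1) * 120 - one$cx_nm)^2 +
                    ((sup[, 1] - 1) * 120 - one$cy_nm)^2))
  expect_lt(abs(r_est - one$radius_nm), 120)

  # a pure ground-truth translation moves the blob by t / pixel size
  gtT <- list(affine = affine_transform(tx_nm = 1000, ty_nm = 0), warp = NULL)
  c0 <- weighted_centroid_px(render_fm(one, NULL, quiet_params())$pixels)
  c1 <- weighted_centroid_px(render_fm(one, gtT, quiet_params())$pixels)
  # FM is the moving modality: reference positions map through the inverse
  expect_equal(unname(c1["x"] - c0["x"]), -1000 / 120, tolerance = 0.02)
  expect_lt(abs(c1["y"] - c0["y"]), 0.05)
})

test_that("SXT renders have absorption contrast with the ring-core structure", {
  one <- sample_scene(1, c(8000, 8000), c(700, 700), 500, seed = 4)
  # filled disc: centre darker than background
  filled <- render_sxt(one, quiet_params(sxt_ring = FALSE))
  ci <- round(one$cy_nm / 29) + 1; cj <- round(one$cx_nm / 29) + 1
  expect_lt(filled$pixels[ci, cj], 0.9)
  # ring: centre brighter than the rim
  ring <- render_sxt(one, quiet_params(sxt_ring = TRUE))
  rim_j <- round((one$cx_nm + one$radius_nm - 75) / 29) + 1
  expect_gt(ring$pixels[ci, cj], ring$pixels[ci, rim_j])

  # physical radius is recovered from the dip half-contrast width
  prof <- line_profile(filled, c(one$cx_nm - 2000, one$cy_nm),
                       c(one$cx_nm + 2000, one$cy_nm), step_nm = 5)
  expect_lt(abs(fwhm(prof, polarity = "dip") / 2 - one$radius_nm), 29)
})

test_that("minimum projection of the slice stack recovers the 2D render", {
  sc <- small_scene(n = 5, seed = 6)
  p <- quiet_params()
  st <- render_sxt_stack(sc, p, n_slices = 3)
  expect_length(st$slices, 3)
  proj <- project_stack(st, "min")
  expect_equal(proj$pixels, render_sxt(sc, p)$pixels)
})

test_that("frc pair construction gives independent noise on a shared base", {
  base <- image_plane(matrix(0.5, 128, 128), 29)
  same <- make_frc_pair(base, 0, seed = 1)
  expect_identical(same[[1]]$pixels, same[[2]]$pixels)
  pair <- make_frc_pair(base, 0.2, seed = 3)
  d <- pair[[1]]$pixels - pair[[2]]$pixels
  expect_lt(abs(mean(d)), 0.01)
  expect_lt(abs(sd(d) - sqrt(2) * 0.2) / (sqrt(2) * 0.2), 0.05)
  pair2 <- make_frc_pair(base, 0.2, seed = 3)
  expect_identical(pair[[1]]$pixels, pair2[[1]]$pixels)
})

test_that("tilt planner returns inclusive arithmetic progressions", {
  expect_equal(plan_tilt_series(-60, 60, 60), c(-60, 0, 60))
  expect_equal(length(plan_tilt_series(-55.5, 54.5, 0.5)), 221)
  expect_error(plan_tilt_series(-60, 60, 7), class = "clxm_planning_error")
  expect_error(plan_tilt_series(60, -60, 1), class = "clxm_input_error")
})

test_that("ground-truth transforms respect their bounds", {
  for (s in 1:5) {
    gt <- sample_ground_truth(seed = s)
    p <- gt$affine$params
    expect_true(abs(p$tx_nm) <= 2000 && abs(p$ty_nm) <= 2000)
    expect_true(abs(p$theta_deg) <= 3)
    expect_true(p$sx >= 0.97 && p$sx <= 1.03 && p$sy >= 0.97 && p$sy <= 1.03)
    # warp capped at its nominal amplitude over the field
    grid <- as.matrix(expand.grid(x = seq(0, 30000, length.out = 25),
                                  y = seq(0, 30000, length.out = 25)))
    mags <- sqrt(rowSums(tps_displacement(gt$warp, grid)^2))
    expect_lte(max(mags), 150 * 1.05)  # calibrated on a finite grid
  }
  expect_null(sample_ground_truth(warp_amp_nm = 0, seed = 1)$warp)
})
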