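# Phase correlation, landmark matching, affine refinement, image warping,
# overlays, and the end-to-end registration contract.

test_that("phase correlation recovers translations on binary masks", {
  sc <- small_scene(n = 6, seed = 9, radius_range = c(300, 600))
  base <- segment_droplets(render_sxt(sc, quiet_params()), modality = "SXT")
  bin <- base$labels > 0
  # identical masks
  d0 <- coarse_align_pcc(bin, bin, pixel_size_nm = 29)
  expect_lt(max(abs(d0)), 0.5 * 29)
  # circular shift of (+5, -3) px at 29 nm => (145, -87) nm
  refm <- roll_mat(bin, -3, 5)
  d <- coarse_align_pcc(refm, bin, pixel_size_nm = 29)
  expect_lt(abs(d[1] - 145), 0.5 * 29)
  expect_lt(abs(d[2] + 87), 0.5 * 29)
  # two single-pixel masks: translation = p_ref - p_mov
  a <- matrix(0, 64, 64); b <- matrix(0, 64, 64)
  a[40, 50] <- 1; b[30, 20] <- 1
  d2 <- coarse_align_pcc(a, b, pixel_size_nm = 10)
  expect_lt(abs(d2[1] - 300), 5)   # dx = (50 - 20) px * 10 nm
  expect_lt(abs(d2[2] - 100), 5)   # dy = (40 - 30) px * 10 nm
  expect_error(coarse_align_pcc(matrix(0, 8, 8), b, pixel_size_nm = 10),
               class = "clxm_input_error")
})

test_that("mutual-nearest matching is one-to-one and gated", {
  set.seed(5)
  ref <- cbind(runif(10, 0, 20000), runif(10, 0, 20000))
  p0 <- match_pairs(ref, ref, gate_nm = 500)
  expect_equal(nrow(p0), 10)
  expect_equal(p0$distance_nm, rep(0, 10))
  expect_equal(p0$ref_index, p0$mov_index)
  # uniform offset within the gate pairs everything at that distance
  off <- match_pairs(ref, ref + 100 / sqrt(2), gate_nm = 500)
  expect_equal(nrow(off), 10)
  expect_equal(off$distance_nm, rep(100, 10), tolerance = 1e-9)
  # an extra point beyond the gate stays unmatched
  mov <- rbind(ref, c(50000, 50000))
  px <- match_pairs(ref, mov, gate_nm = 500)
  expect_equal(nrow(px), 10)
  expect_false(11 %in% px$mov_index)
  expect_true(!anyDuplicated(px$ref_index) && !anyDuplicated(px$mov_index))
})

test_that("affine refinement recovers exact parameters and rejects degenerate input", {
  set.seed(42)
  ref <- cbind(runif(12, 0, 30000), runif(12, 0, 30000))
  A <- affine_transform(tx_nm = 300, ty_nm = -150, theta_deg = 2,
                        sx = 1.02, sy = 0.98, centre_nm = colMeans(ref))
  mov <- apply_affine(invert_affine(A), ref)
  Ar <- refine_affine(ref, mov, init = c(0, 0))
  p <- Ar$params
  expect_lt(abs(p$tx_nm - 300) / 300, 1e-3)
  expect_lt(abs(p$ty_nm + 150) / 150, 1e-3)
  expect_lt(abs(p$theta_deg - 2) / 2, 1e-3)
  expect_lt(abs(p$sx - 1.02) / 1.02, 1e-3)
  expect_lt(abs(p$sy - 0.98) / 0.98, 1e-3)

  # identity when moving equals reference
  Ai <- refine_affine(ref, ref, init = c(0, 0))
  expect_lt(sqrt(Ai$params$tx_nm^2 + Ai$params$ty_nm^2), 1)
  expect_lt(abs(Ai$params$theta_deg), 0.01)
  expect_lt(max(abs(c(Ai$params$sx, Ai$params$sy) - 1)), 1e-4)

  expect_error(refine_affine(ref[1:2, ], mov[1:2, ]),
               class = "clxm_degenerate_geometry_error")
  coll <- cbind(seq(0, 11000, 1000), seq(0, 22000, 2000))
  expect_error(refine_affine(coll, coll),
               class = "clxm_degenerate_geometry_error")
})

test_that("refinement is equivariant under a common translation", {
  set.seed(8)
  ref <- cbind(runif(10, 2000, 28000), runif(10, 2000, 28000))
  A <- affine_transform(tx_nm = -400, ty_nm = 250, theta_deg = -1.5,
                        sx = 0.99, sy = 1.01, centre_nm = colMeans(ref))
  mov <- apply_affine(invert_affine(A), ref)
  A1 <- refine_affine(ref, mov, init = c(0, 0))
  d <- c(1234, -567)
  A2 <- refine_affine(ref + matrix(d, 10, 2, byrow = TRUE),
                      mov + matrix(d, 10, 2, byrow = TRUE), init = c(0, 0))
  probe <- cbind(runif(20, 0, 30000), runif(20, 0, 30000))
  lhs <- apply_affine(A2, probe + matrix(d, 20, 2, byrow = TRUE))
  rhs <- apply_affine(A1, probe) + matrix(d, 20, 2, byrow = TRUE)
  expect_lt(max(abs(lhs - rhs)), 1)
})

test_that("rescaling preserves field of view, intensities, and identity", {
  m <- matrix(runif(100 * 100), 100)
  img <- image_plane(m, 120, "FM")
  out <- rescale_to_reference(img, 29)
  expect_equal(dim(out$pixels), c(414L, 414L))  # 100 * 120/29, rounded
  expect_equal(out$pixel_size_nm, 29)
  # physical FOV preserved within one output pixel
  expect_lt(abs(413 * 29 - 99 * 120), 120)
  # intensity range is not renormalized
  expect_gte(min(out$pixels), min(m)); expect_lte(max(out$pixels), max(m))
  expect_identical(rescale_to_reference(img, 120)$pixels, m)
  const <- rescale_to_reference(image_plane(matrix(7, 50, 50), 120), 29)
  expect_true(all(const$pixels == 7))
})

test_that("images and points map through transforms consistently", {
  a <- affine_transform(tx_nm = 290, ty_nm = -145, theta_deg = 1,
                        sx = 1.01, sy = 0.99, centre_nm = c(750, 750))
  set.seed(3)
  pts <- centroid_set(cbind(runif(8, 0, 1500), runif(8, 0, 1500)))
  fwd <- apply_to_points(pts, a)
  back <- apply_to_points(fwd, invert_affine(a))
  expect_lt(max(abs(as_matrix_points(back) - as_matrix_points(pts))), 1e-6)

  # identity transform leaves an image unchanged
  m <- matrix(runif(64 * 64), 64)
  img <- image_plane(m, 29)
  ident <- apply_to_image(img, affine_transform())
  expect_equal(ident$pixels, m, tolerance = 1e-12)
  # a pure translation moves an impulse by the stated amount
  imp <- matrix(0, 64, 64); imp[20, 20] <- 1
  tr <- apply_to_image(image_plane(imp, 29),
                       affine_transform(tx_nm = 10 * 29, ty_nm = 5 * 29))
  peak <- arrayInd(which.max(tr$pixels), dim(tr$pixels))
  expect_equal(peak[1], 25L)  # y moved +5 px
  expect_equal(peak[2], 30L)  # x moved +10 px
})

test_that("overlay channels encode the two modalities and their coincidence", {
  ref <- image_plane(matrix(c(0, 1, 1, 1), 2, 2), 29)   # droplet = dark = col 1
  mov <- image_plane(matrix(c(0, 0, 1, 0), 2, 2), 29)   # blob = bright = [1,2]
  ov <- compose_overlay(ref, mov)
  expect_equal(dim(ov$rgb), c(2, 2, 3))
  expect_equal(ov$rgb[1, 1, ], c(1, 0, 0))  # X-ray only: pure red
  expect_equal(ov$rgb[2, 2, ], c(0, 0, 0))  # background
  expect_equal(ov$rgb[1, 2, ], c(0, 0, 1))  # fluorescence only: pure blue
  # identical normalized images render gray (R = G = B)
  g <- image_plane(matrix(runif(16), 4), 29)
  ginv <- image_plane(1 - (g$pixels - min(g$pixels)) / diff(range(g$pixels)), 29)
  ov2 <- compose_overlay(ginv, g)
  expect_equal(ov2$rgb[, , 1], ov2$rgb[, , 2], tolerance = 1 / 255)
  expect_equal(ov2$rgb[, , 1], ov2$rgb[, , 3], tolerance = 1 / 255)
  expect_error(compose_overlay(ref, image_plane(matrix(1, 3, 3), 29)),
               class = "clxm_input_error")
})

test_that("registering an image with itself is the identity", {
  sc <- small_scene(n = 5, seed = 12)
  sxt <- render_sxt(sc, render_params(seed = 12))
  res <- register_pair(sxt, sxt)
  p <- res$affine$params
  expect_lt(sqrt(p$tx_nm^2 + p$ty_nm^2), 1)
  expect_lt(abs(p$theta_deg), 0.01)
  expect_lt(max(abs(c(p$sx, p$sy) - 1)), 1e-4)
  expect_lt(max(res$pairs$distance_nm), 1e-6)
  expect_lt(max(res$residuals_after_nm), 1e-6)
})

test_that("the full pipeline aligns a synthetic pair below one SXT pixel", {
  pair <- simulate_pair(seed = 21, warp_amp_nm = 0, params = quiet_params())
  res <- register_pair(pair$sxt, pair$fm)
  expect_gte(nrow(res$pairs), 10)
  expect_lt(mean(res$pairs$distance_nm), 29)   # affine residual < 1 SXT px
  # with local distortion the warp nulls residuals at the controls
  pair2 <- simulate_pair(seed = 22)
  res2 <- register_pair(pair2$sxt, pair2$fm)
  expect_lt(max(res2$residuals_after_nm), 1e-6)
  # the refined cost never exceeds the coarse-only cost
  for (s in 23:25) {
    pp <- simulate_pair(seed = s)
    masks <- segment_pair(pp)
    pcc <- coarse_align_pcc(masks$ref, masks$mov)
    rc <- centroids(masks$ref); mc <- centroids(masks$mov)
    aff <- refine_affine(rc, mc, init = pcc)
    pcc_pairs <- match_pairs(rc, mc,
                             affine_transform(tx_nm = pcc[1], ty_nm = pcc[2]),
                             gate_nm = 2000)
    expect_lte(attr(aff, "cost"), mean(pcc_pairs$distance_nm^2))
  }
})
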