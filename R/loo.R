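# Leave-one-out registration accuracy protocol.
#
# Each landmark is removed from the *moving* binary mask only (the reference
# stays fixed as the coordinate frame), the registration - phase-correlation
# translation followed by cost-driven affine refinement - is recomputed from
# the edited masks, and the held-out landmark's centroid is mapped through
# the recomputed transform.  The prediction error is the Euclidean distance
# to its matched reference centroid.  The thin-plate warp stage is excluded:
# including it would interpolate the held-out point from its fold-mates and
# change the statistic.

#' Leave-one-out co-registration error analysis
#'
#' @param ref_mask reference `segmentation_mask` (kept fixed).
#' @param mov_mask moving `segmentation_mask` on the same pixel grid.
#' @param params a [register_params()] list (the matching gate and affine
#'   refinement options are honoured; the warp stage is not part of the
#'   protocol).
#' @return a `loo_report`: data.frame with one row per moving landmark
#'   (`id`, `pred_x_nm`, `pred_y_nm`, `meas_x_nm`, `meas_y_nm`, `error_nm`,
#'   `excluded`, `reason`) and attributes `mean_nm`, `std_nm`, `n`,
#'   `stages = "pcc+affine"`.
#' @export
loo_errors <- function(ref_mask, mov_mask, params = register_params()) {
  stopifnot(inherits(ref_mask, "segmentation_mask"),
            inherits(mov_mask, "segmentation_mask"))
  if (abs(ref_mask$pixel_size_nm - mov_mask$pixel_size_nm) > 1e-9)
    stop_clxm("clxm_input_error", "masks must share pixel size")
  n_mov <- nrow(mov_mask$stats)
  if (n_mov < 4L)
    stop_clxm("clxm_protocol_error",
              "leave-one-out needs at least 4 moving landmarks (got ",
              n_mov, ")")
  px <- ref_mask$pixel_size_nm
  ref_c <- centroids(ref_mask)
  mov_c <- centroids(mov_mask)

  # full registration fixes the landmark correspondence reused by all folds
  coarse0 <- coarse_align_pcc(ref_mask, mov_mask)
  aff0 <- refine_affine(ref_c, mov_c, init = coarse0,
                        opts = params$refine_opts)
  pairs0 <- match_pairs(ref_c, mov_c, aff0, gate_nm = params$gate_nm)
  match_of_mov <- integer(n_mov)
  match_of_mov[pairs0$mov_index] <- pairs0$ref_index

  # cache the reference-side FFT: every fold reuses it
  a_bin <- ref_mask$labels > 0L
  b_full <- mov_mask$labels
  nr <- good_fft_size(max(nrow(a_bin), nrow(b_full)))
  nc <- good_fft_size(max(ncol(a_bin), ncol(b_full)))
  Fa <- fft(pad_to(a_bin + 0, nr, nc))

  rp <- as_points(ref_c); mp <- as_points(mov_c)
  rows <- vector("list", n_mov)
  for (k in seq_len(n_mov)) {
    if (match_of_mov[k] == 0L) {
      rows[[k]] <- data.frame(id = k, pred_x_nm = NA_real_, pred_y_nm = NA_real_,
                              meas_x_nm = NA_real_, meas_y_nm = NA_real_,
                              error_nm = NA_real_, excluded = TRUE,
                              reason = "unmatched")
      next
    }
    meas <- rp[match_of_mov[k], ]
    fold <- tryCatch({
      b_k <- b_full > 0L & b_full != k
      d_px <- pcc_core(Fa, fft(pad_to(b_k + 0, nr, nc)))
      init_k <- c(d_px["dx"], d_px["dy"]) * px
      aff_k <- refine_affine(rp, mp[-k, , drop = FALSE], init = init_k,
                             opts = params$refine_opts)
      pred <- apply_affine(aff_k, mp[k, , drop = FALSE])
      data.frame(id = k, pred_x_nm = pred[1, 1], pred_y_nm = pred[1, 2],
                 meas_x_nm = meas[1], meas_y_nm = meas[2],
                 error_nm = sqrt(sum((pred[1, ] - meas)^2)),
                 excluded = FALSE, reason = NA_character_)
    }, clxm_error = function(e) {
      data.frame(id = k, pred_x_nm = NA_real_, pred_y_nm = NA_real_,
                 meas_x_nm = meas[1], meas_y_nm = meas[2],
                 error_nm = NA_real_, excluded = TRUE,
                 reason = conditionMessage(e))
    })
    rows[[k]] <- fold
  }
  report <- do.call(rbind, rows)
  used <- report$error_nm[!report$excluded]
  if (length(used) == 0)
    stop_clxm("clxm_protocol_error", "all leave-one-out folds were excluded")
  structure(report,
            mean_nm = mean(used),
            std_nm = if (length(used) > 1) stats::sd(used) else 0,
            single_fold = length(used) == 1L,
            n = length(used), stages = "pcc+affine",
            class = c("loo_report", "data.frame"))
}

#' Summarize a leave-one-out report
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' non-excluded fold errors; a single usable fold reports `std_nm = 0` with
#' the `single_fold` flag set.
#'
#' @param report a `loo_report` from [loo_errors()].
#' @return list with `mean_nm`, `std_nm`, `n`, `single_fold`.
#' @export
summarize_loo <- function(report) {
  stopifnot(inherits(report, "loo_report"))
  used <- report$error_nm[!report$excluded]
  if (length(used) == 0)
    stop_clxm("clxm_protocol_error", "no usable folds to summarize")
  list(mean_nm = mean(used),
       std_nm = if (length(used) > 1) stats::sd(used) else 0,
       n = length(used), single_fold = length(used) == 1L)
}

#' @export
print.loo_report <- function(x, ...) {
  s <- summarize_loo(x)
  cat(sprintf("<loo_report> %d folds (%d excluded): mean %.1f +/- %.1f nm\n",
              nrow(x), sum(x$excluded), s$mean_nm, s$std_nm))
  invisible(x)
}
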