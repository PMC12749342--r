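# Thin-plate-spline (radial basis function) warping with kernel
# U(r) = r^2 log r.  Used twice: to synthesize smooth ground-truth
# distortions, and as the final non-rigid correction stage mapping
# affine-transformed moving landmarks onto their reference partners.

#' @noRd
tps_kernel <- function(r2) {
  # U(r) = r^2 log(r) = r2 * log(r2) / 2, with U(0) = 0
  out <- r2 * log(pmax(r2, .Machine$double.xmin)) / 2
  out[r2 == 0] <- 0
  out
}

#' Fit a thin-plate spline to point displacements
#'
#' With `lambda = 0` the spline interpolates the control displacements
#' exactly; `lambda > 0` trades exactness for smoothness (and regularizes
#' degenerate control geometry).  With fewer than 3 control points the model
#' degenerates to its affine part: a pure translation by the mean
#' displacement.
#'
#' @param ctrl n x 2 matrix of control-point positions `(x, y)` in nm.
#' @param disp n x 2 matrix of displacements at the controls (nm).
#' @param lambda regularization (>= 0); in squared-nm kernel units.
#' @return an object of class `tps_warp`.
#' @export
tps_fit <- function(ctrl, disp, lambda = 0) {
  ctrl <- rbind(ctrl); disp <- rbind(disp)
  stopifnot(nrow(ctrl) == nrow(disp), lambda >= 0)
  n <- nrow(ctrl)
  if (n < 3L) {
    a <- rbind(colMeans(disp), c(0, 0), c(0, 0))
    return(structure(list(ctrl = ctrl, w = matrix(0, n, 2), a = a,
                          scale = 1, lambda = lambda), class = "tps_warp"))
  }
  # solve in scaled coordinates: the interpolant is scale-invariant, the
  # linear system is not (nm-scale kernel entries reach ~1e9 and swamp the
  # polynomial block)
  sc <- max(stats::sd(ctrl[, 1]), stats::sd(ctrl[, 2]), 1)
  cs <- ctrl / sc
  d2 <- outer(cs[, 1], cs[, 1], "-")^2 + outer(cs[, 2], cs[, 2], "-")^2
  K <- tps_kernel(d2) + diag(lambda, n)
  P <- cbind(1, cs)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(disp, matrix(0, 3, 2))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop_clxm("clxm_conditioning_error",
              "thin-plate system is singular (collinear control points?); ",
              "use lambda > 0"))
  structure(list(ctrl = ctrl, w = sol[seq_len(n), , drop = FALSE],
                 a = sol[n + 1:3, , drop = FALSE], scale = sc,
                 lambda = lambda), class = "tps_warp")
}

#' @rdname tps_fit
#' @param w a `tps_warp`.
#' @param pts m x 2 matrix of query positions (nm).
#' @return `tps_displacement`: m x 2 matrix of displacements (nm).
#' @export
tps_displacement <- function(w, pts) {
  pts <- rbind(pts)
  sc <- w$scale %||% 1
  ps <- pts / sc
  out <- cbind(w$a[1, 1] + ps[, 1] * w$a[2, 1] + ps[, 2] * w$a[3, 1],
               w$a[1, 2] + ps[, 1] * w$a[2, 2] + ps[, 2] * w$a[3, 2])
  if (nrow(w$ctrl) > 0 && any(w$w != 0)) {
    cs <- w$ctrl / sc
    d2 <- outer(ps[, 1], cs[, 1], "-")^2 +
          outer(ps[, 2], cs[, 2], "-")^2
    U <- tps_kernel(d2)
    out <- out + U %*% w$w
  }
  colnames(out) <- c("dx_nm", "dy_nm")
  out
}

#' Fit the non-rigid residual warp of a registration
#'
#' Controls sit at the affine-transformed moving landmarks; target
#' displacements carry them exactly onto their matched reference landmarks
#' (when `lambda = 0`).
#'
#' @param pairs a `matched_pairs` data.frame from [match_pairs()].
#' @param ref reference landmarks (`centroid_set` or n x 2 matrix, nm).
#' @param mov_transformed affine-transformed moving landmarks (same form).
#' @param lambda thin-plate regularization (default 0 = exact interpolation).
#' @return a `tps_warp` modelling residual displacements.
#' @export
fit_warp <- function(pairs, ref, mov_transformed, lambda = 0) {
  rp <- as_points(ref); mp <- as_points(mov_transformed)
  if (nrow(pairs) < 3L)
    stop_clxm("clxm_degenerate_geometry_error",
              "need at least 3 matched pairs to fit a warp")
  ctrl <- mp[pairs$mov_index, , drop = FALSE]
  disp <- rp[pairs$ref_index, , drop = FALSE] - ctrl
  tps_fit(ctrl, disp, lambda = lambda)
}

#' @export
print.tps_warp <- function(x, ...) {
  cat(sprintf("<tps_warp> %d control points, lambda = %g, max |w| = %g\n",
              nrow(x$ctrl), x$lambda, if (length(x$w)) max(abs(x$w)) else 0))
  invisible(x)
}
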