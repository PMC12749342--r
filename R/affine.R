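#' 2D affine transforms for landmark registration
#'
#' The registration estimate is a similarity-type affine with anisotropic
#' scaling: in physical (nm) coordinates,
#' \deqn{p' = R(\theta)\,S(s_x, s_y)\,(p - c) + c + t}
#' mapping the *moving* modality onto the *reference* one.  The object always
#' carries the exact linear form `(M, b)` with `p' = M p + b`; the named
#' parameters are retained when the transform was built from them (derived
#' transforms such as inverses carry `params = NULL`, since the anisotropic
#' family is not closed under inversion).
#'
#' @param tx_nm,ty_nm translation in nm.
#' @param theta_deg rotation in degrees (counter-clockwise in (x, y)).
#' @param sx,sy anisotropic scale factors (> 0).
#' @param centre_nm length-2 rotation/scale pivot `(x, y)` in nm.
#' @return an object of class `affine2d`.
#' @examples
#' a <- affine_transform(tx_nm = 300, theta_deg = 2, sx = 1.02)
#' p <- matrix(c(1000, 2000), 1)
#' apply_affine(invert_affine(a), apply_affine(a, p))  # round-trips to p
#' @export
affine_transform <- function(tx_nm = 0, ty_nm = 0, theta_deg = 0,
                             sx = 1, sy = 1, centre_nm = c(0, 0)) {
  if (sx <= 0 || sy <= 0)
    stop_clxm("clxm_input_error", "scale factors must be positive")
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  M <- R %*% diag(c(sx, sy))
  b <- as.numeric(centre_nm + c(tx_nm, ty_nm) - M %*% centre_nm)
  new_affine(M, b, params = list(
    tx_nm = tx_nm, ty_nm = ty_nm, theta_deg = theta_deg,
    sx = sx, sy = sy, centre_nm = as.numeric(centre_nm)))
}

#' @noRd
new_affine <- function(M, b, params = NULL) {
  if (abs(det(M)) < 1e-15)
    stop_clxm("clxm_input_error", "affine transform is not invertible")
  structure(list(M = M, b = as.numeric(b), params = params,
                 convention = COORD_CONVENTION),
            class = "affine2d")
}

#' @rdname affine_transform
#' @param a,a1,a2 `affine2d` objects.
#' @param pts n x 2 matrix of `(x, y)` points in nm.
#' @export
apply_affine <- function(a, pts) {
  pts <- rbind(pts)  # accept a bare length-2 vector
  out <- t(a$M %*% t(pts)) + matrix(a$b, nrow(pts), 2, byrow = TRUE)
  colnames(out) <- c("x_nm", "y_nm")
  out
}

#' @rdname affine_transform
#' @export
invert_affine <- function(a) {
  Mi <- solve(a$M)
  new_affine(Mi, -Mi %*% a$b)
}

#' @rdname affine_transform
#' @description `compose_affine(a2, a1)` returns the transform applying `a1`
#'   first, then `a2`.
#' @export
compose_affine <- function(a2, a1) {
  new_affine(a2$M %*% a1$M, a2$M %*% a1$b + a2$b)
}

#' @export
print.affine2d <- function(x, ...) {
  if (!is.null(x$params)) {
    p <- x$params
    cat(sprintf("<affine2d> t = (%.3g, %.3g) nm, theta = %.4g deg, s = (%.5g, %.5g), centre = (%.4g, %.4g) nm\n",
                p$tx_nm, p$ty_nm, p$theta_deg, p$sx, p$sy,
                p$centre_nm[1], p$centre_nm[2]))
  } else {
    cat("<affine2d> (matrix form)\n")
    print(cbind(x$M, b = x$b))
  }
  invisible(x)
}
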