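#' Sample an intensity profile along a line segment
#'
#' Bilinear sampling at uniform steps from `p0_nm` to `p1_nm` (pixel-centre
#' convention, physical nm coordinates).
#'
#' @param img an [image_plane()].
#' @param p0_nm,p1_nm numeric length-2 segment endpoints `(x, y)` in nm.
#' @param step_nm sampling step (> 0).
#' @return a `line_profile`: data.frame with `position_nm` (distance along
#'   the segment) and `intensity`, plus a `step_nm` attribute.
#' @export
line_profile <- function(img, p0_nm, p1_nm, step_nm) {
  stopifnot(inherits(img, "image_plane"), step_nm > 0)
  px <- img$pixel_size_nm
  lim_x <- (ncol(img$pixels) - 1) * px
  lim_y <- (nrow(img$pixels) - 1) * px
  for (p in list(p0_nm, p1_nm))
    if (p[1] < 0 || p[1] > lim_x || p[2] < 0 || p[2] > lim_y)
      stop_clxm("clxm_input_error", "profile endpoints must lie inside the image")
  len <- sqrt(sum((p1_nm - p0_nm)^2))
  pos <- seq(0, len, by = step_nm)
  u <- if (len > 0) (p1_nm - p0_nm) / len else c(0, 0)
  xs <- p0_nm[1] + pos * u[1]
  ys <- p0_nm[2] + pos * u[2]
  vals <- bilinear_sample(img$pixels, ys / px, xs / px)
  structure(data.frame(position_nm = pos, intensity = vals),
            step_nm = step_nm, class = c("line_profile", "data.frame"))
}

#' Full width at half maximum of a line profile
#'
#' The baseline is the median of the two profile end regions (10% of the
#' samples at each end); the extremum is the maximum (`"peak"`), minimum
#' (`"dip"`), or whichever lies farther from the baseline (`"auto"`).
#' Half-maximum crossings flanking the extremum are located by linear
#' interpolation and the width is their separation.
#'
#' @param profile a `line_profile` from [line_profile()].
#' @param polarity `"peak"`, `"dip"` or `"auto"`.
#' @return width in nm.
#' @export
fwhm <- function(profile, polarity = c("auto", "peak", "dip")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(profile, "line_profile"))
  v <- profile$intensity; x <- profile$position_nm
  n <- length(v)
  if (n < 5)
    stop_clxm("clxm_input_error", "profile too short for a FWHM estimate")
  m <- max(2L, ceiling(0.1 * n))
  baseline <- stats::median(c(v[seq_len(m)], v[(n - m + 1):n]))
  if (polarity == "auto")
    polarity <- if (abs(max(v) - baseline) >= abs(min(v) - baseline))
      "peak" else "dip"
  s <- if (polarity == "peak") v else -v
  base_s <- if (polarity == "peak") baseline else -baseline
  i0 <- which.max(s)
  half <- (s[i0] + base_s) / 2
  cross <- function(idx_range, rising) {
    # first crossing of `half` walking away from the extremum
    for (i in idx_range) {
      a <- s[i]; b <- s[i + 1]
      if ((a >= half && b < half) || (a < half && b >= half)) {
        t <- (half - a) / (b - a)
        return(x[i] + t * (x[i + 1] - x[i]))
      }
    }
    NA_real_
  }
  left <- if (i0 > 1) cross(rev(seq_len(i0 - 1)), TRUE) else NA_real_
  right <- if (i0 < n) cross(i0:(n - 1), FALSE) else NA_real_
  if (is.na(left) || is.na(right))
    stop_clxm("clxm_fwhm_undefined_error",
              "no half-maximum crossing on ",
              if (is.na(left) && is.na(right)) "either side"
              else if (is.na(left)) "the left side" else "the right side",
              " of the extremum")
  right - left
}
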