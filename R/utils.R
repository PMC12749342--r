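# Shared helpers: coordinate convention, bilinear sampling, seeding.
#
# Global coordinate convention (asserted in every transform JSON):
#   0-based indices; position (x, y) with x = column index, y = row index;
#   physical coordinate nm = index * pixel_size_nm, measured at pixel centres;
#   origin at the centre of pixel (0, 0).
COORD_CONVENTION <- "xy=(col,row); 0-based; nm = index * pixel_size_nm; origin at centre of pixel (0,0); affine p' = R(theta) S (p - c) + c + t maps moving -> reference"

#' @noRd
stop_clxm <- function(class, ...) {
  stop(structure(
    class = c(class, "clxm_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Derive a reproducible child seed from a parent seed and a stage label
#'
#' One global seed fans out to per-stage seeds by a fixed arithmetic
#' derivation, so each pipeline stage is independently reproducible.
#' The result is always a valid 32-bit R integer seed.
#'
#' @param seed integer parent seed.
#' @param label character stage label.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 69069 + h) %% (2^31 - 1))
}

#' Bilinear sampling of a matrix at fractional (row, col) positions
#'
#' Positions are 0-based pixel indices (pixel-centre convention).  Samples
#' outside the grid are clamped to the border.
#'
#' @param m numeric matrix.
#' @param row0,col0 numeric vectors of 0-based fractional indices.
#' @return numeric vector of sampled intensities.
#' @keywords internal
bilinear_sample <- function(m, row0, col0) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(row0, 0), nr - 1)
  c <- pmin(pmax(col0, 0), nc - 1)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- m[cbind(r0 + 1, c0 + 1)]
  i01 <- m[cbind(r0 + 1, c1 + 1)]
  i10 <- m[cbind(r1 + 1, c0 + 1)]
  i11 <- m[cbind(r1 + 1, c1 + 1)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}

#' Min-max normalize a matrix to the unit interval
#'
#' A constant matrix maps to all zeros (the range is degenerate).
#' @noRd
norm01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

# Matrix <-> EBImage orientation shim.  Package matrices are [row(y), col(x)];
# EBImage images are [x, y], so both directions are a transpose.
#' @noRd
as_eb <- function(m) EBImage::Image(t(m))
#' @noRd
from_eb <- function(im) t(EBImage::imageData(im))
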