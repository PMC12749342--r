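# Lipid-droplet segmentation: global Otsu threshold on the preprocessed
# image, light morphological cleanup, hole filling (ring-like SXT droplets
# become solid before centroiding), and a size filter on the equivalent
# radius.  Connected components are the landmarks of the registration.

#' Segment lipid droplets and extract landmark statistics
#'
#' @param img an [image_plane()].
#' @param modality `"FM"` (bright droplets) or `"SXT"` (dark droplets);
#'   governs the default polarity.
#' @param p a [preprocess_params()] list applied before thresholding.
#' @param min_radius_nm,max_radius_nm equivalent-radius bounds; components
#'   outside the range are removed (droplet radii span a few hundred nm up
#'   to a micron, so the defaults add margin on both sides).
#' @param polarity `"bright"`, `"dark"`, or `"auto"` (chooses the Otsu class
#'   whose mean lies farther from the image median).
#' @param exclude_border drop components touching the image border
#'   (default `TRUE`: truncated droplets have biased centres of mass and
#'   resampling/equalization edge artifacts cluster there).
#' @param max_fg_fraction largest plausible foreground area fraction;
#'   a global Otsu split assigning more than this to the foreground is
#'   re-thresholded within its upper class (hierarchical Otsu), which keeps
#'   sparse-landmark segmentation stable when local equalization has
#'   stretched empty background tiles.
#' @return a `segmentation_mask`: list with `labels` (integer matrix, 0 =
#'   background), `pixel_size_nm`, `modality`, and `stats` (data.frame:
#'   `id`, `area_px`, `cx_px`, `cy_px`, `eq_radius_nm`).
#' @export
segment_droplets <- function(img, modality = img$modality,
                             p = preprocess_params(),
                             min_radius_nm = 150, max_radius_nm = 1500,
                             polarity = c("auto", "bright", "dark"),
                             exclude_border = TRUE, max_fg_fraction = 0.25) {
  polarity <- match.arg(polarity)
  stopifnot(min_radius_nm > 0, max_radius_nm > min_radius_nm)
  pre <- preprocess(img, p)
  m <- pre$pixels
  if (diff(range(m)) <= 0)
    stop_clxm("clxm_degenerate_input_error",
              "image is constant; Otsu threshold is undefined")
  if (polarity == "auto") {
    if (modality == "FM") polarity <- "bright"
    else if (modality == "SXT") polarity <- "dark"
    else {
      th0 <- EBImage::otsu(as_eb(m), range = c(0, 1))
      med <- stats::median(m)
      polarity <- if (abs(mean(m[m > th0]) - med) >=
                      abs(mean(m[m <= th0]) - med)) "bright" else "dark"
    }
  }
  if (polarity == "dark") m <- 1 - m
  # hierarchical Otsu: droplets are sparse, and local equalization stretches
  # empty background tiles across the full range, which can pull the global
  # threshold into the noise mode.  If the foreground class is implausibly
  # large for landmark segmentation, re-threshold within the upper class.
  th <- EBImage::otsu(as_eb(m), range = c(0, 1))
  for (pass in 1:4) {
    if (mean(m > th) <= max_fg_fraction) break
    th <- EBImage::otsu(EBImage::Image(matrix(m[m > th], nrow = 1)),
                        range = c(0, 1))
  }
  bin <- as_eb(m > th)
  bin <- EBImage::opening(bin, EBImage::makeBrush(3, shape = "disc"))
  bin <- EBImage::fillHull(bin)
  labels_eb <- EBImage::bwlabel(bin)
  labels <- from_eb(labels_eb)
  storage.mode(labels) <- "integer"
  mask_from_labels(labels, img$pixel_size_nm, modality,
                   min_radius_nm, max_radius_nm, polarity, exclude_border)
}

# Build a segmentation_mask from a label matrix, applying the size filter
# and recomputing all per-component stats.
#' @noRd
mask_from_labels <- function(labels, pixel_size_nm, modality,
                             min_radius_nm = 0, max_radius_nm = Inf,
                             polarity = NA_character_,
                             exclude_border = FALSE) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids)) {
    area <- tabulate(labels, nbins = max(ids))[ids]
    eq_r <- sqrt(area / pi) * pixel_size_nm
    keep <- ids[eq_r >= min_radius_nm & eq_r <= max_radius_nm]
    if (exclude_border && length(keep)) {
      on_border <- unique(c(labels[1, ], labels[nrow(labels), ],
                            labels[, 1], labels[, ncol(labels)]))
      keep <- setdiff(keep, on_border)
    }
  } else keep <- integer(0)
  new_labels <- matrix(0L, nrow(labels), ncol(labels))
  stats_df <- data.frame(id = integer(0), area_px = numeric(0),
                         cx_px = numeric(0), cy_px = numeric(0),
                         eq_radius_nm = numeric(0))
  for (k in seq_along(keep)) {
    idx <- which(labels == keep[k], arr.ind = TRUE)
    new_labels[idx] <- k
    stats_df[k, ] <- list(k, nrow(idx),
                          mean(idx[, 2] - 1),   # x = 0-based column
                          mean(idx[, 1] - 1),   # y = 0-based row
                          sqrt(nrow(idx) / pi) * pixel_size_nm)
  }
  structure(list(labels = new_labels, pixel_size_nm = pixel_size_nm,
                 modality = modality, polarity = polarity, stats = stats_df),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d x %d px, %.4g nm/px, %d components (%s)\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_nm,
              nrow(x$stats), x$modality))
  invisible(x)
}

#' Landmark centroids of a segmentation
#'
#' One intensity-unweighted centre of mass per connected component,
#' converted to physical nm via the pixel size, in component-id order.
#'
#' @param mask a `segmentation_mask`.
#' @return a `centroid_set`: data.frame with `x_nm`, `y_nm` and attributes
#'   `modality` and `provenance`.
#' @export
centroids <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  centroid_set(cbind(mask$stats$cx_px, mask$stats$cy_px) * mask$pixel_size_nm,
               modality = mask$modality, provenance = "segmentation")
}

#' @rdname centroids
#' @param points n x 2 matrix or data.frame of `(x_nm, y_nm)` positions.
#' @param modality,provenance metadata tags.
#' @export
centroid_set <- function(points, modality = "OTHER", provenance = NA_character_) {
  points <- rbind(as.matrix(points))
  if (nrow(points) > 0 && !all(is.finite(points)))
    stop_clxm("clxm_input_error", "centroid coordinates must be finite")
  df <- data.frame(x_nm = points[, 1], y_nm = points[, 2])
  structure(df, modality = modality, provenance = provenance,
            class = c("centroid_set", "data.frame"))
}

#' @noRd
as_points <- function(x) {
  if (inherits(x, "centroid_set") || is.data.frame(x))
    return(cbind(x_nm = x$x_nm, y_nm = x$y_nm))
  m <- rbind(as.matrix(x))
  colnames(m) <- c("x_nm", "y_nm")
  m
}
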