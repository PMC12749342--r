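---
title: "Lipid-droplet landmark registration for correlative cryo-FM / soft X-ray microscopy"
author: "clxmreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipid-droplet landmark registration for correlative cryo-FM / soft X-ray microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Correlative light and X-ray microscopy (CLXM) pairs an epifluorescence (FM)
image, which carries molecular identity at roughly 120 nm/px sampling, with a
soft X-ray tomography (SXT) dataset, which carries label-free 3D
ultrastructure at roughly 29 nm/px. Before the two can be interpreted
together they must share one coordinate frame. Externally added fiducial
beads are the classical solution, but they stick to membranes and sample the
field unevenly. Lipid droplets make excellent *endogenous* fiducials: they
are carbon-dense, so they absorb strongly in the water window and appear as
dark, often ring-like bodies in SXT, and they take up BODIPY-class dyes, so
they appear as bright blobs in FM. They are also distributed throughout the
cytoplasm rather than clinging to the cell surface.

`clxmreg` implements a fiducial-free registration pipeline built on these
droplets, the leave-one-out (LOO) protocol used to quantify its accuracy,
the Fourier-ring-correlation (FRC) and FWHM resolution metrics used to
characterize the imaging itself, and a synthetic correlative-scene generator
that makes the entire chain testable without instrument data.

## The pipeline

`register_pair(ref_img, mov_img)` runs five stages; every intermediate is
kept in the returned `registration_result`.

1. **Rescale.** The FM image is resampled by bilinear interpolation onto the
   SXT pixel pitch, preserving the physical field of view. SXT is the fixed
   reference: it is the higher-resolution modality, and keeping it fixed
   avoids resampling it. (Whether the instrument software warps the X-ray or
   the fluorescence image for display is a presentation choice; both
   directions are available here through `apply_to_image`.)
2. **Preprocess and segment.** Both images pass through Gaussian smoothing
   (noise suppression) and contrast-limited adaptive histogram equalization
   (CLAHE; local contrast, so faint droplets survive a global threshold),
   then a global Otsu threshold, a morphological opening with a 1 px disc,
   hole filling (ring-like SXT droplets become solid discs), and an
   equivalent-radius size filter of 150-1500 nm. Centroids of the surviving
   components, converted to physical nm, are the landmarks.
3. **Coarse translation.** Phase cross-correlation (PCC) of the two *binary
   masks* — the modalities have unrelated intensity contrast, the masks do
   not. The correlation peak is refined to subpixel precision by a quadratic
   fit on its 3 x 3 neighbourhood.
4. **Affine refinement.** An ICP-style loop: mutual-nearest-neighbour
   matching within a gate, then a Nelder-Mead simplex minimizing the mean
   squared matched-centroid distance over translation, rotation and
   anisotropic scales `(tx, ty, theta, sx, sy)`, re-matching after each
   round. The convention is `p' = R(theta) S(sx, sy) (p - c) + c + t` with
   the pivot `c` at the reference landmark centroid.
5. **Thin-plate-spline warp.** Residual displacements at the matched
   landmarks are interpolated by a thin-plate spline (kernel
   `U(r) = r^2 log r`, `lambda = 0` by default, i.e. exact interpolation at
   the controls). This absorbs the smooth, low-magnitude distortions left
   over after the affine stage — for instance the slight lensing that the
   dome shape of a plunge-frozen cell imposes on the visible-light path.

`loo_errors()` implements the accuracy protocol: each moving-side landmark
is erased *from the moving binary mask only*, PCC + affine refinement are
recomputed from the edited masks (the reference stays fixed as the
coordinate frame), the held-out centroid is mapped through the recomputed
transform, and its Euclidean distance to the matched reference centroid is
one fold's error. The warp stage is deliberately excluded from the LOO
transform: a spline that interpolates the held-out point from its fold
mates would leak information into the statistic. The fixed landmark
correspondence is established once, before any fold, so folds cannot
relabel pairs.

```{r example}
library(clxmreg)
pair <- simulate_pair(seed = 1)                    # synthetic FM/SXT pair
res  <- register_pair(pair$sxt, pair$fm)           # full pipeline
fm_mask  <- res$mov_mask; sxt_mask <- res$ref_mask
loo  <- loo_errors(sxt_mask, fm_mask)              # accuracy protocol
summarize_loo(loo)
```

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `gaussian_sigma_px` | 2 | px | pre-threshold noise suppression |
| `clahe_clip_limit`, `clahe_tile_px` | 2, 64 | -, px | local contrast enhancement |
| `min_radius_nm`, `max_radius_nm` | 150, 1500 | nm | droplet size gate (radii run from a few hundred nm to a micron; margin on both sides) |
| `max_fg_fraction` | 0.25 | - | hierarchical-Otsu guard (below) |
| `gate_init_nm` / `gate_floor_nm` | 2000 / 300 | nm | match gate, shrinking to 3x the running RMS |
| `scale_bounds`, `theta_bound_deg` | 0.8-1.25, 15 | -, deg | refinement box constraints |
| `lambda` | 0 | kernel units | TPS regularization (0 = exact) |
| `fm_pixel_nm` / `sxt_pixel_nm` | 120 / 29 | nm/px | modality sampling |
| `fm_psf_sigma_nm` | 250 | nm | FM point-spread sigma |

CLAHE parameters follow the semantics of the underlying EBImage
implementation (a multiplicative contrast limit, 2 by default, on 64 px
tiles); they were chosen so that a flat field stays flat while 200 nm
droplets, whose PSF-diluted peaks carry only ~25% of the full blob
amplitude, still clear the global threshold.

## Numerical and design choices

* **Coordinate convention.** 0-based indices, `(x, y)` = (column, row),
  physical nm = index x pixel size, measured at pixel centres. The
  convention string is embedded in every transform JSON.
* **Hierarchical Otsu.** Landmarks are sparse (a percent or two of the
  field), and CLAHE stretches droplet-free background tiles across the full
  intensity range. When that pulls the global Otsu threshold into the noise
  mode, the foreground class becomes implausibly large; if it exceeds
  `max_fg_fraction` the threshold is recomputed within the upper class
  (up to four passes). Dense, well-behaved images never trigger the guard.
* **Filtered phase correlation.** A fully whitened cross-power spectrum
  weights all frequencies equally, but for masks made of a dozen blobs the
  phase beyond the blob scale is noise. A Gaussian low-pass (5 px in real
  space) on the whitened spectrum removes intermittent spurious peaks
  without degrading the subpixel estimate.
* **Border components are dropped.** A droplet truncated by the field edge
  has a biased centre of mass, and resampling/equalization artifacts
  concentrate at borders; both make poor landmarks.
* **TPS conditioning.** The spline system is solved in coordinates scaled
  by the control-point spread; at nm scale the kernel entries reach 1e9 and
  swamp the polynomial block. The interpolant itself is scale-invariant.
  Exactly collinear controls leave the polynomial block rank-deficient —
  that is a hard error for any `lambda`; near-collinear geometries are
  rescued by `lambda > 0`.
* **Anisotropic-affine family.** `R(theta) S(sx, sy)` is not closed under
  inversion when `sx != sy`; transforms therefore always carry their exact
  matrix form, and derived transforms (inverses, compositions) drop the
  named-parameter view rather than approximate it.
* **Warp inversion.** Image resampling pulls reference-grid positions back
  through the transform; the warp is inverted to first order (subtract the
  forward displacement), which for the <= 150 nm smooth distortions it
  models is accurate to well below a pixel.
* **FRC conventions.** Images are mean-subtracted, Hann-windowed by default
  (edge leakage), zero-padded to a common square; rings are one frequency
  bin wide; the numerator takes the real part of the cross-spectrum; the DC
  ring is excluded from the crossing search. The resolution is read at the
  fixed 0.25 threshold — the convention used for comparability with
  published synchrotron optical characterisation, not the half-bit curve —
  and reported as full pitch (1/frequency). Mean subtraction before
  windowing is what makes the curve exactly invariant to a common affine
  intensity rescaling of both inputs.
* **FWHM baseline.** Median of the two profile end regions (10% of samples
  each); the extremum polarity is explicit or chosen as the side farther
  from the baseline; half-maximum crossings are located by linear
  interpolation.

## The synthetic generator

`simulate_pair()` encodes the study conditions used throughout the tests:
15 droplets with radii 200-1000 nm in a 30 x 30 um field with centre
separations of at least 2 um; FM rendered at 120 nm/px through a 250 nm
Gaussian PSF; SXT rendered at 29 nm/px with ring-like absorption (dark rim,
brighter core) on a 0.9 background; a ground-truth affine with |t| <= 2 um,
|theta| <= 3 degrees and scales in 0.97-1.03; a thin-plate local distortion
field capped at 150 nm; additive Gaussian noise sized so the faintest
droplet keeps a contrast-to-noise ratio near 5. Discs are drawn on a 4x
supersampled grid and box-averaged down, so rendered centroids agree with
the analytic positions to well under a pixel.

Two generator constraints are deliberate additions to the stated geometry:
droplets are solid organelles, so sampling enforces a 600 nm
surface-to-surface gap (interpenetrating discs would merge under the FM PSF
and could never segment to the generated count), and droplets keep a 1 um
margin to the field border so the blurred blob stays interior. Centre
separations still respect the 2 um minimum.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate on real data: cytoplasmic background structure and other
carbon-dense organelles that compete with droplets in SXT; non-spherical
and clustered droplets; detector artifacts and illumination gradients;
tilt-series geometry, reconstruction artifacts and the missing wedge
(registration here operates on 2D projections, where these effects are
known to be mild); chromatic or field-dependent optical aberrations beyond
a smooth thin-plate field.

## Problem sizes

The test suite and the acceptance script run the full pipeline on
1034 x 1034 px SXT frames (30 um at 29 nm/px) with 250 x 250 px FM frames,
ten generator seeds for the pooled leave-one-out statistic, and twenty
seeds for affine parameter recovery; FRC properties use 128 x 128
constructions. These sizes were chosen so each property is exercised at
realistic sampling while a complete run stays in the minutes range on one
CPU.

## Limitations

* Landmark-based: cells without segmentable lipid droplets (or with heavy
  droplet clustering) defeat the approach, as the source imaging studies
  note when discussing morphological variability across cell types.
* The LOO statistic quantifies *landmark* consistency; between landmarks
  the warp is an interpolation whose error is unobserved.
* PCC assumes the overlap of the two fields dominates the masks; a moving
  image showing mostly structure absent from the reference will defeat the
  coarse stage before refinement can help.
* 2D only: the SXT stack is collapsed by minimum-intensity projection
  before registration, mirroring the missing 3D information in wide-field
  FM.
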