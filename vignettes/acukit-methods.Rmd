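---
title: "Methods: marker removal, keypoint metrics and 3-D localization for back-acupoint datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker removal, keypoint metrics and 3-D localization for back-acupoint datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acukit)
```

## The problem acukit addresses

Building a supervised dataset for locating therapeutic acupoints on the
human back runs into a chicken-and-egg problem: the back has few visual
landmarks, so ground truth must come from experts palpating the subject
and sticking small round adhesive labels on the skin. Photographs of the
labeled back give precise point annotations (each label center is clicked
once in an annotation tool), but the labels themselves must then be erased
from the images — otherwise a detector simply learns to find stickers.
acukit implements this indirect annotation workflow and everything needed
to evaluate it:

1. **De-labeling** by exemplar-based inpainting (`inpaint_image()`), with
   a classical product-priority baseline and an exponential-priority
   variant with elliptic local search.
2. **Restoration quality** (PSNR/SSIM, `psnr3()`, `ssim_global()`) and
   **processing efficiency** (`per_marker_time()`, `efficiency_gain()`).
3. **Keypoint accuracy**: per-image mean pixel error (`ape_image()`), its
   millimeter conversion (`apde()`), effective-region hit classification
   (`classify_hits()`) and mean per-image recall (`kp_recall()`).
4. **Keypoint-consistent augmentation**: scale, crop, horizontal flip
   with anatomical left/right label swapping (`aug_*`, `augment_random()`).
5. A **SimCC coordinate codec** and a pluggable **two-stage harness**
   (region detector, then keypoint localizer on the cropped region,
   `run_pipeline()`).
6. The **pixel-to-robot-base chain**: depth/color registration, pinhole
   back-projection, rigid camera-to-base transform
   (`localize_keypoints()`).

Everything runs on synthetic fixtures (`make_back_image()`,
`make_depth_frame()`, `mock_predictions()`), so no subject imagery is
required or shipped.

## Exemplar-based de-labeling

The region to remove is $\Omega$ (the union of marker discs), the intact
skin is $\Phi$, and the fill front $\partial\Omega$ is the set of unknown
pixels with a known 4-neighbor. Each iteration fills the patch
$\Psi_p$ of the front pixel $p$ with the highest priority.

**Confidence term.** $C(p)$ is the mean confidence of the known pixels in
$\Psi_p$ (confidence starts at 1 on $\Phi$, 0 on $\Omega$; filled pixels
inherit $C(p)$, capped at 1). As filling proceeds this product decays
toward zero for late pixels.

**Data term.** $D(p) = |\nabla I^{\perp}_p \cdot n_p| / \alpha$, where
$\nabla I^{\perp}$ is the 90°-rotated luminance gradient (the isophote)
and $n_p$ the unit normal of the front. We use Rec.601 luma, masked
central differences (one-sided at borders and next to unknown pixels),
take the strongest known gradient within the patch as the isophote at
$p$, and obtain $n_p$ from the gradient of a 5×5 box-smoothed indicator
of $\Omega$. $\alpha = 255$ for 8-bit images. The isophote is *not*
normalized to unit length — with $\alpha = 255$ a unit isophote would
make $D$ vanish; the classical magnitude-bearing form is the only
internally consistent reading.

**Priority.** Baseline mode uses the classical product $P = C \cdot D$.
Its known failure mode is that the product collapses to zero once
confidence has decayed (or wherever the image is locally flat, $D = 0$),
making the fill order arbitrary. Improved mode uses the exponential sum
$P = e^{C + D}$ with $C$ floored at $k_{thr}$, which is strictly positive
and still orders fronts by the same two cues.

**Search region.** Baseline mode scans every candidate patch in the
image. Improved mode fits each marker component with its equivalent
ellipse (centroid + second moments; half-axes are twice the eigen
standard deviations, so a disc of radius $r$ gets half-axes $\approx r$),
scales it by `ellipse_margin`, removes $\Omega$, and searches only this
band — split into four quadrants along the symmetry axes, visiting the
quadrant containing $p$ first. If the band holds fewer than
`min_candidates` valid candidates the search falls back to the whole
image, so the local search never starves. With `ellipse_margin = Inf`
(or a huge value) the band is the whole image and the fill order equals
the whole-image search — a limit equivalence the test suite asserts.

**Matching.** The source patch minimizes the SSD over the already-known
pixels of $\Psi_p$, among candidate centers whose full patch is inside
the image and free of unknown pixels (already-filled pixels may be
*content* but not carriers of unknowns). Ties break by distance to $p$,
then row-major order, making the fill fully deterministic.

Defaults and their reasons (none of these values is prescribed by the
source procedure; they are package choices):

| parameter | default | rationale |
|---|---|---|
| `patch_radius` | 4 (9×9) | standard exemplar-inpainting patch size |
| `k_thr` | 0.2 | keeps late-fill priorities informative without drowning the confidence signal |
| `alpha` | 255 | dynamic range of 8-bit luma |
| `ellipse_margin` | 2.5 | band of roughly 5 marker radii — enough skin texture around an adhesive label |
| `min_candidates` | 50 | whole-image fallback before the band can starve the match |

## Quality and efficiency metrics

`psnr3()` implements the written three-channel form — a *sum* of three
per-channel `10 log10(255²/MSE)` terms — as `variant = "paper_sum"`, and
its conventional third (`"channel_mean"`, the default). The sum form runs
roughly 3× a conventional PSNR, which matters when comparing against
typical "close to 40 dB" readings; both are kept so either convention can
be reproduced. Zero MSE returns the `+Inf` sentinel, not an error.

`ssim_global()` is the single-window SSIM evaluated from global moments
(no sliding window), per channel and averaged, with
$c_1 = (0.01 L)^2$, $c_2 = (0.03 L)^2$, $L = 255$.

`per_marker_time()` exposes the tension between the definition
(mean of whole-image times) and its stated unit (seconds per acupoint):
`"per_image"` is `mean(T_i)` exactly as written; `"per_marker"`
(default) is `mean(T_i / markers_i)`. `efficiency_gain()` likewise
provides the per-image mean of `1 - T_ip/T_ic` and the ratio-of-means
variant; with the published mean times (13.4817 s vs 4.333 s) the
ratio-of-means gain is ≈ 67.9 %, matching the printed one-decimal figure
to within truncation.

## Keypoint accuracy metrics

`ape_image()` computes the per-image mean of
`max(||P_j - G_j|| - tolerance_px, 0)` over label-matched visible pairs.
The printed error definition subtracts a "10k" term whose units do not
work out (pixels minus 10 × mm-per-px); the only reading consistent with
a reported mean error of 4.45 px alongside ≈ 90 % recall is a plain mean
pixel error, so `tolerance_px` defaults to 0 and the literal constant is
available as `tolerance_px = 10 * scale_k`.

`apde()` converts pixels to millimeters with `scale_k = 1.3` mm/px (the
measured conversion at 640×480 and ~1 m working distance). Note the
published per-sample millimeter values imply k ≈ 1.29; the constant is
configurable and 1.3 is used for headline conversions.

`classify_hits()` implements the effective-region rule: truth and
prediction each carry a 10 mm circular region ("10 mm circular area"
read as *diameter*); two equal circles overlap iff their centers are
closer than the diameter, so TP ⇔ center distance < 10 mm, strictly
(exactly 10 mm is an FN). Missing or invisible predictions are FNs.
`kp_recall()` averages per-image recalls (not the pooled ratio — the two
differ whenever per-image counts differ, and the test suite pins the
distinction). Matching is by label only; fixtures and Labelme files both
carry authoritative labels, so no Hungarian assignment is needed.

## Augmentation

`aug_scale()` (bilinear, keypoints multiplied by the factor, mask by
nearest neighbor), `aug_crop()` (window clamped to bounds, outside
keypoints marked invisible with coordinates retained for audit) and
`aug_hflip()` (`x → W−1−x` under the 0-based pixel-center convention).
Flips swap `L_i ↔ R_i` labels through an involutive map, with midline
`M_i` fixed; swapping is the anatomically correct choice and the map is
configurable. `augment_random()` composes scale ∘ crop ∘ flip under one
seed, resampling the crop (≤ 10 tries) until ≥ 50 % of visible keypoints
survive. Scale range (0.7, 1.3) and the 80 %-side default crop are
package choices; no ranges are prescribed by the source procedure.

## SimCC codec and the two-stage harness

`simcc_encode()` represents a coordinate as a classification target over
sub-pixel bins: `round(extent × ratio)` bins (default `ratio = 2` bins
per pixel), a Gaussian of `sigma_bins = 6` centered at `coord × ratio`,
truncated and renormalized. `simcc_decode()` inverts by the normalized
expectation of bin centers (argmax available), preserving sub-pixel
precision: for interior coordinates ≥ 3σ from the borders the round trip
is exact to well under a quarter pixel. `kl_divergence()` is the
associated training objective (epsilon-floored, renormalized).

`run_pipeline()` is the top-down two-stage composition: detector →
bounding box → padded, aspect-fitted affine crop (`roi_transform()`,
default padding 1.25 into a 192×256 window) → localizer in ROI
coordinates → inverse affine back to image coordinates; localizer output
outside the ROI window is marked invisible. Network inference is out of
scope by design: detectors and localizers are injected functions, and the
package ships oracle and noisy mocks. The source architecture describes
the box as "constraining" a whole-image keypoint stage; the harness
implements the standard crop-based reading (the box genuinely restricts
the pixels the localizer sees), which is what top-down frameworks do in
practice. The localizer receives `(roi_pixels, roi_transform)` — the
transform is ROI metadata, mirroring how pose frameworks pass the crop's
affine alongside the crop.

## Geometry chain

`register_depth()` maps a color pixel to the depth raster by the
resolution ratios `u' = u·s_w`, `v' = v·s_h` (the "normalization factor"
is read as the resolution ratio, the only definition that types-checks),
rounding to the nearest depth pixel by default with bilinear lookup
behind a flag. Depth 0 encodes "no return" (the common depth-camera
convention) and propagates as an explicit invalid signal, never a silent
drop. `pixel_to_camera()` implements the central perspective
back-projection `x_c = (u−u_0)·ρ_w·z/f`, `y_c = (v−v_0)·ρ_h·z/f`,
`z_c = z`; `camera_to_base()` applies the validated rigid transform
(orthonormal rotation, det +1). All pixel indexing is 0-based with
pixel-center sampling, consistently across modules.

## The synthetic world

`make_back_image()` emulates a prone-back photograph at the platform's
640×480 resolution: a uniform skin tone (RGB 205/170/148), two
low-frequency cosine shading fields (amplitude 18 of 255 — mild,
body-scale illumination), Gaussian sensor noise (σ = 3), and anti-aliased
dark discs of radius 8 px at 34 named keypoints (M1–M6 midline, L1–L14 /
R1–R14 in two mirrored paraspinal columns). The anti-aliased disc edge is
confined to the disc footprint so the marker mask covers *every* altered
pixel — otherwise no mask-driven restoration could ever recover the
pristine image. The 34-point layout follows the named-point scheme (the
printed coordinate matrices run to 35 entries while the named set totals
34; the count is configurable, 34 is the default). Depth frames are a
plane (800 mm, the ~1 m working height) plus a single cosine bump
(body bulge) at a configurable resolution ratio.

What a green test on this world establishes: algorithmic correctness of
the fill rules, metric arithmetic, codec round trips and coordinate
chains, and that the improved inpainter does not degrade restoration
relative to the baseline on textured-but-smooth skin-like input. What it
does not establish: performance on real skin (pores, hair, specular
highlights, posture variation), real detector errors, or real depth
noise — the published dataset-level figures depend on proprietary imagery
and trained networks and are deliberately not asserted.

## Numerical choices and degenerate inputs

* Fill-front extraction uses 4-connectivity; marker components use
  4-connected labeling.
* The fill loop is capped at one iteration per masked pixel; exceeding
  the cap (impossible for well-formed masks, since every iteration fills
  at least the front pixel itself) raises an error carrying the count of
  remaining pixels.
* A mask covering the whole image is rejected (no source region).
* Equal images give SSIM exactly 1 and the PSNR `+Inf` sentinel.
* `simcc_encode` rejects out-of-range coordinates; `simcc_decode`
  rejects all-zero vectors.
* Ellipse fitting adds 1/12 per-axis variance (the variance of a
  uniform pixel) so one-pixel-thin components still yield a 2-D ellipse.
* Seeds: every stochastic operation takes an explicit integer seed and
  restores the caller's RNG state (`withr::with_seed`).

## Known limitations

* The inpainter is exemplar-based only; PDE/diffusion and learned
  inpainting are out of scope.
* SSIM is global, not sliding-window; windowed or multi-scale SSIM is
  out of scope.
* No OKS/PCK keypoint metrics, no precision-recall over confidence
  thresholds (predictions carry no scores here).
* Lens distortion, hand-eye calibration and trajectory planning are out
  of scope; intrinsics and the camera-to-base transform are consumed as
  given.
* PNG I/O needs the optional `png` package; the always-available
  interchange format is plain-text PNM.
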