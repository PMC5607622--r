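---
title: "Quantifying hard exudates in colour fundus photographs: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hard exudates: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hequant)
```

## The problem

Hard exudates (HEs) are yellow lipid deposits in the retina, the classical
sign of diabetic retinopathy. Their total area in a colour fundus (CF)
photograph is the quantity a clinician wants to track under treatment, but
manual delineation is impractical: lesions are numerous, small, and vary
enormously in contrast. Fully automatic detection is confounded by other
bright structures — the optic disc, cotton-wool spots, and specular
reflections on vessels — whose intensity profiles overlap the exudates'.
`hequant` therefore implements a *semi-automated* workflow: automatic
detection, scripted removal of recognisable non-exudate detections via
rectangular exclusion boxes, and calibrated area measurement.

## The detection model

Both prongs of the detector share one chain:

1. **White top-hat.** For an intensity image $I$ and a flat disc $B_r$ of
   radius $r$, the opening $I \circ B_r$ is the erosion followed by the
   dilation of $I$ by $B_r$; the white top-hat $I - I \circ B_r$ keeps
   bright structures *narrower than the disc* and flattens everything
   smoother. At image borders the neighbourhood is restricted to the frame
   (an oracle-tested convention: `white_top_hat()` agrees exactly with a
   brute-force sliding min/max). One consequence worth knowing: a trailing
   border strip of width $r$ retains a residual proportional to
   $r \times$ the local slope, because the dilation has no room to restore
   the eroded ramp there.
2. **CLAHE.** Contrast-limited adaptive histogram equalization over a grid
   of contextual tiles with bilinear inter-tile interpolation. The tile
   histogram is clipped at `clip` times the tile pixel count (the clipped
   excess is redistributed), which bounds local contrast amplification.
3. **Fixed threshold**, strictly `>`, on the equalized [0,1] scale.

Step 1 targets *bright* exudates on the BT.601 grayscale image with a disc
of radius one **quarter** of the image width and threshold **0.37**. A disc
that large does not really model the background — its erosion is floored by
the darkest structure (vessels) within reach — so step 1 behaves like a
conservative quasi-global threshold that only the strongest lesions pass.
Step 2 targets *faint* exudates on the **green plane** (where their
contrast is best) with a disc of radius one **twenty-fifth** of the width
and threshold **0.25**: here the opening genuinely tracks the local
background, so a lesion 0.06 above its surroundings survives no matter how
the illumination varies across the field. The union of the two masks is
the detection; intersection with the field-of-view (FOV) mask comes last.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `step1_radius_frac` | 1/4 | step-1 disc radius as a fraction of image width |
| `step1_threshold` | 0.37 | step-1 cut on the equalized [0,1] scale |
| `step2_radius_frac` | 1/25 | step-2 disc radius fraction (green plane) |
| `step2_threshold` | 0.25 | step-2 cut |
| `clahe_tiles` | 8×8 | contextual tile grid |
| `clahe_clip` | 0.01 | clip limit, fraction of tile pixel count |

The radius fractions and the two thresholds are the pipeline's empirically
determined operating point and apply to the *full image width*, rounded to
the nearest pixel (minimum 1). The CLAHE defaults are the convention of
mainstream implementations (8×8 tiles, clip fraction 0.01 of the tile's
pixel count, 256 bins).

### Numerical choices in `adaptive_hist_eq()`

* The input is **globally min–max stretched to [0,1] before the tile
  equalization**. This matches scikit-image's `equalize_adapthist` (which
  rescales with `rescale_intensity` before its Zuiderveld pass) and we
  verified the two agree numerically on shared fixtures. The stretch
  matters: a top-hat image occupies a small sub-range of [0,1], and without
  the stretch a clip fraction of 0.01 leaves the mapping nearly affine, so
  no fixed threshold could separate a 0.06-contrast lesion. With it, the
  fixed thresholds 0.37/0.25 are meaningful across images of different
  dynamic range.
* The clip fraction is converted to `EBImage::clahe()`'s units (multiples
  of the uniform bin height) as `limit = clip * bins`.
* A spatially constant image is returned unchanged (degenerate histogram);
  a 1×1 tile grid falls back to global histogram equalization; images whose
  sides are not divisible by the tile grid are edge-padded and cropped.
* The dark camera matting outside the FOV is set to white before the
  top-hat — erosion then ignores it, giving restricted-window semantics at
  the field rim — and the out-of-FOV top-hat is zeroed before CLAHE so rim
  tiles resemble interior background. Without this, the rim ring dominates
  both stages.

A known residual: in tiles that contain no bright structure at all, CLAHE
necessarily stretches whatever local variation exists (noise and the
erosion floor), so a lesion-free retina still yields a low-percent
detection density rather than a strictly empty mask. This is intrinsic to
a fixed threshold downstream of locally adaptive equalization; the
box-exclusion step absorbs it in practice.

## The maximum-entropy baseline

The comparison protocol selects the green plane, histograms it *within the
FOV* (the black surround would otherwise dominate the background class),
and thresholds at the Kapur–Sahoo–Wong maximum-entropy level: the level
$t$ maximizing $H_b(t) + H_f(t)$, the Shannon entropies of the normalized
class histograms over levels $\le t$ and $> t$. Natural logarithms,
$0\log 0 = 0$; candidates leaving a class empty are skipped (decided on
raw counts, not float remainders); ties break to the smallest level.
Foreground is the bright class. `max_entropy_threshold()` is tested
bin-exactly against an exhaustive 256-candidate evaluation on a thousand
random histograms.

Kapur's criterion is not a valley seeker: on a 4:1-unbalanced two-Gaussian
histogram it typically cuts into the upper tail of the dominant dark mode
rather than the inter-mode valley. What matters for the method comparison
is that the threshold is *global*: any lesion whose green level lies within
the spread of the illumination-modulated background is invisible to it.

## Areas, exclusion and agreement statistics

Exclusion boxes are 0-based, half-open axis-aligned rectangles, applied by
clearing mask pixels; fully out-of-frame boxes warn and are skipped. Area
is `pixel_count * mm_per_pixel^2` with an 8-connected component breakdown
(configurable to 4). Without a user-supplied scale, calibration derives
from the acquisition geometry: a 50° field over the estimated FOV diameter
at 0.288 mm of retina per degree — an explicit, overridable stand-in, since
pixel pitch is rarely recorded; its provenance is tagged in every report.
The method-difference convention is **baseline − proposed**, so a negative
mean means the global-threshold method underestimates.

Observer agreement offers four statistics: the uncentered correlation
$CC = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$ (implemented exactly as
defined; it rewards agreement in magnitude, unlike Pearson's $r$, which is
provided separately); Bland–Altman bias and 1.96·SD limits of agreement
(sample SD, $N-1$); and a two-way mixed-effects, absolute-agreement,
single-measure ICC from the mean-squares decomposition
$\mathrm{ICC}(A,1) = (MS_R - MS_E) / (MS_R + (k-1)MS_E + k(MS_C - MS_E)/n)$.
The ICC model had to be fixed by choice; absolute agreement single-measure
is the variant that penalizes systematic grader offsets. Percentage
gradings are binned over [0,30), [30,60), [60,90), [90,100] — half-open,
with 100 closing the last bin.

## The synthetic scene generator

No public dataset accompanies this protocol, so `generate_scene()` renders
seeded fundus scenes with per-class ground truth. Intensity ranges follow
the characteristic grayscale distribution of DR fundus photographs: HEs
85–200 (bright clusters sample the upper half, faint blobs stay in the
lower half), cotton-wool spots 80–130, optic disc 90–200, vessel
reflections 80–110. Colours are produced from per-class chroma directions
normalized so that BT.601 grayscale equals the sampled level exactly.

Geometry and photometry the ranges do not fix are the package's own
modelling choices:

* **Illumination** (relative amplitude `illumination_gradient`, default
  0.35): an achromatic vignetting tilt (down to 1 − 0.55·a) plus one to
  three broad, smooth bright patches on the nasal side (up to 1 + a) with
  green-dominant spectrum (weights R 0.15, G 1.0, B 0.6). This mimics
  uneven flash illumination and nerve-fibre-layer sheen, which are
  green-bright, while the macula — where exudates concentrate — stays
  comparatively dark in green (luteal pigment absorbs green light). The
  sheen is what gives the green histogram the broad bright shoulder that a
  global threshold must clear, the mechanism behind the two methods'
  difference on faint lesions.
* **Vessels**: 2–4 gently arcing paths fanned from the disc, width 2–6 px
  (at the 512 px reference scale), one optional branch each; grayscale
  80–90 modulated by the illumination field. Their contrast is
  concentrated in the green plane (chroma 1.85/0.60/0.35), as in real
  photographs where the red plane washes vessel contrast out. Bright
  centerline reflection strips cover ~30% of each path.
* **Lesions**: bright-HE clusters of 1–8 elliptical blobs (radii 1–6 px)
  and single faint blobs (radii 2–6 px) in the macular half; cotton-wool
  spots with a 2 px Gaussian-blurred boundary slightly beyond it. Faint
  blobs add exactly `faint_green_excess`·255 to the green channel over
  their local background; their sites additionally require background
  bright enough that the bump keeps their grayscale inside the exudate
  range. Exudates are rejection-sampled (1000 attempts, then an error
  naming the class) clear of the disc *and* the vessel tree, so each truth
  class owns the local contrast it creates.
* **Noise**: per-channel additive Gaussian, SD `noise_sd`·255, clipped.

Truth masks are recorded before blur and noise: detection metrics need
crisp references, and the blur models acquisition, not lesion extent.

The generator samples its entire layout in *normalized coordinates* with a
resolution-independent RNG stream and only then rasterizes, so one seed
describes the same retina at every resolution: pixel counts scale with
resolution squared while mm² areas are stable to a few percent. The same
split makes `generate_scene()` bit-reproducible and keeps the caller's RNG
state untouched.

### What the synthetic scenes do and do not show

The scenes reproduce the *intensity taxonomy* and the illumination regime
of fundus photographs, not their texture: real retinas have choroidal
mottling, nerve-fibre striation and lesion-boundary softness that flat
elliptical blobs lack. Passing the recovery tests therefore demonstrates
that the pipeline's contrast logic is right (bright lesions always found;
faint lesions found locally but invisible globally; recall monotone in
faint contrast), not that clinical sensitivity/specificity would match.
Real-data thresholds may also sit elsewhere — they are exposed as
parameters for exactly that reason.

## Problem sizes used by the test-suite and the acceptance script

Unit tests run on small rasters (8×8 to 128×128) against brute-force
oracles; scene-level tests and `scripts/acceptance.R` use 20 scenes of
512×512 (the generator's default and reference scale), which keeps the
full suite within a few minutes on one CPU while leaving each scene large
enough for the W/4 structuring element to behave as designed.

## Known limitations

* A lesion-free tile still yields a few detections after CLAHE (see
  above); density on a blank retina is seed-dependent at the 1–4% level.
* Step 1's huge disc makes its background estimate vessel-floored;
  illumination fields much stronger than the defaults push its quasi-global
  threshold into the background's upper tail.
* The default calibration is a geometric stand-in; for absolute areas a
  measured `--mm-per-pixel` should be supplied.
* The ICC is a point estimate; no confidence intervals are computed.
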