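---
title: "Counting nuclei in tiled well-plate scans: models and methods"
author: "platescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting nuclei in tiled well-plate scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platescan)
```

# The problem

Benchtop imagers that scan multi-well plates stitch a 3x3 or 4x3 grid
of adjacent microscope fields into one composite image per well. For
growth assays seeded at clonal density — one to a few hundred cells in
a 0.32 cm² well — *every* cell matters, so the entire well must be
imaged and counted, not sampled. Nuclei are labeled with a fluorescent
histone fusion (H2B-GFP) so each cell reads as one bright spot.

The composite images defeat naive counting. The plastic wall of the
well fluoresces as a bright halo ring; the well's position inside the
frame varies between wells and plates; each contributing field is
brightest at its center and dims toward its edges, which tiles into a
soft grid across the mosaic; the flat-field correction that removes
that grid also attenuates the nuclear signal; and debris, read noise
and occasional whole-frame vertical compression corrupt what remains.
`platescan` implements a processing chain in which each of these
problems is addressed by a specific, ordered stage, plus a synthetic
generator that reproduces all of them with known ground truth.

# Processing model

For a well image $I \in [0,1]^{H \times W}$ the chain is:

1. **Well isolation.** The halo is treated as one very large object:
   invert, Gaussian-smooth heavily ($\sigma_w$ = 25 px), threshold
   (Otsu), keep the largest connected component whose equivalent
   diameter is at least half the short frame side (components holding
   three or more frame corners are the exterior and are excluded), fill
   holes. A least-squares circle fit to the component boundary gives a
   provisional center; the growth-area outline is then refined at full
   resolution by marching 720 rays from that center and taking the
   inner edge of the outermost long bright run — the halo — on each ray
   (short bright runs from debris are ignored; a 5-point circular
   median across angles removes single-ray flukes). The mask is the
   star-shaped region enclosed by the refined outline. This two-step
   coarse-to-fine design is what delivers >99% coverage of the true
   growth disc regardless of where the well sits: the blurred coarse
   component alone is biased inwards by roughly the smoothing radius.
   Eccentricity comes from the second-moment eigenvalues of the final
   region; a vertically compressed (ovoid) frame yields a visibly
   eccentric region and is flagged rather than corrected, because the
   fault is an acquisition problem whose fix belongs upstream.
2. **Mask erosion** by a disc of 1% of the fitted radius (at least
   3 px) pulls the mask off the halo's inner shoulder so edge
   perturbances are not segmented as cells.
3. **Log contrast transform**, $f(x) = \log(1 + kx)/\log(1 + k)$ with
   $k = 255$ by default (the classic 8-bit log mapping; $f$ fixes 0
   and 1 and is strictly increasing). It runs *after masking and
   before illumination correction*: the transform lifts dim nuclei
   away from the background so the subsequent division by the
   illumination function cannot push them below the detection
   threshold. This ordering is the load-bearing design decision of the
   whole chain; the package's tests demonstrate both directions
   (with the log stage the full pipeline recovers all dim nuclei; the
   variant that corrects without it loses them at the same threshold
   settings).
4. **Illumination function.** The per-pixel median across all masked,
   log-transformed wells of the plate (median, not mean, so wells dense
   with cells do not imprint their nuclei on the field; nuclei sit at
   different positions in every well and vanish under the median).
   Pixels never covered by any mask are imputed from the tile-local
   radial profile of observed values; the surface is Gaussian-smoothed,
   floored, and normalized to maximum 1. Correction is division (a
   multiplicative shading model — vignetting is a gain phenomenon),
   clipped back to $[0,1]$.
5. **Denoising** with a mild Gaussian blur ($\sigma$ = 1 px), which
   flattens 1–3 px debris specks far more than nucleus-scale spots.
6. **Segmentation.** Threshold over in-mask pixels; with declumping on
   (the default) objects are the basins of a distance-transform
   watershed over the whole foreground, so two nuclei whose blobs
   touch separate at the waist of their combined component while a
   convex single spot keeps exactly one basin (the watershed tolerance
   absorbs ridge-line ripple); then a diameter gate: equivalent
   diameter within [3, 20] px keeps nuclei while discarding residual
   debris (below) and halo remnants or condensation patches (above).
   Restricting the watershed to over-size components only was
   considered and rejected: a touching pair of large nuclei merges
   into a blob that still passes the gate, and at high seeding
   densities such pairs are routine, so shape-based declumping must
   see every object.

Counts aggregate into growth curves as population doublings
$\mathrm{PD}(t) = \log_2 N_t / N_0$ against each well's own baseline
scan (seeding efficiency varies, so the first scan — not the seeded
cell number — is the honest baseline), summarized as mean ± sample SD
(n − 1) across replicate wells.

# Thresholding

The automatic default is Otsu computed over in-mask pixels only, with
one guard: when the Otsu threshold would label more than 15% of the
growth area as foreground, the histogram is effectively unimodal —
Otsu is known to misplace its threshold inside the background mode when
the foreground fraction is tiny, which is precisely the clonal-density
regime this pipeline exists for — and the threshold falls back to a
robust background model, median + 5 × MAD-based sigma, of the same
in-mask pixels. A fixed manual threshold can be set instead
(`pipelineConfig(nucleusThreshold = 0.55)`) and overrides the
automatic method; batch workflows that optimize one threshold per
experiment are the historical practice for this kind of pipeline, and
the pipeline-variant comparisons in the tests hold the threshold fixed
across variants for exactly that reason.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `logGainK` | 255 | — | gain of the normalized log transform |
| `wellSmoothSigma` | 25 | px | blur while finding the well object |
| `wellMinDiameterFrac` | 0.5 | — | size gate for the well object |
| `erosionPx` | auto | px | mask contraction; auto = 1% of radius, ≥ 3 |
| `illumSmoothSigma` | 15 | px | smoothing of the illumination surface |
| `illumFloorEps` | 0.05 | — | gain floor; caps amplification at 20x |
| `denoiseSigma` | 1 | px | pre-segmentation blur |
| `nucleusDiameterPx` | (3, 20) | px | accepted equivalent diameter |
| `nucleusThreshold` | "otsu" | — | guarded Otsu or fixed manual value |
| `declump` | watershed | — | split over-size components |
| `ovoidEccentricityMax` | 0.25 | — | OVOID QC bound |
| `minMaskAreaFrac` | 0.2 | — | LOW_MASK_AREA QC bound |

`illumSmoothSigma` deserves a note: the smoothing must be small
relative to the ~300 px tile period, because a Gaussian of sigma
$\sigma$ attenuates a pattern of wavelength $\lambda$ by
$\exp(-2\pi^2\sigma^2/\lambda^2)$ — at $\sigma = 60$ px the estimated
field would retain only ~45% of the seam pattern and the correction
would leave most of the grid in the images. At the default 15 px the
field keeps ~95% of the pattern while still suppressing noise and any
nuclei that survive the median.

The diameter gate reflects nucleus size (10–20 µm) at typical 4x
mosaic sampling of a few µm per pixel; both bounds are configuration,
not constants, because the equivalent instrument settings vary.

# The synthetic generator

`syntheticWellSpec()` describes one well; `renderWell()` composes, in
order: uniform background (medium autofluorescence, default 0.05);
halo ring (default +0.7, 40 px wide) at the well radius; a per-tile
multiplicative radial falloff $g(r) = 1 - v\,(r/r_{\mathrm{corner}})^2$
applied to background and halo (default $v = 0.25$; $v$ is the
fractional dimming at tile corners, and adjacent dim tile edges form
the grid); Gaussian-profile nuclei ($\sigma$ = diameter/4, diameters
uniform in 6–12 px, peak +0.5) placed uniformly in the disc with
reject-resample non-overlap (no two centers closer than max diameter
+ 2 px) and kept ~3% inside the wall, where real cells are optically
swallowed by the halo; 1–3 px debris specks (+0.9) anywhere in the
frame; Gaussian read noise (sd 0.01, consistent with 8-bit
quantization plus shot noise at this background); multiplication by an
exposure gain; optional vertical compression of the whole frame (the
ovoid artifact) with vacated rows filled at background level; clipping
to $[0,1]$. Ground truth records the (possibly compressed) nucleus
centers and well geometry. A plate render jitters the well center
uniformly per axis and derives per-well sub-seeds by hashing the
master seed with the well's index, so any single well can be
reproduced without rendering the plate and nearby master seeds give
unrelated plates.

Defaults were chosen once for visual and statistical resemblance to
real 4x GFP scans: a bright, high-contrast halo; a faint background;
nuclei that a human can count by eye. Numbers the source imagery does
not pin down (vignette depth, halo brightness, debris density) are
free parameters of the spec.

What the generator does *not* emulate: optical point-spread functions,
nucleus texture and shape, focus gradients across the plate, cell
clumping or division during a scan, autofluorescent media gradients.
Passing the synthetic benchmark therefore demonstrates the geometric
and photometric logic of the chain — isolation, enhancement ordering,
artifact suppression, gating — but not biological segmentation
fidelity on textured nuclei; on real data the diameter gate and
threshold need the per-experiment check that the configurable
`PipelineConfig` exists for.

One structural property of the model is worth stating because it
bounds what artifact comparisons can show: the illumination field is
normalized to maximum 1 and applied by division, so correction only
ever brightens, and the grid's seams are the *dim* part of the
pattern. A variant pipeline that skips the correction therefore sees a
background everywhere dimmer than the corrected one; with bright,
well-resolved default nuclei its automatic threshold still lands in
the nuclei/background valley and the count is unchanged. The
overcounting that motivates the correction appears when nuclei are
dim or small enough that the grid rivals them in the histogram — the
regime the source imagery describes — and the correction's value in
this package is demonstrated on exactly that dim-nuclei regime
(see the log-transform and grid tests), not on bright ones.

# Numerical choices and degenerate inputs

* Intensities are doubles in $[0,1]$; 8- and 16-bit sources divide by
  $2^b - 1$. Coordinates are 1-based (row, col), pixel centers at
  integers.
* Gaussian blurs use reflective padding (EBImage's native circular
  boundary would bleed opposite frame edges into each other).
* Blank frames (no large-scale structure after smoothing) raise a
  `NO_WELL_FOUND` condition; plate runs convert that into a flagged
  zero-count row rather than aborting, as they do for unreadable
  files.
* Erosion that annihilates a mask raises `LOW_MASK_AREA`.
* Wells with a zero baseline count are excluded from growth curves
  with a warning — their doublings are undefined — rather than
  propagated as infinities.
* Truth matching is greedy nearest-neighbor within 5 px, deterministic
  and adequate for non-overlapping truth; an optimal assignment would
  differ only for pathological configurations.
* The 16-bit PNG writer used to persist illumination fields emits the
  format directly (deflate + CRC-32); gain surfaces survive the
  quantization round trip to ~1e-5, and the JSON sidecar restores the
  exact recorded range.

# Problem sizes used in validation

The test suite and `scripts/acceptance.R` exercise: a 20-well scan at
the full default 1000 x 1200 mosaic geometry with 10–500 nuclei per
well; ten-seed paired runs of the grid-artifact and ovoid scenarios;
a full 96-well plate with ±40 px jitter at a 700 x 800 frame with a
260 px well — a geometry chosen so the jitter-to-radius ratio matches
the documented regime in which a fixed shared mask loses more than a
quarter of the growth area (at the default 430 px radius, ±40 px of
jitter cannot produce that loss); and growth series of 12 replicate
wells over 14 days with ±5% count noise. These sizes keep the whole
validation within a few minutes on one CPU while leaving every
per-well computation at full scale.

# Known limitations

* One well per frame is assumed (the scan contract); multi-well frames
  are out of scope.
* The OVOID flag is advisory; compressed wells are still counted, and
  their counts are only as good as the distorted geometry allows.
* The illumination function is estimated per plate and timepoint;
  with fewer than ~8 usable wells the median is noisy and reusing a
  saved field (`--illum-load`, `loadIlluminationField()`) is the
  better workflow.
* Heavily confluent wells violate the sparse-foreground assumptions of
  both the automatic threshold and the non-overlap benchmark; counts
  saturate as nuclei merge.
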