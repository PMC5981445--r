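---
title: "Quantifying collagen fiber organization with ftshg: models, parameters and design choices"
author: "ftshg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collagen fiber organization with ftshg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftshg)
```

## The measurement model

Second-harmonic generation (SHG) microscopy produces grayscale z-stacks in
which fibrillar collagen appears as bright, elongated, quasi-parallel
structures against a dark background. `ftshg` reduces each slice to three
scalar parameters and a cell-wise orientation classification, then
compares conditions through percent changes and a two-sample test.

**Density $I_d$.** The slice is tiled with square cells (16 px by
default, the scale at which individual fibers and inter-fiber spaces are
both visible at typical SHG sampling). Each cell records the fraction of
its pixels strictly above the noise threshold; $I_d$ is the grid mean.
When the grid tiles the image exactly this equals the global
above-threshold pixel fraction — an exact rational identity that the test
suite exercises. $I_d$ is invariant under any intensity transform that
preserves the above/below-threshold partition.

**Peak spectral intensity $I_s$.** The 2-D FFT magnitude of a selected
region (zero-frequency term centered, then excluded — see below) is
integrated radially: for each angular bin over $[0°, 180°)$ a ray is cast
from the spectrum center and the amplitude is summed at unit radial
steps, with bilinear interpolation, from `rMinPx` (default 2) to the
largest radius inside the spectrum. $I_s$ is the profile maximum.
Because parallel fibers concentrate spectral energy perpendicular to the
fiber axis, the profile peak angle plus 90° (mod 180) is the implied
real-space fiber orientation. $I_s$ is homogeneous of degree 1 in image
intensity and invariant to circular translation.

**Anisotropy ratio $r$.** The magnitude spectrum is normalized by its
maximum, binarized at a relative threshold (`frac`, default 0.1), and the
set of retained pixels is summarized by its equivalent ellipse — the
ellipse with the same second central moments, whose full axes are
$4\sqrt{\lambda_{1,2}}$ of the coordinate covariance (population
divisor). For a filled ellipse of pixels this recovers the axes exactly.
$r = \alpha/\beta \ge 1$ grows with spectral elongation, i.e. with
orientation coherence of the texture. $r$ is invariant to intensity
scaling (the threshold is relative) and to translation.

**Cell classification.** Independently of the spectral route, each grid
cell is labelled through the gradient structure tensor: Gaussian-derivative
gradients ($\sigma = 1$ px) are computed, their outer product is summed
over the cell, and the tensor's coherence $(\lambda_1 - \lambda_2) /
(\lambda_1 + \lambda_2)$ classifies the cell as *anisotropic*
($\ge$ `coherenceThresh`, default 0.5) or *isotropic*; cells whose mean
intensity falls below `darkThresh` are *dark*. For anisotropic cells the
fiber orientation is the eigenvector of the smaller eigenvalue (fibers
run perpendicular to the dominant intensity gradient). A cell with
numerically zero gradient energy (constant intensity) is isotropic with
coherence 0 by definition; the zero test is scaled to the image intensity
so FFT round-off in the convolution never masquerades as structure.

**Stack averaging and comparison.** All three parameters are measured per
slice and averaged over the stack. Before/after change is
$100 (x_{\text{after}} - x_{\text{before}}) / x_{\text{before}}$
(undefined, and an error, for a zero before-value), computed on the
stack-averaged parameters; a per-slice alternative would weight slices
differently only when slice counts differ within a pair. Groups of
changes are summarized as mean ± sample SD and compared with the
unpaired two-tailed Student $t$ test with pooled variance,
$df = n_A + n_B - 2$. The pooled (not Welch) form is the package default
because it is the classic small-sample test and, fed with published group
summaries of this kind, reproduces the published significance figures;
Welch is available via `method = "welch"`. The test accepts either raw
samples or (mean, SD, n) summaries — the two entry points agree exactly.

## Angle and coordinate conventions

Pixel coordinates are 0-based, half-open, in (row, col) order; partial
edge cells of a grid are dropped, never padded. All angles are degrees
counterclockwise from the +x (column) axis with +y pointing up, reduced
mod 180 (orientations are axial). The same convention covers the
structure tensor, the angular profile, the ellipse orientation and the
phantom generator, which is what makes the cross-module recovery tests
(tensor vs spectral orientation within a few degrees) meaningful.

## Choices where the method is underdetermined

Several steps of the published procedure admit more than one reading;
the package fixes each with an explicit, overridable default:

- **Noise level.** The threshold behind $I_d$ is estimated as the image
  median plus $k$ MAD ($k = 3$), with a percentile knob and a fixed-value
  override. This is robust and reproducible, but it *assumes background
  pixels are the majority*: on frames dominated by bright fibers the
  median climbs into the fiber mode and the threshold overshoots. For
  such frames — including dense synthetic phantoms — pass a fixed
  threshold (for phantoms, the known background level
  `noiseMean + 3 * noiseSd` is the natural choice). "Above the noise
  level" is strict (`>`), which makes the all-zero image at threshold 0
  unambiguous ($I_d = 0$). Whether the threshold is estimated per slice
  or once per stack is selectable (`thresholdScope`); per slice is the
  default.
- **DC handling.** The zero-frequency term would dominate both the
  angular profile and the binarized mask, so it is excluded by default
  before either; the innermost sampled radius is 2 px. A constant image
  therefore yields an all-zero spectrum — flagged, not an error — while
  binarization of an all-zero spectrum *is* an error ("no signal to
  binarize").
- **Radial integration.** Sampling along rays with bilinear
  interpolation gives every angular bin the same number of samples;
  raw wedge sums would weight bins unevenly on a square grid. Amplitude
  (not power) is integrated, which keeps $I_s$ linear in intensity.
- **Ellipse fit.** Second central moments (the equivalent ellipse), not
  boundary least squares: it is parameter-free, exact for filled
  ellipses, and degrades gracefully to the documented degeneracies
  (fewer than 3 pixels, collinear sets). Note that *perfectly* parallel
  continuous fibers produce an exactly line-shaped binarized spectrum,
  for which $r$ is genuinely undefined — the fit raises the degeneracy
  error rather than inventing a number. Any dispersion, fragmentation or
  noise (i.e. any realistic image) removes the degeneracy. Equal
  eigenvalues report orientation 0° by convention.
- **Windowing.** No window by default (matching a plain transform of the
  selected region); a Hann taper is available for user data with strong
  edge leakage.

## The synthetic phantom: what it emulates, and what it does not

`fiberPhantomConfig()` describes a tendon-like field: straight fibers
(tendon fibers are straight at the 100-µm field scale; curvature would be
a config extension) with a Gaussian cross profile ($\sigma$ = 2.5 px),
orientation drawn per fiber from a normal around the mean angle,
rendered by maximum composition, on a default 512 × 512 frame covering
100 × 100 µm (0.195 µm/px). Three structured degradations mirror what
SHG shows in real tissue:

- **Punctate fragmentation** — fixed-length segments (24 px) along each
  fiber are blanked independently with probability `punctateFraction`
  (default 0.5). This is the single-knob model of the fragmented, dashed
  appearance of weakly cross-linked fibers. Blanking uniforms are drawn
  once per geometry seed and thresholded at render time, so lowering the
  fraction (more cross-linked) restores a *superset* of fragments —
  before/after pairs change where the physics says they should, nowhere
  else.
- **Inter-bundle gaps** — periodic dark bands parallel to the mean fiber
  direction (period 128 px, width 16 px).
- **Dark patches** — random discs of radius 0.15 × frame covering an
  expected fraction of the frame (the disc count is Poisson-corrected
  for overlap). The radius is chosen large relative to the 16-px cells
  so patches are interior- rather than boundary-dominated and a nominal
  coverage translates into a comparable dark-cell fraction.

The background is `noiseMean` (default 3 × `noiseSd`) plus Gaussian noise
of SD `noiseSd` (default 30 at fiber amplitude 1000), clipped at zero and
rounded to integer counts. The explicit offset models the detector
baseline of real acquisitions; without it, more than half the background
would clip to exactly zero and median-based noise estimation would
degenerate. Geometry and noise have separate seeds so a before/after
pair can share fiber geometry (the same tissue region) while observing
independent noise, as consecutive acquisitions do.

Stacks share one geometry; slices differ by a small jitter of the
fragment phase (z decorrelation of the punctate pattern) plus fresh
noise. The default stack is 31 slices at a 0.5 µm step — a 15 µm axial
span.

**Effects.** `effectSpec("crosslinking")` (punctate −0.2, amplitude
×1.25, gap width +8 px) raises all three parameters by tens of percent;
`effectSpec("wet_damage")` (dispersion +30°, dark-patch coverage +0.3)
lowers all three. The effect sizes were set so simulated percent changes
land in the same order of magnitude as e-beam effects observed in real
tendon — an emulation of the direction and rough scale of the phenomenon,
not a reproduction of any specific measurement.

**What passing tests show — and don't.** The phantom validates the
pipeline's geometry, invariances and sign behavior with known ground
truth. It does not model SHG image formation (no optical PSF, no
$\chi^{(2)}$ physics, no speckle), fiber curvature or crossing bundles,
or the intensity statistics of real detectors beyond
offset + Gaussian noise. Agreement on phantoms is therefore evidence of
a correct implementation, not of biological validity on any particular
tissue.

## Numerical and degenerate-input behavior

- Integer-valued stacks round-trip TIFF I/O exactly (16-bit container);
  other data use a 32-bit container with a power-of-two scale recorded in
  the JSON sidecar, round-tripping to better than 1e-9 relative error.
- The FFT spectrum agrees with a direct DFT summation to ~1e-14 relative
  on 32 × 32 inputs (asserted at 1e-9 in the tests).
- Angular-profile ties go to the smaller angle; profile bins are 1°
  (180 bins) by default, bounding quantization error well inside the 2°
  recovery tolerance.
- Degenerate inputs follow documented contracts: constant image → flagged
  zero spectrum, error on binarization; all-zero image → threshold 0,
  $I_d = 0$, fully dark grid; ROI outside the image, sub-16-px ROI, or a
  sub-3-pixel/collinear spectrum mask → errors; both group SDs zero with
  equal means → $t = 0$, $p = 1$; with unequal means → $p = 0$ with a
  degeneracy flag.

## Problem sizes used in validation

The shipped validation runs single-slice pairs at the default 512-px
frame for the directional-fidelity study (20 seeded pairs per effect;
the spectral region of interest is the centered 256-px square), 256-px
single-orientation phantoms for recovery checks, and 32 × 32 images for
the DFT oracle. These sizes give stable statistics for every claim being
checked while keeping a full validation run in the order of a minute;
all of them are configuration values, and nothing in the implementation
is specific to them.

## Known limitations

- The noise-threshold default assumes background-majority frames (see
  above); fiber-dominated fields need a fixed threshold.
- $r$ is undefined for mathematically perfect parallel texture
  (line-shaped spectrum) and the package treats it as a degeneracy
  rather than reporting an arbitrary large value.
- Orientation analysis reports a single preferred angle per cell;
  crossing-fiber decomposition is out of scope.
- The t test assumes approximately normal group changes; with n of 3–4
  per group this is an assumption inherited from the experimental design,
  not something the package can verify.
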