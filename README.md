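# ftshg

Quantitative Fourier-transform analysis of second-harmonic generation
(SHG) micrographs of fibrillar collagen.

SHG microscopy images fibrillar collagen (type I) with high specificity,
and spatial Fourier analysis of those images ("FT-SHG") turns fiber
texture into a handful of scalar parameters that can be compared across
conditions — for example before and after a tissue sample has been exposed
to an electron beam, where increases indicate cross-linking of fibers and
decreases indicate structural damage. This package implements that
pipeline for anyone quantifying oriented fibrous texture in grayscale
images or z-stacks: microscopists comparing treatment conditions, and
methodologists who need a tested, synthetic-data-backed reference
implementation.

## The parameters

For each image slice:

- **Density `I_d`** — the image is tiled with 16 × 16-pixel cells; each
  cell scores the fraction of its pixels above the noise level, and `I_d`
  is the mean over the grid: `I_d ∈ [0, 1]`.
- **Peak spectral intensity `I_s`** — the 2-D Fourier magnitude spectrum
  of a selected region is integrated radially along rays at each
  orientation angle over [0°, 180°); `I_s` is the maximum of that angular
  profile. Stronger, more continuous alignment ⇒ larger `I_s`.
- **Anisotropy ratio `r`** — the spectrum is max-normalized, binarized,
  and fitted with its equivalent ellipse (second central moments);
  `r = α/β ≥ 1` is the ratio of the full major to minor axis. Isotropic
  texture gives `r ≈ 1`, parallel fibers give large `r`.

All three are averaged over a z-stack. Before/after change is expressed
in percent, `100 · (after − before) / before`, and groups of changes are
compared with the unpaired two-tailed Student's *t* test (pooled
variance, `df = n_A + n_B − 2`), which also runs directly from printed
summary statistics (mean ± SD, n).

A separate structure-tensor module classifies grid cells as
*anisotropic* (coherent orientation), *isotropic*, or *dark*, and reports
the preferred fiber orientation of each anisotropic cell — the
image-gradient counterpart to the spectral analysis.

A synthetic fiber-phantom generator (straight fibers with Gaussian cross
profile, controllable orientation dispersion, punctate fragmentation,
inter-bundle gaps, dark patches, background noise; full ground truth)
supports every test, including before/after pairs emulating
cross-linking-like and wet-damage-like change.

## Worked example

```r
library(ftshg)

## a simulated before/after pair: same tissue region, cross-linking-like
## change applied to the "after" image
cfg  <- fiberPhantomConfig(seed = 11)
pair <- simulatePair(cfg, effectSpec("crosslinking"))

roi    <- centeredRoi(pair$before, 256)       # region for Is and r
before <- summarizeStack(pair$before, roi = roi)
after  <- summarizeStack(pair$after,  roi = roi)
before
#> StackSummary over 1 slice(s): Id = 0.1679, Is = 3.44829e+07, r = 4.0453
after
#> StackSummary over 1 slice(s): Id = 0.2154, Is = 5.26293e+07, r = 5.7848

round(percentChange(before, after), 2)
#>   dId   dIs    dr
#> 28.27 52.62 43.00
```

All three parameters rise — denser coverage (`dId`), a stronger oriented
spectral peak (`dIs`), and a more elongated spectrum (`dr`) — the
signature of fibers becoming brighter and more continuous.

Group comparison runs straight from summary statistics. With one group of
percent changes at 10.14 ± 5.83 % (n = 3) against a control group at
−3.01 ± 1.64 % (n = 3):

```r
studentsTTest(10.14, 5.83, 3, -3.01, 1.64, 3)
#> GroupComparison (pooled t test)
#>   A: 10.14 +/- 5.83 (n = 3)   B: -3.01 +/- 1.64 (n = 3)
#>   t = 3.761, df = 4, p = 0.020
```

The difference is significant at p < 0.05.

Cell-wise orientation classification:

```r
om <- classifyCells(getSlice(pair$before, 1))
om
#> OrientationMap: 32 x 32 cells of 16 px
#>   anisotropic 256, isotropic 43, dark 725
preferredOrientation(om)   # coherence-weighted mean fiber angle, degrees
```

A thin command-line front end over the same functions ships in
`inst/scripts/ftshg-cli.R` (subcommands `simulate`, `density`,
`spectral`, `orient`, `pair`, `group`, `ttest`).

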