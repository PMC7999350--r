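---
title: "Depth-resolved PhC fluorescence profiling: methods and design"
author: "phcDepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved PhC fluorescence profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phcDepth)
```

## The measurement problem

Leaves stained with Naturstoff reagent A and excited with UV light emit
three separable fluorescence colors: red from chlorophyll (mesophyll
only — epidermal pavement cells lack chloroplasts), blue from cell-wall
phenolics, vascular bundles and sclerenchyma, and yellow from
flavonoid–reagent chelates. The quantity of interest is how the yellow
phenolic-compound (PhC) signal is distributed across the depth of the
mesophyll — from the adaxial (upper) to the abaxial (lower) surface — and
how cultivation conditions (barley variety, CO2 concentration, light
regime) shift that distribution. `phcDepth` turns a color micrograph of a
half-lamina cross-section into five layer means (AD, UM, MM, LM, AB) per
section, aggregates them over sections and biological replicates, and
tests treatment effects with a factorial fixed-effects ANOVA.

Fluorescence brightness is reported in relative "pixel brightness" units
on [0, 1]. No absolute calibration is possible (excitation light
penetrates tissue unevenly — the sieve effect — and no standard is imaged),
so all comparisons are relative and within-study.

## Pipeline, step by step

1. **Spectral separation** (`isolatePhC`, `channelMask`). Each pixel is
   converted to HSV. A channel keeps a pixel's *value* (max of R, G, B,
   scaled to [0, 1]) when its hue lies in the channel's closed window, its
   saturation is at least `sat_min` and its value at least `val_min`;
   otherwise the output is exactly 0. Defaults: yellow 30–90°, blue
   190–270°, red as the two wrap-around windows 330–360° and 0–30°, all
   with `sat_min = 0.2`, `val_min = 0.04`. Hue is the axis that separates
   the three emission colors; the value channel is used as the intensity
   metric (rather than the channel mean) so that pure-color identities are
   exact — a saturated yellow pixel (255, 255, 0) has intensity exactly 1.
   The thresholds cannot be derived from first principles: `sat_min`
   rejects near-grey noise whose hue is meaningless, `val_min` rejects
   pixels too dark for their hue to be reliable after 8-bit quantization.
   Both are deliberately permissive and exposed in the configuration.
   Whether the original image-editor selection also thresholded on
   brightness is unknowable; `val_min` is this package's choice.
2. **Tissue mask** (`detectTissue`). Brightness above `bg_threshold`
   (default 0.02, i.e. ~5/255 — above read noise, below any real
   emission), then the largest 8-connected component (dropping debris and
   specks), then a 3×3 morphological closing to fill pinholes.
3. **Mesophyll spans** (`mesophyllSpans`). Per image column, the mesophyll
   is the longest vertical run of chlorophyll-positive pixels, because
   chlorophyll fills the mesophyll and is absent from the epidermis. This
   is robust to magnification, unlike fixed pixel offsets. Gaps up to
   `gap_tolerance_px = 2` rows are bridged (intercellular air spaces);
   runs shorter than `min_span_px = 5` are invalid (degenerate margins).
4. **Vascular exclusion** (`vascularExclusion`). A column whose span has
   more than `vascular_frac = 0.15` blue-positive pixels is treated as
   vascular and excluded, and the excluded set is dilated by
   `dilate_cols = 3` columns per side to clear bundle sheaths. The midrib
   needs no separate detector: its sclerenchyma is blue-saturated, so its
   columns fail this test (or have no valid chlorophyll span at all).
5. **Systematic transects** (`placeTransects`). Five vertical transects at
   stride s = W/5 with a *single* shared offset u ~ Uniform(0, s), after
   trimming `edge_margin_frac = 0.03` of the width per side. One shared
   offset — not five independent ones — is what makes systematic uniform
   random sampling unbiased: every usable column has inclusion probability
   exactly n/W. Excluded nominal columns move to the nearest allowed
   column, ties toward the midrib. The margin default keeps transects off
   sectioning artifacts at the cut edges while discarding almost no
   lamina; the original protocol says only "near the midrib … near the
   edge", so the exact margin is a package choice.
6. **Depth binning** (`binProfile`). Pixel i of a length-L transect joins
   the layer containing its relative-depth midpoint,
   bin = floor(5(i − 0.5)/L) (0-based). This midpoint rule is symmetric
   under flipping the leaf and keeps bin counts within one pixel of each
   other for any L. For L < 5, empty bins inherit the nearest non-empty
   bin's value (ties toward the adaxial side) with a recorded count of 0.
7. **Aggregation** (`aggregateSection`, `aggregateReplicate`). Unweighted
   means over the 5 transects of a section and the 3 sections of a
   replicate. Unweighted is a real decision: the lamina thins toward the
   margin, so weighting transects by length would systematically
   re-weight marginal tissue. The replicate is the statistical unit —
   transects and sections are pre-averaged before any inference, avoiding
   pseudo-replication.
8. **Inference** (`anovaFixed`, `fisherLSD`, `classifyPattern`). Full
   factorial fixed-effects ANOVA over Var (2) × CO2 (3) × Light (2) ×
   Loc (5); for the balanced design all sums-of-squares types coincide,
   and unbalanced tables are rejected outright rather than silently fitted
   with a type-I/III choice. Fisher's LSD at α = 0.05 assigns letters so
   that two means share a letter exactly when they differ by at most the
   LSD; no further multiplicity correction is applied, matching common
   practice for this design. Loc is an unordered fixed factor even though
   layers are spatially ordered; trend modelling is out of scope. The LSD
   grouping can be run within each variety or pooled (`lsd_grouping`),
   since either convention is defensible.

## The synthetic generator and what it does (not) show

`renderSection` draws a half-lamina with known ground truth: a lamina
tapering from 78% of image height at the midrib to 50% at the margin,
5-px epidermis bands with faint blue walls (0.14) and no chlorophyll, a
blue-saturated midrib block, 3 vascular column groups, and a mesophyll in
which chlorophyll (0.55 ± 0.08 texture) and PhC emission occupy
*alternating pixel rows*. The interleave is deliberate: chlorophyll runs
stay continuous per column (gaps of 1 ≤ the gap tolerance) while PhC
pixels stay spectrally pure yellow, so the geometric and spectral parts of
the pipeline are exercised without confounding them through subpixel color
mixing. The cost is a uniform factor ≈ 1/2 on recovered layer means
(half the mesophyll pixels carry PhC signal); correlations, peak
locations and treatment ratios are unaffected.

The PhC depth gradient is the closed form

g(d) = s·[b + A_ad·e^(−d/λ) + A_ab·e^(−(1−d)/λ) + B·e^(−(d−0.7)²/(2·0.15²))],

the simplest family expressing both observed patterns: exponential
surface peaks (A_ad > A_ab, B = 0) for high-light or elevated-CO2 leaves,
and a lower-mesophyll Gaussian bump (B > 0, small surface peaks) for
low-light leaves at low/ambient CO2. Each shape is normalized to unit
depth-mean, so the scale s *is* the leaf's mean intensity; the HL:LL
scale ratio at low CO2 is 1.46 (the reported 46% light effect), and the
scale tables (LL 1.00/1.05/1.35, HL 1.46/1.48/1.55 for LC/AC/EC over a
reference mean of 0.25) make the HL−LL gap shrink with rising CO2 —
elevated CO2 partly substitutes for high light. The magnitude of that
substitution is only qualitatively constrained by observation, so the EC
multipliers are free configuration values, not measured ones. Bojos gets
a 1.08 boost under EC. Noise is Poisson shot noise at a 500-count full
well followed by Gaussian read noise of 2/255.

The diurnal model is piecewise linear (ramp 05:00–10:00, plateau to
15:00, ramp to 20:00, night exactly 0), whose trapezoidal integral
reproduces the cultivation daily integrals exactly: 54 and 14.4 mol
m⁻² day⁻¹ PAR, 144 and 27 kJ m⁻² day⁻¹ UV-A. Note the UV-A unit: with
maxima of 4 and 0.75 W m⁻², the daily integrals can only be of order
10⁴–10⁵ J; this package reports kJ m⁻² day⁻¹, the unit consistent with
the stated maxima.

What passing the recovery tests does **not** show: real micrographs have
mixed-hue pixels (overlapping emissions), uneven illumination, depth-
dependent excitation (sieve effect), stomata, trichomes and bulliform
cells, none of which the generator emulates. The synthetic suite
validates the estimator — spectral gating, geometry, sampling, binning,
aggregation, inference — not the biology of any particular image.

## Numerical and degenerate-input choices

* Hue intervals are closed; the red channel's wrap-around is two explicit
  windows rather than modular arithmetic, preserving the simple
  low < high invariant. Shared endpoints (hue exactly 30°) belong to both
  adjacent windows; with 8-bit inputs this affects a measure-zero set of
  colors.
* 16-bit inputs are linearly rescaled on load; all internal math is on
  [0, 1] with 8-bit quantization only at render/write time.
* Transect relocation chooses among not-yet-chosen columns, so the five
  columns are always distinct and strictly increasing.
* Ties: relocation ties break toward the midrib; empty-bin fill ties
  break toward the adaxial side; both are deterministic.
* A numerically constant ANOVA response reports F = 0, p = 1 for every
  term instead of 0/0.
* All randomness (offset draws, noise, simulations) flows from explicit
  seeds; batch runs derive one sub-seed per image from the global seed
  and the image identity, so adding images never perturbs existing ones.

## Validation scale

The shipped validation uses deliberately modest problem sizes chosen to
exercise every code path at full fidelity: 160 × 480 px sections (36 of
them for the 12-cell recovery study), 1000 Monte-Carlo offsets for the
unbiasedness check, 1000 null and 500 alternative tables for ANOVA
calibration, and exhaustive transect lengths 1–25 against the
hand-enumerated binning oracle. At 200 px of mesophyll the binning error
against analytic layer integrals is ~10⁻⁵, far below the 0.01 documented
bound.

## Known limitations

* Hue-window gating is not spectral unmixing; strongly overlapping
  emissions would need linear decomposition of emission spectra, which is
  out of scope.
* No flat-field or illumination correction; acquire accordingly.
* Single-page TIFF/PNG only; no z-stacks or paradermal views.
* The unbiasedness guarantee of systematic sampling holds for the offset
  distribution itself; relocation around excluded columns introduces a
  (small, local) deviation near vascular bundles that is not corrected.
* Sections and transects are pre-averaged; if per-section variance is of
  interest it must be extracted from the section-level output.
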