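---
title: "Methods: residual variograms, theta statistics and the sill threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual variograms, theta statistics and the sill threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanovario)
```

## The measurement model

An AFM scan of a histological section is a square raster of z-heights with
physical pixel size `scan_size_um / n_px` (97.66 nm for the canonical
50 µm / 512-point scan). The working hypothesis is second-order
stationarity: the mean and variance of the height field do not depend on
pixel position, so spatial structure is summarized by how the expected
squared height difference grows with the lag between pixel pairs. Tissue
texture differences of interest live at sub-micrometre scales, below the
resolution of optical histology.

The pipeline has four stages.

**1. Gaussian residual.** The field is smoothed by a separable Gaussian of
standard deviation σ (pixels), truncated at a box of exactly 6σ + 1 pixels
(nearest odd integer, ties upward), weights normalized to sum to one. σ = 5
px gives the 31 px kernel; with a 97.66 nm pixel the box spans ≈3 µm, which
is therefore the cut-off wavelength of the high-pass residual
`z − smooth(z)`. The smoother is implemented as banded operator matrices
(`S Z Sᵀ`), which keeps the truncation and boundary semantics exact rather
than inherited from a library default. The phrase "3D Gaussian filter" in
the AFM literature is interpreted as this 2D spatial filter applied to the
scalar z-field — a literal 3D convolution over a 2D grid is not computable.
Boundary handling is not standardized in the field; the default is
`reflect` (edge pixel repeated), which avoids the edge ramps that `wrap` or
zero padding would inject into the residual and hence into the sill.
No plane fit, line levelling or scar removal is applied: levelling is a
low-order component that the residual subtracts anyway, and silently
altering the input would make sills irreproducible across tools.

**2. RMS-deviation variograms.** For each signed lag h = (v, p),
`D(h) = sqrt(mean((z(x, y) − z(x+v, y+p))²))` over all in-bounds pairs,
covering all four sign quadrants; the pair set of (v, p) equals that of
(−v, −p), so the 2D map is exactly centrosymmetric, and
`N(v, p) = (n−|v|)(n−|p|)`. Although the defining sums are sometimes
printed without the radical, the quantity is a *root* mean square deviation
reported in µm; the square root is therefore applied. The radial (1D)
variogram pools squared differences from all directions into bins of
|h| = √(v²+p²), pair-count weighted, so each bin's base value B(h) is the
grand mean squared difference of its pairs. Generalized moments are
`γ(h, q) = B(h)^q`. Two unit conventions coexist: q = 0.5 gives the RMS
deviation D in length units (what sill plots in µm show), q = 1 the plain
variogram in µm². Both are exposed; the per-lag identity
`γ(h, q) = γ(h, 1)^q` means the moments add no per-lag information — their
classification value arises from the nonlinear interaction of the power
transform with plateau averaging and group thresholds.

The per-lag sums are computed by FFT cross-correlation plus exact prefix
sums of z² (the field is mean-centred first, which suppresses the DC term
that dominates FFT roundoff); a direct shifted-slice route is kept as a
slower exact alternative and the test suite verifies both against an
all-pairs double loop at 1e−12 relative tolerance. Residual FFT noise in D
is of order √ε ≈ 1e−8 absolute, visible only where the true value is
exactly zero.

**3. Sill estimation.** The sill — the plateau value where spatial
correlation has died out — is estimated as the pair-count-weighted mean of
γ over the trailing 30% of the lag domain (`plateau_fraction = 0.3`).
Defaults: bin width 1 px (bins centred on integer radii, nugget limit at
1 px), maximum lag n/4 px, which keeps ≥75% pair overlap per lag and
comfortably spans the flattened regime. A weighted slope is fitted over the
plateau window; if the relative change across the window exceeds
`slope_cap = 0.25` the estimate is flagged `rising` (tilted planes and
other drifting fields never flatten) rather than erroring. The procedure is
deliberately the simplest deterministic reading of "the variogram flattens
off"; absolute sill values depend on the binning and plateau choices, so
cross-study comparisons should fix them.

**4. Threshold classification.** Per-sample sills at a chosen q give two
labelled groups; the threshold is the median of the two group means (their
midpoint for two groups — the rule generalizes to the median if more groups
are ever configured). Samples above are called non-metastatic-like, below
metastatic-like; exact ties go to non-metastatic (conservative toward
follow-up screening) and are flagged. Calls are scale-equivariant: rescaling
all sills rescales the threshold and changes nothing else. Group separation
is reported two ways: `separation = (mean_nm − mean_m)/mean_m`, the
quantity that provably grows with q when the groups are disjoint (the
ratio of group power-means is increasing in q), and `cohen_d`, the gap in
pooled-sd units. The t-test defaults to Welch (unequal variances, unequal
group sizes such as 11 vs 7); Student's pooled variant is available.
Per-moment p-values are reported uncorrected by default, with an optional
Bonferroni factor over the sweep.

A property worth knowing: at high q the power transform is so convex that
the largest within-group sill dominates its group mean, which can drag the
midpoint threshold past smaller same-group samples. Borderline samples can
therefore flip sides as q grows — in either direction, depending on which
group's spread dominates.

## Theta statistics

Each interior pixel is treated as a tiny planar facet with inclination
θ = arctan |∇z| (degrees), ∇z from central differences scaled by the pixel
size; a k × k least-squares plane-fit facet is available
(`facet_px = k`), with 1-pixel facets as the default — the smallest facet
consistent with the idea. Angles enter skewness and excess kurtosis
(Fisher convention, normal = 0) as a raw sample, never via the histogram.
θ is invariant to z-offsets and equivariant under z-rescaling
(θ′ = arctan(k·tan θ)). On the phantoms, the smooth class concentrates
angles near zero with a long right tail, so its skewness exceeds the rough
class's — the same marker direction as the tissue motivation. This is a
property of the phantom construction, not a universal law; on real data the
sign depends on texture regularity, which is why the sign-based
`theta_call()` is documented as a secondary marker with an explicit
agreement rate.

## Baseline battery

* **Surface statistics** — moments of the z-sample (population
  conventions), channel-agnostic so phase rasters reuse them.
* **Rescaled range.** Classic R/S with dyadic windows from 8 to length/4,
  least-squares slope on log2–log2 points. Two image schemes: the
  row-concatenated n² series, and per-line fits whose mean and distribution
  are reported. R/S presumes a stationary increment series, so profiles are
  differenced first (`difference = TRUE`); on raw self-affine profiles the
  statistic saturates near 1 regardless of the true exponent. Single rows
  are short series, for which raw R/S is biased upward; per-line fits
  therefore default to the Anis–Lloyd small-sample correction (slope of the
  excess over the iid expectation, plus 0.5), while long series keep the
  uncorrected classic statistic. On spectrally synthesized (periodic)
  surfaces the concatenated scheme is additionally biased low at windows
  beyond the row length, because cumulative sums close on themselves each
  period; the two schemes are expected to disagree.
* **Monofractal dimension.** Four standard estimators, each a log–log fit
  over dyadic scales: cube counting `N(ℓ) ∝ ℓ^(−D)`, triangulated area per
  unit projected area `A(ℓ) ∝ ℓ^(2−D)`, radial PSD slope
  (`D = 3 − H`, `H = (β−2)/2`), and partition (mean within-block variance
  `∝ ℓ^(2H)`). The metric estimators depend on the z-aspect convention, so
  the height range is mapped to `z_aspect` (default 8) times the lateral
  extent before counting, which keeps the fit in the slope-dominated regime
  where the D = 3 − H law holds. Default fit ranges are 2…n/4 px, except
  cube counting, which starts at max(2, n/32) px: at the smallest scales the
  extreme-value inflation of block relief (max − min over a block grows
  with the block's point count faster than the increment scale) flattens
  the count curve and pulls D toward 2, a bias visible on synthetic fBm.
  Estimates are clamped to [2, 3] with a flag. Validation is against the
  D = 3 − H relation on generated fBm surfaces, where prototyping at
  n = 256, H = 0.5 gives ≈2.51 (triangulation), ≈2.38 (cube counting),
  ≈2.54 (power spectrum), ≈2.49 (partition).

## The synthetic generator

`generate_surface()` is seed-deterministic (identical spec ⇒ bit-identical
surface) and covers analytic fixtures (constant, plane, sine ridge, white
noise), spectrally synthesized fBm (`P(f) ∝ f^(−2H−2)`, chosen precisely so
the power-spectrum estimator has a known ground truth), and two-class
tissue phantoms. A phantom is a sum of:

* a large-scale relief — Gaussian-correlated field, 10 µm correlation
  length, RMS `amplitude_um` (default 1 µm) — shared in distribution (and,
  at fixed seed, in realization) between the classes; and
* fine texture of RMS `fine_texture_rms_um` (default 0.5 µm for the rough,
  non-metastatic-like class; divided by `contrast = 2` for the smooth,
  metastatic-like class): 95% of its variance is Gaussian speckle of 0.6 µm
  correlation length and 5% white noise.

The fine texture sits entirely below the ≈3 µm residual cut-off, so the
class contrast lives exactly in the band the Gaussian residual isolates.
The speckle-dominated mix is what makes sills invariant across resolutions
at fixed σ in µm: block-mean decimation preserves variance at correlation
lengths of a few coarse pixels, whereas pure white texture would lose 4× of
variance per decimation level and break the invariance. Cohorts add a 10%
lognormal between-sample jitter on the fine-texture RMS, giving realistic
within-group spread, and label smooth phantoms metastatic / rough phantoms
non-metastatic with `m{i}.{j}` / `nm{i}.{j}` ids.

What the phantoms do *not* emulate: cell morphology, nuclei, ECM fibres,
staining artefacts, scanner drift, or any specific tissue statistics beyond
second-order texture. Passing tests on phantoms show the pipeline measures
what it claims on fields with known structure — not that any particular
clinical threshold transfers to real tissue.

## Problem sizes and numerical choices

Analyses in the test suite and the acceptance script use sizes chosen to
exercise each property at sufficient statistical power while staying quick:
end-to-end cohorts of 11 + 7 samples at 256 px (the generator default
remains the canonical 512 px / 50 µm geometry), fBm checks at 256 px over
10 seeds, resolution-invariance on native 512 px phantoms, oracle
equivalence on ≤32 px rasters. Degenerate inputs are handled explicitly:
constant fields give zero residuals, zero variograms, D = 2 for metric
fractal estimators and an error for the PSD method; zero-variance R/S
windows are skipped; empty variogram bins are kept but excluded from sill
estimation; a classifier with both groups at zero variance flags its
p-value as undefined rather than fabricating one.

Known limitations: absolute sill values depend on binning, maximum lag and
plateau choices, so only within-configuration comparisons are meaningful;
the facet definition underlying theta statistics is the minimal 1-pixel
one; fractal estimates on self-affine surfaces are convention-dependent
(z-aspect) and cube counting carries a documented residual negative bias;
and the phantom parameters are modelling choices, not fitted tissue values.
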