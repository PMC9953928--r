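# nanovario

Variogram-based nanoscale texture analysis of AFM rasters of histological
sections.

## What it is for

Atomic force microscopy images a histological section as a height raster
z(x, y) with ~100 nm lateral resolution (a 50 µm × 50 µm scan at 512 × 512
points has a 97.66 nm pixel). At that scale, tissue whose cells retain an
epithelial phenotype shows fine, complex surface texture, while tissue rich
in motile, mesenchymal-like (metastasis-prone) cells is smoother. `nanovario`
turns that difference into a numeric index:

1. **Gaussian residual.** The height field is smoothed with a truncated
   Gaussian (kernel box 6σ + 1 px; σ = 5 px gives the canonical 31 px
   kernel). The residual `z − smooth(z)` is a high-pass field carrying the
   sub-kernel-scale roughness.
2. **RMS-deviation variograms.** For a lag vector h = (v, p) the RMS
   deviation is

   D(h) = √( (1/N) Σᵢⱼ [z(xᵢ, yⱼ) − z(xᵢ₊ᵥ, yⱼ₊ₚ)]² ),

   over all N = (n−|v|)(n−|p|) in-bounds pixel pairs. Pooling squared
   differences over radial bins of |h| = √(v² + p²) gives the empirical
   variogram; its **sill** — the plateau where spatial correlation dies out —
   is the per-sample texture index. Generalized moments γ(h, q) = B(h)^q
   (B the binned mean squared difference; q = 0.5 is exactly D) stretch the
   contrast between groups.
3. **Threshold classification.** The threshold is the midpoint of the two
   group-mean sills; samples above it are called non-metastatic-like, below
   it metastatic-like. Group separation is tested with a Welch t-test.
4. **Theta statistics.** The skewness/kurtosis of the facet inclination
   distribution θ = arctan |∇z| serve as a secondary marker.
5. **Baseline battery.** Surface statistics, two rescaled-range Hurst
   schemes and four monofractal dimension estimators (cube counting,
   triangulation, power spectrum, partition) are provided for comparison.

Because real patient rasters are not redistributable, the package ships a
seed-deterministic generator of analytic fixtures, fractional Brownian
surfaces of known Hurst exponent, and two-class tissue phantoms whose
fine-texture contrast emulates the metastatic/non-metastatic difference.

## Worked example

```r
library(nanovario)

# simulate an 18-sample two-class cohort (50 µm scans, 256 × 256 px)
cohort <- generate_cohort(11, 7, surface_spec("phantom_rough", n_px = 256),
                          seed = 42)

# residual variogram sills for q = 0.5 … 5 and the threshold sweep
sills <- cohort_sills(cohort, vario_config())
sweep <- moment_sweep(sills)
sweep[, c("q", "threshold", "separation", "p_value", "n_correct")]
#>       q threshold separation    p_value n_correct
#> 1   0.5  0.351          1.01 0.00000111        18
#> 2   1    0.139          3.01 0.0000381         18
#> 3   2    0.0271        14.6  0.000699          17
#> 4   3    0.00614       57.8  0.00335           17
#> 5   4    0.00148      214.   0.00936           15
#> 6   5    0.000365     763.   0.0190            15

fit <- fit_threshold(dplyr::filter(sills, moment_q == 1), q = 1)
fit
#> <sill_classifier> q = 1: threshold 0.1385 (met mean 0.05525, non-met mean 0.2218)
#>   18/18 labelled samples called correctly; welch p = 3.81e-05
head(tidy(fit), 4)
#>   sample_id label        sill call       tied  correct
#> 1 m1.1      metastatic 0.0363 metastatic FALSE TRUE
#> 2 m1.2      metastatic 0.0715 metastatic FALSE TRUE
#> 3 m1.3      metastatic 0.0546 metastatic FALSE TRUE
#> 4 m1.4      metastatic 0.0394 metastatic FALSE TRUE
```

Reading the output: at every moment q the non-metastatic-like (rough) group
mean sill sits above the metastatic-like (smooth) one, the relative
separation `(mean_nm − mean_m)/mean_m` grows monotonically with q (from 1.0
at q = 0.5 to ≈760 at q = 5), and the q = 1 midpoint threshold classifies
all 18 samples correctly with Welch p ≈ 4 × 10⁻⁵. `n_correct` can drop at
high q because the convex power transform lets the largest within-group sill
dominate its group mean and drag the midpoint threshold past smaller
same-group samples.

Single-raster tooling works the same way:

```r
m   <- cohort$map[[1]]
res <- gaussian_residual(m, filter_spec(sigma_px = 5))
estimate_sill(radial_variogram(res))
#>    sill lag_lo_um lag_hi_um method       moment_q rising
#> 1 0.190      8.79      12.4 plateau_mean      0.5 FALSE
```

`autoplot()` renders height maps, 2D deviation maps, variogram curves,
theta spectra and classifier threshold plots. Rasters travel as plain text
or float TIFF with a YAML sidecar (`read_raster()` / `write_raster()`), and
cohorts as a CSV manifest (`write_cohort()` / `read_cohort()`). A thin
command-line front end lives at `inst/cli/nanovario.R`
(`simulate`, `run`, `variogram` subcommands).

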