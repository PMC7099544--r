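# icfhpf

High-pass filtering of 2D grayscale images through the
**intensity-curvature functional (ICF)** of the bivariate cubic B-spline
model polynomial function, with the comparison machinery a study of such
filters needs: a traditional convolutional high-pass filter (HPF), a
particle-swarm-optimization (PSO) filter, k-space magnitude analysis,
inverse-Fourier reconstruction, difference maps, Gaussian histogram
summaries, and synthetic MRI-like phantoms. It is aimed at researchers in
medical image analysis who want a reproducible, testable implementation of
curvature-based filtering to compare against conventional spatial and
spectral filters.

## The model

At every pixel the image is modelled by the bivariate cubic B-spline

```
h4(x, y) = f(0,0) + α3·[½ s³ − s² + ⅔] + α2·[−⅙ s³ + s² − 2s + 4/3],   s = x + y,
```

where `f(0,0)` is the pixel intensity and `α2 = f(0,0) − f(½, ½)`,
`α3 = f(0,0) − f(−½, −½)` are diagonal finite differences. Two
*intensity-curvature terms* integrate intensity × classic-curvature (the
sum of the four second partials of `h4`) over the pixel: before
interpolation,

```
E0(x, y) = 4xy · f(0,0) · (−2α3 + 2α2),
```

and after interpolation, `EIN(x, y) = ∫∫ 4·h4·[α3(3s−2) + α2(−s+2)] dx dy`
in closed form. Their ratio `ΔE = E0/EIN` is the ICF image; the filter's
transfer function is `TF = ΔE / f(0,0)`, with input/output functions

```
y[n] = x[n]·e12 / [4(x[n]·α3·e1 + x[n]·α2·e2) + ω],
x[n] = ω·y[n] / [e12 − 4y[n]·(α3·e1 + α2·e2)],
```

built from closed-form polynomial terms `e1…e12, ω`. Writing
`ΔE = f·ζ / (f·γ + λ)` with `ζ = e12`, `γ = 4(α3 e1 + α2 e2)`, `λ = ω`,
the numerical prevalence of `(ζ, γ, λ)` over `f(0,0)` decides whether the
ICF looks like the departing image (*image-like*) or like a high-pass
filtered signal (*gradient-like*); `classify_icf_behavior()` implements
the full characterization table.

## Worked example

```r
library(icfhpf)

img <- synth_image(synth_spec("sphere"))      # 128x128 spherical light source
res <- icf_image(img)
res
#> ICF result: 128 x 128 pixels, evaluation point (1, 1), canonical mode
#>   delta_e range [-152.347, 2549.12], 7870 degenerate pixels (48.0%)

# On the smooth phantom the pixel intensity prevails:
lab <- classify_icf_map(img, factor = 10)
mean(lab == "image-like")
#> [1] 0.5736084

# Attenuating two of every three diagonals reverses the prevalence:
gd  <- gradient_dominant_variant(img, 100)
rgd <- icf_image(gd)
lgd <- classify_icf_map(gd, factor = 10)
mean(lgd[!rgd$degenerate] == "gradient-like")      # 0.667
lowfreq_energy_fraction(gd)                        # 0.346  (original)
lowfreq_energy_fraction(rgd$delta_e)               # 0.0166 (ICF)
lowfreq_energy_fraction(traditional_hpf(gd))       # 4.4e-06 (traditional HPF)
```

The degenerate pixels are those with flat diagonal neighbourhoods (zero
curvature denominator), set to zero like any HPF's response to constant
input. The low-frequency energy fractions are the operational high-pass
check: both the ICF image and the convolutional HPF hold far less of
their spectral energy near DC than the image they filtered.

The full pipeline — filtered images, transfer functions, k-space
magnitudes, pairwise difference maps, reconstructions, histogram
summaries, and a hashed JSON manifest — runs with:

```r
out <- run_comparison(run_config(synth_spec("sphere"),
                                 filters = c("icf", "traditional", "pso"),
                                 output_dir = "comparison", seed = 1))
```

A command-line front end with `synth`, `filter`, `kspace`, `reconstruct`,
`stats` and `compare` subcommands is installed at
`system.file("cli", "icfhpf.R", package = "icfhpf")`.

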