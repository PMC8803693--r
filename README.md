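# ecoplateR

Kinetic community-level physiological profiling (CLPP) of Biolog®
EcoPlate™ optical-density time series, with a biodegradability model for
landfilled solid waste.

## The problem

Biolog EcoPlates expose a microbial community to 31 single carbon sources
(plus a water blank), each in triplicate, on a 96-well plate. Respiration
on a substrate reduces a tetrazolium dye; the optical density at 590 nm,
read repeatedly over several days, traces a growth-like curve per
substrate. The common summary of such plates — average well colour
development (AWCD) — throws away both the kinetics and the substrate
identity. `ecoplateR` instead keeps the full kinetic signal:

1. **Preprocess** — per sample and time point, subtract the mean blank,
   clip negative values to 0, average the technical replicates, and (for
   solid samples only) impute a missing replicate reactor as the
   element-wise mean of its siblings.
2. **Kinetics** — anchor each curve at (0 h, 0 OD), interpolate with a
   natural cubic spline on a 100-point grid over 0–96 h (later reads
   support the spline but the grid stops at 96 h), and fit the Gompertz
   growth model in the Zwietering parametrization

   `y(t) = A · exp(−exp( (μ·e/A)·(λ − t) + 1 ))`

   with asymptote `A` (OD), maximum slope `μ` (OD/h) and lag time `λ` (h),
   by Levenberg–Marquardt least squares from a heuristic start. The
   per-substrate activity statistic is the **area under the curve** over
   0–96 h (OD·h): from the fitted Gompertz curve when the fit converges
   with `λ ≥ 0`, from the spline itself when `λ < 0` or the fit fails
   (curves already past their inflection at the first read), and exactly 0
   for wells with no colour development at all.
3. **Profile** — sum AUCs into five substrate guilds (amines, amino
   acids, carbohydrates, carboxylic acids, polymers), scale each reactor ×
   guild series to its day-0 baseline, and min–max normalize variables to
   [0, 1].
4. **Infer** — an ordinary least squares model linking the four-day
   respiration index RI₄ (mg O₂ kg⁻¹ dry weight, the standard aerobic
   biodegradability proxy for solid waste) to the normalized guild
   activities:

   `RI4 = β₀ + β_carb · Carbohydrates + β_poly · Polymers`

   plus the treatment/time comparisons: Levene + Shapiro preconditions,
   one-way ANOVA with Tukey HSD and a compact letter display, and
   Wilcoxon rank-sum tests (solid vs. leachate sampling) with star
   encoding.

A synthetic-data generator emulates the experiment these methods were
built for — nine landfill simulation reactors in three aeration
treatments (aerobic / mixed / anaerobic), sampled at days 0, 57, 114, 358
and 763 in solid and leachate matrices, with one missing solid replicate —
so every stage can be exercised and validated end to end without any
external data.

## Worked example

```r
library(ecoplateR)

sim <- generate_experiment(generator_config(seed = 42))
sim
#> Synthetic EcoPlate experiment (seed 42):
#>    71 samples, 34080 well readings, 36 RI4 records
#>   classes: negative_lag 354, normal 1639, zero 239

run <- run_pipeline(sim$plate, sim$ri4)
run
#> CLPP pipeline run
#>   samples: 72  curves: 2232
#>   outcomes: gompertz=1654, spline_fallback=393, zero=185
#>   cleaning: clipped 3949 values, imputed 1 sample(s)
#> Biodegradability model (OLS on min-max normalized scales):
#>   RI4 = 0.359 +0.525 * Carbohydrates -0.399 * Polymers
#>   adjusted R^2 = 0.719, n = 36
#>   p-values: (Intercept) = 7.41e-09 ***; carbohydrates = 5.04e-09 ***; polymers = 0.000171 ***

head(run$tables$success_table, 4)
#>   treatment day n_success n_total percent
#> 1   aerobic   0        74      93    79.6
#> 2   aerobic  57        67      93    72.0
#> 3   aerobic 114        70      93    75.3
#> 4   aerobic 358        70      93    75.3
```

Reading the output: of the 71 measured samples (the 72nd is the imputed
missing solid replicate), each contributes 31 substrate curves. Most
curves are integrated through a converged Gompertz fit; curves that were
already past their inflection at the first 24-h read fall back to the
spline integral, and dead wells integrate to exactly 0. The success table
counts Gompertz successes per treatment × day over the measured solid
samples (93 curves for three reactors, 62 where one sample is missing).
The regression links the normalized RI₄ of the 36 solid samples to their
normalized carbohydrate (positive) and polymer (negative) guild
activities; under the generator's default noise the fitted slopes are
attenuated relative to the noise-free generative values because min–max
normalization of a noisy response inflates its range.

`write_run(run, "out/")` writes all result tables as schema-headed CSV
plus the model summary and a digest manifest; `read_result_table()` reads
them back losslessly.

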