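# ntcpct

CT-based dose–response modelling of radiation-induced lung density change.

## The problem

Stereotactic body radiotherapy (SBRT) deposits a steep dose gradient around
a lung target, so a single patient's follow-up chest CT contains tissue
exposed to everything from ~0 Gy up to the prescription dose. The local
increase in CT Hounsfield units (HU) after treatment — inflammation early,
fibrosis late — is a graded, objectively measurable surrogate of
radiation-induced lung injury. Plotting the pixel-wise HU change against
the pixel-wise planned dose yields a full, patient-specific dose–response
curve from a single scan pair.

`ntcpct` implements that measurement pipeline and the statistical layer on
top of it, for researchers in radiation oncology / medical physics:

1. **Imaging**: lung segmentation by HU thresholding and morphological
   cleanup; 3D rigid registration of the follow-up CT to the planning CT by
   normalized cross-correlation (coarse-to-fine pyramid, exhaustive coarse
   translation search plus simplex refinement); nearest-neighbour mapping
   of the planned dose grid into follow-up space.
2. **Dose–response extraction**: pixel-wise ΔHU inside the lung mask,
   binned into 6-Gy bins from 0–60 Gy, normalized per patient to the
   maximal bin, and optionally pooled across patients.
3. **NTCP model fitting and comparison**: bounded nonlinear least squares
   of four classical normal tissue complication probability (NTCP) models,
   all parameterized by `D50` (dose of half-maximal response, Gy) and
   `gamma50` (normalized slope at `D50`):

   | model   | P(D) |
   |---------|------|
   | Lyman   | `0.5 (1 − erf[γ₅₀ √π (1 − D/D₅₀)])` |
   | Logit   | `1 / (1 + (D₅₀/D)^(4 γ₅₀))` |
   | Weibull | `1 − exp[−ln2 · (D/D₅₀)^((2/ln2) γ₅₀)]` |
   | Poisson | `2^(−exp[e γ₅₀ (1 − D/D₅₀)])` |

   Fits are compared by SSR, adjusted R², AIC and BIC, with an
   extra-sum-of-squares F test for fit significance and one-way ANOVA for
   cross-model differences in the fitted parameters.
4. **Robustness**: a registration-error sensitivity experiment that
   perturbs the registration by ±`shift_mm` (default 3 mm) along each
   anatomical axis and reports the maximal percent change of `D50` and
   `gamma50` — quantifying the finding that `D50` is robust to registration
   error while `gamma50` is highly sensitive to it.
5. **Synthetic phantoms**: a seeded generator of thoracic CT pairs
   (air/body/lung compartments with HU noise), SBRT-like dose blocks with a
   sharp radial falloff, known rigid mis-alignments and a known ground-truth
   sigmoid HU response, so every stage is testable without patient data.

## Worked example

Simulate a misaligned phantom, run the full pipeline, and compare models:

```r
library(ntcpct)

cfg  <- phantom_config(misalignment = rigid_transform(translation = c(4, -2, 3)),
                       seed = 42)
pair <- generate_ct_pair(cfg)            # planning CT, follow-up CT, dose block

mask <- segment_lungs(pair$followup, min_component_volume = 10000)
reg  <- register_rigid(pair$planning, pair$followup, translation_only = TRUE)
round(reg$par, 3)
#> 4.031 -2.009 3.017        # the simulated (4, -2, 3) mm shift, recovered

dose_f <- map_dose_to_followup(pair$dose, reg$transform, pair$followup)
delta  <- compute_hu_change(pair$followup, pair$planning, reg$transform)
curve  <- normalize_curve(bin_curve(delta, dose_f, mask, patient_id = "phantom"))

report <- compare_models(curve)
report$ranking
#> <model_ranking>
#>    model   d50 gamma50       ssr adj_r2     aic     bic rank_ssr rank_adj_r2 rank_aic rank_bic
#>  weibull 35.33   1.382 0.0001744 0.9999 -105.57 -104.96        1           1        1        1
#>    lyman 35.19   1.401 0.0003849 0.9997  -97.65  -97.05        2           2        2        2
#>    logit 34.56   1.497 0.0068464 0.9942  -68.87  -68.26        3           3        3        3
#>  poisson 34.31   1.481 0.0084802 0.9928  -66.73  -66.12        4           4        4        4
#> consensus best model: weibull
```

All four models recover the phantom's ground truth (`D50 = 35.29` Gy,
`gamma50 = 1.35`, Lyman-generated) to within a fraction of a dose bin; the
ranking columns show each criterion agreeing on the winner. The fitted
response is overwhelmingly better than a flat (no-response) null:

```r
sig <- fit_significance_anova(report$fits$lyman)
#> F(1, 8) = 31389.4, p = 1.2e-15
```

The registration-robustness experiment (±3 mm shifts on a steep-gradient
phantom) reproduces the headline asymmetry — `gamma50` is an order of
magnitude more sensitive to registration error than `D50`:

```r
rob <- run_shift_experiment(pair$planning, pair$followup, pair$dose,
                            reg$transform, mask = mask)
c(rob$d50_error_max_pct, rob$gamma50_error_max_pct)
```

A thin command-line front-end over the same functions lives at
`inst/cli/ntcpct.R` (subcommands `simulate`, `analyze`, `robustness`,
`fit-curve`).

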