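# aposcan

Tools for testing whether warning coloration honestly advertises
chemical defence, for researchers in sensory ecology and predator–prey
signalling. The package models prey coloration through an avian (blue
tit) visual system, quantifies defence with Daphnia bioassays, analyses
field predation on artificial prey, and ties the three together in the
headline "signal honesty" regressions — with a synthetic world generator
(known ground truth) so every stage can be checked by parameter
recovery.

## The models at the core

**Quantum catch.** For reflectance R(λ), illuminant I(λ) (CIE D65) and
receptor sensitivity S(λ):

    q = ∫ R I S dλ / ∫ I S dλ

so a perfect reflector has q = 1 in every channel.

**Receptor-noise-limited discriminability.** With Δf_i = ln(q_i(a)/q_i(b))
and channel noise ω_i = ν·√(η_max/η_i), the chromatic distance in "just
noticeable differences" (JND) is the noise-weighted quadratic form

    ΔS² = Δf' (D⁻¹ − D⁻¹11'D⁻¹ / 1'D⁻¹1) Δf ,   D = diag(ω²)

which equals the classical pairwise tetrachromat formula (kept in the
package as an independent oracle). Luminance contrast uses the double
cone: ΔL = |ln(q_dbl(a)/q_dbl(b))| / ω_dbl. Values ≲1–3 JND are at the
discrimination threshold.

**Calibration.** Raw 8-bit images are linearised per channel against
Spectralon grey standards (power-law fit raw = a·linearᵇ), normalised to
the 40% standard, and mapped to predicted cone catches by polynomial
least squares over the camera channels.

**Toxicity.** Mean dead Daphnia at 3 h across a 7-point dilution series,
log-transformed as ln(mean+1); LC50 by binomial GLM on log-dose.

**Survival.** Kaplan–Meier (product-limit, Greenwood variance) and Cox
proportional hazards (Breslow partial likelihood, transect as stratum)
implemented from first principles and validated against the `survival`
package in the tests.

## Worked example

A red beetle against a nettle leaf, as the blue tit sees it:

```r
library(aposcan)
wl     <- wl_grid()
viewer <- blue_tit_sensitivities()
noise  <- receptor_noise()

red  <- compute_cone_catch(sigmoid_reflectance(wl, 595, low = 0.04, high = 0.65), viewer)
leaf <- compute_cone_catch(gaussian_reflectance(wl, 550, 35, 0.10, 0.05), viewer)
red
#> <cone_catch> uv=0.04 sw=0.04027 mw=0.06018 lw=0.3066 dbl=0.1596

chromatic_jnd(red, leaf, noise)      # 27.35 JND: highly conspicuous
achromatic_jnd(red, leaf, noise)     # 8.01 JND
saturation(to_tetrahedral(red))      # 0.437 (max 0.75)
classify_discriminability(chromatic_jnd(red, leaf, noise))
#> [1] discriminable
```

The chromatic contrast of 27 JND means the beetle's colour is far above
the ~1–3 JND discrimination threshold against its own background; its
saturation of 0.44 places it over half-way from the achromatic centre to
a spectral vertex of the tetrahedral colour space.

One full synthetic replicate of the study — spectra → camera frames →
calibration → cone mapping → colour metrics → JNDs → bioassays → honesty
model:

```r
run <- run_honesty_pipeline(world_config(seed = 5))
run
#> <honesty_run> seed=5, n=216 specimens
#> contrast effect: 0.0586 (se 0.0186, p 0.00186)
```

The species-adjusted slope of log-toxicity on chromatic background
contrast is positive and significant: in this synthetic world (generating
slope 0.07 per JND), more contrasting individuals really are measured as
more toxic — the signal is honest, and the pipeline recovers it.

Field predation, from the command line:

```sh
Rscript inst/scripts/aposcan simulate --seed 3 --out sim/
Rscript inst/scripts/aposcan survival --in sim/predation.csv --out surv/
#> attack rate: 5/144 = 3.5% (95% CI 1.1-7.9%)
```

## Package layout

- `R/spectra.R`, `R/vision.R` — reflectance spectra, D65, pigment
  templates, quantum catches
- `R/camera_sim.R`, `R/calibration.R`, `R/cone_mapping.R` — synthetic
  camera, grey-standard calibration, polynomial cone mapping
- `R/colour_metrics.R`, `R/discriminability.R` — tetrahedral space,
  saturation, luminance, JNDs
- `R/bioassay_sim.R`, `R/toxicity.R` — Daphnia assays, 3 h summaries,
  LC50
- `R/predation_sim.R`, `R/survival_stats.R` — field predation,
  Kaplan–Meier, Cox, contrasts
- `R/world.R`, `R/pipeline.R`, `R/honesty.R` — the synthetic world and
  the honesty analyses
- `R/model_design.R` — printable prey-model colour matching
- `vignettes/aposcan-methods.Rmd` — models, assumptions, design
  decisions, limitations
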