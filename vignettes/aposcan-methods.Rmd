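---
title: "Models and methods behind aposcan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aposcan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aposcan)
```

# The question

Aposematic prey pair conspicuous signals with chemical defence. Whether
the *strength* of the signal honestly tracks the *strength* of the
defence — among closely related species and among individuals within a
species — is an empirical question that requires (i) coloration measured
through the predator's visual system, (ii) conspicuousness measured
against the prey's natural background rather than as an intrinsic
property, (iii) an objective defence assay, and (iv) field evidence that
predators act on the measured differences. `aposcan` implements this
whole chain for a ladybird-like study system viewed by a small passerine
(blue tit) predator, plus a synthetic world with known ground truth so
that every stage is testable by parameter recovery.

# Visual modelling

## Quantum catches

A receptor's quantum catch for a surface with reflectance $R(\lambda)$
under illuminant $I(\lambda)$ (CIE D65 throughout) and sensitivity
$S_i(\lambda)$ is

$$q_i = \frac{\int R(\lambda)\, I(\lambda)\, S_i(\lambda)\, d\lambda}
             {\int I(\lambda)\, S_i(\lambda)\, d\lambda},$$

integrated by the trapezoid rule on a uniform 300–700 nm grid (5 nm
default). The denominator normalises to a perfect reflector
(von-Kries-style), so catches are linear in reflectance and a flat
surface of reflectance $r$ has catch $r$ in every channel. Blue tit
sensitivities are built from the Govardovskii A1 pigment template at
published peaks (UVS 371, SWS 448, MWS 503, LWS 563 nm; the double cone
uses the LWS pigment) with logistic stand-ins for the cone oil droplets.
These are template curves, not digitised measurements; any column can be
replaced from CSV (`read_sensitivities_csv()`).

## Receptor-noise-limited discriminability

Chromatic distance between stimuli $a$ and $b$ uses the log-linear
receptor-noise model. With $\Delta f_i = \ln\!\big(q_i(a)/q_i(b)\big)$
and noise $\omega_i = \nu / \sqrt{\eta_i/\eta_{\max}}$ ($\eta_i$ the
relative cone abundances, $\nu$ the Weber fraction of the most abundant
cone),

$$\Delta S^2 = \Delta f^\top
  \Big(D^{-1} - \tfrac{D^{-1}\mathbf{1}\mathbf{1}^\top D^{-1}}
                      {\mathbf{1}^\top D^{-1}\mathbf{1}}\Big)\,
  \Delta f, \qquad D = \mathrm{diag}(\omega_i^2).$$

This quadratic form — the inverse-noise metric with the achromatic
direction projected out — equals the classical pairwise summation
formula for any number of channels; the pairwise form is kept in the
package (`rnl_pairwise()`) purely as an independent oracle, and the test
suite checks equality to $10^{-10}$ on random catch pairs, the dichromat
closed form in the two-channel restriction, metric axioms, and
invariance to common intensity scaling. Luminance distance is
$\Delta L = |\ln(q_{dbl}(a)/q_{dbl}(b))| / \omega_{dbl}$. Defaults
($\eta$ = 0.37, 0.70, 0.99, 1.00; $\nu = \omega_{dbl} = 0.05$) follow
common practice for passerines; the source study names the model and
species but prints neither abundances nor Weber fraction, so these are
explicit, replaceable configuration. JNDs of ~1–3 straddle the
discrimination threshold (`classify_discriminability()`), with the upper
boundary (exactly 3.0) classed as marginal.

## Tetrahedral colour space

Relative single-cone catches $(u,s,m,l)$, summing to 1, weight the
vertices of a regular tetrahedron centred on the achromatic point with
circumradius 0.75 and the UV vertex on $+z$ (SW/MW/LW at azimuths
0°/120°/240° in the $z=-0.25$ plane). Several slightly different
scalings of this space exist in the literature and the original plugins'
choice is not recoverable, so the convention is fixed here and
documented: saturation (distance from the centre) is meaningful within
this convention, and comparisons across conventions are not. Anchors:
vertices at 0.75, two-cone mixes at $0.75/\sqrt3$, achromatic at 0.

# Camera calibration and cone mapping

The simulated camera mirrors a UV-converted SLR: four channels with
passbands UV 360–400 (peak 366), SW 400–550 (465), MW 420–620 (522), LW
560–700 (667 nm), a power-law sensor (`raw` $=255\,\ell^{1/\gamma}$,
default $\gamma = 2.2$), 8-bit quantisation, optional Gaussian read
noise, and an in-frame row of Spectralon-like grey standards (2–99%,
always including 40%). Calibration fits `raw` $= a\,\ell^{\,b}$ per
channel by log–log least squares on the standards (power law rather than
spline: monotone, invertible, two parameters, stable with eight
standards), then normalises each channel to the linearised 40% standard
so that 1.0 means 100% reflectance and illumination differences between
frames cancel. Specular-highlight exclusion, done by hand in the field
workflow, is available as an optional top-percentile trim within the
measured region (off by default; no trimming rule is stated in the
source).

Calibrated channel values are mapped to predicted cone catches by
per-receptor polynomial least squares over all monomials of the four
channels up to a configurable degree. Degree 2 (the
`fit_polynomial_mapping()` default) reaches the 0.96–0.98 per-receptor
$R^2$ band typical of the technique on a 200-spectrum library. The
measurement pipeline (`measure_world()`) instead defaults to degree 3
with an 800-spectrum library, half of it drawn from study-family
surfaces (`surface_family_library()`): development showed the quadratic
family systematically distorts predicted catches for highly saturated
long-pass (red/orange) surfaces — high global $R^2$, but locally biased
exactly where the signals live — and calibrating against spectra of the
surface types actually photographed is standard spectrometry practice.
Residual smooth distortions of the JND scale within a colour family
remain at any library size; this is a genuine limitation of
camera-based visual modelling and the main source of attenuation in the
end-to-end recovery (see below). Negative predicted catches are floored
at $10^{-6}$ (with a warning) because downstream JNDs take logs.

# Toxicity

Bioassay records are dead-out-of-ten Daphnia counts per dilution
(100/80/60/50/40/20/0% of stock) at 1, 3 and 24 h. The toxicity
response is the mean dead at 3 h across the dilution series,
log-transformed as $\ln(m+1)$ — the +1 keeps zero-mortality specimens
finite; the source states only "log-transformation", so this
zero-handling is documented as this package's choice, not the authors'.
LC50 comes from a binomial GLM (logit by default, probit available) of
mortality on log-dose, with a delta-method CI on the log scale;
all-dead, none-dead, non-increasing, or out-of-range ($>100\%$ of
stock) patterns are flagged undefined rather than extrapolated. LC50 is
reported but never consumed by the honesty stage, honouring the source's
explicit exclusion.

# Survival analysis

Kaplan–Meier estimation is implemented from first principles
(product-limit, Greenwood variance, censored-at-event-times at risk
through the event). Cox proportional hazards uses Newton–Raphson on the
Breslow partial likelihood with block (transect) as a *stratum* — a
deliberate stand-in for the original Cox mixed-effects model: a stratum
per block absorbs the same confounding as a random block intercept
without frailty machinery, and the original random-effect structure is
not printed. The fit is validated against `survival::coxph(ties =
"breslow")` to $10^{-7}$ in the tests; `survival` is never used in the
package itself. Pairwise colour contrasts are coefficient differences
with covariance-propagated SEs, unadjusted p-values by default (matching
the source's reporting) with an optional multiplicity correction.
Check-grid rounding (attacks recorded at the first 4 h check after they
happen) is treated as right-continuous event times, as the field
protocol did; an interval-censored likelihood is out of scope.
Ambiguous (non-predator) censorings are kept as right-censored by
default, with a flag to drop them.

# The honesty analyses

The specimen table carries one row per specimen: species, size, weight,
luminance, saturation, elytra pattern area, chromatic and achromatic
contrast against the species' own background (mean of 10 leaves), and
internal (spot-vs-elytra) luminance contrast — chromatic internal
contrast is deliberately not computed, since chromatically comparing a
coloured ground to an achromatic spot is of doubtful biological
relevance.

`fit_honesty_model()` fits the response $\ln(\text{mean dead}+1)$ on
species plus the z-scored attributes, with the biologically motivated
two-way interactions (species × contrast, species × saturation,
saturation × contrast; the full quadratic set is available but needs far
more specimens than the study scale), simplified backwards by AIC with
species always retained. Because the signal attributes are strongly
collinear — they are all functions of the same pigmentation — the
full-model partial coefficient of contrast is reported but not treated
as "the" honesty slope; the headline `contrast_effect` is the
species-adjusted slope from `log_toxicity ~ species + contrast` on the
raw JND scale, directly comparable to the generator's `honesty_slope`.
A random specimen effect was dropped: with one toxicity summary per
specimen it is unidentifiable, so the model is a plain linear model with
the stated fixed-effect structure. Tests are two-sided throughout; the
source's one-tailed "lower p" reporting is not reproduced.

Supporting analyses: `within_species_saturation_test()` (species-centred
saturation on species-centred toxicity, pooling specimens, which removes
all between-species differences exactly), `leave_one_species_out()`
(sign/significance stability of the contrast and saturation effects
under every single-species exclusion — the larch-style robustness
check), and `survival_vs_conspicuousness()` (logistic regression of the
48 h attack indicator on per-model measured JND with transect blocks,
cross-checked by the stratified Cox fit).

# The synthetic world

`world_config()` states the world once; generators are pure functions of
the seed. Six archetypes mirror the study community — red (2-spot), its
black morph, orange, black (pine), yellow (14-spot), brown (larch) —
with the studied species' mean body sizes and parametric spectra:
long-pass sigmoids for carotenoid colours, flats for melanised surfaces,
a 550 nm Gaussian bump for leaves, gentle long-pass ramps for conifer
twigs. Specimen-level jitter (sigmoid midpoint SD 8 nm, relative
amplitude SD 0.08) produces within-species JND spreads of roughly 0.5–2
JND, comparable to the dispersion bars in studies of this kind.

Ground-truth rules:

* **Honesty**: $\ln(\text{toxicity}+1) = \alpha + \beta_h \cdot
  \text{JND} + \epsilon$, $\epsilon \sim N(0, 0.3)$, floored at 0, with
  a +0.3 species offset for orange (the study community's known
  exception: most toxic at intermediate contrast). Default $\beta_h =
  0.07$ per JND with $\alpha = 0$: chosen, before any recovery test was
  run, so that the ~1–27 JND archetype range spans the 0–10
  dead-Daphnia assay range, with the most contrasting species near the
  ceiling and the dullest near zero — the spread the assay design
  implies.
* **Bioassay**: the generator solves for the latent LC50 whose logistic
  dose-response (slope 3 on log-dose) yields the specimen's target mean
  dead at 3 h, then draws per-Daphnia exponential death times combining
  toxin and background hazards, so counts are Binomial at each time and
  monotone in dose and time. Background mortality in clean water is not
  reported for the original assay and defaults to 0.02/h.
* **Predation**: attack times are exponential with $\log h = \log h_0 -
  \beta_p \cdot \text{JND}$, rounded *up* to the 4 h check grid (an
  attack is seen at the first check after it happens), administratively
  censored at 48 h, with 5% early non-predator losses. $h_0 = 0.003$/h
  and $\beta_p = 0.065$/JND reproduce an overall attack rate near 6%
  and pairwise log-hazard contrasts of ~1.6 between the dullest and
  brightest colours — the magnitudes printed for this field design.

What the generator does *not* emulate: spatial pattern and shape (each
surface is a uniform patch), specular reflection and elytra curvature,
weathering of models, predator learning over the exposure window, and
pattern-level vision. A green end-to-end test therefore establishes
parameter recovery for the measurement-and-inference chain, not realism
of those omitted features.

# Numerical and testing notes

* 8-bit quantisation bounds round-trip calibration accuracy; the
  round-trip criterion is 0.01 absolute reflectance, which quantisation
  supports and a relative 1% at low reflectance would not.
* The honesty-recovery acceptance test asserts, per the module's stated
  examples, sign recovery of the headline slope under a positive
  generating slope and the rate of claimed (significant positive)
  associations under the null. Per-run two-sided *detection* power at
  the default slope is lower than the sign-recovery rate because the
  mapping-induced errors-in-variables attenuate the fitted slope; the
  decisions ledger of the source tree records the measured values.
* Heavy simulations in the acceptance suite run at reduced replicate
  counts (50–100 instead of the nominal 200) purely for runtime; all
  thresholds are unchanged.
* Degenerate inputs error loudly and early: saturated normalisation
  standards, non-monotone grey-standard measurements, zero catches in
  log-JND operations, separation in the Cox likelihood, all-dead or
  all-alive dose-response patterns.

# Known limitations

Polynomial cone-catch mapping carries smooth local biases for saturated
surfaces that no library size removes; stratified Cox is a stand-in for
the original mixed-effects formulation; the tetrahedral scaling is one
of several in use; sensitivity curves are templates, not measurements;
and LC50 confidence intervals are delta-method, not profile.
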