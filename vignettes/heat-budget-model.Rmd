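---
title: "The stationary-forager heat-budget model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stationary-forager heat-budget model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeheat)
```

## The model

Foraging honeybees are endothermic throughout the foraging cycle: the flight
muscles keep the thorax well above air temperature so the bee can take off
immediately. For a stationary forager in thermal steady state, energy gain
equals energy loss, so metabolic heat production M can be recovered from the
measurable heat fluxes:

$$ M = r_l\,R_{loss} \;-\; r_g\,R_{gain} \;+\; E_{cv} \;+\; e_{lev}\,E_{ev}. $$

The terms are mechanistic — Stefan–Boltzmann radiative loss
$R_{loss} = \epsilon_b \sigma T_b^4 A_b$ from the whole body surface,
radiative gain $R_{gain} = R_{gIR} + R_{gSOL}$ with infrared and solar
components each acting on half the surface, segment-wise convective loss
$E_{cv}$, and a fixed evaporative loss $E_{ev} \approx 4$ mW — but each is
weighted by a correlative coefficient ($r_l$, $r_g$, $e_{lev}$, and the
convection coefficients) fitted to visit-level data. This mixed design uses
physical structure where it is known and lets the data absorb what cannot be
measured in the field: the exact radiative environment, posture effects, and
above all respiratory (internal) convection. Conduction occurs only through
the leg tips and is neglected.

Five convection variants are supported (`model_variants()`):

* `simple_eq7` — one whole-body coefficient,
  $E_{cv} = h_b A_b (T_b - T_a)$ with $T_b$ the unweighted mean of head,
  thorax and abdomen surface temperature. This variant performs poorly
  precisely because a single fixed $h_b$ cannot follow the environmental
  variation.
* `advanced_eq13` / `advanced_eq14` — one term per body segment,
  $h\,A\,(T - T_a)$, with each $h$ a linear function of air temperature,
  $h = a + b\,T_a$ (eq14 holds the abdomen coefficient constant). The
  $T_a$-dependence reflects the experimental finding that respiratory
  ventilation frequency — the dominant driver of convective loss in
  stationary foragers — covaries with air temperature, not with oxygen
  turnover.
* `three_comp_eq15` / `three_comp_eq16` — head and abdomen exchange heat
  with the thorax (the heat source, via haemolymph circulation and tracheal
  ventilation) rather than with the air: the driving differences are
  $T_{th}-T_{hd}$ and $T_{th}-T_{ab}$, without area factors, so these
  coefficients are absolute (W per degC). Only the thorax term keeps its
  area factor.

The per-segment and three-compartment bases of equal size span exactly the
same linear space — $(T_{th}-T_{hd})$ is a linear combination of the two
excess-over-air columns because the areas are constants — so the equal-size
pairs produce identical fitted values and residuals, with coefficient
vectors related by an exact basis change. The package tests assert this.

Fitted coefficient presets for all five variants ship as JSON
(`coef_preset()`), entered digit-for-digit as published. Negative fitted
head/abdomen coefficients are physiologically meaningful (those segments on
average receive more heat than they emit) and are accepted without warning.
Two published values for the simplified variants (`table2b`'s `e_lev` and
`b_hhd`) carry t-values that appear transposed relative to the matching
three-compartment set; the presets keep the printed values and flag the
ambiguity in their `note` field rather than correcting the source.

## Geometry and constants

Segment areas use standard shape approximations: sphere (thorax), oblate
spheroid (head), prolate spheroid (abdomen), without wings and legs. The
published constant areas are the default (`body_surface()`): A_hd = 30.80,
A_th = 47.78, A_ab = 85.91 mm². The published whole-body area, 163.7 mm²,
differs from the component sum (164.49 mm²) by 0.79 mm²; both are carried —
`total = "printed"` (default) versus `total = "sum"` — and neither is
silently corrected. The default `body_dimensions()` are a synthetic
reference morphometry back-solved from those areas (thorax diameter
$\sqrt{47.78/\pi} \approx 3.90$ mm, etc.), not measured values.

Radiative constants (`thermal_constants()`): cuticle emissivity
$\epsilon_b = 0.97$, infrared absorptivity equal by Kirchhoff's law, solar
absorptivity 0.825 (already corrected for reduced absorption towards the
curved body edges by a cosine law; the correction is used as given, not
re-derived), chamber-paint absorptivity 0.95, $\sigma = 5.669\times10^{-8}$
W m⁻² K⁻⁴, and $E_{ev} = 4$ mW held constant across air temperatures
(foragers' mouthparts are wet from drinking under all conditions). All
interfaces take °C; the Kelvin shift (+273.15) is internal and exact, and
absolute zero is admitted as a limiting value where $T^4 = 0$.

The infrared-gain closure deserves a note: the calibration dataset recorded
global (solar) radiation but the published model leaves the infrared input
unstated, absorbing radiative uncertainty into $r_l$ and $r_g$. This
package's default closure treats the surroundings as a blackbody at air
temperature, acting on half the surface as direct and half as
ground-emitted, with reflected infrared zero (the black chamber paint
reabsorbs it). `T_surround` is an explicit argument throughout so other
closures can be substituted; the shipped coefficient presets are only
guaranteed meaningful under a closure consistent with their original
computation.

## Fitting

Every variant is linear in its free coefficients, so the design matrix
(`build_design_matrix()`) has one column per coefficient — $R_{loss}$,
$-R_{gain}$, the constant $E_{ev}$, and the convection basis — and the
response is measured M in W. Two fitting routes exist deliberately:

* `fit_linear()` — closed-form least squares via QR; the exact reference.
* `fit_iterative()` — a Levenberg–Marquardt loop (damped normal-equation
  steps on column-normalised data, damping shrunk tenfold per accepted step
  and grown tenfold per rejected one), matching the iterative procedure
  used to calibrate the published coefficients. Convergence is declared
  when an accepted step changes the reduced $\chi^2$ (RSS/df) by less than
  the tolerance (default $10^{-9}$) — but only once the damping no longer
  dominates the step, because the $\chi^2$-change test alone can trigger
  while a weakly-determined coefficient direction is still far from its
  optimum. A rejected step at heavy damping signals the round-off floor and
  also terminates. A single start (all ones) suffices: the problem is
  convex with a unique optimum, and the tests require the two routes to
  agree to $10^{-6}$ relative (and cross-check against an independent
  external Levenberg–Marquardt implementation). Coefficients are always
  fitted jointly — they are not determined independently of one another, so
  the full set is needed for prediction.

Statistics follow the conventions the presets were reported with: SD of
residuals uses the df denominator $\sqrt{RSS/df}$ with
df $= N - p$; SEM$_{res}$ = SD$_{res}/\sqrt{N}$; adjusted
$R^2 = 1 - (RSS/df)/(TSS/(N-1))$ with centred TSS; per-coefficient t values
and two-sided P from the t distribution with df degrees of freedom, with no
multiple-testing correction. The overall F value uses the uncentred
no-intercept ANOVA convention, $((\sum y^2 - RSS)/p)/(RSS/df)$; published
F values for these models are not reproducible from the other printed
statistics under any standard convention, so this package documents its own
and does not attempt to match them. Shade and sunshine visits (threshold:
global radiation strictly above 100 W m⁻²) are fitted pooled, as the
presets were.

## The synthetic-visit generator

The calibration dataset (872 visits) is not deposited, so the package
generates synthetic visit sets with its documented structure
(`simulate_visits()`): air temperature uniform on 14.8–37.5 °C; an even
shade/sun split with global radiation uniform on 3.4–100 or 100–921 W m⁻²;
thorax temperature responding weakly to air temperature and radiation
($T_{th} = 28.4 + 0.30\,T_a + 0.0088\,G$ plus N(0, 1.8 °C) jitter, clipped
to the observed 33.3–45 °C and kept above $T_a$); head and abdomen placed
between air and thorax temperature with jittered fractions (abdomen nearest
air, fraction 0.25 ± 0.07; head at 0.52 ± 0.12 of the remaining gap),
giving the ordering $T_a \le T_{ab} \le T_{hd} \le T_{th}$ by construction;
and measured M generated from the model itself (preset `table2a`) plus
N(0, 5.78 mW) noise, rejection-resampled into 4–85 mW. Only the ranges and
spreads of the source data are known; every distributional form here is the
generator's own choice, and the response-surface coefficients were
calibrated once so that the SD of generated M lands at ≈ 17.59 mW
(17.0–18.1 over seeds) with a rejection rate near 7%, then left alone.

What the generator does *not* emulate: condition-specific conductance
differences between feeding regimes (the condition label is carried but has
no effect), sun-heated abdomens breaking the temperature ordering, weather
time series, or any correlation structure beyond the thorax response
surface. Passing parameter-recovery tests on these data therefore shows
that the fitting machinery is correct and well-conditioned under realistic
ranges — not that the model would fit any particular field dataset equally
well. Two further caveats are documented deliberately: rejection-resampling
is a selection on M, which biases refitted coefficients by up to about half
a reported SE at the defaults (visible in the calibration tests as
per-coefficient 3-SE coverage of ~0.99 rather than the nominal ~0.997); and
clipping the thorax temperature produces a point mass at 45 °C in hot sunny
draws.

## Numerical choices and degenerate inputs

* Ellipsoid areas use the closed forms with an exact sphere-limit branch at
  zero eccentricity; both are tested against adaptive surface-of-revolution
  quadrature to $10^{-9}$ relative across axis ratios.
* Rank deficiency (e.g. constant air temperature making intercept and slope
  convection columns proportional) is detected via pivoted QR and reported
  with the names of the collinear columns rather than silently dropping
  terms.
* Conductance estimates at $T_b = T_a$ return `NA` with a warning, not an
  error.
* Visit files embed units in column names (`_C`, `_Wm2`, `_mW`); the model
  computes in W internally and reports mW at user-facing surfaces, the
  single most dangerous unit boundary in this model.
* The shade/sun threshold (100 W m⁻², strict) is one constant shared by the
  reader, the generator and reports.

## Problem sizes

The test suite exercises fits at N between 40 and 872 and the full
parameter-recovery calibration at N = 872 with 100 replicates; the whole
suite runs in a few seconds on one CPU. The acceptance script regenerates
one default 872-visit dataset per run.

## Known limitations

The model is steady-state by construction and applies to *stationary*
foragers; free flight changes the balance between external and internal
convection and needs its own coefficient set. Coefficient presets are tied
to the blackbody-at-air-temperature infrared closure described above.
Morphometric defaults describe one reference worker; there is no allometric
scaling across castes or body sizes.
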