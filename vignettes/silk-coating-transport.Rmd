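---
title: "Models and methods: transport and postharvest analysis of silk fibroin coatings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: transport and postharvest analysis of silk fibroin coatings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkcoat)
```

Silk fibroin can be dip-coated from a dilute aqueous suspension onto
perishable fruit, where it self-assembles into a micrometre-thin edible
membrane. Water-annealing the coating (water vapour under vacuum at room
temperature) raises the protein's relative beta-sheet content, and the
crystallinity in turn governs how fast oxygen and water vapour cross the
film — the two transport properties that control fruit respiration and
dehydration after harvest. This vignette documents the models the package
implements, the choices behind their defaults, and what the synthetic-data
validation does and does not establish.

## Two-chamber oxygen diffusivity

A film of area $A_M$ and thickness $l$ separates a donor chamber held at a
constant dissolved-oxygen concentration $c_D$ from a receiving chamber of
volume $V_R$ whose concentration $c_R(t)$ is recorded every 10 minutes.
Under the standard assumptions (well-mixed chambers, no oxygen consumption,
linear concentration profile in the film, instantaneous steady state) the
receiving-chamber balance combines the membrane flux with the rig's
baseline leak into a single first-order law:

$$\frac{dc_R}{dt} = k_M D_{e,M} (c_D - c_R) + \frac{D_B}{V_R}(c^* - c_R),
\qquad k_M = \frac{A_M}{l\,V_R},$$

where $D_{e,M}$ (cm²/s) is the effective membrane oxygen diffusivity,
$D_B$ (cm³/min) the baseline volumetric diffusion factor of the rig, and
$c^*$ the saturation concentration, taken equal to $c_D$ because the donor
sits at air saturation. With $c^* = c_D$ the law integrates to
$c_R(t) = c_D - (c_D - c_R0)\,e^{-\alpha t}$ with
$\alpha = k_M D_{e,M} + D_B/V_R$, so $\ln(c_D - c_R)$ is linear in time.
`fit_diffusion_factor()` estimates $\alpha$ as minus the OLS slope of that
log-deficit; `baseline_factor()` estimates the rig-only rate $\alpha_{rs}$
from a run with an impermeable rubber stopper in place of the film
($D_{e,M} = 0$, hence $D_B = \alpha_{rs} V_R$); and
`effective_diffusivity()` subtracts the two:
$D_{e,M} = (\alpha - \alpha_{rs})/k_M$.

Numerical and policy choices:

* $\alpha$ is carried in min⁻¹ (matching the 10-minute sampling); the
  diffusivity is reported in cm²/s.
* Sensor overshoot points with $c_D - c_R \le 0$ are excluded from the
  log fit (their count is reported) rather than aborting the replicate; at
  least 4 usable points are required.
* A film rate at or below the baseline ($\alpha \le \alpha_{rs}$) is
  physically a film whose transport is indistinguishable from zero, so the
  estimate clips to 0 with a `below_baseline` flag instead of going
  negative.
* `analyze_film()` fits each of the (typically 3) consecutive replicate
  runs separately, reports mean ± sd of $\alpha$, and derives one
  $D_{e,M}$ from the mean; replicates whose fit fails are dropped with a
  warning.
* $V_R$ = 100 cm³ and $c_D$ = 8 mg/L (air-saturated water at 22 °C) are
  rig-dependent defaults, exposed as parameters because they are
  apparatus properties, not constants of the method.

## Cup-method water vapour permeability

A desiccant-filled cup sealed by the film sits in a 75 % RH desiccator;
moisture crossing the film accumulates as weight gain. The water vapour
transmission rate is the OLS slope of weight on time per unit opening
area, converted to g m⁻² s⁻¹, and the permeability normalizes by film
thickness and driving pressure:

$$\mathrm{WVP} = \frac{\mathrm{WVTR}\cdot d}{S\,(RH_1 - RH_2)/100},$$

with $S = 2645$ Pa the saturation vapour pressure of water at 22 °C, so
the default driving pressure for 75 %→0 % RH is 1983.75 Pa. Some reports
quote a different driving pressure for nominally the same boundary
conditions (1753.55 Pa corresponds to saturation near 20 °C); the formula
value is the default and `delta_p_pa` overrides it explicitly when a
quoted pressure must be reproduced. Regressions with $r^2 \le 0.98$ carry
a quality flag — that is the linearity gate used for accepting cup runs —
and weight-loss (inverted-cup) records are handled by absolute slope with
a direction flag.

## Amide III beta-sheet quantification

The Amide III region (1200–1350 cm⁻¹) is sensitive to protein secondary
structure and insensitive to water, which matters for water-annealed
films. `fit_amide3()` restricts the spectrum to that region, subtracts a
linear baseline anchored at the two endpoint absorbances (deterministic,
unlike rubber-band baselines), clips negative residuals (counted),
rescales to unit area, and decomposes the result into 12 Gaussian bands by
bounded Levenberg–Marquardt least squares. Band centers may move at most
±8 cm⁻¹ from their initial positions, widths are bounded to
$\sigma \in [2, 25]$ cm⁻¹ and amplitudes to be non-negative. The relative
beta-sheet content is $100 \times$ the fitted area of bands whose centers
fall in the beta window (default 1216–1250 cm⁻¹, following common
Amide III assignments; it is a parameter, not a fixed truth) over the
total fitted area.

The optimizer is deterministic: starting amplitudes come from the
non-negative linear least-squares solution at the initial centers/widths
(amplitudes enter the model linearly), and a fixed sequence of restart
widths (6, 4, 10 cm⁻¹) runs only when the first deviance exceeds the
high-frequency noise floor of the data, guarding against a degenerate
local minimum in which a few very broad bands soak up the whole region.
Default initial centers are evenly spaced over 1205–1345 cm⁻¹; the
pipeline passes its scenario's known band positions instead, as an analyst
would initialize at literature band assignments.

One identifiability caveat is worth stating plainly: when neighbouring
bands overlap strongly, individual band areas are only weakly identified —
solutions differing by several percent in single-band areas fit the data
equally well — while the *sum* of areas over the beta window, which is the
quantity of scientific interest, remains stable. Per-replicate beta
estimates at 1 % spectral noise therefore scatter by roughly ±2 points
with occasional larger excursions when a band sits near the window edge;
this mirrors the ±2–5 point replicate spread typical of the physical
measurement, and beta content is reported as the mean over replicate
spectra, exactly as replicate films are averaged in practice.

## Postharvest metrics

* **Respiration**: in a hermetic jar of free volume $V$ (ml) containing
  fruit of mass $m$ (kg), the rate is
  $(\Delta CO_2/100 \cdot V)/(m\,\Delta t)$ in ml CO₂ kg⁻¹ h⁻¹, with
  $\Delta CO_2$ the endpoint difference over the chosen window. An OLS
  `method = "slope"` variant is provided for noisy analysers. The default
  sampling schedule is every 30 min for 5 h, every 90 min to the 12th
  hour — the 90-min cadence does not land on hour 12, so the boundary
  sample is included explicitly — then every 180 min to hour 36 (24
  samples including $t = 0$). The jar's free volume must be measured and
  supplied; it is not derivable from jar size.
* **Dehydration**: weight-loss fraction $1 - w(d)/w_0$, linearly
  interpolated between sampling days (defaults 0, 1, 3, 5, 7, 14).
* **Firmness**: maximum force over the first 8 mm of a puncture
  force–displacement record (5 mm flat probe, 1 mm/s); truncated curves
  are used with a warning; replicates aggregate as mean ± sd.
* **Statistics**: `group_compare()` wraps one-way ANOVA (the default) and
  an additive two-way design with Tukey HSD at $\alpha = 0.05$; both
  designs exist because weight-loss style data are analysed either way
  depending on whether dip count is treated as a factor.

## The synthetic-data generators

Every generator is a pure function of its parameters and an explicit seed
(`withr::with_seed`; the caller's RNG state is never touched), and at zero
noise its output satisfies the corresponding estimator's model exactly, so
noiseless recovery is exact to numerical precision and noisy recovery
quantifies estimator variance honestly. Noise models and defaults, chosen
once as realistic instrument characteristics:

* oxygen sensor: 1 % multiplicative Gaussian noise (optical-sensor error
  is reading-proportional);
* balance (cup and berry weighings): additive Gaussian; for cup runs the
  scenario uses sd = 1 % of the weight gained per 12-h weighing interval,
  the regime of a 0.1 mg balance against mg-scale daily gains;
* FTIR: additive noise with sd = 1 % of the peak absorbance;
* CO₂ analyser: 0.02 % CO₂ absolute; load cell: 0.02 N.

The dehydration generator uses a first-order approach to an equilibrium
weight, $w(t) = w_{eq} + (w_0 - w_{eq})e^{-kt}$ with $w_{eq} = 0.25\,w_0$:
empirical drying curves constrain only their endpoints, so the exponential
form is this package's modelling choice, selected as the simplest shape
with the right asymptote. The puncture generator uses the unimodal
$F(d) = F_p (d/d_p) e^{1 - d/d_p}$, rising to exactly $F_p$ at depth
$d_p$ and softening beyond (tissue rupture).

`scenario_conditions()` defines the four study arms: water-annealing times
0, 1, 6, 12 h mapping to beta-sheet contents 23, 36, 48, 58 %. Film
oxygen diffusivity spans a two-orders-of-magnitude decrease across that
series (ratio configurable via `d_ratio`; a roughly 50-fold decrease is
an equally defensible reading of the underlying measurements, which is why
it is a parameter). WVP anchors to the measured values
7.93·10⁻⁹, 5.37·10⁻¹⁰ and 6.49·10⁻¹¹ g m⁻¹ s⁻¹ Pa⁻¹ at 36/48/58 % and
extrapolates the same log-linear trend to 23 %. Respiration
(22→10 ml kg⁻¹ h⁻¹), dehydration rate (0.193→0.070 day⁻¹, the top value
chosen so an uncoated berry loses ~70 % of its weight in 14 days) and
day-7 firmness (2.0→3.5 N) follow the qualitative postharvest trends with
magnitudes realistic for strawberries at 22 °C.

What passing recovery tests show — and what they do not: they establish
that each estimator inverts its own forward model correctly at realistic
noise, and that the end-to-end pipeline preserves the scientific orderings
(diffusivity and WVP falling, beta content rising with annealing). They do
not validate the forward models against real instruments: real spectra
have non-Gaussian baselines and band shapes, real berries do not dry
exponentially, and real rigs drift. The generators are test harnesses, not
fruit physiology simulators.

## Reproducibility and problem sizes

`run_scenario()` derives every random stream from one master seed via
fixed per-stage offsets recorded in the manifest, so a rerun with the same
config reproduces the manifest values exactly. The validation suite uses
problem sizes chosen to estimate each property stably: 200 seeded runs per
decade of oxygen diffusivity (three decades, with the stopper rate sized
at ~10 % of the film rate), 20 spectra per beta-sheet fraction, three cup
decades, a 1000-point grid for the closed-form/ODE consistency check, and
60 random small designs against a 2000-draw permutation oracle for the
ANOVA accept/reject agreement.

## Known limitations

Single-layer films with concentration-independent diffusivity and a
non-respiring receiving chamber; a user-supplied constant saturation
pressure rather than a temperature model; relative (not absolute)
crystallinity from a fixed 12-band decomposition with a configurable beta
window; no decay scoring, colour analysis or modified-atmosphere gas
modelling.
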