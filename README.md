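# silkcoat

Quantitative analysis of silk-fibroin edible coatings and their effect on
fruit postharvest physiology.

Regenerated silk fibroin, dip-coated from a 1 wt% aqueous suspension, forms
a micrometre-thin edible membrane on fruit. Water-annealing the coating
raises the protein's relative beta-sheet content (from ~23 % untreated to
~58 % after 12 h), and that crystallinity controls how fast oxygen and
water vapour cross the film — which in turn sets the fruit's respiration
rate, dehydration and firmness retention in storage. `silkcoat` implements
the full measurement pipeline for characterizing such coatings, for
researchers working on biopolymer barrier films and postharvest
preservation.

## What it computes

**Effective membrane oxygen diffusivity** from two-chamber permeation
kinetics. The receiving-chamber concentration obeys the combined
first-order law

    dc_R/dt = k_M D_eM (c_D − c_R) + (D_B / V_R)(c* − c_R),   k_M = A_M / (l V_R)

whose integral makes ln(c_D − c_R) linear in time with slope −α,
α = k_M·D_eM + D_B/V_R. A rubber-stopper run (D_eM = 0) measures the rig
baseline α_rs (D_B = α_rs·V_R), and the film diffusivity is
D_eM = (α − α_rs)/k_M, reported in cm²/s with a `below_baseline` flag when
film transport is indistinguishable from the rig leak.

**Water vapour permeability** by the desiccant-cup method: WVTR is the OLS
slope of cup weight on time per unit opening area (quality gate at
r² ≤ 0.98), and WVP = WVTR·d / (S·ΔRH/100) with S = 2645 Pa at 22 °C.

**Relative beta-sheet content** from the Amide III region
(1200–1350 cm⁻¹): endpoint-anchored baseline correction, unit-area
normalization, bounded 12-Gaussian deconvolution, and summation of the
band areas falling in the beta window (default 1216–1250 cm⁻¹).

**Postharvest metrics**: closed-jar respiration rate
(ΔCO₂/100·V)/(m·Δt) in ml CO₂ kg⁻¹ h⁻¹, gravimetric weight-loss fraction,
puncture-test firmness (max force over 8 mm), and one-/two-way ANOVA with
Tukey HSD.

**Seeded synthetic-instrument generators** (`gen_*`) for all five channels
with known ground truth, and an end-to-end scenario pipeline
(`run_scenario()`, `report()`) that simulates the four annealing
conditions, refits every channel, and checks the scientific orderings.

## Worked example

Fit a film's oxygen diffusivity from three simulated replicate runs plus a
stopper baseline (true D_eM = 1e-6 cm²/s, D_B = 0.02 cm³/min, 1 % sensor
noise):

```r
library(silkcoat)
g <- chamber_geometry(area_cm2 = 2.75, thickness_um = 75, volume_cm3 = 100)
reps <- lapply(1:3, function(k)
  gen_oxygen_experiment(1e-6, 0.02, g, seed = k, replicate_id = paste0("rep", k)))
stopper <- gen_stopper_experiment(0.02, g, seed = 99)
analyze_film(reps, stopper, g)
#> Two-chamber oxygen diffusivity fit
#>   alpha     = 0.0004199 +/- 2.1e-06 min^-1 (3 replicate(s))
#>   alpha_rs  = 0.0001996 min^-1 (D_B = 0.01996 cm^3/min)
#>   D_eM      = 1.002e-06 cm^2/s
```

The fitted relaxation rate α (min⁻¹) carries both film and rig transport;
subtracting the stopper rate α_rs and dividing by the cell constant
k_M = 3.67 cm⁻² recovers the true diffusivity within 0.2 %. The same
pattern runs the other channels:

```r
fit_wvp(gen_cup_series(2e-3, noise_sd_g = 1e-4, seed = 4))
#> Cup-method water vapour fit
#>   WVTR = 0.001999 g m^-2 s^-1 (r^2 = 1.0000, gain)
#>   WVP  = 7.559e-11 g m^-1 s^-1 Pa^-1 (delta_p = 1983.75 Pa)

fit_amide3(gen_amide3_spectrum(beta_fraction = 0.48, noise_sd = 0.01, seed = 5))
#> Amide III 12-Gaussian decomposition
#>   beta-sheet content = 48.9% (window 1216-1250 cm^-1)
#>   rss = 6.75e-06, converged = TRUE
```

An end-to-end run over the four annealing conditions (0, 1, 6, 12 h →
23, 36, 48, 58 % beta-sheet):

```r
man <- run_scenario(default_scenario_config(seed = 1))
report(man)
```

prints recovered-versus-true diffusivity, WVP, beta content, respiration
and firmness per condition, the WVP fold changes between conditions
(36 %/58 % ≈ 122), and PASS/FAIL for the orderings (D_eM and WVP strictly
decreasing, beta content strictly increasing with annealing time).

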