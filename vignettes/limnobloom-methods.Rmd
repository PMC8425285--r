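---
title: "Methods: from lake profiles to bloom dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from lake profiles to bloom dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`limnobloom` quantifies the physical controls on metalimnetic
cyanobacterial blooms — winter mixing depth, stratification structure and
the underwater light field — from routine monitoring profiles. This
vignette documents the models, the numerical choices, and what the
synthetic-lake generator does and does not emulate.

## Water-column physics

Density is computed in three steps. Salinity comes from conductivity
normalised to 25 °C through a single lake-specific factor
(0.7999 × 10⁻³ ‰ per µS cm⁻¹, appropriate where calcium carbonate
dominates the ion budget). In-situ temperature is corrected adiabatically
to the surface: the freshwater lapse rate Γ = g α(T) T_abs / c_p is
evaluated with the thermal expansion coefficient α taken from the
pure-water density polynomial, and applied in a single step
(θ = T − Γ z). Over 0–140 m the correction is below 0.02 K, so higher
order pressure integration would change nothing at instrument precision;
the polynomial itself is a Chen–Millero-type sixth-order fit with its
density maximum near 4 °C. Finally the haline contraction
ρ = ρ_θ (1 + βS), β = 0.807 × 10⁻³ ‰⁻¹, adds the dissolved-solids effect.

Stability is N²(z) = −(g/ρ)(∂ρ/∂z), positive when density increases
downward. The gradient uses centred differences at interior grid points
and one-sided differences at the ends, and N² is reported at the grid
depths so it aligns with the other per-depth quantities (the choice of
stencil is ours; any consistent stencil reproduces a linear profile's
closed form to 10⁻⁸ s⁻², which the tests assert).

The mixed-layer depth is the shallowest depth whose density strictly
exceeds the mean density of the top 2 m by 0.01 kg m⁻³. The 2-m
reference guards against transient near-surface stratification on sunny
mornings. Two deliberate choices: the exceedance is *strict* (a profile
touching the threshold exactly is not stratified), and a profile that
never meets the criterion returns the deepest grid depth with a
`full_mixing` flag rather than `NA`, because such winter profiles mean
holomixis, not missing data.

The metalimnion centre is the depth of maximum N² (ties broken toward
the shallower depth, relevant for plateaus); its boundaries are the first
half-maximum crossings walking outward from the centre, linearly
interpolated between grid points for sub-grid precision. Multimodal
profiles are resolved by the global maximum. The detection is valid only
if N²_max > 2 × 10⁻⁴ s⁻² and the thickness stays under 20 m — thresholds
tuned to this lake's stratification climate and exposed in
`lake_constants()`. A boundary with no crossing is clipped to the grid
end, which normally fails the thickness test and flags the profile
invalid; a fully unstable column reports no boundaries at all.

## Light structure

K_d is minus the slope of ordinary least squares of ln(E_d) on depth.
Because a dense bloom layer steepens attenuation locally, the
stratified-season fit must stop above it. The fit range starts at the
surface with four points and is extended downward while two conditions
hold: the next point's ln(E_d) falls within a prediction band of the
running fit (4 residual standard deviations, floored at 0.06 log units ≈
three times a 2 % sensor noise so that noise-free profiles still extend),
and the running R² stays at or above 0.99. A lone out-of-band point is
tolerated as a noise outlier; two consecutive out-of-band points indicate
a real attenuation change and stop the fit. A pure running-R² rule was
rejected because R² is span-normalised: a single opaque-layer point after
a long clean fit leaves R² ≈ 0.996, so R² alone never truncates —
the prediction band is what encodes "strict linearity". In
`full-profile` mode (autumn/winter option) the whole recorded profile
above the 0.05 µmol m⁻² s⁻¹ sensor floor is used. A fit with
non-positive slope (night or degenerate casts) raises a typed no-fit
error rather than returning a meaningless K_d.

Threshold depths (euphotic 1 % level via z_eu = ln(100)/K_d, and the
species-intrinsic 0.8 / 6.5 / 25 µmol m⁻² s⁻¹ depths) interpolate
crossings linearly in ln(E_d) — exponential decay between samples is the
physically consistent interpolant. Non-monotone noisy profiles take the
*shallowest* crossing, since each threshold defines the top of its light
zone. A threshold above the surface irradiance yields `NA` ("no such
layer today"); a threshold never reached within the recorded profile
returns the deepest recorded depth with an `unbounded` flag.

## Population metrics

Whole-lake mass follows the unit chain µg L⁻¹ ≡ mg m⁻³ → mg per 1-m
layer (× hypsographic volume) → metric tons (÷ 10⁹), summed over the
0–120 m grid that holds 98 % of the basin volume. The 20-m strata are
half-open `[top, bottom)` so every cell belongs to exactly one stratum.
Missing cells contribute zero mass and are counted — a documented
divergence from the "missing stays missing" policy used elsewhere,
because integration forces a choice and zero is conservative.

Net growth is µ = (ln B₁ − ln B₀)/Δt(days). Below-detection masses are
floored at a configurable whole-lake detection mass (default 0.05 t) so
µ stays defined, and every floored interval carries a flag. Intervals
are labelled by the regime at their start date: `metalimnetic` when a
valid metalimnion exists and the chlorophyll maximum sits at or below its
upper boundary, `mixed` otherwise.

Annual extremes follow the bloom-year convention: the year of vernal
deep mixing labels the cycle. The vernal minimum is searched inside a
configurable spring window (default April 1 – July 31, wide enough to
catch late minima after weak mixing); the following maximum is the
highest mass between this minimum and the next year's. Survival divides
the minimum by the *preceding* year's maximum, recovery by the
*following* one. Whether "preceding maximum" should mean the preceding
season's or the all-time preceding maximum is genuinely open; we use the
preceding season's, which matches the year-by-year bookkeeping of the
ratios.

## Surface heat flux

The budget is q_net = q_sw_net + q_lw_in − q_lw_out + q_latent +
q_sensible, positive toward the lake. Bulk turbulent fluxes use neutral
10-m transfer coefficients (C_D = 1.3 × 10⁻³, C_H = C_E = 1.35 × 10⁻³)
adjusted iteratively with Businger–Dyer stability functions until the
coefficients converge (relative change < 10⁻⁴, at most 50 iterations;
non-convergence falls back to neutral, flagged). Radiative terms:
q_sw_net = (1 − albedo) SW with albedo 0.07; q_lw_out = ε_w σ T_s⁴ with
ε_w = 0.97; q_lw_in = a · ε_atm · σ T_a⁴ with the Brutsaert clear-sky
emissivity 1.24 (e_a/T_a)^{1/7} and a (1 + 0.22 C²) cloud correction.
The cloudiness proxy C is one minus the ratio of observed to clear-sky
shortwave, with clear-sky radiation from solar geometry at the lake's
latitude and a fixed transmissivity of 0.75. These coefficient values
are documented configuration defaults, not claims about any particular
station's calibration; the chain is validated by closure and recovery
properties, not by coefficient matching.

The longwave constant `a` multiplies q_lw_in, so q_net is affine in `a`
and the closure fit against observed lake heat content (cumulative
q_net × area vs ΔH) has a closed-form least-squares solution — unique
whenever the longwave signal is non-degenerate, otherwise a typed
unidentifiability error. Heat content integrates ρ(θ) c_p T over the
hypsography relative to 0 °C with c_p = 4186 J kg⁻¹ K⁻¹.

Seasonal climatologies use DJF/MAM/JJA/SON with December assigned to the
*following* year's winter; anomalies are season-year means minus the
long-term seasonal mean, flagged beyond one long-term SD.

## Trend statistics

Spearman correlations go through `stats::cor.test` (average ranks for
ties, large-sample approximation). The seasonal Mann–Kendall test is
implemented in the package: Kendall's S per seasonal block on the yearly
values (multiple observations within a season-year are averaged),
variance with the standard tie correction, S and variance summed across
blocks, tau = ΣS divided by the summed pair counts, and a two-sided p
from the continuity-corrected normal approximation. Seasonal blocking
defaults to calendar month — the natural choice for a biweekly series —
and is configurable. Exact small-sample tables are out of scope; the
tests verify S and tau against exhaustive pair enumeration and the
type-I error rate against 2,000 null replicates. Correlation tables are
reported without multiplicity adjustment by default (a Holm option
exists), matching how such tables are conventionally presented.

## The synthetic lake

`simulate_lake_scenario()` emulates the *statistical and physical
structure* the analysis assumes, not lake mechanics. Twelve years of 26
biweekly profiles on the 0–120 m grid are generated from: a scheduled
mixed-layer depth (piecewise-linear over the year, deepening to each
year's prescribed winter maximum — the default schedule alternates
holomictic 120 m years with incomplete 47–115 m years); an epilimnion
temperature cycle clamped at the winter mixed temperature; an
exponential thermocline of 4 m width over a 4.6 °C hypolimnion; and a
deep conductivity excess (+40 µS cm⁻¹, 2 m e-folding) that keeps
winter profiles density-stable the way calcite-rich deep water does.

The cyanobacterial layer is a 2-m Gaussian centred on the generator's
*own* neutral-buoyancy depth — the 6.5 µmol m⁻² s⁻¹ isolume of its light
field, found by fixed-point iteration so self-shading is honoured —
while the schedule is stratified, and is mixed uniformly through the
mixed layer otherwise. This builds the light-not-stability coupling into
the synthetic truth, which is exactly the property the depth-correlation
analysis probes. Growth is bimodal by construction: a metalimnetic
window (mid-June–September) and an autumn epilimnetic window
(October–December) with logistic damping toward a 25 t ceiling, decay
during winter mixing scaled by mixing depth, and a one-time kill of the
volume fraction below the 100 m gas-vesicle collapse depth in holomictic
years. Eukaryote chlorophyll is uniform through the lit zone, so the
surface fit range of the light field is genuinely log-linear.

Measurement noise is additive Gaussian for temperature (0.01 K) and
conductivity (0.5 µS cm⁻¹) — sonde-grade precision — and multiplicative
lognormal for chlorophyll (5 %) and PAR (2 %). Ground-truth
stratification quantities are defined by running the water-column
operators on the *noise-free* fields, so recovery tests measure
robustness to measurement noise alone, not agreement between two
different definitions of "truth". Per-year true survival ratios are
computed from the noise-free mass series at the sampling dates.

Daily meteorology (seasonal air temperature, humidity, pressure, wind,
cloud-modulated shortwave with persistent cloud autocorrelation) is
drawn independently, and the lake heat-content series is *derived* by
integrating the package's own flux model with the imposed constant
a_true — the budget closes by construction, which is what makes the
calibration recoverable and the closure check meaningful. Optional
multiplicative noise on the daily increments emulates observation error.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: no internal waves or storm-driven
metalimnion erosion (beyond the scheduled mixing), no nutrient dynamics
or grazing, no horizontal patchiness, no sensor drift or spikes, no
coupling of the profile temperatures to the meteorology. Recovery rates
on real profiles will be correspondingly worse, especially for K_d on
optically heterogeneous days.

## Problem sizes and runtime choices

The test suite and the acceptance script run the full 12-year scenario
(312 profiles × 121 depths), 500 random profiles for the detection
oracles, 1,000 replicates for the K_d bias check and 2,000 null
replicates for the Mann–Kendall calibration — sizes chosen so the whole
chain, including the end-to-end recovery, executes in a few minutes on a
single core while keeping Monte-Carlo standard errors well below the
asserted tolerances.

## Known limitations

- The freshwater density polynomial plus haline contraction is not a
  full equation of state; it is adequate for dilute calcite lakes only.
- The surface-linear K_d rule assumes the top of the profile is the
  cleanest part; wave-focusing contamination at 0 m can be excluded with
  `drop_surface = TRUE`, but systematic near-surface sensor error is not
  modelled.
- The heat-flux formulation fixes one documented set of bulk and
  radiative coefficient defaults; transferring absolute flux values to
  another lake requires re-calibrating `a` (and ideally the transfer
  coefficients) by closure there.
- The seasonal Mann–Kendall p value is asymptotic; for fewer than ~5
  years per season it should be read qualitatively.
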