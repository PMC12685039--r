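---
title: "Methods: chamber N-gas fluxes, moisture physics, and warming responses in warmflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chamber N-gas fluxes, moisture physics, and warming responses in warmflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warmflux)
```

warmflux implements the computational chain of an automated-chamber
soil-warming study: estimating NO and N~2~O fluxes from chamber closures,
aggregating them to daily, seasonal and annual values, relating them to soil
temperature and moisture, upscaling N~2~ from N~2~O, computing net N
transformation rates from incubations, and summarizing warming responses as
effect sizes. A seeded synthetic generator reproduces the statistical
structure of such an experiment so that every stage is testable without
field data. This vignette documents the models, their assumptions, the
tunable parameters, and the design choices made where the methods left the
design open.

## 1. The flux estimator

A chamber closure is modelled as a well-mixed vented chamber. The analyzer
continuously withdraws chamber air at flow `Q` (0.18 m^3^ h^-1^ = 3 L
min^-1^) and ambient makeup air replaces it, so the headspace obeys the mass
balance

$$V\,\frac{dc}{dt} \;=\; F\,A \;+\; Q\,(c_\mathrm{in} - c),$$

with `V` the total system volume (0.091 m^3^), `A` the covered soil area
(0.18 m^2^), `F` the soil flux and `c` mass concentration. The flux
estimator is the hybrid accumulation + dynamic form

$$\hat F \;=\; \left(\frac{dC}{dt}\cdot\frac{V}{A} \;+\;
 (C_\mathrm{out}-C_\mathrm{in})\cdot\frac{Q}{A}\right)\cdot
 \frac{M}{V_0}\cdot\frac{P}{P_0}\cdot\frac{T_0}{T},$$

where `dC/dt` is the OLS slope of the dry mole fraction over the
species-specific regression window — minutes 5–10 for NO (5 min) and 5–20
for N~2~O (15 min), after a 3-min flush with unlocked lids —
`C_out` is the mean chamber concentration over that window, and `C_in` is
the ambient concentration from the 30-s post-opening window. The final
factor (`M` g N per mole of gas: 14 for NO, 28 for N~2~O; `V0` = 22.4 L
mol^-1^, `P0` = 1013 hPa, `T0` = 273 K) converts nmol mol^-1^ to
µg N m^-3^; at standard conditions it is 0.625 (NO) and 1.25 (N~2~O)
µg N m^-3^ per nmol mol^-1^. Input series already in mass-concentration
units bypass the factor via `units = "ug_m3"`.

Two properties are worth noting, and are tested:

* the two terms compensate: over a closure the slope decays like
  $e^{-t/\tau}$ (with $\tau = V/Q \approx 30$ min) exactly as the dilution
  term grows like $1-e^{-t/\tau}$, so on noiseless mass-balance closures
  the estimator recovers the true flux to well under 1 % for both windows;
* `simulate_closure()` evaluates the exact solution of the linear mass
  balance by default, and `method = "ode"` integrates it numerically with
  `deSolve::lsoda()` — the two routes agree to < 0.1 % and are used as
  mutual cross-checks.

Quality control is deliberately light, since the measurement protocol
specifies none: a median-absolute-deviation spike filter (threshold 5 MADs
within the regression window), a minimum of 4 window samples (fewer yields
a flagged record with no flux), and an optional minimum regression R^2^
that is off by default.

## 2. Aggregation and integration

Daily treatment means weight chambers equally (mean over chambers of
chamber means), balancing unequal closure counts; the reported SE is taken
across chamber means and therefore describes chamber-scale spread — the
chambers are nested in plots, so it is not fully independent replication.

Cumulative fluxes treat each daily mean as representative of its 24 h
(1 µg N m^-2^ h^-1^ sustained for one day = 2.4 × 10^-4^ kg N ha^-1^);
interior gaps are filled by linear interpolation up to 7 days, beyond which
the period value is flagged and its coverage fraction reported rather than
silently filled. Annual NO totals assume negligible flux under snow cover
(December 1 – March 31 contributes zero); N~2~O is integrated year-round
because freeze–thaw pulses dominate its dormant-season budget. The season
calendar splits the year into a growing season (May 1 – October 31) and a
dormant season; the simulation calendar uses day-of-year 1–365 with no leap
days.

## 3. Soil physics

WFPS is computed for the 0–10 cm mineral layer as
$\mathrm{WFPS} = \mathrm{VWC} / (1 - \mathrm{BD}/2.65) \times 100$
(bulk density default 0.70 g cm^-3^, quartz particle density 2.65 g
cm^-3^), capped at 100 % with a warning. The organic horizon is tracked
gravimetrically and has no WFPS; WFPS-based operations accept mineral
layers only. The warming-induced moisture change is
$\Delta\mathrm{WFPS} = (\mathrm{WFPS_W} - \mathrm{WFPS_C}) /
\mathrm{WFPS_C} \times 100$. Microbial biomass C and N are derived from
fumigation flushes with extraction efficiencies 0.45 and 0.54; negative
flushes are flagged missing rather than returned as negative biomass.

## 4. Response models and counterfactuals

Fluxes are related to soil state on binned means — 0.5 °C temperature bins
and 1 % WFPS bins, left-closed — which reduces the leverage of the dense
mid-range. The temperature response is $F = A e^{kT}$, fitted by
Levenberg–Marquardt least squares initialized from the log-linear
regression of the positive bins (parameter tolerance 1e-10; bins with
non-positive means are excluded from the initialization only). The apparent
sensitivity is $Q_{10} = e^{10k}$, stored so that the identity with the
fitted `k` is exact. Bins are unweighted by default, matching how binned
response curves are usually plotted; an n-weighted option exists because
no weighting convention is stated for such fits. Whether such fits should
use chamber-level data before binning is unknowable from a figure caption;
the binned-means default follows the caption, and raw-data fits remain
possible by passing unbinned values as single-observation bins.

The moisture response is an ordinary quadratic on WFPS bin means; the
optimum $-c_1/(2c_2)$ is reported only when curvature is negative and the
vertex lies inside the fitted range, since an extrapolated vertex is an
artefact of the polynomial.

The Q~10~-expected counterfactual flux under warming is
$F_\mathrm{exp} = F_\mathrm{control}\,Q_{10}^{\Delta T/10}$, applicable at
any granularity; with $Q_{10}$ = 3.5 (NO) and 2.1 (N~2~O), 2 °C of warming
predicts +28 % and +16 %. `expected_vs_observed()` reports the shortfall
$(F_\mathrm{warmed}/F_\mathrm{exp}-1)\times 100$, the quantity that
contrasts a temperature-only expectation with what drying soils actually
deliver.

## 5. N2 upscaling and incubation rates

N~2~ cannot be measured by chamber in the field; it is scaled from N~2~O
through a moisture-dependent product ratio,
$F_{N_2} = \max(0,\,0.13\,\mathrm{WFPS} - 1.10)\cdot F_{N_2O}$. The linear
model is deliberately temperature-free: the calibration incubations showed
moisture, not temperature, governs the ratio. Below the ratio root
(WFPS ≈ 8.5 %) the ratio clamps to zero — a negative N~2~ efflux from
denitrification is non-physical — and days with negative N~2~O flux return
a flagged missing N~2~ value. The calibration's WFPS domain is not printed
anywhere; the validity range defaults to the span of field WFPS
observations and is configurable, with out-of-range evaluation warning but
proceeding. Scaled N~2~ is integrated over the growing season only, since
the ratio calibration does not extend to frozen soil.

Net N mineralization and nitrification rates come from one-week
incubations: $R_M = ((\mathrm{NH_4^+} + \mathrm{NO_3^-})_\mathrm{after} -
(\mathrm{NH_4^+} + \mathrm{NO_3^-})_\mathrm{before})/T$ and
$R_N = (\mathrm{NO_3^-}_\mathrm{after} -
\mathrm{NO_3^-}_\mathrm{before})/T$; negative net rates are meaningful
(consumption) and are not clipped. Temperature dependence across the 5–25
°C gradient is fitted as $R = a e^{bT}$ (Arrhenius-style apparent
sensitivity over a narrow range) and extrapolated to field temperatures
(15 °C control, 17 °C warmed growing-season means) with a ±5 °C guard band
beyond which prediction warns. The same functional form as the flux
response is fitted by the same routine, and a cross-module test holds the
two to 1e-9 agreement on identical data.

## 6. Effect sizes and the cross-study regression

Warming responses are expressed as $\mathrm{lnRR} = \ln X_W - \ln X_C$
(missing, with a flag, when either mean is non-positive) and as the
per-degree response $\mathrm{RRn} = ((X_W - X_C)/X_C)/\Delta T$, which
makes experiments with different warming magnitudes comparable.
`effect_table()` averages relative effects across sampling times and
attaches a seeded 1000-resample bootstrap SE; the resampling scheme behind
published ±SE values is rarely stated, so a seeded bootstrap is used and
documented. `meta_regression()` is an unweighted OLS of per-site RRn on
ΔWFPS — a cross-site regression, not a variance-weighted meta-analysis —
with the site table echoed into the result for provenance. The predictor's
unit (percent vs fraction) only rescales the slope; R^2^ is invariant, and
that invariance is tested.

The bundled 10-site table (`synthetic_site_table()`,
`inst/extdata/site_table_synthetic.csv`) is synthetic: no real study is
represented. It is constructed to carry the published cross-study pattern —
a positive RRn–ΔWFPS slope with R^2^ = 0.45, and soil-moisture losses
concentrated at sites receiving under ~1,000 mm annual precipitation — by
building residuals orthogonal to the predictor and scaling them to the
target R^2^, then storing internally consistent control/warmed N~2~O means
so the regression is genuinely recomputed from the data. With 10 sites and
R^2^ = 0.45 the slope's t-test gives p ≈ 0.03; the function reports the
computed p-value.

## 7. The synthetic generator

The generator emulates a 6-year, two-treatment (3 + 3 plots, 5 chambers
each, 4 closures per chamber-day) infrared-heater experiment in a temperate
monsoon forest. Its defaults are the study conditions, not free dials:

* **Climate.** Mineral soil temperature is a seasonal sinusoid (mean 10 °C,
  amplitude 15 °C, peaking in late July) plus AR(1) noise (φ = 0.8,
  innovation SD 0.75 °C), spanning roughly −5 to 25 °C. Precipitation is a
  seasonally inhomogeneous event process calibrated to 811 mm y^-1^ with
  ~80 % falling May–September and occasional heavy (≥ 30 mm) events
  (gamma-distributed amounts, shape 0.55). All plots share one weather
  realization; microsite offsets are paired between treatments (plot *j*
  warmed shares the stream of control plot *j*), a matched-pair layout that
  makes the null treatment exactly null.
* **Moisture.** Each layer is a bucket: infiltration gain proportional to
  precipitation (plus snowpack melt released over the days after thaw),
  evapotranspiration proportional to temperature and current wetness, and,
  in the mineral layer, fast drainage above field capacity. Parameters were
  chosen so the control 0–10 cm layer averages ~0.27 m^3^ m^-3^
  (WFPS ≈ 37 %, 2nd–98th percentile ≈ 23–54 %) and the organic horizon
  ~0.81 g H~2~O g^-1^ in the growing season. Moisture observations carry
  small multiplicative noise.
* **Warming.** Warmed plots get +ΔT (default 2.0 °C) year-round and an
  evapotranspiration multiplier calibrated by `uniroot` on the
  deterministic bucket so realized growing-season deficits equal the
  configured −16 % (organic) and −5 % (mineral); the drying scales with
  ΔT/2, so ΔT = 0 reproduces the control bit-for-bit. Setting a layer's
  moisture change to exactly zero switches the moisture pathway off
  entirely — the warmed plot reuses its control pair's moisture series —
  because calibrating only the seasonal mean would leave a daily
  temperature–moisture covariance that contaminates the temperature-only
  limit. The freeze–thaw anchor of warmed plots is advanced by a uniform
  8–11 days, consistent with what the +2 °C shift does to the spring 0 °C
  crossing (~0.19 °C d^-1^ warming rate).
* **Flux surfaces.** NO: $A\,S\,e^{kT}\,g(W)$ with $k = \ln(3.5)/10$,
  $g$ a downward parabola peaking at 35 % WFPS with zeros at 0 and 70
  (clipped at 0), shut off in frozen soil. N~2~O:
  $A\,S\,e^{k_2 T}\,(W/35)$ with $k_2 = \ln(2.1)/10$ — moisture-increasing,
  as growing-season N~2~O behaves. $S$ is a substrate-supply multiplier,
  $(m_O/0.81)^{\gamma}$ on the plot-year growing-season mean
  organic-horizon moisture, with γ = 2.6 (NO) and 1.4 (N~2~O):
  nitrification-driven NO is more substrate-limited than
  denitrification-driven N~2~O. The multiplier operates at plot-year
  resolution because substrate pools integrate moisture slowly; this keeps
  the daily apparent temperature sensitivity clean. It is this pathway —
  not the 2-point WFPS shift through the broad moisture curve — that lets
  16 % surface drying override a +28 % temperature expectation.
* **Freeze–thaw pulses.** After the thaw anchor, both gases receive an
  additive pulse decaying with a 14-day e-folding time, confined to four
  decay times. The pulse carries the substrate multiplier (and the WFPS
  factor for N~2~O) but no temperature factor: it is a transient substrate
  burst near 0 °C, and a temperature factor would let its tail be
  re-amplified by summer warmth. Amplitudes (N~2~O 210, NO 17
  µg N m^-2^ h^-1^) were calibrated once so that the dormant season carries
  ~78 % of annual N~2~O and the growing season ~85–92 % of annual NO.
* **Measurement.** Chamber-day heterogeneity is mean-one lognormal
  (log-SD 0.35); analyzer noise is white (0.2 / 0.3 nmol mol^-1^ for
  NO / N~2~O); ambient mole fractions default to 1 (NO) and 330 (N~2~O)
  nmol mol^-1^ — conventional values, flagged in the configuration because
  the site's ambients are not constrained. One root seed drives everything;
  each stage and each plot-pair × chamber unit derives an independent
  substream, so adding chambers does not perturb existing ones and
  identical configurations reproduce outputs bit-for-bit.
* **Incubations.** Before/after NH~4~^+^/NO~3~^-^ pools at 5–25 °C are
  generated from $R = a e^{bT}$ (b = ln 2 / 10) with net nitrification
  moving NH~4~^+^ to NO~3~^-^, so noiseless pools invert exactly to the
  configured rates. Warmed organic-horizon soils get rate multipliers 0.79
  (mineralization) and 0.86 (nitrification); the mineral layer is
  unaffected, mirroring where drying acts. Moisture is held at its initial
  value — the incubation simulator has no moisture dynamics.

`simulate_experiment()` offers two measurement paths: `"closure"` runs
every chamber-day through closure simulation and the flux estimator
(vectorized; a full 6-year single-species, single-treatment experiment —
131,400 closures — takes about a second), while `"daily"` records the
heterogeneous chamber fluxes directly. Multi-seed treatment-contrast
studies use the daily path because the estimator's fidelity is established
separately (noiseless recovery < 1 %, Monte-Carlo bias < 10 % at realistic
noise); parameter-recovery runs for the apparent Q~10~ use the full closure
path at the default experiment size, 10 seeds.

### What the generator does and does not emulate

It reproduces seasonal and event-scale structure (monsoon precipitation,
freeze–thaw pulses, drying-mediated suppression), the magnitudes of annual
budgets (~0.6 / 1.2 / 0.9 kg N ha^-1^ y^-1^ for NO / N~2~O / N~2~ in
control plots), and the measurement chain. It does not emulate: soil heat
transport or mechanistic evapotranspiration; plant N uptake; diurnal cycles
(all closures in a day share that day's conditions); spatially structured
heterogeneity beyond lognormal chamber effects; instrument drift or data
gaps. Passing tests therefore demonstrate the correctness and internal
consistency of the analysis chain under realistic statistical structure —
not that any particular field dataset would yield the same numbers.

## 8. Numerical choices and degenerate inputs

Exponential fits use Levenberg–Marquardt (`minpack.lm::nlsLM`, parameter
tolerance 1e-10) with a Gauss–Newton fallback; exactly constant inputs
short-circuit to the degenerate solution (k = 0) rather than relying on the
optimizer. A constant concentration window yields slope exactly 0. The
WFPS formula errors when BD ≥ 2.65 (non-positive porosity) and caps
supersaturated readings at 100 % with a warning. `cumulative_flux` treats
daily means as day-step values — the convention under which a constant
10 µg N m^-2^ h^-1^ over 365 days integrates to exactly 0.876 kg N
ha^-1^ — making adjacent-window integration exactly additive.
Configuration files round-trip through YAML at full double precision.

## 9. Known limitations

* The apparent Q~10~ recovered from the full pipeline sits slightly below
  the generator's intrinsic 3.5 (typically ~3.3–3.5 across seeds) because
  moisture co-varies with temperature in the field-like series — the same
  apparent-vs-intrinsic gap the method itself is subject to.
* The dynamic-term convention (post-opening window = incoming ambient air)
  resolves an ambiguity in how such systems are usually described; systems
  that genuinely record outgoing air in that window would need the sign
  convention flipped.
* The SE attached to daily means quantifies chamber spread, not plot-level
  replication; formal treatment inference should use plot means (three per
  treatment) and repeated-measures machinery, which this package invokes
  from standard statistical routines rather than re-implementing.
* The N~2~ estimate inherits every assumption of the moisture-ratio
  calibration, including its transfer from a nearby site and the absence
  of a temperature term.
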