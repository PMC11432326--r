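---
title: "Models and methods behind thermolyase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermolyase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermolyase)
```

thermolyase implements the quantitative analysis chain of a thermostable
enzyme characterization: converting raw spectrophotometric readings into
molar rates, fitting steady-state kinetics, deriving thermal-inactivation
thermodynamics, and fitting two-state thermal-denaturation curves. This
vignette explains each model, its assumptions, the numerical choices, and
what the synthetic-data generators do and do not emulate.

## Units and constants

All energies are in kcal mol⁻¹ and entropies in kcal K⁻¹ mol⁻¹, the
convention of the inactivation tables this kind of study prints; a kJ
display conversion would be cosmetic only and internal computation never
leaves kcal units. `hal_constants()` bundles the gas constant
(R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹), the Boltzmann and Planck constants (SI),
the Eyring transmission coefficient κ (default 1), and the molar extinction
coefficient of *trans*-urocanic acid at 280 nm
(ε = 18,800 M⁻¹ cm⁻¹). Any field can be overridden through a config list;
values must be positive and unknown keys are rejected, so a typo cannot
silently change the thermodynamics.

Temperatures are converted with T = t + 273.15. Published inactivation
tables in this field often label 65/70/75/80 °C as 338/343/348/353 K —
integer kelvins with the 0.15 dropped. Whether that is rounding or
truncation is undecidable from the printed numbers (both reproduce the
tables at print precision), so the package exposes it as an explicit
choice: a `legacy_kelvin` flag converts with the integer offset 273, and
the table-reproduction tests use it because the printed thermodynamics are
consistent with integer kelvins. Exact conversion remains the default
everywhere else.

## Assay conversions

`absorbance_to_rate()` is Beer–Lambert arithmetic on product appearance:
a slope dA/dt over path length l and extinction coefficient ε is a
concentration rate, times reaction volume a molar rate. The instrument's
effective path length is rarely stated, so `pathlength` is a first-class
argument (default 1 cm) rather than a buried constant. The default volume
is 500 µL, the usual scale of these assays.

Optimum profiling returns the raw argmax of the activity profile plus a
plateau interval (conditions within 95 % of the maximum by default). No
smoothing is applied: a smoothed optimum would claim resolution the assay
grid does not have. Ties break toward the lower condition value so the
result is deterministic.

Substrate screening uses the conventional limit-of-detection rule: active
⇔ rate > k·SD(blank) with k = 3 by default. The threshold is recorded in
every result row because the call depends on it.

SEC calibration regresses log₁₀(mass) on retention time — that direction,
not the reverse, because unknowns are read off from a measured retention
time. At least three markers are required; a non-negative slope (larger
proteins eluting later) is physically wrong for size exclusion and warns.
Read-off more than 20 % outside the calibrated range warns about
extrapolation but still returns a value, since a single query point just
outside the markers is routine practice.

## Michaelis–Menten kinetics

`fit_michaelis_menten()` fits v = Vmax·S/(Km+S) by Levenberg–Marquardt,
unweighted by default: assays of this type are usually fitted as plain
hyperbolae without a stated weighting scheme, and an optional 1/v² weighting
is available for data whose error scales with signal. Starting values are
Vmax⁰ = 1.2·max(v) and Km⁰ = the smallest substrate concentration at which
v reaches half its maximum — the standard heuristic, robust because the
design spans 0.25–50 mM. Both parameters are bounded below by zero.
Identifiability requires at least four points with three distinct positive
concentrations; replicates at a single concentration are rejected up front
rather than letting the optimizer wander. A fitted Km outside the sampled
substrate range warns that the fit is poorly constrained.

kcat is never inferred: the molar enzyme amount is an explicit input
because published kcat/Vmax pairs are only consistent with an enzyme
amount that is not itself printed (assay concentrations are typically given
only as a range, e.g. 0.4–4.3 µM). Efficiency kcat/Km is computed from
full-precision fitted values; display layers round afterwards. This
ordering matters: in reference tables of this kind the printed efficiency
differs in the third decimal from the ratio of the printed (rounded) kcat
and Km, which shows the original analyses also divided unrounded values.

## Thermal inactivation

Residual activity is assumed to decay as a single first-order process,
A(t)/A₀ = exp(−kd·t). The fit is ordinary least squares of ln(residual) on
time with a free intercept: the intercept absorbs a normalisation error at
t = 0 instead of letting it bias kd. Points with residual ≤ 0 cannot enter
the log and are dropped with a warning; values above 1.5 are interpreted
as percentages and divided by 100 (also with a warning, never silently).
An estimated kd ≤ 0 — activity rising during pre-incubation — is flagged
and excluded from all downstream thermodynamics. A direct nonlinear
exponential fit is available behind `method = "nls"` for comparison; on
clean first-order data the two agree.

The Arrhenius stage regresses ln kd on 1/T, unweighted, using every
supplied temperature with no outlier rejection; Ea = −slope·R. Two
temperatures give an exact line and warn that no diagnostics remain.
The regression standard error of Ea is reported even though tables of this
kind print none.

Eyring transition-state parameters use

ΔG\* = −R·T·ln(kd·h/(κ·kB·T)),  ΔH\* = Ea − R·T,  ΔS\* = (ΔH\* − ΔG\*)/T,

with kd converted from min⁻¹ to s⁻¹ before entering the Eyring expression
and κ = 1. This combination — per-second rate constants, κ = 1,
kcal units, integer kelvins — is the one convention that reproduces
published activation free energies of this assay type cell-for-cell;
the identities ΔG\* = ΔH\* − T·ΔS\* and ΔH\* = Ea − R·T then hold exactly
by construction, and ΔH\* decreases (weakly) with temperature.

`build_inactivation_table()` chains decay fits → one Arrhenius regression
per enzyme → per-temperature Eyring rows, so a whole campaign reduces to
one tidy table with the per-enzyme Arrhenius fits attached as an
attribute. Unusable series (no decay) are dropped with a warning and the
enzyme's Ea comes from the remaining temperatures; fewer than two usable
temperatures is an error because no activation energy exists then.

One caveat the test suite documents explicitly: in the bundled reference
table, one enzyme block (R280K) prints an activation energy that
least-squares Arrhenius regression of its own printed rate constants does
not reproduce (the regression gives ≈56 kcal/mol against a printed 44.41),
although its per-row ΔG\*/ΔH\*/ΔS\* cells are internally consistent with
the printed value. Which points or precision entered the original
regression is unknowable from the printed table, so the reproduction tests
anchor on the three blocks that are reproducible and record this one as a
discrepancy rather than forcing agreement. Similarly, one printed ΔTm cell
(1.40 K) disagrees with the difference of its own printed melting
temperatures (358.80 − 357.36 = 1.44 K); `delta_tm()` returns the
arithmetic difference.

## Two-state CD melts

The observed ellipticity of a protein unfolding between native (N) and
unfolded (U) states with linear temperature baselines
S_N = A_N + B_N·T and S_U = A_U + B_U·T is

S_obs(T) = (S_N + S_U·K_eq) / (1 + K_eq),
K_eq(T) = exp[−(ΔH_vH/R)·(1/T − 1/Tm)],

so that exactly half the protein is unfolded at Tm. The fraction unfolded
is computed through `plogis()` on the log scale, which saturates cleanly
to 0/1 for extreme enthalpies instead of overflowing.

`fit_two_state_melt()` fits all six parameters (Tm, ΔH_vH, four baseline
coefficients) by Levenberg–Marquardt. ΔH_vH is log-parameterised during
optimisation: a cooperative unfolding transition has positive van't Hoff
enthalpy, and the log keeps the optimizer away from the sign boundary
without a hard constraint. Initialisation: baselines from straight-line
fits to the first and last 10 % of points; Tm from the extremum of the
derivative of signal versus temperature, computed on a median-smoothed
(running median, window 7) signal differenced over a five-point gap —
point-to-point differences on a dense 0.2 K grid are dominated by detector
noise and made the start point unreliable, while the smoothed derivative
locates the transition to within a few grid steps at the noise levels the
generator produces. If that extremum falls at the edge of the grid there
is no transition inside the window and the fit is flagged rather than
returned; a pure straight line is therefore rejected, not "fitted".

The fitting window defaults to 62–95 °C (335.15–368.15 K), the span over
which melts of these thermostable enzymes show both baselines and the
transition; points outside are excluded with a message and `window = NULL`
fits everything. The model is invariant under any affine rescaling of the
signal, so fitting in mdeg or mean-residue ellipticity gives identical Tm
and ΔH_vH (only the RSS units change) and no unit conversion is required
or performed.

Thermal unfolding of these proteins is irreversible — they aggregate upon
heating and do not refold — so the two-state fit is an operational
description of the transition, not an equilibrium analysis. Outputs are
deliberately labelled Tm(app) and ΔH_vH(app), and the package never
derives an equilibrium unfolding free energy from them.

## Synthetic data

The generators produce data with the statistical structure each fitter
assumes, under a mandatory integer seed (identical parameters ⇒ identical
output):

- `sim_mm_dataset()` — velocities on a 12-point geometric ladder over
  0.25–50 mM (the span of these assays), multiplicative gaussian noise by
  default because absorbance-assay error scales with signal; additive
  noise is available. Negative draws clip to zero and are counted.
- `sim_decay_series()` — exponential decays with multiplicative noise;
  nonpositive draws are resampled (with a message) so the log fit stays
  defined. Default time grids span roughly two half-lives, minutes at the
  hottest temperatures and up to 24 h at the coolest, matching assay
  practice.
- `sim_arrhenius_campaign()` — per-temperature rate constants from
  kd(T) = exp(lnA − Ea/(R·T)), fixed either by lnA or by an anchor pair
  (T_ref, kd_ref) through which the law passes exactly; one decay series
  per temperature with derived per-temperature seeds.
- `sim_melt_curve()` — two-state signal on a 335–368 K grid at 0.2 K steps
  (the acquisition density of a thermostated CD melt) with additive noise
  scaled by the transition amplitude, since detector noise does not track
  the ellipticity signal. A midpoint outside the grid is allowed but
  warned about — deliberately unfittable curves are useful test inputs.

Default noise levels (2 % for rates and melts, 3 % for decays) are package
conventions chosen as realistic replicate scatter for these instruments;
true replicate noise magnitudes are not published for this assay family.
The generators emulate noise structure and design grids only. They do not
simulate instrument drift, scan-rate effects, aggregation kinetics during
the melt, substrate depletion during initial-rate measurement, or
systematic pipetting error — so a passing recovery suite demonstrates that
the estimators are unbiased and well-calibrated under the assumed error
model, not that real data meet those assumptions.

## Test design and problem sizes

Every fitter is checked three ways: exact recovery on noiseless generator
output; agreement with an independent brute-force oracle (a 200×200
log-spaced (Km, Vmax) grid for the hyperbola; a 50×50 (Tm, ΔH_vH) grid
with baselines solved by linear least squares at each node for the melt);
and Monte-Carlo calibration over 200 seeded replicates per experiment type
(12-point rate datasets at 2 % noise, 8-point decays at 3 %, 165-point
melts at 2 % of amplitude), with median bias required below 2 % for
Km/Vmax, 1 % for kd, and 0.05 K for Tm. These sizes keep the full suite
under a minute while leaving the Monte-Carlo medians stable to well within
the asserted bounds.

## Known limitations

- Single-exponential inactivation only: no biphasic or Lumry–Eyring
  (unfolding-then-aggregation) models, although irreversibility is exactly
  why the melt outputs are labelled apparent.
- No substrate inhibition, Hill cooperativity, or bi-substrate kinetics;
  no progress-curve (integrated rate law) fitting.
- CD secondary-structure decomposition is out of scope; retention-time
  peak picking is out of scope (retention times are inputs).
- Asymptotic standard errors from the nonlinear fits are first-order
  approximations; for small noisy datasets a bootstrap would be more
  honest, and none is provided.
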