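# thermolyase

Quantitative analysis of the biochemical characterization of thermostable
histidine ammonia-lyases (HALs) and similar enzymes. HAL catalyses the
non-oxidative deamination of L-histidine to *trans*-urocanate; its activity
is followed spectrophotometrically through urocanate absorbance at 280 nm
(ε = 18,800 M⁻¹ cm⁻¹). The package covers the full desk-side analysis chain
of such a characterization study, for enzymologists and protein
biophysicists who have raw assay readings, residual-activity time courses,
or CD melt traces and want kinetic constants and stability thermodynamics
with reproducible provenance:

- **Assay arithmetic** — Beer–Lambert conversion of absorbance slopes into
  molar rates, pH/temperature optimum profiling, substrate-panel screening
  with a limit-of-detection rule, and size-exclusion calibration
  (log₁₀ Mm vs retention time) with native-mass and oligomeric-state
  read-off.
- **Michaelis–Menten kinetics** — nonlinear least-squares fits of
  *v* = *V*max·*S*/(*K*m + *S*), turnover numbers
  *k*cat = *V*max/60/*n*E, catalytic efficiencies *k*cat/*K*m, and
  fold-decreases against a reference enzyme.
- **Thermal inactivation** — first-order decay fits of residual activity
  (ln *A/A₀* vs *t*, *k*d = −slope, *t*₁/₂ = ln 2/*k*d), Arrhenius
  regression of ln *k*d vs 1/*T* for the activation energy *E*a, and Eyring
  transition-state thermodynamics
  ΔG\* = −*RT* ln(*k*d·*h*/(κ·*k*B·*T*)), ΔH\* = *E*a − *RT*,
  ΔS\* = (ΔH\* − ΔG\*)/*T*, in kcal-based units.
- **CD thermal denaturation** — six-parameter two-state van't Hoff fits of
  ellipticity melts with linear native/unfolded baselines, yielding the
  apparent midpoint *T*m(app), the apparent van't Hoff enthalpy, the
  fraction-unfolded curve, and ΔTm comparisons between variants.
- **Synthetic data** — seeded generators for every experiment type
  (hyperbolic rate curves, exponential decays tied together by an Arrhenius
  law, sigmoidal melts), so the whole pipeline is testable and
  demonstrable without instrument data.

All user-facing functions take a data frame first and return tibbles or
small S3 fit objects with `tidy()`, `glance()`, `predict()` and
`autoplot()` methods, so analyses chain with the pipe.

## Worked example

Simulate a four-temperature inactivation campaign (65–80 °C) whose rate
constants follow an Arrhenius law with *E*a = 49.42 kcal/mol, anchored at
*k*d(353 K) = 0.0206 min⁻¹, with 3 % multiplicative noise — then run the
full analysis chain:

```r
library(thermolyase)

camp <- sim_arrhenius_campaign(Ea = 49.42, anchor = c(353, 0.0206),
                               noise_sd = 0.03, seed = 101, enzyme = "WT")
tab <- build_inactivation_table(camp)
render_table2(tab)
#> # A tibble: 4 × 8
#>   enzyme Ea_kcal_mol temperature_K t_half_min kd_min dG_kcal_mol dH_kcal_mol
#> 1 WT            49.3           353         34 0.0203        26.4        48.6
#> 2 WT            49.3           348         96 0.0073        26.7        48.6
#> 3 WT            49.3           343        267 0.0026        27.0        48.6
#> 4 WT            49.3           338        777 0.0009        27.3        48.7
attr(tab, "arrhenius")$WT
#> Arrhenius fit (4 temperatures): Ea = 49.34 kcal mol^-1 (SE 0.23), lnA = 66.434, R^2 = 1.0000
```

Each row is one pre-incubation temperature: the half-life and rate constant
come from the log-linear decay fit, the single *E*a from the Arrhenius
regression across temperatures, and ΔG\*/ΔH\*/ΔS\* from the Eyring
relations at that temperature. With 3 % noise the recovered *E*a (49.34)
sits well within one standard error of the generating 49.42 kcal/mol.

The same pattern drives the other stages:

```r
# Michaelis-Menten: Km/Vmax/kcat/efficiency from initial rates
d <- sim_mm_dataset(Km = 4.83, Vmax = 4.243e-7, noise_sd = 0.02, seed = 101)
fit_michaelis_menten(d, enzyme_moles = 5.78e-10)
#> Michaelis-Menten fit (12 points):
#>   Km   = 4.675 mM (SE 0.093)
#>   Vmax = 4.217e-07 mol min^-1 (SE 2.6e-09)
#>   kcat = 12.16 s^-1;  kcat/Km = 2.601 mM^-1 s^-1

# CD melt: apparent Tm from a two-state fit with linear baselines
mc <- sim_melt_curve(Tm = 357.36, dHvH = 150, noise_sd = 0.02, seed = 101)
fit_two_state_melt(mc)
#> Two-state melt fit (165 points):
#>   Tm(app)   = 357.46 K (SE 0.0969)
#>   dHvH(app) = 141.9 kcal mol^-1
```

Published inactivation tables of this kind print both their inputs (the
per-temperature *k*d) and their outputs (*E*a, *t*₁/₂, ΔG\*, ΔH\*, ΔS\*),
so the whole thermodynamic chain can be recomputed directly from printed
values, e.g. `eyring_parameters(353, 0.0206, Ea = 49.42)` returns
ΔG\* = 26.38, ΔH\* = 48.72, ΔS\* = 0.063.

A thin command-line front end over the same functions ships in
`inst/scripts/thermolyase.R` (subcommands `simulate`, `mm-fit`,
`inactivate`, `melt-fit`, `secfit`, `screen`; CSV in, TSV + JSON out).

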