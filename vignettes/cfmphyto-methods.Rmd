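---
title: "CFM-Phyto-T: model, pipeline and synthetic mesocosm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CFM-Phyto-T: model, pipeline and synthetic mesocosm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmphyto)
```

# The scientific problem

Phytoplankton elemental stoichiometry (N:C, P:C, N:P) and the partitioning of
biomass among functional macromolecules respond strongly to temperature,
light and nutrient supply, with consequences that propagate up freshwater
food webs: zooplankton require relatively P-rich food, so warming that raises
phytoplankton N:P degrades food quality even when biomass rises.  This
package implements CFM-Phyto-T, a coarse-grained, steady-state cell model
that predicts stoichiometry and macromolecular allocation from three
forcings — temperature, irradiance and the realized specific growth rate —
under a phosphorus-limited regime, together with the full analysis pipeline
needed to drive it from mesocosm tank time series and to compare its
predictions with observations.

# The cell model

The cell is divided into five pools, each a bundle of biomolecules with fixed
elemental composition:

* **biosynthetic** — ribosomes/RNA plus biosynthetic protein; scales with
  growth demand and shrinks as temperature raises enzymatic efficiency;
* **photosynthetic** — chlorophyll, photosynthetic protein, thylakoid
  membranes; sized so carbon fixation pays the carbon bills;
* **C storage** — carbohydrate/lipid reserve; the residual of the carbon
  budget;
* **N storage** — a fixed nitrogen reserve with its carbon skeleton;
* **essential** — DNA and the structural minimum; constant.

All pool sizes are expressed as fractions of total cell carbon.  Three rate
laws drive the budget:

$$P^{chl}(I) = P^{chl}_{max}\,(1 - e^{-a_I I}), \qquad
  R_m(T) = R_m^{ref}\,Q_{10}^{(T - T_{ref})/10}, \qquad
  k_{bio}(T) = k_{bio}^{ref}\,e^{\frac{E_a}{R}
  \left(\frac{1}{T_{ref}} - \frac{1}{T}\right)}.$$

The steady-state carbon balance requires chlorophyll-specific photosynthesis
to cover growth, biosynthetic overhead and maintenance:

$$\mathrm{Chl{:}C} = \frac{\mu\,(1 + E_{bio}) + R_m(T)}{P^{chl}(I)},$$

giving a photosynthetic pool $\mathrm{Chl{:}C}\,(1 + f_{pp} + f_{thy})$.
The biosynthetic pool is $\mu / k_{bio}(T)$, split internally between RNA
(share $f_{rna}$) and biosynthetic protein.  The essential pool is the
constant $C_{ess}$ (DNA share $f_{dna,ess}$), the N store contributes
$N_{store}/\mathrm{N{:}C}_{nstore}$ of skeleton carbon, and C storage takes
the remainder of the unit carbon budget.  A negative remainder means the
forcing cannot be sustained; this is an explicit infeasibility error carrying
the offending tank and day, never a silent clamp.

Nitrogen and phosphorus contents follow from the composition table
(`default_composition()`): protein and chlorophyll carry N but no P; RNA and
DNA carry both; the thylakoid membrane carries a small phospholipid P:C; the
carbohydrate store carries neither.  Because the model is built for a
phosphorus-limited regime, **no phosphorus is ever allocated to storage**:
cellular P is dominated by RNA, which is why warming — which shrinks the
biosynthetic pool — raises N:P.  The same mechanism makes the biosynthetic
carbon fraction decrease with temperature and increase with growth rate,
the photosynthetic fraction decrease with irradiance, and C storage move
opposite to the other variable pools.

```{r}
sw <- sweep_allocation(seq(16, 28, by = 4), I = 300, mu = 0.3,
                       cell_parameters_profile("eukaryote"))
sw[c("T_C", "NC", "PC", "NP", "C_biosynthetic", "C_C_storage")]
```

## Interpreting the constancy of essential and N-storage pools

Per unit total carbon, the essential pool ($C_{ess}$, with its N and P) and
the N store ($N_{store}$ and its skeleton) are exactly invariant to forcing.
Their *shares* of total N or P necessarily co-vary with the totals; the
package's invariance tests therefore assert constancy of the carbon
fractions and of the per-unit-carbon element contents, which is the model's
actual structural property.

## Parameters

All constants live in `inst/extdata/parameters.yaml`, not in code.  Two
profiles ship: `community` (average-community calibration) and `eukaryote`
(a Raphidocelis-like green alga).  Defaults and rationale:

| parameter | default | units | rationale |
|---|---|---|---|
| `Pmax_ref` | 25 | d⁻¹ | chlorophyll-carbon-specific fixation; literature range roughly 20–60 d⁻¹ for freshwater chlorophytes. Lower values force unrealistically high Chl:C (> 0.2) at mesocosm growth rates |
| `a_I` | 0.01 | (µmol photons m⁻² s⁻¹)⁻¹ | saturation near 300–500 µmol photons m⁻² s⁻¹ |
| `E_bio` | 0.25 | – | ~20% of fixed carbon lost to biosynthetic overhead/excretion |
| `Rm_ref` | 0.1 (community), 0.25 (eukaryote) | d⁻¹ | the eukaryote profile's raised maintenance carbohydrate consumption is the tuned delta; the exact tuned value is not published, so it is provisional |
| `Q10_R` | 2 | – | canonical respiration Q10 |
| `k_bio_ref` | 2 | d⁻¹ | biosynthetic pool of 0.25 of cell C sustains µ = 0.5 d⁻¹ at 20 °C |
| `Ea_bio` | 70 000 | J mol⁻¹ | mid-range activation energy for protein synthesis |
| `T_ref` | 293.15 | K | 20 °C, the ambient mesocosm regime |
| `f_pp`, `f_thy` | 1.5, 0.4 | – | photosynthetic protein and thylakoid C per chlorophyll C |
| `C_ess` | 0.15 (community), 0.18 (eukaryote) | – | structural minimum |
| `N_store` | 0.01 | mol N (mol C)⁻¹ | small fixed N reserve |
| `f_rna` | 0.35 | – | RNA share of biosynthetic carbon; fixed, so declining RNA with warming follows from the shrinking pool |
| `f_dna_ess` | 0.1 | – | DNA share of essential carbon |

Composition ratios use standard biochemistry: protein N:C = 0.27, RNA/DNA
N:C ≈ 0.38/0.39 and P:C = 0.105, chlorophyll-a N:C = 4/55 ≈ 0.073,
thylakoid P:C = 0.024 (phospholipid), N-store N:C = 0.5
(cyanophycin-like).  A Q10 law is used for maintenance (vs Arrhenius)
because maintenance consumption is treated as a tuned constant with mild
temperature scaling; the choice is swappable through the parameter file.

## Numerical choices

* Kelvin internally, Celsius at every I/O boundary.
* Negative observed growth rates (bloom crash) are clamped to zero before
  model evaluation — the steady-state balance describes a growing cell —
  and the raw rate is preserved alongside (`mu`, `mu_model`).
* N:P is reported `NA` (never infinite) when P:C = 0.
* Infeasible forcings are flagged rows in sweeps and predictions, errors in
  single-point calls.
* Parameter fitting minimises relative residuals of N:C and P:C by
  Levenberg–Marquardt on log- (positive parameters) or logit-
  (`C_ess`) transformed coordinates; infeasible trial points contribute a
  finite penalty residual of 10³.

# Forcing from tank time series

Sensor streams are reduced to the 07:00–09:00 (closed-open) morning window
mean, matching the time of grab sampling.  Growth rates use the standard
exponential estimator $\mu = \ln(C_f / C_i) / \Delta t$ on triplicate-mean
counts, with $\Delta t$ the actual day gap; the rate of the interval
starting at day $d$ is assigned to day $d$, and the final day carries its
backward interval.  (A superficially similar form sometimes seen in print,
$\ln(C_f - C_i)/\Delta t$, is dimensionally inconsistent and cannot produce
the negative rates a bloom crash requires; the ratio form above is the
standard estimator.)  Days missing
temperature or irradiance are excluded with a logged reason.  Nutrient
limitation defaults to constant P limitation, as fixed by the experimental
design; an optional dissolved-N:SRP ratio rule (threshold 16) is available
but off by default.

# The synthetic mesocosm generator

The generator emulates the design and statistical structure of a 12-tank
warming experiment: 2 populations × 2 treatments × 3 replicates over days
0–14, heated tanks +4.5 °C above ambient from Day 1 (ramping during Day 0,
when heating starts at inoculation), ambient daily means spanning
18.6–21.5 °C with the warmest day on Day 8 and the coldest on Day 11, a
storm-driven low-irradiance event on days 9–11 (Day 0 the brightest), daily
triplicate counts, every-3rd-day stoichiometry and nutrient samples, and a
P-limited bloom and crash.  The nutrient addition is configured by its
molar supply ratio directly (default N:P = 100).  The reagent masses
associated with this design — 55 g NaNO₃ (≈ 0.647 mol N) and 1.811 g
KH₂PO₄ (≈ 0.0133 mol P) per tank, nominally 100 mol N : 1 mol P — in fact
imply a molar ratio near 49; the generator follows the nominal ratio and
leaves the discrepancy noted here rather than resolving it.

Bloom dynamics are deliberately *simpler* than CFM-Phyto-T — daily-step
growth scaled by a Q10 temperature factor, a saturating light factor and
Monod uptake on dissolved P, with drawdown against fixed cell quotas
stopping at machine zero and a constant background mortality — so that
generator and model are not circular for count dynamics.  Only the
stoichiometry *observations* are model-derived truth (evaluated under the
realized morning-window forcing, eukaryote profile for the monoculture and
community profile for the mixed tanks, with 5% lognormal measurement
noise), which is exactly what parameter-recovery and pipeline round-trip
validation require.  Generator defaults (µ_max = 1 d⁻¹ at 20 °C,
Q10 = 2, mortality 0.15 d⁻¹, quotas 1.5·10⁻¹³ mol C, 2.5·10⁻¹⁴ mol N,
5·10⁻¹⁵ mol P per cell, inoculum 10³ cells mL⁻¹, 2.5 µmol P L⁻¹ supplied)
produce peak densities near 4·10⁸ cells L⁻¹ with heated tanks peaking
higher and earlier, in the range the mesocosm literature reports for green
algal blooms.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: species contamination and succession, zooplankton
grazing, self-shading and the reflectance-based irradiance measurement,
nutrient remineralisation from dead biomass (dead cells retain their quota),
luxury P uptake, and any mismatch between the steady-state model and real
cell physiology.  The pipeline round-trip (regression slope ≈ 1, R² > 0.9
on synthetic data) demonstrates that the *plumbing* attributes misfit to
data rather than to itself, not that the model fits real mesocosms.

All stochastic components derive from one seed via per-stage substreams;
`noise = FALSE` disables every one of them (sensor noise, climatology
anomaly, cloudiness draws, count/sample noise), leaving the deterministic
design, which is what the daily-mean temperature envelope statistics are
computed from.  Runs are regenerable byte-identically from the written
manifest.

# Model–observation comparison

Observed ratios are regressed on predictions by OLS with intercept (the
1:1-plot regression), matched on (tank, day); unmatched rows are reported.
Two-factor fixed-effects ANOVA (treatment × population, per-tank means as
replicates, interaction when replicated) tests design effects; empty design
cells are an explicit error, and raw p-values are reported without
multiple-testing adjustment.  The chlorophyll comparison converts predicted
Chl:C to µg chl-a L⁻¹ via observed particulate carbon (893.5 g chl-a per
55 mol chlorophyll C) and flags order-of-magnitude agreement.  Because the
ANOVA factor pairing is not uniquely determined by the source design,
treatment × population with days collapsed by mean is the default and the
factor columns are arguments.

# Problem sizes and test design

The test suite exercises: 1000 random forcings for element conservation
(sums to 1 within 10⁻⁹), temperature sweeps at 0.5 °C resolution over
15–30 °C for both profiles, irradiance sweeps over 25–1000 µmol photons
m⁻² s⁻¹, parameter recovery with n = 30 observations at 5% lognormal noise
(15% recovery tolerance confirmed by pilot runs: typical errors are ~2% for
`k_bio_ref` and ~4% for `Ea_bio`), and the full default 12-tank × 15-day
pipeline.  These sizes were chosen as the smallest that exercise every
mechanism at the study's own scale; the complete suite runs in well under a
minute.

# Known limitations

* Steady-state only: no dynamic (time-stepping) cell model, no
  nutrient-uptake kinetics, cell-size scaling, photoinhibition or mortality
  terms inside the cell model.
* The eukaryote profile's deltas (raised `Rm_ref`, larger `C_ess`) are
  provisional: which constants beyond maintenance consumption were tuned in
  the original calibration, and to what values, is not published.
* Whether maximum photosynthesis photoacclimates with temperature is not
  determinable from the source experiment; `Pmax_ref` is
  temperature-independent here.
* The generator emits downwelling-style irradiance; no reflectance transform
  is applied because no transfer function is available.
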