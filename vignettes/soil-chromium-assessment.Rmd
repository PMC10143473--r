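---
title: "Assessing soil chromium in industrial regions: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing soil chromium in industrial regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crsoil)
```

## The problem

Total chromium accumulates in industrial soils through mining and smelting
waste, electroplating effluent, tannery sludge, and — most severely —
chromite ore processing residue from chromium-salt production. National
pictures of this contamination are typically assembled from published
site studies: one row per industrial region, carrying the province, the
industry type, the sampling year, and the measured total-Cr concentration.
`crsoil` implements the full assessment chain such a compilation feeds:
pollution indices, ecological risk, human health risk with uncertainty,
hotspot-area summaries, and a temporal trend.

Six industry-type codes are used throughout: `M` (mining), `S` (smelting
and heavy-metal processing), `E-w` (e-waste treatment), `El`
(electroplating), `T` (tanning and tannery-sludge storage), `C`
(chromium-salt production and residue disposal).

## Pollution and ecological-risk indices

For a region with measured concentration $C_n$ (mg/kg) and geochemical
background $B_n$ (mg/kg), the geoaccumulation index is

$$I_{geo} = \log_2\!\frac{C_n}{1.5\,B_n},$$

the 1.5 damping natural lithogenic variability in the baseline. The
Hakanson monomial potential ecological risk index is

$$E = T_n \cdot \frac{C_n}{B_n},$$

with toxic response coefficient $T_n = 2$ for Cr. The two are linked by
the exact identity $I_{geo} = \log_2(E / (1.5\,T_n))$, which the test
suite uses as an internal consistency oracle.

Classification follows the standard schemes. $I_{geo}$: class 0 for
$I_{geo} \le 0$, unit-interval classes $(k-1, k]$ for $k = 1..5$
(upper-closed), class 6 ("extremely polluted") beyond 5. $E$: low
$< 40$, moderate $[40, 80)$, considerable $[80, 160)$, high $[160, 320)$,
significant high $\ge 320$ (lower-closed). Both boundary conventions are
deliberate, documented choices — class membership at exactly 0, 5, 40 or
320 is pinned by tests — and the $E$ breaks are overridable for
sensitivity analyses.

Background values: the package ships only the 61 mg/kg national soil-Cr
background as the universal fallback. Provincial backgrounds vary by
compilation and era, so they are user-supplied via the config; every
per-region result records `bn_used`, keeping the provincial-vs-national
choice auditable. Exceedance comparisons (background, and the 2500 mg/kg
industrial screening value) use strict `>` by default — "exceeding" a
threshold is read as being beyond it — with a `strict = FALSE` switch.
The sample standard deviation uses the unbiased $n-1$ denominator and
$CV = 100\,s/\bar{x}$.

## Health-risk model

The non-carcinogenic model is the USEPA three-pathway soil exposure
scheme. Doses in mg/(kg·day):

$$ADD_{ing} = \frac{C_n \cdot IngR \cdot EF \cdot ED \cdot CF}{BW \cdot AT},
\qquad
ADD_{derm} = \frac{C_n \cdot SA \cdot AF \cdot ABS \cdot EF \cdot ED \cdot CF}{BW \cdot AT},
\qquad
ADD_{inh} = \frac{C_n \cdot InhR \cdot EF \cdot ED}{PEF \cdot BW \cdot AT}.$$

The reported hazard quotient is the sum over pathways of $ADD_i / RfD_i$
(a single-metal hazard index); a config switch restricts the sum to any
pathway subset for variants of the model that consider ingestion only.
Everything is linear in $C_n$, so receptor-to-receptor ratios are
concentration-independent — another identity the tests exploit.

Default exposure parameters are the handbook conventions (child: soil
ingestion 200 mg/day, body weight 15 kg, exposure 350 days/year over 6
years; adults: 100 mg/day over 24 years; particulate emission factor
$1.36\times 10^9$ m³/kg; conversion factor $10^{-6}$ kg/mg). Reference
doses default to the conservative total-Cr-as-Cr(VI) values: oral
$3\times10^{-3}$, dermal $7.5\times10^{-5}$ (oral × 0.025
gastrointestinal absorption), inhalation $2.86\times10^{-5}$ mg/(kg·day)
from the Cr(VI) particulate reference concentration. These are
repository defaults, clearly not survey-asserted values; any published
parameterisation can be reproduced exactly through the YAML config.
With these defaults children carry the highest HQ at any concentration,
consistent with their higher intake-to-body-weight ratio. Carcinogenic
risk of Cr(VI) is out of scope: speciated Cr(VI) concentrations are
rarely reported, so only total-Cr non-carcinogenic risk is modelled.

## Monte Carlo uncertainty

`run_mc()` draws every stochastic input (`cn` and/or any exposure
parameter) from its configured distribution (point, uniform, normal,
lognormal, triangular; optional truncation), evaluates the deterministic
model per iteration, and summarises the total HQ. Numerical choices:

* One seeded RNG stream per run with a fixed iteration order, so results
  are exactly reproducible and independent of any parallel scheduling.
* Truncation is applied by inverse-CDF restriction (uniforms mapped into
  the truncated CDF range), never by rejection — no draws are discarded,
  which keeps the draw count and the stream position deterministic.
* Percentiles use the median-unbiased estimator (`quantile(type = 8)`);
  spreadsheet Monte Carlo tools do not document their estimator, so a
  defensible one is fixed here.
* 10,000 iterations by default, the conventional size for probabilistic
  health-risk assessment; with all inputs point masses the summary
  collapses exactly onto the deterministic HQ, a limit the tests assert.

`rank_sensitivity()` reports the Spearman correlation of each stochastic
input with the HQ, the standard companion analysis: monotone-increasing
inputs (concentration, intake rates) show $\rho > 0$, denominator-only
inputs (body weight) $\rho < 0$.

## Spatial and temporal structure

Regions aggregate into five priority hotspot areas (Yangtze River Delta,
Bohai Rim, Pearl River Delta, Yangtze River Basin, Yellow River Basin)
plus `other`, via a province→area map. The shipped default map takes the
deltas' and rim's core provinces and standard riparian membership for the
basins; it is fully overridable, and a province listed under two areas in
a user map resolves to the delta/rim label (the priority order of
`hotspot_areas`) with a warning. Per area the package reports class
distributions of both indices and each area's share of the
screening-value exceedance count.

The temporal trend is fitted to the *median* concentration of each
sampling year — medians because the data are strongly right-skewed — on
the log scale. The default model is a quadratic in calendar year on
log10 medians: the minimal shape able to express the documented
rise-then-fall of industrial soil Cr, with its vertex $-b/(2a)$ the
turning year. Both the degree (2 or 3) and the log base (log10 or ln)
are config options, since compilations differ and neither choice is
canonical. Years are centered before solving the normal equations
(conditioning), and coefficients are de-centered for reporting; on exact
quadratic input the calendar-year coefficients are recovered to a
relative $10^{-9}$. A fitted $|a| < 10^{-12}$ reports the vertex as
absent rather than a meaningless far-away year.

## The synthetic-data generator

National literature compilations are rarely deposited, so the package
generates statistically faithful stand-ins. Within industry type,
concentrations are lognormal — heavy right skew is the defining feature
of industrial soil-metal data — with a type-specific geometric mean and
GSD. A shared multiplicative year effect $10^{q(y) - \bar q}$ moves the
population log-median along the configured quadratic $q$; subtracting the
year-range mean $\bar q$ preserves each type's marginal geometric mean,
and means the generator and `fit_trend()` share one model, giving clean
parameter-recovery tests. Provinces are drawn from fixed per-area lists.

`default_paperlike_spec()` fixes the study conditions: 506 regions over
2002–2021; type mix dominated by mining and smelting with small tanning
(3.4%) and chromium-salt (5.1%) shares; type geometric means expressed as
$91.5 \cdot 2^g$ so that $g$ is the type's expected mean $I_{geo}$
against the 61 mg/kg background, with
$g = (-0.73, -0.24, 0.30, 1.11, 3.7, 5.1)$ for M, S, E-w, El, T, C; GSDs
of $e^{0.9}$ for the four common types and $e^{1.0}$, $e^{1.15}$ for T
and C; trend vertex 2009 with curvature $a = -0.006$ per year². The C
and T levels and the curvature were set once by a normal-theory power
calculation so that a 500-region draw reproduces the qualitative
fingerprints — per-type mean $I_{geo}$ ordering C > T > El > E-w > S > M
in at least 95% of seeds, overall CV above 300%, and vertex recovery
within ±1.5 years at 2,000 regions — while keeping the overall mean
concentration (≈500–700 mg/kg) and range realistic for such compilations.
The widened C–T gap (1.4 in $\log_2$ rather than the ≈0.7 typical of
printed per-type means) is deliberate: with realistic GSDs and only
~17–26 regions in those types, a narrower gap cannot be ordered reliably,
and the generator targets distributional structure, not any particular
compilation's point estimates.

What the generator does *not* emulate: spatial correlation within
provinces, publication bias toward heavily polluted sites, censored
non-detects, repeated measurements of one site across years, and any
type-by-area interaction. Passing tests on synthetic draws therefore
demonstrate the pipeline's correctness and statistical power under the
stated model, not claims about any real region.

## Degenerate inputs and edge behaviour

Non-positive concentrations are rejected at parse time ($I_{geo}$ is
undefined at 0; substitution policies for non-detects are a config
concern, off by default). Empty industry types or areas are omitted from
summaries with a warning. Zero exceedances make area shares 0 rather
than 0/0. A GSD of exactly 1 is allowed in the generator and collapses a
type onto its (year-adjusted) median — the closed-form limit used in
tests. Monte Carlo runs below 100 iterations warn about unstable
percentiles.

## Problem sizes

The shipped tests run the full chain at the sizes the analyses are meant
for: single draws of 250–506 regions for pipeline checks, 100-seed
ensembles of 500-region draws for the generator-fidelity checks, 100-seed
ensembles of 2,000-region draws for vertex recovery, and 10,000-iteration
Monte Carlo runs. The complete suite finishes in well under a minute on
one CPU.

## Known limitations

* Only total Cr is modelled; Cr(VI) speciation, and with it carcinogenic
  risk, is excluded.
* The health-risk defaults are handbook conventions; absolute HQ levels
  are only as good as the exposure parameters supplied.
* The trend model is descriptive curve-fitting on yearly medians, not a
  causal or autocorrelation-aware time-series model; with few distinct
  years the vertex estimate is fragile.
* The default province→area map is coarse; basin membership in
  particular is a modelling convenience and should be overridden when a
  specific delineation is required.
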