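# crsoil

Assessment of total chromium (Cr) contamination in industrial soils:
pollution level, ecological risk, human health risk, spatial hotspot
summaries, and temporal trends. The package is aimed at environmental
scientists and regulators who compile soil-Cr measurements from many
industrial regions (mining, smelting, e-waste, electroplating, tanning,
chromium-salt production) and need reproducible region-level and
national-level risk statistics.

## Models

**Geoaccumulation index** (Müller index), per region with measured
concentration `Cn` (mg/kg) and geochemical background `Bn` (mg/kg):

    Igeo = log2( Cn / (1.5 * Bn) )

classified into seven classes, from class 0 (`Igeo <= 0`, unpolluted) to
class 6 (`Igeo > 5`, extremely polluted).

**Monomial potential ecological risk index** (Hakanson), with toxic
response coefficient `Tn` (2 for Cr):

    E = Tn * Cn / Bn

classified as low (`E < 40`), moderate, considerable, high, and
significant high (`E >= 320`).

**Non-carcinogenic health risk** follows the USEPA three-pathway soil
exposure model. For each receptor group (child, adult male, adult female)
the average daily doses are

    ADD_ing  = Cn * IngR * EF * ED * CF / (BW * AT)
    ADD_derm = Cn * SA * AF * ABS * EF * ED * CF / (BW * AT)
    ADD_inh  = Cn * InhR * EF * ED / (PEF * BW * AT)

and the reported hazard quotient is `HQ = sum(ADD_i / RfD_i)` over the
three pathways; `HQ > 1` flags a potential non-carcinogenic effect.
Exposure-parameter uncertainty is propagated by seeded Monte Carlo
simulation (10,000 iterations by default) with Spearman rank-correlation
sensitivity analysis.

**Temporal trend**: ordinary least squares of `log10(median Cr)` per
sampling year on a centered-year quadratic; the vertex `-b/(2a)` marks the
year the accumulation trend turns around.

Because national literature compilations of this kind are rarely deposited,
the package includes a seeded synthetic-data generator
(`default_paperlike_spec()`) producing region tables with the documented
structure of such compilations: lognormal within-industry concentrations,
overall CV well above 300%, industry ordering C > T > El > E-w > S > M in
mean Igeo, and a rise-then-fall log-median trend peaking near 2009.

## Worked example

```r
library(crsoil)

csv <- system.file("extdata", "example_regions.csv", package = "crsoil")
regions <- read_region_table(csv)
describe_regions(regions)
#> Soil Cr concentrations, n = 40 regions
#>   range   9.97 - 12007.39 mg/kg
#>   mean    558.06 mg/kg   median 72.72 mg/kg   sd 1946.10
#>   CV      348.72%
#>   above background value:      57.50%
#>   above screening (2500 mg/kg):  5.00%
```

The CV near 350% says the concentrations are dominated by anthropogenic
inputs, and 5% of these regions exceed the 2500 mg/kg industrial screening
value. Per-region indices and per-industry summaries:

```r
idx <- assess_regions(regions)           # national background, Tn = 2
head(idx, 3)
#>   region_id     igeo igeo_class   e_value e_class bn_used
#> 1    R00001 3.636175          4 37.300863     low      61
#> 2    R00002 1.098845          2  6.425495     low      61
#> 3    R00003 3.072386          4 25.234904     low      61
summarize_by_type(idx, regions)$means
#>   industry_type  n  mean_igeo     mean_e
#> 1             M 13 -0.7381536   2.440336
#> 2             S  7 -0.2167181   3.273383
#> 3           E-w  8 -0.3353310   6.735648
#> 4            El  9  1.0528584   8.901242
#> 5             T  2  4.4063967  74.784345
#> 6             C  1  7.0359352 393.684935
```

Tanning (T) and chromium-salt (C) regions carry mean Igeo above 4 — heavy
to extreme pollution — while mining (M) sits below background. Health risk
for a child at 1500 mg/kg, and the Monte Carlo picture when the
concentration itself is uncertain:

```r
p <- default_receptors()$child
hazard_quotients(1500, p)$hq_total       # 7.13: well above the HQ = 1 line
run_mc(NA, p, mc = mc_spec(10000, seed = 1,
       params = list(cn = dist_spec("lognormal", meanlog = log(700),
                                    sdlog = 1.2))))
#> Monte Carlo HQ, group child: 10000 iterations (seed 1)
#>   mean 6.831  sd 11.25
#>   p5 0.4547  p50 3.284  p95 24.7
#>   P(HQ > 1) = 0.8403
```

Temporal trend on a larger synthetic compilation:

```r
big <- generate_regions(default_paperlike_spec(seed = 1, n_regions = 2000))
fit_trend(yearly_medians(big))
#> Temporal trend: log10(median Cr) ~ degree-2 polynomial in year (20 years)
#>   vertex (maximum) at year 2008.3
#>   R-squared 0.9485
```

The fitted maximum near 2009 reproduces the configured turning point of the
generator: concentrations rise through the 2000s and decline afterwards.

## Command line

`inst/cli/crsoil.R` exposes subcommands
`generate | assess | health-risk | mc | spatial | trend | report`;
`report` runs the whole pipeline into an output directory (CSV tables,
`trend_fit.json`, `report.txt`, `manifest.json`). Exit codes: 0 success,
2 config error, 3 input error, 4 stage failure.

```sh
Rscript inst/cli/crsoil.R report --input regions.csv --out-dir out --seed 1
```

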