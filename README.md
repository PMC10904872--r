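# metalrisk

Probabilistic human-health risk assessment of toxic metals (Pb, Cr, Cd, Ni,
As) in drinking water, built as a reusable, tested R pipeline. The package
covers the full chain a water-quality risk assessor works through:

1. **Survey stage** — read site-level concentration records (with
   below-LOD censoring), summarize them per metal, and screen the summaries
   against EPA/WHO drinking-water limits.
2. **Exposure stage** — chronic daily intake (CDI, mg/kg-day) by the
   ingestion and dermal contact routes, following the USEPA dose equations

   ```
   CDI_ingestion = (Cw·10⁻³) · DI · ABS · EF · EP / (BW · AT)
   CDI_dermal    = (Cw·10⁻³) · SA · Kp · ABS · EF · EP · CF / (BW · AT)
   ```

   with Cw the concentration (µg/L), DI daily intake (L/d), SA skin area
   (cm²), Kp the dermal permeability coefficient (cm/h), EF exposure
   frequency (d/y), EP exposure duration (y), CF the volumetric conversion
   (L/cm³), BW body weight (kg) and AT the averaging time (d).
3. **Risk stage** — hazard quotient `HQ = CDI / RfD`, hazard index
   `HI = ΣHQ` over metals and routes, and incremental lifetime cancer risk
   `ILCR = CDI · CSF` for registered carcinogens (As), with the
   conventional screening labels (HI > 1; ILCR 10⁻⁶ / 10⁻⁴; multi-substance
   sum vs 10⁻⁵).
4. **Uncertainty stage** — a declarative Monte Carlo engine
   (point/normal/lognormal/triangular/uniform specs with rejection-enforced
   truncation) that propagates parameter distributions through the whole
   pipeline and reports empirical summaries per quantity.
5. **Spatial stage** — inverse-distance-weighted (IDW) interpolation of
   site concentrations onto regular grids, written as ESRI ASCII raster
   text.
6. **Synthetic surveys** — a generator that reproduces published per-metal
   summary statistics (via moment-calibrated truncated normals) so every
   stage runs, and is tested, without the unpublished raw survey data.

The bundled reference values (exposure factors, reference doses, slope
factors, guideline limits, concentration summaries) are those of a
published assessment of the Isfahan (Iran) drinking-water distribution
network; all of them are plain tibbles and can be swapped for other
surveys.

## Worked example

```r
library(metalrisk)

# a reproducible 80-site survey calibrated to the published summaries
survey <- generate_survey(generator_config(n_sites = 80, seed = 7))
summ   <- summarize_concentrations(survey)
compare_to_guidelines(summ)[, c("metal", "n", "mean", "sd",
                                "who_limit", "mean_exceeds_who")]
#>   metal     n  mean    sd who_limit mean_exceeds_who
#> 1 Pb       80 10.4  4.82         10 TRUE
#> 2 Cr       80 37.5  8.20         50 FALSE
#> 3 Cd       80  2.97 0.345         3 FALSE
#> 4 Ni       80 68.7  7.76        70 FALSE
#> 5 As       80  6.25 3.02        10 FALSE

assess_risk(setNames(summ$mean, summ$metal), exposure_parameters("adult"))
#> <risk_result> cohort: adult  HQ mode: strict
#> Hazard index by route:
#>   ingestion 6.29e-01  [acceptable]
#>   dermal    6.79e-03  [acceptable]
#>   total     6.35e-01  [acceptable]
#> ILCR (carcinogenic averaging time):
#>   As  2.85e-04  [harmful]
#>   sum 2.85e-04  [exceeds multi-substance limit]
#> No CSF (skipped for ILCR): Pb, Cr, Cd, Ni
```

The hazard index stays far below 1 (no non-carcinogenic concern; arsenic
contributes most of it because its oral reference dose, 3·10⁻⁴ mg/kg-day,
is by far the smallest), while the arsenic cancer risk of ~2.9·10⁻⁴ exceeds
the 10⁻⁴ screening level — the assessment's central finding.

The end-to-end reproduction command re-derives the published result tables
with the calibrated Monte Carlo specification sets (100,000 iterations) and
collects every known print inconsistency in a discrepancy report:

```r
reproduce_published(n = 1e5, seed = 7)
#> <reproduction_bundle> n = 1e+05  seed = 7
#> Adult ingestion CDI, computed vs published (mg/kg-day):
#>   Pb  3.15e-04 vs 3.15e-04  (-0.13%)
#>   Cr  1.19e-03 vs 1.19e-03  (-0.42%)
#>   Cd  9.26e-05 vs 9.32e-05  (-0.63%)
#>   Ni  2.19e-03 vs 2.20e-03  (-0.38%)
#>   As  1.99e-04 vs 1.99e-04  (+0.19%)
#> Published-table identities: 23 / 24 agree at 3 s.f.
#> Known print deviations documented: 5
```

A thin command-line wrapper with subcommands `synth`, `summarize`, `risk`,
`mc`, `map` and `reproduce` lives at `inst/cli/metalrisk-cli.R`:

```sh
Rscript inst/cli/metalrisk-cli.R synth --out out --n-sites 80 --seed 7
Rscript inst/cli/metalrisk-cli.R mc --samples out/synthetic_samples.csv --out out
Rscript inst/cli/metalrisk-cli.R map --samples out/synthetic_samples.csv --metal Ni --out out
```

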