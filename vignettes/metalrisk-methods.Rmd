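---
title: "Methods: probabilistic metal risk assessment in drinking water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic metal risk assessment in drinking water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalrisk)
```

## The model

`metalrisk` implements the standard USEPA exposure-and-risk chain for
waterborne metals. For a cohort with daily water intake $DI$ (L/d), body
weight $BW$ (kg), exposure frequency $EF$ (d/y), exposure duration $EP$ (y)
and averaging time $AT$ (d), the chronic daily intake of a metal at water
concentration $C_w$ (µg/L) is

$$\mathrm{CDI_{ing}} = \frac{C_w \cdot 10^{-3} \cdot DI \cdot ABS \cdot EF \cdot EP}{BW \cdot AT},
\qquad
\mathrm{CDI_{derm}} = \frac{C_w \cdot 10^{-3} \cdot SA \cdot K_p \cdot ABS \cdot EF \cdot EP \cdot CF}{BW \cdot AT},$$

in mg/kg-day; the fixed $10^{-3}$ converts µg/L to mg/L. Non-carcinogenic
risk is screened by the hazard quotient $HQ = \mathrm{CDI}/\mathrm{RfD}$
(oral RfD for the ingestion route, dermal RfD for the dermal route) and the
hazard index $HI = \sum HQ$ over metals and routes; carcinogenic risk by
$\mathrm{ILCR} = \mathrm{CDI} \cdot \mathrm{CSF}$, computed on the
70-year-averaged intake. Screening labels use the conventional thresholds
— $HI > 1$, single-substance ILCR bands at $10^{-6}$ and $10^{-4}$, a
multi-substance sum level of $10^{-5}$ — with *strict* inequalities, so a
value exactly at a threshold falls in the non-exceeding class.

Of the five bundled metals only As carries a cancer slope factor
(1.5 (mg/kg-day)$^{-1}$); the toxicity table is an ordinary tibble and
extensible.

## Exposure parameter sets

Two cohort sets are bundled (`exposure_parameters("adult")`, `"child"`):

| parameter | adult | child | units |
|---|---|---|---|
| DI | 2.2 | 0.51 | L/d |
| SA | 18 000 | 8 000 | cm² |
| EF | 350 | 350 | d/y |
| EP | 70 | 4 | y |
| BW | 70 | 16 | kg |
| AT (non-carc.) | 25 550 | 1 460 | d |
| AT (carc.) | 25 550 | 25 550 | d |
| CF | 0.001 | 0.001 | L/cm³ |
| ET | 0.2 | 0.2 | h/event |

Three choices here were genuinely open and deserve their rationale:

* **Ingestion absorption factor.** The source tabulates $ABS = 0.001$ for
  all routes, but applying it to the ingestion equation yields intakes
  three orders of magnitude below every published intake value; the
  published numbers are recovered only with unit absorption. The package
  therefore defaults `abs_ing = 1` (and `abs_derm = 1`), keeping both
  configurable; the `table1_literal` scenario uses 0.001 throughout.
* **Exposure time (ET).** The dermal equation as published does not
  reference ET although it is tabulated. `cdi_dermal()` excludes it by
  default and offers `include_et = TRUE` for the standard dermal-dose
  formulation that multiplies it in.
* **Averaging times.** Carcinogenic intake always averages over 70 years
  (25 550 d) per standard practice; non-carcinogenic intake averages over
  the exposure duration ($EP \times 365$: 25 550 d adult, 1 460 d child).

Kp values are tabulated for Pb (0.001), Cr (0.002) and Ni (0.0002) cm/h;
Cd and As are missing in the source and fall back to the generic inorganic
default 0.001 cm/h. `default_kp()` flags the defaulted symbols so reports
can disclose them.

## The dual hazard-quotient mode

The published hazard tables print "HQ" values that are numerically
identical to the intake tables — the RfD division of the defining equation
is not reflected in them (with the real RfDs, the strict As HQ at the mean
intake is ≈ 0.66, not 2·10⁻⁴). The package's default mode is `strict`
(divide by RfD); the `as_published` mode (divisor 1) exists solely to
reproduce the published tables, and every report records the active mode.
This is why the worked examples show a strict HI around 0.6 dominated by
As while the reproduction bundle shows the printed 4·10⁻³ scale.

## Monte Carlo engine and the calibrated specification sets

`dist_spec()` declares one stochastic parameter (point, normal, lognormal,
triangular or uniform, with optional truncation); `sample_dist()` draws
i.i.d. samples, enforcing truncation by rejection with adaptively sized
batches and a resampling cap that turns an (effectively) massless
truncation region into an error instead of an endless loop. Lognormals are
parameterized by their natural-scale mean and SD and converted internally
by moment matching. Parameters are sampled independently; the source
asserts no correlation structure, and none is modelled.

The bundled `isfahan_*_reproduction` sets hold EF at its 350 d/y point
value and sample $DI \sim N(2.2, 0.27)$ truncated positive (child
$N(0.51, 0.14)$) and $BW \sim \mathrm{LogN}(70, 13.6)$ (child
$\mathrm{LogN}(16, 3.8)$). Two calibration points matter:

* **Why EF is a point value.** Sampling the tabulated triangular EF
  (180, 350, 365), whose mean is 298.3 d/y, depresses every intake mean by
  ≈ 15% relative to the published table; the published means are recovered
  only with EF at 350. The triangular EF and ET remain available as the
  `table1_literal` scenario.
* **Why the concentration distributions are calibrated.** A truncated
  normal naively parameterized by the published mean/SD does not *have*
  that mean (for Cd the truncated mean shifts from 2.96 to ≈ 3.17 µg/L,
  +7%). `fit_truncated_normal()` therefore solves for parent parameters
  $(\mu, \sigma)$ such that the truncated mean equals the target exactly
  (the truncated mean is strictly increasing in $\mu$, so the inner solve
  is a bracketed root find over $[\,a - 6\sigma,\, b + 6\sigma\,]$; the
  outer solve adjusts $\sigma$ for the SD, with interval masses evaluated
  tail-aware to stay accurate far into a tail).

With these sets, the Monte Carlo ingestion-intake mean factorizes as
$E[C_w]\,E[DI]\,EF\,EP\,E[1/BW]/AT$, and the lognormal reciprocal moment
$E[1/BW] = (1 + (s/m)^2)/m$ explains the ≈ 4% gap between the point
evaluation at mean body weight and the published (probabilistic) means —
a closed form the tests verify against the simulation.

An important honesty note: the published Cd SD (3.02 µg/L on the range
[2.44, 3.91]) and As SD (4.27 on [2.33, 14.36]) exceed what *any*
distribution bounded on those ranges can attain (the truncated-normal
supremum is the uniform limit, width/$\sqrt{12}$). The calibration
prioritizes the mean, caps $\sigma$ at 1.5× the range width, and reports
the achieved SD and its bias (`sd_attained = FALSE`) instead of hiding the
inconsistency.

## What the synthetic generator does and does not emulate

`generate_survey()` draws per-site concentrations from the calibrated
truncated normals and places sites uniformly or in Gaussian clusters on a
planar square (default 100 × 100 in arbitrary units — the source publishes
no coordinates). It reproduces the published summary structure: means
(exactly, in expectation), SDs (where attainable), hard min/max bounds, and
the 80-site size. It does **not** emulate spatial autocorrelation of real
distribution networks, temporal trends (the source pools three months),
between-metal correlation at a site, or measurement error beyond the LOD
flag. Tests passing on generated surveys therefore validate the *pipeline
arithmetic and its statistical contracts*, not distributional claims about
real Isfahan water.

Tolerances for generator recovery tests are set from first principles: the
sample mean of $n$ truncated draws has standard error
$\mathrm{SD}_{\mathrm{trunc}}/\sqrt{n}$, which for the high-CV metals
exceeds a flat 3% band at $n = 80$ (Pb: ≈ 3.9%); recovery is therefore
asserted within the larger of the stated band and three standard errors,
alongside the noise-free analytic check that the calibrated truncated mean
equals the target.

`generate_hotspot_survey()` plants a contamination cluster by scaling the
whole truncated distribution (mean, SD and bounds alike) for the sites of
one cluster — scaling the values *after* truncating to the base range
would clip the enrichment away. The cluster's bounding box is returned so
the spatial round trip (rasterize, take the argmax) can verify recovery.

## Spatial interpolation

`idw_interpolate()` is Shepard's method: weights $d_i^{-p}$ with the power
$p = 2$ by default (the common GIS default; the source names none), all
sites in the neighborhood (a `k`-nearest option exists), and an exact-hit
radius of $10^{-9}$ coordinate units within which a query returns the
nearest site's value — keeping the interpolant defined and exact at the
data. Values are convex combinations of site values, hence never leave the
observed range. Duplicate coordinates with conflicting values are an
error; repeat measurements at a site are averaged first. Rasters follow
the ESRI ASCII text convention (which implies square cells; the writer
refuses non-square grids). Coordinates are an arbitrary planar system — no
geodetic projection handling, matching the source's silence on the matter.

## Censoring, numerical and degenerate-input choices

* Below-LOD values substitute LOD/2 by default (`zero` and full-`lod`
  variants available); the source does not state its rule, and LOD/2 is
  the common screening convention.
* Guideline exceedance uses strict `>`, consistent with the source
  treating a mean of 70.03 vs the WHO 70 as an exceedance and 2.96 vs 3 as
  not one; absent limits (EPA for Ni) yield `NA` flags, never silent
  skips.
* Summaries use the sample (n−1) SD; a single observation reports SD 0.
* Empty sample tables summarize to an empty tibble, not an error; an empty
  hazard-quotient set has HI 0.
* The YAML run-configuration key for iteration count is `iterations`
  (YAML 1.1 parses a bare `n` as a boolean); the `n` spelling is remapped.
* Seeds: every stochastic entry point (`sample_dist()`,
  `run_monte_carlo()`, the generators) is reproducible given its seed, and
  `sample_dist(seed =)` restores the caller's RNG state.

## Problem sizes

The reproduction analyses use 100,000 Monte Carlo iterations — the
simulation size of the source assessment — at which the Monte Carlo
standard error of an intake mean is below 0.1%. Unit tests exercise the
same code paths at 10³–10⁴ iterations, where the statistical assertions
are still separated from their tolerances by comfortable margins;
closed-form moment checks (triangular mean, lognormal mean and reciprocal
moment) use 10⁶ draws. Convergence is quantified by `convergence_check()`
(relative drift of means between runs of different size).

## Known limitations

* The published dermal intake column is not derivable from the dermal
  equation under any combination of the tabulated ABS/CF/ET values; the
  package computes the equation as written and lists the deviation in the
  reproduction discrepancy report rather than matching the print.
* Several published min/max columns are internally inconsistent
  (minima exceeding means for Cr and As; the cancer-risk table's extrema
  reversed); only mean columns are treated as reproduction surfaces.
* The cancer-risk table's adult/child labels appear interchanged
  (the printed 3.00·10⁻⁴ equals the *adult* mean total intake × CSF);
  `reproduce_published()` reports both cohorts explicitly and leaves the
  labels to the discrepancy report.
* Inhalation exposure, food-chain pathways, dose-response beyond the
  linear slope factor, correlated sampling, and variance-based sensitivity
  indices are out of scope.
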