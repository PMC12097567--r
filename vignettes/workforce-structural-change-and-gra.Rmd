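---
title: "Structural change and grey relational analysis of workforce panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural change and grey relational analysis of workforce panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greyhealth)
```

## What the package computes

greyhealth implements two desk-scale procedures used to characterise a
national health workforce from short annual panels, here China's oral-health
workforce (licensed and assistant dental physicians) over 2017–2022.

**Structural change analysis** works on a *composition panel*: a
year-by-category table of percentage shares of one workforce attribute
(age band, years of work experience, educational qualification,
professional/technical qualification), each row summing to 100. For the
period ending in year $t$, with $p_j(t)$ the share of category $j$ in
percent:

* the **structural change value** of category $j$ is the signed fraction
  $\mathrm{SCV}_j(t) = \bigl(p_j(t) - p_j(t-1)\bigr)/100$ — positive when
  the category's share is rising;
* the **structural change degree** is
  $\mathrm{SCD}(t) = 100 \sum_j |\mathrm{SCV}_j(t)|$ (%), the total
  percentage-point movement of the whole composition;
* the **structural change contribution rate** of category $j$ is
  $\mathrm{SCC}_j(t) = 100\,|\mathrm{SCV}_j(t)| \big/ \sum_k
  |\mathrm{SCV}_k(t)|$ (%), the fraction of the period's movement that
  category accounts for.

**Grey relational analysis** (GRA, Deng form) works on a *factor panel*:
one strictly positive reference series $x_0$ (the annual workforce count)
and $m$ comparison series $x_1,\dots,x_m$ (candidate drivers: resident
population, share aged 65+, dependency ratio, urbanization, per-capita
GDP, per-capita disposable income, per-capita health expenditure, health
expenditure as a share of GDP). After dimensionless normalization
$x_i'(k) = x_i(k)/x_i(1)$ (the initial-value method, the default), with
$\Delta_i(k) = |x_0'(k) - x_i'(k)|$ and the two-level extrema
$\Delta_{\min},\Delta_{\max}$ taken over all series and years, the grey
relational coefficient is

$$\xi_i(k) = \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
                 {\Delta_i(k) + \rho\,\Delta_{\max}},$$

the **relational degree** $r_i$ is the unweighted arithmetic mean of
$\xi_i(k)$ over years, and factors are ranked by descending degree. GRA
scores the similarity of growth *shapes*, not levels; it is suited to the
"small sample, poor information" regime of a six-point annual series where
regression would be hopeless.

## Tunable parameters

* **Discrimination (resolution) coefficient $\rho \in (0,1]$**, default
  0.5 — the conventional value. Smaller $\rho$ stretches the contrast
  between coefficients; every $\xi_i(k)$, and hence every degree, is
  non-decreasing in $\rho$ (a tested invariant).
* **Normalization**: `initial_value` (default), `mean_value`, or `none`.
  Under initial-value normalization every series starts at 1, so
  $\Delta_i(1) = 0$, $\Delta_{\min} = 0$, and all coefficients lie in
  $[\rho/(1+\rho), 1]$ — $[1/3, 1]$ at $\rho = 0.5$. The chosen method is
  recorded on the result object, never applied silently.
* **Row-sum tolerance** for composition panels, default ±0.5 percentage
  points: published shares are rounded to one decimal, so exact sums of
  100 cannot be demanded. The reader rejects rows outside the tolerance
  rather than renormalizing.
* **Baseline vector**: published structural-change tables sometimes report
  a change for the panel's first year, implying a composition for the year
  before the panel starts. Because that base composition is usually
  unpublished, `run_structural_change()` takes an optional explicit
  `baseline`; without one, the first period is (first year → second year).
* **SCD threshold for "active change" labels**: none by default. Published
  narratives call large degrees "active" without defining a cutoff, so the
  package only labels periods when the analyst supplies a threshold.

## Numerical choices

* Internal arithmetic is full double precision; display rounding — half
  away from zero, 3 d.p. for change values and coefficients, 2 d.p. for
  percentages — is applied only when a table is written. `round_half_up()`
  is exported because R's `round()` rounds half to even, which does not
  match how published tables are rounded.
* A period with no change at all would make the contribution rate 0/0;
  `contribution_rates()` returns zeros and a `degenerate` flag instead,
  keeping result tables rectangular.
* If every comparison series is identical to the reference
  ($\Delta_{\max}=0$), all coefficients are defined as 1.
* Ties in ranking get dense ranks (tied degrees share the smaller rank,
  the next distinct degree takes the next integer) and are reported via a
  `ties` attribute. Published six-year panels rarely tie, but the behaviour
  must be defined.

## What published tables can and cannot be reproduced

Recomputing the degree and contribution rates from a published table's own
change values reproduces its printed cells exactly, and recomputing the
relational degree row from a published coefficient table reproduces the
printed degrees and ranks; the bundled reference tables
(`published_table()`) are verified this way in the test suite. One
published degree (the dependency ratio) sits exactly on a rounding
boundary (its column mean is 0.63550) and is asserted at full precision
instead of at 3 d.p.

Per-year *coefficient* tables are a different matter. Under strict
initial-value normalization every series' first-year difference is zero,
forcing all first-year coefficients to 1 — yet published coefficient
tables for this workforce print first-year values well below 1. Their
normalization or base point therefore differs from the stated
initial-value method, in a way the published description does not pin
down. The package implements the stated method; full-pipeline
reproduction of per-year coefficients from raw factor series is
consequently not guaranteed and is not asserted, while
degrees-from-coefficients and ranks-from-degrees are. The mean-value
normalization is offered as a documented alternative.

A related convention issue: published structural-change tables for
2017–2022 include a 2017 row, implying a 2016 baseline that is not part of
the published panel. The rows are internally consistent (degree equals the
sum of absolute values), but their change values cannot be recomputed from
the 2017–2022 shares alone — hence the explicit `baseline` argument.

## The synthetic generator

`synthetic_spec()` + `generate_composition_panel()` /
`generate_factor_panel()` emulate the *statistical shape* of yearbook
panels so that every stage is testable without any external data: six
years, five or six categories per attribute, one reference plus eight
drivers. They do not attempt to match real magnitudes beyond positivity,
smooth trends and those dimensions.

* Shares follow linear percentage-point trends; noise is added on the
  logistic scale and rows are renormalized, which keeps every share in
  (0, 100) and every row summing to exactly 100. Default noise sd is 0.05
  on the logit scale — visible year-to-year wiggle without swamping
  percentage-point drifts. Drifts whose trend line would leave (0, 100)
  within the horizon are rejected up front.
* The reference factor series grows exponentially (default 5 %/yr, the
  order of magnitude of this workforce's growth). Factor $i$ blends the
  reference's normalized shape (weight = its `association` $a_i \in
  [0,1]$) with an independent exponential shape, rescaled to its own
  level, times log-normal noise (default sd 0.02) — so series stay
  strictly positive and `association = 1` with zero noise is exactly
  proportional to the reference (degree 1, a tested identity).
* One integer seed drives the whole generator through a private random
  stream; the caller's `.Random.seed` is untouched.

One subtlety shaped the recovery scenario used in the tests: under
initial-value GRA, a driver whose *own* growth rate happens to equal the
reference's is indistinguishable from a perfectly associated one — shape
similarity is exactly what the method measures. So the planted-factor
scenario (`association` 0.95 for one factor against 0.25 for seven others)
gives the competitors independent growth rates at least 7 percentage
points away from the reference's, ensuring the association weight, not an
accidental growth-rate coincidence, decides the winner. Under that
scenario the planted factor is recovered at rank 1 in at least 95 % of 200
seeded replicates, and mean estimated drifts match specified drifts within
three standard errors over 100 replicates (both asserted in the suite;
those replicate counts keep the whole suite in the tens of seconds on one
CPU). What passing these tests shows is that the pipeline recovers known
structure planted by this generator — not that real yearbook data satisfy
the generator's assumptions (linear drifts, log-normal noise,
exponential drivers).

## Limitations

* No inferential statistics: the procedures are descriptive, and with
  n = 6 years no uncertainty quantification is attempted.
* Only the classical Deng GRA variant is implemented — no absolute or
  slope-type degrees, no grey entropy weighting, no GM(1,1) forecasting,
  no year weighting.
* Coefficients are set-dependent through the global extrema: adding or
  removing a comparison series can change every coefficient. Degrees are
  order-invariant but not subset-invariant; this is a property of the
  method, documented and tested rather than "fixed".
* No smoothing or imputation: panels with missing years are rejected.
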