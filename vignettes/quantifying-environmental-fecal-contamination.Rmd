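---
title: "Quantifying environmental fecal contamination from Quanti-Tray well counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying environmental fecal contamination from Quanti-Tray well counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpnenv)
```

## The problem

Urban exposure assessments of fecal contamination enumerate *E. coli*, the
standard fecal indicator bacterium, across many environmental compartments at
once: open drains, surface water, floodwater, bathing and drinking water,
soil, latrine surfaces, fresh produce, and street food. The workhorse assay
is the IDEXX Quanti-Tray 2000 with Colilert defined-substrate medium: 100 mL
of (possibly diluted) assay fluid is partitioned into 49 large wells of
1.86 mL and 48 small wells of 0.186 mL, incubated, and the positive
(fluorescing) wells counted. The well pattern yields a most probable number
(MPN) of organisms, quantifiable between just over 1 and 2419.6 MPN per
tray. Because environmental concentrations span ten orders of magnitude,
each sample is assayed at one to three serial dilutions, and the resulting
censored tray estimates must be aggregated and converted to the matrix's
reporting unit before any statistics can be computed.

`mpnenv` implements that full chain — tray-level maximum-likelihood MPN
estimation, censoring policy, dilution aggregation, unit normalization,
stratum summaries and contrasts — plus a seeded generator that simulates
studies with the same statistical structure, so the pipeline can be
validated end to end without access to any particular deposited dataset.

## The MPN model

Organisms are assumed Poisson-distributed in the assay fluid at
concentration $\lambda$ per mL, and wells are independent. A well of volume
$v$ is then negative with probability $e^{-\lambda v}$, so for $p$ positive
wells out of $n$ in each size class the log-likelihood is

$$
\ell(\lambda) = \sum_{\text{classes}} \Big[\, p \log\!\big(1 - e^{-\lambda v}\big)
  - (n - p)\,\lambda v \,\Big].
$$

The score $\ell'(\lambda)$ is strictly decreasing, positive near zero
whenever any well is positive, and tends to minus the total negative-well
volume, so the MLE is the unique root of a monotone function. `mpn_estimate()`
finds it with `uniroot()` on the log-$\lambda$ scale over
$[10^{-9}, 10^{3}]$ per mL at a relative tolerance of $10^{-8}$ — bisection
on a monotone score, deterministic, no seeds. The estimate is reported per
the geometry's reference volume (100 mL by default), which makes "MPN per
tray" and "MPN per 100 mL of assayed fluid" interchangeable for the default
preset, whose total well volume ($49 \times 1.86 + 48 \times 0.186 \approx
100$ mL) supports that equivalence.

Two degenerate well patterns carry no point estimate: an all-negative tray
is a non-detect (concentration below the limit of detection) and an
all-positive tray is over-range. The estimator only *classifies* these;
numeric substitution is deliberately left to the pipeline so that censoring
policy is auditable and separable from estimation. Confidence intervals are
profile-likelihood sets $\{\lambda : 2[\ell(\hat\lambda) - \ell(\lambda)]
\le \chi^2_1(\text{level})\}$; censored trays get one-sided bounds flagged
as such.

```{r}
mpn_estimate(p_large = 1, p_small = 0)
mpn_confint(p_large = 1, p_small = 0)
```

A single positive large well gives $\approx 1.0$ MPN/100 mL, matching the
assay's advertised lower quantifiable bound of "$>1$".

The well geometry (49/48 wells, 1.86/0.186 mL) is a manufacturer constant
rather than a quantity any study protocol reprints; it lives in
`tray_geometry()` as a configurable preset and is never hard-coded
elsewhere. Estimates agree with the manufacturer's lookup table to within
that table's rounding, but the table itself is not a dependency.

## Censoring and dilution aggregation

`combine_dilutions()` applies the substitution-and-averaging policy used in
SaniPath-style deployments:

* non-detect trays are substituted with **0.5 MPN** (half the lower
  quantifiable bound), over-range trays with **2419.6 MPN**, per tray,
  before dilution scaling;
* if *all* trays of a sample are non-detect, the lowest (most sensitive)
  dilution is used: the sample value is $0.5 \times D_{\min}$,
  left-censored;
* if *all* trays are over-range, the highest dilution is used:
  $2419.6 \times D_{\max}$, right-censored;
* otherwise the arithmetic mean of $\text{MPN} \times D$ over the
  quantifiable trays, ignoring censored trays.

The rules are stated for "all assayed dilutions", so they apply unchanged to
two- and three-dilution samples. Averaging is on the arithmetic MPN scale —
the literal reading of "average concentration" — with a `"geometric"`
switch available for sensitivity analyses; the shipped defaults use
arithmetic. One logically inconsistent pattern (a quantifiable tray together
with a non-detect at a *lower* dilution) cannot arise under the dilution
model but can in data; it follows the averaging rule and is flagged in the
output (`inconsistent = TRUE`) rather than silently accepted or rejected.

## Matrix units

Concentrations are reported per 100 mL for all waters (drains included), per
swab for latrine swabs, per single serving for produce, and per gram for
street food and soil. The assay, however, always sees a fluid. The
conversions reconstruct the laboratory processing chain from its recorded
volumes, all configurable in `matrix_metadata()`:

| matrix | processing | conversion from MPN/100 mL of assay fluid |
|---|---|---|
| waters | assayed directly | identity |
| latrine swab | eluted in 14 mL PBST | $\times\, 14/100$ per swab |
| produce | rinsed in 500 mL PBST | $\times\, 500/100$ per serving |
| street food | 10 g in 90 mL water | $\times\, (100/100)/10$ per gram |
| soil | 10 g in 20 mL PBST | $\times\, (20/100)/10$ per gram |

The swab conversion is what makes sub-zero log10 values (e.g. $-0.15$
log10 MPN/swab) reachable: 14 mL of eluate can carry less than one organism
even when the tray is quantifiable. Soil moisture would add
$\text{mass} \times \text{water fraction}$ to the eluate volume;
`soil_water_fraction` defaults to 0 because moisture is not measured in the
field protocol. The street-food homogenate volume counts the food mass
itself (10 g + 90 mL $\approx$ 100 mL), matching how a homogenate is
actually assayed.

```{r}
process_sample("street_food", dilution_factor = c(10, 100),
               p_large = c(48, 20), p_small = c(40, 4))
```

## Comparison statistics

Concentrations are analyzed throughout on the log10 scale.
`summarize_concentrations()` gives stratum means, sample SDs, and the
percent of positive samples (those not left-censored).
`compare_strata()` estimates a two-stratum mean difference with a Gaussian
identity-link linear model containing a single group indicator — the only
"generalized linear regression" consistent with symmetric CIs around a mean
difference — so the estimate is exactly the difference of stratum means and
the SE is the pooled two-sample SE. The CI multiplier is 1.96 by default; at
stratum sizes of 40–50 the t quantile differs by under 2% of the SE, and a
switch (`ci_multiplier = NULL`) substitutes it for small-sample use. No
multiplicity correction is applied anywhere, and significance is annotated
in the conventional 0.05/0.01/0.001 tiers. `feces_proximity_test()` runs the
pooled-variance t-test and the Wilcoxon rank-sum test for the soil
visible-feces comparison, with a tie-corrected normal approximation (and a
defined $p = 1$ on fully tied data).

## The synthetic study generator

`simulate_study()` emulates the sampling design the analysis targets: 10
neighborhoods (4 low-income, 4 high-income, 2 floating/transient; five in
each of the two city corporations) × 10 sample types × 10 samples per cell =
1000 samples. Contamination is modeled as log10-normal per (sample type ×
stratum) — the minimal model consistent with reporting means and SDs of
log10 concentrations — with no spatial correlation. The shipped calibration
(`contamination_profiles()`, a plain-text CSV in `inst/extdata/`) carries
the study-summary means and SDs per sample type overall and per
neighborhood category; the overall-row SD mixes between- and
within-neighborhood variance, which is the right dispersion for
single-stratum simulations, while category rows reproduce between-category
contrasts. Corporation rows carry municipal-water means only (no SD is
published for them) and therefore calibrate contrasts, not simulations.

Each sample draws a true log10 concentration, inverts the unit
normalization to an assay-fluid concentration, and turns each well positive
independently with probability $1 - e^{-(\lambda/D)v}$ — the same
Poisson-dilution model the estimator inverts, with independence across
wells and dilutions and no plating error or inhibition. True values below
the scheme's quantifiable band generate honest all-negative trays, so the
left-censoring rule is exercised by construction. A single study seed
derives per-sample seeds through one `sample.int()` draw, making any subset
of samples reproducible without regenerating the study.

What passing recovery tests does **not** show about real data: the generator
contains no within-tray overdispersion, no matrix inhibition, no
measurement error in the processing volumes, and no spatial or temporal
correlation, so recovery accuracy here bounds only the statistical error of
the estimation/aggregation chain, not field variability.

```{r}
sim <- simulate_stratum(100, "drain_water", mu = 6.91, sigma = 0.92,
                        seed = 20170601)
res <- process_samples(sim)
summarize_concentrations(res)
```

## Numerical and design choices

* **Solver brackets**: $\lambda \in [10^{-9}, 10^{3}]$ per mL covers
  concentrations from far below one organism per tray to far above the
  all-positive saturation point of any supported geometry; the root is
  bracketed by sign checks before `uniroot()` is called.
* **Precision**: $\log(1 - e^{-x})$ is evaluated via `log(-expm1(-x))` to
  avoid catastrophic cancellation at small $x$.
* **Tie-breaks and degenerate inputs**: fully tied proximity data return
  $p = 1$; strata with $n < 2$ have their comparison suppressed with a
  warning rather than producing an unstable SE; empty strata are omitted.
* **Problem sizes**: the validation suite uses 200 random trays for the
  oracle comparison, cohorts of 50–100 samples per type for recovery
  checks, and 1000 replicates for the test-size simulation — sizes at which
  Monte-Carlo error is small relative to the tolerances being checked while
  the whole suite runs in well under a minute.
* **Reproducibility**: every output CSV embeds a configuration hash and the
  study seed in a `#` comment header.

## Known limitations

Within-tray overdispersion and error propagation from tray CIs into
stratum contrasts are out of scope; censored substitution (0.5/2419.6)
introduces the usual mild bias near the detection limits, visible as a few
hundredths of a log10 upward shift for matrices whose distribution straddles
the lower band edge; Stata ingestion relies on `foreign::read.dta` and hence
on Stata formats up to version 12 (newer files should be exported to CSV).
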