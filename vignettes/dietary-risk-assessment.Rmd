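---
title: "Deterministic dietary risk assessment of pesticide residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic dietary risk assessment of pesticide residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(residuerisk)
library(dplyr)
```

## The problem

Multi-residue monitoring surveys screen food commodities for hundreds of
pesticides at once and answer three questions: *how often and at what level
does each residue occur*, *how many samples violate the applicable maximum
residue limits (MRLs)*, and *does the resulting dietary exposure pose a
health risk*. `residuerisk` implements that full chain for sample-level
residue tables (one row per sample and pesticide, concentrations in µg/kg,
non-detects censored at the LOD) or for published occurrence summaries,
together with the LC–MS method-validation calculators that accompany such
surveys. The packaged registries describe a 260-sample survey of five
fruit cultivars (strawberry, watermelon, melon, peach, grape) from
Shanghai, with Chinese and EU limits, toxicological reference doses for
the 57 detected pesticides, and six consumer strata.

## Occurrence statistics

A residue is *detected* when it is quantifiable (≥ LOD). Occurrence is
summarised per (commodity, pesticide) as the number of detects and the
minimum, maximum and mean over **detected samples only** — no zero or
LOD/2 substitution. This is the convention under which a detects-only
min–max range is reported alongside a mean, and it is also what makes the
downstream exposure tables reproduce: the chronic intake model consumes
exactly this mean. Censored-statistics estimators (Kaplan–Meier, ROS)
are deliberately out of scope. Detection rates and multi-residue
distributions (how many samples carry *k* distinct residues) are tied by
the identity `detection_rate = 100 − 100·n(k = 0)/n`, which the test suite
checks.

## MRL compliance conventions

* Exceedance is **strict**: a residue at exactly its limit complies.
* A limit applies regardless of basis: Chinese temporary limits (`*`) and
  EU defaults at the lower limit of analytical determination (`**`) bind
  exactly like standard MRLs — surveys count exceedances against them.
* A (commodity, pesticide) pair with no limit in a jurisdiction is
  `not_assessable` and never counts against a sample, so compliance rates
  are percentages of *all* samples under the limits that exist.
* Residue definitions that sum several analytes (e.g. spirotetramat plus
  spirotetramat-enol) are aggregated within each sample before comparison
  and reported under the parent name.
* Jurisdictions are independent: edits to one registry cannot change
  verdicts under another (a property test guards this).

## The exposure model

Chronic exposure uses the national-estimated-daily-intake model

$$\mathrm{NEDI} = \frac{\sum_c R_c \cdot F}{bw}, \qquad
\%\mathrm{ADI} = 100 \cdot \frac{\mathrm{NEDI}}{\mathrm{ADI}},$$

where \(R_c\) is the mean residue (mg/kg) of the pesticide in commodity
\(c\), \(F\) the daily consumption (kg/day) and \(bw\) body weight (kg).
Acute exposure replaces the mean with the highest residue \(HR_c\) and the
mean consumption with a large portion \(LP\):

$$\mathrm{ESTI} = \frac{\sum_c HR_c \cdot LP}{bw}, \qquad
\%\mathrm{ARfD} = 100 \cdot \frac{\mathrm{ESTI}}{\mathrm{ARfD}}.$$

A hazard quotient below 100% is an acceptable risk. Concentrations are
kept in µg/kg throughout the occurrence and compliance layers and divided
by 1000 exactly once, at the exposure boundary, where the toxicological
doses are in mg/kg bw/day.

Pesticides without an established ARfD are not errors: the acute
assessment is *skipped* with a recorded reason (`arfd_unnecessary` when
the evaluating body judged acute risk negligible, `arfd_not_established`
otherwise), mirroring how surveys report them.

### Consumption ratios and their calibration

Both equations depend on the group only through the scalar ratios
\(F/bw\) and \(LP/bw\) (kg food per kg body weight per day). The
underlying absolute body weights and consumption amounts for the packaged
survey are not published, but any printed hazard-quotient cell of a
pesticide with known summed residue determines the group's ratio exactly:

$$F/bw = \frac{\%\mathrm{ADI}}{100}\cdot\frac{\mathrm{ADI}}{\sum_c R_c}.$$

`calibrate_consumption_ratios()` performs this back-derivation from one
designated reference pesticide per endpoint (bifenazate for chronic,
fluopyram for acute) and requires independent reference pesticides
(boscalid and fosthiazate; carbendazim and acetamiprid) to agree within
0.3% relative — a guard against transcription errors or a wrong
aggregation model. That a *single* per-group ratio reproduces every cell,
including multi-commodity pesticides through \(\sum_c R_c\), shows the
source survey applied one common consumption figure to all five fruits.
The packaged `china_consumer_groups()` stores these derived ratios to five
significant figures:

```{r}
china_consumer_groups()
```

Per-commodity ratios remain supported through the `consumption` argument
of `risk_table()` for surveys with commodity-specific diets.

### Acute aggregation

The acute model above sums the highest residues across **all**
commodities in which a pesticide was detected — the convention the
packaged survey's tables follow (verified by the carbendazim
strawberry-plus-peach cell). International short-term-intake conventions
(IESTI) instead assess one commodity at a time, often with unit
variability factors. `risk_table(acute_aggregation = "max_commodity")`
switches to the single-worst-commodity variant; the whole-diet sum
remains the default because it is what the packaged reference tables
encode. Variability factors, processing/peeling factors, cumulative
hazard indices and probabilistic (Monte-Carlo) exposure are out of scope.

### Group rankings

Because every quotient factorises into a pesticide-specific scalar times
the group ratio, the risk ordering of groups is pesticide-independent:
`rank_groups()` simply orders by ratio, flags exact ties, and breaks them
by label order. With the packaged ratios, the chronic order is 2–4 F >
2–4 M > 18–30 F > 18–30 M > 60–70 F > 60–70 M, and the acute order swaps
18–30 M below 60–70 F — children and females bear the higher dietary
risk per kilogram of body weight.

## Method-validation metrics

* Matrix effect: \(ME = 100\,(A_{matrix} - A_{solvent})/A_{solvent}\);
  classified suppression below −20%, enhancement above +20%. The
  acceptable band is conventionally quoted as the open interval
  −20% < ME < 20%, leaving the boundary unassigned; this package places
  exactly ±20 in `negligible`.
* Recovery: mean of replicate measured concentrations over the spiked
  level, with the SANTE window 70–120% and an RSD ≤ 20% flag. RSD uses
  the sample (n−1) standard deviation, the replicate-data convention.
* LOD/LOQ: 3× and 10× the spiked blank's signal-to-noise, extrapolated
  linearly from a single spiked level, so LOQ/LOD = 10/3 exactly. No
  clipping to nominal tiers is applied — the definition alone is
  implemented.
* Linearity: pass only for \(r^2\) strictly above 0.990.

Summary percentages are displayed to one decimal, rounding halves away
from zero.

## The synthetic generator

Two generators make the pipeline testable without any external data.

`generate_samples()` draws per-pair Bernoulli detections and log-normal
concentrations redrawn until at or above the censor limit (at most 1000
redraws, then an error), so generated detects are ≥ LOD exactly as
reported concentrations are. The log-normal family is an assumption —
residue levels are positive, right-skewed quantities for which it is the
standard first choice — not an empirical claim about any particular crop.

`emulate_occurrence_table()` inverts a published occurrence summary into
a sample-level dataset. Counts are reproduced **exactly**: sample counts,
detect counts, and the number of detects strictly above each
jurisdiction's limit (values are placed segment-by-segment between the
sorted limits). The published mean of detects is matched by nudging
interior values within their admissible segment, with the endpoints
pinned at the published min and max; the suite requires agreement within
5% relative, and for the packaged survey the detect counts were chosen so
the mean is attainable essentially exactly. Because detection counts are
not published, the packaged fixture carries *assumed* counts
(`assume_detect_counts()`): one for single-value rows, forced equal to
the exceedance count where even the minimum detect exceeds the limit
(grape triflumuron: all 40), and otherwise the smallest feasible count.

What the emulation does **not** model: which residues co-occur in the
same sample. Exceedances of different pesticides are assigned to samples
independently, so any statistic that depends on cross-pesticide
co-occurrence — notably the EU sample-level compliance rate, where many
pesticides exceed in a few commodities — is reproduced only in
distribution, not in value. The Chinese compliance headline is immune to
this: the survey's only Chinese exceedances are the 13 strawberry
fluopyram samples, so 247/260 = 95.0% holds under any assignment. The
tests and the acceptance script assert the Chinese headline and
per-pesticide exceedance rates, never the EU sample-level headline.

## Numerical choices

* Table-reproduction tolerance: |computed − published| ≤ max(0.003,
  0.2% relative) per cell, absorbing the reference tables' four-decimal
  rounding and the calibration's own rounding. The suite verifies all
  342 chronic and 150 acute cells of the packaged survey at this
  tolerance, and that every cell sits below the 100% acceptability line.
* Display rounding is half-away-from-zero (`round_half_away()`); percent
  columns print to four decimals, concentrations to one, matching the
  reference tables. Internal values are never rounded. (A survey's own
  display rounding can be inconsistent — 75/80 prints as 93.7% in the
  source, suggesting truncation — so displayed rates are not used as
  verification targets.)
* Unit conversion is a pure factor-of-1000 scaling; round-trips are exact
  to 1 ulp for decimal inputs.
* Problem sizes in the test suite are chosen to keep the full run in well
  under a minute while leaving the statistical checks sharp: 10 000 draws
  for the log-normal mean check (3 standard errors), 400–500 samples for
  binomial detection-probability recovery (99% interval), 1000 replicates
  for recovery-parameter recovery (±1%), and ≥ 1000 random measurements
  for the brute-force compliance oracle sweeps.

## Known limitations

* Consumption ratios are back-derived, not primary data; their absolute
  scale is only as good as the published reference cells (about four
  significant figures — a small residual in the worst acute cell
  suggests the source carried more digits than it printed).
* The watermelon "sample" of the packaged survey pools three fruits, and
  peach residues are expressed on a pit-included mass basis; both affect
  interpretation of the occurrence statistics, not any computation here.
* No spatial or temporal sampling structure, no between-field
  correlation, no instrument-level (chromatogram) processing: validation
  metrics accept externally integrated peak areas and fitted \(r^2\)
  values.
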