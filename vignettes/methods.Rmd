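---
title: "Models and methods behind herbrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind herbrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbrisk)
```

herbrisk implements the standard USEPA-style ingestion risk chain for
potentially toxic elements in liquid herbal preparations, together with the
quality-control statistics that accompany an ICP-OES campaign and a
relative-abundance summariser for GC-MS identified-compound tables. This
vignette records the models, the defaults and the reasoning behind the
numerical choices, in enough detail that a reviewer can re-derive every
number the package produces.

## The exposure model

For an element at concentration $C$ (mg per kg of preparation), chronic
daily intake is

$$\mathrm{EDI} = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT}
\quad \text{(mg/kg body weight/day)},$$

with ingestion rate $IR$ (kg/day), exposure frequency $EF$ (days/year),
exposure duration $ED$ (years), body weight $BW$ (kg) and averaging time
$AT$ (days). The defaults describe a 70 kg adult ingesting 8 g of the
preparation every day of a 70-year exposure, with $AT = 365 \cdot ED$ — the
convention for non-carcinogenic endpoints, under which $EF$ and $ED$ cancel
algebraically and $\mathrm{EDI} = C \cdot IR / BW$. The ingested dose is
assumed fully absorbed, a deliberately protective simplification.

Non-carcinogenic hazard is the quotient $\mathrm{THQ} = \mathrm{EDI} /
\mathrm{RfD}$ against the element's oral reference dose, and the per-sample
hazard index is the plain sum $\mathrm{HI} = \sum_i \mathrm{THQ}_i$ over
the detected elements — an additivity assumption that ignores interaction
between metals but is the accepted screening convention. Carcinogenic risk
is $\mathrm{CR} = \mathrm{EDI} \cdot \mathrm{CSF}$ for the elements with a
published cancer slope factor (in the bundled reference table: Cr, As, Pb),
banded with inclusive boundaries: negligible below $10^{-6}$, acceptable
from $10^{-6}$ to $10^{-4}$, potential risk above. The boundary values
themselves are classified "acceptable" because the conventional wording
places the range inclusively between the two thresholds.

Non-detects are excluded from the risk chain entirely — no $\mathrm{LOD}/2$
or similar substitution. A screening assessment of elements whose
concentrations span five orders of magnitude gains nothing from imputing
values below detection, and substitution would manufacture hazard
contributions for elements the instrument could not see. The point estimate
uses the replicate mean as $C$; the replicate SD enters only through the
probabilistic analysis.

## Probabilistic analysis

The Monte Carlo stage treats only $C$ as uncertain; $IR$, $BW$, $EF$, $ED$
are scenario constants, not measured quantities, so giving them
distributions would mix variability sources without data to support it.
Each (sample, element) cell's replicate mean $m$ and standard deviation $s$
parameterise a normal distribution truncated at zero by rejection
resampling: negative draws are redrawn until non-negative. The truncated
normal is the minimal choice that (a) is symmetric around the measured mean
where truncation is immaterial, so the simulated P50 tracks the
deterministic estimate, and (b) never produces a negative concentration.
For the bundled reference data the truncation mass is below 1% everywhere
(the most variable cell, arsenic in sample A, has $m/s \approx 2.5$), so
the closed-form quantile of the truncated distribution —
`truncnorm_quantile()`, $F^{-1}(p) = \Phi^{-1}(F_0 + p(1-F_0))$ scaled back
to $(m, s)$, with $F_0 = \Phi(-m/s)$ — is the independent yardstick the
test suite compares simulated percentile ratios against.

Within each iteration one concentration is drawn per element, the full
chain is evaluated, and the hazard index is summed *within the iteration*;
percentiles (default P50 and P95, the empirical type-7 linear-interpolation
quantile) are taken afterwards. Summing per-element percentiles instead
would be wrong — quantiles do not add — and the suite asserts the
per-iteration identity $\mathrm{HI}_j = \sum_i \mathrm{THQ}_{ij}$ exactly.
The default 10,000 iterations put the Monte Carlo standard error of a P50
around 1% of the estimate for the CVs in the reference data; the seed is
set once per run, draws proceed in sorted (sample, element) order, and
repeated runs with one seed are bit-identical.

## Quality-control statistics

*Limit of detection.* $\mathrm{LOD} = 3 \cdot SD_b / m$ from replicate
blank signals and the calibration slope. The sample standard deviation
($n-1$ denominator) is used everywhere in the package, including here:
with triplicates it is the estimator consistent with the Student-t
confidence intervals below, and mixing denominators across stages would be
indefensible. A measurement exactly at the LOD counts as a detection
(the conventional $\ge$ rule). The bundled `calibration_synthetic.csv` is a
constructed stand-in — blank triplets built so that the 3-sigma rule
reproduces the instrument LODs of the reference campaign — not recorded
instrument output, and is named accordingly.

*Replicate summaries.* Mean, sample SD, $\mathrm{CV\%} = 100\,s/\bar{x}$
(reported only for positive means), and the Student-t interval
$\bar{x} \pm t_{0.975,\,n-1}\, s/\sqrt{n}$. At $n = 3$,
$t_{0.975,2} = 4.303$; a normal-quantile interval would be some 54%
narrower and does not reproduce the reference tables, which is direct
evidence the t-interval is the right model for triplicate data.

*Limit tests.* A two-sided one-sample t-test of the replicates against the
WHO/FAO permissible concentration, delegated to `stats::t.test()`; the
suite cross-checks the statistic against the textbook formula
$(\bar{x} - \mu_0)/(s/\sqrt{n})$. Two-sided because the scientific question
is whether concentrations *differ* from the limit, not merely fall below
it. No multiple-testing correction is applied: each element/sample pair is
reported as its own pre-specified comparison, matching practice in this
literature. Zero-variance replicates raise an error rather than a fake
infinite statistic.

## GC-MS class aggregation

The GC-MS stage consumes an identified-compound table (compound, formula,
class, retention time, one relative-abundance column per sample), not raw
chromatograms. Relative abundance is peak area over total integrated area,
summing to 100% exactly before rounding. Compounds recurring at several
retention times are distinct records — isomer elution makes this real, and
collapsing them would under-count their class. Class labels are taken
verbatim from the table; no ontology normalisation is attempted, since any
re-mapping would editorialise the upstream identification. Per-sample class
totals partition the total identified percentage exactly (every compound
has one class), and bundled-table totals must not exceed 100% beyond a 0.5
rounding slack.

## The synthetic-data generator

`generate_measurements()` emulates the design of a triplicate elemental
campaign: per-cell true mean and true CV, normal noise truncated at zero,
and cell-level non-detects (the whole element missing for a sample, which
is how instruments report ND — not per replicate). Noise is
CV-parameterised rather than absolute-SD so one spec scales across the
orders of magnitude separating trace and major elements.
`generate_blank_series()` and `generate_compound_table()` exercise the LOD
rule and the abundance contract the same way. What the generator does *not*
emulate: instrument drift, matrix effects, inter-day batches, correlated
elements, or asymmetric concentration distributions. Passing the
parameter-recovery tests therefore shows the statistical machinery is
correct under the stated model, not that real concoction data satisfy that
model.

The bundled reference fixture reconstructs triplicates from published
per-cell means and SDs as $(m - s,\; m,\; m + s)$, which has sample mean
$m$ and sample SD $s$ exactly; raw replicate values were never published,
and any triplet matching those two moments is equivalent for every
statistic the package computes from them.

## Problem sizes and tolerances

The test suite runs the reference dataset (3 samples × 11 elements × 3
replicates), Monte Carlo checks at 10,000 iterations, and
parameter-recovery harnesses over 1,000 seeded replicate cells — sizes at
which Monte Carlo error bands (3 standard errors for means, ~2% for a P50,
5% for percentile ratios against the closed form) are tight enough to be
meaningful while the whole suite stays fast. Risk quantities are written
with 3 significant figures in scientific notation, the display convention
of regulatory tables; internal computation and the full-precision schemas
keep double precision throughout.

## Known limitations

Ingestion is the only pathway (no dermal or inhalation route); the scenario
is a single adult parameter set; concentration is the only stochastic
input; elements are assumed toxicologically independent in the HI; and the
truncated-normal uncertainty model is an assumption, not an inference from
the triplicates. These match the package's screening-level scope: it ranks
and flags, and anything it flags deserves a proper follow-up study.
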