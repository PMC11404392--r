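---
title: "Methods behind the opioid prescribing scorecard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the opioid prescribing scorecard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxscorecard)
```

# The procedure

`rxscorecard` implements a quarterly audit-and-feedback pipeline for
ambulatory opioid prescribing in a multi-division health system. One run
takes prescription-level records, a drug conversion table, and a
configuration, and produces per-provider metrics, per-(division, specialty)
outlier thresholds, three report tiers, and programme-evaluation statistics.
This vignette records the model, the parameters that matter, and the design
decisions taken where more than one defensible reading existed.

## Dose arithmetic

Every prescription carries a structured sig: `units_per_dose` dispensing
units per administration and `max_doses_per_day` administrations per day.
From these:

- **MEDD** (mg oral morphine per day) =
  `strength_mg_per_unit × units_per_dose × max_doses_per_day × mme_factor`.
  PRN sigs contribute their maximum permitted frequency — the conservative
  convention in MME auditing, since the audit asks what the prescription
  *permits*, not what the patient took.
- **Calculated day supply** (days) =
  `quantity_dispensed / (units_per_dose × max_doses_per_day)`, real-valued
  and never rounded.

Refills are excluded from both quantities: the prescription, not its
renewals, is the audited act. Refills *are* used when deciding whether a
prescription is still active for the chronic registry (below). Combination
products carry only the opioid component's strength; the conversion factors
ship as a versioned CSV (`inst/extdata/drugs.csv`) rather than being
hard-coded. Methadone's dose-dependent conversion tiers and
transdermal/buccal kinetics are out of scope, so no such entries ship.

## Cohort rules

- **Attribution.** A prescription counts toward `authorizing_id` when
  present (orders by advanced practice providers or house staff), else
  toward `prescriber_id`.
- **Eligibility.** A provider receives a scorecard for quarter *Q* iff at
  least one opioid prescription is attributed to them in the trailing-year
  window `(as_of − 365 d, as_of]`, where `as_of` is the last calendar day of
  *Q*. Eligible providers with zero in-quarter prescriptions appear as zero
  rows — they are part of the peer distribution.
- **Chronic registry.** A patient is chronic at a date iff they have ≥ 3
  opioid prescriptions in the trailing year *and* at least one prescription
  is still active. "Active" is not defined in most source systems, so the
  package pins the most inclusive defensible reading:
  `written_date + ceiling(day_supply × (refills + 1)) ≥ as_of`.
- **Chronicity of a prescription** is the patient's registry status on the
  day it was written, with the prescription excluded from its own count. A
  patient's third-ever prescription is therefore still "nonchronic" — a
  prescription never flips its own patient's class, which keeps labels
  deterministic and independent of processing order. Other prescriptions
  written the same day do count.
- All windows are half-open (`[start, end)` for quarters,
  `(as_of − lookback, as_of]` for lookbacks) so that quarter partitions are
  disjoint and exhaustive.

## Metrics and thresholds

Five metrics per provider per quarter: prescription count, distinct patient
count, nonchronic prescriptions over a 5-day supply, nonchronic exceedances
of 50 MEDD, chronic exceedances of 90 MEDD. A prescription exceeding several
flags counts in each applicable metric — the metrics are defined
independently, not as a partition.

Metrics 4 and 5 can be counted in units of **distinct patients** (default)
or **prescriptions** (`metric4_unit` / `metric5_unit`). Both readings occur
in practice descriptions of such programmes; the patient unit is the default
because outlier narratives are about how many *people* received high doses.
The chosen unit is recorded in every stage output's header and in the report
metadata, and the patient unit is never larger than the prescription unit.

Per (division, specialty) and metric, with zero-row providers included:

- quartiles use linear interpolation between closest ranks
  (`stats::quantile` type 7). The definition is pinned because quartile
  conventions differ across software and the thresholds must reproduce
  exactly;
- `outlier_threshold = outlier_k × IQR` (default `outlier_k = 1.5`) in the
  default `iqr_multiple` mode. The phrase "1.5 times the IQR" is how such
  programmes describe their cutoff, but it is ambiguous between this literal
  reading and the Tukey fence `Q3 + 1.5 × IQR`; both are implemented
  (`threshold_mode = "tukey_fence"`), the literal reading is the default,
  and the mode used is stamped into the report metadata. Note the literal
  rule compares the *value* to `1.5 × IQR`, so in a degenerate group with
  IQR 0 any provider strictly above 0 is flagged;
- `extreme_threshold = 3 × outlier_threshold`; strictly above it is an
  extreme outlier (which is always also an outlier);
- all comparisons are strict `>`: a provider exactly at a threshold, or a
  prescription of exactly a 5-day supply or exactly 50 MEDD, is compliant;
- groups smaller than `min_group_size` (default 5) keep their thresholds but
  carry a `low_n_flag` — flagging preserves auditability where suppression
  would hide small specialties;
- thresholds are recomputed each quarter from that quarter's distribution.

## Reports

- **Provider scorecards**: five panels (value, specialty median, outlier
  threshold, status); values are copied from the stage outputs, never
  recomputed.
- **Leadership scorecards**: per metric, the partition
  `n_included = n_zero_prescribers + n_within + n_outlier`, a top-15 list
  ranked by metric value descending (the value, not the value/threshold
  ratio, matches how the charts are axis-labelled) with ties broken by
  provider id for determinism, the full scatter series, and a
  Freedman–Diaconis histogram floored at 5 bins (no binning rule is given by
  scorecard conventions; FD adapts to the heavy right tail).
- **CMO reports**: one per division plus an enterprise union, listing
  providers extreme on ≥ 1 metric, sorted by worst value-to-threshold ratio
  (a positive value over a zero threshold sorts first). Colour semantics are
  encoded as status keys; pixels are a rendering detail. JSON/CSV renderings
  are deterministic and byte-stable; PNG charts are a best-effort extra.

## Evaluation statistics

- **Quarterly trend**: Poisson GLM `log E[count] = β₀ + β₁ × quarter_index`
  (index 0..n−1, no offset, no overdispersion adjustment — noted in the
  output metadata), fitted by iteratively reweighted least squares via
  `stats::glm` with a tightened convergence tolerance (relative deviance
  change < 1e-10, ≤ 50 iterations). Reported as
  `pct_change_per_quarter = 100 × (1 − exp(β₁))`, positive for a decline;
  Wald p-value for β₁. All-zero series and non-convergence are errors, never
  silent.
- **Pre/post comparison**: the baseline quarter (before any scorecard was
  released) against the pooled subsequent quarters; uncorrected Pearson
  chi-square on the 2×2 table, 1 df. No continuity correction and Wilson
  score intervals (via `stats::prop.test(correct = FALSE)`) are pinned
  because both are standard, well-defined, and testable against closed
  forms; tests verify the chi-square against `n(ad−bc)²/(r₁r₂c₁c₂)` and the
  intervals against the hand-written Wilson formula.
- No multiplicity adjustment is applied across metrics: the flags are
  descriptive audit artifacts, not hypothesis tests.

# The synthetic-data generator

No real prescription data can ship with the package, so
`simulate_prescribing_data()` generates datasets with known ground truth.
Its defaults emulate the enterprise conditions the pipeline is designed for:
3 divisions, 68 specialties, 30 active providers per specialty (~2,040
prescribers) plus 10% licensed-but-non-prescribing providers, a role mix of
69.7% attendings / 16.3% NPs / 8.3% PAs / 5.5% residents, five scored
quarters with a quarterly volume ratio of 0.984, and pre-period
guideline-exceedance fractions of 27.31% (>5-day, nonchronic), 13.06%
(>50 MEDD, nonchronic) and 6.64% (>90 MEDD, chronic).

Where the emulated conditions do not pin a value, the choice was made once:

- per-provider quarterly rates are log-normal (`sdlog = 0.6`, i.e. the 95th
  percentile prescriber writes ~2.7× the median) with a specialty-level
  shift (`sdlog = 0.3`), and realized counts are negative binomial with
  `size = 12` (variance ≈ 2× mean at the median rate). Together these give
  a heavy right tail and overdispersion — the phenomenon the scorecard
  targets — while keeping a provider injected at 5× their specialty's
  median rate reliably above the `1.5 × IQR` cutoff in groups of ≥ 30,
  which is the designed detectability property of the generator;
- injected outliers (3% of providers by default) prescribe at
  `outlier_rate_multiplier` (default 5) × their specialty's **median** rate,
  never below their own draw;
- chronic patients receive a deterministic 30-day maintenance fill every 30
  days (day supply 30, one refill), which guarantees they satisfy the
  registry rule from their third fill onward; the chronic share of
  prescribing is set by `chronic_rx_fraction` (default 0.15);
- four unscored lead-in quarters give the 12-month lookbacks real data;
- each acute prescription goes to a fresh patient — a simplification that
  leaves the registry's accumulation logic exercised only by the chronic
  streams and the hand-built fixture.

What passing tests on this generator do **not** show about real data:
real sigs are free text (the package requires them pre-parsed), real
patients see multiple prescribers and accumulate prescriptions in messier
patterns, drug mixes are site-specific, and real quarterly counts carry
seasonality and calendar artefacts the generator omits. The generator
validates the *machinery* — conservation, partition identities, threshold
arithmetic, recovery of planted signal — not clinical realism.

The ground-truth file (`truth.csv`) is the contract between generator and
tests; pipeline code never reads it.

# The worked fixture

`generate_worked_fixture()` builds a 41-prescription, 10-provider dataset
whose metrics, thresholds, and flags were computed by hand once and
committed (`inst/extdata/worked/`). It pins every boundary: a prescription
of exactly a 5.0-day supply and one of exactly 50 MEDD (both compliant under
strict `>`), a third-ever prescription that is still nonchronic and a fourth
that is chronic, attribution of a resident's order to its authorizing
attending, an eligible zero-prescription provider, and all three status
values including an extreme flag born of a zero-IQR group. The test suite
also checks the same dataset against a brute-force oracle that replays the
rules one prescription at a time.

# Problem sizes and numerical checks

The shipped tests run the full pipeline at its default scale (3 divisions,
68 specialties, ~2,000 active providers, 5 scored plus 4 lead-in quarters,
roughly a quarter-million prescriptions), chosen to exercise the enterprise
configuration end-to-end while keeping a complete test run to a couple of
minutes. Statistical properties use seeded replication: 200 trend fits at a
baseline of 400,000 prescriptions/quarter, 100 pre/post tables at the same
volume, 500-replicate coverage of the Wald interval, and 1,000 random
groups/tables for the outlier and chi-square oracles.

# Known limitations

- Free-text sig parsing, EHR/warehouse extraction, and report distribution
  are out of scope; the package starts at structured CSV extracts.
- Flat MME factors only: no methadone tiers, no transdermal forms.
- The chronic registry is purely prescription-count-based; no diagnosis
  codes are consulted.
- The Poisson trend carries no offset for eligible-prescriber counts and no
  overdispersion correction; its p-values are anti-conservative if quarterly
  counts are overdispersed.
- The literal `1.5 × IQR` threshold flags aggressively in groups with small
  IQRs; the Tukey-fence mode is the conventional alternative when that is
  unwanted.
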