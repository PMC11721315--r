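---
title: "Scoring oxygenation quality from breath-by-breath ventilator logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring oxygenation quality from breath-by-breath ventilator logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventzone)
```

## The problem

Modern ICU ventilators log every breath: the measured pulse-oximetry
saturation (SpO2, %), the positive end-expiratory pressure (PEEP, cm H2O)
and the inspired oxygen fraction (FiO2, %), together with the set values of
PEEP and FiO2, the ventilation mode, the state of any closed-loop
controllers (automated / manual / frozen) and oxygenation-related alarm
flags. Closed-loop modes adjust PEEP and FiO2 breath by breath toward an
SpO2 target; conventional pressure-controlled or pressure-support
ventilation leaves those adjustments to the bedside clinician. Whether the
two strategies deliver comparable *quality of oxygenation* — and at what
cost in clinician interventions and alarm burden — is naturally studied in
a randomized crossover design: each patient receives both modes for a few
hours, separated by a washout, and serves as their own control.

ventzone implements the full analysis pipeline for such a crossover study:
per-breath oxygenation-zone scoring, per-patient endpoint aggregation,
event mining, and the paired between-arm comparison, plus a synthetic
log generator so the whole pipeline can be validated without clinical
data.

## The zone model

Each breath is scored in three steps.

1. **SpO2 zone.** The saturation is looked up in a set of bands
   partitioning [50, 100]%. The shipped default (table version
   `default_v1`) uses optimal 93–97%, acceptable 90–92% or 98–100%, and
   critical below 90%. These cutoffs follow the published SpO2 target
   ranges for invasively ventilated patients; they are a documented
   reconstruction, not a device vendor table, and every analysis can
   substitute its own bands via `read_zone_table()`. The upper acceptable
   band reflects the hyperoxia risk of saturations pinned at 98–100%.

2. **PEEP/FiO2 zone.** The (PEEP, FiO2) pair is scored against a
   lower-PEEP/higher-FiO2 titration grid — the ARDS Network pairing of
   FiO2 bins with allowed PEEP ranges, e.g. FiO2 ≈ 30% with PEEP 5, up to
   FiO2 ≈ 100% with PEEP 18–24. A pair inside its FiO2 bin's PEEP range is
   optimal. Otherwise its *grid-step distance* is the minimum number of
   FiO2-row moves plus PEEP increments (`peep_step`, default 2 cm H2O per
   step) needed to reach an optimal cell, found by brute-force search over
   all rows; a distance of at most `pf_tolerance_steps` (default 1) is
   acceptable, anything further critical. The tolerance encodes "one
   titration step away from the table".

3. **Combination.** The default `worst_of` rule takes the worse of the two
   scores on the order optimal < acceptable < critical: a breath is only as
   good as its weaker component. An alternative `spo2_priority` rule is
   provided for sensitivity analyses (the SpO2 score wins; a non-optimal
   PEEP/FiO2 score can only demote optimal to acceptable). Either input
   missing makes the breath `unclassified`.

The two classifiers are deliberately orthogonal: SpO2 = 100% is handled by
the SpO2 bands alone, and any FiO2-dependent hyperoxia penalty belongs in
the grid, not in a cross-term.

## Endpoints

For each patient, phase and classification view (combined, SpO2-only,
PEEP/FiO2-only):

* **Percentage of breaths in a zone** = 100 × (breaths in zone) /
  (classified breaths). Unclassified breaths are excluded from the
  denominator — the three zone percentages then sum to exactly 100 — and
  their fraction is reported separately. With zero classified breaths the
  endpoint is undefined (`NA`), never zero.
* **Percentage of time in a zone** weights each breath by its duration:
  the gap to the next breath, capped at 15 s so signal dropouts cannot
  dominate, with the final breath (which has no successor) inheriting the
  median of the other capped durations. When all durations are equal the
  time fraction equals the breath fraction exactly, which the tests
  assert.
* **Setting-change events.** A raw change is a breath whose set PEEP or
  set FiO2 differs from the previous breath by at least 0.5 cm H2O or 1
  percentage point respectively (smaller moves are telemetry jitter).
  Consecutive raw changes of the same parameter, direction and origin
  within a 60 s window coalesce into one event — a clinician stepping FiO2
  40 → 45 → 50 over a few breaths made one intervention. Origin is manual
  when the controller status at the change breath is `manual` or `frozen`
  (a frozen controller implies clinician override), automated otherwise.
  Near-simultaneous PEEP and FiO2 changes count as two events, one per
  parameter. All thresholds are arguments (and CLI flags), so a
  sensitivity analysis is one flag away.
* **Alarm episodes.** Maximal runs of alarm-flagged breaths; runs
  separated by a single non-alarmed breath merge (a one-breath flicker
  does not end an episode). Episode duration runs from the first alarmed
  breath to the last alarmed breath plus its own duration. Episodes
  straddling a phase boundary are split and their minutes apportioned.

Phase assignment is half-open `[start, end)` throughout; washout breaths
and events are tallied but excluded from all between-arm endpoints.

## The paired comparison

Endpoints are compared between arms with a Wilcoxon signed-rank test
implemented in the package. Differences are automated − conventional;
zero differences are discarded before ranking (classic Wilcoxon; the Pratt
variant, which ranks zeros and then drops them, is available); absolute
differences receive midranks under ties. For up to 20 non-zero differences
the two-sided p-value is exact: the null distribution of the statistic over
all $2^m$ sign assignments, computed by convolving the doubled midranks
(doubling makes tied half-ranks integral, so the enumeration is exact).
Beyond that a normal approximation with tie-corrected variance
($\operatorname{Var} W^+ = \sum_i r_i^2/4$, which reduces to
$m(m+1)(2m+1)/24$ without ties) and a continuity correction is used. The
crossover at $m = 20$ keeps the exact path instant while the approximation
error at that size is already far below the reporting precision. A test
suite cross-checks the exact path against a literal $2^m$ enumeration loop
and against `stats::wilcox.test` on tie-free data.

Descriptives follow the median [IQR] and mean (SD) convention, with
quartiles by linear interpolation (R type 7) and the $n-1$ standard
deviation. All endpoints are reported with raw p-values and an
informational significance flag at α = 0.05 — no multiple-testing
correction is applied, deliberately mirroring how such crossover endpoint
tables are conventionally presented; readers should treat the many
secondary p-values accordingly. No period or carryover modelling is
attempted: with two 3 h phases and a washout, the design's own symmetry is
relied on, and the package makes no claim beyond the paired comparison.

## The synthetic generator

`generate_cohort()` emulates the *statistical structure* of a crossover
ventilator log, not lung physiology:

* **Design constants.** Two 3 h phases, 30 min washout, 1:1 alternating
  allocation of the first mode, respiratory rate 18 breaths/min — the
  defaults of `synthetic_config()`. A 53-patient cohort at these defaults
  produces ≈ 343,000 phase breaths.
* **Breath timing** is a renewal process with gamma inter-breath
  intervals (CV = `rr_jitter`, default 0.15); `rr_jitter = 0` is the
  noise-free mode with perfectly regular breaths.
* **Oxygenation values by zone-preimage sampling.** A target combined
  zone is drawn per dwell period (exponential, mean 120 s, giving realistic
  serial correlation; `dwell_mean_s = 0` gives i.i.d. draws for variance
  checks) with the configured occupancy probabilities, and each breath's
  (SpO2, PEEP, FiO2) triple is drawn uniformly from that zone's preimage —
  the set of integer triples the zone table maps to that zone, computed
  once by exhaustive sweep. This guarantees the pipeline classifies every
  generated breath back into its target zone, so occupancy is controlled
  exactly and recovery tests are sharp. The default occupancies
  (46/20/34 both arms) match the scale of published crossover cohorts.
  A custom table with an unreachable zone raises an empty-preimage error.
* **Events and alarms** are Poisson processes per phase — manual changes
  at 0.43/h (automated arm) vs 0.7/h (conventional), automated changes at
  11.3/h in the automated arm only, alarm episodes at 2.3/h vs 0.47/h
  with ≈ 60 s exponential durations — thinned so consecutive events stay
  outside the coalescence window and episodes stay several breaths apart.
  The realized (post-thinning) counts are the ground truth, so in
  noise-free mode the detectors recover them exactly; alarm *minutes* are
  breath-quantized at detection and recovered approximately.
* **Reproducibility.** One master seed; patient *i* uses the substream
  seed `(seed + 100003·i) mod (2^31 − 1)`, so cohorts are byte-identical
  across runs and patients are independently regenerable.

What the generator does **not** emulate: closed-loop controller dynamics
(only their observable log signature of frequent small automated changes),
physiological coupling between SpO2 and the settings, drift within a
phase, missing-data bursts, or sensor artifacts beyond what the io layer's
tests construct directly. Passing recovery tests therefore demonstrates
the pipeline's correctness on logs with the assumed structure, not
robustness to every failure mode of real bedside data.

## Numerical and degenerate-input choices

* Timestamps are seconds (numeric or parsed ISO-8601); strictly
  increasing or the reader aborts citing the first offending row.
* Missing tokens: empty cell, `NA`, `NaN` (case-insensitive). Any other
  non-numeric token drops the row with a warning and a parse-report count;
  `rows_read = rows_kept + rows_dropped` always.
* Out-of-physical-range measurements (SpO2 outside [50, 100], FiO2 outside
  [21, 100], PEEP outside [0, 30]) become missing at ingestion and are
  counted; the classifiers, by contrast, reject out-of-range values passed
  to them directly.
* Zone band and FiO2-bin edges are half-open on the left, with the top
  interval closed, so the bands partition their domain with no gaps,
  overlaps or double counting — verified by an exhaustive integer-grid
  sweep.
* Single-breath segments have no defined durations: time-in-zone is `NA`
  with a warning. All-zero difference vectors give p = 1 with a
  degenerate-sample warning; an empty pair set is an error.

## Problem sizes in the shipped tests

The test suite validates occupancy recovery at ~10,000 breaths per phase
(the binomial sampling error there is well inside the ±2 percentage-point
band asserted), event-count recovery on a noise-free 53-patient cohort at
the full 3 h design, exact-test agreement with enumeration for up to 12
non-zero differences over 100 random samples, and the type-I error of the
paired test at n = 50 patients over 1,000 null replicates (expected
rejection rate within [0.03, 0.07] at α = 0.05; the continuity correction
makes the test mildly conservative). These sizes were chosen so each
property is measured with negligible Monte-Carlo ambiguity while the whole
suite stays interactive.

## Known limitations

* The default zone table is a reconstruction from published target ranges;
  analyses against a unit's own protocol must supply their table, and the
  table version is stamped into every output for that reason.
* Arterial blood-gas (PaO2/FiO2) zoning is out of scope: classification is
  pulse-oximetry based only.
* Alarm causes are not classified; the schema carries a single binary
  oxygenation-alarm flag.
* The event coalescence window (60 s) and minimum-change thresholds are
  heuristics for "one clinical intervention"; conclusions about
  intervention counts should be checked for sensitivity to them.
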