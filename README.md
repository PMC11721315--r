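# ventzone

Oxygenation-quality analysis of breath-by-breath ventilator logs from
randomized crossover studies of automated (closed-loop) versus
conventional mechanical ventilation.

ICU ventilators running closed-loop modes adjust PEEP and FiO2 breath by
breath toward an SpO2 target; under conventional pressure-controlled or
pressure-support ventilation the bedside clinician makes those
adjustments by hand. ventzone scores every logged breath into an
**optimal / acceptable / critical oxygenation zone** and compares the two
strategies within patients:

1. an SpO2 **band** score (default: optimal 93–97%, acceptable 90–92% or
   98–100%, critical < 90%; a documented reconstruction of published
   target ranges, fully overridable by a YAML zone table);
2. a **PEEP/FiO2** score against a lower-PEEP/higher-FiO2 titration grid
   (the ARDS Network pairing of FiO2 bins with allowed PEEP ranges): a
   pair in its bin's PEEP range is optimal, within one grid step of an
   optimal cell acceptable, otherwise critical;
3. a **combined** zone, by default the worse of the two
   (optimal < acceptable < critical).

Per patient and crossover phase it computes, for the combined, SpO2-only
and PEEP/FiO2-only views,

```
percentage of breaths in zone = 100 × (breaths in zone) / (classified breaths)
```

together with its duration-weighted time-in-zone counterpart, mines
manual vs automated PEEP/FiO2 setting changes and oxygenation alarm
episodes from the log, and compares arms with an **exact paired Wilcoxon
signed-rank test** (full sign-assignment null distribution up to 20
non-zero differences; tie-corrected, continuity-corrected normal
approximation beyond). A seeded synthetic cohort generator with known
ground truth (zone-preimage sampling, Poisson event processes) makes the
whole pipeline testable end to end.

## Worked example

```r
library(ventzone)

cfg <- synthetic_config(n_patients = 6, phase_minutes = 60,
                        washout_minutes = 10, seed = 42)
cohort <- generate_cohort(cfg)
fit <- crossover_analysis(cohort$logs, cohort$manifest)
fit
#> Crossover oxygenation-zone analysis
#>   6 patient(s), zone table [default_v1]
#>   breaths in optimal zone: automated 48.2 [43.7-50.9]% vs conventional 47.1 [46.2-50.0]% (p = 0.844)

z <- fit$comparison$zones
z[z$view == "combined" & z$metric == "pct_breaths",
  c("zone", "n_pairs", "automated_median", "conventional_median", "p_value")]
#>         zone n_pairs automated_median conventional_median p_value
#> 1    optimal       6             48.2                47.1   0.844
#> 2 acceptable       6             12.3                35.0   0.219
#> 3   critical       6             40.3                25.3   0.156

fit$comparison$events[, c("endpoint", "automated_median",
                          "conventional_median", "p_value")]
#>        endpoint automated_median conventional_median p_value
#> 1   n_automated            10.50                 0.0  0.0312
#> 2      n_manual             0.00                 0.5  0.5000
#> 3      n_alarms             3.50                 0.0  0.0625
#> 4 alarm_minutes             1.92                 0.0  0.0625
```

The zone rows read: over the six synthetic patients, the median
percentage of breaths in the optimal combined zone was 48.2% under
automated and 47.1% under conventional ventilation (paired signed-rank
p = 0.84 — no difference, as configured). The event rows show the
generator's asymmetry: frequent automated setting changes and more alarm
minutes in the automated arm, sparser manual changes than the
conventional arm.

The exact test itself:

```r
wilcoxon_signed_rank(c(1, 2, 3))
#> Paired Wilcoxon signed-rank test (exact (2^3 sign assignments))
#>   W+ = 6 over 3 non-zero of 3 pairs (0 zero, 0 missing)
#>   median difference = 2, two-sided p = 0.25
```

Real cohorts enter through `read_breath_log()` (CSV, schema-mapped
column names, robust missing-value handling) and `read_manifest()`;
`run_analysis()` writes the full report bundle (endpoint comparison
tables, per-patient summaries, ECDF and bar-plot data, run log) with
provenance headers. A thin command-line wrapper is installed under
`exec/`:

```sh
ventzone simulate --out cohort/ --seed 42
ventzone analyze --input cohort/ --out results/
```

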