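# ventzone default oxygenation zone table, version default_v1.
#
# NOTE: these cutoffs are a documented reconstruction from the published
# literature (SpO2 target bands; ARDS Network lower-PEEP/higher-FiO2 table),
# not a vendor table. Override any field and load with read_zone_table() to
# run an analysis against a different definition.
#
# spo2_bands: half-open [lower, upper) in percent SpO2; the top band also
#   includes its upper edge so the bands partition [50, 100].
# pf_grid: FiO2 bins (percent, half-open, top bin closed) with the inclusive
#   PEEP range (cm H2O) considered optimal for that bin. peep_step is the
#   PEEP increment (cm H2O) counted as one grid step when measuring the
#   distance of an off-table (PEEP, FiO2) pair from the nearest optimal cell;
#   pairs within pf_tolerance_steps grid steps score acceptable.
version: default_v1
combination_rule: worst_of
pf_tolerance_steps: 1
peep_step: 2
spo2_bands:
- lower: 50.0
  upper: 90.0
  label: critical
- lower: 90.0
  upper: 93.0
  label: acceptable
- lower: 93.0
  upper: 98.0
  label: optimal
- lower: 98.0
  upper: 100.0
  label: acceptable
pf_grid:
- fio2_lower: 21.0
  fio2_upper: 35.0
  peep_lower: 5.0
  peep_upper: 5.0
- fio2_lower: 35.0
  fio2_upper: 45.0
  peep_lower: 5.0
  peep_upper: 8.0
- fio2_lower: 45.0
  fio2_upper: 55.0
  peep_lower: 8.0
  peep_upper: 10.0
- fio2_lower: 55.0
  fio2_upper: 65.0
  peep_lower: 10.0
  peep_upper: 10.0
- fio2_lower: 65.0
  fio2_upper: 75.0
  peep_lower: 10.0
  peep_upper: 14.0
- fio2_lower: 75.0
  fio2_upper: 85.0
  peep_lower: 14.0
  peep_upper: 14.0
- fio2_lower: 85.0
  fio2_upper: 95.0
  peep_lower: 14.0
  peep_upper: 18.0
- fio2_lower: 95.0
  fio2_upper: 100.0
  peep_lower: 18.0
  peep_upper: 24.0
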