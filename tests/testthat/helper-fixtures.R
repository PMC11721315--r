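# Programmatic fixtures: breath-log data.frames and manifests built in code.

make_log <- function(time, spo2 = 95, peep = 5, fio2 = 30,
                     mode = "automated", controller = "automated",
                     alarm = FALSE, set_peep = NULL, set_fio2 = NULL) {
  n <- length(time)
  data.frame(time = time,
             spo2 = rep_len(spo2, n),
             peep = rep_len(peep, n),
             fio2 = rep_len(fio2, n),
             mode = rep_len(mode, n),
             controller = rep_len(controller, n),
             alarm = rep_len(alarm, n),
             set_peep = rep_len(if (is.null(set_peep)) peep else set_peep, n),
             set_fio2 = rep_len(if (is.null(set_fio2)) fio2 else set_fio2, n),
             stringsAsFactors = FALSE)
}

make_manifest <- function(patient_id = "P001", first_mode = "automated",
                          phase_s = 3 * 3600, washout_s = 1800) {
  data.frame(patient_id = patient_id, first_mode = first_mode,
             phase1_start = 0, phase1_end = phase_s,
             phase2_start = phase_s + washout_s,
             phase2_end = 2 * phase_s + washout_s,
             stringsAsFactors = FALSE)
}

# A zone table that maps every input to `optimal`, for config-sensitivity
# checks.
all_optimal_table <- function() {
  zone_table(
    spo2_bands = data.frame(lower = 50, upper = 100, label = "optimal"),
    pf_grid = data.frame(fio2_lower = 21, fio2_upper = 100,
                         peep_lower = 0, peep_upper = 30),
    pf_tolerance_steps = 0L, version = "degenerate_all_optimal")
}
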