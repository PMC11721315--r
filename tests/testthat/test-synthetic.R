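test_that("the generator is deterministic given the seed", {
  cfg <- synthetic_config(n_patients = 2, phase_minutes = 10,
                          washout_minutes = 5, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$logs, b$logs)
  expect_identical(a$ground_truth, b$ground_truth)
  cfg2 <- synthetic_config(n_patients = 2, phase_minutes = 10,
                           washout_minutes = 5, seed = 100)
  c_ <- generate_cohort(cfg2)
  expect_false(identical(a$logs[[1]], c_$logs[[1]]))
  expect_identical(names(a$logs[[1]]), names(c_$logs[[1]]))
})

test_that("written cohorts are byte-identical across runs with one seed", {
  cfg <- synthetic_config(n_patients = 2, phase_minutes = 5,
                          washout_minutes = 2, seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cfg, dir = d1)
  generate_cohort(cfg, dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("first modes alternate 1:1 across the cohort", {
  cfg <- synthetic_config(n_patients = 4, phase_minutes = 5,
                          washout_minutes = 2, seed = 5)
  co <- generate_cohort(cfg)
  expect_equal(sum(co$manifest$first_mode == "automated"), 2)
  expect_equal(sum(co$manifest$first_mode == "conventional"), 2)
  expect_equal(co$manifest$first_mode[1:2], c("automated", "conventional"))
})

test_that("breath counts follow the renewal-process expectation", {
  cfg <- synthetic_config(n_patients = 6, phase_minutes = 60,
                          washout_minutes = 10, rr_mean = 15.2, seed = 8)
  co <- generate_cohort(cfg)
  total <- sum(co$ground_truth$n_breaths)
  expected <- 2 * 6 * 60 * 15.2
  expect_lt(abs(total - expected) / expected, 0.05)
})

test_that("degenerate occupancy (1,0,0) makes every classified breath optimal", {
  cfg <- synthetic_config(
    n_patients = 1, phase_minutes = 10, washout_minutes = 5,
    zone_occupancy = list(automated = c(1, 0, 0), conventional = c(1, 0, 0)),
    seed = 14)
  co <- generate_cohort(cfg)
  s <- summarize_cohort(co$logs, co$manifest)
  comb <- s[s$view == "combined", ]
  expect_true(all(comb$pct_breaths[comb$zone == "optimal"] == 100))
  expect_true(all(comb$pct_breaths[comb$zone != "optimal"] == 0))
})

test_that("pipeline occupancy converges to the target as O(n^-1/2)", {
  # i.i.d. zone draws (dwell 0) so the binomial rate applies; the larger run
  # has 16x the breaths, so its mean error should drop to about a quarter
  # and at least below half.
  err_at <- function(minutes) {
    errs <- vapply(1:20, function(s) {
      cfg <- synthetic_config(n_patients = 1, phase_minutes = minutes,
                              washout_minutes = 2, dwell_mean_s = 0,
                              rr_jitter = 0, seed = 1000 + s)
      co <- generate_cohort(cfg)
      s_ <- summarize_cohort(co$logs, co$manifest)
      opt <- s_[s_$view == "combined" & s_$zone == "optimal" &
                  s_$phase == "automated", "pct_breaths"]
      abs(opt - 46)
    }, numeric(1))
    mean(errs)
  }
  e_small <- err_at(14)    # ~250 breaths
  e_large <- err_at(224)   # ~4000 breaths
  expect_lt(e_large, e_small / 2)
})

test_that("noise-free mode recovers event and alarm counts exactly", {
  cfg <- synthetic_config(n_patients = 4, phase_minutes = 60,
                          washout_minutes = 10, rr_jitter = 0, seed = 11)
  co <- generate_cohort(cfg)
  ec <- do.call(rbind, lapply(co$manifest$patient_id, function(pid)
    events_per_phase(co$logs[[pid]],
                     co$manifest[co$manifest$patient_id == pid, ])$counts))
  m <- merge(ec[ec$phase != "washout", ], co$ground_truth,
             by = c("patient_id", "phase"), suffixes = c("_det", "_gt"))
  expect_equal(nrow(m), 8)
  expect_identical(m$n_manual_det, m$n_manual_gt)
  expect_identical(m$n_automated_det, m$n_automated_gt)
  expect_identical(m$n_alarms_det, m$n_alarms_gt)
  # detected alarm minutes never exceed the phase duration
  expect_true(all(m$alarm_minutes_det <= 60))
})

test_that("pipeline zone percentages match the generator ground truth", {
  cfg <- synthetic_config(n_patients = 2, phase_minutes = 30,
                          washout_minutes = 5, seed = 77)
  co <- generate_cohort(cfg)
  s <- summarize_cohort(co$logs, co$manifest)
  gt <- co$ground_truth
  for (i in seq_len(nrow(gt))) {
    sub <- s[s$patient_id == gt$patient_id[i] & s$phase == gt$phase[i] &
               s$view == "combined", ]
    est <- setNames(sub$pct_breaths, sub$zone)
    expect_equal(unname(est["optimal"]), gt$occ_optimal[i], tolerance = 1e-9)
    expect_equal(unname(est["acceptable"]), gt$occ_acceptable[i], tolerance = 1e-9)
    expect_equal(unname(est["critical"]), gt$occ_critical[i], tolerance = 1e-9)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(zone_occupancy = list(
    automated = c(0.5, 0.5, 0.5), conventional = c(0.4, 0.3, 0.3))),
    "simplex")
  expect_error(synthetic_config(phase_minutes = 0), "positive")
  expect_error(synthetic_config(manual_rate = c(automated = -1,
                                                conventional = 1)), "rates")
  # a table with an unreachable zone has an empty preimage
  expect_error(
    generate_patient(synthetic_config(n_patients = 1, phase_minutes = 5,
                                      washout_minutes = 2, seed = 1),
                     1, table = all_optimal_table()),
    "empty preimage")
})
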