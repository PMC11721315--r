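test_that("constant settings produce zero events", {
  log <- make_log(seq(0, 100, by = 2))
  expect_equal(nrow(detect_setting_changes(log)), 0)
  expect_equal(nrow(detect_setting_changes(make_log(numeric(0)))), 0)
})

test_that("a stepped FiO2 titration coalesces into one manual event", {
  # 40 -> 45 -> 50 on consecutive breaths 2 s apart, clinician at the knob
  log <- make_log(seq(0, 20, by = 2), mode = "conventional_pc",
                  controller = "manual",
                  set_fio2 = c(40, 40, 45, 50, 50, 50, 50, 50, 50, 50, 50))
  ev <- detect_setting_changes(log)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$parameter, "FiO2")
  expect_equal(ev$old_value, 40)
  expect_equal(ev$new_value, 50)
  expect_equal(ev$origin, "manual")
})

test_that("origin follows the controller status, frozen counting as manual", {
  log <- make_log(seq(0, 20, by = 2), set_peep = c(rep(8, 5), rep(10, 6)))
  ev <- detect_setting_changes(log)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$origin, "automated")
  log$controller <- "frozen"
  expect_equal(detect_setting_changes(log)$origin, "manual")
})

test_that("window expiry or direction reversal splits titrations into events", {
  # ramp up at t = 0..4, then a ramp down starting 120 s later
  t <- c(0, 2, 4, 124, 126)
  log <- make_log(t, mode = "conventional_pc", controller = "manual",
                  set_fio2 = c(40, 45, 50, 45, 40))
  ev <- detect_setting_changes(log)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$new_value, c(50, 40))
  # same gap, same direction, still within the window: merged
  t2 <- c(0, 2, 4, 50, 52)
  log2 <- make_log(t2, mode = "conventional_pc", controller = "manual",
                   set_fio2 = c(40, 45, 50, 55, 60))
  expect_equal(nrow(detect_setting_changes(log2)), 1)
})

test_that("sub-threshold wobble is ignored", {
  log <- make_log(seq(0, 10, by = 2), set_peep = c(8, 8.2, 8, 8.2, 8, 8.2))
  expect_equal(nrow(detect_setting_changes(log)), 0)
})

test_that("alarm episodes cover maximal runs with single-breath gap merging", {
  expect_equal(nrow(detect_alarm_episodes(make_log(seq(0, 100, 4)))), 0)
  # 30 consecutive alarmed breaths at 4 s/breath last 2.0 minutes
  n <- 40
  alarm <- c(rep(FALSE, 5), rep(TRUE, 30), rep(FALSE, 5))
  log <- make_log(seq(0, by = 4, length.out = n), alarm = alarm)
  ep <- detect_alarm_episodes(log)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration_minutes, 2.0)
  # two runs separated by one non-alarmed breath merge
  alarm2 <- c(rep(TRUE, 5), FALSE, rep(TRUE, 5), rep(FALSE, 29))
  log2 <- make_log(seq(0, by = 4, length.out = n), alarm = alarm2)
  expect_equal(nrow(detect_alarm_episodes(log2)), 1)
  # two non-alarmed breaths keep the runs apart
  alarm3 <- c(rep(TRUE, 5), FALSE, FALSE, rep(TRUE, 5), rep(FALSE, 28))
  log3 <- make_log(seq(0, by = 4, length.out = n), alarm = alarm3)
  ep3 <- detect_alarm_episodes(log3)
  expect_equal(nrow(ep3), 2)
  expect_true(all(ep3$start_timestamp[-1] > ep3$end_timestamp[-nrow(ep3)]))
})

test_that("per-phase counting assigns events and splits straddling alarms", {
  m <- make_manifest(first_mode = "conventional", phase_s = 600, washout_s = 60)
  events <- data.frame(patient_id = "P001",
                       timestamp = c(10, 50, 700),
                       parameter = "FiO2", old_value = 40, new_value = 45,
                       origin = c("manual", "manual", "automated"),
                       stringsAsFactors = FALSE)
  # one episode from 580 to 640: 20 s in phase 1, 40 s in the washout
  episodes <- data.frame(patient_id = "P001", start_timestamp = 580,
                         end_timestamp = 640, duration_minutes = 1,
                         stringsAsFactors = FALSE)
  counts <- count_events_per_phase(events, episodes, m)
  conv <- counts[counts$phase == "conventional", ]
  expect_equal(conv$n_manual, 2)
  expect_equal(conv$n_automated, 0)
  expect_equal(conv$n_alarms, 1)
  expect_equal(conv$alarm_minutes, 20 / 60)
  wash <- counts[counts$phase == "washout", ]
  expect_equal(wash$alarm_minutes, 40 / 60)
  expect_equal(counts[counts$phase == "automated", "n_automated"], 1)
  # conservation: per-phase event counts sum to the total
  expect_equal(sum(counts$n_manual) + sum(counts$n_automated), nrow(events))
})

test_that("empty event lists count to zeros", {
  m <- make_manifest()
  log <- make_log(seq(0, 100, 4))
  r <- events_per_phase(log, m)
  expect_true(all(r$counts$n_manual == 0) && all(r$counts$n_alarms == 0))
})

test_that("the detector is idempotent on a log rebuilt from its own events", {
  set.seed(21)
  t <- seq(0, 3000, by = 3)
  fio2 <- rep(40, length(t))
  for (ts in c(300, 900, 1800)) fio2[t >= ts] <- fio2[t >= ts] + 5
  log <- make_log(t, mode = "conventional_pc", controller = "manual",
                  set_fio2 = fio2)
  ev1 <- detect_setting_changes(log)
  # rebuild from baseline plus detected events, re-detect
  fio2_rebuilt <- rep(ev1$old_value[1], length(t))
  for (k in seq_len(nrow(ev1)))
    fio2_rebuilt[t >= ev1$timestamp[k]] <- ev1$new_value[k]
  log2 <- make_log(t, mode = "conventional_pc", controller = "manual",
                   set_fio2 = fio2_rebuilt)
  ev2 <- detect_setting_changes(log2)
  expect_equal(ev2, ev1)
})
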