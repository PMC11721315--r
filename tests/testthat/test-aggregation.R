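test_that("phase segmentation uses half-open intervals and the manifest arms", {
  m <- make_manifest(first_mode = "automated", phase_s = 10800, washout_s = 1800)
  log <- make_log(c(0, 5000, 10799, 10800, 12000, 12600, 20000, 23399, 23400))
  segs <- segment_phases(log, m)
  expect_equal(attr(segs$phase1, "phase_label"), "automated")
  expect_equal(attr(segs$washout, "phase_label"), "washout")
  expect_equal(attr(segs$phase2, "phase_label"), "conventional")
  expect_equal(nrow(segs$phase1), 3)
  # boundary breaths fall into the later interval (half-open convention)
  expect_true(10800 %in% segs$washout$time)
  expect_true(12600 %in% segs$phase2$time)
  expect_equal(nrow(segs$phase2), 3)
  # 23400 = phase2_end falls outside every interval
  expect_equal(attr(segs, "n_outside"), 1)

  m2 <- make_manifest(first_mode = "conventional")
  segs2 <- segment_phases(log, m2)
  expect_equal(attr(segs2$phase1, "phase_label"), "conventional")
  expect_equal(attr(segs2$phase2, "phase_label"), "automated")

  empty <- segment_phases(make_log(numeric(0)), m)
  expect_equal(nrow(empty$phase1), 0)
})

test_that("percentage of breaths follows the counting equation", {
  labs <- rep(c("optimal", "critical"), c(50, 150))
  expect_equal(percent_breaths_in_zone(labs, "optimal"), 25.0)
  expect_equal(percent_breaths_in_zone(rep("optimal", 7), "optimal"), 100.0)
  expect_equal(percent_breaths_in_zone(rep("optimal", 7), "critical"), 0)
  # unclassified breaths leave the denominator; all-unclassified is undefined
  expect_equal(percent_breaths_in_zone(c("optimal", "unclassified"), "optimal"), 100)
  expect_true(is.na(percent_breaths_in_zone(rep("unclassified", 5), "optimal")))
})

test_that("breath durations cap long gaps and impute the final breath", {
  expect_equal(breath_durations(c(0, 4, 8, 12)), c(4, 4, 4, 4))
  # a 60 s dropout is credited at most the cap
  expect_equal(breath_durations(c(0, 4, 64, 68))[2], 15)
  # final breath inherits the median of the other capped durations
  expect_equal(breath_durations(c(0, 1, 4)), c(1, 3, 2))
  expect_true(is.na(breath_durations(5)))
  expect_length(breath_durations(numeric(0)), 0)
})

test_that("time-in-zone weights breaths by duration under the stated rule", {
  # durations 1, 3, then median 2 for the closing breath
  log <- make_log(c(0, 1, 4))
  labs <- c("optimal", "critical", "critical")
  expect_equal(percent_time_in_zone(log, labs, "optimal"), 100 * 1 / 6)
  expect_equal(percent_time_in_zone(log, labs, "critical"), 100 * 5 / 6)
  # constant durations: time fraction equals breath fraction exactly
  n <- 200
  log2 <- make_log(seq(0, by = 4, length.out = n))
  labs2 <- rep(c("optimal", "critical"), c(50, 150))
  expect_equal(percent_time_in_zone(log2, labs2, "optimal"),
               percent_breaths_in_zone(labs2, "optimal"))
  expect_warning(p1 <- percent_time_in_zone(make_log(1), "optimal", "optimal"),
                 "single-breath")
  expect_true(is.na(p1))
})

test_that("per-patient summaries partition breaths and sum to 100 per view", {
  set.seed(11)
  m <- make_manifest(phase_s = 600, washout_s = 120)
  n <- 500
  log <- make_log(seq(0, by = 2.6, length.out = n),
                  spo2 = sample(c(85:100, NA), n, TRUE),
                  peep = sample(0:24, n, TRUE),
                  fio2 = sample(21:100, n, TRUE))
  s <- summarize_patient(log, m)
  expect_equal(nrow(s), 2 * 3 * 3)   # 2 phases x 3 views x 3 zones
  sums <- aggregate(pct_breaths ~ phase + view, s, sum)
  expect_true(all(abs(sums$pct_breaths - 100) < 1e-9))
  sums_t <- aggregate(pct_time ~ phase + view, s, sum)
  expect_true(all(abs(sums_t$pct_time - 100) < 1e-9))
  # conservation of breath counts per phase and view
  labs <- classify_breaths(log, view = "all")
  segs <- segment_phases(log, m)
  in_p1 <- log$time >= 0 & log$time < 600
  n_cls <- sum(labs$zone[in_p1] != "unclassified")
  expect_equal(unique(s$n_breaths[s$phase == "automated" & s$view == "combined"]),
               n_cls)
  expect_equal(n_cls + sum(labs$zone[in_p1] == "unclassified"), sum(in_p1))
})

test_that("a single-zone log yields a 100/0/0 summary", {
  m <- make_manifest(phase_s = 100, washout_s = 50)
  log <- make_log(seq(0, 249, by = 2), spo2 = 95, peep = 5, fio2 = 30)
  s <- summarize_patient(log, m)
  comb <- s[s$view == "combined" & s$phase == "automated", ]
  expect_equal(comb$pct_breaths[comb$zone == "optimal"], 100)
  expect_equal(comb$pct_breaths[comb$zone == "acceptable"], 0)
  expect_equal(comb$pct_breaths[comb$zone == "critical"], 0)
})

test_that("washout-only logs give empty phases with undefined percentages", {
  m <- make_manifest(phase_s = 100, washout_s = 100)
  log <- make_log(seq(100, 199, by = 2))   # entirely inside the washout
  s <- summarize_patient(log, m)
  expect_true(all(s$n_breaths == 0))
  expect_true(all(is.na(s$pct_breaths)))
})

test_that("breath percentages are invariant under within-phase reordering of labels", {
  set.seed(5)
  labs <- sample(c("optimal", "acceptable", "critical"), 300, TRUE)
  p1 <- percent_breaths_in_zone(labs, "optimal")
  p2 <- percent_breaths_in_zone(rev(labs), "optimal")
  p3 <- percent_breaths_in_zone(sample(labs), "optimal")
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})
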