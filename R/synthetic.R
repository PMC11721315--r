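# Seeded synthetic ventilator-log generator. The generator does not simulate
# lung physiology or a closed-loop controller: it reproduces the statistical
# structure the analysis assumes — a crossover of two phases with a washout,
# breath timestamps from a jittered renewal process, per-breath
# (SpO2, PEEP, FiO2) triples drawn from the preimage of a target oxygenation
# zone (which guarantees exact control of zone occupancy), sparse manual
# setting changes vs frequent automated ones, and Poisson alarm episodes —
# together with the ground truth needed to check the pipeline end to end.

#' Configuration of the synthetic crossover cohort
#'
#' Defaults mirror the crossover design the analysis targets: two 3-hour
#' phases separated by a 30-minute washout, a respiratory rate around 18
#' breaths/min, combined-zone occupancies near 46/20/34
#' (optimal/acceptable/critical) in both arms, roughly 0.4 (automated arm)
#' vs 0.7 (conventional arm) manual setting changes per hour, about 11
#' automated changes per hour in the automated arm only, and oxygenation
#' alarms at about 2.3/h lasting a minute on average in the automated arm vs
#' 0.5/h in the conventional arm.
#'
#' @param n_patients cohort size.
#' @param phase_minutes duration of each crossover phase.
#' @param washout_minutes washout between the phases (excluded from
#'   endpoints).
#' @param rr_mean mean respiratory rate, breaths/min.
#' @param rr_jitter coefficient of variation of the inter-breath interval;
#'   0 gives the noise-free mode with perfectly regular breaths.
#' @param zone_occupancy named list with elements `automated` and
#'   `conventional`, each a 3-vector of target (optimal, acceptable,
#'   critical) occupancy summing to 1.
#' @param manual_rate named numeric: manual setting changes per hour per arm.
#' @param automated_rate automated setting changes per hour (automated arm).
#' @param alarm_rate named numeric: alarm episodes per hour per arm.
#' @param alarm_duration_mean mean episode duration, seconds.
#' @param dwell_mean_s mean dwell time between zone re-draws, seconds
#'   (serial correlation of the oxygenation state); 0 re-draws every breath.
#' @param peep_floor,peep_ceiling bounds for the set-PEEP trajectory, cm H2O.
#' @param seed integer master seed; per-patient substreams are derived from
#'   it by a fixed counter scheme (`seed + 100003 * patient_index`, modulo
#'   2^31 - 1) so patients are independently reproducible.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 53, phase_minutes = 180,
                             washout_minutes = 30, rr_mean = 18,
                             rr_jitter = 0.15,
                             zone_occupancy = list(
                               automated = c(optimal = 0.46, acceptable = 0.20,
                                             critical = 0.34),
                               conventional = c(optimal = 0.46, acceptable = 0.21,
                                                critical = 0.33)),
                             manual_rate = c(automated = 0.43, conventional = 0.7),
                             automated_rate = 11.3,
                             alarm_rate = c(automated = 2.3, conventional = 0.47),
                             alarm_duration_mean = 60,
                             dwell_mean_s = 120,
                             peep_floor = 5, peep_ceiling = 12,
                             seed = 1L) {
  cfg <- list(n_patients = n_patients, phase_minutes = phase_minutes,
              washout_minutes = washout_minutes, rr_mean = rr_mean,
              rr_jitter = rr_jitter, zone_occupancy = zone_occupancy,
              manual_rate = manual_rate, automated_rate = automated_rate,
              alarm_rate = alarm_rate, alarm_duration_mean = alarm_duration_mean,
              dwell_mean_s = dwell_mean_s, peep_floor = peep_floor,
              peep_ceiling = peep_ceiling, seed = as.integer(seed))
  for (arm in c("automated", "conventional")) {
    occ <- cfg$zone_occupancy[[arm]]
    if (length(occ) != 3 || any(occ < 0) || abs(sum(occ) - 1) > 1e-9)
      stop("zone_occupancy$", arm, " must be a length-3 simplex summing to 1")
  }
  if (cfg$phase_minutes <= 0 || cfg$washout_minutes <= 0)
    stop("phase and washout durations must be positive")
  if (any(unlist(cfg[c("manual_rate", "automated_rate", "alarm_rate")]) < 0))
    stop("event rates must be >= 0")
  class(cfg) <- "synthetic_config"
  cfg
}

# Integer-grid preimage of each combined zone under a zone table, by
# brute-force sweep of SpO2 50..100 x PEEP 0..24 x FiO2 21..100. Cached per
# table version. Sampling a breath uniformly from a zone's preimage
# guarantees the pipeline classifies it back into that zone.
.zone_preimage <- function(table) {
  key <- paste0("preimage_", table$version)
  if (!is.null(.vz_cache[[key]])) return(.vz_cache[[key]])
  grid <- expand.grid(spo2 = 50:100, peep = 0:24, fio2 = 21:100)
  sz <- classify_spo2(grid$spo2, table)
  pz <- classify_peep_fio2(grid$peep, grid$fio2, table)
  cz <- as.character(combine_zones(sz, pz, table$combination_rule))
  pre <- lapply(zone_levels()[1:3], function(z)
    as.matrix(grid[cz == z, , drop = FALSE]))
  names(pre) <- zone_levels()[1:3]
  empty <- names(pre)[vapply(pre, nrow, integer(1)) == 0]
  if (length(empty))
    stop("zone table '", table$version, "' has an empty preimage for zone: ",
         paste(empty, collapse = ", "))
  .vz_cache[[key]] <- pre
  pre
}

.patient_seed <- function(seed, patient_index) {
  as.integer((as.numeric(seed) + 100003 * patient_index) %% (2^31 - 1))
}

# Poisson event times on [0, span_s), thinned so consecutive events are at
# least min_gap_s apart (keeps detector output aligned with ground truth).
.poisson_times <- function(rate_per_h, span_s, min_gap_s = 0) {
  n <- stats::rpois(1, rate_per_h * span_s / 3600)
  if (n == 0) return(numeric(0))
  t <- sort(stats::runif(n, 0, span_s))
  if (min_gap_s > 0 && length(t) > 1) {
    keep <- c(TRUE, rep(FALSE, length(t) - 1))
    last <- t[1]
    for (i in seq_along(t)[-1]) {
      if (t[i] - last >= min_gap_s) { keep[i] <- TRUE; last <- t[i] }
    }
    t <- t[keep]
  }
  t
}

# One contiguous segment (a phase or the washout) of a patient log.
.gen_segment <- function(cfg, table, arm, t0, span_s, is_washout, pre) {
  ibi <- 60 / cfg$rr_mean
  n_max <- ceiling(span_s / ibi * (1.3 + 3 * cfg$rr_jitter)) + 10
  if (cfg$rr_jitter > 0) {
    shape <- 1 / cfg$rr_jitter^2
    gaps <- stats::rgamma(n_max, shape = shape, rate = shape / ibi)
  } else {
    gaps <- rep(ibi, n_max)
  }
  t <- t0 + cumsum(gaps) - gaps[1]
  t <- t[t < t0 + span_s]
  n <- length(t)
  if (n == 0) return(NULL)

  occ <- cfg$zone_occupancy[[arm]]
  # dwell blocks: a target zone is held for an exponential dwell time
  if (cfg$dwell_mean_s > 0) {
    n_blocks <- ceiling(span_s / cfg$dwell_mean_s * 3) + 5
    bounds <- t0 + cumsum(stats::rexp(n_blocks, 1 / cfg$dwell_mean_s))
    block <- findInterval(t, bounds) + 1L
  } else {
    block <- seq_len(n)
  }
  n_blocks <- max(block)
  block_zone <- sample(zone_levels()[1:3], n_blocks, replace = TRUE, prob = occ)
  zone <- block_zone[block]
  vals <- matrix(NA_real_, n, 3)
  for (z in zone_levels()[1:3]) {
    idx <- which(zone == z)
    if (!length(idx)) next
    rows <- sample.int(nrow(pre[[z]]), length(idx), replace = TRUE)
    vals[idx, ] <- pre[[z]][rows, ]
  }

  mode <- if (arm == "automated") "automated" else "conventional_pc"
  controller <- rep(if (arm == "automated") "automated" else "manual", n)

  rec <- data.frame(time = t,
                    spo2 = vals[, 1], peep = vals[, 2], fio2 = vals[, 3],
                    mode = mode, controller = controller,
                    alarm = FALSE,
                    set_peep = NA_real_, set_fio2 = NA_real_,
                    stringsAsFactors = FALSE)
  list(records = rec, zone = zone, is_washout = is_washout, arm = arm,
       t0 = t0, span_s = span_s)
}

# Apply setting-change events to a segment's set_peep/set_fio2 trajectories
# and mark the controller status at manual-change breaths. Returns the
# updated values plus realized event counts.
.apply_events <- function(rec, cfg, arm, t0, span_s, base, coalesce_window = 60) {
  n <- nrow(rec)
  set_peep <- rep(base$peep, n); set_fio2 <- rep(base$fio2, n)
  n_manual <- 0L; n_automated <- 0L
  lay_down <- function(ts, origin) {
      i <- which(rec$time >= t0 + ts)[1]
      if (is.na(i) || i < 2) return(invisible())
      if (stats::runif(1) < 0.5) {
        step <- sample(c(-2, 2), 1)
        newv <- min(max(set_peep[i] + step, cfg$peep_floor), cfg$peep_ceiling)
        if (abs(newv - set_peep[i]) < 0.5) newv <- set_peep[i] - step
        newv <- min(max(newv, 0), 24)
        if (abs(newv - set_peep[i]) < 0.5) return(invisible())
        set_peep[i:n] <<- newv
      } else {
        step <- sample(c(-5, 5), 1)
        newv <- min(max(set_fio2[i] + step, 21), 100)
        if (abs(newv - set_fio2[i]) < 1) newv <- set_fio2[i] - step
        if (abs(newv - set_fio2[i]) < 1) return(invisible())
        set_fio2[i:n] <<- newv
      }
      if (origin == "manual") {
        if (rec$controller[i] == "automated") rec$controller[i] <<- "manual"
        n_manual <<- n_manual + 1L
      } else n_automated <<- n_automated + 1L
      invisible()
  }
  gap <- coalesce_window * 1.5
  manual_t <- .poisson_times(cfg$manual_rate[[arm]], span_s, gap)
  auto_t <- if (arm == "automated")
    .poisson_times(cfg$automated_rate, span_s, gap) else numeric(0)
  # interleave in time order while preserving the minimum gap across origins
  all_t <- sort(c(manual_t, auto_t))
  if (length(all_t) > 1) all_t <- all_t[c(TRUE, diff(all_t) >= gap)]
  origin_of <- ifelse(all_t %in% manual_t, "manual", "automated")
  for (k in seq_along(all_t)) lay_down(all_t[k], origin_of[k])
  rec$set_peep <- set_peep; rec$set_fio2 <- set_fio2
  list(records = rec, n_manual = n_manual, n_automated = n_automated)
}

# Alarm episodes for a segment: Poisson starts, exponential durations,
# thinned so episodes stay separated by several breaths.
.apply_alarms <- function(rec, cfg, arm, t0, span_s) {
  ibi <- 60 / cfg$rr_mean
  starts <- .poisson_times(cfg$alarm_rate[[arm]], span_s,
                           min_gap_s = cfg$alarm_duration_mean + 10 * ibi)
  n_alarms <- 0L; minutes <- 0
  for (s in starts) {
    dur <- stats::rexp(1, 1 / cfg$alarm_duration_mean)
    dur <- min(max(dur, 2 * ibi), cfg$alarm_duration_mean + 4 * ibi)
    sel <- rec$time >= t0 + s & rec$time < t0 + s + dur
    if (!any(sel)) next
    rec$alarm[sel] <- TRUE
    n_alarms <- n_alarms + 1L
    minutes <- minutes + dur / 60
  }
  list(records = rec, n_alarms = n_alarms, alarm_minutes = minutes)
}

#' Generate one synthetic crossover patient
#'
#' Builds the full breath log (phase 1, washout, phase 2), the manifest row
#' and the ground-truth record for one patient, reproducibly from the
#' config seed and the patient index.
#'
#' @param config a [synthetic_config()].
#' @param patient_index 1-based index; odd indices start with automated
#'   ventilation, even with conventional (1:1 alternating allocation).
#' @param table the [zone_table] the occupancy targets refer to.
#' @return List with `records` (breath log), `manifest` (one-row
#'   data.frame) and `ground_truth` (data.frame, one row per phase:
#'   realized zone occupancy of the combined classification, event counts,
#'   alarm counts and minutes).
#' @export
generate_patient <- function(config, patient_index, table = default_zone_table()) {
  pre <- .zone_preimage(table)
  set.seed(.patient_seed(config$seed, patient_index))
  pid <- sprintf("P%03d", patient_index)
  first_mode <- if (patient_index %% 2 == 1) "automated" else "conventional"
  arms <- if (first_mode == "automated") c("automated", "conventional")
          else c("conventional", "automated")
  p_s <- config$phase_minutes * 60
  w_s <- config$washout_minutes * 60
  t_starts <- c(0, p_s, p_s + w_s)
  spans <- c(p_s, w_s, p_s)
  seg_arms <- c(arms[1], arms[2], arms[2])  # washout logs under the incoming mode
  is_washout <- c(FALSE, TRUE, FALSE)
  base <- list(peep = 8, fio2 = 40)

  rec_list <- list(); gt <- list()
  for (k in 1:3) {
    seg <- .gen_segment(config, table, seg_arms[k], t_starts[k], spans[k],
                        is_washout[k], pre)
    if (is.null(seg)) next
    rec <- seg$records
    if (!is_washout[k]) {
      ev <- .apply_events(rec, config, seg_arms[k], t_starts[k], spans[k], base)
      rec <- ev$records
      al <- .apply_alarms(rec, config, seg_arms[k], t_starts[k], spans[k])
      rec <- al$records
      occ <- table(factor(seg$zone, levels = zone_levels()[1:3]))
      gt[[length(gt) + 1L]] <- data.frame(
        patient_id = pid, phase = seg_arms[k],
        n_breaths = nrow(rec),
        occ_optimal = 100 * occ[["optimal"]] / nrow(rec),
        occ_acceptable = 100 * occ[["acceptable"]] / nrow(rec),
        occ_critical = 100 * occ[["critical"]] / nrow(rec),
        n_manual = ev$n_manual, n_automated = ev$n_automated,
        n_alarms = al$n_alarms, alarm_minutes = al$alarm_minutes,
        stringsAsFactors = FALSE)
    } else {
      rec$set_peep <- base$peep; rec$set_fio2 <- base$fio2
    }
    rec_list[[k]] <- rec
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  manifest <- data.frame(patient_id = pid, first_mode = first_mode,
                         phase1_start = 0, phase1_end = p_s,
                         phase2_start = p_s + w_s, phase2_end = 2 * p_s + w_s,
                         stringsAsFactors = FALSE)
  list(records = records, manifest = manifest,
       ground_truth = do.call(rbind, gt))
}

#' Generate a synthetic crossover cohort
#'
#' Runs [generate_patient()] for `n_patients` with alternating first mode
#' (1:1 allocation). With `dir = NULL` the cohort is returned in memory;
#' otherwise one CSV per patient plus `manifest.csv` and `ground_truth.csv`
#' are written in the exact dialect [read_breath_log()] consumes.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory (created if needed).
#' @param table the [zone_table] occupancy targets refer to.
#' @return List with `logs` (named list of breath logs), `manifest` and
#'   `ground_truth` data.frames; invisibly when writing to `dir`.
#' @export
generate_cohort <- function(config, dir = NULL, table = default_zone_table()) {
  if (config$n_patients < 1) stop("n_patients must be >= 1")
  pats <- lapply(seq_len(config$n_patients), function(i)
    generate_patient(config, i, table))
  logs <- lapply(pats, `[[`, "records")
  manifest <- do.call(rbind, lapply(pats, `[[`, "manifest"))
  names(logs) <- manifest$patient_id
  ground_truth <- do.call(rbind, lapply(pats, `[[`, "ground_truth"))
  out <- list(logs = logs, manifest = manifest, ground_truth = ground_truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (pid in names(logs))
      write_breath_log(logs[[pid]], file.path(dir, paste0(pid, ".csv")))
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    utils::write.csv(ground_truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
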