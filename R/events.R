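# Event mining from breath logs: manual vs automated ventilator-setting
# changes (PEEP, FiO2) and oxygenation alarm episodes, counted per
# crossover phase.

#' Detect PEEP/FiO2 setting changes
#'
#' A raw change is any breath whose set PEEP or set FiO2 differs from the
#' previous breath by at least the parameter's minimum-change threshold
#' (default 0.5 cm H2O for PEEP, 1 percentage point for FiO2; smaller moves
#' are treated as telemetry jitter). Consecutive raw changes of the same
#' parameter, same direction and same origin separated by less than the
#' coalescence window merge into a single event spanning the first old value
#' to the last new value — a clinician titrating FiO2 over a few breaths is
#' one intervention. The origin is `manual` when the controller status at
#' the change breath is `manual` or `frozen` (a frozen controller implies
#' clinician override), else `automated`.
#'
#' @param records breath-log data.frame, time-ordered.
#' @param patient_id id attached to the events.
#' @param peep_threshold minimum PEEP change, cm H2O.
#' @param fio2_threshold minimum FiO2 change, percentage points.
#' @param coalesce_window seconds; same-direction raw changes closer than
#'   this merge.
#' @return data.frame with columns `patient_id`, `timestamp`, `parameter`
#'   (`"PEEP"`/`"FiO2"`), `old_value`, `new_value`, `origin`
#'   (`"manual"`/`"automated"`), ordered by timestamp.
#' @export
detect_setting_changes <- function(records, patient_id = "patient",
                                   peep_threshold = 0.5, fio2_threshold = 1,
                                   coalesce_window = 60) {
  empty <- data.frame(patient_id = character(), timestamp = numeric(),
                      parameter = character(), old_value = numeric(),
                      new_value = numeric(), origin = character(),
                      stringsAsFactors = FALSE)
  if (nrow(records) < 2) return(empty)
  one_param <- function(values, parameter, threshold) {
    dv <- diff(values)
    idx <- which(!is.na(dv) & abs(dv) >= threshold) + 1L
    if (!length(idx)) return(empty)
    origin <- ifelse(records$controller[idx] %in% c("manual", "frozen"),
                     "manual", "automated")
    dirn <- sign(values[idx] - values[idx - 1L])
    ev <- list()
    for (k in seq_along(idx)) {
      i <- idx[k]
      last <- if (length(ev)) ev[[length(ev)]] else NULL
      if (!is.null(last) &&
          records$time[i] - last$last_time < coalesce_window &&
          dirn[k] == last$direction && origin[k] == last$origin) {
        last$new_value <- values[i]
        last$last_time <- records$time[i]
        ev[[length(ev)]] <- last
      } else {
        ev[[length(ev) + 1L]] <- list(
          timestamp = records$time[i], old_value = values[i - 1L],
          new_value = values[i], origin = origin[k],
          direction = dirn[k], last_time = records$time[i])
      }
    }
    data.frame(patient_id = patient_id,
               timestamp = vapply(ev, `[[`, numeric(1), "timestamp"),
               parameter = parameter,
               old_value = vapply(ev, `[[`, numeric(1), "old_value"),
               new_value = vapply(ev, `[[`, numeric(1), "new_value"),
               origin = vapply(ev, `[[`, character(1), "origin"),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_param(records$set_peep, "PEEP", peep_threshold),
               one_param(records$set_fio2, "FiO2", fio2_threshold))
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect oxygenation alarm episodes
#'
#' An episode is a maximal run of breaths with the alarm flag active; runs
#' separated by a gap of at most `max_gap_breaths` non-alarmed breaths merge
#' (a one-breath flicker does not end an episode). The episode lasts from
#' the first alarmed breath's timestamp to the last alarmed breath's
#' timestamp plus that breath's duration (see [breath_durations()]).
#'
#' @param records breath-log data.frame, time-ordered.
#' @param patient_id id attached to the episodes.
#' @param max_gap_breaths gap tolerance, breaths.
#' @param duration_cap seconds, for the closing breath's duration.
#' @return data.frame with `patient_id`, `start_timestamp`, `end_timestamp`,
#'   `duration_minutes`; episodes are non-overlapping and time-ordered.
#' @export
detect_alarm_episodes <- function(records, patient_id = "patient",
                                  max_gap_breaths = 1L, duration_cap = 15) {
  empty <- data.frame(patient_id = character(), start_timestamp = numeric(),
                      end_timestamp = numeric(), duration_minutes = numeric(),
                      stringsAsFactors = FALSE)
  al <- which(records$alarm %in% TRUE)
  if (!length(al)) return(empty)
  new_run <- c(TRUE, diff(al) > max_gap_breaths + 1L)
  run_id <- cumsum(new_run)
  dur <- breath_durations(records$time, duration_cap)
  starts <- tapply(al, run_id, min)
  ends <- tapply(al, run_id, max)
  end_time <- records$time[ends] + ifelse(is.na(dur[ends]), 0, dur[ends])
  data.frame(patient_id = patient_id,
             start_timestamp = unname(records$time[starts]),
             end_timestamp = unname(end_time),
             duration_minutes = unname((end_time - records$time[starts]) / 60),
             stringsAsFactors = FALSE)
}

#' Count events and alarm minutes per crossover phase
#'
#' Setting-change events are assigned to phase 1, washout or phase 2 by
#' timestamp (half-open intervals); washout events are tallied but excluded
#' from between-arm comparisons downstream. An alarm episode straddling a
#' phase boundary is split at the boundary: each phase it touches counts one
#' (sub-)episode and receives the apportioned minutes.
#'
#' @param events output of [detect_setting_changes()] for one patient.
#' @param episodes output of [detect_alarm_episodes()] for that patient.
#' @param manifest_row the patient's manifest row.
#' @return data.frame with one row per phase (`automated`, `conventional`,
#'   `washout`): `patient_id`, `phase`, `n_manual`, `n_automated`,
#'   `n_alarms`, `alarm_minutes`.
#' @export
count_events_per_phase <- function(events, episodes, manifest_row) {
  m <- as.list(manifest_row)
  arms <- if (m$first_mode == "automated") c("automated", "conventional")
          else c("conventional", "automated")
  ivs <- list(c(m$phase1_start, m$phase1_end),
              c(m$phase1_end, m$phase2_start),
              c(m$phase2_start, m$phase2_end))
  labels <- c(arms[1], "washout", arms[2])
  out <- data.frame(patient_id = as.character(m$patient_id), phase = labels,
                    n_manual = 0L, n_automated = 0L, n_alarms = 0L,
                    alarm_minutes = 0, stringsAsFactors = FALSE)
  for (i in seq_along(ivs)) {
    iv <- ivs[[i]]
    if (nrow(events)) {
      sel <- events$timestamp >= iv[1] & events$timestamp < iv[2]
      out$n_manual[i] <- sum(sel & events$origin == "manual")
      out$n_automated[i] <- sum(sel & events$origin == "automated")
    }
    if (nrow(episodes)) {
      ov <- pmin(episodes$end_timestamp, iv[2]) -
        pmax(episodes$start_timestamp, iv[1])
      out$n_alarms[i] <- sum(ov > 0)
      out$alarm_minutes[i] <- sum(pmax(ov, 0)) / 60
    }
  }
  out
}

#' Detect and count a patient's events in one call
#'
#' Convenience wrapper chaining [detect_setting_changes()],
#' [detect_alarm_episodes()] and [count_events_per_phase()].
#'
#' @param records breath-log data.frame for one patient.
#' @param manifest_row the patient's manifest row.
#' @param ... thresholds passed to the detectors.
#' @return List with `events`, `episodes`, `counts`.
#' @export
events_per_phase <- function(records, manifest_row, ...) {
  args <- list(...)
  pid <- as.character(manifest_row$patient_id)
  det_args <- args[names(args) %in% c("peep_threshold", "fio2_threshold",
                                      "coalesce_window")]
  al_args <- args[names(args) %in% c("max_gap_breaths", "duration_cap")]
  events <- do.call(detect_setting_changes,
                    c(list(records = records, patient_id = pid), det_args))
  episodes <- do.call(detect_alarm_episodes,
                      c(list(records = records, patient_id = pid), al_args))
  list(events = events, episodes = episodes,
       counts = count_events_per_phase(events, episodes, manifest_row))
}
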