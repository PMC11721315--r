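# Phase segmentation and the per-patient endpoint aggregates: percentage of
# breaths and percentage of time in each oxygenation zone, per crossover
# phase and classification view.

#' Segment a breath log into crossover phases
#'
#' Assigns every record to phase 1, washout or phase 2 by timestamp using
#' half-open intervals `[start, end)`; records outside all three intervals
#' are dropped and counted (attribute `n_outside`). Phase labels are the
#' ventilation arms derived from the manifest's `first_mode`.
#'
#' @param records breath-log data.frame for one patient.
#' @param manifest_row one-row manifest data.frame (or list) for that patient.
#' @return Named list of data.frames (`phase1`, `washout`, `phase2`), each
#'   with attributes `phase_label` (`automated`, `conventional` or
#'   `washout`) and `interval`; the list carries `n_outside`.
#' @export
segment_phases <- function(records, manifest_row) {
  m <- as.list(manifest_row)
  if (m$phase1_end > m$phase2_start) stop("phase intervals overlap")
  if (m$phase1_end <= m$phase1_start || m$phase2_end <= m$phase2_start)
    stop("non-positive phase duration")
  arms <- if (m$first_mode == "automated") c("automated", "conventional")
          else c("conventional", "automated")
  ivs <- list(phase1 = c(m$phase1_start, m$phase1_end),
              washout = c(m$phase1_end, m$phase2_start),
              phase2 = c(m$phase2_start, m$phase2_end))
  labels <- c(arms[1], "washout", arms[2])
  out <- vector("list", 3)
  names(out) <- names(ivs)
  assigned <- rep(FALSE, nrow(records))
  for (i in seq_along(ivs)) {
    iv <- ivs[[i]]
    sel <- records$time >= iv[1] & records$time < iv[2]
    seg <- records[sel, , drop = FALSE]
    rownames(seg) <- NULL
    attr(seg, "phase_label") <- labels[i]
    attr(seg, "interval") <- iv
    out[[i]] <- seg
    assigned <- assigned | sel
  }
  attr(out, "n_outside") <- sum(!assigned)
  out
}

#' Percentage of breaths in a zone
#'
#' The zone endpoint: 100 times the number of classified breaths carrying the
#' given label over the number of classified breaths. Unclassified breaths
#' are excluded from the denominator; with no classified breaths the value is
#' undefined and `NA` is returned (never zero).
#'
#' @param labels factor/character of zone labels.
#' @param zone one of `"optimal"`, `"acceptable"`, `"critical"`.
#' @return Percentage in \[0, 100\], or `NA_real_`.
#' @examples
#' percent_breaths_in_zone(rep(c("optimal", "critical"), c(50, 150)), "optimal")
#' @export
percent_breaths_in_zone <- function(labels, zone) {
  zone <- match.arg(zone, zone_levels()[1:3])
  l <- as.character(labels)
  n_cls <- sum(l != "unclassified", na.rm = TRUE)
  if (n_cls == 0) return(NA_real_)
  100 * sum(l == zone, na.rm = TRUE) / n_cls
}

#' Per-breath durations from timestamps
#'
#' A breath lasts until the next breath starts, capped at `cap` seconds to
#' bound the influence of signal dropouts; the final breath, which has no
#' successor, inherits the median of the other (capped) durations.
#'
#' @param time numeric vector of strictly increasing timestamps (seconds).
#' @param cap maximum credited duration, seconds.
#' @return Numeric vector of durations parallel to `time`; for a single
#'   breath the duration is `NA`.
#' @export
breath_durations <- function(time, cap = 15) {
  n <- length(time)
  if (n == 0) return(numeric(0))
  if (n == 1) return(NA_real_)
  d <- pmin(diff(time), cap)
  c(d, stats::median(d))
}

#' Percentage of time spent in a zone
#'
#' Duration-weighted counterpart of [percent_breaths_in_zone()]: each
#' breath's duration comes from [breath_durations()], and the percentage is
#' the summed duration of classified breaths in the zone over the summed
#' duration of all classified breaths. Equals the breath fraction exactly
#' when all durations are equal.
#'
#' @param records breath-log data.frame (only `time` is used).
#' @param labels parallel zone labels.
#' @param zone target zone label.
#' @param cap duration cap in seconds.
#' @return Percentage in \[0, 100\], or `NA_real_` (with a warning for a
#'   single-breath segment).
#' @export
percent_time_in_zone <- function(records, labels, zone, cap = 15) {
  zone <- match.arg(zone, zone_levels()[1:3])
  if (nrow(records) == 1) {
    warning("single-breath segment: time-in-zone undefined")
    return(NA_real_)
  }
  if (nrow(records) == 0) return(NA_real_)
  d <- breath_durations(records$time, cap)
  l <- as.character(labels)
  cls <- l != "unclassified" & !is.na(l)
  tot <- sum(d[cls])
  if (tot <= 0) return(NA_real_)
  100 * sum(d[cls & l == zone]) / tot
}

#' Summarize one patient's zone endpoints per crossover phase
#'
#' Classifies the patient's breaths, segments them into phases, and computes
#' the percentage of breaths and of time in each zone for the three
#' classification views mirroring the endpoint table: the combined
#' oxygenation zones, the SpO2-only zones and the PEEP/FiO2-only zones.
#' Washout breaths are excluded. Unclassified breaths are excluded from the
#' percentage denominators; their fraction is reported separately.
#'
#' @param records breath-log data.frame for one patient.
#' @param manifest_row the patient's manifest row.
#' @param table a [zone_table].
#' @param duration_cap cap for [breath_durations()], seconds.
#' @return Long data.frame with one row per phase x view x zone:
#'   `patient_id`, `phase` (arm label), `view` (`combined`/`spo2`/`pf`),
#'   `zone`, `pct_breaths`, `pct_time`, `n_breaths` (classified breaths in
#'   that phase and view), `unclassified_fraction`.
#' @export
summarize_patient <- function(records, manifest_row, table = default_zone_table(),
                              duration_cap = 15) {
  views <- classify_breaths(records, table, view = "all")
  segs <- segment_phases(records, manifest_row)
  out <- list()
  for (seg_name in c("phase1", "phase2")) {
    seg <- segs[[seg_name]]
    phase <- attr(seg, "phase_label")
    idx <- which(records$time >= attr(seg, "interval")[1] &
                   records$time < attr(seg, "interval")[2])
    for (v in c("combined", "spo2", "pf")) {
      lab <- switch(v, combined = views$zone, spo2 = views$spo2_zone,
                    pf = views$pf_zone)[idx]
      l <- as.character(lab)
      n_cls <- sum(l != "unclassified")
      uf <- if (length(l)) mean(l == "unclassified") else NA_real_
      for (z in zone_levels()[1:3]) {
        pt <- if (nrow(seg) >= 2) {
          suppressWarnings(percent_time_in_zone(seg, lab, z, duration_cap))
        } else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          patient_id = as.character(manifest_row$patient_id),
          phase = phase, view = v, zone = z,
          pct_breaths = percent_breaths_in_zone(lab, z),
          pct_time = pt,
          n_breaths = n_cls,
          unclassified_fraction = uf,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Summarize every patient of a cohort
#'
#' Applies [summarize_patient()] across a cohort and stacks the results into
#' the tidy endpoint table consumed by [compare_all_endpoints()] and the
#' plotting helpers.
#'
#' @param logs named list of breath-log data.frames keyed by patient id, or a
#'   directory containing `<patient_id>.csv` files.
#' @param manifest manifest data.frame covering those patients.
#' @param table a [zone_table].
#' @param duration_cap seconds.
#' @return Row-bound [summarize_patient()] output for all patients.
#' @export
summarize_cohort <- function(logs, manifest, table = default_zone_table(),
                             duration_cap = 15) {
  validate_manifest(manifest)
  if (is.character(logs) && length(logs) == 1 && dir.exists(logs)) {
    dirpath <- logs
    logs <- lapply(manifest$patient_id, function(pid)
      read_breath_log(file.path(dirpath, paste0(pid, ".csv"))))
    names(logs) <- manifest$patient_id
  }
  res <- lapply(manifest$patient_id, function(pid) {
    summarize_patient(logs[[pid]], manifest[manifest$patient_id == pid, ],
                      table, duration_cap)
  })
  do.call(rbind, res)
}
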