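# CSV ingestion of breath-by-breath ventilator logs and the patient
# manifest. Device exports vary in column naming, so the reader takes a
# schema mapping; timestamps may be numeric seconds or ISO-8601 datetimes
# and are normalized to seconds.

#' Default column schema for breath logs
#'
#' Maps the package's internal field names to the CSV column names it expects.
#' Replace values (not names) to read a vendor export without preprocessing,
#' e.g. `sch <- default_schema(); sch["spo2"] <- "SpO2_pct"`.
#'
#' @return Named character vector `internal_field = csv_column`.
#' @export
default_schema <- function() {
  c(time = "time", spo2 = "spo2", peep = "peep", fio2 = "fio2",
    mode = "mode", controller = "controller", alarm = "alarm",
    set_peep = "set_peep", set_fio2 = "set_fio2")
}

.modes <- c("automated", "conventional_pc", "conventional_ps")
.controller_states <- c("automated", "manual", "frozen")
.missing_tokens <- c("", "na", "nan")

# Parse a character column to numeric. Recognized missing tokens map to NA;
# any other non-numeric token marks the row for dropping.
.parse_num <- function(x) {
  x <- trimws(x)
  miss <- is.na(x) | tolower(x) %in% .missing_tokens
  val <- suppressWarnings(as.numeric(x))
  list(value = ifelse(miss, NA_real_, val),
       missing = miss,
       bad = !miss & is.na(val))
}

.parse_time <- function(x) {
  p <- .parse_num(x)
  if (any(p$bad)) {
    # fall back to ISO-8601 datetimes, normalized to epoch seconds
    dt <- suppressWarnings(as.POSIXct(trimws(x), tz = "UTC",
                                      tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                     "%Y-%m-%d %H:%M:%OS")))
    conv <- p$bad & !is.na(dt)
    p$value[conv] <- as.numeric(dt[conv])
    p$bad[conv] <- FALSE
  }
  p
}

.parse_bool <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "", "na")] <- FALSE
  list(value = out, bad = is.na(out))
}

# Set out-of-physical-range values to NA and count them (sensor artifacts are
# recorded in the parse report rather than aborting the read).
.range_censor <- function(v, lo, hi) {
  out <- !is.na(v) & (v < lo | v > hi)
  v[out] <- NA_real_
  list(value = v, n = sum(out))
}

#' Read a breath-by-breath ventilator log
#'
#' Reads a CSV export (comma delimiter, header row, "." decimal separator)
#' into a validated breath-log data.frame with one row per breath and the
#' internal columns `time` (seconds), `spo2`, `peep`, `fio2`, `mode`,
#' `controller`, `alarm`, `set_peep`, `set_fio2`. Empty cells, `NA` and
#' `NaN` (case-insensitive) become missing values; rows holding any other
#' non-numeric token in a numeric column are dropped with a warning.
#' Out-of-range measurements (SpO2 outside \[50, 100\], FiO2 outside
#' \[21, 100\], PEEP outside \[0, 30\]) become missing and are counted.
#' A parse report (rows read/kept/dropped, per-column missing and
#' out-of-range counts) travels with the result; retrieve it with
#' [parse_report()].
#'
#' @param path CSV file path.
#' @param schema named character vector mapping internal field names to the
#'   file's column names; see [default_schema()].
#' @return data.frame of breaths in timestamp order, with attribute
#'   `parse_report`.
#' @export
read_breath_log <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("breath log not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols))
    stop("required column(s) missing from ", basename(path), ": ",
         paste(missing_cols, collapse = ", "))
  rows_read <- nrow(raw)

  num_fields <- c("time", "spo2", "peep", "fio2", "set_peep", "set_fio2")
  parsed <- lapply(num_fields, function(f) {
    if (f == "time") .parse_time(raw[[schema[[f]]]]) else .parse_num(raw[[schema[[f]]]])
  })
  names(parsed) <- num_fields
  alarm <- .parse_bool(raw[[schema[["alarm"]]]])

  bad_row <- Reduce(`|`, lapply(parsed, `[[`, "bad")) | alarm$bad
  bad_row <- bad_row | is.na(parsed$time$missing) | parsed$time$missing
  if (any(bad_row))
    warning(sum(bad_row), " row(s) dropped (unparseable field)")

  rec <- data.frame(
    time = parsed$time$value,
    spo2 = parsed$spo2$value,
    peep = parsed$peep$value,
    fio2 = parsed$fio2$value,
    mode = trimws(raw[[schema[["mode"]]]]),
    controller = trimws(raw[[schema[["controller"]]]]),
    alarm = alarm$value,
    set_peep = parsed$set_peep$value,
    set_fio2 = parsed$set_fio2$value,
    stringsAsFactors = FALSE)
  rec <- rec[!bad_row, , drop = FALSE]
  rownames(rec) <- NULL

  oor <- c(spo2 = 0L, peep = 0L, fio2 = 0L)
  cs <- .range_censor(rec$spo2, 50, 100); rec$spo2 <- cs$value; oor["spo2"] <- cs$n
  cp <- .range_censor(rec$peep, 0, 30);   rec$peep <- cp$value; oor["peep"] <- cp$n
  cf <- .range_censor(rec$fio2, 21, 100); rec$fio2 <- cf$value; oor["fio2"] <- cf$n

  validate_breath_log(rec)

  missing_counts <- vapply(rec[c("time", "spo2", "peep", "fio2",
                                 "set_peep", "set_fio2")],
                           function(v) sum(is.na(v)), integer(1))
  attr(rec, "parse_report") <- list(
    rows_read = rows_read,
    rows_kept = nrow(rec),
    rows_dropped = rows_read - nrow(rec),
    missing_counts = missing_counts,
    out_of_range = oor)
  rec
}

#' Retrieve the parse report attached to a breath log
#'
#' @param records a breath log returned by [read_breath_log()].
#' @return List with `rows_read`, `rows_kept`, `rows_dropped`,
#'   `missing_counts`, `out_of_range`, or `NULL` if absent.
#' @export
parse_report <- function(records) attr(records, "parse_report")

#' Validate a breath-log data.frame
#'
#' Asserts the record invariants: strictly increasing timestamps, known mode
#' and controller-status values, and the conventional-mode rule that the
#' controller status is `manual` whenever the mode is conventional.
#'
#' @param records breath-log data.frame.
#' @return `records`, invisibly; errors cite the first offending row.
#' @export
validate_breath_log <- function(records) {
  if (nrow(records) == 0) return(invisible(records))
  dt <- diff(records$time)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1] + 1L
    stop("timestamps not strictly increasing at row ", i,
         " (", records$time[i - 1], " -> ", records$time[i], ")")
  }
  badm <- !records$mode %in% .modes
  if (any(badm))
    stop("unknown ventilation mode at row ", which(badm)[1], ": ",
         records$mode[which(badm)[1]])
  badc <- !records$controller %in% .controller_states
  if (any(badc))
    stop("unknown controller status at row ", which(badc)[1], ": ",
         records$controller[which(badc)[1]])
  conv <- grepl("^conventional", records$mode)
  bad <- conv & records$controller != "manual"
  if (any(bad))
    stop("controller status must be 'manual' under a conventional mode (row ",
         which(bad)[1], ")")
  invisible(records)
}

#' Write a breath log to CSV
#'
#' Writes the internal columns under the default schema names; missing values
#' become empty cells. Reading the file back with [read_breath_log()]
#' reproduces the records field-for-field.
#'
#' @param records breath-log data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_breath_log <- function(records, path) {
  validate_breath_log(records)
  cols <- names(default_schema())
  utils::write.csv(records[, cols, drop = FALSE], path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

#' Read a patient manifest
#'
#' One row per patient: `patient_id`, `first_mode` (`automated` or
#' `conventional`), and the four phase boundary timestamps `phase1_start`,
#' `phase1_end`, `phase2_start`, `phase2_end` in seconds (the washout is the
#' implied interval between the phases). Validates positive phase durations
#' and non-overlapping phases.
#'
#' @param path CSV file path.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
}

#' Validate a patient manifest
#' @param manifest manifest data.frame.
#' @return The manifest, invisibly on success.
#' @export
validate_manifest <- function(manifest) {
  req <- c("patient_id", "first_mode", "phase1_start", "phase1_end",
           "phase2_start", "phase2_end")
  miss <- setdiff(req, names(manifest))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (!all(manifest$first_mode %in% c("automated", "conventional")))
    stop("first_mode must be 'automated' or 'conventional'")
  bad <- manifest$phase1_end <= manifest$phase1_start |
    manifest$phase2_end <= manifest$phase2_start
  if (any(bad)) stop("non-positive phase duration for patient ",
                     manifest$patient_id[which(bad)[1]])
  if (any(manifest$phase1_end > manifest$phase2_start))
    stop("phase intervals overlap for patient ",
         manifest$patient_id[which(manifest$phase1_end > manifest$phase2_start)[1]])
  if (anyDuplicated(manifest$patient_id))
    stop("duplicated patient_id in manifest")
  invisible(manifest)
}

#' Write a patient manifest to CSV
#' @param manifest manifest data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
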