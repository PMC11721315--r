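# Orchestration and paper-shaped outputs: the classed crossover analysis
# object, ECDF and bar-plot data, and the CSV report bundle with provenance
# headers.

#' Empirical cumulative distribution points
#'
#' One step per distinct value: the returned `fraction` at a value is the
#' proportion of observations less than or equal to it, rising to exactly 1
#' at the maximum.
#'
#' @param values non-empty numeric vector (missing values removed).
#' @return data.frame with columns `value` (sorted distinct values) and
#'   `fraction` (non-decreasing, ending at 1).
#' @examples
#' ecdf_points(c(5, 5, 10))
#' @export
ecdf_points <- function(values) {
  v <- sort(values[!is.na(values)])
  if (!length(v)) stop("ecdf_points: empty input")
  u <- unique(v)
  data.frame(value = u,
             fraction = cumsum(tabulate(match(v, u))) / length(v))
}

#' Mean zone percentages per arm and classification view
#'
#' Bar-plot data: the arithmetic mean over patients of the per-patient
#' percentage of breaths in each zone, per ventilation arm and view. Within
#' each arm and view the three means sum to 100 over classified breaths (up
#' to patients with undefined percentages, which are dropped pairwise).
#'
#' @param summaries [summarize_cohort()] output.
#' @param metric `"pct_breaths"` (default) or `"pct_time"`.
#' @return data.frame with `phase`, `view`, `zone`, `mean_pct`, `n_patients`.
#' @export
zone_bar_data <- function(summaries, metric = c("pct_breaths", "pct_time")) {
  metric <- match.arg(metric)
  sub <- summaries[summaries$phase != "washout", ]
  agg <- stats::aggregate(sub[[metric]],
                          by = list(phase = sub$phase, view = sub$view,
                                    zone = sub$zone),
                          FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                              n = sum(!is.na(v))))
  data.frame(phase = agg$phase, view = agg$view, zone = agg$zone,
             mean_pct = agg$x[, "mean"], n_patients = agg$x[, "n"],
             stringsAsFactors = FALSE)
}

#' Full crossover oxygenation analysis of a cohort
#'
#' The central fitting-style entry point: classifies every breath of every
#' patient, aggregates the zone endpoints per crossover phase, mines setting
#' changes and alarm episodes, and runs the paired between-arm comparisons.
#'
#' @param logs named list of breath logs keyed by patient id, or a directory
#'   of `<patient_id>.csv` files.
#' @param manifest patient manifest data.frame (see [read_manifest()]).
#' @param table a [zone_table].
#' @param duration_cap breath-duration cap, seconds.
#' @param peep_threshold,fio2_threshold,coalesce_window event-detection
#'   thresholds, see [detect_setting_changes()].
#' @param alpha significance flag threshold for the comparison tables.
#' @param on_error `"stop"` aborts on the first corrupt patient log;
#'   `"skip"` analyses the remaining patients and collects per-patient
#'   errors in the result's `error_manifest`.
#' @return Object of class `ventzone`: `summaries`, `events`, `episodes`,
#'   `event_counts`, `comparison` (`$zones`, `$events`), `ecdf` (per
#'   variable and arm), `bars`, `zone_table_version`, `error_manifest`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 2,
#'                                            phase_minutes = 10,
#'                                            washout_minutes = 5, seed = 7))
#' fit <- crossover_analysis(cohort$logs, cohort$manifest)
#' print(fit)
#' @export
crossover_analysis <- function(logs, manifest, table = default_zone_table(),
                               duration_cap = 15, peep_threshold = 0.5,
                               fio2_threshold = 1, coalesce_window = 60,
                               alpha = 0.05, on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  validate_manifest(manifest)
  if (is.character(logs) && length(logs) == 1 && dir.exists(logs)) {
    dirpath <- logs
    logs <- list()
    for (pid in manifest$patient_id) {
      logs[[pid]] <- tryCatch(
        read_breath_log(file.path(dirpath, paste0(pid, ".csv"))),
        error = function(e) e)
    }
  }
  errs <- list()
  summaries <- list(); events <- list(); episodes <- list(); counts <- list()
  for (pid in manifest$patient_id) {
    mrow <- manifest[manifest$patient_id == pid, ]
    res <- tryCatch({
      rec <- logs[[pid]]
      if (inherits(rec, "error")) stop(conditionMessage(rec))
      if (is.null(rec)) stop("no log for patient ", pid)
      s <- summarize_patient(rec, mrow, table, duration_cap)
      e <- events_per_phase(rec, mrow, peep_threshold = peep_threshold,
                            fio2_threshold = fio2_threshold,
                            coalesce_window = coalesce_window,
                            duration_cap = duration_cap)
      list(s = s, e = e)
    }, error = function(err) err)
    if (inherits(res, "error")) {
      if (on_error == "stop")
        stop("patient ", pid, ": ", conditionMessage(res))
      errs[[pid]] <- conditionMessage(res)
      next
    }
    summaries[[pid]] <- res$s
    events[[pid]] <- res$e$events
    episodes[[pid]] <- res$e$episodes
    counts[[pid]] <- res$e$counts
  }
  if (!length(summaries)) stop("no analysable patients")
  summaries <- do.call(rbind, summaries)
  event_counts <- do.call(rbind, counts)
  rownames(summaries) <- rownames(event_counts) <- NULL

  comparison <- if (length(unique(summaries$patient_id)) >= 2)
    compare_all_endpoints(summaries, event_counts, alpha) else NULL

  ok_ids <- setdiff(manifest$patient_id, names(errs))
  ecdf_list <- list()
  for (var in c("spo2", "peep", "fio2")) {
    for (arm in c("automated", "conventional")) {
      vals <- unlist(lapply(ok_ids, function(pid) {
        segs <- segment_phases(logs[[pid]],
                               manifest[manifest$patient_id == pid, ])
        seg <- if (attr(segs$phase1, "phase_label") == arm) segs$phase1
               else segs$phase2
        seg[[var]]
      }))
      vals <- vals[!is.na(vals)]
      if (length(vals))
        ecdf_list[[paste(var, arm, sep = "_")]] <-
          cbind(variable = var, phase = arm, ecdf_points(vals))
    }
  }

  out <- list(summaries = summaries,
              events = do.call(rbind, events),
              episodes = do.call(rbind, episodes),
              event_counts = event_counts,
              comparison = comparison,
              ecdf = do.call(rbind, ecdf_list),
              bars = zone_bar_data(summaries),
              zone_table_version = table$version,
              n_patients = length(ok_ids),
              error_manifest = if (length(errs))
                data.frame(patient_id = names(errs),
                           error = unlist(errs), row.names = NULL)
              else NULL,
              settings = list(duration_cap = duration_cap,
                              peep_threshold = peep_threshold,
                              fio2_threshold = fio2_threshold,
                              coalesce_window = coalesce_window,
                              alpha = alpha))
  class(out) <- "ventzone"
  out
}

#' @export
print.ventzone <- function(x, ...) {
  cat("Crossover oxygenation-zone analysis\n")
  cat(sprintf("  %d patient(s), zone table [%s]\n", x$n_patients,
              x$zone_table_version))
  if (!is.null(x$error_manifest))
    cat("  ", nrow(x$error_manifest), "patient(s) skipped with errors\n")
  if (!is.null(x$comparison)) {
    opt <- x$comparison$zones
    opt <- opt[opt$view == "combined" & opt$metric == "pct_breaths" &
                 opt$zone == "optimal", ]
    cat(sprintf(paste0("  breaths in optimal zone: automated %.1f",
                       " [%.1f-%.1f]%% vs conventional %.1f [%.1f-%.1f]%%",
                       " (p = %.3f)\n"),
                opt$automated_median, opt$automated_q1, opt$automated_q3,
                opt$conventional_median, opt$conventional_q1,
                opt$conventional_q3, opt$p_value))
  }
  invisible(x)
}

#' @export
summary.ventzone <- function(object, ...) {
  cat("Crossover oxygenation-zone analysis —", object$n_patients,
      "patient(s)\n\n")
  if (is.null(object$comparison)) {
    cat("(fewer than 2 patients: no paired comparison)\n")
    return(invisible(object))
  }
  z <- object$comparison$zones
  fmt <- function(r) sprintf(
    "  %-10s %-11s %-10s  %6.1f [%5.1f-%5.1f]  %6.1f [%5.1f-%5.1f]  %6.3f%s",
    r$view, r$metric, r$zone,
    r$automated_median, r$automated_q1, r$automated_q3,
    r$conventional_median, r$conventional_q1, r$conventional_q3,
    r$p_value, if (isTRUE(r$significant)) " *" else "")
  cat("Zone endpoints (median [IQR] per arm; paired signed-rank p):\n")
  cat("  view       metric      zone       automated             conventional          p\n")
  for (i in seq_len(nrow(z))) cat(fmt(z[i, ]), "\n")
  if (!is.null(object$comparison$events)) {
    e <- object$comparison$events
    cat("\nSetting changes and alarms (per patient per phase):\n")
    for (i in seq_len(nrow(e)))
      cat(sprintf("  %-13s %6.1f [%5.1f-%5.1f]  %6.1f [%5.1f-%5.1f]  %6.3f%s\n",
                  e$endpoint[i], e$automated_median[i], e$automated_q1[i],
                  e$automated_q3[i], e$conventional_median[i],
                  e$conventional_q1[i], e$conventional_q3[i], e$p_value[i],
                  if (isTRUE(e$significant[i])) " *" else ""))
  }
  invisible(object)
}

#' @export
plot.ventzone <- function(x, which = c("bars", "ecdf"), ...) {
  which <- match.arg(which)
  if (which == "bars") {
    b <- x$bars
    views <- c("combined", "spo2", "pf")
    old <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(old))
    for (v in views) {
      sub <- b[b$view == v, ]
      m <- matrix(NA_real_, 3, 2,
                  dimnames = list(zone_levels()[1:3],
                                  c("automated", "conventional")))
      for (i in seq_len(nrow(sub))) m[sub$zone[i], sub$phase[i]] <- sub$mean_pct[i]
      graphics::barplot(m, beside = TRUE, main = v, ylim = c(0, 100),
                        ylab = "mean % of breaths",
                        legend.text = (v == "combined"), ...)
    }
  } else {
    e <- x$ecdf
    old <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(old))
    for (var in c("spo2", "peep", "fio2")) {
      sub <- e[e$variable == var, ]
      graphics::plot(NA, xlim = range(sub$value), ylim = c(0, 1),
                     xlab = var, ylab = "cumulative fraction", main = var)
      for (arm in c("automated", "conventional")) {
        s <- sub[sub$phase == arm, ]
        graphics::lines(s$value, s$fraction, type = "s",
                        col = if (arm == "automated") "steelblue" else "purple")
      }
    }
  }
  invisible(x)
}

# Polynomial rolling hash of a character string, rendered in hex: a compact
# fingerprint of the analysis configuration for output provenance headers.
.config_hash <- function(obj) {
  s <- paste(deparse(obj), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run a full analysis and write the report bundle
#'
#' Reads a cohort (directory of per-patient CSV logs plus a manifest), runs
#' [crossover_analysis()], and writes the output bundle: the zone and event
#' comparison tables, the per-patient endpoint table, ECDF and bar-plot data
#' files, and a run log. Every CSV carries provenance header comments
#' (package version, zone-table version, configuration fingerprint), so two
#' runs on identical inputs produce byte-identical files.
#'
#' @param input_dir directory containing `<patient_id>.csv` logs.
#' @param manifest_path path to the manifest CSV (defaults to
#'   `manifest.csv` inside `input_dir`).
#' @param out_dir output directory (created if needed).
#' @param zone_table_path optional YAML zone table; default table otherwise.
#' @param ... options forwarded to [crossover_analysis()] (thresholds,
#'   `on_error`, ...).
#' @return The `ventzone` object, invisibly.
#' @export
run_analysis <- function(input_dir, manifest_path = file.path(input_dir, "manifest.csv"),
                         out_dir, zone_table_path = NULL, ...) {
  table <- if (is.null(zone_table_path)) default_zone_table()
           else read_zone_table(zone_table_path)
  manifest <- read_manifest(manifest_path)
  fit <- crossover_analysis(input_dir, manifest, table = table, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(paste0("ventzone ", as.character(utils::packageVersion("ventzone"))),
           paste0("zone_table ", table$version),
           paste0("config ", .config_hash(fit$settings)))
  .write_with_header(fit$summaries, file.path(out_dir, "patient_summaries.csv"), hdr)
  if (!is.null(fit$comparison)) {
    .write_with_header(fit$comparison$zones,
                       file.path(out_dir, "zone_comparison.csv"), hdr)
    .write_with_header(fit$comparison$events,
                       file.path(out_dir, "event_comparison.csv"), hdr)
  }
  .write_with_header(fit$event_counts, file.path(out_dir, "event_counts.csv"), hdr)
  .write_with_header(fit$ecdf, file.path(out_dir, "ecdf_data.csv"), hdr)
  .write_with_header(fit$bars, file.path(out_dir, "zone_bar_data.csv"), hdr)
  if (!is.null(fit$error_manifest))
    .write_with_header(fit$error_manifest,
                       file.path(out_dir, "error_manifest.csv"), hdr)
  writeLines(c(paste0("# ", hdr),
               paste0("patients_analysed: ", fit$n_patients),
               paste0("patients_failed: ",
                      if (is.null(fit$error_manifest)) 0
                      else nrow(fit$error_manifest)),
               paste0("settings: ", paste(names(fit$settings),
                                          unlist(fit$settings),
                                          sep = "=", collapse = " "))),
             file.path(out_dir, "run_log.txt"))
  invisible(fit)
}
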