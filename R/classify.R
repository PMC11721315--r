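# Per-breath oxygenation zone classification: an SpO2 band lookup, a
# PEEP/FiO2 grid score, and a combination of the two.

#' Classify SpO2 values into oxygenation zones
#'
#' Band lookup against the table's SpO2 bands. Missing values yield
#' `unclassified`; values outside \[50, 100\] are rejected as sensor
#' artifacts.
#'
#' @param spo2 numeric vector of percent saturation, `NA` allowed.
#' @param table a [zone_table].
#' @return Factor with levels [zone_levels()], parallel to `spo2`.
#' @examples
#' classify_spo2(c(94, 88, 91, 99, NA), default_zone_table())
#' @export
classify_spo2 <- function(spo2, table = default_zone_table()) {
  bad <- !is.na(spo2) & (spo2 < 50 | spo2 > 100)
  if (any(bad))
    stop("spo2 outside [50, 100] at position ", which(bad)[1],
         " (value ", spo2[which(bad)[1]], "); sensor artifact?")
  b <- table$spo2_bands[order(table$spo2_bands$lower), , drop = FALSE]
  idx <- findInterval(spo2, c(b$lower, b$upper[nrow(b)]), rightmost.closed = TRUE)
  lab <- as.character(b$label)[idx]
  lab[is.na(spo2)] <- "unclassified"
  .zone_factor(lab)
}

#' Classify PEEP/FiO2 combinations into oxygenation zones
#'
#' Locates the grid row containing the FiO2 value; the pair is `optimal` when
#' PEEP lies within that row's optimal range, `acceptable` when it is within
#' `pf_tolerance_steps` grid steps of any optimal cell (see
#' [pf_grid_distance()]), and `critical` otherwise. Missing inputs yield
#' `unclassified`.
#'
#' @param peep numeric vector, cm H2O in \[0, 30\].
#' @param fio2 numeric vector, percent in \[21, 100\].
#' @param table a [zone_table].
#' @return Factor with levels [zone_levels()].
#' @examples
#' classify_peep_fio2(c(5, 5), c(30, 100), default_zone_table())
#' @export
classify_peep_fio2 <- function(peep, fio2, table = default_zone_table()) {
  n <- max(length(peep), length(fio2))
  peep <- rep_len(peep, n); fio2 <- rep_len(fio2, n)
  if (any(!is.na(fio2) & (fio2 < 21 | fio2 > 100)))
    stop("fio2 outside [21, 100]: ",
         fio2[which(!is.na(fio2) & (fio2 < 21 | fio2 > 100))[1]])
  if (any(!is.na(peep) & (peep < 0 | peep > 30)))
    stop("peep outside [0, 30]: ",
         peep[which(!is.na(peep) & (peep < 0 | peep > 30))[1]])
  d <- pf_grid_distance(peep, fio2, table)
  lab <- rep("unclassified", n)
  lab[!is.na(d) & d == 0L] <- "optimal"
  lab[!is.na(d) & d > 0L & d <= table$pf_tolerance_steps] <- "acceptable"
  lab[!is.na(d) & d > table$pf_tolerance_steps] <- "critical"
  .zone_factor(lab)
}

#' Combine the SpO2 and PEEP/FiO2 zone scores of a breath
#'
#' Under `worst_of` (the default rule) the combined zone is the worse of the
#' two scores on the order optimal < acceptable < critical; under
#' `spo2_priority` the SpO2 score wins and the PEEP/FiO2 score only breaks
#' an optimal SpO2 down to acceptable. Either input `unclassified` makes the
#' result `unclassified`.
#'
#' @param spo2_zone,pf_zone factors (or characters) of zone labels.
#' @param rule `"worst_of"` or `"spo2_priority"`.
#' @return Factor with levels [zone_levels()].
#' @export
combine_zones <- function(spo2_zone, pf_zone, rule = c("worst_of", "spo2_priority")) {
  rule <- match.arg(rule)
  s <- as.character(spo2_zone); p <- as.character(pf_zone)
  n <- max(length(s), length(p))
  s <- rep_len(s, n); p <- rep_len(p, n)
  out <- rep("unclassified", n)
  ok <- s != "unclassified" & p != "unclassified" & !is.na(s) & !is.na(p)
  if (rule == "worst_of") {
    rank <- c(optimal = 1L, acceptable = 2L, critical = 3L)
    out[ok] <- names(rank)[pmax(rank[s[ok]], rank[p[ok]])]
  } else {
    out[ok] <- s[ok]
    demote <- ok & s == "optimal" & p != "optimal"
    out[demote] <- "acceptable"
  }
  .zone_factor(out)
}

#' Classify every breath of a log into oxygenation zones
#'
#' Applies the three-step classification to each record: SpO2 band, PEEP/FiO2
#' grid score, combination per the table's rule. The measured `peep` and
#' `fio2` columns are used (set values only drive event detection).
#'
#' @param records a breath-log data.frame (see [read_breath_log()]).
#' @param table a [zone_table].
#' @param view `"combined"` (default), `"spo2"` or `"pf"` to return a single
#'   classification view, or `"all"` for a data.frame with the three parallel
#'   views (`spo2_zone`, `pf_zone`, `zone`).
#' @return Factor parallel to `records` rows, or a data.frame for
#'   `view = "all"`.
#' @examples
#' log <- data.frame(time = 0:2, spo2 = c(95, 88, NA), peep = 5, fio2 = 30,
#'                   mode = "automated", controller = "automated",
#'                   alarm = FALSE, set_peep = 5, set_fio2 = 30)
#' classify_breaths(log, view = "all")
#' @export
classify_breaths <- function(records, table = default_zone_table(),
                             view = c("combined", "spo2", "pf", "all")) {
  view <- match.arg(view)
  sz <- classify_spo2(records$spo2, table)
  pz <- classify_peep_fio2(records$peep, records$fio2, table)
  if (view == "spo2") return(sz)
  if (view == "pf") return(pz)
  cz <- combine_zones(sz, pz, table$combination_rule)
  if (view == "combined") return(cz)
  data.frame(spo2_zone = sz, pf_zone = pz, zone = cz)
}
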