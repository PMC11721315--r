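# Paired crossover statistics: an exact/approximate Wilcoxon signed-rank
# test implemented in-package, descriptive summaries in the median [IQR] /
# mean (SD) style, and the endpoint comparison tables.

# Exact null distribution of the signed-rank statistic W+ over all 2^m sign
# assignments, computed by convolving the doubled midranks (doubling makes
# tied .5 ranks integral, so the support is exact). counts[w + 1] holds the
# number of assignments with doubled statistic w.
.signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- rep(0, total + 1)
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Paired Wilcoxon signed-rank test
#'
#' Compares two paired arms (or a vector of within-pair differences) with the
#' Wilcoxon signed-rank test. Differences are `x - y`; pairs with a missing
#' member are excluded and counted. Zero differences are discarded before
#' ranking under the classic `"wilcoxon_discard"` policy (default) or kept in
#' the ranking but excluded from the statistic under `"pratt"`. Ties receive
#' midranks. With `mode = "auto"` the two-sided p-value is exact — the full
#' distribution of the statistic over all `2^m` sign assignments — for up to
#' `exact_limit` non-zero differences, and otherwise uses the normal
#' approximation with tie-corrected variance and a continuity correction.
#'
#' @param x numeric vector: first arm values, or differences when `y` is
#'   `NULL`.
#' @param y optional numeric vector: second arm values, paired with `x`.
#' @param zero_policy `"wilcoxon_discard"` or `"pratt"`.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @param exact_limit largest number of non-zero differences for which
#'   `"auto"` enumerates exactly.
#' @return Object of class `zone_signed_rank`: `statistic` (W+, the sum of
#'   ranks of positive differences), `p_value` (two-sided), `n_pairs_used`
#'   (non-missing pairs), `n_zero`, `n_missing`, `method`,
#'   `median_difference`, and per-arm [describe()] summaries when `y` is
#'   given.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))            # exact p = 0.25
#' wilcoxon_signed_rank(c(5, 7, 9, 4), c(4, 9, 2, 4))
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 zero_policy = c("wilcoxon_discard", "pratt"),
                                 mode = c("auto", "exact", "normal_approx"),
                                 exact_limit = 20L) {
  zero_policy <- match.arg(zero_policy)
  mode <- match.arg(mode)
  if (!is.null(y)) {
    if (length(x) != length(y)) stop("x and y must be paired (equal length)")
    keep <- !is.na(x) & !is.na(y)
    d <- x[keep] - y[keep]
    n_missing <- sum(!keep)
    arm_summaries <- list(arm1 = describe(x[keep]), arm2 = describe(y[keep]))
  } else {
    d <- x[!is.na(x)]
    n_missing <- sum(is.na(x))
    arm_summaries <- NULL
  }
  n_pairs_used <- length(d)
  if (n_pairs_used == 0) stop("no complete pairs")

  n_zero <- sum(d == 0)
  if (n_zero == n_pairs_used) {
    warning("all differences are zero: degenerate sample, p = 1")
    res <- list(statistic = 0, p_value = 1, n_pairs_used = n_pairs_used,
                n_nonzero = 0L, n_zero = n_zero, n_missing = n_missing,
                method = "degenerate", median_difference = 0,
                arm_summaries = arm_summaries)
    class(res) <- "zone_signed_rank"
    return(res)
  }

  if (zero_policy == "wilcoxon_discard") {
    dn <- d[d != 0]
    r <- rank(abs(dn))
  } else {
    r_all <- rank(abs(d))
    dn <- d[d != 0]
    r <- r_all[d != 0]
  }
  m <- length(dn)
  W <- sum(r[dn > 0])
  S <- sum(r)

  use_exact <- mode == "exact" || (mode == "auto" && m <= exact_limit)
  if (use_exact) {
    r2 <- round(2 * r)
    counts <- .signed_rank_counts(r2)
    W2 <- round(2 * W); S2 <- sum(r2)
    dev <- abs(seq(0, S2) - S2 / 2)
    p <- sum(counts[dev >= abs(W2 - S2 / 2) - 1e-9]) / 2^m
    method <- sprintf("exact (2^%d sign assignments)", m)
  } else {
    E <- S / 2
    V <- sum(r^2) / 4
    num <- W - E
    z <- if (num == 0) 0 else (num - 0.5 * sign(num)) / sqrt(V)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  res <- list(statistic = W, p_value = p, n_pairs_used = n_pairs_used,
              n_nonzero = m, n_zero = n_zero, n_missing = n_missing,
              method = method, median_difference = stats::median(d),
              arm_summaries = arm_summaries)
  class(res) <- "zone_signed_rank"
  res
}

#' @export
print.zone_signed_rank <- function(x, ...) {
  cat("Paired Wilcoxon signed-rank test (", x$method, ")\n", sep = "")
  cat(sprintf("  W+ = %g over %d non-zero of %d pairs (%d zero, %d missing)\n",
              x$statistic, x$n_nonzero, x$n_pairs_used, x$n_zero, x$n_missing))
  cat(sprintf("  median difference = %g, two-sided p = %.4g\n",
              x$median_difference, x$p_value))
  invisible(x)
}

#' Descriptive summary: median [IQR], mean (SD)
#'
#' Quartiles use the linear-interpolation convention (R quantile type 7); the
#' standard deviation uses the n - 1 denominator and is `NA` for a single
#' value. Missing values are removed first.
#'
#' @param values numeric vector.
#' @return Named numeric vector `n`, `median`, `q1`, `q3`, `mean`, `sd`
#'   (all `NA` except `n = 0` for empty input).
#' @examples
#' describe(c(1, 2, 3, 4, 5))
#' @export
describe <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v))
    return(c(n = 0, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
             mean = NA_real_, sd = NA_real_))
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
    mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_)
}

# Paired per-patient vectors for one endpoint, pivoted from a long table.
.pair_endpoint <- function(df, value_col) {
  a <- df[df$phase == "automated", c("patient_id", value_col)]
  c_ <- df[df$phase == "conventional", c("patient_id", value_col)]
  ids <- union(a$patient_id, c_$patient_id)
  list(patient_id = ids,
       automated = a[[value_col]][match(ids, a$patient_id)],
       conventional = c_[[value_col]][match(ids, c_$patient_id)])
}

.endpoint_row <- function(auto, conv, alpha = 0.05) {
  da <- describe(auto); dc <- describe(conv)
  keep <- !is.na(auto) & !is.na(conv)
  p <- if (sum(keep) >= 1 && any(auto[keep] != conv[keep])) {
    wilcoxon_signed_rank(auto[keep], conv[keep])$p_value
  } else if (sum(keep) >= 1) 1 else NA_real_
  data.frame(n_pairs = sum(keep),
             automated_median = da["median"], automated_q1 = da["q1"],
             automated_q3 = da["q3"], automated_mean = da["mean"],
             automated_sd = da["sd"],
             conventional_median = dc["median"], conventional_q1 = dc["q1"],
             conventional_q3 = dc["q3"], conventional_mean = dc["mean"],
             conventional_sd = dc["sd"],
             p_value = p, significant = !is.na(p) & p < alpha,
             row.names = NULL)
}

#' Compare every zone and event endpoint between ventilation arms
#'
#' Builds the two endpoint comparison tables of a crossover analysis. The
#' zone table covers the three classification views (combined, SpO2-only,
#' PEEP/FiO2-only) by two metrics (percentage of breaths, percentage of
#' time) by three zones; the event table covers automated and manual setting
#' changes, alarm counts and cumulative alarm minutes per patient. Each row
#' reports per-arm median \[IQR\] and mean (SD) plus the paired signed-rank
#' p-value; the `significant` flag (alpha = 0.05) is informational and never
#' filters rows. No multiple-testing correction is applied: raw p-values are
#' reported for every endpoint.
#'
#' @param summaries [summarize_cohort()] output.
#' @param event_counts row-bound [count_events_per_phase()] output.
#' @param alpha flagging threshold.
#' @return List of data.frames `zones` (view x metric x zone rows) and
#'   `events` (one row per event endpoint).
#' @export
compare_all_endpoints <- function(summaries, event_counts = NULL, alpha = 0.05) {
  if (length(unique(summaries$patient_id)) < 2)
    stop("paired comparison requires >= 2 patients with both phases")
  rows <- list()
  for (v in c("combined", "spo2", "pf")) {
    for (metric in c("pct_breaths", "pct_time")) {
      for (z in zone_levels()[1:3]) {
        sub <- summaries[summaries$view == v & summaries$zone == z, ]
        pr <- .pair_endpoint(sub, metric)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(view = v, metric = metric, zone = z),
          .endpoint_row(pr$automated, pr$conventional, alpha))
      }
    }
  }
  zones <- do.call(rbind, rows)

  events <- NULL
  if (!is.null(event_counts)) {
    ec <- event_counts[event_counts$phase != "washout", ]
    erows <- list()
    for (ep in c("n_automated", "n_manual", "n_alarms", "alarm_minutes")) {
      pr <- .pair_endpoint(ec, ep)
      erows[[length(erows) + 1L]] <- cbind(
        data.frame(endpoint = ep),
        .endpoint_row(pr$automated, pr$conventional, alpha))
    }
    events <- do.call(rbind, erows)
  }
  list(zones = zones, events = events)
}
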