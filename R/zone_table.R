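# Zone-table configuration: SpO2 bands plus a lower-PEEP/higher-FiO2 scoring
# grid. Everything the per-breath classifiers consult lives in this object so
# an analysis is reproducible against a named table version.

#' Ordered oxygenation zone labels
#'
#' Zone labels used throughout the package, ordered from best to worst:
#' `optimal < acceptable < critical`, with `unclassified` reserved for breaths
#' whose inputs are missing.
#'
#' @return Character vector of the four labels in severity order.
#' @export
zone_levels <- function() c("optimal", "acceptable", "critical", "unclassified")

.zone_factor <- function(x) factor(x, levels = zone_levels())

#' Construct an oxygenation zone table
#'
#' A zone table bundles the SpO2 bands, the PEEP/FiO2 scoring grid and the
#' rule for combining the two per-breath scores into a single oxygenation
#' zone. SpO2 bands are half-open `[lower, upper)` intervals in percent, with
#' the top band closed so the bands partition \[50, 100\]. Grid rows are
#' half-open FiO2 bins (top bin closed, union covering \[21, 100\]) paired
#' with the inclusive PEEP range considered optimal for that bin.
#'
#' @param spo2_bands data.frame with columns `lower`, `upper`, `label`
#'   partitioning SpO2 \[50, 100\].
#' @param pf_grid data.frame with columns `fio2_lower`, `fio2_upper`,
#'   `peep_lower`, `peep_upper`; rows in ascending, non-overlapping FiO2
#'   order covering \[21, 100\].
#' @param pf_tolerance_steps non-negative integer; a (PEEP, FiO2) pair within
#'   this many grid steps of an optimal cell scores `acceptable`.
#' @param peep_step PEEP increment (cm H2O) counted as one grid step.
#' @param combination_rule `"worst_of"` (default) or `"spo2_priority"`.
#' @param version character tag identifying the table in output provenance.
#' @return An object of class `zone_table`.
#' @seealso [default_zone_table()], [read_zone_table()], [classify_breaths()]
#' @export
zone_table <- function(spo2_bands, pf_grid, pf_tolerance_steps = 1L,
                       peep_step = 2, combination_rule = c("worst_of", "spo2_priority"),
                       version = "custom") {
  combination_rule <- match.arg(combination_rule)
  spo2_bands <- as.data.frame(spo2_bands)
  pf_grid <- as.data.frame(pf_grid)
  tbl <- structure(
    list(spo2_bands = spo2_bands, pf_grid = pf_grid,
         pf_tolerance_steps = as.integer(pf_tolerance_steps),
         peep_step = peep_step, combination_rule = combination_rule,
         version = version),
    class = "zone_table")
  validate_zone_table(tbl)
  tbl
}

#' Validate a zone table
#'
#' Checks the structural invariants: SpO2 bands partition \[50, 100\] with no
#' gaps or overlaps; FiO2 bins are ascending, non-overlapping and cover
#' \[21, 100\]; PEEP ranges are ordered; the tolerance is non-negative.
#'
#' @param table a `zone_table`.
#' @return The table, invisibly; errors describe the first violated invariant.
#' @export
validate_zone_table <- function(table) {
  stopifnot(inherits(table, "zone_table"))
  b <- table$spo2_bands
  req <- c("lower", "upper", "label")
  if (!all(req %in% names(b)))
    stop("spo2_bands needs columns: ", paste(req, collapse = ", "))
  b <- b[order(b$lower), , drop = FALSE]
  if (b$lower[1] != 50 || b$upper[nrow(b)] != 100)
    stop("spo2_bands must span [50, 100]")
  if (any(b$upper <= b$lower)) stop("each spo2 band needs upper > lower")
  if (nrow(b) > 1 && any(abs(b$lower[-1] - b$upper[-nrow(b)]) > 1e-9))
    stop("spo2_bands must be contiguous (no gaps or overlaps)")
  bad <- setdiff(unique(as.character(b$label)), zone_levels()[1:3])
  if (length(bad)) stop("unknown spo2 band label: ", bad[1])

  g <- table$pf_grid
  req <- c("fio2_lower", "fio2_upper", "peep_lower", "peep_upper")
  if (!all(req %in% names(g)))
    stop("pf_grid needs columns: ", paste(req, collapse = ", "))
  g <- g[order(g$fio2_lower), , drop = FALSE]
  if (g$fio2_lower[1] != 21 || g$fio2_upper[nrow(g)] != 100)
    stop("pf_grid FiO2 bins must cover [21, 100]")
  if (any(g$fio2_upper <= g$fio2_lower)) stop("each FiO2 bin needs upper > lower")
  if (nrow(g) > 1 && any(abs(g$fio2_lower[-1] - g$fio2_upper[-nrow(g)]) > 1e-9))
    stop("pf_grid FiO2 bins must be contiguous and non-overlapping")
  if (any(g$peep_upper < g$peep_lower)) stop("pf_grid PEEP ranges must have upper >= lower")
  if (table$pf_tolerance_steps < 0) stop("pf_tolerance_steps must be >= 0")
  if (!is.numeric(table$peep_step) || table$peep_step <= 0)
    stop("peep_step must be a positive number")
  invisible(table)
}

.vz_cache <- new.env(parent = emptyenv())

#' The shipped default zone table
#'
#' Loads (and caches) the versioned default table installed with the package:
#' SpO2 optimal 93--97%, acceptable 90--92% or 98--100%, critical below 90%;
#' the ARDS Network lower-PEEP/higher-FiO2 grid with a one-step tolerance;
#' `worst_of` combination. These cutoffs are a documented reconstruction from
#' the published target ranges, not a device vendor table; any analysis can
#' substitute its own table via [read_zone_table()].
#'
#' @return A `zone_table`, version `"default_v1"`.
#' @examples
#' tbl <- default_zone_table()
#' classify_spo2(c(94, 88, NA), tbl)
#' @export
default_zone_table <- function() {
  if (is.null(.vz_cache$default_table)) {
    path <- system.file("extdata", "zone_table_default_v1.yaml",
                        package = "ventzone", mustWork = TRUE)
    .vz_cache$default_table <- read_zone_table(path)
  }
  .vz_cache$default_table
}

#' Read a zone table from a YAML file
#'
#' @param path YAML file with fields `version`, `combination_rule`,
#'   `pf_tolerance_steps`, `peep_step`, `spo2_bands`, `pf_grid` (see the
#'   shipped `zone_table_default_v1.yaml` for the layout).
#' @return A validated `zone_table`.
#' @export
read_zone_table <- function(path) {
  if (!file.exists(path)) stop("zone table file not found: ", path)
  y <- yaml::read_yaml(path)
  bands <- do.call(rbind, lapply(y$spo2_bands, as.data.frame))
  grid <- do.call(rbind, lapply(y$pf_grid, as.data.frame))
  zone_table(spo2_bands = bands, pf_grid = grid,
             pf_tolerance_steps = y$pf_tolerance_steps %||% 1L,
             peep_step = y$peep_step %||% 2,
             combination_rule = y$combination_rule %||% "worst_of",
             version = y$version %||% "unversioned")
}

#' Write a zone table to a YAML file
#'
#' Inverse of [read_zone_table()]: `read_zone_table(write_zone_table(x, f))`
#' reproduces `x`.
#'
#' @param table a `zone_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_zone_table <- function(table, path) {
  validate_zone_table(table)
  y <- list(version = table$version,
            combination_rule = table$combination_rule,
            pf_tolerance_steps = table$pf_tolerance_steps,
            peep_step = table$peep_step,
            spo2_bands = lapply(seq_len(nrow(table$spo2_bands)), function(i)
              as.list(table$spo2_bands[i, ])),
            pf_grid = lapply(seq_len(nrow(table$pf_grid)), function(i)
              as.list(table$pf_grid[i, ])))
  yaml::write_yaml(y, path)
  invisible(path)
}

# Grid row index containing each fio2 value (half-open bins, top bin closed).
.pf_row <- function(fio2, table) {
  g <- table$pf_grid
  idx <- findInterval(fio2, c(g$fio2_lower, g$fio2_upper[nrow(g)]),
                      rightmost.closed = TRUE)
  idx[fio2 < g$fio2_lower[1] | fio2 > g$fio2_upper[nrow(g)]] <- NA_integer_
  idx
}

#' Grid-step distance from a (PEEP, FiO2) pair to the nearest optimal cell
#'
#' The distance is the minimum, over all grid rows, of the number of row moves
#' in FiO2 plus the number of `peep_step` increments needed to bring the PEEP
#' value inside that row's optimal range, found by brute-force search over the
#' grid. Distance 0 means the pair sits in an optimal cell.
#'
#' @param peep,fio2 numeric vectors (recycled to common length).
#' @param table a `zone_table`.
#' @return Integer vector of distances; `NA` where an input is missing.
#' @export
pf_grid_distance <- function(peep, fio2, table = default_zone_table()) {
  n <- max(length(peep), length(fio2))
  peep <- rep_len(peep, n); fio2 <- rep_len(fio2, n)
  g <- table$pf_grid
  row0 <- .pf_row(fio2, table)
  # brute force over every grid row: row moves plus PEEP increments
  cost <- lapply(seq_len(nrow(g)), function(r) {
    gap <- pmax(0, g$peep_lower[r] - peep, peep - g$peep_upper[r])
    abs(row0 - r) + ceiling(gap / table$peep_step - 1e-9)
  })
  out <- as.integer(do.call(pmin, cost))
  out[is.na(peep) | is.na(row0)] <- NA_integer_
  out
}

#' @export
print.zone_table <- function(x, ...) {
  cat("Oxygenation zone table [", x$version, "]\n", sep = "")
  cat("SpO2 bands (% saturation):\n")
  b <- x$spo2_bands
  for (i in seq_len(nrow(b)))
    cat(sprintf("  [%g, %g%s -> %s\n", b$lower[i], b$upper[i],
                if (i == nrow(b)) "]" else ")", b$label[i]))
  cat("PEEP/FiO2 grid (", nrow(x$pf_grid), " FiO2 bins, tolerance ",
      x$pf_tolerance_steps, " step(s) of ", x$peep_step, " cm H2O)\n", sep = "")
  cat("Combination rule:", x$combination_rule, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
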