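# Independent oracles, deliberately coded scalar and brute-force so they
# share no code path with the package implementation.

# Scalar re-classification of one breath against a zone table.
oracle_classify_breath <- function(spo2, peep, fio2, table) {
  worse <- function(a, b) {
    order_ <- c("optimal", "acceptable", "critical")
    order_[max(match(a, order_), match(b, order_))]
  }
  # SpO2 band by linear scan
  sz <- NA_character_
  if (is.na(spo2)) sz <- "unclassified" else {
    b <- table$spo2_bands[order(table$spo2_bands$lower), ]
    for (i in seq_len(nrow(b))) {
      hi_ok <- if (i == nrow(b)) spo2 <= b$upper[i] else spo2 < b$upper[i]
      if (spo2 >= b$lower[i] && hi_ok) { sz <- as.character(b$label[i]); break }
    }
  }
  # PEEP/FiO2 distance by expanding ring search over the grid
  pz <- NA_character_
  if (is.na(peep) || is.na(fio2)) pz <- "unclassified" else {
    g <- table$pf_grid[order(table$pf_grid$fio2_lower), ]
    r0 <- NA
    for (r in seq_len(nrow(g))) {
      hi_ok <- if (r == nrow(g)) fio2 <= g$fio2_upper[r] else fio2 < g$fio2_upper[r]
      if (fio2 >= g$fio2_lower[r] && hi_ok) { r0 <- r; break }
    }
    best <- Inf
    for (r in seq_len(nrow(g))) {
      # smallest k such that k moves of peep_step (the last move may stop
      # inside the range) reach the row's PEEP range from peep
      k <- 0
      while (peep - k * table$peep_step > g$peep_upper[r] + 1e-9 &&
             k < 100) k <- k + 1
      j <- 0
      while (peep + j * table$peep_step < g$peep_lower[r] - 1e-9 &&
             j < 100) j <- j + 1
      steps <- abs(r0 - r) + max(k, j)
      best <- min(best, steps)
    }
    pz <- if (best == 0) "optimal"
          else if (best <= table$pf_tolerance_steps) "acceptable"
          else "critical"
  }
  if (sz == "unclassified" || pz == "unclassified") return("unclassified")
  if (table$combination_rule == "worst_of") worse(sz, pz)
  else if (sz == "optimal" && pz != "optimal") "acceptable" else sz
}

# Literal 2^m sign-assignment enumeration of the two-sided signed-rank p.
oracle_wilcoxon_exact <- function(d, zero_policy = "wilcoxon_discard") {
  d <- d[!is.na(d)]
  if (zero_policy == "wilcoxon_discard") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  m <- length(d)
  if (m == 0) return(1)
  W_obs <- sum(r[d > 0])
  E <- sum(r) / 2
  hits <- 0L
  for (mask in 0:(2^m - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    W <- sum(r[signs])
    if (abs(W - E) >= abs(W_obs - E) - 1e-9) hits <- hits + 1L
  }
  hits / 2^m
}
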