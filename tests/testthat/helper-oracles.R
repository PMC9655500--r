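# Independent oracles used across the suite. Each re-derives the quantity
# from its definition by brute force, sharing no code path with the
# implementation it checks.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
          "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(len, cys_prob = NA) {
  if (is.na(cys_prob)) return(paste(sample(AA20, len, TRUE), collapse = ""))
  prob <- rep((1 - cys_prob) / 19, 20)
  prob[AA20 == "C"] <- cys_prob
  paste(sample(AA20, len, TRUE, prob = prob), collapse = "")
}

# brute-force motif oracle: enumerate every cysteine-position tuple and
# check the printed spacing bounds directly on the sequence
oracle_motif <- function(peptide) {
  res <- strsplit(peptide, "")[[1]]
  cys <- which(res == "C")
  gap_clean <- function(a, b) !any(res[seq(a + 1, b - 1)] == "C")
  gap_len <- function(a, b) b - a - 1L

  hit6 <- FALSE
  if (length(cys) >= 6) {
    for (tup in asplit(combn(cys, 6), 2)) {
      g <- diff(tup) - 1L
      ok <- g[1] >= 3 && g[1] <= 6 && g[2] >= 4 && g[2] <= 7 &&
        g[3] >= 4 && g[3] <= 7 && g[4] >= 4 && g[4] <= 17 && g[5] == 1
      if (ok && all(mapply(gap_clean, tup[-6], tup[-1]))) {
        hit6 <- TRUE
        break
      }
    }
  }
  if (hit6) return("NCR6")
  if (length(cys) >= 4) {
    for (tup in asplit(combn(cys, 4), 2)) {
      g <- diff(tup) - 1L
      ok <- g[1] == 5 && res[tup[2] - 1] == "D" &&
        g[2] >= 11 && g[2] <= 17 && g[3] == 4
      if (ok && all(mapply(gap_clean, tup[-4], tup[-1]))) return("NCR4")
    }
  }
  "NONE"
}

# position-by-position application of the three signal-peptide rules
oracle_signal <- function(peptide) {
  res <- strsplit(peptide, "")[[1]]
  L <- length(res)
  if (L < 15) return(NA_integer_)
  if (!any(res[1:5] %in% c("K", "R"))) return(NA_integer_)
  hydro <- c("A", "V", "L", "I", "M", "F", "W", "C")
  small <- c("A", "G", "S", "C", "T")
  for (cc in 8:min(45, L - 1)) {
    if (sum(res[(cc - 7):cc] %in% hydro) >= 6 &&
        res[cc - 2] %in% small && res[cc] %in% small)
      return(cc)
  }
  NA_integer_
}

# 0.001-step grid search on the charge curve
oracle_pI_grid <- function(peptide, table = pka_table()) {
  grid <- seq(0.5, 13.5, by = 0.001)
  ch <- net_charge(peptide, grid, table)
  grid[which.min(abs(ch))]
}

# definition-based Benjamini-Hochberg: all m ranks explicitly, running
# minimum from the largest rank
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# definition-based quantile normalization: k-th order statistic replaced by
# the mean of all samples' k-th order statistics; ties get the mean of
# their tied-rank targets
oracle_quantile_norm <- function(x) {
  target <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r)
    hi <- ceiling(r)
    (target[lo] + target[hi]) / 2
  })
}

# simulated study-condition fixtures, small enough for unit tests
tiny_genome_sim <- function(seed = 7) {
  simulate_genome(sim_config(seed = seed, n_decoy_genes = 20, n_ncr4 = 3,
                             n_ncr6 = 3, n_defensin = 2,
                             n_intronless_ncr = 1))
}
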