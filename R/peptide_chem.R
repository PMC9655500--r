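# Isoelectric point and charge-class machinery for mature nodule peptides.
# The pKa value set is a choice, not a constant of nature, so it is exposed:
# published catalogs differ by several tenths of a pH unit depending on set.

.PKA_SETS <- list(
  emboss = list(nterm = 8.6, cterm = 3.6,
                C = 8.5, D = 3.9, E = 4.1, H = 6.5,
                K = 10.8, R = 12.5, Y = 10.1),
  bjellqvist = list(nterm = 7.5, cterm = 3.55,
                    C = 9.0, D = 4.05, E = 4.45, H = 5.98,
                    K = 10.0, R = 12.0, Y = 10.0))

#' Side-chain and terminal pKa table
#'
#' @param name `"emboss"` (default) or `"bjellqvist"`, or a named list with
#'   entries `nterm`, `cterm`, `C`, `D`, `E`, `H`, `K`, `R`, `Y` to supply
#'   custom values.
#' @return A named list of pKa values with attribute `"name"`.
#' @export
pka_table <- function(name = "emboss") {
  if (is.list(name)) {
    needed <- c("nterm", "cterm", "C", "D", "E", "H", "K", "R", "Y")
    if (!all(needed %in% names(name)))
      stop("custom pKa table must name: ", paste(needed, collapse = ", "))
    tab <- name[needed]
    attr(tab, "name") <- "custom"
  } else {
    name <- match.arg(name, names(.PKA_SETS))
    tab <- .PKA_SETS[[name]]
    attr(tab, "name") <- name
  }
  vals <- unlist(tab)
  if (any(vals <= 0 | vals >= 14)) stop("pKa values must lie in (0, 14)")
  tab
}

.check_residues <- function(peptide) {
  res <- strsplit(peptide, "")[[1L]]
  bad <- setdiff(res, AA_ALPHABET)
  if (length(bad))
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  res
}

#' Net charge of a peptide at a given pH
#'
#' Henderson--Hasselbalch sum: basic groups (N-terminus, K, R, H) contribute
#' `1/(1 + 10^(pH - pKa))`, acidic groups (C-terminus, D, E, C, Y) contribute
#' `-1/(1 + 10^(pKa - pH))`. `X` residues contribute nothing. Vectorized
#' over `pH`.
#'
#' @param peptide amino-acid string (20 standard letters plus `X`).
#' @param pH pH value(s) in (0, 14).
#' @param table a [pka_table()].
#' @return Net charge, one value per element of `pH`.
#' @export
net_charge <- function(peptide, pH, table = pka_table()) {
  stopifnot(nchar(peptide) >= 1L, all(pH > 0 & pH < 14))
  res <- .check_residues(peptide)
  n_of <- function(a) sum(res == a)
  basic <- c(nterm = 1, K = n_of("K"), R = n_of("R"), H = n_of("H"))
  acidic <- c(cterm = 1, D = n_of("D"), E = n_of("E"), C = n_of("C"),
              Y = n_of("Y"))
  pka_b <- unlist(table[c("nterm", "K", "R", "H")])
  pka_a <- unlist(table[c("cterm", "D", "E", "C", "Y")])
  vapply(pH, function(p) {
    sum(basic / (1 + 10^(p - pka_b))) - sum(acidic / (1 + 10^(pka_a - p)))
  }, numeric(1))
}

#' Isoelectric point by charge-curve bisection
#'
#' Finds the pH at which [net_charge()] crosses zero by bisection on
#' `[0.5, 13.5]`. The charge curve is strictly decreasing in pH, so the root
#' is unique and the search is deterministic. Bisection continues until the
#' bracketing interval is narrower than `tol` *and* the residual charge at
#' the midpoint is within `tol` (steep charge curves -- many ionizable
#' groups -- need the second condition).
#'
#' @inheritParams net_charge
#' @param tol tolerance on both the pH interval and the residual charge
#'   (default `1e-3`).
#' @return The isoelectric point (pH units).
#' @export
compute_pI <- function(peptide, table = pka_table(), tol = 1e-3) {
  lo <- 0.5
  hi <- 13.5
  if (net_charge(peptide, lo, table) < 0) return(lo)
  if (net_charge(peptide, hi, table) > 0) return(hi)
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    ch <- net_charge(peptide, mid, table)
    if (hi - lo <= tol && abs(ch) <= tol) break
    if (ch > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Charge class from isoelectric point
#'
#' Cationic peptides have pI strictly above 9.0, anionic strictly below 4.0;
#' everything else (boundaries included) is neutral. Cationic nodule
#' peptides are the candidate antimicrobials.
#'
#' @param pI numeric vector of isoelectric points.
#' @return Character vector in `{"CATIONIC", "ANIONIC", "NEUTRAL"}`.
#' @export
classify_charge <- function(pI) {
  ifelse(pI > 9.0, "CATIONIC", ifelse(pI < 4.0, "ANIONIC", "NEUTRAL"))
}

#' Histogram counts of isoelectric points
#'
#' Bins are left-closed right-open `[e_i, e_{i+1})`; values below the first
#' edge and at-or-above the last edge are counted in overflow buckets.
#'
#' @param pIs numeric vector of isoelectric points.
#' @param bin_edges strictly increasing numeric vector of edges.
#' @return Named integer vector of counts: underflow, one per bin, overflow.
#' @export
bin_pI <- function(pIs, bin_edges) {
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing with at least two edges")
  idx <- findInterval(pIs, bin_edges, rightmost.closed = FALSE)
  k <- length(bin_edges)
  labs <- c(sprintf("<%g", bin_edges[1L]),
            sprintf("[%g,%g)", bin_edges[-k], bin_edges[-1L]),
            sprintf(">=%g", bin_edges[k]))
  counts <- tabulate(idx + 1L, nbins = k + 1L)
  setNames(as.integer(counts), labs)
}
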