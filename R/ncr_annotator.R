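# Motif-based identification of NCR and defensin-like peptide genes.
#
# NCR peptides carry 4 or 6 conserved cysteines with characteristic spacing:
#   4-cys:  C-(X4)-DC-(X11-17)-C-(X4)-C
#   6-cys:  C-(X3-6)-C-(X4-7)-C-(X4-7)-C-(X4-17)-C-(X1)-C
# X is any residue except cysteine by default, which keeps the conserved
# cysteine count exact and stops 6-cys peptides from silently matching the
# 4-cys pattern through an internal cysteine. Peptides whose mature region
# carries >= 8 cysteines are classified defensin-like instead, overriding
# any NCR motif hit.

.ncr_patterns <- function(x_allows_cys = FALSE) {
  X <- if (x_allows_cys) "." else "[^C]"
  list(
    NCR4 = paste0("C", X, "{4}DC", X, "{11,17}C", X, "{4}C"),
    NCR6 = paste0("C", X, "{3,6}C", X, "{4,7}C", X, "{4,7}C", X, "{4,17}C",
                  X, "{1}C"))
}

#' Match the NCR cysteine-spacing motifs
#'
#' Scans a peptide for the six-cysteine motif first (six-cysteine peptides
#' can contain four-cysteine sub-patterns), then the four-cysteine motif.
#' The defensin-like override (mature cysteine count >= 8) is applied at
#' [annotate_gene()] level, not here.
#'
#' @param peptide amino-acid string (20 standard letters plus `X`).
#' @param x_allows_cys if `TRUE`, the spacer positions of the motifs may be
#'   cysteine (default `FALSE`).
#' @param ncr6_first test the six-cysteine motif before the four-cysteine
#'   one (default `TRUE`).
#' @return List with `label` (`"NCR4"`, `"NCR6"` or `"NONE"`), `match_span`
#'   (first-match residue interval, or `NULL`), and `cysteine_count` within
#'   the span (0 for no match).
#' @export
match_ncr_motif <- function(peptide, x_allows_cys = FALSE, ncr6_first = TRUE) {
  stopifnot(nchar(peptide) >= 1L)
  .check_residues(peptide)
  pats <- .ncr_patterns(x_allows_cys)
  order_ <- if (ncr6_first) c("NCR6", "NCR4") else c("NCR4", "NCR6")
  for (lab in order_) {
    m <- regexpr(pats[[lab]], peptide, perl = TRUE)
    if (m[1L] != -1L) {
      span <- c(start = m[1L], end = m[1L] + attr(m, "match.length") - 1L)
      hit <- substr(peptide, span[1L], span[2L])
      return(list(label = lab, match_span = span,
                  cysteine_count = lengths(regmatches(
                    hit, gregexpr("C", hit, fixed = TRUE)))))
    }
  }
  list(label = "NONE", match_span = NULL, cysteine_count = 0L)
}

.HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "C")
.SMALL <- c("A", "G", "S", "C", "T")

#' Heuristic signal-peptide prediction
#'
#' A lightweight built-in stand-in for a dedicated predictor, applying three
#' classic rules to candidate cleavage sites (cleavage after residue `c`,
#' scanned earliest-first over `c = 8..45`):
#' \enumerate{
#'   \item n-region: at least one K/R among residues 1--5;
#'   \item h-region: at least 6 hydrophobic residues (A,V,L,I,M,F,W,C) in the
#'     8-residue window ending at the cleavage site (positions `c-7..c`);
#'   \item c-region: small residues (A,G,S,C,T) at the -3 and -1 positions
#'     relative to the site (positions `c-2` and `c`).
#' }
#' The earliest site satisfying all three wins. Per-gene predictions from an
#' external tool can be substituted via the `signal_calls` argument of
#' [annotate_gene()].
#'
#' @param peptide amino-acid string; peptides shorter than 15 residues get
#'   an absent call.
#' @param min_pos,max_pos candidate cleavage-site range (residue index after
#'   which cleavage occurs).
#' @return List with `cleavage_after` (residue index or `NA`), `score`
#'   (fraction of rules satisfied at the best site) and `method`.
#' @export
predict_signal_peptide <- function(peptide, min_pos = 8L, max_pos = 45L) {
  absent <- list(cleavage_after = NA_integer_, score = 0, method = "heuristic")
  L <- nchar(peptide)
  if (L < 15L) return(absent)
  res <- .check_residues(peptide)
  n_ok <- any(res[1:5] %in% c("K", "R"))
  best <- 0
  for (cc in seq.int(min_pos, min(max_pos, L - 1L))) {
    h_ok <- sum(res[(cc - 7L):cc] %in% .HYDROPHOBIC) >= 6L
    c_ok <- res[cc - 2L] %in% .SMALL && res[cc] %in% .SMALL
    score <- mean(c(n_ok, h_ok, c_ok))
    if (n_ok && h_ok && c_ok)
      return(list(cleavage_after = cc, score = 1, method = "heuristic"))
    best <- max(best, score)
  }
  absent$score <- best
  absent
}

#' Classify the exon structure of a nodule-peptide gene
#'
#' The canonical NCR gene has two exons interrupted by an intron near the
#' signal-peptide cleavage site; a minority carry a second 3' intron whose
#' terminal exon encodes only one to a few codons before the stop, and a few
#' are intronless.
#'
#' @param model a [gene_model()].
#' @param signal a signal-peptide call (see [predict_signal_peptide()]), used
#'   to report the first intron's offset from the cleavage site, in residues.
#' @param max_terminal_codons largest number of coding codons (stop excluded)
#'   allowed in the terminal exon of the three-exon class (default 5).
#' @return List with `label` in `{"TWO_EXON_CANONICAL", "THREE_EXON_3PRIME",
#'   "INTRONLESS", "OTHER"}` and `intron1_offset_from_cleavage` (residues,
#'   or `NA`).
#' @export
classify_structure <- function(model, signal = NULL, max_terminal_codons = 5L) {
  n_exon <- nrow(model$exons)
  cds_lens <- model$cds[, 2L] - model$cds[, 1L] + 1
  offset <- NA_real_
  if (n_exon >= 2L && !is.null(signal) && !is.na(signal$cleavage_after)) {
    intron_residue <- ceiling(cds_lens[1L] / 3)
    offset <- intron_residue - signal$cleavage_after
  }
  label <- if (n_exon == 1L) "INTRONLESS"
  else if (n_exon == 2L) "TWO_EXON_CANONICAL"
  else if (n_exon == 3L &&
           ceiling(cds_lens[length(cds_lens)] / 3) - 1L <= max_terminal_codons)
    "THREE_EXON_3PRIME"
  else "OTHER"
  list(label = label, intron1_offset_from_cleavage = offset)
}

#' Locus name from chromosome and start coordinate
#'
#' Loci are named deterministically by chromosome number and gene start
#' location, e.g. `name_locus(3, 123916883)` is `"Tp3_123916883"`. A leading
#' `chr`/`Chr` prefix on the chromosome name is dropped.
#'
#' @param chromosome chromosome name or number.
#' @param start 1-based start coordinate of the gene.
#' @return Character locus name.
#' @export
name_locus <- function(chromosome, start) {
  stopifnot(all(start >= 1))
  chrom <- sub("^[Cc]hr", "", as.character(chromosome))
  sprintf("Tp%s_%s", chrom,
          format(start, scientific = FALSE, trim = TRUE))
}

#' Annotate one gene model as a nodule-peptide candidate
#'
#' Composes the full classification: CDS translation, signal-peptide call,
#' mature-peptide extraction, motif matching on the mature peptide,
#' defensin-like override at >= 8 mature cysteines, exon-structure class,
#' and isoelectric point / charge class of the mature peptide. Genes whose
#' motif matches but that lack a predicted signal peptide are retained and
#' flagged, not dropped.
#'
#' @param model a [gene_model()].
#' @param genome named character vector from [read_genome()].
#' @param signal_calls optional data frame with columns `gene_id` and
#'   `cleavage_after` supplying external signal-peptide predictions that
#'   replace the built-in heuristic.
#' @param pka a [pka_table()].
#' @param x_allows_cys,ncr6_first motif options, see [match_ncr_motif()].
#' @param max_terminal_codons see [classify_structure()].
#' @return List of class `"peptide_annotation"`.
#' @export
annotate_gene <- function(model, genome, signal_calls = NULL,
                          pka = pka_table(), x_allows_cys = FALSE,
                          ncr6_first = TRUE, max_terminal_codons = 5L) {
  pep <- translate_cds(model, genome)
  if (!is.null(signal_calls) && model$gene_id %in% signal_calls$gene_id) {
    ca <- signal_calls$cleavage_after[match(model$gene_id,
                                            signal_calls$gene_id)]
    signal <- list(cleavage_after = if (is.na(ca)) NA_integer_ else
      as.integer(ca), score = 1, method = "external")
  } else {
    signal <- predict_signal_peptide(pep$residues)
  }
  mature <- if (!is.na(signal$cleavage_after) &&
                signal$cleavage_after < nchar(pep$residues))
    substr(pep$residues, signal$cleavage_after + 1L, nchar(pep$residues))
  else pep$residues

  motif <- match_ncr_motif(mature, x_allows_cys = x_allows_cys,
                           ncr6_first = ncr6_first)
  cys_total <- sum(strsplit(mature, "")[[1L]] == "C")
  if (cys_total >= 8L)
    motif <- list(label = "DEFENSIN_LIKE", match_span = motif$match_span,
                  cysteine_count = cys_total)
  structure_ <- classify_structure(model, signal, max_terminal_codons)
  pI <- compute_pI(mature, pka)
  start <- min(model$exons)
  structure(list(
    gene_id = model$gene_id,
    mrna_id = model$mrna_id,
    locus_name = name_locus(model$chromosome, start),
    chromosome = model$chromosome,
    start = start,
    strand = model$strand,
    motif = motif,
    structure = structure_,
    signal = signal,
    peptide = pep$residues,
    mature_peptide = mature,
    pI = pI,
    charge_class = classify_charge(pI)),
    class = "peptide_annotation")
}

#' @export
print.peptide_annotation <- function(x, ...) {
  cat(sprintf("<peptide_annotation> %s (%s): %s, %s, %s, pI %.2f (%s)\n",
              x$locus_name, x$gene_id, x$motif$label, x$structure$label,
              if (is.na(x$signal$cleavage_after)) "no signal peptide"
              else sprintf("cleavage after %d", x$signal$cleavage_after),
              x$pI, x$charge_class))
  invisible(x)
}

#' Scan a genome for nodule-peptide genes
#'
#' Annotates every gene model and assembles the catalog. Translation
#' failures (e.g. internal stop codons) become per-gene warnings, not
#' pipeline aborts. When a gene has several mRNAs, the one with a motif hit
#' is kept; ties are broken by longest mature peptide, then mRNA id.
#'
#' @inheritParams annotate_gene
#' @param models list of [gene_model()] objects.
#' @param keep_all keep motif-less genes in the catalog (default `FALSE`:
#'   only NCR4/NCR6/defensin-like rows are returned).
#' @return A data frame of class `"ncr_catalog"` with one row per locus.
#' @export
scan_catalog <- function(models, genome, signal_calls = NULL,
                         pka = pka_table(), x_allows_cys = FALSE,
                         ncr6_first = TRUE, max_terminal_codons = 5L,
                         keep_all = FALSE) {
  anns <- list()
  for (m in models) {
    ann <- tryCatch(
      annotate_gene(m, genome, signal_calls, pka, x_allows_cys,
                    ncr6_first, max_terminal_codons),
      error = function(e) {
        warning("skipping ", m$gene_id, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(ann)) anns[[length(anns) + 1L]] <- ann
  }
  anns <- .collapse_isoforms(anns)
  rows <- lapply(anns, function(a) data.frame(
    locus_name = a$locus_name, gene_id = a$gene_id, mrna_id = a$mrna_id,
    chrom = a$chromosome, start = a$start, strand = a$strand,
    motif_class = a$motif$label, structure_class = a$structure$label,
    cys_count = sum(strsplit(a$mature_peptide, "")[[1L]] == "C"),
    signal_present = !is.na(a$signal$cleavage_after),
    cleavage_after = a$signal$cleavage_after,
    mature_length = nchar(a$mature_peptide),
    pI = a$pI, charge_class = a$charge_class,
    stringsAsFactors = FALSE))
  cat <- do.call(rbind, rows)
  if (is.null(cat))
    cat <- data.frame(locus_name = character(0), gene_id = character(0),
                      mrna_id = character(0), chrom = character(0),
                      start = numeric(0), strand = character(0),
                      motif_class = character(0),
                      structure_class = character(0), cys_count = integer(0),
                      signal_present = logical(0),
                      cleavage_after = integer(0), mature_length = integer(0),
                      pI = numeric(0), charge_class = character(0))
  if (!keep_all)
    cat <- cat[cat$motif_class != "NONE", , drop = FALSE]
  cat <- cat[order(cat$chrom, cat$start, cat$gene_id), , drop = FALSE]
  rownames(cat) <- NULL
  class(cat) <- c("ncr_catalog", "data.frame")
  cat
}

# one annotation per locus: motif hit beats none; then longest mature
# peptide; then mrna_id for determinism
.collapse_isoforms <- function(anns) {
  if (length(anns) < 2L) return(anns)
  ids <- vapply(anns, function(a) a$gene_id, character(1))
  keep <- tapply(seq_along(anns), ids, function(idx) {
    score <- vapply(anns[idx], function(a)
      (a$motif$label != "NONE") * 1e6 + nchar(a$mature_peptide), numeric(1))
    tie <- vapply(anns[idx], function(a) a$mrna_id, character(1))
    idx[order(-score, tie)][1L]
  })
  anns[sort(unname(keep))]
}

#' Summarize a nodule-peptide catalog
#'
#' Counts per motif class, structure class and charge class, plus the
#' percentage of cationic peptides among NCRs (rounded to the nearest
#' integer, as reported; `NA` when the catalog holds no NCR).
#'
#' @param catalog an `ncr_catalog` data frame from [scan_catalog()], or any
#'   data frame with `motif_class`, `structure_class`, `charge_class`
#'   columns.
#' @param expressed optional logical vector flagging expressed loci; when
#'   given, an expressed-loci count is included and the cationic percentage
#'   is computed over expressed NCRs.
#' @return List of class `"ncr_summary"`.
#' @export
summarize_catalog <- function(catalog, expressed = NULL) {
  count_by <- function(col, levels_) {
    tab <- table(factor(catalog[[col]], levels = levels_))
    setNames(as.integer(tab), names(tab))
  }
  motif <- count_by("motif_class",
                    c("NCR4", "NCR6", "DEFENSIN_LIKE", "NONE"))
  struct <- count_by("structure_class",
                     c("TWO_EXON_CANONICAL", "THREE_EXON_3PRIME",
                       "INTRONLESS", "OTHER"))
  charge <- count_by("charge_class", c("CATIONIC", "ANIONIC", "NEUTRAL"))
  is_ncr <- catalog$motif_class %in% c("NCR4", "NCR6")
  sel <- if (is.null(expressed)) is_ncr else is_ncr & expressed
  n_ncr <- sum(sel)
  n_cat <- sum(sel & catalog$charge_class == "CATIONIC")
  structure(list(
    n_total = nrow(catalog),
    n_ncr = sum(is_ncr),
    n_expressed = if (is.null(expressed)) NA_integer_ else sum(expressed),
    motif_counts = motif,
    structure_counts = struct,
    charge_counts = charge,
    percent_cationic = if (n_ncr == 0L) NA_real_ else
      round(100 * n_cat / n_ncr)),
    class = "ncr_summary")
}

#' @export
print.ncr_summary <- function(x, ...) {
  cat("Nodule-peptide catalog summary\n")
  cat("  loci:", x$n_total, " NCR:", x$n_ncr, "\n")
  cat("  motif:  ", paste(names(x$motif_counts), x$motif_counts,
                          sep = "=", collapse = "  "), "\n")
  cat("  struct: ", paste(names(x$structure_counts), x$structure_counts,
                          sep = "=", collapse = "  "), "\n")
  cat("  charge: ", paste(names(x$charge_counts), x$charge_counts,
                          sep = "=", collapse = "  "), "\n")
  cat("  cationic NCR: ",
      if (is.na(x$percent_cationic)) "NA" else
        paste0(x$percent_cationic, "%"), "\n")
  invisible(x)
}

#' Write / read an NCR catalog TSV
#'
#' @param catalog an `ncr_catalog` data frame.
#' @param path TSV path.
#' @return `path` invisibly (writer); catalog data frame (reader).
#' @export
write_catalog <- function(catalog, path) {
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  cat <- read.delim(path, stringsAsFactors = FALSE)
  class(cat) <- c("ncr_catalog", "data.frame")
  cat
}
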