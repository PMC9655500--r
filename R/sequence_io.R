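#' nodpep: nodule peptide annotation and expression analysis
#'
#' Tools for identifying nodule-specific cysteine-rich (NCR) and
#' defensin-like peptide genes in an annotated genome, classifying them by
#' cysteine-spacing motif, signal peptide, exon structure and isoelectric
#' point, and running a quantile-normalization + per-gene ANOVA
#' differential-expression pipeline for nodulated (Nod+) versus
#' uninoculated (Nod-) root transcriptomes, with hypergeometric GO
#' enrichment and a fully deterministic synthetic-data generator.
#'
#' @importFrom stats oneway.test p.adjust phyper cor hclust as.dist rlnorm
#'   rnbinom runif setNames
#' @importFrom utils read.delim write.table head
#' @importFrom graphics plot abline
#' @keywords internal
"_PACKAGE"

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Construct a gene model
#'
#' A gene model is one mRNA: its chromosome, strand, and ordered exon and
#' CDS intervals. Intervals are 1-based closed (GFF3 convention) and are
#' stored in transcription order, i.e. ascending genomic coordinates on the
#' `+` strand and descending on the `-` strand.
#'
#' @param gene_id gene (locus) identifier.
#' @param chromosome chromosome / scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of exon intervals in
#'   transcription order.
#' @param cds two-column matrix (start, end) of CDS intervals in
#'   transcription order; defaults to `exons`.
#' @param cds_phase integer vector of per-CDS-segment phases.
#' @param mrna_id mRNA identifier; defaults to `gene_id`.
#' @return An object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons, cds = exons,
                       cds_phase = rep(0L, nrow(cds)), mrna_id = gene_id) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  exons <- .as_interval_matrix(exons, "exons")
  cds <- .as_interval_matrix(cds, "cds")
  .check_transcription_order(exons, strand, gene_id)
  .check_transcription_order(cds, strand, gene_id)
  structure(
    list(gene_id = gene_id, mrna_id = mrna_id, chromosome = chromosome,
         strand = strand, exons = exons, cds = cds,
         cds_phase = as.integer(cds_phase)),
    class = "gene_model")
}

.as_interval_matrix <- function(x, what) {
  x <- matrix(as.numeric(x), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  if (any(x[, 1L] < 1L))
    stop(what, ": coordinates must be >= 1 (1-based closed intervals)")
  if (any(x[, 1L] > x[, 2L]))
    stop(what, ": interval start exceeds end")
  x
}

.check_transcription_order <- function(iv, strand, gene_id) {
  if (nrow(iv) < 2L) return(invisible(TRUE))
  genomic <- iv[order(iv[, 1L]), , drop = FALSE]
  if (any(genomic[-1L, 1L] <= genomic[-nrow(genomic), 2L]))
    stop(gene_id, ": overlapping intervals")
  ok <- if (strand == "+") all(diff(iv[, 1L]) > 0) else all(diff(iv[, 1L]) < 0)
  if (!ok)
    stop(gene_id, ": intervals not in transcription order for strand ", strand)
  invisible(TRUE)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d strand %s, %d exon(s)\n",
              x$gene_id, x$mrna_id, x$chromosome,
              min(x$exons), max(x$exons), x$strand, nrow(x$exons)))
  invisible(x)
}

#' Read a genome FASTA file
#'
#' Reads a (plain or gzipped) FASTA file into a named character vector of
#' uppercase sequences, keyed by the first whitespace-delimited token of each
#' header.
#'
#' @param path path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  keys <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(keys))
    stop("duplicate FASTA header(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  setNames(toupper(as.character(seqs)), keys)
}

#' Write a genome FASTA file
#'
#' Records are written sorted by name so output is deterministic.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(seqs, path) {
  seqs <- seqs[order(names(seqs))]
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features (1-based closed coordinates) into one
#' [gene_model()] per mRNA. Exon and CDS lists are returned in transcription
#' order: the genomic order is reversed for `-` strand models.
#'
#' @param path path to a GFF3 file.
#' @return List of `gene_model` objects, sorted by (chromosome, start).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID else
    rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(S4Vectors::mcols(gr)))
    vapply(gr$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
  else rep(NA_character_, length(gr))

  is_mrna <- type %in% c("mRNA", "transcript")
  mrna_ids <- ids[is_mrna]
  mrna_parent <- parents[is_mrna]
  kid <- type %in% c("exon", "CDS")
  bad <- kid & (is.na(parents) | !(parents %in% mrna_ids))
  if (any(bad))
    stop("exon/CDS feature(s) without a parent mRNA: ",
         paste(utils::head(unique(parents[bad]), 5L), collapse = ", "))

  out <- vector("list", sum(is_mrna))
  mseq <- as.character(GenomeInfoDb::seqnames(gr))
  mstr <- as.character(BiocGenerics::strand(gr))
  starts <- BiocGenerics::start(gr)
  ends <- BiocGenerics::end(gr)
  phase <- if ("phase" %in% names(S4Vectors::mcols(gr))) gr$phase else
    rep(NA_integer_, length(gr))

  for (i in seq_along(mrna_ids)) {
    mid <- mrna_ids[i]
    sel_m <- which(is_mrna)[i]
    take <- function(feat) {
      j <- which(type == feat & parents == mid)
      j[order(starts[j])]
    }
    je <- take("exon")
    jc <- take("CDS")
    if (length(je) == 0L) je <- sel_m   # exonless annotation: mRNA span
    if (length(jc) == 0L) jc <- je
    strand_i <- mstr[sel_m]
    if (strand_i == "-") {
      je <- rev(je)
      jc <- rev(jc)
    }
    ph <- phase[jc]
    ph[is.na(ph)] <- 0L
    out[[i]] <- gene_model(
      gene_id = if (!is.na(mrna_parent[i])) mrna_parent[i] else mid,
      mrna_id = mid,
      chromosome = mseq[sel_m],
      strand = strand_i,
      exons = cbind(starts[je], ends[je]),
      cds = cbind(starts[jc], ends[jc]),
      cds_phase = ph)
  }
  ord <- order(vapply(out, function(m) m$chromosome, character(1)),
               vapply(out, function(m) min(m$exons), numeric(1)))
  out[ord]
}

#' Write gene models to a GFF3 file
#'
#' Emits gene/mRNA/exon/CDS features, deterministically ordered by
#' (chromosome, start, gene id).
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  ord <- order(vapply(models, function(m) m$chromosome, character(1)),
               vapply(models, function(m) min(m$exons), numeric(1)),
               vapply(models, function(m) m$gene_id, character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, feat, s, e, strand, phase, attr)
    sprintf("%s\tnodpep\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, feat, as.integer(s), as.integer(e), strand, phase, attr)
  for (m in models[ord]) {
    gs <- min(m$exons); ge <- max(m$exons)
    writeLines(c(
      fmt(m$chromosome, "gene", gs, ge, m$strand, ".",
          sprintf("ID=%s", m$gene_id)),
      fmt(m$chromosome, "mRNA", gs, ge, m$strand, ".",
          sprintf("ID=%s;Parent=%s", m$mrna_id, m$gene_id))), con)
    ex <- m$exons[order(m$exons[, 1L]), , drop = FALSE]
    for (k in seq_len(nrow(ex)))
      writeLines(fmt(m$chromosome, "exon", ex[k, 1L], ex[k, 2L], m$strand,
                     ".", sprintf("ID=%s.exon%d;Parent=%s", m$mrna_id, k,
                                  m$mrna_id)), con)
    # phase = (3 - preceding CDS length mod 3) mod 3, in transcription order
    cds_t <- m$cds
    lens <- cds_t[, 2L] - cds_t[, 1L] + 1
    ph_t <- (3L - (cumsum(c(0, lens[-length(lens)])) %% 3L)) %% 3L
    ord_g <- order(cds_t[, 1L])
    for (k in ord_g)
      writeLines(fmt(m$chromosome, "CDS", cds_t[k, 1L], cds_t[k, 2L],
                     m$strand, ph_t[k],
                     sprintf("ID=%s.cds;Parent=%s", m$mrna_id, m$mrna_id)),
                 con)
  }
  invisible(path)
}

#' Translate the CDS of a gene model
#'
#' Concatenates the CDS intervals (reverse-complementing `-` strand models),
#' translates with the standard genetic code, and strips the terminal stop.
#' Ambiguous codons translate to `X`. An internal stop codon is an error
#' (pseudogene-like model); a trailing partial codon is truncated with a
#' warning.
#'
#' @param model a [gene_model()].
#' @param genome named character vector from [read_genome()].
#' @return List with `gene_id`, `residues` (amino-acid string) and
#'   `complete` (`TRUE` if a terminal stop codon was present).
#' @export
translate_cds <- function(model, genome) {
  if (!model$chromosome %in% names(genome))
    stop(model$gene_id, ": chromosome '", model$chromosome,
         "' not in genome")
  chrom <- genome[[model$chromosome]]
  cds <- model$cds[order(model$cds[, 1L]), , drop = FALSE]
  if (max(cds) > nchar(chrom))
    stop(model$gene_id, ": CDS coordinates exceed chromosome length")
  dna <- paste(substring(chrom, cds[, 1L], cds[, 2L]), collapse = "")
  if (model$strand == "-")
    dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  n <- nchar(dna)
  if (n < 3L) stop(model$gene_id, ": CDS shorter than one codon")
  if (n %% 3L != 0L) {
    warning(model$gene_id, ": CDS length ", n,
            " not divisible by 3; truncating trailing partial codon")
    dna <- substr(dna, 1L, n - n %% 3L)
    n <- nchar(dna)
  }
  # vectorized lookup of the standard code; codons with ambiguity letters
  # fall outside the table and translate to X
  codons <- substring(dna, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
  aa_vec <- unname(Biostrings::GENETIC_CODE[codons])
  aa_vec[is.na(aa_vec)] <- "X"
  aa <- paste(aa_vec, collapse = "")
  stops <- gregexpr("\\*", aa)[[1L]]
  complete <- FALSE
  if (stops[1L] != -1L) {
    if (any(stops < nchar(aa)))
      stop(model$gene_id, ": internal stop codon at residue ",
           stops[stops < nchar(aa)][1L], " (pseudogene-like CDS)")
    aa <- substr(aa, 1L, nchar(aa) - 1L)
    complete <- TRUE
  }
  if (nchar(aa) == 0L) stop(model$gene_id, ": empty translation")
  list(gene_id = model$gene_id, residues = aa, complete = complete)
}
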