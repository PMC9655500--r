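# Synthetic genomes, gene models and count matrices with planted ground
# truth, so that the scanner and the DE pipeline can be tested end to end
# without any external download. All randomness flows through R's RNG from
# the single config seed, so every emission is reproducible byte for byte.

#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: two-group root
#' transcriptomes with four replicate plants per group, nodule-peptide genes
#' that are essentially silent in uninoculated roots and very highly
#' expressed in nodulated ones, planted among decoy genes, with
#' negative-binomial count noise.
#'
#' @param seed integer RNG seed.
#' @param n_decoy_genes decoy (non-nodule-peptide) genes.
#' @param n_ncr4,n_ncr6 planted four- and six-cysteine NCR genes.
#' @param n_defensin planted defensin-like (>= 8 cysteine) genes.
#' @param n_intronless_ncr how many of the planted NCRs are intronless.
#' @param chromosome_count chromosomes to distribute genes over.
#' @param replicates_per_group samples per group (default 4).
#' @param de_fraction fraction of decoy genes with a planted expression
#'   difference.
#' @param planted_log2fc absolute log2 fold change planted in DE decoys.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param library_size_range per-sample library-size factor range.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_decoy_genes = 100L, n_ncr4 = 10L,
                       n_ncr6 = 10L, n_defensin = 5L, n_intronless_ncr = 3L,
                       chromosome_count = 2L, replicates_per_group = 4L,
                       de_fraction = 0.05, planted_log2fc = 3,
                       nb_dispersion = 0.1,
                       library_size_range = c(0.8, 1.25)) {
  cfg <- list(seed = as.integer(seed), n_decoy_genes = n_decoy_genes,
              n_ncr4 = n_ncr4, n_ncr6 = n_ncr6, n_defensin = n_defensin,
              n_intronless_ncr = n_intronless_ncr,
              chromosome_count = chromosome_count,
              replicates_per_group = replicates_per_group,
              de_fraction = de_fraction, planted_log2fc = planted_log2fc,
              nb_dispersion = nb_dispersion,
              library_size_range = library_size_range)
  stopifnot(all(unlist(cfg[c("n_decoy_genes", "n_ncr4", "n_ncr6",
                             "n_defensin", "n_intronless_ncr")]) >= 0),
            cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$nb_dispersion > 0, cfg$replicates_per_group >= 2)
  structure(cfg, class = "sim_config")
}

# synonymous codons of the standard code, stops excluded
.codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))[setdiff(unique(gc), "*")]
}

.SIGNAL_PREFIX <- "MKKLLLLLLLLAQA"   # heuristic-satisfying; cleavage after 14

.spacer_alphabet <- function(charge_target) {
  base <- setdiff(AA_ALPHABET, c("C", "X"))
  switch(charge_target,
         cationic = list(letters = base,
                         prob = ifelse(base %in% c("K", "R"), 0.30 / 2,
                                       0.70 / (length(base) - 2))),
         anionic = list(letters = base,
                        prob = ifelse(base %in% c("D", "E"), 0.30 / 2,
                                      0.70 / (length(base) - 2))),
         list(letters = base, prob = rep(1 / length(base), length(base))))
}

.spacer <- function(n, alph) {
  if (n == 0L) return("")
  paste(sample(alph$letters, n, replace = TRUE, prob = alph$prob),
        collapse = "")
}

.mature_peptide <- function(class, charge_target) {
  alph <- .spacer_alphabet(charge_target)
  sp <- function(lo, hi = lo) .spacer(sample(lo:hi, 1L), alph)
  core <- switch(class,
    NCR4 = paste0("C", .spacer(4L, alph), "D", "C", sp(11L, 17L),
                  "C", .spacer(4L, alph), "C"),
    NCR6 = paste0("C", sp(3L, 6L), "C", sp(4L, 7L), "C", sp(4L, 7L),
                  "C", sp(4L, 17L), "C", sp(1L), "C"),
    DEFENSIN_LIKE = paste(c(rbind(rep("C", 10L),
                                  vapply(1:10, function(i) sp(2L, 6L),
                                         character(1)))),
                          collapse = ""),
    stop("cannot build class ", class))
  mature <- paste0(sp(2L), core, sp(3L))
  # push the isoelectric point across the class threshold if targeted
  if (charge_target == "cationic")
    while (compute_pI(mature) <= 9.05) mature <- paste0(mature, "K")
  if (charge_target == "anionic")
    while (compute_pI(mature) >= 3.95) mature <- paste0(mature, "D")
  mature
}

.reverse_translate <- function(peptide, codons) {
  res <- strsplit(peptide, "")[[1L]]
  paste(vapply(res, function(a) {
    opts <- codons[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

.random_intron <- function() {
  n <- sample(76:116, 1L)
  paste0("GT", paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                     collapse = ""), "AG")
}

#' Build one synthetic nodule-peptide gene
#'
#' Emits a DNA sequence and local-coordinate gene model whose translation
#' carries a heuristic-satisfying signal peptide and a mature region
#' matching the requested cysteine motif, with spacer lengths drawn
#' uniformly within the motif bounds and residue composition optionally
#' biased to push the mature pI above 9 (cationic) or below 4 (anionic).
#' Uses the current RNG state; seed outside for reproducibility.
#'
#' @param class `"NCR4"`, `"NCR6"` or `"DEFENSIN_LIKE"`.
#' @param structure `"TWO_EXON_CANONICAL"`, `"THREE_EXON_3PRIME"` or
#'   `"INTRONLESS"`.
#' @param charge_target `"none"`, `"cationic"` or `"anionic"`.
#' @param gene_id identifier for the emitted model.
#' @return List with `dna` (gene-local sequence, `+` orientation), `model`
#'   (a [gene_model()] in gene-local coordinates) and `truth` (one-row data
#'   frame).
#' @export
build_ncr_gene <- function(class = c("NCR4", "NCR6", "DEFENSIN_LIKE"),
                           structure = c("TWO_EXON_CANONICAL",
                                         "THREE_EXON_3PRIME", "INTRONLESS"),
                           charge_target = c("none", "cationic", "anionic"),
                           gene_id = "synthNCR") {
  class <- match.arg(class)
  structure <- match.arg(structure)
  charge_target <- match.arg(charge_target)
  codons <- .codons_by_aa()
  mature <- .mature_peptide(class, charge_target)
  peptide <- paste0(.SIGNAL_PREFIX, mature)
  cds <- paste0(.reverse_translate(peptide, codons), "TGA")
  n <- nchar(cds)
  # first intron one codon after the cleavage site (after codon 15);
  # optional second intron leaving 2 codons + stop in the terminal exon
  cds_lens <- switch(structure,
                     INTRONLESS = n,
                     TWO_EXON_CANONICAL = c(45L, n - 45L),
                     THREE_EXON_3PRIME = c(45L, n - 45L - 9L, 9L))
  pieces <- character(0)
  exons <- matrix(numeric(0), ncol = 2)
  pos <- 1L
  off <- 0L
  for (k in seq_along(cds_lens)) {
    piece <- substr(cds, off + 1L, off + cds_lens[k])
    off <- off + cds_lens[k]
    exons <- rbind(exons, c(pos, pos + cds_lens[k] - 1L))
    pieces <- c(pieces, piece)
    pos <- pos + cds_lens[k]
    if (k < length(cds_lens)) {
      intron <- .random_intron()
      pieces <- c(pieces, intron)
      pos <- pos + nchar(intron)
    }
  }
  dna <- paste(pieces, collapse = "")
  model <- gene_model(gene_id, chromosome = "local", strand = "+",
                      exons = exons)
  truth <- data.frame(gene_id = gene_id, class = class,
                      structure = structure, charge_target = charge_target,
                      nodule_specific = TRUE, stringsAsFactors = FALSE)
  list(dna = dna, model = model, truth = truth)
}

# decoy: composition-shuffled protein-like gene, ~2% cysteine, so false
# motif hits are possible but rare
.build_decoy_gene <- function(gene_id) {
  len <- sample(80:120, 1L)
  alph <- setdiff(AA_ALPHABET, c("C", "X", "M"))
  prob <- c(0.02, rep(0.98 / length(alph), length(alph)))
  body <- paste(sample(c("C", alph), len - 1L, replace = TRUE, prob = prob),
                collapse = "")
  peptide <- paste0("M", body)
  cds <- paste0(.reverse_translate(peptide, .codons_by_aa()), "TGA")
  n <- nchar(cds)
  n_exon <- sample(1:2, 1L)
  if (n_exon == 2L) {
    cut <- 3L * sample(10:(n %/% 3L - 10L), 1L)
    intron <- .random_intron()
    dna <- paste0(substr(cds, 1L, cut), intron, substr(cds, cut + 1L, n))
    exons <- rbind(c(1L, cut),
                   c(cut + nchar(intron) + 1L, nchar(dna)))
  } else {
    dna <- cds
    exons <- rbind(c(1L, n))
  }
  model <- gene_model(gene_id, chromosome = "local", strand = "+",
                      exons = exons)
  truth <- data.frame(gene_id = gene_id, class = "NONE",
                      structure = NA_character_, charge_target = "none",
                      nodule_specific = FALSE, stringsAsFactors = FALSE)
  list(dna = dna, model = model, truth = truth)
}

# shift a gene-local + strand model onto a chromosome at `pos`, flipping
# coordinates for - strand placements
.place_model <- function(local, chrom, pos, strand) {
  L <- max(local$exons)
  flip <- function(iv) {
    out <- cbind(pos + L - iv[, 2L], pos + L - iv[, 1L])
    out[order(-out[, 1L]), , drop = FALSE]
  }
  shift <- function(iv) {
    out <- cbind(pos + iv[, 1L] - 1L, pos + iv[, 2L] - 1L)
    out[order(out[, 1L]), , drop = FALSE]
  }
  gene_model(local$gene_id,
             chromosome = chrom, strand = strand,
             exons = if (strand == "+") shift(local$exons)
             else flip(local$exons),
             cds = if (strand == "+") shift(local$cds) else flip(local$cds),
             mrna_id = paste0(local$gene_id, ".t1"))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with planted nodule-peptide genes
#'
#' Plants the configured numbers of NCR4/NCR6/defensin-like genes (a third
#' of NCRs cationic, one anionic, the rest untargeted; `n_intronless_ncr`
#' intronless, every fifth of the remainder carrying the 3' second intron)
#' among composition-shuffled decoy genes at non-overlapping loci on random
#' strands, with random intergenic spacers.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, `genome.fa`, `genes.gff3`
#'   and `truth.tsv` are written there.
#' @return List with `genome` (named character vector), `models` (list of
#'   [gene_model()]), and `truth` (data frame, one row per gene).
#' @export
simulate_genome <- function(config = sim_config(), outdir = NULL) {
  set.seed(config$seed)
  n_ncr <- config$n_ncr4 + config$n_ncr6
  if (config$n_intronless_ncr > n_ncr)
    stop("n_intronless_ncr exceeds the number of NCR genes")
  classes <- c(rep("NCR4", config$n_ncr4), rep("NCR6", config$n_ncr6))
  structures <- rep("TWO_EXON_CANONICAL", n_ncr)
  if (config$n_intronless_ncr > 0)
    structures[seq_len(config$n_intronless_ncr)] <- "INTRONLESS"
  rest <- which(structures == "TWO_EXON_CANONICAL")
  if (length(rest) >= 5L)
    structures[rest[seq(5L, length(rest), by = 5L)]] <- "THREE_EXON_3PRIME"
  charges <- rep("none", n_ncr)
  if (n_ncr > 0) {
    charges[seq(1L, n_ncr, by = 3L)] <- "cationic"
    charges[n_ncr] <- "anionic"
  }
  specs <- list()
  for (i in seq_len(n_ncr))
    specs[[length(specs) + 1L]] <-
      list(kind = "ncr", class = classes[i], structure = structures[i],
           charge = charges[i])
  for (i in seq_len(config$n_defensin))
    specs[[length(specs) + 1L]] <-
      list(kind = "ncr", class = "DEFENSIN_LIKE",
           structure = "TWO_EXON_CANONICAL", charge = "none")
  for (i in seq_len(config$n_decoy_genes))
    specs[[length(specs) + 1L]] <- list(kind = "decoy")
  if (length(specs) == 0L) stop("config plants no genes")
  specs <- specs[sample.int(length(specs))]

  chrom_names <- sprintf("chr%d", seq_len(config$chromosome_count))
  chrom_seq <- setNames(rep("", length(chrom_names)), chrom_names)
  chrom_of <- rep(chrom_names, length.out = length(specs))
  models <- list()
  truths <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    gid <- sprintf("g%04d", i)
    built <- if (sp$kind == "ncr")
      build_ncr_gene(sp$class, sp$structure, sp$charge, gene_id = gid)
    else .build_decoy_gene(gid)
    chrom <- chrom_of[i]
    gap <- .random_dna(sample(200:400, 1L))
    pos <- nchar(chrom_seq[[chrom]]) + nchar(gap) + 1L
    strand <- sample(c("+", "-"), 1L)
    insert <- if (strand == "+") built$dna else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(built$dna)))
    chrom_seq[[chrom]] <- paste0(chrom_seq[[chrom]], gap, insert)
    model <- .place_model(built$model, chrom, pos, strand)
    models[[length(models) + 1L]] <- model
    tr <- built$truth
    tr$chromosome <- chrom
    tr$start <- min(model$exons)
    tr$strand <- strand
    truths[[length(truths) + 1L]] <- tr
  }
  # trailing intergenic tail on every chromosome
  for (chrom in chrom_names)
    chrom_seq[[chrom]] <- paste0(chrom_seq[[chrom]],
                                 .random_dna(sample(200:400, 1L)))
  truth <- do.call(rbind, truths)
  ord <- order(vapply(models, function(m) m$chromosome, character(1)),
               vapply(models, function(m) min(m$exons), numeric(1)))
  models <- models[ord]
  truth <- truth[order(truth$chromosome, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  out <- list(genome = chrom_seq, models = models, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_genome(chrom_seq, file.path(outdir, "genome.fa"))
    write_gene_models(models, file.path(outdir, "genes.gff3"))
    write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Minimal truth table for counts-only simulations
#'
#' For studies of the DE pipeline alone, creates `n_genes` decoy-class
#' genes with no planted peptide identity.
#'
#' @param n_genes number of genes.
#' @return Data frame compatible with [simulate_counts()].
#' @export
simulate_expression_truth <- function(n_genes) {
  data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
             class = "NONE", structure = NA_character_,
             charge_target = "none", nodule_specific = FALSE,
             stringsAsFactors = FALSE)
}

#' Simulate a two-group count matrix with planted truth
#'
#' Decoy genes draw a log-normal baseline mean; a `de_fraction` of them get
#' a planted log2 fold change of random sign. Nodule-specific genes (the
#' planted peptide loci) emulate the nodule expression profile: near-zero
#' mean in Nod- samples and a high log-normal mean in Nod+ samples. Counts
#' are negative binomial at the configured dispersion, scaled by per-sample
#' library-size factors.
#'
#' @param truth truth data frame from [simulate_genome()] or
#'   [simulate_expression_truth()].
#' @param config a [sim_config()]; counts use RNG seed `config$seed + 1`.
#' @return List with `cm` (a [count_matrix()]) and `truth` augmented with
#'   `baseline`, `true_log2fc` and `true_de` columns.
#' @export
simulate_counts <- function(truth, config = sim_config()) {
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  reps <- config$replicates_per_group
  nod_spec <- truth$nodule_specific
  baseline <- numeric(n)
  mean_minus <- numeric(n)
  mean_plus <- numeric(n)
  true_lfc <- numeric(n)
  true_de <- logical(n)

  idx_decoy <- which(!nod_spec)
  n_de <- round(config$de_fraction * length(idx_decoy))
  de_idx <- if (n_de > 0) sample(idx_decoy, n_de) else integer(0)
  sign_ <- sample(c(-1, 1), length(de_idx), replace = TRUE)

  baseline[idx_decoy] <- rlnorm(length(idx_decoy), log(200), 1.2)
  mean_minus[idx_decoy] <- baseline[idx_decoy]
  mean_plus[idx_decoy] <- baseline[idx_decoy]
  true_lfc[de_idx] <- sign_ * config$planted_log2fc
  true_de[de_idx] <- TRUE
  mean_plus[de_idx] <- baseline[de_idx] * 2^true_lfc[de_idx]

  idx_nod <- which(nod_spec)
  if (length(idx_nod)) {
    mean_minus[idx_nod] <- 0.3
    mean_plus[idx_nod] <- rlnorm(length(idx_nod), log(2000), 1)
    baseline[idx_nod] <- mean_plus[idx_nod]
    true_lfc[idx_nod] <- log2(mean_plus[idx_nod] / mean_minus[idx_nod])
    true_de[idx_nod] <- TRUE
  }

  samples <- c(sprintf("NodP%d", seq_len(reps)),
               sprintf("NodM%d", seq_len(reps)))
  group <- setNames(rep(c("NodPlus", "NodMinus"), each = reps), samples)
  sf <- runif(length(samples), config$library_size_range[1L],
              config$library_size_range[2L])
  mu <- cbind(matrix(rep(mean_plus, reps), ncol = reps),
              matrix(rep(mean_minus, reps), ncol = reps))
  mu <- sweep(mu, 2L, sf, `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu,
                           size = 1 / config$nb_dispersion),
                   nrow = n, dimnames = list(truth$gene_id, samples))
  truth$baseline <- baseline
  truth$true_log2fc <- true_lfc
  truth$true_de <- true_de
  list(cm = count_matrix(counts, group), truth = truth)
}
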