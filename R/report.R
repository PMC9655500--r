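# Report tables shaped like the study's headline outputs, and a one-call
# orchestration of the full pipeline with a reproducible run manifest.

#' Top expressed genes in one group
#'
#' Rows sorted descending by the chosen group's normalized mean (ties
#' broken by gene id, so output is deterministic).
#'
#' @param de an `ncr_de` object from [run_de()], or its `results` frame.
#' @param group `"NodPlus"` (default) or `"NodMinus"`.
#' @param n number of rows (default 20; capped at the row count).
#' @param annotations optional named character vector mapping gene id to a
#'   product annotation.
#' @return Data frame with `gene_id`, `mean_nodminus`, `mean_nodplus`,
#'   `log2fc` and (when supplied) `product`.
#' @export
top_expressed_table <- function(de, group = c("NodPlus", "NodMinus"),
                                n = 20L, annotations = NULL) {
  group <- match.arg(group)
  res <- if (inherits(de, "ncr_de")) de$results else de
  key <- if (group == "NodPlus") res$mean_nodplus else res$mean_nodminus
  ord <- order(-key, res$gene_id)
  out <- res[ord, c("gene_id", "mean_nodminus", "mean_nodplus", "log2fc"),
             drop = FALSE]
  out <- utils::head(out, max(n, 0L))
  if (!is.null(annotations))
    out$product <- unname(annotations[out$gene_id])
  rownames(out) <- NULL
  out
}

#' Most down-regulated genes (Nod- dominant)
#'
#' Rows called `DOWN_IN_NODPLUS`, sorted by the magnitude of the log2 ratio
#' descending. The printed `log2_magnitude` column is unsigned, matching the
#' convention of reporting Nod- dominant genes by magnitude; the signed
#' value is kept in `log2fc`.
#'
#' @inheritParams top_expressed_table
#' @return Data frame with `gene_id`, `mean_nodminus`, `mean_nodplus`,
#'   `log2fc`, `log2_magnitude` and (when supplied) `product`.
#' @export
most_down_table <- function(de, n = 20L, annotations = NULL) {
  res <- if (inherits(de, "ncr_de")) de$results else de
  res <- res[res$call == "DOWN_IN_NODPLUS", , drop = FALSE]
  ord <- order(-abs(res$log2fc), res$gene_id)
  out <- res[ord, c("gene_id", "mean_nodminus", "mean_nodplus", "log2fc"),
             drop = FALSE]
  out$log2_magnitude <- abs(out$log2fc)
  out <- utils::head(out, max(n, 0L))
  if (!is.null(annotations))
    out$product <- unname(annotations[out$gene_id])
  rownames(out) <- NULL
  out
}

.config_hash <- function(params) {
  flat <- paste(names(params), vapply(params, function(p)
    paste(format(p, digits = 12), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # small deterministic polynomial hash; provenance tag, not cryptography
  h <- 0
  for (ch in utf8ToInt(flat)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

.write_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nodpep config_hash=%s", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full nodulation-peptide analysis
#'
#' Orchestrates catalog scan, pI histogram, differential expression,
#' enrichment and the report tables, writing deterministic TSVs (each tagged
#' with a hash of the run configuration) and a run manifest. Any stage
#' failure aborts with the stage name.
#'
#' @param genome named character vector (see [read_genome()]) or FASTA path.
#' @param gff list of gene models (see [read_gene_models()]) or GFF3 path.
#' @param counts a [count_matrix()] or counts TSV path (then `design` must
#'   be the design TSV path or data frame).
#' @param design design data frame / TSV path when `counts` is a matrix or
#'   path.
#' @param go_mapping optional gene-to-term mapping data frame or TSV path;
#'   when present, enrichment of the down-regulated DEGs is run against the
#'   filtered-gene background.
#' @param outdir output directory.
#' @param min_mean,fold,fdr_cutoff DE thresholds (defaults 5, 2, 0.1).
#' @param pka a [pka_table()].
#' @param pi_bin_width width of the pI histogram bins (default 1 pH unit).
#' @param signal_calls optional external signal-peptide calls (see
#'   [annotate_gene()]).
#' @return List with `catalog`, `summary`, `pi_hist`, `de`, `enrichment`,
#'   `top_table`, `down_table` and `manifest`, invisibly.
#' @export
run_report <- function(genome, gff, counts, design = NULL,
                       go_mapping = NULL, outdir, min_mean = 5, fold = 2,
                       fdr_cutoff = 0.1, pka = pka_table(),
                       pi_bin_width = 1, signal_calls = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  input_paths <- c(genome = if (is.character(genome) && length(genome) == 1 &&
                               file.exists(genome)) genome else NA,
                   gff = if (is.character(gff)) gff else NA,
                   counts = if (is.character(counts)) counts else NA)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- stage("read_genome", read_genome(genome))
  if (is.character(gff))
    gff <- stage("read_gene_models", read_gene_models(gff))
  if (is.character(counts)) {
    if (!is.character(design)) stop("stage 'read_counts' failed: design ",
                                    "file required with a counts path")
    counts <- stage("read_counts", read_counts(counts, design))
  } else if (!inherits(counts, "count_matrix")) {
    counts <- stage("count_matrix", count_matrix(counts, design))
  }
  if (is.character(go_mapping))
    go_mapping <- stage("read_go_mapping", read_go_mapping(go_mapping))

  params <- list(min_mean = min_mean, fold = fold, fdr_cutoff = fdr_cutoff,
                 pka = attr(pka, "name"), pi_bin_width = pi_bin_width)
  hash <- .config_hash(params)

  catalog <- stage("scan", scan_catalog(gff, genome,
                                        signal_calls = signal_calls,
                                        pka = pka))
  summary_ <- stage("summarize", summarize_catalog(catalog))
  edges <- seq(floor(min(c(catalog$pI, 4))),
               ceiling(max(c(catalog$pI, 12))), by = pi_bin_width)
  pi_hist <- stage("pi", bin_pI(catalog$pI, edges))
  de <- stage("de", run_de(counts, min_mean = min_mean, fold = fold,
                           fdr_cutoff = fdr_cutoff))
  enr <- NULL
  if (!is.null(go_mapping)) {
    degs <- de$results$gene_id[de$results$call == "DOWN_IN_NODPLUS"]
    degs <- intersect(degs, go_mapping$gene_id)
    if (length(degs))
      enr <- stage("enrich", enrich(degs, de$results$gene_id, go_mapping))
  }
  top <- stage("tables", top_expressed_table(de))
  down <- stage("tables", most_down_table(de))

  .write_tsv(catalog, file.path(outdir, "catalog.tsv"), hash)
  .write_tsv(data.frame(bin = names(pi_hist), count = as.integer(pi_hist)),
             file.path(outdir, "pi_hist.tsv"), hash)
  .write_tsv(de$results, file.path(outdir, "de.tsv"), hash)
  .write_tsv(volcano_table(de), file.path(outdir, "volcano.tsv"), hash)
  .write_tsv(top, file.path(outdir, "top_expressed.tsv"), hash)
  .write_tsv(down, file.path(outdir, "most_down.tsv"), hash)
  if (!is.null(enr)) .write_tsv(enr, file.path(outdir, "enrichment.tsv"),
                                hash)
  dc <- attr(de$results, "deg_counts")
  manifest <- c(
    sprintf("nodpep_version=%s",
            as.character(utils::packageVersion("nodpep"))),
    sprintf("config_hash=%s", hash),
    sprintf("%s=%s", names(params), unlist(lapply(params, format))),
    sprintf("n_loci_catalog=%d", nrow(catalog)),
    sprintf("n_genes_tested=%d", de$params$n_tested),
    sprintf("deg_up=%d", dc[["up"]]), sprintf("deg_down=%d", dc[["down"]]))
  on_disk <- as.character(input_paths[!is.na(input_paths)])
  if (length(on_disk))
    manifest <- c(manifest,
                  sprintf("input_md5_%s=%s",
                          names(input_paths)[!is.na(input_paths)],
                          unname(tools::md5sum(on_disk))))
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(list(catalog = catalog, summary = summary_, pi_hist = pi_hist,
                 de = de, enrichment = enr, top_table = top,
                 down_table = down, manifest = manifest))
}
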