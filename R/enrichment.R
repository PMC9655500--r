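# GO-term over-representation for a DEG list against a background, by the
# upper-tail hypergeometric test (one-sided Fisher), BH-adjusted.

#' GO-term enrichment of a gene list
#'
#' For each term with `k = |input ∩ term| > 0`, `K = |background ∩ term|`,
#' `n = |input|`, `N = |background|`, computes the upper-tail
#' hypergeometric probability `P(X >= k)` and adjusts across tested terms
#' with Benjamini--Hochberg. Terms with no input gene are skipped. Results
#' are sorted by p-value.
#'
#' @param input_genes character vector of genes of interest (e.g. DEGs);
#'   must be a subset of `background_genes`.
#' @param background_genes character vector defining the testing universe
#'   (typically all genes surviving the expression filter).
#' @param mapping data frame with columns `gene_id`, `term_id`, `ontology`
#'   and `description` (one row per gene-term link).
#' @param adjust multiple-testing method (default `"BH"`).
#' @return Data frame with columns `term_id`, `ontology`, `description`,
#'   `n_input`, `n_background`, `p_value`, `fdr`.
#' @export
enrich <- function(input_genes, background_genes, mapping, adjust = "BH") {
  input_genes <- unique(input_genes)
  background_genes <- unique(background_genes)
  missing <- setdiff(input_genes, background_genes)
  if (length(missing))
    stop("input gene(s) absent from background: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  stopifnot(all(c("gene_id", "term_id") %in% names(mapping)))
  if (nrow(mapping) == 0L) stop("empty gene-to-term mapping")
  if (!"ontology" %in% names(mapping)) mapping$ontology <- NA_character_
  if (!"description" %in% names(mapping)) mapping$description <- NA_character_

  mapping <- mapping[mapping$gene_id %in% background_genes, , drop = FALSE]
  N <- length(background_genes)
  n <- length(input_genes)
  terms <- split(mapping, mapping$term_id)
  rows <- lapply(terms, function(tm) {
    genes <- unique(tm$gene_id)
    k <- sum(genes %in% input_genes)
    if (k == 0L) return(NULL)
    K <- length(genes)
    data.frame(term_id = tm$term_id[1L],
               ontology = tm$ontology[1L],
               description = tm$description[1L],
               n_input = k, n_background = K,
               p_value = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), ontology = character(0),
                      description = character(0), n_input = integer(0),
                      n_background = integer(0), p_value = numeric(0),
                      fdr = numeric(0)))
  out$fdr <- p.adjust(out$p_value, method = adjust)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene-to-GO mapping TSV
#'
#' Expects columns `gene_id`, `term_id`, and optionally `ontology` and
#' `description`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_go_mapping <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
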