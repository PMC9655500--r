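# Differential expression between nodulated (Nod+) and uninoculated (Nod-)
# roots: +1 transform, quantile normalization, per-gene one-way ANOVA on
# log2 values, Benjamini-Hochberg FDR, and fold-change + FDR DEG calls.

.GROUPS <- c("NodMinus", "NodPlus")

.normalize_group <- function(g) {
  g <- as.character(g)
  map <- c("NodPlus" = "NodPlus", "Nod+" = "NodPlus", "nodplus" = "NodPlus",
           "NodMinus" = "NodMinus", "Nod-" = "NodMinus",
           "nodminus" = "NodMinus")
  map[paste0("Nod", "\u2212")] <- "NodMinus"   # unicode-minus spelling
  out <- unname(map[g])
  if (anyNA(out))
    stop("unknown group label(s): ",
         paste(unique(g[is.na(out)]), collapse = ", "),
         " (expected NodPlus/NodMinus)")
  out
}

#' Construct a two-group count matrix
#'
#' @param counts numeric matrix of non-negative counts, genes in rows
#'   (rownames = gene ids), samples in columns (colnames = sample ids).
#' @param design data frame with columns `sample_id` and `group`
#'   (`NodPlus`/`NodMinus`, `Nod+`/`Nod-` accepted), or a named character
#'   vector of group labels.
#' @return Object of class `"count_matrix"`: list with `counts` and `group`
#'   (named character vector aligned to columns).
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))
  if (is.data.frame(design)) {
    stopifnot(all(c("sample_id", "group") %in% names(design)))
    design <- setNames(as.character(design$group), design$sample_id)
  }
  if (is.null(colnames(counts))) colnames(counts) <- names(design)
  if (!setequal(colnames(counts), names(design)))
    stop("design samples do not match count-matrix columns")
  group <- .normalize_group(design[colnames(counts)])
  names(group) <- colnames(counts)
  tab <- table(factor(group, levels = .GROUPS))
  if (any(tab < 2L))
    stop("need >= 2 replicates per group; got ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  structure(list(counts = counts, group = group), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(names(table(x$group)), table(x$group), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Read counts and design TSV files
#'
#' The counts file has a `gene_id` column followed by one column per sample;
#' the design file has columns `sample_id` and `group`.
#'
#' @param counts_path,design_path TSV paths.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, design_path) {
  cts <- read.delim(counts_path, stringsAsFactors = FALSE, comment.char = "#")
  des <- read.delim(design_path, stringsAsFactors = FALSE, comment.char = "#")
  m <- as.matrix(cts[, -1L, drop = FALSE])
  rownames(m) <- cts[[1L]]
  count_matrix(m, des)
}

#' Filter genes on minimum average reads
#'
#' A gene is retained iff its raw-count mean over the Nod+ samples or over
#' the Nod- samples reaches `min_mean` (inclusive). Applied on the raw count
#' scale, before the +1/quantile transform.
#'
#' @param cm a [count_matrix()].
#' @param min_mean minimum group mean (default 5).
#' @return A filtered `count_matrix` (gene order preserved).
#' @export
filter_min_reads <- function(cm, min_mean = 5) {
  mp <- rowMeans(cm$counts[, cm$group == "NodPlus", drop = FALSE])
  mm <- rowMeans(cm$counts[, cm$group == "NodMinus", drop = FALSE])
  keep <- mp >= min_mean | mm >= min_mean
  if (!any(keep)) warning("no genes pass the minimum-reads filter")
  structure(list(counts = cm$counts[keep, , drop = FALSE],
                 group = cm$group), class = "count_matrix")
}

#' Add-one transform and quantile normalization
#'
#' Adds 1 to every count (eliminating zeros) and then quantile-normalizes
#' across samples: each sample's k-th order statistic is replaced by the
#' mean of all samples' k-th order statistics, ties receiving the mean of
#' their tied-rank target values.
#'
#' @param cm a [count_matrix()].
#' @return A `count_matrix` whose `counts` are normalized values.
#' @export
transform_counts <- function(cm) {
  x <- cm$counts + 1
  if (ncol(x) == 1L) {
    warning("single sample: quantile normalization is the identity")
    norm <- x
  } else {
    norm <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(norm) <- dimnames(x)
  }
  structure(list(counts = norm, group = cm$group), class = "count_matrix")
}

#' Two-group one-way ANOVA for one gene
#'
#' Equal-variance one-way ANOVA (equivalently a pooled-variance two-sided
#' t-test), p-value from F(1, n1+n2-2). With zero pooled variance, p is 1
#' for equal means and 0 (flagged degenerate) for unequal means.
#'
#' @param values_plus,values_minus log2-scale values per group (>= 2 each).
#' @param var_equal pooled-variance ANOVA (default); `FALSE` gives the
#'   Welch variant.
#' @return p-value with attribute `"degenerate"` when the pooled variance
#'   collapsed.
#' @export
test_gene <- function(values_plus, values_minus, var_equal = TRUE) {
  stopifnot(length(values_plus) >= 2L, length(values_minus) >= 2L)
  if (all(values_plus == values_plus[1L]) &&
      all(values_minus == values_minus[1L])) {
    if (values_plus[1L] == values_minus[1L]) return(1)
    return(structure(0, degenerate = TRUE))
  }
  y <- c(values_plus, values_minus)
  g <- factor(rep(c("plus", "minus"),
                  c(length(values_plus), length(values_minus))))
  unname(oneway.test(y ~ g, var.equal = var_equal)$p.value)
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Step-up adjustment `p_(i) * m / i` with a running minimum from the
#' largest rank, capped at 1, returned in the input order.
#'
#' @param p_values raw p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
adjust_fdr <- function(p_values) {
  stopifnot(all(p_values > 0 & p_values <= 1))
  p.adjust(p_values, method = "BH")
}

#' Signed log2 expression ratio
#'
#' @param mean_plus,mean_minus group means on the normalized (strictly
#'   positive) scale.
#' @return `log2(mean_plus / mean_minus)`.
#' @export
log2_ratio <- function(mean_plus, mean_minus) {
  if (any(mean_plus <= 0) || any(mean_minus <= 0))
    stop("means must be strictly positive on the normalized scale")
  log2(mean_plus / mean_minus)
}

#' Call differentially expressed genes
#'
#' A gene is up-regulated in Nod+ iff `log2fc >= log2(fold)` and
#' `p_adjusted <= fdr_cutoff`; down-regulation is symmetric; everything else
#' is not significant.
#'
#' @param results data frame with `log2fc` and `p_adjusted` columns.
#' @param fold fold-change threshold (default 2).
#' @param fdr_cutoff BH-adjusted p cutoff (default 0.1).
#' @param p_cutoff optional additional raw-p cutoff (`NULL` = off).
#' @return `results` with a `call` column plus attribute `"deg_counts"`
#'   (up, down, not_sig, total).
#' @export
call_degs <- function(results, fold = 2, fdr_cutoff = 0.1, p_cutoff = NULL) {
  lfc <- log2(fold)
  sig <- results$p_adjusted <= fdr_cutoff
  if (!is.null(p_cutoff)) sig <- sig & results$p_value <= p_cutoff
  call <- ifelse(sig & results$log2fc >= lfc, "UP_IN_NODPLUS",
                 ifelse(sig & results$log2fc <= -lfc, "DOWN_IN_NODPLUS",
                        "NOT_SIG"))
  results$call <- call
  attr(results, "deg_counts") <- c(
    up = sum(call == "UP_IN_NODPLUS"),
    down = sum(call == "DOWN_IN_NODPLUS"),
    not_sig = sum(call == "NOT_SIG"),
    total = length(call))
  results
}

#' Run the Nod+ vs Nod- differential-expression pipeline
#'
#' Filters on minimum average raw reads, applies the +1/quantile transform,
#' log2-transforms, runs the per-gene equal-variance ANOVA, adjusts with
#' Benjamini--Hochberg, and calls DEGs at the fold-change + FDR criteria.
#' Group means are reported on the normalized (post-transform) scale.
#'
#' @param cm a [count_matrix()], or a raw counts matrix if `design` given.
#' @param design optional design (see [count_matrix()]).
#' @param min_mean minimum group-mean raw reads (default 5).
#' @param fold fold-change criterion (default 2).
#' @param fdr_cutoff BH-adjusted p criterion (default 0.1).
#' @param var_equal equal-variance ANOVA (default `TRUE`).
#' @param p_cutoff optional extra raw-p cutoff (default `NULL`).
#' @return Object of class `"ncr_de"`: list with `results` (per-gene data
#'   frame), `normalized` (matrix), `group`, and `params`.
#' @export
run_de <- function(cm, design = NULL, min_mean = 5, fold = 2,
                   fdr_cutoff = 0.1, var_equal = TRUE, p_cutoff = NULL) {
  if (!inherits(cm, "count_matrix")) cm <- count_matrix(cm, design)
  n_input <- nrow(cm$counts)
  cm <- filter_min_reads(cm, min_mean)
  tcm <- transform_counts(cm)
  norm <- tcm$counts
  logn <- log2(norm)
  plus <- tcm$group == "NodPlus"
  minus <- tcm$group == "NodMinus"
  mean_plus <- rowMeans(norm[, plus, drop = FALSE])
  mean_minus <- rowMeans(norm[, minus, drop = FALSE])
  p <- numeric(nrow(norm))
  degen <- logical(nrow(norm))
  for (i in seq_len(nrow(norm))) {
    pi_ <- test_gene(logn[i, plus], logn[i, minus], var_equal)
    degen[i] <- isTRUE(attr(pi_, "degenerate"))
    p[i] <- as.numeric(pi_)
  }
  results <- data.frame(
    gene_id = rownames(norm),
    mean_nodminus = mean_minus,
    mean_nodplus = mean_plus,
    log2fc = log2_ratio(mean_plus, mean_minus),
    p_value = p,
    p_adjusted = adjust_fdr(pmax(p, .Machine$double.xmin)),
    degenerate = degen,
    row.names = NULL, stringsAsFactors = FALSE)
  results <- call_degs(results, fold, fdr_cutoff, p_cutoff)
  structure(list(
    results = results,
    normalized = norm,
    group = tcm$group,
    params = list(min_mean = min_mean, fold = fold,
                  fdr_cutoff = fdr_cutoff, var_equal = var_equal,
                  p_cutoff = p_cutoff, n_input = n_input,
                  n_tested = nrow(norm))),
    class = "ncr_de")
}

#' @export
print.ncr_de <- function(x, ...) {
  dc <- attr(x$results, "deg_counts")
  cat("Nod+ vs Nod- differential expression\n")
  cat(sprintf("  %d genes in, %d tested (min mean reads %g)\n",
              x$params$n_input, x$params$n_tested, x$params$min_mean))
  cat(sprintf("  criteria: |fold| >= %g, BH-adjusted p <= %g\n",
              x$params$fold, x$params$fdr_cutoff))
  cat(sprintf("  DEGs: %d (%d up in Nod+, %d down in Nod+)\n",
              dc[["up"]] + dc[["down"]], dc[["up"]], dc[["down"]]))
  invisible(x)
}

#' Summarize a differential-expression fit
#'
#' Prints the thresholds, DEG counts and the top genes by adjusted p.
#'
#' @param object an `ncr_de` object from [run_de()].
#' @param n number of top genes to show (default 10).
#' @param ... unused.
#' @return `object`, invisibly.
#' @method summary ncr_de
#' @export
summary.ncr_de <- function(object, n = 10L, ...) {
  print(object)
  res <- object$results
  top <- res[order(res$p_adjusted, -abs(res$log2fc)), ]
  cat("\nTop genes by adjusted p:\n")
  print(utils::head(top[, c("gene_id", "mean_nodminus", "mean_nodplus",
                            "log2fc", "p_value", "p_adjusted", "call")], n),
        row.names = FALSE, digits = 4)
  invisible(object)
}

#' Volcano plot of a differential-expression fit
#'
#' Signed log2 fold change against -log10 raw p, significant calls in
#' color, fold thresholds dotted.
#'
#' @param x an `ncr_de` object from [run_de()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @method plot ncr_de
#' @export
plot.ncr_de <- function(x, ...) {
  v <- volcano_table(x)
  sig <- x$results$call != "NOT_SIG"
  plot(v$log2fc, v$neg_log10_p, pch = 20,
       col = ifelse(sig, "firebrick", "grey50"),
       xlab = "log2 (Nod+ / Nod-)", ylab = "-log10 p", ...)
  abline(v = c(-log2(x$params$fold), log2(x$params$fold)), lty = 3)
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Average-linkage agglomerative clustering on `1 - Pearson correlation`
#' between samples, computed on log2 normalized values. A zero-variance
#' sample has undefined correlations; its distances are set to 1 with a
#' warning.
#'
#' @param x an `ncr_de` object or a normalized matrix (genes x samples).
#' @return An [stats::hclust] dendrogram.
#' @export
cluster_samples <- function(x) {
  mat <- if (inherits(x, "ncr_de")) x$normalized else as.matrix(x)
  if (ncol(mat) < 3L) stop("need >= 3 samples to cluster")
  logm <- log2(mat)
  cc <- suppressWarnings(cor(logm))
  if (anyNA(cc)) {
    warning("zero-variance sample(s): undefined correlations set to 0 ",
            "(distance 1)")
    cc[is.na(cc)] <- 0
  }
  d <- as.dist(1 - cc)
  hclust(d, method = "average")
}

#' Volcano-plot table
#'
#' One row per tested gene: signed log2 fold change and `-log10` of the raw
#' p-value. No thresholds are applied.
#'
#' @param x an `ncr_de` object or its `results` data frame.
#' @return Data frame with `gene_id`, `log2fc`, `neg_log10_p`.
#' @export
volcano_table <- function(x) {
  res <- if (inherits(x, "ncr_de")) x$results else x
  data.frame(gene_id = res$gene_id,
             log2fc = res$log2fc,
             neg_log10_p = -log10(res$p_value),
             stringsAsFactors = FALSE)
}
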