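---
title: "Methods: nodule-peptide annotation and Nod+/Nod- expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nodule-peptide annotation and Nod+/Nod- expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodpep)
```

## The biological problem

Legumes of the inverted-repeat-lacking clade (IRLC) — *Medicago*,
*Trifolium*, *Pisum* and relatives — drive their rhizobial symbionts into
terminal differentiation inside root nodules. The plant side of that
program is dominated by large families of small secreted peptides, chief
among them the nodule-specific cysteine-rich (NCR) peptides: short,
signal-peptide-bearing proteins carrying four or six cysteines in a
conserved spacing, expressed essentially only in nodulated (Nod+) roots.
Their highly cationic members (isoelectric point above 9) are candidate
antimicrobials. Related cysteine-rich families with eight or more
cysteines behave like defensins and are conventionally kept apart from the
NCRs.

`nodpep` implements the full desk-side workflow around these families:

1. motif-based discovery and classification of NCR and defensin-like genes
   from a genome FASTA + GFF3 annotation (`scan_catalog()`);
2. peptide chemistry: isoelectric point by charge-curve bisection and
   cationic/anionic classification (`compute_pI()`, `classify_charge()`);
3. a two-group differential-expression pipeline for Nod+ versus Nod-
   root counts (`run_de()`);
4. hypergeometric GO-term enrichment (`enrich()`);
5. a deterministic synthetic-data generator with planted ground truth
   (`simulate_genome()`, `simulate_counts()`), which is what makes every
   stage testable without the source assembly.

## Motif model

The cysteine-spacing consensus is matched as a regular expression on the
mature peptide:

* four-cysteine class: `C-(X4)-DC-(X11-17)-C-(X4)-C`
* six-cysteine class: `C-(X3-6)-C-(X4-7)-C-(X4-7)-C-(X4-17)-C-(X1)-C`

Two conventions needed fixing where the consensus notation is silent:

* **`X` excludes cysteine** by default. This keeps the conserved cysteine
  count of a match exact (4 or 6) and prevents a six-cysteine peptide from
  silently satisfying the four-cysteine pattern through an internal
  cysteine. `match_ncr_motif(x_allows_cys = TRUE)` restores the permissive
  reading.
* **The six-cysteine pattern is tested first** (six-cysteine peptides can
  contain four-cysteine sub-patterns); `ncr6_first = FALSE` flips the
  precedence.
* Spacing bounds are treated as inclusive on both ends.

A mature peptide with eight or more cysteines is classified
`DEFENSIN_LIKE` regardless of any NCR motif hit — cysteine count, not
spacing, is what separates the defensin-like family.

Ambiguous nucleotides translate to `X`, and `X` never matches where a
cysteine is required, which biases classification conservatively.

## Signal peptides and gene structure

Signal-peptide prediction is an interface, not a dependency: per-gene
calls from an external predictor can be supplied as a table
(`annotate_gene(signal_calls = ...)`), and a built-in heuristic is the
default. The heuristic applies three classic rules to candidate cleavage
sites `c = 8..45`, earliest site first: a K/R in the first five residues
(n-region), at least six of eight hydrophobic residues in the window
ending at the site (h-region; we define the window as positions
`c-7..c`, so the earliest legal site still has a full window), and small
residues at the -3 and -1 positions. It is a deliberately transparent
stand-in — the point is a reproducible, dependency-free default whose
rules the tests can re-apply independently, not a re-implementation of a
trained predictor.

Gene structure is classified from the exon count: the canonical NCR gene
has two exons with the intron near the signal-peptide cleavage site
(the offset in residues is reported); three-exon genes qualify as the
3'-intron class only when the terminal exon encodes at most
`max_terminal_codons = 5` codons before the stop ("one to a few codons"
is not a number; five is our cut, exposed as an argument); single-exon
genes are intronless; everything else is `OTHER`.

When a locus has several mRNAs, one annotation is kept per locus: a
motif-bearing isoform beats a motif-less one, ties go to the longest
mature peptide, then to the lexicographically first mRNA id. Genes that
match a motif but lack a signal peptide are retained and flagged, since
expressed signal-less NCRs are a real (minority) class.

## Isoelectric point

Net charge at a given pH is the standard Henderson–Hasselbalch sum over
basic groups (N-terminus, K, R, H) and acidic groups (C-terminus, D, E,
C, Y). The pI is found by bisection on pH ∈ [0.5, 13.5]. The charge curve
is strictly decreasing, so the root is unique; bisection stops only when
*both* the bracketing interval and the residual charge at the midpoint
are below `tol = 1e-3`. The second condition matters: on peptides with
many ionizable groups the charge curve is steep, and an interval
criterion alone does not bound the residual charge.

The pKa value set is a real degree of freedom — published pI catalogs
differ by tenths of a pH unit depending on the set — so it is exposed:
EMBOSS values are the default, the Bjellqvist set ships as an
alternative, and a custom table is accepted
(`pka_table()`). Charge classes use strict thresholds as conventionally
stated: cationic means pI > 9.0, anionic means pI < 4.0, boundary values
are neutral. Because the pKa set is a choice, cross-catalog percentage
comparisons (e.g. fraction cationic) are robust to it only near the
thresholds; the tests therefore check threshold semantics and oracle
agreement, not absolute pI values.

pI is computed on the mature peptide when a cleavage site exists, else on
the full translated peptide.

## Differential expression

The pipeline follows a deliberately simple, fully specified procedure:

1. **Filter**: keep a gene iff its *raw* mean over Nod+ samples or over
   Nod- samples is ≥ 5 (inclusive). Filtering is applied on the raw count
   scale before any transform — the plain reading of "average reads" —
   and the threshold is an argument.
2. **Transform**: add 1 to every count (eliminating zeros), then quantile
   normalization: each sample's k-th order statistic is replaced by the
   mean of all samples' k-th order statistics, ties receiving the mean of
   their tied-rank targets (`limma::normalizeQuantiles(ties = TRUE)`
   semantics). Normalization happens on the count scale and log2 is taken
   afterwards for testing.
3. **Test**: per gene, equal-variance one-way ANOVA on log2 normalized
   values — identical to a pooled-variance two-sided t-test, with p from
   F(1, n1+n2-2). A Welch variant sits behind `var_equal = FALSE`. Zero
   pooled variance is handled explicitly: p = 1 for equal means, p = 0
   with a degeneracy flag otherwise.
4. **Adjust**: Benjamini–Hochberg step-up.
5. **Call**: up-regulated in Nod+ iff log2 fold change ≥ log2(2) and
   BH-adjusted p ≤ 0.1; down symmetric. The single operative significance
   rule is the BH-adjusted p; an optional raw-p cutoff exists
   (`p_cutoff`) because published descriptions of such workflows
   sometimes quote a raw-p threshold alongside the FDR one, and the two
   are not always mutually consistent.

Group means in all reports are means of normalized (post-transform)
values, which is the scale on which published expression tables print
them. Signed log2 ratios are kept internally; the "most down-regulated"
report table prints magnitudes, following the convention of reporting
Nod--dominant genes by the size of the change.

Sample clustering is average-linkage agglomerative clustering on
1 − Pearson correlation between samples over log2 normalized values.
A zero-variance sample has no defined correlation; its distances fall
back to 1 with a warning.

## Enrichment

GO over-representation is the upper-tail hypergeometric test (one-sided
Fisher) per term, BH-adjusted across tested terms; terms without input
genes are skipped. The gene-to-term mapping is taken as given — no
GO-graph ancestor propagation — because species GO lists of the kind this
module consumes are typically already flattened. The recommended
background is the set of genes surviving the expression filter, not the
whole genome; the background is an explicit argument, since this choice
moves p-values substantially and is rarely recoverable from published
enrichment tables. BH replaces the Yekutieli correction some enrichment
servers default to, for consistency with the DE module.

## The synthetic-data generator

`simulate_genome()` plants NCR4/NCR6/defensin-like genes — built
base-by-base to satisfy the motif, the signal heuristic and the requested
exon structure — among decoy genes on random strands with random
intergenic spacers, and emits FASTA, GFF3 and a truth table.
`simulate_counts()` emulates the corresponding expression study:
four replicate samples per group by default; decoy genes draw log-normal
baselines (log-mean log 200, log-sd 1.2, so almost all pass the
minimum-reads filter); a configurable fraction of decoys gets a planted
log2 fold change of ±3; planted peptide loci are "nodule-specific" —
near-zero mean (0.3) in Nod- samples and a high log-normal mean
(log-mean log 2000) in Nod+ — mirroring the defining expression profile
of these families; counts are negative binomial at dispersion 0.1 with
per-sample library-size factors in [0.8, 1.25]. Negative binomial is the
accepted bulk RNA-seq noise model and stresses the pipeline realistically
even though the tested procedure makes no distributional claim.

Decoys are composition-shuffled protein-like sequences of 80–120 residues
with ~2% cysteine: long and cysteine-rich enough that false motif hits
and accidental eight-cysteine decoys are *possible* (otherwise
specificity tests are vacuous), rare enough (binomial tail ~0.1% per
decoy) that they do not dominate. Everything is driven by R's RNG from
the single config seed (`simulate_counts` uses seed + 1 so genome and
counts draws do not overlap), making all emissions byte-identical across
runs.

One scale caveat: the default genome configuration (25 planted peptide
genes among 100 decoys) is sized for *motif-recovery* testing, not for
expression realism. Feeding its 125 genes straight into the DE pipeline
puts ~20% of the transcriptome under massive planted change, which
violates the central assumption of quantile normalization (most genes
unchanged) and inflates false calls on the remainder — a real property
of quantile normalization, faithfully reproduced. Expression-side
calibration therefore uses counts-only truth tables
(`simulate_expression_truth()`) at a realistic differential fraction
(5% by default, against ~2% nodule-specific genes in a real IRLC
transcriptome).

What the generator does *not* emulate — and therefore what passing
recovery tests do not show about real data: alternative splicing and
isoform collapsing at real loci, UTRs and non-coding overlap,
pseudogenes, GC/codon biases, batch effects, library-size extremes, and
real signal peptides as a trained predictor would see them. The planted
signal peptides satisfy the built-in heuristic by construction, so
recovery tests validate the pipeline's plumbing and statistics, not
signal-peptide prediction accuracy.

## Numerical choices and degenerate inputs

* pI bisection: interval *and* residual-charge stopping rule at 1e-3
  (see above); deterministic, at most 60 iterations.
* Quantile normalization: the "identical sorted columns" identity is
  exact only on tie-free data; with ties, tied entries share the mean of
  their tied-rank targets by design.
* BH p-values of exactly 0 (degenerate-variance genes) are floored to the
  smallest positive double before adjustment.
* `call_degs` conservation (up + down + not-significant = tested) holds
  structurally for every input.
* Empty catalogs, empty filters, single samples and zero-variance samples
  warn rather than abort; translation failures (internal stop codons)
  are per-gene warnings during a scan.
* Locus names are `Tp{chromosome}_{start}`, deterministic and ordered
  like the genome.

## Problem sizes in the shipped tests

The suite exercises the scanner/oracle equivalence on 10,000 random
60-mers, pI bisection against a 0.001-step grid on 500 random peptides,
genome-scale recovery on the default configuration (25 planted genes
among 100 decoys, plus a 400-decoy specificity run), and DE recovery and
null calibration on 1000- and 500-gene count matrices over 10 seeds each.
These sizes give stable empirical rates for the properties being checked
(decoy false-positive rate below 1%, DE sensitivity ≥ 0.9, empirical FDR
≤ 0.15 at a nominal 0.1) while keeping the whole suite fast.

## Known limitations

* The motif scanner is a stand-in for HMM-based peptide gene finding; it
  will not discover loci absent from the supplied annotation.
* The built-in signal heuristic is intentionally crude; for production
  catalogs, feed external predictions through `signal_calls`.
* Absolute pI values depend on the pKa set; only threshold-based classes
  are comparable across tools.
* The enrichment module does not model GO term-term structure.
* Published catalog totals for any particular assembly depend on that
  assembly and its annotation; this package reproduces the *procedure*
  and validates it on planted truth.
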