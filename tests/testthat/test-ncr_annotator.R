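test_that("motif scanner recognizes hand-built NCR4 and rejects no-cys", {
  pep <- "CAAAADCAAAAAAAAAAACAAAAC"  # C-X4-DC-X11-C-X4-C
  hit <- match_ncr_motif(pep)
  expect_identical(hit$label, "NCR4")
  expect_equal(unname(hit$match_span), c(1, 24))
  expect_identical(hit$cysteine_count, 4L)

  expect_identical(match_ncr_motif("GGGGGGGG")$label, "NONE")
  expect_error(match_ncr_motif("ACDB"), "unknown residue")
})

test_that("six-cysteine motif takes precedence and counts six cysteines", {
  pep6 <- paste0("MM", "C", "AAAA", "C", "AAAAA", "C", "GGGGG", "C",
                 "KKKKKK", "C", "A", "C", "WW")
  hit <- match_ncr_motif(pep6)
  expect_identical(hit$label, "NCR6")
  expect_identical(hit$cysteine_count, 6L)
})

test_that("motif scanner agrees with the cysteine-tuple oracle", {
  set.seed(31)
  for (i in 1:500) {
    pep <- random_peptide(60, cys_prob = sample(c(NA, 0.12, 0.2), 1))
    expect_identical(match_ncr_motif(pep)$label, oracle_motif(pep),
                     label = paste("peptide", pep))
  }
})

test_that("signal-peptide heuristic follows the three rules", {
  pep <- paste0("MKK", strrep("L", 10), "AQA", "CDDDDDDDDDD")
  call <- predict_signal_peptide(pep)
  expect_identical(call$cleavage_after, oracle_signal(pep))
  expect_identical(call$cleavage_after, 16L)  # the A of AQA
  expect_identical(call$score, 1)

  # all-aspartate peptide: no n- or h-region possible
  expect_true(is.na(predict_signal_peptide(strrep("D", 30))$cleavage_after))
  # below the minimum length
  expect_true(is.na(predict_signal_peptide("MKKLLLLLLA")$cleavage_after))
})

test_that("signal-peptide heuristic matches the rule oracle on random input", {
  set.seed(37)
  for (i in 1:300) {
    pep <- paste0(sample(c("M", "MK", "MR", "MD"), 1),
                  random_peptide(sample(15:60, 1)))
    expect_identical(predict_signal_peptide(pep)$cleavage_after,
                     oracle_signal(pep), label = pep)
  }
})

test_that("structure classes follow exon counts and terminal-exon length", {
  sig <- list(cleavage_after = 24L)
  two <- gene_model("g", "chr1", "+", exons = rbind(c(1, 75), c(176, 300)))
  cls <- classify_structure(two, sig)
  expect_identical(cls$label, "TWO_EXON_CANONICAL")
  expect_equal(cls$intron1_offset_from_cleavage, 1)  # codon 25 vs residue 24

  three <- gene_model("g", "chr1", "+",
                      exons = rbind(c(1, 75), c(176, 291), c(392, 400)))
  expect_identical(classify_structure(three, sig)$label,
                   "THREE_EXON_3PRIME")  # 9 nt terminal exon: 2 codons + stop

  big_term <- gene_model("g", "chr1", "+",
                         exons = rbind(c(1, 75), c(176, 291), c(392, 451)))
  expect_identical(classify_structure(big_term, sig)$label, "OTHER")

  one <- gene_model("g", "chr1", "+", exons = cbind(1, 300))
  expect_identical(classify_structure(one, sig)$label, "INTRONLESS")
})

test_that("locus names are deterministic and sort genomically", {
  expect_identical(name_locus(3, 123916883), "Tp3_123916883")
  expect_identical(name_locus("chr3", 123916883), "Tp3_123916883")
  expect_identical(name_locus(3, 123916883), name_locus(3, 123916883))

  set.seed(41)
  chrom <- sample(1:8, 50, TRUE)
  start <- sample(1e3:1e8, 50)
  names <- name_locus(chrom, start)
  ord <- order(chrom, start)
  key <- as.numeric(sub("Tp(\\d+)_.*", "\\1", names)) * 1e9 +
    as.numeric(sub("Tp\\d+_", "", names))
  expect_identical(order(key), ord)
})

test_that("annotate_gene recovers planted classes and flags decoys", {
  set.seed(43)
  ncr <- build_ncr_gene("NCR4", "TWO_EXON_CANONICAL", "cationic",
                        gene_id = "planted")
  genome <- setNames(ncr$dna, "local")
  ann <- annotate_gene(ncr$model, genome)
  expect_identical(ann$motif$label, "NCR4")
  expect_identical(ann$structure$label, "TWO_EXON_CANONICAL")
  expect_false(is.na(ann$signal$cleavage_after))
  expect_identical(ann$charge_class, "CATIONIC")

  def <- build_ncr_gene("DEFENSIN_LIKE", "TWO_EXON_CANONICAL", "none",
                        gene_id = "def")
  ann_def <- annotate_gene(def$model, setNames(def$dna, "local"))
  expect_identical(ann_def$motif$label, "DEFENSIN_LIKE")
  expect_gte(ann_def$motif$cysteine_count, 8L)
})

test_that("external signal calls replace the heuristic", {
  set.seed(47)
  ncr <- build_ncr_gene("NCR6", "TWO_EXON_CANONICAL", "none", gene_id = "g9")
  genome <- setNames(ncr$dna, "local")
  ext <- data.frame(gene_id = "g9", cleavage_after = 10L)
  ann <- annotate_gene(ncr$model, genome, signal_calls = ext)
  expect_identical(ann$signal$method, "external")
  expect_identical(ann$signal$cleavage_after, 10L)
  expect_identical(nchar(ann$mature_peptide), nchar(ann$peptide) - 10L)
})

test_that("catalog scan keeps motif-less genes out and one row per locus", {
  sim <- tiny_genome_sim(seed = 17)
  catalog <- scan_catalog(sim$models, sim$genome)
  planted <- sim$truth[sim$truth$nodule_specific, ]
  merged <- merge(planted, catalog, by = "gene_id")
  expect_identical(nrow(merged), nrow(planted))
  expect_identical(merged$motif_class, merged$class)
  expect_identical(merged$structure_class, merged$structure)
  expect_false(any(duplicated(catalog$gene_id)))

  full <- scan_catalog(sim$models, sim$genome, keep_all = TRUE)
  expect_identical(nrow(full), nrow(sim$truth))
  expect_true(all(full$motif_class %in%
                    c("NCR4", "NCR6", "DEFENSIN_LIKE", "NONE")))
})

test_that("catalog summary counts classes and the cationic percentage", {
  catalog <- data.frame(
    motif_class = c(rep("NCR4", 300), rep("NCR6", 160), rep("DEFENSIN_LIKE", 25)),
    structure_class = "TWO_EXON_CANONICAL",
    charge_class = c(rep("CATIONIC", 149), rep("NEUTRAL", 310),
                     rep("ANIONIC", 1), rep("NEUTRAL", 25)))
  s <- summarize_catalog(catalog)
  expect_identical(s$n_ncr, 460L)
  expect_identical(unname(s$charge_counts["CATIONIC"]), 149L)
  expect_identical(s$percent_cationic, 32)

  s0 <- summarize_catalog(catalog[0, ])
  expect_true(is.na(s0$percent_cationic))
  expect_identical(s0$n_total, 0L)
})
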