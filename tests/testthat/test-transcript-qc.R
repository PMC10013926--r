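# reference: one gene, two isoforms sharing junctions, on each strand
qc_reference <- function() {
  make_models(list(
    list(id = "r1", gene = "gA", chrom = "chr1", strand = "+",
         exons = cbind(c(1001, 2001, 3001, 4001), c(1200, 2200, 3200, 4200))),
    list(id = "r2", gene = "gA", chrom = "chr1", strand = "+",
         exons = cbind(c(2001, 3001, 4001, 5001), c(2200, 3200, 4200, 5200)))))
}

test_that("splice classes follow chain / sub-chain / catalog membership", {
  ref <- qc_reference()
  q <- make_models(list(
    # chain equal to r1 (different end exon lengths): FSM
    list(id = "qf", gene = "gA", chrom = "chr1", strand = "+",
         exons = cbind(c(1101, 2001, 3001, 4001), c(1200, 2200, 3200, 4500))),
    # consecutive sub-chain of r1: ISM
    list(id = "qi", gene = "gA", chrom = "chr1", strand = "+",
         exons = cbind(c(2001, 3001), c(2200, 3200))),
    # combines r1's first junction with r2's last: NIC
    list(id = "qn", gene = "gA", chrom = "chr1", strand = "+",
         exons = cbind(c(1001, 2001, 3001, 4001, 5001),
                       c(1200, 2200, 3200, 4200, 5200))),
    # novel acceptor: NNC
    list(id = "qx", gene = "gA", chrom = "chr1", strand = "+",
         exons = cbind(c(1001, 2051), c(1200, 2200))),
    # no gene-body overlap: intergenic
    list(id = "qo", gene = "gB", chrom = "chr1", strand = "+",
         exons = cbind(c(90001, 91001), c(90200, 91200)))))
  cls <- classify_splice_match(q, ref)
  got <- setNames(as.character(cls$class), cls$transcript_id)
  expect_equal(got[c("qf", "qi", "qn", "qx", "qo")],
               c(qf = "FSM", qi = "ISM", qn = "NIC", qx = "NNC",
                 qo = "intergenic"))
  expect_equal(cls$matched_ref[cls$transcript_id == "qf"], "r1")
})

test_that("mono-exonic queries: exon containment, genic overlap, intergenic", {
  ref <- qc_reference()
  q <- make_models(list(
    list(id = "m1", gene = "gA", chrom = "chr1", strand = "+",
         exons = cbind(2050, 2150)),          # inside r1 exon 2
    list(id = "m2", gene = "gA", chrom = "chr1", strand = "-",
         exons = cbind(2050, 2150)),          # wrong strand: not FSM
    list(id = "m3", gene = "gA", chrom = "chr1", strand = "+",
         exons = cbind(2300, 2600)),          # intronic: genic but no exon
    list(id = "m4", gene = "gB", chrom = "chr1", strand = "+",
         exons = cbind(70001, 70400))))       # off gene
  cls <- classify_splice_match(q, ref)
  got <- setNames(as.character(cls$class), cls$transcript_id)
  expect_equal(unname(got[c("m1", "m2", "m3", "m4")]),
               c("FSM", "NNC", "NNC", "intergenic"))
})

test_that("classifier agrees with brute-force sub-chain enumeration", {
  for (seed in c(101, 202, 303)) {
    tr <- random_transcriptome(seed, n_ref = sample(10:50, 1))
    multi <- tr$query$tx$transcript_id[tr$query$tx$n_exons > 1]
    q <- subset_models(tr$query, multi)
    got <- classify_splice_match(q, tr$reference)
    want <- bf_classify(q, tr$reference)
    expect_equal(as.character(got$class), unname(want))
    # FSM and ISM are mutually exclusive, every query gets exactly one class
    expect_false(anyNA(got$class))
  }
})

test_that("support filters remove transcripts sequentially with counts", {
  m <- make_models(lapply(1:5, function(i) {
    g0 <- i * 10000
    list(id = paste0("t", i), gene = paste0("g", i), chrom = "chr1",
         strand = "+", exons = cbind(c(g0, g0 + 1000), c(g0 + 200, g0 + 1200)))
  }))
  sup <- data.frame(
    transcript_id = paste0("t", 1:5),
    fl_count = c(1, 5, 5, 5, 5),
    n_samples = c(3, 1, 2, 2, 2),
    min_junction_cov = c(5, 5, 0, 5, 5),
    has_coverage = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  res <- support_filters(m, sup)
  expect_equal(unname(res$removed), c(1L, 1L, 1L, 1L))
  expect_equal(res$retained, "t5")
  expect_error(support_filters(m, sup[-1, ]), "missing support")
})

test_that("intra-priming boundary is inclusive at 16 of 20 adenines", {
  seqs <- c(
    paste0(strrep("C", 100), strrep("A", 16), strrep("C", 84)),
    paste0(strrep("C", 100), strrep("A", 15), strrep("C", 85)))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- c("chrA", "chrB")
  m <- make_models(list(
    list(id = "hit", gene = "g1", chrom = "chrA", strand = "+",
         exons = cbind(50, 100)),   # window 101..120: 16 A, 4 C
    list(id = "miss", gene = "g2", chrom = "chrB", strand = "+",
         exons = cbind(50, 100))))  # window: 15 A
  flags <- intra_priming_flag(m, genome)
  expect_true(flags[["hit"]])
  expect_false(flags[["miss"]])
})

test_that("intra-priming is strand-symmetric under reverse complement", {
  set.seed(17)
  L <- 2000L
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c(0.4, 0.2, 0.2, 0.2))
  genome <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(genome) <- "chr1"
  starts <- seq(100, 1700, by = 200)
  fwd <- make_models(lapply(seq_along(starts), function(i) {
    list(id = paste0("t", i), gene = paste0("g", i), chrom = "chr1",
         strand = "+", exons = cbind(starts[i], starts[i] + 99))
  }))
  # mirror: position x -> L - x + 1, strand flipped, genome reverse-complemented
  rc_genome <- Biostrings::reverseComplement(genome)
  names(rc_genome) <- "chr1"
  rev <- make_models(lapply(seq_along(starts), function(i) {
    list(id = paste0("t", i), gene = paste0("g", i), chrom = "chr1",
         strand = "-", exons = cbind(L - (starts[i] + 99) + 1,
                                     L - starts[i] + 1))
  }))
  expect_identical(intra_priming_flag(fwd, genome),
                   intra_priming_flag(rev, rc_genome))
})

test_that("5'-degraded transcripts collapse into suffix-matching longer ones", {
  m <- make_models(list(
    list(id = "long", gene = "g", chrom = "chr1", strand = "+",
         exons = cbind(c(1001, 2001, 3001), c(1200, 2200, 3200))),
    list(id = "short", gene = "g", chrom = "chr1", strand = "+",
         exons = cbind(c(2001, 3001), c(2200, 3200))),
    list(id = "shorter", gene = "g", chrom = "chr1", strand = "+",
         exons = cbind(3050, 3200))))  # mono-exonic, in 3'-terminal exon
  col <- collapse_5prime_degraded(m)
  expect_equal(col$models$tx$transcript_id, "long")
  expect_equal(sort(col$mapping$representative), rep("long", 3))
  # different TTS: both kept
  m2 <- make_models(list(
    list(id = "a", gene = "g", chrom = "chr1", strand = "+",
         exons = cbind(c(1001, 2001), c(1200, 2200))),
    list(id = "b", gene = "g", chrom = "chr1", strand = "+",
         exons = cbind(c(1001, 2001), c(1200, 2250)))))
  expect_equal(nrow(collapse_5prime_degraded(m2)$models$tx), 2L)
  # non-suffix chain with identical TTS: kept
  m3 <- make_models(list(
    list(id = "a", gene = "g", chrom = "chr1", strand = "+",
         exons = cbind(c(1001, 2001, 3001), c(1200, 2200, 3200))),
    list(id = "b", gene = "g", chrom = "chr1", strand = "+",
         exons = cbind(c(1001, 2051, 3001), c(1200, 2200, 3200)))))
  expect_equal(nrow(collapse_5prime_degraded(m3)$models$tx), 2L)
  # minus strand: 3' end is the genomic left; suffix is the genomic-left chain
  m4 <- make_models(list(
    list(id = "L", gene = "g", chrom = "chr1", strand = "-",
         exons = cbind(c(1001, 2001, 3001), c(1200, 2200, 3200))),
    list(id = "S", gene = "g", chrom = "chr1", strand = "-",
         exons = cbind(c(1001, 2001), c(1200, 2200)))))
  col4 <- collapse_5prime_degraded(m4)
  expect_equal(col4$models$tx$transcript_id, "L")
})

test_that("TTS distances are signed strand-aware", {
  ref <- make_models(list(
    list(id = "rp", gene = "g1", chrom = "chr1", strand = "+",
         exons = cbind(c(1001, 2001), c(1200, 2200))),
    list(id = "rm", gene = "g2", chrom = "chr1", strand = "-",
         exons = cbind(c(9001, 10001), c(9200, 10200)))))
  q <- make_models(list(
    list(id = "qp", gene = "g1", chrom = "chr1", strand = "+",
         exons = cbind(c(1001, 2001), c(1200, 3200))),   # +1000 extension
    list(id = "qe", gene = "g1", chrom = "chr1", strand = "+",
         exons = cbind(c(1001, 2001), c(1200, 2200))),   # identical
    list(id = "qm", gene = "g2", chrom = "chr1", strand = "-",
         exons = cbind(c(8501, 10001), c(9200, 10200)))))# 3' extension on -
  mt <- data.frame(transcript_id = c("qp", "qe", "qm"),
                   matched_ref = c("rp", "rp", "rm"))
  d <- tts_distance(q, ref, mt)
  expect_equal(unname(d), c(1000, 0, 500))
  expect_error(tts_distance(q, ref, data.frame(transcript_id = "qp",
                                               matched_ref = NA)),
               "unmatched")
})

test_that("TSS coverage ratio is strand-aware with a pseudocount", {
  cov <- rep(0, 1000)
  cov[501:600] <- 2   # downstream of a + TSS at 501
  cov[401:500] <- 1   # upstream
  expect_equal(tss_coverage_ratio(501, "+", cov, window = 100,
                                  pseudocount = 0), 1)
  expect_equal(tss_coverage_ratio(501, "+", rep(3, 1000), 100, 0), 0)
  cov2 <- rep(0, 1000)
  cov2[481:500] <- c(rep(0, 5), rep(1, 15))
  expect_equal(tss_coverage_ratio(500, "-", cov2, window = 100,
                                  pseudocount = 1), log2(16))
  # minus strand mirrors the windows
  cov3 <- rep(0, 1000)
  cov3[401:500] <- 2
  cov3[501:600] <- 1
  expect_equal(tss_coverage_ratio(500, "-", cov3, 100, 0), 1)
  expect_warning(tss_coverage_ratio(30, "+", cov, 100, 1), "truncated")
})

test_that("transcriptome statistics summarise classes and detection", {
  m <- make_models(lapply(1:10, function(i) {
    g0 <- i * 10000
    gene <- paste0("g", ceiling(i / 2.5))   # 10 transcripts over 4 genes
    list(id = paste0("t", i), gene = gene, chrom = "chr1", strand = "+",
         exons = cbind(c(g0, g0 + 1000), c(g0 + 200, g0 + 1200)))
  }))
  cls <- data.frame(transcript_id = paste0("t", 1:10),
                    class = factor(c(rep("FSM", 4), rep("ISM", 2),
                                     rep("NIC", 2), rep("NNC", 2)),
                                   levels = c("FSM", "ISM", "NIC", "NNC",
                                              "intergenic")))
  tpm <- matrix(0, nrow = 10, ncol = 9,
                dimnames = list(paste0("t", 1:10), paste0("tis", 1:9)))
  tpm[1:6, 1:5] <- 5      # known transcripts detected in 5 of 9 tissues
  tpm[7:10, 1] <- 5       # novel: detected in 1 tissue
  st <- transcriptome_stats(m, cls, tpm)
  expect_equal(st$isoform_gene_ratio, 2.5)
  expect_equal(st$n_multi_exonic, 10L)
  expect_equal(unname(st$detected_hist_known[["5"]]), 6L)
  expect_equal(st$frac_known_in_half_tissues, 1)
  expect_equal(as.integer(st$class_counts[c("FSM", "ISM")]), c(4L, 2L))
  expect_equal(unname(st$dominant_isoform["g1", "tis1"]), "t1")
})
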