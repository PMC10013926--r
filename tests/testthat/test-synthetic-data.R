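small_cfg <- function(seed = 3, ...) {
  sim_config(seed = seed, n_chroms = 1L, chrom_length = 5e5,
             genes_per_chrom = 12L, n_true_elements = 30L,
             n_repressed = 15L, n_noise_peaks = 40L,
             loops_per_chrom = 2L, n_linked_pairs = 4L, ...)
}

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  g1 <- simulate_genome(cfg, ann)
  g2 <- simulate_genome(cfg, ann)
  expect_identical(as.character(g1), as.character(g2))
  expect_identical(simulate_annotation(cfg)$manifest, ann$manifest)
  expect_identical(simulate_peaks_and_histones(cfg)$manifest$membership,
                   simulate_peaks_and_histones(cfg)$manifest$membership)
})

test_that("chromosome sizes match the configured genome", {
  cfg <- sim_config(seed = 1, n_chroms = 2L, chrom_length = 1e4)
  sz <- sim_chrom_sizes(cfg)
  expect_equal(sum(sz), 2e4)
  g <- simulate_genome(cfg)
  expect_equal(unname(lengths(g)), unname(sz))
})

test_that("without planted windows the intra-priming rate matches the binomial background", {
  cfg <- small_cfg(intra_priming_fraction = 0)
  ann <- simulate_annotation(cfg)
  genome <- simulate_genome(cfg, ann)
  flags <- intra_priming_flag(ann$models, genome)
  # background: P(>= 16 A in 20 bp at p = 0.25) per transcript
  p_bg <- sum(stats::dbinom(16:20, 20, 0.25))
  n <- length(flags)
  # exact binomial bound: expect at most the 1 - 1e-6 quantile of flags
  expect_lte(sum(flags), stats::qbinom(1 - 1e-6, n, p_bg))
})

test_that("planted intra-priming windows are recovered exactly", {
  cfg <- small_cfg(intra_priming_fraction = 0.2)
  ann <- simulate_annotation(cfg)
  genome <- simulate_genome(cfg, ann)
  flags <- intra_priming_flag(ann$models, genome)
  truth <- ann$manifest$intra_priming[match(names(flags),
                                            ann$manifest$transcript_id)]
  expect_gt(sum(truth), 0)
  expect_identical(unname(flags), truth)
})

test_that("annotation manifest classes are realised by the classifier", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  ref <- subset_models(ann$models, ann$reference_ids)
  qry <- subset_models(ann$models, ann$query_ids)
  cls <- classify_splice_match(qry, ref)
  intended <- ann$manifest$intended_class[match(cls$transcript_id,
                                                ann$manifest$transcript_id)]
  expect_identical(as.character(cls$class), intended)
  expect_setequal(unique(intended), c("FSM", "ISM", "NIC", "NNC", "intergenic"))
  expect_true(all(ann$models$tx$n_exons >= 1))
})

test_that("planted true peaks overlap the constructed RP set", {
  cfg <- small_cfg()
  ph <- simulate_peaks_and_histones(cfg)
  el <- ph$manifest$elements
  for (tis in setdiff(cfg$tissues, cfg$tissues_without_histones)[1:3]) {
    h <- ph$histones[[tis]]
    truth <- build_truth_sets(h$h3k4me1, h$h3k4me3, h$h3k27ac, h$h3k27me3)
    for (pk in ph$atac[[tis]]) {
      is_true <- pk %over% el[mcols(el)$kind == "true"]
      expect_true(all(countOverlaps(pk[is_true], truth$rp) > 0))
    }
  }
})

test_that("zero noise and repressed peaks give FPR 0 at every cutoff", {
  cfg <- small_cfg(n_noise_peaks = 0L, n_repressed = 0L)
  ph <- simulate_peaks_and_histones(cfg)
  tis <- setdiff(cfg$tissues, cfg$tissues_without_histones)[1L]
  # no H3K27me3 elements exist, so RN must be supplied externally
  # RN window placed mid-gap of the element grid so no peak can reach it
  truth <- list(rp = ph$manifest$elements, rn = gr("chr1", 491500, 491600))
  roc <- roc_curve(ph$atac[[tis]][[1L]], truth)
  expect_true(all(roc$points$fpr == 0))
})

test_that("well-separated score distributions give AUC >= 0.99", {
  cfg <- small_cfg()
  ph <- simulate_peaks_and_histones(cfg)
  tis <- setdiff(cfg$tissues, cfg$tissues_without_histones)[1L]
  h <- ph$histones[[tis]]
  truth <- build_truth_sets(h$h3k4me1, h$h3k4me3, h$h3k27ac, h$h3k27me3)
  pooled <- iterative_nonoverlap_merge(
    unlist(GRangesList(unname(ph$atac[[tis]])), use.names = FALSE))
  expect_gte(roc_curve(pooled, truth)$auc, 0.99)
})

test_that("the loop scanner recovers every manifest loop; decoys emit none", {
  cfg <- small_cfg()
  sms <- simulate_states_motifs_loops(cfg)
  pred <- scan_loops(sms$motifs)
  expect_equal(granges(pred), granges(sms$manifest$loops))
  # a decoy-only chromosome yields zero loops
  decoys <- sms$motifs[strand(sms$motifs) == "-" &
                         start(sms$motifs) < min(start(sms$manifest$loops))]
  expect_length(scan_loops(decoys), 0L)
  # every planted CRE lies within a manifest loop
  expect_true(all(countOverlaps(sms$manifest$cres, sms$manifest$loops,
                                type = "within") > 0))
})

test_that("count matrices are non-negative integers with planted structure", {
  cfg <- small_cfg()
  sms <- simulate_states_motifs_loops(cfg)
  ann <- simulate_annotation(cfg)
  ref <- subset_models(ann$models, ann$reference_ids)
  cres <- build_cres(sms$states_by_tissue[[1L]], ref)
  loops <- pan_tissue_loops(lapply(sms$motifs_by_tissue, scan_loops),
                            sim_chrom_sizes(cfg))$loops
  cnt <- simulate_counts(cfg, cres, ref, loops)
  expect_true(all(cnt$cre_counts >= 0), all(cnt$cre_counts %% 1 == 0))
  expect_true(all(cnt$gene_counts >= 0), all(cnt$gene_counts %% 1 == 0))
  expect_equal(ncol(cnt$cre_counts), sum(cfg$replicates))
  expect_gt(nrow(cnt$manifest), 0)
  # linked pairs share a loop by construction
  expect_true(all(cnt$manifest$cre_id %in% mcols(cres)$cre_id))
})

test_that("a zero link effect removes the linked/unlinked rho difference", {
  cfg <- sim_config(seed = 5, link_effect = 0)
  sms <- simulate_states_motifs_loops(cfg)
  ann <- simulate_annotation(cfg)
  ref <- subset_models(ann$models, ann$reference_ids)
  cres <- build_cres(sms$states_by_tissue[[1L]], ref)
  loops <- pan_tissue_loops(lapply(sms$motifs_by_tissue, scan_loops),
                            sim_chrom_sizes(cfg))$loops
  cnt <- simulate_counts(cfg, cres, ref, loops)
  links <- spearman_link(cnt$cre_counts, cnt$gene_counts, cres, ref, loops)
  man <- paste(cnt$manifest$cre_id, cnt$manifest$gene_id)
  is_linked <- paste(links$cre_id, links$gene_id) %in% man
  ks <- suppressWarnings(stats::ks.test(links$rho[is_linked],
                                        links$rho[!is_linked]))
  expect_gt(ks$p.value, 0.01)
})

test_that("differential tables plant exact quadrants and the target correlation", {
  cfg <- sim_config(seed = 2)
  dt <- simulate_differential_tables(cfg)
  q <- quadrant_classify(dt$pairs, dt$deg, dt$dar)
  expect_identical(as.integer(q$pair_counts),
                   as.integer(dt$manifest$quadrant_counts))
  expect_lt(abs(dt$manifest$realized_r - dt$manifest$planted_r), 0.1)
  # an all-null table classifies nothing
  dt$deg$p_adj <- 1
  q0 <- quadrant_classify(dt$pairs, dt$deg, dt$dar)
  expect_equal(sum(q0$pair_counts), 0L)
})
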