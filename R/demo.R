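#' Run the full synthetic demonstration pipeline
#'
#' Exercises every stage on seeded synthetic data - simulate, fixed-width
#' peak construction, hierarchical merging, histone-anchored ROC calibration
#' (quantile fallback for tissues without histone data), tissue-sharing
#' classification, insertion-count matrix, genic annotation, chromatin-state
#' enrichment, CTCF loop prediction and pan-tissue merging, CRE assembly and
#' within-loop Spearman linking, transcript QC, and differential concordance -
#' and compares each stage against the generators' truth manifests.
#'
#' @param seed Master seed.
#' @param fpr_target FPR bound for ROC cutoff selection.
#' @param quantile_q Quantile fallback for tissues without histone truth sets.
#' @param link_fdr FDR threshold for CRE-gene links.
#' @param config A `sim_config` (defaults to `sim_config(seed)`).
#' @param outdir Optional directory to write result tables into.
#' @return List with `report` (named summary metrics), `peak_table`
#'   (Table-1-style per-tissue metrics), and the main intermediate objects.
#' @export
run_demo <- function(seed = 1L, fpr_target = 0.25, quantile_q = 0.85,
                     link_fdr = 0.05, config = sim_config(seed),
                     outdir = NULL) {
  sizes <- sim_chrom_sizes(config)
  ann <- simulate_annotation(config)
  genome <- simulate_genome(config, ann)
  ref_models <- subset_models(ann$models, ann$reference_ids)
  query_models <- subset_models(ann$models, ann$query_ids)

  ## ---- open chromatin: fixed peaks, per-tissue merge, calibration ----
  ph <- simulate_peaks_and_histones(config)
  fixed <- lapply(ph$atac, function(reps) {
    lapply(reps, summits_to_fixed_peaks, flank = 250L, chrom_sizes = sizes)
  })
  hu <- hierarchical_union(fixed)

  peak_rows <- list()
  filtered <- list()
  retained_true <- 0L
  present_true <- 0L
  aucs <- c()
  elements <- ph$manifest$elements
  true_el <- elements[mcols(elements)$kind == "true"]
  for (tis in names(hu$tissue_sets)) {
    ts <- hu$tissue_sets[[tis]]
    hist_t <- ph$histones[[tis]]
    if (is.null(hist_t)) {
      cutoff <- quantile_cutoff(ts, quantile_q)
      row <- data.frame(tissue = tis, raw_count = length(ts),
                        method = "quantile", cutoff = cutoff,
                        ntp = NA, nfp = NA, tpr = NA, fpr = NA, auc = NA)
    } else {
      truth <- build_truth_sets(hist_t$h3k4me1, hist_t$h3k4me3,
                                hist_t$h3k27ac, hist_t$h3k27me3)
      roc <- roc_curve(ts, truth)
      cutoff <- select_cutoff(roc, fpr_target)
      at <- roc$points[roc$points$cutoff == cutoff, ]
      aucs[tis] <- roc$auc
      row <- data.frame(tissue = tis, raw_count = length(ts),
                        method = "roc", cutoff = cutoff,
                        ntp = at$ntp, nfp = at$nfp, tpr = at$tpr,
                        fpr = at$fpr, auc = roc$auc)
    }
    keep <- ts[mcols(ts)$score >= cutoff]
    filtered[[tis]] <- keep
    row$remaining <- length(keep)
    peak_rows[[tis]] <- row
    if (!is.null(hist_t)) {
      pres <- true_el[ph$manifest$membership[
        mcols(elements)$kind == "true", tis]]
      present_true <- present_true + length(pres)
      retained_true <- retained_true +
        sum(countOverlaps(pres, keep, ignore.strand = TRUE) > 0L)
    }
  }
  union_set <- hierarchical_union(lapply(filtered, list))$union
  sharing <- classify_sharing(union_set, filtered)
  for (tis in names(filtered)) {
    peak_rows[[tis]]$tissue_specific <-
      sum(sharing$n_tissues == 1L & sharing[[tis]])
  }
  peak_table <- do.call(rbind, peak_rows)
  rownames(peak_table) <- NULL

  ## ---- insertion-count matrix ----
  set.seed(config$seed + 707L)
  samples <- sample_names(config)
  tis_of <- sample_tissues(config)
  sites <- lapply(seq_along(samples), function(si) {
    pres <- elements[ph$manifest$membership[, tis_of[si]] &
                       mcols(elements)$kind == "true"]
    n_per <- stats::rpois(length(pres), 5)
    pos <- unlist(lapply(seq_along(pres), function(i) {
      if (n_per[i] == 0L) return(integer(0))
      sample(start(pres)[i]:end(pres)[i], n_per[i], replace = TRUE)
    }))
    chr <- rep(as.character(seqnames(pres)), n_per)
    bg_chr <- sample(names(sizes), 100L, replace = TRUE)
    bg_pos <- vapply(bg_chr, function(ch) sample(sizes[[ch]], 1L), 0L)
    GRanges(c(chr, bg_chr), IRanges(c(pos, bg_pos), width = 1L))
  })
  names(sites) <- samples
  counts_atac <- insertion_count_matrix(union_set, sites)

  ## ---- genic annotation of union peaks ----
  peak_classes <- annotate_peaks(union_set, ref_models)

  ## ---- states, loops, CREs ----
  sms <- simulate_states_motifs_loops(config)
  pred_base <- scan_loops(sms$motifs)
  man_loops <- sms$manifest$loops
  exact <- countOverlaps(man_loops, pred_base, type = "equal") > 0L
  loop_recovery <- mean(exact)
  per_tissue_loops <- lapply(sms$motifs_by_tissue, scan_loops)
  pt <- pan_tissue_loops(per_tissue_loops, sizes)

  cres <- build_cres(sms$states_by_tissue[[1L]], ref_models,
                     active_states = config$active_states)
  cre_recovery <- mean(countOverlaps(sms$manifest$cres, cres,
                                     ignore.strand = TRUE) > 0L)

  ## ---- counts and CRE-gene linking ----
  cnt <- simulate_counts(config, cres, ref_models, pt$loops)
  links <- spearman_link(cnt$cre_counts, cnt$gene_counts, cres, ref_models,
                         pt$loops, fdr = link_fdr)
  link_key <- paste(links$cre_id, links$gene_id)
  man_key <- paste(cnt$manifest$cre_id, cnt$manifest$gene_id)
  sig <- links[links$significant, , drop = FALSE]
  link_recovery <- mean(man_key %in% paste(sig$cre_id, sig$gene_id))
  link_fdr_emp <- if (nrow(sig) == 0L) 0 else
    mean(!paste(sig$cre_id, sig$gene_id) %in% man_key)
  dsum <- distance_summary(sig)

  ## ---- state enrichment (first tissue) ----
  enr <- state_enrichment_matrix(sms$states_by_tissue[1L], ref_models,
                                 cnt$tpm, sizes)

  ## ---- transcript QC ----
  cls <- classify_splice_match(query_models, ref_models)
  intended <- ann$manifest$intended_class[match(cls$transcript_id,
                                                ann$manifest$transcript_id)]
  splice_agreement <- mean(as.character(cls$class) == intended)
  ip_flags <- intra_priming_flag(ann$models, genome)
  ip_truth <- ann$manifest$intra_priming[match(names(ip_flags),
                                               ann$manifest$transcript_id)]
  intra_priming_agreement <- mean(ip_flags == ip_truth)
  collapse <- collapse_5prime_degraded(ann$models)
  fsm_multi <- cls[cls$class == "FSM" & !is.na(cls$matched_ref), ]
  fsm_multi <- fsm_multi[query_models$tx$n_exons[
    match(fsm_multi$transcript_id, query_models$tx$transcript_id)] > 1L, ]
  ttsd <- tts_distance(query_models, ref_models, fsm_multi)

  ## ---- differential concordance ----
  dt <- simulate_differential_tables(config)
  qres <- quadrant_classify(dt$pairs, dt$deg, dt$dar)
  quadrant_exact <- all(qres$pair_counts == dt$manifest$quadrant_counts)
  fcc <- fc_correlation(dt$pairs, dt$deg, dt$dar)

  report <- list(
    n_union_peaks = length(union_set),
    n_conserved_peaks = sum(sharing$label %in% "conserved"),
    n_unique_peaks = sum(sharing$label %in% "unique"),
    mean_auc = mean(aucs),
    true_peak_retention = retained_true / present_true,
    insertion_matrix_total = sum(counts_atac),
    peak_class_fractions = prop.table(table(peak_classes)),
    loop_recovery = loop_recovery,
    n_pan_tissue_loops = length(pt$loops),
    loop_genome_coverage = pt$coverage,
    n_cres = length(cres),
    cre_recovery = cre_recovery,
    n_links_tested = nrow(links),
    n_links_significant = nrow(sig),
    link_recovery = link_recovery,
    link_empirical_fdr = link_fdr_emp,
    median_abs_link_distance = dsum$all$median_abs_distance,
    frac_links_within_1mb = dsum$all$frac_within_1mb,
    splice_class_agreement = splice_agreement,
    intra_priming_agreement = intra_priming_agreement,
    n_collapsed_5prime = sum(collapse$mapping$transcript_id !=
                               collapse$mapping$representative),
    median_fsm_tts_shift = stats::median(ttsd),
    quadrant_counts = qres$pair_counts,
    quadrant_exact_recovery = quadrant_exact,
    fc_pearson_r = fcc$r,
    fc_pearson_p = fcc$p,
    max_state_enrichment = max(enr$fold, na.rm = TRUE)
  )
  out <- list(report = report, peak_table = peak_table, links = links,
              sharing = sharing, enrichment = enr, classes = cls,
              union = union_set, loops = pt$loops, cres = cres)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(peak_table, file.path(outdir, "peak_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(links, file.path(outdir, "cre_gene_links.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr, file.path(outdir, "state_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(pt$loops, file.path(outdir, "pan_tissue_loops.bed"))
    write_bed(union_set, file.path(outdir, "union_peaks.bed"))
  }
  out
}
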