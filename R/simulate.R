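#' Simulation configuration
#'
#' Fixes the study conditions emulated by the synthetic-data generators:
#' nine tissues with four biological replicates each except ovary and testis
#' with two (32 samples); well-separated true vs noise ATAC score
#' distributions; negative-binomial counts with a shared log-normal latent
#' activity linking planted CRE-gene pairs; CTCF loops covering most of the
#' genome. Every generator derives its own RNG stream from `seed` plus a
#' fixed offset, so adding a generator never perturbs the others and a fixed
#' seed gives byte-identical outputs.
#'
#' @param seed Master seed (integer).
#' @param ... Overrides for any default listed below.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome
    n_chroms = 2L, chrom_length = 2e6,
    # annotation
    genes_per_chrom = 60L, gene_offset = 5000L, gene_spacing = 33000L,
    exon_width = 200L, intron_width = 1800L, n_exons = 6L,
    intra_priming_fraction = 0.1,
    # tissues / samples
    tissues = c("adipose", "cortex", "heart", "lamina", "liver",
                "lung", "muscle", "ovary", "testis"),
    replicates = c(4L, 4L, 4L, 4L, 4L, 4L, 4L, 2L, 2L),
    tissues_without_histones = "testis",
    # peaks
    n_true_elements = 200L, n_repressed = 100L, n_noise_peaks = 400L,
    true_score_mean = 100, true_score_sd = 5,
    noise_score_mean = 20, noise_score_sd = 5,
    element_halfwidth = 200L, summit_jitter = 20L,
    mean_tissues_per_element = NA,  # uniform 1..n_tissues when NA
    # loops / states
    loops_per_chrom = 12L, loop_span = 140000L, loop_spacing = 165000L,
    loop_offset = 10000L, motif_width = 19L, anchor_jitter = 2000L,
    n_decoy_motifs = 4L,
    cres_per_loop = 4L, cre_width = 1500L,
    active_states = c(2:5, 8:11), repressed_state = 13L,
    # counts
    n_linked_pairs = 40L, link_effect = 1,
    latent_sdlog = log(8) / 2, nb_dispersion = 0.1,
    cre_base_mean = 200, gene_base_mean = 300,
    # differential tables
    n_diff_pairs = 5000L, diff_r = 0.4, diff_sig_frac = 0.55,
    diff_lfc_sd = 1.5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field: ", unknown[1L])
  cfg[names(dots)] <- dots
  stopifnot(cfg$chrom_length >= 10000,
            length(cfg$replicates) == length(cfg$tissues))
  class(cfg) <- "sim_config"
  cfg
}

#' Chromosome sizes implied by a simulation config
#'
#' @param config A `sim_config`.
#' @return Named vector of chromosome lengths.
#' @export
sim_chrom_sizes <- function(config) {
  stats::setNames(rep(config$chrom_length, config$n_chroms),
                  paste0("chr", seq_len(config$n_chroms)))
}

sample_names <- function(config) {
  unlist(lapply(seq_along(config$tissues), function(i) {
    paste0(config$tissues[i], "_rep", seq_len(config$replicates[i]))
  }))
}

sample_tissues <- function(config) {
  rep(config$tissues, config$replicates)
}

#' Simulate a transcript annotation with planted splice classes
#'
#' Genes are laid on a fixed grid on alternating strands, each with six
#' evenly spaced exons. Genes cycle through six roles; each contributes a
#' reference isoform (NIC genes contribute two overlapping reference
#' isoforms) and a query isoform constructed to realise a designated splice
#' class: FSM (same junction chain, different ends), ISM (3'-anchored
#' sub-chain), NIC (combination of the two reference chains), NNC (one
#' shifted, novel acceptor), mono-exonic FSM (contained in a reference exon),
#' and intergenic (mono-exonic, between gene slots). A manifest records each
#' transcript's role and intended class, plus which TTS groups are designated
#' intra-priming positives (their downstream windows are overwritten with
#' A-rich sequence by [simulate_genome()]).
#'
#' @param config A `sim_config`.
#' @return List with `models` (all transcripts), `reference_ids`,
#'   `query_ids`, and `manifest` (data.frame: transcript_id, gene_id, role,
#'   intended_class, intra_priming).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 202L)
  ew <- config$exon_width
  iw <- config$intron_width
  step <- ew + iw
  roles <- c("FSM", "ISM", "NIC", "NNC", "mono_FSM", "intergenic")
  exon_rows <- list()
  manifest <- list()
  add_tx <- function(chrom, strand, starts, widths, txid, gene,
                     role, intended) {
    exon_rows[[length(exon_rows) + 1L]] <<- data.frame(
      chrom = chrom, start = starts, end = starts + widths - 1L,
      strand = strand, transcript_id = txid, gene_id = gene)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      transcript_id = txid, gene_id = gene, role = role,
      intended_class = intended, stringsAsFactors = FALSE)
  }
  for (ci in seq_len(config$n_chroms)) {
    chrom <- paste0("chr", ci)
    for (gi in seq_len(config$genes_per_chrom)) {
      g0 <- config$gene_offset + (gi - 1L) * config$gene_spacing
      strand <- if (gi %% 2L == 0L) "-" else "+"
      gene <- sprintf("gene_%s_%03d", chrom, gi)
      role <- roles[(gi - 1L) %% length(roles) + 1L]
      ex_starts <- g0 + (seq_len(config$n_exons) - 1L) * step
      full <- seq_len(config$n_exons)
      ref_idx <- full[-config$n_exons]                    # exons 1..5
      add_tx(chrom, strand, ex_starts[ref_idx], rep(ew, length(ref_idx)),
             paste0(gene, "_ref1"), gene, "reference", NA)
      if (role == "FSM") {
        st <- ex_starts[ref_idx]
        wd <- rep(ew, length(ref_idx))
        st[1L] <- st[1L] + 100L
        wd[1L] <- wd[1L] - 100L
        wd[length(wd)] <- wd[length(wd)] + 300L  # 3' extension, same chain
        add_tx(chrom, strand, st, wd, paste0(gene, "_qFSM"), gene,
               "query", "FSM")
      } else if (role == "ISM") {
        idx <- ref_idx[-1L]                               # exons 2..5
        add_tx(chrom, strand, ex_starts[idx], rep(ew, length(idx)),
               paste0(gene, "_qISM"), gene, "query", "ISM")
      } else if (role == "NIC") {
        idx2 <- full[-1L]                                 # exons 2..6
        add_tx(chrom, strand, ex_starts[idx2], rep(ew, length(idx2)),
               paste0(gene, "_ref2"), gene, "reference", NA)
        add_tx(chrom, strand, ex_starts[full], rep(ew, length(full)),
               paste0(gene, "_qNIC"), gene, "query", "NIC")
      } else if (role == "NNC") {
        st <- ex_starts[ref_idx]
        wd <- rep(ew, length(ref_idx))
        st[3L] <- st[3L] + 50L                            # novel acceptor
        wd[3L] <- wd[3L] - 50L
        add_tx(chrom, strand, st, wd, paste0(gene, "_qNNC"), gene,
               "query", "NNC")
      } else if (role == "mono_FSM") {
        add_tx(chrom, strand, ex_starts[2L] + 50L, ew - 100L,
               paste0(gene, "_qMONO"), gene, "query", "FSM")
      } else {
        pos <- g0 + 15000L                                # between gene slots
        add_tx(chrom, strand, pos, 400L,
               paste0(gene, "_qINTER"), paste0(gene, "_novel"),
               "query", "intergenic")
      }
    }
  }
  ex <- do.call(rbind, exon_rows)
  gr <- GRanges(ex$chrom, IRanges(ex$start, ex$end), strand = ex$strand)
  mcols(gr)$transcript_id <- ex$transcript_id
  mcols(gr)$gene_id <- ex$gene_id
  models <- transcript_models(gr)
  man <- do.call(rbind, manifest)

  # designate intra-priming positives at the level of distinct TTS groups so
  # transcripts sharing a TTS are flagged consistently
  tx <- models$tx
  key <- paste(tx$chrom, tx$strand, tx$tts)
  groups <- unique(key)
  n_pick <- floor(config$intra_priming_fraction * length(groups))
  picked <- if (n_pick > 0L) sample(groups, n_pick) else character(0)
  ip <- stats::setNames(key %in% picked, tx$transcript_id)
  man$intra_priming <- unname(ip[man$transcript_id])
  man <- man[order(man$transcript_id), , drop = FALSE]
  rownames(man) <- NULL
  list(models = models,
       reference_ids = man$transcript_id[man$role == "reference"],
       query_ids = man$transcript_id[man$role == "query"],
       manifest = man)
}

#' Simulate a genome sequence
#'
#' Uniform-random A/C/G/T per chromosome, deterministic under the seed. When
#' an annotation is supplied, the 20 bp sense-strand windows downstream of the
#' TTS of its designated intra-priming transcripts are overwritten with
#' adenine-rich sequence (poly-A on + transcripts, poly-T on - transcripts),
#' planting intra-priming positives.
#'
#' @param config A `sim_config`.
#' @param annotation Optional result of [simulate_annotation()].
#' @param window Intra-priming window size in bp.
#' @return Named `DNAStringSet`.
#' @export
simulate_genome <- function(config, annotation = NULL, window = 20L) {
  set.seed(config$seed + 101L)
  sizes <- sim_chrom_sizes(config)
  seqs <- vapply(sizes, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, "")
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(sizes)
  if (!is.null(annotation)) {
    tx <- annotation$models$tx
    flagged <- annotation$manifest$transcript_id[
      annotation$manifest$intra_priming]
    for (id in flagged) {
      i <- match(id, tx$transcript_id)
      len <- sizes[tx$chrom[i]]
      if (tx$strand[i] == "+") {
        from <- tx$tts[i] + 1L
        to <- min(len, tx$tts[i] + window)
        fill <- "A"
      } else {
        from <- max(1L, tx$tts[i] - window)
        to <- tx$tts[i] - 1L
        fill <- "T"
      }
      if (from > to) next
      Biostrings::subseq(genome[[tx$chrom[i]]], from, to) <-
        Biostrings::DNAString(paste(rep(fill, to - from + 1L), collapse = ""))
    }
  }
  genome
}

# Non-overlapping element slots across the genome (randomised grid).
element_slots <- function(config, n_total) {
  sizes <- sim_chrom_sizes(config)
  slots <- do.call(rbind, lapply(names(sizes), function(chr) {
    centers <- seq(2000L, sizes[[chr]] - 2000L, by = 4000L)
    data.frame(chrom = chr, center = centers, stringsAsFactors = FALSE)
  }))
  if (n_total > nrow(slots)) stop("too many elements for the genome size")
  slots[sample(nrow(slots), n_total), , drop = FALSE]
}

#' Simulate ATAC peaks and histone truth sets with planted ground truth
#'
#' True regulatory elements receive per-tissue ATAC peaks with scores from
#' the high distribution plus H3K4me1, H3K4me3 and H3K27ac peaks; decoy
#' repressed elements receive low-score ATAC peaks and H3K27me3; noise peaks
#' overlap no histone mark. Each element is active in a random subset of
#' tissues, and histone peaks cover exactly the elements active in that
#' tissue. Tissues listed in `config$tissues_without_histones` get ATAC peaks
#' but no histone sets (forcing the quantile-cutoff fallback downstream).
#'
#' @param config A `sim_config`.
#' @return List with `atac` (tissue -> replicate -> GRanges with score and
#'   summit), `histones` (tissue -> list of four GRanges, or NULL), and
#'   `manifest` (list: `true`, `repressed`, `noise` GRanges plus per-element
#'   tissue membership matrices).
#' @export
simulate_peaks_and_histones <- function(config) {
  set.seed(config$seed + 303L)
  n_tis <- length(config$tissues)
  hw <- config$element_halfwidth
  n_tot <- config$n_true_elements + config$n_repressed + config$n_noise_peaks
  slots <- element_slots(config, n_tot)
  kind <- rep(c("true", "repressed", "noise"),
              c(config$n_true_elements, config$n_repressed,
                config$n_noise_peaks))
  membership <- t(vapply(seq_len(n_tot), function(i) {
    k <- sample(n_tis, 1L)
    seq_len(n_tis) %in% sample(n_tis, k)
  }, logical(n_tis)))
  colnames(membership) <- config$tissues

  elements <- GRanges(slots$chrom,
                      IRanges(slots$center - hw, slots$center + hw))
  mcols(elements)$kind <- kind
  mcols(elements)$center <- slots$center

  atac <- list()
  histones <- list()
  for (ti in seq_len(n_tis)) {
    tis <- config$tissues[ti]
    present <- which(membership[, ti])
    reps <- list()
    for (r in seq_len(config$replicates[ti])) {
      idx <- present
      ctr <- slots$center[idx] +
        sample(-config$summit_jitter:config$summit_jitter, length(idx),
               replace = TRUE)
      is_true <- kind[idx] == "true"
      score <- numeric(length(idx))
      score[is_true] <- pmax(0.1, stats::rnorm(sum(is_true),
                                               config$true_score_mean,
                                               config$true_score_sd))
      score[!is_true] <- pmax(0.1, stats::rnorm(sum(!is_true),
                                                config$noise_score_mean,
                                                config$noise_score_sd))
      pk <- GRanges(slots$chrom[idx], IRanges(ctr - hw, ctr + hw))
      mcols(pk)$score <- score
      mcols(pk)$summit <- as.integer(ctr)
      reps[[paste0("rep", r)]] <- pk
    }
    atac[[tis]] <- reps
    if (tis %in% config$tissues_without_histones) {
      histones[tis] <- list(NULL)
      next
    }
    jit <- function(idx, extra) {
      j <- sample(-50:50, length(idx), replace = TRUE)
      GRanges(slots$chrom[idx],
              IRanges(slots$center[idx] - hw - extra + j,
                      slots$center[idx] + hw + extra + j))
    }
    tr <- present[kind[present] == "true"]
    rp <- present[kind[present] == "repressed"]
    histones[[tis]] <- list(h3k4me1 = jit(tr, 200L),
                            h3k4me3 = jit(tr, 100L),
                            h3k27ac = jit(tr, 150L),
                            h3k27me3 = jit(rp, 200L))
  }
  list(atac = atac, histones = histones,
       manifest = list(elements = elements, membership = membership))
}

#' Simulate chromatin-state segmentations, CTCF motifs and true loops
#'
#' Loops are planted at fixed positions per chromosome: a forward CTCF motif
#' at the left anchor and a reverse motif at the right anchor (convergent).
#' Unpaired decoy motifs are placed where they cannot pair (reverse decoys
#' before the first loop, forward decoys after the last). Per tissue, anchor
#' positions are jittered. Active-state blocks (the planted CREs) are placed
#' inside each loop, with repressed-state blocks between loops.
#'
#' @param config A `sim_config`.
#' @return List with `motifs` (base, manifest-level GRanges, stranded),
#'   `motifs_by_tissue`, `states_by_tissue` (GRanges with `state`),
#'   `manifest` (list: `loops` GRanges, `cres` GRanges with loop index).
#' @export
simulate_states_motifs_loops <- function(config) {
  set.seed(config$seed + 404L)
  mw <- config$motif_width
  base_motifs <- list()
  loops <- list()
  cres <- list()
  states <- list()
  for (ci in seq_len(config$n_chroms)) {
    chrom <- paste0("chr", ci)
    anchors <- config$loop_offset +
      (seq_len(config$loops_per_chrom) - 1L) * config$loop_spacing
    plus <- GRanges(chrom, IRanges(anchors, width = mw), strand = "+")
    minus <- GRanges(chrom, IRanges(anchors + config$loop_span - mw + 1L,
                                    width = mw), strand = "-")
    # decoys that cannot pair under any left-to-right convergent rule
    decoy_minus <- GRanges(chrom,
                           IRanges(seq(2500L, by = 700L,
                                       length.out = config$n_decoy_motifs),
                                   width = mw), strand = "-")
    last_end <- end(minus)[length(minus)]
    decoy_plus <- GRanges(chrom,
                          IRanges(seq(last_end + 2000L, by = 700L,
                                      length.out = config$n_decoy_motifs),
                                  width = mw), strand = "+")
    base_motifs[[chrom]] <- c(decoy_minus, plus, minus, decoy_plus)
    loops[[chrom]] <- GRanges(chrom, IRanges(start(plus), end(minus)))

    offs <- round(seq(0.15, 0.85, length.out = config$cres_per_loop) *
                    config$loop_span)
    for (li in seq_along(anchors)) {
      cs <- anchors[li] + offs
      cre <- GRanges(chrom, IRanges(cs, width = config$cre_width))
      mcols(cre)$state <- sample(config$active_states,
                                 config$cres_per_loop, replace = TRUE)
      mcols(cre)$loop_chrom <- chrom
      mcols(cre)$loop_index <- li
      cres[[length(cres) + 1L]] <- cre
    }
    gaps_start <- c(1L, end(loops[[chrom]]) + 5000L)
    rep_blocks <- GRanges(chrom, IRanges(gaps_start, width = 3000L))
    mcols(rep_blocks)$state <- config$repressed_state
    # poised-promoter blocks (state 1, not an active state) at forward-gene
    # TSS positions so promoter-proximal enrichment is visible downstream
    plus_tss <- config$gene_offset +
      (seq(1L, config$genes_per_chrom, by = 2L) - 1L) * config$gene_spacing
    prom_blocks <- GRanges(chrom, IRanges(pmax(1L, plus_tss - 500L),
                                          plus_tss + 500L))
    mcols(prom_blocks)$state <- 1L
    states[[chrom]] <- c(rep_blocks, prom_blocks)
  }
  motifs <- sort(unlist(GRangesList(base_motifs), use.names = FALSE))
  loop_manifest <- sort(unlist(GRangesList(loops), use.names = FALSE))
  cre_manifest <- unlist(GRangesList(cres), use.names = FALSE)
  repressed <- unlist(GRangesList(states), use.names = FALSE)

  base_states <- c(granges(cre_manifest), granges(repressed))
  mcols(base_states)$state <- c(mcols(cre_manifest)$state,
                                mcols(repressed)$state)

  motifs_by_tissue <- list()
  states_by_tissue <- list()
  for (tis in config$tissues) {
    jit <- sample(-config$anchor_jitter:config$anchor_jitter,
                  length(motifs), replace = TRUE)
    mt <- shift(motifs, jit)
    motifs_by_tissue[[tis]] <- mt
    states_by_tissue[[tis]] <- base_states
  }
  list(motifs = motifs, motifs_by_tissue = motifs_by_tissue,
       states_by_tissue = states_by_tissue,
       manifest = list(loops = loop_manifest, cres = cre_manifest))
}

#' Simulate H3K27ac and RNA count matrices with planted CRE-gene links
#'
#' For each of `n_linked_pairs` manifest pairs - a CRE and a gene whose TSS
#' share a loop - a per-sample latent activity (log-normal, `latent_sdlog`)
#' multiplies both negative-binomial means, inducing a rank correlation
#' across the 32 samples. `link_effect` in `[0, 1]` is the shared fraction of
#' the latent variance: 1 = fully shared (default), 0 = independent (null).
#' All other CREs and genes vary independently.
#'
#' @param config A `sim_config`.
#' @param cres GRanges of CREs with `cre_id` (see [build_cres()]).
#' @param models A `transcript_models` object (gene TSS positions).
#' @param loops GRanges of merged loops.
#' @return List with `cre_counts`, `gene_counts` (matrices, features x
#'   samples), `tpm` (genes x tissues), and `manifest` (data.frame of linked
#'   pairs: cre_id, gene_id).
#' @export
simulate_counts <- function(config, cres, models, loops) {
  set.seed(config$seed + 505L)
  samples <- sample_names(config)
  n_s <- length(samples)
  size <- 1 / config$nb_dispersion

  mid <- GRanges(seqnames(cres),
                 IRanges(floor((start(cres) + end(cres)) / 2), width = 1L))
  cre_loop <- findOverlaps(mid, loops, ignore.strand = TRUE)
  gt <- gene_tss_table(models)
  tss_gr <- GRanges(gt$chrom, IRanges(gt$tss, width = 1L))
  gene_loop <- findOverlaps(tss_gr, loops, ignore.strand = TRUE)

  cre_by_loop <- split(queryHits(cre_loop), subjectHits(cre_loop))
  gene_by_loop <- split(queryHits(gene_loop), subjectHits(gene_loop))
  shared <- intersect(names(cre_by_loop), names(gene_by_loop))

  used_cre <- integer(0)
  used_gene <- integer(0)
  pairs <- list()
  for (lp in shared) {
    cs <- setdiff(cre_by_loop[[lp]], used_cre)
    gs <- setdiff(gene_by_loop[[lp]], used_gene)
    n_here <- min(length(cs), length(gs), 2L)
    if (n_here == 0L) next
    for (k in seq_len(n_here)) {
      pairs[[length(pairs) + 1L]] <- c(cs[k], gs[k])
      used_cre <- c(used_cre, cs[k])
      used_gene <- c(used_gene, gs[k])
    }
    if (length(pairs) >= config$n_linked_pairs) break
  }
  pairs <- pairs[seq_len(min(length(pairs), config$n_linked_pairs))]
  pm <- do.call(rbind, pairs)
  linked <- data.frame(cre_id = mcols(cres)$cre_id[pm[, 1L]],
                       gene_id = gt$gene_id[pm[, 2L]],
                       stringsAsFactors = FALSE)

  cre_ids <- mcols(cres)$cre_id
  gene_ids <- gt$gene_id
  w <- sqrt(config$link_effect)
  cre_lat <- matrix(stats::rnorm(length(cre_ids) * n_s), ncol = n_s,
                    dimnames = list(cre_ids, samples))
  gene_lat <- matrix(stats::rnorm(length(gene_ids) * n_s), ncol = n_s,
                     dimnames = list(gene_ids, samples))
  shared_lat <- matrix(stats::rnorm(nrow(linked) * n_s), ncol = n_s,
                       dimnames = list(NULL, samples))
  for (k in seq_len(nrow(linked))) {
    cre_lat[linked$cre_id[k], ] <- w * shared_lat[k, ] +
      sqrt(1 - w^2) * cre_lat[linked$cre_id[k], ]
    gene_lat[linked$gene_id[k], ] <- w * shared_lat[k, ] +
      sqrt(1 - w^2) * gene_lat[linked$gene_id[k], ]
  }
  cre_mu <- config$cre_base_mean * exp(config$latent_sdlog * cre_lat)
  gene_mu <- config$gene_base_mean * exp(config$latent_sdlog * gene_lat)
  cre_counts <- matrix(stats::rnbinom(length(cre_mu), mu = cre_mu,
                                      size = size),
                       nrow = nrow(cre_mu), dimnames = dimnames(cre_mu))
  gene_counts <- matrix(stats::rnbinom(length(gene_mu), mu = gene_mu,
                                       size = size),
                        nrow = nrow(gene_mu), dimnames = dimnames(gene_mu))

  tpm_sample <- sweep(gene_counts, 2L, colSums(gene_counts), "/") * 1e6
  tis <- sample_tissues(config)
  tpm <- vapply(config$tissues, function(t) {
    rowMeans(tpm_sample[, tis == t, drop = FALSE])
  }, numeric(nrow(gene_counts)))
  list(cre_counts = cre_counts, gene_counts = gene_counts, tpm = tpm,
       manifest = linked)
}

#' Simulate differential-expression and differential-accessibility tables
#'
#' Draws `n_diff_pairs` promoter peak-gene pairs with bivariate-normal log2
#' fold changes at planted Pearson correlation `diff_r`, assigns each table's
#' adjusted p below/above 0.05 independently with probability
#' `diff_sig_frac`, and records the realised quadrant counts among pairs
#' significant in both tables as the manifest.
#'
#' @param config A `sim_config`.
#' @return List with `deg`, `dar` (data.frames: feature_id, log2fc, p_adj),
#'   `pairs` (peak_id, gene_id), and `manifest` (list: quadrant_counts,
#'   planted_r, realized_r, n_sig_both).
#' @export
simulate_differential_tables <- function(config) {
  set.seed(config$seed + 606L)
  n <- config$n_diff_pairs
  r <- config$diff_r
  x <- stats::rnorm(n, 0, config$diff_lfc_sd)                 # accessibility
  y <- r * x + sqrt(1 - r^2) * stats::rnorm(n, 0, config$diff_lfc_sd)
  sig_deg <- stats::runif(n) < config$diff_sig_frac
  sig_dar <- stats::runif(n) < config$diff_sig_frac
  p_deg <- ifelse(sig_deg, stats::runif(n, 0, 0.049),
                  stats::runif(n, 0.051, 1))
  p_dar <- ifelse(sig_dar, stats::runif(n, 0, 0.049),
                  stats::runif(n, 0.051, 1))
  gene_id <- sprintf("dgene_%05d", seq_len(n))
  peak_id <- sprintf("dpeak_%05d", seq_len(n))
  both <- sig_deg & sig_dar
  quad <- ifelse(y > 0, ifelse(x > 0, "Q1", "Q2"),
                 ifelse(x < 0, "Q3", "Q4"))
  list(
    deg = data.frame(feature_id = gene_id, log2fc = y, p_adj = p_deg,
                     stringsAsFactors = FALSE),
    dar = data.frame(feature_id = peak_id, log2fc = x, p_adj = p_dar,
                     stringsAsFactors = FALSE),
    pairs = data.frame(peak_id = peak_id, gene_id = gene_id,
                       stringsAsFactors = FALSE),
    manifest = list(
      quadrant_counts = table(factor(quad[both],
                                     levels = c("Q1", "Q2", "Q3", "Q4"))),
      planted_r = r, realized_r = stats::cor(x, y),
      n_sig_both = sum(both)))
}
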