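#' Annotate peaks by overlapping genic feature
#'
#' Each peak receives exactly one class by priority: promoter-TSS (within
#' `promoter_halfwidth` of any TSS) > TTS (within `tts_halfwidth` of any TTS)
#' > exon (overlaps any exon) > intron (overlaps a gene body but no exon) >
#' intergenic. Overlap means >= 1 shared base.
#'
#' @param peaks GRanges.
#' @param models A `transcript_models` object.
#' @param promoter_halfwidth,tts_halfwidth Window half-widths in bp.
#' @return Factor of classes, one per peak.
#' @export
annotate_peaks <- function(peaks, models, promoter_halfwidth = 2000,
                           tts_halfwidth = 2000) {
  classes <- c("promoter-TSS", "TTS", "exon", "intron", "intergenic")
  tssw <- end_windows(models, "tss", promoter_halfwidth)
  ttsw <- end_windows(models, "tts", tts_halfwidth)
  ex <- unlist(models$exons, use.names = FALSE)
  gb <- gene_bodies(models)
  out <- rep("intergenic", length(peaks))
  ov <- function(x) countOverlaps(peaks, x, ignore.strand = TRUE) > 0L
  out[ov(gb)] <- "intron"
  out[ov(ex)] <- "exon"
  out[ov(ttsw)] <- "TTS"
  out[ov(tssw)] <- "promoter-TSS"
  factor(out, levels = classes)
}

#' Base-pair fold enrichment of an annotation in a chromatin state
#'
#' Computes `(N_ann_and_state / N_ann) / (N_state / N_genome)`: the fraction
#' of annotated bases falling in the state relative to the state's genomic
#' density. Both input sets are reduced internally, so overlapping inputs are
#' counted once.
#'
#' @param annotation GRanges of the annotation (genes, exons, TSS windows,
#'   peaks, ...).
#' @param state GRanges of the state segments.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return List with `n_both`, `n_ann`, `n_state`, `n_genome`, `fold`.
#' @export
fold_enrichment <- function(annotation, state, chrom_sizes) {
  ann <- reduce(granges(annotation), ignore.strand = TRUE)
  st <- reduce(granges(state), ignore.strand = TRUE)
  n_ann <- sum(as.numeric(width(ann)))
  n_state <- sum(as.numeric(width(st)))
  if (n_ann == 0 || n_state == 0) stop("undefined enrichment: empty set")
  n_genome <- sum(as.numeric(chrom_sizes))
  n_both <- intersect_bp(ann, st)
  list(n_both = n_both, n_ann = n_ann, n_state = n_state,
       n_genome = n_genome,
       fold = (n_both / n_ann) / (n_state / n_genome))
}

#' Classify genes as high or low expression per tissue
#'
#' @param tpm Numeric matrix, genes x tissues, of aggregated TPM values.
#' @param threshold TPM at or above which a gene is "high" (default 1).
#' @return Character matrix of "high"/"low", same shape as `tpm`.
#' @export
expression_class <- function(tpm, threshold = 1) {
  out <- ifelse(tpm >= threshold, "high", "low")
  dimnames(out) <- dimnames(tpm)
  out
}

#' Chromatin-state enrichment across genic features by expression class
#'
#' For every tissue, state, genic feature (gene body, exon, TSS +/- 2 kb, TES
#' +/- 2 kb) and expression class (TPM >= 1 vs < 1 in that tissue), computes
#' the base-pair fold enrichment of the feature set (restricted to genes of
#' that class) in the state. Raw folds are always emitted; an optional
#' per-column min-max normalization is provided for display only.
#'
#' @param segments_by_tissue Named list of GRanges with a `state` metadata
#'   column (integer 1-14).
#' @param models A `transcript_models` object.
#' @param tpm Genes x tissues TPM matrix (rownames = gene ids, colnames must
#'   cover the tissues in `segments_by_tissue`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param halfwidth Half-width of the TSS/TES windows in bp.
#' @param normalize Also emit min-max normalized folds per (feature, class,
#'   tissue) column.
#' @return Long data.frame: tissue, state, feature, expr_class, fold (and
#'   `fold_norm` when `normalize = TRUE`). Empty feature cells are NA.
#' @export
state_enrichment_matrix <- function(segments_by_tissue, models, tpm,
                                    chrom_sizes, halfwidth = 2000,
                                    normalize = FALSE) {
  stopifnot(!is.null(rownames(tpm)), !is.null(colnames(tpm)))
  gb <- gene_bodies(models)
  ex_all <- unlist(models$exons, use.names = FALSE)
  tss <- end_windows(models, "tss", halfwidth, per_gene = TRUE)
  tes <- end_windows(models, "tts", halfwidth, per_gene = TRUE)
  feature_of <- list(
    gene_body = function(g) gb[names(gb) %in% g],
    exon = function(g) ex_all[mcols(ex_all)$gene_id %in% g],
    tss = function(g) tss[mcols(tss)$gene_id %in% g],
    tes = function(g) tes[mcols(tes)$gene_id %in% g]
  )
  rows <- list()
  for (tis in names(segments_by_tissue)) {
    seg <- segments_by_tissue[[tis]]
    stopifnot(!is.null(mcols(seg)$state))
    if (!tis %in% colnames(tpm)) stop("no TPM column for tissue ", tis)
    cls <- expression_class(tpm[, tis, drop = FALSE])
    for (ec in c("high", "low")) {
      genes <- rownames(tpm)[cls == ec]
      for (feat in names(feature_of)) {
        fgr <- feature_of[[feat]](genes)
        for (st in sort(unique(mcols(seg)$state))) {
          sgr <- seg[mcols(seg)$state == st]
          fold <- if (length(fgr) == 0L) NA_real_ else
            fold_enrichment(fgr, sgr, chrom_sizes)$fold
          rows[[length(rows) + 1L]] <- data.frame(
            tissue = tis, state = st, feature = feat, expr_class = ec,
            fold = fold)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (normalize) {
    key <- paste(out$tissue, out$feature, out$expr_class)
    out$fold_norm <- stats::ave(out$fold, key, FUN = function(v) {
      rng <- range(v, na.rm = TRUE)
      if (!is.finite(rng[1L]) || rng[1L] == rng[2L]) return(v * 0)
      (v - rng[1L]) / (rng[2L] - rng[1L])
    })
  }
  out
}

#' Tissue-sharing histogram of a chromatin state
#'
#' Base mode: for each base covered by the state in at least one tissue, the
#' number of tissues covering it; returns the histogram of those counts.
#' Segment mode: each segment (pooled across tissues) is counted as shared
#' with tissue T iff it overlaps a same-state segment of T.
#'
#' @param segments_by_tissue Named list of GRanges with `state` metadata.
#' @param state State label to summarise.
#' @param mode "base" or "segment".
#' @return Named integer vector: histogram over number of tissues (1..n).
#' @export
state_tissue_sharing <- function(segments_by_tissue, state,
                                 mode = c("base", "segment")) {
  mode <- match.arg(mode)
  stopifnot(length(segments_by_tissue) >= 2L)
  known <- unique(unlist(lapply(segments_by_tissue,
                                function(s) mcols(s)$state)))
  if (!state %in% known) stop("unknown state label: ", state)
  per_tissue <- lapply(segments_by_tissue, function(s) {
    reduce(granges(s[mcols(s)$state == state]), ignore.strand = TRUE)
  })
  n_tis <- length(per_tissue)
  if (mode == "base") {
    # disjoint pieces of the pooled state footprint are covered all-or-none
    # by each tissue, so per-base tissue counts are piecewise constant
    pieces <- disjoin(unlist(GRangesList(per_tissue)))
    n <- rowSums(vapply(per_tissue, function(ts) {
      countOverlaps(pieces, ts, ignore.strand = TRUE) > 0L
    }, logical(length(pieces))))
    counts <- integer(n_tis)
    for (k in seq_len(n_tis)) {
      counts[k] <- sum(width(pieces)[n == k])
    }
    names(counts) <- seq_len(n_tis)
    return(counts)
  }
  pooled <- unlist(GRangesList(lapply(per_tissue, identity)))
  shared <- vapply(per_tissue, function(ts) {
    countOverlaps(pooled, ts, ignore.strand = TRUE) > 0L
  }, logical(length(pooled)))
  n <- rowSums(matrix(shared, nrow = length(pooled)))
  tab <- table(factor(n, levels = seq_len(n_tis)))
  stats::setNames(as.integer(tab), names(tab))
}
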