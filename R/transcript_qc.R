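SPLICE_CLASSES <- c("FSM", "ISM", "NIC", "NNC", "intergenic")

# Is `short` a consecutive infix of `long`? Chains are junction-key vectors.
chain_is_infix <- function(short, long) {
  ns <- length(short)
  nl <- length(long)
  if (ns == 0L || ns > nl) return(FALSE)
  for (off in 0:(nl - ns)) {
    if (identical(long[(off + 1):(off + ns)], short)) return(TRUE)
  }
  FALSE
}

#' Classify query transcripts against a reference annotation
#'
#' Splice-match classification by junction chains (exact coordinate
#' equality): `FSM` (full-splice match) when the query's junction chain
#' equals some reference transcript's chain; `ISM` (incomplete-splice match)
#' when it equals a consecutive sub-chain of a reference chain without being
#' FSM; `NIC` (novel in catalog) when every query junction exists in the
#' reference junction catalog but no chain or sub-chain matches; `NNC` (novel
#' not in catalog) when at least one junction is novel; `intergenic` when the
#' query overlaps no reference gene body. Mono-exonic queries are FSM when
#' fully contained in a same-strand reference exon, otherwise NNC when
#' overlapping a reference gene body, otherwise intergenic.
#'
#' @param query,reference `transcript_models` objects.
#' @return data.frame: transcript_id, class (factor), matched_ref (reference
#'   transcript id for FSM/ISM, NA otherwise).
#' @export
classify_splice_match <- function(query, reference) {
  ref_chains <- reference$junctions
  ref_strs <- vapply(ref_chains, paste, "", collapse = ";")
  catalog <- unique(unlist(ref_chains, use.names = FALSE))
  gb <- gene_bodies(reference)
  ref_ex <- unlist(reference$exons, use.names = FALSE)

  qtx <- query$tx
  n <- nrow(qtx)
  cls <- character(n)
  matched <- rep(NA_character_, n)
  q_span <- GRanges(qtx$chrom, IRanges(qtx$start, qtx$end))
  overlaps_gene <- countOverlaps(q_span, gb, ignore.strand = TRUE) > 0L

  for (i in seq_len(n)) {
    qj <- query$junctions[[qtx$transcript_id[i]]]
    if (length(qj) == 0L) {
      hit <- which(as.character(seqnames(ref_ex)) == qtx$chrom[i] &
                     as.character(strand(ref_ex)) == qtx$strand[i] &
                     start(ref_ex) <= qtx$start[i] &
                     end(ref_ex) >= qtx$end[i])
      if (length(hit) > 0L) {
        cls[i] <- "FSM"
        matched[i] <- mcols(ref_ex)$transcript_id[hit[1L]]
      } else if (overlaps_gene[i]) {
        cls[i] <- "NNC"
      } else {
        cls[i] <- "intergenic"
      }
      next
    }
    qstr <- paste(qj, collapse = ";")
    fsm <- which(ref_strs == qstr)
    if (length(fsm) > 0L) {
      cls[i] <- "FSM"
      matched[i] <- names(ref_chains)[fsm[1L]]
      next
    }
    ism <- which(vapply(ref_chains, function(rc) chain_is_infix(qj, rc), TRUE))
    if (length(ism) > 0L) {
      cls[i] <- "ISM"
      matched[i] <- names(ref_chains)[ism[1L]]
      next
    }
    if (!overlaps_gene[i]) {
      cls[i] <- "intergenic"
      next
    }
    cls[i] <- if (all(qj %in% catalog)) "NIC" else "NNC"
  }
  data.frame(transcript_id = qtx$transcript_id,
             class = factor(cls, levels = SPLICE_CLASSES),
             matched_ref = matched, stringsAsFactors = FALSE)
}

#' Sequential long-read transcript support filters
#'
#' Applies, in order: (1) supported by >= 2 full-length reads; (2) detected
#' in more than one sample; (3) every splice junction covered by short-read
#' data (coverage >= 1; mono-exonic transcripts pass); (4) any short-read
#' coverage at all. Removal counts are reported per filter in application
#' order, so a transcript failing several filters is charged to the first.
#'
#' @param models A `transcript_models` object.
#' @param support data.frame with columns `transcript_id`, `fl_count`,
#'   `n_samples`, `min_junction_cov` (NA for mono-exonic), `has_coverage`.
#' @return List with `retained` (transcript ids) and `removed` (named integer
#'   vector of per-filter removal counts).
#' @export
support_filters <- function(models, support) {
  ids <- models$tx$transcript_id
  miss <- setdiff(ids, support$transcript_id)
  if (length(miss)) stop("missing support record for transcript ", miss[1L])
  s <- support[match(ids, support$transcript_id), , drop = FALSE]
  removed <- integer(4)
  names(removed) <- c("fl_reads_lt_2", "single_sample",
                      "uncovered_junction", "no_coverage")
  alive <- rep(TRUE, length(ids))
  fail1 <- alive & s$fl_count < 2
  removed[1L] <- sum(fail1)
  alive <- alive & !fail1
  fail2 <- alive & s$n_samples < 2
  removed[2L] <- sum(fail2)
  alive <- alive & !fail2
  jc <- ifelse(is.na(s$min_junction_cov), Inf, s$min_junction_cov)
  fail3 <- alive & jc < 1
  removed[3L] <- sum(fail3)
  alive <- alive & !fail3
  fail4 <- alive & !s$has_coverage
  removed[4L] <- sum(fail4)
  alive <- alive & !fail4
  list(retained = ids[alive], removed = removed)
}

#' Flag potential intra-priming artifacts
#'
#' A transcript is flagged when the 20 bp genomic window immediately 3' of
#' its TTS contains 80% or more adenines on the transcript's sense strand
#' (genomic A for + transcripts; genomic T, read as sense-strand A, for -
#' transcripts) - the signature of oligo-dT mispriming on an A-rich tract.
#' Windows truncated at the chromosome end use the available bases.
#'
#' @param models A `transcript_models` object.
#' @param genome Named `DNAStringSet` (chromosome sequences).
#' @param window Window size in bp downstream of the TTS.
#' @param a_fraction Flagging threshold on the A fraction (inclusive).
#' @return Named logical vector per transcript.
#' @export
intra_priming_flag <- function(models, genome, window = 20L,
                               a_fraction = 0.80) {
  tx <- models$tx
  out <- logical(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    chr_seq <- genome[[tx$chrom[i]]]
    len <- length(chr_seq)
    if (tx$strand[i] == "+") {
      from <- tx$tts[i] + 1L
      to <- min(len, tx$tts[i] + window)
      base <- "A"
    } else {
      from <- max(1L, tx$tts[i] - window)
      to <- tx$tts[i] - 1L
      base <- "T"
    }
    if (from > to) {
      warning("empty TTS-downstream window for ", tx$transcript_id[i])
      next
    }
    win <- Biostrings::subseq(chr_seq, from, to)
    frac <- Biostrings::letterFrequency(win, base) / length(win)
    out[i] <- frac >= a_fraction
  }
  stats::setNames(out, tx$transcript_id)
}

# Junction chain in transcript (5'->3') orientation.
oriented_chain <- function(models, id) {
  j <- models$junctions[[id]]
  if (models$tx$strand[match(id, models$tx$transcript_id)] == "-") rev(j) else j
}

#' Collapse 5'-degraded transcripts
#'
#' Transcripts with identical 3' ends (same chromosome, strand and TTS,
#' within `tts_tol`) whose junction chain is a 3'-anchored suffix of a longer
#' transcript's chain are absorbed into that longer transcript (mono-exonic
#' transcripts: absorbed when contained in the longer transcript's 3'-terminal
#' exon). The representative of each group is the longest member.
#'
#' @param models A `transcript_models` object.
#' @param tts_tol TTS matching tolerance in bp (default 0 = identical).
#' @return List with `models` (collapsed set) and `mapping` (data.frame:
#'   transcript_id, representative).
#' @export
collapse_5prime_degraded <- function(models, tts_tol = 0L) {
  tx <- models$tx
  rep_of <- stats::setNames(tx$transcript_id, tx$transcript_id)
  for (key in unique(paste(tx$chrom, tx$strand))) {
    idx <- which(paste(tx$chrom, tx$strand) == key)
    if (length(idx) < 2L) next
    # cluster by TTS within tolerance
    o <- idx[order(tx$tts[idx])]
    cl <- cumsum(c(1L, diff(tx$tts[o]) > tts_tol))
    for (g in split(o, cl)) {
      if (length(g) < 2L) next
      g <- g[order(-(tx$end[g] - tx$start[g]), tx$transcript_id[g])]
      reps <- integer(0)
      for (i in g) {
        id_i <- tx$transcript_id[i]
        ch_i <- oriented_chain(models, id_i)
        absorbed <- FALSE
        for (r in reps) {
          id_r <- tx$transcript_id[r]
          ch_r <- oriented_chain(models, id_r)
          if (length(ch_i) == 0L) {
            # mono-exonic: must sit inside the representative's 3'-terminal exon
            ex_r <- models$exons[[id_r]]
            term <- if (tx$strand[r] == "+") ex_r[length(ex_r)] else ex_r[1L]
            if (start(term) <= tx$start[i] && end(term) >= tx$end[i]) {
              absorbed <- TRUE
            }
          } else if (length(ch_i) <= length(ch_r) &&
                     identical(utils::tail(ch_r, length(ch_i)), ch_i)) {
            absorbed <- TRUE
          }
          if (absorbed) {
            rep_of[id_i] <- id_r
            break
          }
        }
        if (!absorbed) reps <- c(reps, i)
      }
    }
  }
  keep <- names(rep_of)[rep_of == names(rep_of)]
  list(models = subset_models(models, keep),
       mapping = data.frame(transcript_id = names(rep_of),
                            representative = unname(rep_of),
                            stringsAsFactors = FALSE))
}

#' Signed TTS distance between matched query and reference transcripts
#'
#' Positive values mean the query TTS extends 3' beyond the reference TTS;
#' negative values mean a shorter 3' end.
#'
#' @param query,reference `transcript_models` objects.
#' @param matches data.frame with `transcript_id` (query) and `matched_ref`
#'   columns, e.g. from [classify_splice_match()].
#' @return Named numeric vector of signed distances.
#' @export
tts_distance <- function(query, reference, matches) {
  if (any(is.na(matches$matched_ref))) {
    stop("unmatched query transcript: ",
         matches$transcript_id[is.na(matches$matched_ref)][1L])
  }
  qi <- match(matches$transcript_id, query$tx$transcript_id)
  ri <- match(matches$matched_ref, reference$tx$transcript_id)
  if (anyNA(qi) || anyNA(ri)) stop("unknown transcript id in matches")
  strand <- query$tx$strand[qi]
  d <- ifelse(strand == "+",
              query$tx$tts[qi] - reference$tx$tts[ri],
              reference$tx$tts[ri] - query$tx$tts[qi])
  stats::setNames(d, matches$transcript_id)
}

#' Log2 ratio of RNA-seq coverage downstream vs upstream of a TSS
#'
#' A genuine TSS shows higher coverage in the 100 bp window just inside the
#' transcript than just outside it. Windows falling off the chromosome are
#' truncated with a warning.
#'
#' @param tss TSS position (1-based).
#' @param strand "+" or "-".
#' @param coverage Numeric per-bp coverage vector for the chromosome.
#' @param window Window size in bp on each side.
#' @param pseudocount Added to both sums before the ratio.
#' @return log2((downstream + pseudocount) / (upstream + pseudocount)).
#' @export
tss_coverage_ratio <- function(tss, strand, coverage, window = 100L,
                               pseudocount = 1) {
  len <- length(coverage)
  clamp <- function(from, to) {
    if (from < 1L || to > len) {
      warning("TSS window truncated at chromosome bounds")
    }
    c(max(1L, from), min(len, to))
  }
  if (strand == "+") {
    dn <- clamp(tss, tss + window - 1L)
    up <- clamp(tss - window, tss - 1L)
  } else {
    dn <- clamp(tss - window + 1L, tss)
    up <- clamp(tss + 1L, tss + window)
  }
  sum_in <- function(w) if (w[1L] > w[2L]) 0 else sum(coverage[w[1L]:w[2L]])
  log2((sum_in(dn) + pseudocount) / (sum_in(up) + pseudocount))
}

#' Transcriptome summary statistics
#'
#' @param models A `transcript_models` object.
#' @param classes Result of [classify_splice_match()] for these transcripts.
#' @param tpm Transcripts x tissues TPM matrix (rownames = transcript ids).
#' @param detect_threshold TPM at or above which a transcript counts as
#'   detected in a tissue.
#' @return List of summaries: class counts, multi-exonic count, isoform:gene
#'   ratio, tissues-detected histograms for known (FSM/ISM) vs novel
#'   transcripts, fraction of known transcripts detected in at least half the
#'   tissues, per-tissue fraction of multi-isoform genes expressing more than
#'   one isoform, and the dominant isoform per gene per tissue.
#' @export
transcriptome_stats <- function(models, classes, tpm, detect_threshold = 0.1) {
  tx <- models$tx
  stopifnot(identical(sort(rownames(tpm)), sort(tx$transcript_id)))
  tpm <- tpm[tx$transcript_id, , drop = FALSE]
  cls <- classes$class[match(tx$transcript_id, classes$transcript_id)]
  known <- cls %in% c("FSM", "ISM")
  det <- tpm >= detect_threshold
  n_det <- rowSums(det)
  n_tis <- ncol(tpm)

  hist_of <- function(sel) table(factor(n_det[sel], levels = 0:n_tis))

  gene_of <- tx$gene_id
  multi_iso_genes <- names(which(table(gene_of) > 1L))
  frac_multi <- vapply(colnames(tpm), function(tis) {
    expressed <- det[, tis]
    per_gene <- tapply(expressed, gene_of, sum)
    per_gene <- per_gene[multi_iso_genes]
    active <- per_gene[per_gene >= 1L]
    if (length(active) == 0L) return(NA_real_)
    mean(active > 1L)
  }, 0)

  dominant <- sapply(colnames(tpm), function(tis) {
    vapply(split(seq_len(nrow(tx)), gene_of), function(i) {
      tx$transcript_id[i[which.max(tpm[i, tis])]]
    }, "")
  })

  list(class_counts = table(cls),
       n_transcripts = nrow(tx),
       n_multi_exonic = sum(tx$n_exons > 1L),
       n_genes = length(unique(gene_of)),
       isoform_gene_ratio = nrow(tx) / length(unique(gene_of)),
       detected_hist_known = hist_of(known),
       detected_hist_novel = hist_of(!known),
       frac_known_in_half_tissues = mean(n_det[known] >= n_tis / 2),
       frac_multi_isoform_expressed = frac_multi,
       dominant_isoform = dominant)
}
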