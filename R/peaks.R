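#' Extend peak summits to fixed-width peaks
#'
#' Each summit is extended by `flank` bp on both sides, giving fixed-width
#' peaks of `2 * flank + 1` bp (501 bp at the default), clipped to chromosome
#' bounds. Clipped edge peaks are kept. Score and summit are preserved.
#'
#' @param peaks GRanges with `score` and `summit` metadata.
#' @param flank Extension on each side of the summit, bp.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return GRanges of fixed-width (post-clipping) peaks.
#' @export
summits_to_fixed_peaks <- function(peaks, flank = 250L, chrom_sizes) {
  validate_peaks(peaks)
  chr <- as.character(seqnames(peaks))
  if (any(!chr %in% names(chrom_sizes))) {
    stop("peak on unknown chromosome: ", setdiff(chr, names(chrom_sizes))[1L])
  }
  s <- mcols(peaks)$summit
  if (any(s < 1L) || any(s > chrom_sizes[chr])) {
    stop("summit outside chromosome bounds")
  }
  out <- GRanges(chr, IRanges(pmax(1L, s - flank),
                              pmin(chrom_sizes[chr], s + flank)))
  mcols(out)$score <- mcols(peaks)$score
  mcols(out)$summit <- s
  out
}

# Deterministic greedy order: score desc, then chrom, start, end ascending.
greedy_order <- function(peaks) {
  order(-mcols(peaks)$score, as.character(seqnames(peaks)),
        start(peaks), end(peaks))
}

#' Iterative non-overlap merge of scored peaks
#'
#' Greedy filtering by significance: peaks are visited in descending score
#' order (ties broken by chromosome, then start, then end, so the leftmost
#' peak wins) and a peak is retained iff it overlaps no already-retained peak.
#' This yields a reproducible, pairwise non-overlapping peak set in which the
#' most significant peak of every overlapping cluster survives.
#'
#' @param peaks GRanges with `score` metadata (summit optional).
#' @return Retained peaks, sorted by coordinate.
#' @export
iterative_nonoverlap_merge <- function(peaks) {
  if (length(peaks) == 0L) return(peaks)
  stopifnot(!is.null(mcols(peaks)$score))
  ord <- greedy_order(peaks)
  hits <- findOverlaps(peaks, peaks, ignore.strand = TRUE)
  hits <- hits[queryHits(hits) != subjectHits(hits)]
  nbr <- split(subjectHits(hits), queryHits(hits))
  kept <- logical(length(peaks))
  blocked <- logical(length(peaks))
  for (i in ord) {
    if (blocked[i]) next
    kept[i] <- TRUE
    ni <- nbr[[as.character(i)]]
    if (!is.null(ni)) blocked[ni] <- TRUE
  }
  sort(peaks[kept], ignore.strand = TRUE)
}

#' Merge replicate peak sets into tissue sets and a union set
#'
#' Replicate-level fixed-width peaks are pooled and greedily merged per tissue
#' with [iterative_nonoverlap_merge()]; the tissue-level results are then
#' pooled and merged once more into the union set, mirroring the two-level
#' merge used to build a cross-tissue open-chromatin catalog.
#'
#' @param peaks_by_tissue Named list (tissue) of lists (replicate) of GRanges
#'   with `score` metadata, already fixed-width.
#' @return List with `tissue_sets` (named list of GRanges) and `union`
#'   (GRanges).
#' @export
hierarchical_union <- function(peaks_by_tissue) {
  stopifnot(length(peaks_by_tissue) >= 1L, !is.null(names(peaks_by_tissue)))
  tissue_sets <- list()
  for (tis in names(peaks_by_tissue)) {
    reps <- peaks_by_tissue[[tis]]
    reps <- reps[lengths(reps) > 0L]
    if (length(reps) == 0L) {
      warning("tissue with no peaks excluded: ", tis)
      next
    }
    pooled <- suppressWarnings(do.call(c, unname(reps)))
    tissue_sets[[tis]] <- iterative_nonoverlap_merge(pooled)
  }
  if (length(tissue_sets) == 0L) stop("no tissue contributed any peaks")
  pooled <- suppressWarnings(do.call(c, unname(tissue_sets)))
  list(tissue_sets = tissue_sets,
       union = iterative_nonoverlap_merge(pooled))
}

#' Classify union peaks by tissue sharing
#'
#' A union peak is present in a tissue iff it overlaps (>= 1 bp) at least one
#' peak of that tissue's set. Peaks present in exactly one tissue are labelled
#' `unique`; peaks present in all tissues are labelled `conserved`.
#'
#' @param union GRanges union peak set.
#' @param tissue_sets Named list of per-tissue GRanges.
#' @return data.frame with `n_tissues`, `label`, and one logical column per
#'   tissue.
#' @export
classify_sharing <- function(union, tissue_sets) {
  pres <- vapply(tissue_sets, function(ts) {
    countOverlaps(union, ts, ignore.strand = TRUE) > 0L
  }, logical(length(union)))
  pres <- matrix(pres, nrow = length(union),
                 dimnames = list(NULL, names(tissue_sets)))
  n <- rowSums(pres)
  if (any(n == 0L)) {
    stop("union peak present in zero tissues (index ", which(n == 0L)[1L], ")")
  }
  label <- rep(NA_character_, length(union))
  label[n == 1L] <- "unique"
  label[n == length(tissue_sets)] <- "conserved"
  data.frame(n_tissues = n, label = label, pres)
}

#' Count transposase insertion events per peak per sample
#'
#' Insertion sites are single-bp positions (Tn5 shift applied upstream).
#'
#' @param union GRanges union peak set.
#' @param sites_by_sample Named list of width-1 GRanges, one per sample.
#' @return Integer matrix, peaks x samples.
#' @export
insertion_count_matrix <- function(union, sites_by_sample) {
  stopifnot(length(sites_by_sample) >= 1L, !is.null(names(sites_by_sample)))
  m <- vapply(sites_by_sample, function(s) {
    if (length(s) > 0L) stopifnot(all(width(s) == 1L))
    countOverlaps(union, s, ignore.strand = TRUE)
  }, integer(length(union)))
  m <- matrix(m, nrow = length(union),
              dimnames = list(paste0("peak_", seq_along(union)),
                              names(sites_by_sample)))
  m
}

#' Build histone-anchored truth sets for ROC calibration
#'
#' Real positives (RP) are H3K4me1 and H3K4me3 peaks merged together and
#' filtered to elements overlapping at least one H3K27ac peak (active
#' enhancer/promoter evidence). Real negatives (RN) are H3K27me3 peaks;
#' any RN element overlapping an RP element is dropped as uninformative.
#'
#' @param h3k4me1,h3k4me3,h3k27ac,h3k27me3 GRanges of histone peaks from one
#'   tissue.
#' @return List with `rp` and `rn` GRanges.
#' @export
build_truth_sets <- function(h3k4me1, h3k4me3, h3k27ac, h3k27me3) {
  merged <- merge_intervals(c(granges(h3k4me1), granges(h3k4me3)), gap = 0L)
  rp <- merged[countOverlaps(merged, h3k27ac, ignore.strand = TRUE) > 0L]
  rn <- granges(h3k27me3)
  rn <- rn[countOverlaps(rn, rp, ignore.strand = TRUE) == 0L]
  if (length(rp) == 0L || length(rn) == 0L) {
    stop("tissue cannot be ROC-calibrated: empty RP or RN set")
  }
  list(rp = rp, rn = rn)
}

#' ROC curve of peak scores against histone truth sets
#'
#' At each distinct score cutoff (peaks with score >= cutoff retained), nTP is
#' the number of retained peaks overlapping any RP element and nFP the number
#' overlapping any RN element; TPR = nTP/nRP and FPR = nFP/nRN divide by the
#' number of truth *elements*, so TPR/FPR can exceed 1 when several peaks hit
#' one element and are reported unclamped. Precision = nTP/(nTP+nFP) (NA when
#' no peaks are retained). AUC is the trapezoidal area over (FPR, TPR) after
#' clamping the curve to the unit box and anchoring at (0,0) and (1,1).
#'
#' @param peaks GRanges with `score` metadata.
#' @param truth List with `rp` and `rn` GRanges (see [build_truth_sets()]).
#' @return List with `points` (data.frame: cutoff, ntp, nfp, tpr, fpr,
#'   precision, cutoffs descending) and `auc`.
#' @export
roc_curve <- function(peaks, truth) {
  stopifnot(length(truth$rp) > 0L, length(truth$rn) > 0L)
  n_rp <- length(truth$rp)
  n_rn <- length(truth$rn)
  score <- mcols(peaks)$score
  hit_rp <- countOverlaps(peaks, truth$rp, ignore.strand = TRUE) > 0L
  hit_rn <- countOverlaps(peaks, truth$rn, ignore.strand = TRUE) > 0L
  ord <- order(score, decreasing = TRUE)
  s_sorted <- score[ord]
  cum_tp <- cumsum(hit_rp[ord])
  cum_fp <- cumsum(hit_rn[ord])
  # last index at each distinct cutoff = all peaks with score >= cutoff
  last <- cumsum(rle(s_sorted)$lengths)
  cutoff <- s_sorted[last]
  ntp <- cum_tp[last]
  nfp <- cum_fp[last]
  nret <- last
  pts <- data.frame(cutoff = cutoff, ntp = ntp, nfp = nfp,
                    tpr = ntp / n_rp, fpr = nfp / n_rn,
                    precision = ifelse(nret > 0L, ntp / pmax(ntp + nfp, 1L),
                                       NA_real_))
  pts$precision[ntp + nfp == 0L] <- NA_real_
  x <- pmin(pmax(pts$fpr, 0), 1)
  y <- pmin(pmax(pts$tpr, 0), 1)
  x <- c(0, x, 1)
  y <- c(0, y, 1)
  o <- order(x, y)
  x <- x[o]
  y <- y[o]
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Select a score cutoff at a target false positive rate
#'
#' Returns the smallest cutoff whose FPR is at or below the target, i.e. the
#' most permissive threshold honouring the FPR bound (the study filtered each
#' tissue at 25% FPR). If no cutoff satisfies the bound, the maximum cutoff is
#' returned with a warning.
#'
#' @param roc Result of [roc_curve()].
#' @param fpr_target Maximum tolerated FPR (default 0.25).
#' @return Score cutoff; peaks with score below it are removed.
#' @export
select_cutoff <- function(roc, fpr_target = 0.25) {
  pts <- roc$points
  stopifnot(nrow(pts) > 0L)
  ok <- pts$fpr <= fpr_target
  if (!any(ok)) {
    warning("no cutoff achieves FPR <= ", fpr_target, "; using maximum cutoff")
    return(max(pts$cutoff))
  }
  min(pts$cutoff[ok])
}

#' Quantile score cutoff for tissues without histone truth sets
#'
#' Fallback used when no histone data exist for a tissue (testis in the
#' study): the cutoff is the q-th quantile of peak scores (type 7, linear
#' interpolation) and peaks with score >= cutoff (the top 1-q fraction) are
#' retained.
#'
#' @param peaks GRanges with `score` metadata.
#' @param q Quantile in `[0, 1]` (default 0.85).
#' @return Score cutoff.
#' @export
quantile_cutoff <- function(peaks, q = 0.85) {
  if (q < 0 || q > 1) stop("quantile must be in [0, 1]")
  stopifnot(length(peaks) >= 1L)
  unname(stats::quantile(mcols(peaks)$score, probs = q, type = 7))
}
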