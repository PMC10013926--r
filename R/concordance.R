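#' Pair peaks with genes through promoter-TSS windows
#'
#' A peak pairs with a gene iff it overlaps the TSS +/- `halfwidth` window of
#' any of the gene's transcripts. A peak may pair with several genes and a
#' gene with several peaks.
#'
#' @param peaks GRanges with a `name` metadata column (peak ids).
#' @param models A `transcript_models` object.
#' @param halfwidth Promoter window half-width in bp.
#' @return data.frame with `peak_id`, `gene_id`.
#' @export
pair_promoter_peaks <- function(peaks, models, halfwidth = 2000) {
  tssw <- end_windows(models, "tss", halfwidth, per_gene = TRUE)
  hits <- findOverlaps(peaks, tssw, ignore.strand = TRUE)
  ids <- mcols(peaks)$name
  if (is.null(ids)) ids <- paste0("peak_", seq_along(peaks))
  unique(data.frame(peak_id = ids[queryHits(hits)],
                    gene_id = mcols(tssw)$gene_id[subjectHits(hits)],
                    stringsAsFactors = FALSE))
}

#' Classify promoter peak-gene pairs into concordance quadrants
#'
#' Pairs whose differential-expression and differential-accessibility records
#' are both significant (adjusted p below `fdr`) are assigned a quadrant by
#' the signs of the two log2 fold changes: Q1 both up, Q3 both down
#' (concordant); Q2 expression up / accessibility down, Q4 the reverse
#' (discordant). Zero fold changes are excluded. Gene-level counts
#' deduplicate genes paired with several significant peaks by majority
#' fold-change sign of their peaks (ties excluded).
#'
#' @param pairs data.frame with `peak_id`, `gene_id`.
#' @param deg data.frame with `feature_id`, `log2fc`, `p_adj` for genes.
#' @param dar Same, for peaks.
#' @param fdr Significance threshold on both adjusted p-values.
#' @return List with `calls` (pair-level data.frame: peak_id, gene_id,
#'   log2fc_expr, log2fc_acc, quadrant), `pair_counts`, `gene_counts`,
#'   `n_excluded_zero_fc`, `n_excluded_tied_genes`.
#' @export
quadrant_classify <- function(pairs, deg, dar, fdr = 0.05) {
  gi <- match(pairs$gene_id, deg$feature_id)
  pi <- match(pairs$peak_id, dar$feature_id)
  missing <- is.na(gi) | is.na(pi)
  if (any(missing)) {
    message(sum(missing), " pair(s) skipped: no differential record")
  }
  keep <- !missing
  df <- data.frame(peak_id = pairs$peak_id[keep],
                   gene_id = pairs$gene_id[keep],
                   log2fc_expr = deg$log2fc[gi[keep]],
                   p_expr = deg$p_adj[gi[keep]],
                   log2fc_acc = dar$log2fc[pi[keep]],
                   p_acc = dar$p_adj[pi[keep]],
                   stringsAsFactors = FALSE)
  df <- df[df$p_expr < fdr & df$p_acc < fdr, , drop = FALSE]
  zero <- df$log2fc_expr == 0 | df$log2fc_acc == 0
  if (any(zero)) message(sum(zero), " pair(s) excluded: zero fold change")
  df <- df[!zero, , drop = FALSE]
  df$quadrant <- ifelse(df$log2fc_expr > 0,
                        ifelse(df$log2fc_acc > 0, "Q1", "Q2"),
                        ifelse(df$log2fc_acc < 0, "Q3", "Q4"))
  pair_counts <- table(factor(df$quadrant, levels = c("Q1", "Q2", "Q3", "Q4")))

  # gene-level: majority accessibility sign across the gene's peaks
  tied <- 0L
  gene_rows <- list()
  for (g in unique(df$gene_id)) {
    sub <- df[df$gene_id == g, , drop = FALSE]
    sgn <- sum(sign(sub$log2fc_acc))
    if (sgn == 0) {
      tied <- tied + 1L
      next
    }
    gene_rows[[g]] <- data.frame(
      gene_id = g, log2fc_expr = sub$log2fc_expr[1L],
      acc_sign = sign(sgn),
      quadrant = ifelse(sub$log2fc_expr[1L] > 0,
                        ifelse(sgn > 0, "Q1", "Q2"),
                        ifelse(sgn < 0, "Q3", "Q4")))
  }
  if (tied > 0L) message(tied, " gene(s) excluded: tied peak signs")
  gene_df <- do.call(rbind, gene_rows)
  gene_counts <- table(factor(if (is.null(gene_df)) character(0) else
    gene_df$quadrant, levels = c("Q1", "Q2", "Q3", "Q4")))
  list(calls = df, pair_counts = pair_counts, gene_counts = gene_counts,
       n_excluded_zero_fc = sum(zero), n_excluded_tied_genes = tied)
}

#' Pearson correlation of accessibility and expression fold changes
#'
#' @param pairs data.frame with `peak_id`, `gene_id`.
#' @param deg,dar Differential tables (`feature_id`, `log2fc`, `p_adj`).
#' @param restrict "all" uses every pair with records in both tables;
#'   "dar-significant" restricts to pairs whose accessibility record is
#'   significant at `fdr`.
#' @param fdr Threshold used by the `dar-significant` restriction.
#' @return List with `r` (Pearson), `p` (one-sided, H1: r > 0), `n`.
#' @export
fc_correlation <- function(pairs, deg, dar,
                           restrict = c("all", "dar-significant"),
                           fdr = 0.05) {
  restrict <- match.arg(restrict)
  gi <- match(pairs$gene_id, deg$feature_id)
  pi <- match(pairs$peak_id, dar$feature_id)
  keep <- !is.na(gi) & !is.na(pi)
  x <- dar$log2fc[pi[keep]]
  y <- deg$log2fc[gi[keep]]
  if (restrict == "dar-significant") {
    sig <- dar$p_adj[pi[keep]] < fdr
    x <- x[sig]
    y <- y[sig]
  }
  n <- length(x)
  if (n < 3L) stop("need >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in fold changes")
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = stats::pt(tstat, df = n - 2, lower.tail = FALSE), n = n)
}
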