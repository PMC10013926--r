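#' Predict CTCF-anchored chromatin loops from oriented motifs
#'
#' Scans each chromosome left to right over strand-oriented CTCF motif
#' occurrences and pairs motifs into convergent loops. The default `stack`
#' rule maintains a stack of unpaired forward (+) motifs; every reverse (-)
#' motif pops the most recent unpaired + motif and emits a loop from the +
#' motif's start to the - motif's end, giving nested convergent pairing.
#' Alternative rules are provided for sensitivity analysis: `nearest_next`
#' pairs each + motif with the nearest following unused - motif (sequential,
#' non-nested), and `all_convergent` emits every +/- pair within `max_span`.
#'
#' @param motifs GRanges of motif occurrences with strand `+` or `-`.
#' @param rule Pairing rule (see Details).
#' @param max_span Maximum loop span in bp for `all_convergent`.
#' @return GRanges of loops, sorted.
#' @export
scan_loops <- function(motifs, rule = c("stack", "nearest_next",
                                        "all_convergent"),
                       max_span = 3e6) {
  rule <- match.arg(rule)
  if (length(motifs) == 0L) return(GRanges())
  if (any(!as.character(strand(motifs)) %in% c("+", "-"))) {
    stop("motifs must be stranded (+ or -)")
  }
  loops <- list()
  for (chr in unique(as.character(seqnames(motifs)))) {
    m <- motifs[seqnames(motifs) == chr]
    m <- m[order(start(m), end(m))]
    st <- as.character(strand(m))
    if (rule == "stack") {
      stack <- integer(0)
      for (i in seq_along(m)) {
        if (st[i] == "+") {
          stack <- c(stack, i)
        } else if (length(stack) > 0L) {
          j <- stack[length(stack)]
          stack <- stack[-length(stack)]
          loops[[length(loops) + 1L]] <-
            GRanges(chr, IRanges(start(m)[j], end(m)[i]))
        }
      }
    } else if (rule == "nearest_next") {
      used_minus <- logical(length(m))
      minus_idx <- which(st == "-")
      for (i in which(st == "+")) {
        nxt <- minus_idx[minus_idx > i & !used_minus[minus_idx]]
        if (length(nxt) == 0L) next
        j <- nxt[1L]
        used_minus[j] <- TRUE
        loops[[length(loops) + 1L]] <-
          GRanges(chr, IRanges(start(m)[i], end(m)[j]))
      }
    } else {
      for (i in which(st == "+")) {
        for (j in which(st == "-")) {
          if (j > i && end(m)[j] - start(m)[i] + 1L <= max_span) {
            loops[[length(loops) + 1L]] <-
              GRanges(chr, IRanges(start(m)[i], end(m)[j]))
          }
        }
      }
    }
  }
  if (length(loops) == 0L) return(GRanges())
  sort(unlist(GRangesList(loops), use.names = FALSE), ignore.strand = TRUE)
}

#' Merge per-tissue loops into a pan-tissue catalog
#'
#' Loops from all tissues are merged (overlapping or bookended unioned) into
#' a catalog of non-overlapping pan-tissue loops, and the fraction of the
#' genome covered is reported.
#'
#' @param loops_by_tissue Named list of GRanges of loops.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return List with `loops` (sorted, disjoint GRanges) and `coverage`
#'   (fraction of genome covered).
#' @export
pan_tissue_loops <- function(loops_by_tissue, chrom_sizes) {
  stopifnot(length(loops_by_tissue) >= 1L)
  pooled <- do.call(c, unname(lapply(loops_by_tissue, granges)))
  merged <- merge_intervals(pooled, gap = 0L)
  list(loops = merged,
       coverage = genome_fraction_covered(merged, chrom_sizes))
}

# Representative TSS per gene: the 5'-most TSS over the gene's transcripts.
gene_tss_table <- function(models) {
  tx <- models$tx
  sp <- split(seq_len(nrow(tx)), tx$gene_id)
  data.frame(
    gene_id = names(sp),
    chrom = vapply(sp, function(i) tx$chrom[i[1L]], ""),
    strand = vapply(sp, function(i) tx$strand[i[1L]], ""),
    tss = vapply(sp, function(i) {
      if (tx$strand[i[1L]] == "+") min(tx$tss[i]) else max(tx$tss[i])
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Signed distance from a point to a gene TSS; negative = point is 5' (upstream)
# of the TSS on the gene's strand.
signed_tss_distance <- function(point, tss, strand) {
  ifelse(strand == "+", point - tss, tss - point)
}

#' Assemble candidate cis-regulatory elements from active chromatin states
#'
#' Segments in active states (promoter/enhancer/insulator states 2-5 and
#' 8-11 by default) are merged when overlapping or within `gap` bp, then
#' annotated by proximity to genes: `TSS-promoter` if the CRE overlaps any
#' TSS +/- `promoter_halfwidth` window, else `genic` if it overlaps any gene
#' body, else `intergenic`. The closest gene is the one whose representative
#' TSS is nearest the CRE midpoint; the signed distance is negative when the
#' CRE lies upstream (5') of that TSS on the gene's strand.
#'
#' @param segments GRanges with a `state` metadata column.
#' @param models A `transcript_models` object.
#' @param active_states Integer vector of active state labels.
#' @param gap Merge gap in bp (default 0 = overlapping/bookended).
#' @param promoter_halfwidth TSS window half-width in bp.
#' @return GRanges of CREs with `cre_id`, `proximity`, `closest_gene`,
#'   `tss_distance` metadata.
#' @export
build_cres <- function(segments, models,
                       active_states = c(2:5, 8:11), gap = 0L,
                       promoter_halfwidth = 2000) {
  stopifnot(!is.null(mcols(segments)$state))
  act <- segments[mcols(segments)$state %in% active_states]
  cres <- merge_intervals(granges(act), gap = gap)
  if (length(cres) == 0L) return(cres)
  mcols(cres)$cre_id <- paste0("cre_", seq_along(cres))

  tssw <- end_windows(models, "tss", promoter_halfwidth)
  gb <- gene_bodies(models)
  prox <- rep("intergenic", length(cres))
  prox[countOverlaps(cres, gb, ignore.strand = TRUE) > 0L] <- "genic"
  prox[countOverlaps(cres, tssw, ignore.strand = TRUE) > 0L] <- "TSS-promoter"
  mcols(cres)$proximity <- prox

  gt <- gene_tss_table(models)
  mid <- floor((start(cres) + end(cres)) / 2)
  closest <- rep(NA_character_, length(cres))
  dist <- rep(NA_real_, length(cres))
  for (i in seq_along(cres)) {
    cand <- which(gt$chrom == as.character(seqnames(cres))[i])
    if (length(cand) == 0L) next
    d <- abs(gt$tss[cand] - mid[i])
    j <- cand[which.min(d)]
    closest[i] <- gt$gene_id[j]
    dist[i] <- signed_tss_distance(mid[i], gt$tss[j], gt$strand[j])
  }
  mcols(cres)$closest_gene <- closest
  mcols(cres)$tss_distance <- dist
  cres
}

#' TMM scaling factors (weighted trimmed mean of M-values)
#'
#' Between-sample normalization factors for count matrices, robust to
#' composition bias. The reference sample is the one whose 75th-percentile
#' count fraction is closest to the mean across samples. For every other
#' sample, gene-wise log ratios M and mean log abundances A are computed on
#' genes with positive counts in both sample and reference, doubly trimmed
#' (`trim_m` of the M values, `trim_a` of the A values), and the factor is
#' 2 to the inverse-variance-weighted mean of the surviving M values. Factors
#' are rescaled to geometric mean 1.
#'
#' @param counts Non-negative count matrix, features x samples (>= 2 samples,
#'   no all-zero columns).
#' @param trim_m Fraction of M values trimmed from each tail (default 0.30).
#' @param trim_a Fraction of A values trimmed from each tail (default 0.05).
#' @return Named numeric vector of scaling factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2L, all(counts >= 0))
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample column")
  f75 <- apply(counts, 2L, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    obs <- counts[, j]
    rfc <- counts[, ref]
    pos <- obs > 0 & rfc > 0
    obs <- obs[pos]
    rfc <- rfc[pos]
    m <- log2((obs / lib[j]) / (rfc / lib[ref]))
    a <- 0.5 * log2((obs / lib[j]) * (rfc / lib[ref]))
    v <- (lib[j] - obs) / (lib[j] * obs) + (lib[ref] - rfc) / (lib[ref] * rfc)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1
    hi_a <- n + 1 - lo_a
    rm_ <- rank(m)
    ra <- rank(a)
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
    if (sum(keep) < 10L) {
      warning("fewer than 10 features survive trimming; using untrimmed mean")
      keep <- rep(TRUE, n)
    }
    2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  }, 0)
  fac <- fac / exp(mean(log(fac)))
  stats::setNames(fac, colnames(counts))
}

# Spearman rho with average-rank ties plus two-sided p via the t
# approximation: t = rho * sqrt((n-2)/(1-rho^2)).
spearman_test <- function(x, y) {
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Link CREs to target genes by within-loop expression correlation
#'
#' Every (CRE, gene) pair whose CRE midpoint and gene TSS fall inside the same
#' merged loop is tested: Spearman correlation between the CRE's normalized
#' H3K27ac counts and the gene's normalized RNA counts across shared samples,
#' two-sided p by the t approximation, Benjamini-Hochberg adjustment over all
#' tested pairs jointly. Pairs with adjusted p at or below `fdr` are flagged
#' significant. Counts are scaled by TMM factor x library size before
#' correlation (rank-invariant, kept for table interpretability).
#'
#' @param cre_counts H3K27ac count matrix, CREs x samples (rownames = cre ids).
#' @param gene_counts RNA count matrix, genes x samples.
#' @param cres GRanges from [build_cres()].
#' @param models A `transcript_models` object (gene TSS positions).
#' @param loops GRanges of merged pan-tissue loops.
#' @param fdr FDR threshold for the `significant` flag (default 0.05).
#' @param normalize Apply TMM x library-size scaling before correlating.
#' @return data.frame of all tested pairs: cre_id, gene_id, loop_id, rho,
#'   p_raw, p_adj, proximity, tss_distance, significant.
#' @export
spearman_link <- function(cre_counts, gene_counts, cres, models, loops,
                          fdr = 0.05, normalize = TRUE) {
  samples <- intersect(colnames(cre_counts), colnames(gene_counts))
  if (length(samples) < 5L) stop("need >= 5 shared samples")
  cm <- as.matrix(cre_counts[, samples, drop = FALSE])
  gm <- as.matrix(gene_counts[, samples, drop = FALSE])
  if (normalize) {
    cm <- sweep(cm, 2L, tmm_factors(cm) * colSums(cm), "/") * 1e6
    gm <- sweep(gm, 2L, tmm_factors(gm) * colSums(gm), "/") * 1e6
  }

  mid <- GRanges(seqnames(cres),
                 IRanges(floor((start(cres) + end(cres)) / 2), width = 1L))
  cre_loop <- findOverlaps(mid, loops, ignore.strand = TRUE)
  gt <- gene_tss_table(models)
  gt <- gt[gt$gene_id %in% rownames(gm), , drop = FALSE]
  tss_gr <- GRanges(gt$chrom, IRanges(gt$tss, width = 1L))
  gene_loop <- findOverlaps(tss_gr, loops, ignore.strand = TRUE)

  cre_by_loop <- split(queryHits(cre_loop), subjectHits(cre_loop))
  gene_by_loop <- split(queryHits(gene_loop), subjectHits(gene_loop))
  shared_loops <- intersect(names(cre_by_loop), names(gene_by_loop))

  pairs <- list()
  seen <- character(0)
  for (lp in shared_loops) {
    for (ci in cre_by_loop[[lp]]) {
      for (gi in gene_by_loop[[lp]]) {
        key <- paste0(ci, "_", gi)
        if (key %in% seen) next
        seen <- c(seen, key)
        pairs[[length(pairs) + 1L]] <- c(as.integer(lp), ci, gi)
      }
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(cre_id = character(0), gene_id = character(0),
                      loop_id = integer(0), rho = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      proximity = character(0), tss_distance = numeric(0),
                      significant = logical(0)))
  }
  pm <- do.call(rbind, pairs)
  cre_ids <- mcols(cres)$cre_id[pm[, 2L]]
  gene_ids <- gt$gene_id[pm[, 3L]]

  keep <- cre_ids %in% rownames(cm)
  pm <- pm[keep, , drop = FALSE]
  cre_ids <- cre_ids[keep]
  gene_ids <- gene_ids[keep]

  rho <- p <- rep(NA_real_, length(cre_ids))
  for (k in seq_along(cre_ids)) {
    x <- cm[cre_ids[k], ]
    y <- gm[gene_ids[k], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # constant: skipped
    st <- spearman_test(x, y)
    rho[k] <- st["rho"]
    p[k] <- st["p"]
  }
  dropped <- is.na(p)
  if (any(dropped)) {
    message(sum(dropped), " pair(s) skipped: constant count vector")
  }
  mid_pos <- floor((start(cres) + end(cres)) / 2)[pm[, 2L]]
  gidx <- pm[, 3L]
  out <- data.frame(
    cre_id = cre_ids, gene_id = gene_ids, loop_id = pm[, 1L],
    rho = rho, p_raw = p, p_adj = NA_real_,
    proximity = mcols(cres)$proximity[pm[, 2L]],
    tss_distance = signed_tss_distance(mid_pos, gt$tss[gidx],
                                       gt$strand[gidx]),
    significant = FALSE, stringsAsFactors = FALSE)
  out <- out[!dropped, , drop = FALSE]
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj <= fdr
  rownames(out) <- NULL
  out
}

#' Summarise CRE-to-target distances of significant links
#'
#' Reports, separately for all links and for intergenic links, the median
#' absolute CRE-TSS distance, the fraction of CREs within 1 Mb of their
#' target TSS, the fraction located downstream (3') of the target TSS
#' (positive signed distance), and proximity-class counts.
#'
#' @param links data.frame of links with `tss_distance` and `proximity`.
#' @return List with elements `all` and `intergenic`.
#' @export
distance_summary <- function(links) {
  one <- function(df) {
    if (nrow(df) == 0L) {
      return(list(n = 0L, median_abs_distance = NA_real_,
                  frac_within_1mb = NA_real_, frac_downstream = NA_real_))
    }
    list(n = nrow(df),
         median_abs_distance = stats::median(abs(df$tss_distance)),
         frac_within_1mb = mean(abs(df$tss_distance) <= 1e6),
         frac_downstream = mean(df$tss_distance > 0))
  }
  list(all = c(one(links),
               list(proximity_counts = table(links$proximity))),
       intergenic = one(links[links$proximity == "intergenic", , drop = FALSE]))
}
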