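library(GenomicRanges)

# shorthand interval builders (1-based closed, as GRanges)
gr <- function(chrom, start, end, strand = "*") {
  GRanges(chrom, IRanges(start, end), strand = strand)
}

peaks_gr <- function(chrom, start, end, score, summit = NULL) {
  g <- GRanges(chrom, IRanges(start, end))
  mcols(g)$score <- score
  mcols(g)$summit <- if (is.null(summit)) {
    as.integer(floor((start + end) / 2))
  } else {
    as.integer(summit)
  }
  g
}

# transcript models from a compact spec: list of list(id, gene, chrom, strand,
# exons = matrix/2-col of (start, end))
make_models <- function(txs) {
  rows <- lapply(txs, function(t) {
    ex <- t$exons
    g <- GRanges(t$chrom, IRanges(ex[, 1], ex[, 2]), strand = t$strand)
    mcols(g)$transcript_id <- t$id
    mcols(g)$gene_id <- t$gene
    g
  })
  transcript_models(unlist(GRangesList(rows), use.names = FALSE))
}

# independent oracle for the greedy non-overlap merge: repeatedly select the
# best remaining peak (score desc, chrom, start, end) and delete everything
# overlapping it -- O(n^2) selection/deletion, a different route from the
# implementation's precomputed adjacency walk
oracle_nonoverlap_merge <- function(peaks) {
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks), end = end(peaks),
                   score = mcols(peaks)$score)
  kept <- integer(0)
  remaining <- seq_len(nrow(df))
  while (length(remaining) > 0L) {
    o <- remaining[order(-df$score[remaining], df$chrom[remaining],
                         df$start[remaining], df$end[remaining])]
    best <- o[1L]
    kept <- c(kept, best)
    ov <- remaining[df$chrom[remaining] == df$chrom[best] &
                      df$start[remaining] <= df$end[best] &
                      df$end[remaining] >= df$start[best]]
    remaining <- setdiff(remaining, ov)
  }
  sort(peaks[kept], ignore.strand = TRUE)
}

# brute-force splice classifier: enumerate every reference chain and every
# consecutive sub-chain into lookup sets, then classify by membership
bf_classify <- function(query, reference) {
  chains <- vapply(reference$junctions, paste, "", collapse = ";")
  subchains <- unique(unlist(lapply(reference$junctions, function(rc) {
    n <- length(rc)
    if (n == 0L) return(character(0))
    out <- character(0)
    for (len in 1:n) {
      for (off in 0:(n - len)) {
        out <- c(out, paste(rc[(off + 1):(off + len)], collapse = ";"))
      }
    }
    out
  })))
  catalog <- unique(unlist(reference$junctions, use.names = FALSE))
  gb <- gene_bodies(reference)
  qtx <- query$tx
  vapply(seq_len(nrow(qtx)), function(i) {
    qj <- query$junctions[[qtx$transcript_id[i]]]
    span <- gr(qtx$chrom[i], qtx$start[i], qtx$end[i])
    hits_gene <- countOverlaps(span, gb, ignore.strand = TRUE) > 0L
    if (length(qj) == 0L) stop("mono-exonic query not supported by oracle")
    qs <- paste(qj, collapse = ";")
    if (qs %in% chains) return("FSM")
    if (qs %in% subchains) return("ISM")
    if (!hits_gene) return("intergenic")
    if (all(qj %in% catalog)) "NIC" else "NNC"
  }, "")
}

# random toy transcriptome: reference chains over a shared exon grid plus
# queries of every flavour (copies, sub-chains, chain mixtures, perturbed
# junctions, off-gene placements)
random_transcriptome <- function(seed, n_ref = 20) {
  set.seed(seed)
  ew <- 100L
  step <- 1000L
  ref_list <- list()
  for (r in seq_len(n_ref)) {
    g0 <- 1000L + (r - 1L) * 20000L
    n_ex <- sample(3:6, 1L)
    starts <- g0 + (seq_len(n_ex) - 1L) * step +
      cumsum(sample(0:50, n_ex, replace = TRUE))
    strand <- sample(c("+", "-"), 1L)
    gene <- sprintf("g%02d", r)
    ref_list[[r]] <- list(id = sprintf("ref%02d", r), gene = gene,
                          chrom = "chr1", strand = strand,
                          exons = cbind(starts, starts + ew - 1L))
  }
  reference <- make_models(ref_list)
  q_list <- list()
  qi <- 0L
  for (r in seq_len(n_ref)) {
    t <- ref_list[[r]]
    n_ex <- nrow(t$exons)
    flavour <- sample(c("copy", "sub", "perturb", "offgene"), 1L)
    qi <- qi + 1L
    ex <- t$exons
    if (flavour == "sub" && n_ex >= 3L) {
      ex <- ex[2:n_ex, , drop = FALSE]
    } else if (flavour == "perturb") {
      ex[2L, 1L] <- ex[2L, 1L] + 7L  # novel acceptor
    } else if (flavour == "offgene") {
      ex <- ex + 500000L
    }
    q_list[[qi]] <- list(id = sprintf("q%02d", qi), gene = t$gene,
                         chrom = "chr1", strand = t$strand, exons = ex)
  }
  list(reference = reference, query = make_models(q_list))
}

# the full synthetic demo is expensive; compute once per session
.demo_cache <- new.env(parent = emptyenv())
demo_fixture <- function(seed = 1L) {
  key <- as.character(seed)
  if (is.null(.demo_cache[[key]])) {
    .demo_cache[[key]] <- run_demo(seed)
  }
  .demo_cache[[key]]
}
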