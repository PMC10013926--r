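#' Build a set of transcript models from exons
#'
#' The central gene-model container: a list with a per-transcript table
#' (`tx`: transcript_id, gene_id, chrom, strand, start, end, tss, tts,
#' n_exons), a named `GRangesList` of exons, and a named list of splice
#' junction keys in genomic order. A junction key encodes chromosome, strand,
#' donor (last exonic base) and acceptor (first exonic base of the next exon),
#' so chains are comparable across transcripts by string equality.
#'
#' TSS is the strand-aware 5' end and TTS the strand-aware 3' end
#' (transcription start / termination site).
#'
#' @param exons GRanges of exons with `transcript_id` and `gene_id` metadata
#'   columns and strand `+` or `-`.
#' @return An object of class `transcript_models`.
#' @export
transcript_models <- function(exons) {
  stopifnot(is(exons, "GRanges"),
            !is.null(mcols(exons)$transcript_id),
            !is.null(mcols(exons)$gene_id))
  if (length(exons) == 0L) stop("no exons supplied")
  if (any(!as.character(strand(exons)) %in% c("+", "-"))) {
    stop("transcript exons must be stranded (+ or -)")
  }
  txid <- mcols(exons)$transcript_id
  ord <- order(txid, start(exons))
  exons <- exons[ord]
  txid <- txid[ord]
  grl <- split(exons, txid)

  chrom <- vapply(grl, function(g) {
    u <- unique(as.character(seqnames(g)))
    if (length(u) != 1L) stop("transcript on multiple chromosomes: ",
                              mcols(g)$transcript_id[1L])
    u
  }, "")
  str <- vapply(grl, function(g) {
    u <- unique(as.character(strand(g)))
    if (length(u) != 1L) stop("transcript with mixed strand: ",
                              mcols(g)$transcript_id[1L])
    u
  }, "")
  ok <- vapply(grl, function(g) {
    length(g) == 1L || all(start(g)[-1L] > end(g)[-length(g)])
  }, TRUE)
  if (!all(ok)) stop("overlapping exons within transcript: ",
                     names(grl)[!ok][1L])

  gene <- vapply(grl, function(g) mcols(g)$gene_id[1L], "")
  tx_start <- vapply(grl, function(g) min(start(g)), 0)
  tx_end <- vapply(grl, function(g) max(end(g)), 0)
  tss <- ifelse(str == "+", tx_start, tx_end)
  tts <- ifelse(str == "+", tx_end, tx_start)

  junc <- lapply(seq_along(grl), function(i) {
    g <- grl[[i]]
    if (length(g) < 2L) return(character(0))
    paste0(chrom[i], str[i], ":", end(g)[-length(g)], "-", start(g)[-1L])
  })
  names(junc) <- names(grl)

  out <- list(
    tx = data.frame(transcript_id = names(grl), gene_id = unname(gene),
                    chrom = unname(chrom), strand = unname(str),
                    start = unname(tx_start), end = unname(tx_end),
                    tss = unname(tss), tts = unname(tts),
                    n_exons = unname(lengths(grl)),
                    stringsAsFactors = FALSE),
    exons = grl,
    junctions = junc
  )
  class(out) <- "transcript_models"
  out
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", nrow(x$tx), "transcripts,",
      length(unique(x$tx$gene_id)), "genes\n")
  invisible(x)
}

#' Subset transcript models by transcript id
#'
#' @param models A `transcript_models` object.
#' @param ids Transcript ids to keep.
#' @return A `transcript_models` object restricted to `ids`.
#' @export
subset_models <- function(models, ids) {
  keep <- models$tx$transcript_id %in% ids
  out <- list(tx = models$tx[keep, , drop = FALSE],
              exons = models$exons[models$tx$transcript_id[keep]],
              junctions = models$junctions[models$tx$transcript_id[keep]])
  class(out) <- "transcript_models"
  out
}

#' Gene body intervals for a transcript set
#'
#' One interval per gene: union span of the gene's transcripts.
#'
#' @param models A `transcript_models` object.
#' @return GRanges named by gene id.
#' @export
gene_bodies <- function(models) {
  tx <- models$tx
  sp <- split(seq_len(nrow(tx)), tx$gene_id)
  gr <- GRanges(vapply(sp, function(i) tx$chrom[i[1L]], ""),
                IRanges(vapply(sp, function(i) min(tx$start[i]), 0),
                        vapply(sp, function(i) max(tx$end[i]), 0)),
                strand = vapply(sp, function(i) tx$strand[i[1L]], ""))
  names(gr) <- names(sp)
  gr
}

#' Strand-aware windows around transcript 5' or 3' ends
#'
#' @param models A `transcript_models` object.
#' @param end Which end: "tss" or "tts".
#' @param halfwidth Window half-width in bp on each side.
#' @param per_gene Collapse windows to one reduced set per gene.
#' @return GRanges of windows (clipped at position 1).
#' @export
end_windows <- function(models, end = c("tss", "tts"), halfwidth = 2000,
                        per_gene = FALSE) {
  end <- match.arg(end)
  tx <- models$tx
  pos <- if (end == "tss") tx$tss else tx$tts
  gr <- GRanges(tx$chrom, IRanges(pmax(1, pos - halfwidth), pos + halfwidth))
  mcols(gr)$gene_id <- tx$gene_id
  mcols(gr)$transcript_id <- tx$transcript_id
  if (per_gene) {
    grl <- split(gr, mcols(gr)$gene_id)
    gr <- unlist(reduce(grl), use.names = TRUE)
    mcols(gr)$gene_id <- names(gr)
    names(gr) <- NULL
  }
  gr
}

#' Read a GTF file into transcript models
#'
#' GTF 1-based closed coordinates map directly onto the internal GRanges
#' convention. Exon features are grouped per transcript; transcripts declared
#' without exons are an error, as are transcripts spanning chromosomes or
#' mixing strands.
#'
#' @param path Path to a GTF2.2 file.
#' @return A `transcript_models` object.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("GTF contains no exon features")
  declared <- unique(gr$transcript_id[gr$type %in% c("transcript", "mRNA")])
  declared <- declared[!is.na(declared)]
  missing <- setdiff(declared, unique(ex$transcript_id))
  if (length(missing)) stop("transcript with zero exons: ", missing[1L])
  keep <- GRanges(seqnames(ex), ranges(ex), strand = strand(ex))
  mcols(keep)$transcript_id <- ex$transcript_id
  mcols(keep)$gene_id <- ex$gene_id
  transcript_models(keep)
}

#' Write transcript models to GTF
#'
#' @param models A `transcript_models` object.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  ex <- unlist(models$exons, use.names = FALSE)
  lines <- sprintf(
    "%s\tequicre\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    as.character(seqnames(ex)), start(ex), end(ex),
    as.character(strand(ex)), mcols(ex)$gene_id, mcols(ex)$transcript_id)
  writeLines(lines, path)
}
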