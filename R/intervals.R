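#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits runValue runLength
#' @importFrom methods is
NULL

# Internal coordinates are GRanges (1-based closed). BED/narrowPeak files are
# 0-based half-open; conversion happens only in the readers/writers below.

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a tab-separated file with chromosome name and length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  stats::setNames(as.integer(df$size), df$chrom)
}

#' Write a chrom.sizes file
#'
#' @param sizes Named vector of chromosome lengths.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), as.integer(sizes)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a BED3-BED6 file into a GRanges
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' GRanges convention. Optional name, score and strand columns are kept as
#' metadata. Malformed lines raise errors naming the offending line.
#'
#' @param path Path to a BED file with 3-6 tab-separated columns.
#' @return GRanges, input order preserved.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L | nf > 6L)) {
    bad <- which(nf < 3L | nf > 6L)[1L]
    stop("malformed BED line ", bad, ": expected 3-6 columns, got ", nf[bad])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0)) {
    bad <- which(is.na(start0) | is.na(end0))[1L]
    stop("malformed BED line ", bad, ": non-numeric coordinates")
  }
  if (any(start0 >= end0)) {
    bad <- which(start0 >= end0)[1L]
    stop("malformed BED line ", bad, ": empty or inverted interval (start >= end)")
  }
  strand <- rep("*", length(lines))
  has6 <- nf >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  if (any(nf >= 4L)) {
    nm <- rep(NA_character_, length(lines))
    nm[nf >= 4L] <- vapply(fields[nf >= 4L], `[[`, "", 4L)
    mcols(gr)$name <- nm
  }
  if (any(nf >= 5L)) {
    sc <- rep(NA_real_, length(lines))
    sc[nf >= 5L] <- suppressWarnings(as.numeric(vapply(fields[nf >= 5L], `[[`, "", 5L)))
    mcols(gr)$score <- sc
  }
  gr
}

#' Write a GRanges to BED
#'
#' Emits BED6 when name/score/strand information is present, BED3 otherwise.
#'
#' @param gr GRanges, optionally with `name` and `score` metadata.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  has_meta <- !is.null(mcols(gr)$name) || !is.null(mcols(gr)$score) ||
    any(as.character(strand(gr)) != "*")
  if (has_meta) {
    nm <- mcols(gr)$name
    if (is.null(nm)) nm <- rep(".", length(gr))
    sc <- mcols(gr)$score
    if (is.null(sc)) sc <- rep(0, length(gr))
    st <- as.character(strand(gr))
    st[st == "*"] <- "."
    df <- cbind(df, name = nm, score = sc, strand = st)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read an ENCODE narrowPeak file into scored peaks
#'
#' narrowPeak is BED6+4; column 10 is the summit offset from the peak start
#' (0-based), or -1 when the caller did not report a summit, in which case the
#' interval midpoint is used and a message is emitted. Peaks are returned as a
#' GRanges with `score` and `summit` (absolute 1-based position) metadata.
#'
#' @param path Path to a 10-column narrowPeak file.
#' @return GRanges with `name`, `score` and `summit` metadata columns.
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "",
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "numeric", "character",
                                         "numeric", "numeric", "numeric",
                                         "numeric"))
  if (ncol(df) != 10L) stop("narrowPeak requires 10 columns, got ", ncol(df))
  if (any(df[[2]] >= df[[3]])) {
    stop("malformed narrowPeak line ", which(df[[2]] >= df[[3]])[1L],
         ": start >= end")
  }
  offset <- df[[10]]
  len <- df[[3]] - df[[2]]
  if (any(offset >= len)) {
    stop("narrowPeak summit offset beyond peak length at line ",
         which(offset >= len)[1L])
  }
  missing_summit <- offset < 0
  if (any(missing_summit)) {
    message(sum(missing_summit), " peak(s) without summit; using midpoint")
    offset[missing_summit] <- floor(len[missing_summit] / 2)
  }
  st <- df[[6]]
  st[!st %in% c("+", "-")] <- "*"
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]), strand = st)
  mcols(gr)$name <- df[[4]]
  mcols(gr)$score <- df[[5]]
  mcols(gr)$summit <- as.integer(df[[2]] + offset + 1L)
  validate_peaks(gr)
  gr
}

#' Write scored peaks to narrowPeak
#'
#' @param peaks GRanges with `score` and `summit` metadata.
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_peaks(peaks)
  nm <- mcols(peaks)$name
  if (is.null(nm)) nm <- paste0("peak_", seq_along(peaks))
  st <- as.character(strand(peaks))
  st[st == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = nm, score = mcols(peaks)$score, strand = st,
                   signalValue = 0, pValue = -1, qValue = -1,
                   peak = mcols(peaks)$summit - start(peaks))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

# Assert the ScoredPeak invariants: score >= 0, start <= summit <= end.
validate_peaks <- function(peaks) {
  stopifnot(is(peaks, "GRanges"),
            !is.null(mcols(peaks)$score), !is.null(mcols(peaks)$summit))
  if (any(mcols(peaks)$score < 0)) stop("peak scores must be non-negative")
  bad <- mcols(peaks)$summit < start(peaks) | mcols(peaks)$summit > end(peaks)
  if (any(bad)) stop("peak summit outside peak interval at index ",
                     which(bad)[1L])
  invisible(peaks)
}

#' Merge overlapping or near-adjacent intervals
#'
#' bedtools-merge semantics: intervals on the same chromosome whose gap is at
#' most `gap` bases (0 = overlapping or bookended) are unioned. Strand is
#' ignored. Output is sorted and pairwise disjoint.
#'
#' @param gr GRanges.
#' @param gap Maximum separating gap in bp (default 0).
#' @return Sorted, disjoint GRanges.
#' @export
merge_intervals <- function(gr, gap = 0L) {
  stopifnot(gap >= 0)
  sort(reduce(gr, min.gapwidth = gap + 1L, ignore.strand = TRUE))
}

#' Fraction of the genome covered by a set of intervals
#'
#' @param gr GRanges (duplicates and overlaps counted once).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return Fraction of total genome bases covered, in `[0, 1]`.
#' @export
genome_fraction_covered <- function(gr, chrom_sizes) {
  if (length(gr) == 0L) return(0)
  chr <- as.character(seqnames(gr))
  unknown <- setdiff(unique(chr), names(chrom_sizes))
  if (length(unknown)) stop("intervals on unknown chromosome: ", unknown[1L])
  if (any(end(gr) > chrom_sizes[chr]) || any(start(gr) < 1L)) {
    stop("interval beyond chromosome bounds")
  }
  sum(width(reduce(gr, ignore.strand = TRUE))) / sum(as.numeric(chrom_sizes))
}

# Total bases in the intersection of two (not necessarily disjoint) sets.
intersect_bp <- function(a, b) {
  sum(as.numeric(width(intersect(reduce(a, ignore.strand = TRUE),
                                 reduce(b, ignore.strand = TRUE),
                                 ignore.strand = TRUE))))
}
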