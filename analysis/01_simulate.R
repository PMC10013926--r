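#!/usr/bin/env Rscript
# Generate the synthetic study inputs: genome, annotation, per-tissue ATAC
# and histone peak sets, chromatin-state segmentations, CTCF motifs and the
# truth manifests. Everything downstream reads from results/sim/.
suppressMessages(library(equicre))
suppressMessages(library(GenomicRanges))

seed <- 1L
cfg <- sim_config(seed)
outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ann <- simulate_annotation(cfg)
genome <- simulate_genome(cfg, ann)
sizes <- sim_chrom_sizes(cfg)

Biostrings::writeXStringSet(genome, file.path(outdir, "genome.fa"))
write_chrom_sizes(sizes, file.path(outdir, "genome.chrom.sizes"))
write_gtf(ann$models, file.path(outdir, "annotation.gtf"))
write.table(ann$manifest, file.path(outdir, "annotation_manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ph <- simulate_peaks_and_histones(cfg)
for (tis in cfg$tissues) {
  for (r in names(ph$atac[[tis]])) {
    write_narrowpeak(ph$atac[[tis]][[r]],
                     file.path(outdir, sprintf("atac_%s_%s.narrowPeak",
                                               tis, r)))
  }
  if (!is.null(ph$histones[[tis]])) {
    for (mark in names(ph$histones[[tis]])) {
      write_bed(ph$histones[[tis]][[mark]],
                file.path(outdir, sprintf("%s_%s.bed", mark, tis)))
    }
  }
}

sms <- simulate_states_motifs_loops(cfg)
write_bed(sms$motifs, file.path(outdir, "ctcf_motifs.bed"))
write_bed(sms$manifest$loops, file.path(outdir, "true_loops.bed"))

message(sprintf(
  "simulated %d chroms x %.1f Mb, %d transcripts (%d genes), %d elements, %d planted loops",
  cfg$n_chroms, cfg$chrom_length / 1e6, nrow(ann$models$tx),
  length(unique(ann$models$tx$gene_id)),
  length(ph$manifest$elements), length(sms$manifest$loops)))
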