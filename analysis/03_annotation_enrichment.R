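#!/usr/bin/env Rscript
# Annotate the filtered union peaks by genic feature and compute base-pair
# fold enrichment of every chromatin state across gene features split by
# expression class (TPM >= 1 vs < 1).
suppressMessages(library(equicre))
suppressMessages(library(GenomicRanges))

seed <- 1L
cfg <- sim_config(seed)
sizes <- sim_chrom_sizes(cfg)
dir.create("results", showWarnings = FALSE)

ann <- simulate_annotation(cfg)
ref <- subset_models(ann$models, ann$reference_ids)
union_set <- read_bed("results/union_peaks.bed")

classes <- annotate_peaks(union_set, ref)
comp <- as.data.frame(prop.table(table(classes)))
write.table(comp, "results/peak_annotation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("union peak composition:")
print(round(prop.table(table(classes)), 3))

# state enrichment needs expression classes: reuse the simulated RNA counts
sms <- simulate_states_motifs_loops(cfg)
cres <- build_cres(sms$states_by_tissue[[1L]], ref)
loops <- pan_tissue_loops(lapply(sms$motifs_by_tissue, scan_loops),
                          sizes)$loops
cnt <- simulate_counts(cfg, cres, ref, loops)

enr <- state_enrichment_matrix(sms$states_by_tissue[1:2], ref, cnt$tpm,
                               sizes, normalize = TRUE)
write.table(enr, "results/state_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
top <- enr[order(-enr$fold), ][1:5, ]
message("strongest state enrichments (fold over genomic expectation):")
print(top, row.names = FALSE)

share <- state_tissue_sharing(sms$states_by_tissue, 1L, mode = "base")
message("poised-promoter state bases by number of sharing tissues:")
print(share)
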