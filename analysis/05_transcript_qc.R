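#!/usr/bin/env Rscript
# Long-read transcript curation on the synthetic annotation: splice-match
# classification against the designated reference subset, intra-priming
# detection against the simulated genome, 5'-degradation collapse, and
# 3'-end distance statistics for matched transcripts.
suppressMessages(library(equicre))
suppressMessages(library(GenomicRanges))

seed <- 1L
cfg <- sim_config(seed)
dir.create("results", showWarnings = FALSE)

ann <- simulate_annotation(cfg)
genome <- simulate_genome(cfg, ann)
ref <- subset_models(ann$models, ann$reference_ids)
qry <- subset_models(ann$models, ann$query_ids)

cls <- classify_splice_match(qry, ref)
intended <- ann$manifest$intended_class[match(cls$transcript_id,
                                              ann$manifest$transcript_id)]
write.table(cls, "results/splice_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("splice-class counts (agreement with planted classes ",
        sprintf("%.0f%%):", 100 * mean(as.character(cls$class) == intended)))
print(table(cls$class))

flags <- intra_priming_flag(ann$models, genome)
truth <- ann$manifest$intra_priming[match(names(flags),
                                          ann$manifest$transcript_id)]
message(sprintf("intra-priming: %d flagged of %d transcripts (%d planted)",
                sum(flags), length(flags), sum(truth)))

col <- collapse_5prime_degraded(ann$models)
message(sprintf("5'-degradation collapse absorbed %d of %d transcripts",
                sum(col$mapping$transcript_id != col$mapping$representative),
                nrow(ann$models$tx)))

fsm <- cls[cls$class == "FSM", ]
fsm <- fsm[qry$tx$n_exons[match(fsm$transcript_id,
                                qry$tx$transcript_id)] > 1L, ]
d <- tts_distance(qry, ref, fsm)
message(sprintf(
  "FSM queries extend the reference 3' end by a median of %d bp (range %d..%d)",
  median(d), min(d), max(d)))
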