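# equicre

Integrated regulatory-element annotation for a multi-tissue functional
genomics panel, implemented as a tested R package plus a numbered analysis
workflow. The package provides the bespoke computations that sit between
standard tools in such a project — the steps a consortium would otherwise
script ad hoc:

* **Open-chromatin calibration** — summit-centered 501 bp fixed-width peaks,
  greedy iterative non-overlap merging (replicates → tissues → union),
  histone-anchored ROC calibration with cutoff selection at a target false
  positive rate (RP = merged H3K4me1/H3K4me3 ∩ H3K27ac, RN = H3K27me3;
  TPR = nTP/nRP, FPR = nFP/nRN, precision = nTP/(nTP+nFP)), a score-quantile
  fallback for tissues without histone data, tissue-sharing classification
  and a transposition-event count matrix.
* **Annotation & enrichment** — single-class genic annotation
  (promoter-TSS > TTS > exon > intron > intergenic) and the base-pair fold
  enrichment (N\_Ann∩State / N\_Ann) / (N\_State / N\_genome) across
  states × genic features × expression classes (TPM ≥ 1) × tissues.
* **Loops & CRE–gene links** — convergent CTCF-motif loop prediction
  (stack rule, alternatives configurable), pan-tissue loop merging, CRE
  assembly from active chromatin states {2–5, 8–11}, TMM scaling factors,
  within-loop Spearman linking of H3K27ac signal to gene expression with
  Benjamini–Hochberg FDR control, and CRE–TSS distance summaries.
* **Long-read transcript QC** — FSM/ISM/NIC/NNC splice-match
  classification by junction chains, sequential support filters,
  intra-priming detection (≥80% A in the 20 bp past the TTS),
  5′-degradation collapse, signed TTS distances and TSS coverage ratios.
* **Differential concordance** — promoter peak–gene pairing, Q1–Q4
  quadrant classification of jointly significant fold changes, and
  accessibility–expression fold-change Pearson correlation.
* **Synthetic data** — seeded generators for every input (genome,
  annotation, peaks, histone marks, states, motifs, counts, differential
  tables) with planted ground-truth manifests, so the whole pipeline is
  exercisable and testable at desk scale without any external download.

See `vignettes/methods.Rmd` for the full account of the models,
parameters and design decisions.

## Worked example

The one-call demonstration runs every stage on synthetic data and compares
each against the generators' manifests:

```r
library(equicre)
d <- run_demo(seed = 1)
d$peak_table[, c("tissue", "raw_count", "method", "cutoff", "tpr", "fpr",
                 "remaining")]
#>     tissue raw_count   method    cutoff tpr       fpr remaining
#> 1  adipose       394      roc  26.97724   1 0.2413793       178
#> 2   cortex       386      roc  27.84337   1 0.2452830       174
#> ...
#> 9   testis       381 quantile 102.10090  NA        NA        58
str(d$report[c("n_union_peaks", "loop_genome_coverage", "link_recovery",
               "link_empirical_fdr", "fc_pearson_r")])
#> $ n_union_peaks       : int 516
#> $ loop_genome_coverage: num 0.859
#> $ link_recovery       : num 1
#> $ link_empirical_fdr  : num 0
#> $ fc_pearson_r        : num 0.394
```

Each tissue's peak scores are thresholded at the smallest cutoff with
FPR ≤ 0.25 (testis, generated without histone data, falls back to the 85th
score quantile); the filtered tissue sets merge into a 516-peak union. The
24 planted CTCF loops are all recovered and cover 85.9% of the synthetic
genome after pan-tissue merging; all 40 planted CRE–gene links are
re-identified at 5% FDR with no false discoveries among 432 tested
within-loop pairs; and the differential tables' planted fold-change
correlation (r = 0.4) is estimated at 0.394.

The same stages can be run piecewise as a narrative workflow:

```sh
Rscript analysis/01_simulate.R            # inputs + truth manifests
Rscript analysis/02_peak_calibration.R    # ROC-calibrated peak sets
Rscript analysis/03_annotation_enrichment.R
Rscript analysis/04_loops_links.R
Rscript analysis/05_transcript_qc.R
Rscript analysis/06_diff_concordance.R
```

Each script states what it found on stderr and writes its tables under
`results/`.

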