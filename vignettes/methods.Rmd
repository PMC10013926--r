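---
title: "Methods: integrated regulatory-element annotation at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated regulatory-element annotation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`equicre` implements the bespoke computations of an integrated functional
annotation workflow for a mammalian genome — the kind of analysis a
farm-animal functional-genomics consortium runs when combining long-read
transcriptome assembly, ATAC-seq, histone ChIP-seq, chromatin-state
segmentation and RNA-seq over a panel of tissues. This vignette explains the
models and procedures, the parameters that matter, what the synthetic-data
generators emulate, and the design choices made where the methods were
genuinely open.

## Coordinate conventions and containers

All intervals are held as `GenomicRanges::GRanges` (1-based, closed), the
Bioconductor convention; BED and narrowPeak files (0-based, half-open) are
converted at the I/O boundary and GTF (1-based, closed) maps directly.
"Overlap" always means at least one shared base, matching the bedtools
default, and chromosome names are compared by exact string match. Scored
peaks carry `score` and `summit` metadata columns; a summit must lie inside
its peak and scores are non-negative. narrowPeak summit offsets of −1 (a
peak caller run without summit calling) fall back to the interval midpoint,
with a message.

Transcript models are the one structure built for purpose: exons grouped
per transcript with derived splice junctions, strand-aware TSS
(transcription start site, the 5′ end) and TTS (transcription termination
site, the 3′ end). A junction is keyed by chromosome, strand, donor (last
exonic base) and acceptor (first exonic base of the next exon), so junction
chains compare by string equality — an exact-coordinate convention chosen
deliberately: fuzzy junction windows add parameters without a testable
anchor.

## Open-chromatin peak calibration

Peak calling itself (MACS-style) and Tn5 read shifting are upstream
contracts; the pipeline starts from scored peaks with summits.

1. **Fixed-width peaks.** Each summit is extended ±250 bp, giving 501 bp
   peaks clipped at chromosome bounds. Clipped edge peaks are kept rather
   than discarded — dropping them would silently lose telomeric signal.
2. **Iterative non-overlap merge.** Peaks are visited in descending score
   order and kept iff they overlap no already-kept peak, so the most
   significant peak of every overlapping cluster survives at fixed width.
   The tie-break (score desc, then chromosome, start, end) makes the result
   a total order and therefore reproducible. The same merge is applied to
   pooled replicates per tissue, and again to pooled tissue sets to form the
   union catalog.
3. **Histone-anchored ROC.** Per tissue, "real positive" (RP) elements are
   H3K4me1 ∪ H3K4me3 peaks merged and filtered to those overlapping
   H3K27ac; "real negatives" (RN) are H3K27me3 peaks, minus any element
   overlapping RP (a region carrying both labels is uninformative; removing
   it is this package's choice). At each score cutoff,
   TPR = nTP/nRP and FPR = nFP/nRN where nTP and nFP count *retained ATAC
   peaks* overlapping RP and RN while the denominators count *truth
   elements*. The entity mixing is intentional — it is the calibration
   statistic as used in this workflow — and means TPR can exceed 1 when
   several peaks hit one element; values are reported unclamped, and the
   curve is clamped to the unit box only for trapezoidal AUC integration.
4. **Cutoff.** The selected cutoff is the smallest score whose FPR is at or
   below the target (default 25%), i.e. the most permissive threshold
   honouring the bound; peaks below it are removed. Tissues without histone
   data fall back to a score quantile (default 0.85, type-7 linear
   interpolation — recorded so results are reproducible).

Union peaks are then labelled by tissue sharing (present in a tissue iff
they overlap ≥1 peak of its filtered set): `unique` when present in exactly
one tissue, `conserved` when present in all.

## Genic annotation and state enrichment

Peaks receive exactly one genic class in the priority order
promoter-TSS (TSS ± 2 kb) > TTS (± 2 kb) > exon > intron > intergenic.
A fixed precedence is required because single-class percentages are
reported; promoter assignment is given priority because promoter proximity
is the strongest functional signal. Per-gene features are unions over the
gene's transcripts, avoiding isoform double counting, and "TES" is treated
as synonymous with TTS.

Fold enrichment of an annotation in a chromatin state is the base-pair
statistic

\[
\frac{N_{\mathrm{Ann}\cap\mathrm{State}}/N_{\mathrm{Ann}}}
     {N_{\mathrm{State}}/N_{\mathrm{genome}}},
\]

computed exactly on reduced interval sets. It is scale invariant, equals 1
when the annotation is the whole genome, and equals 1 in expectation for a
uniformly random state. The enrichment matrix crosses states × features
(gene body, exon, TSS ± 2 kb, TES ± 2 kb) × expression class (aggregated
TPM ≥ 1 = high, else low) × tissues. Column-wise min–max normalization is
available for display only; raw folds are always emitted because the
normalization has no inferential content.

## CTCF loops and CRE–gene linking

Chromatin loops are predicted from strand-oriented CTCF motif occurrences
(motif scanning itself is an upstream contract). A one-sentence "pair of
parallel and anti-parallel motifs" rule underdetermines the algorithm, so
the scanning rule is configurable; the default is a stack rule: scanning
left to right, forward motifs push onto a stack and each reverse motif pops
the most recent unpaired forward motif, emitting a convergent, possibly
nested loop from the + motif start to the − motif end. Alternatives
(`nearest_next` sequential pairing, `all_convergent` within a maximum span)
are provided for sensitivity analysis. Per-tissue loops are merged
(bedtools-merge semantics) into a disjoint pan-tissue catalog whose genome
coverage is reported; coverage is invariant to tissue processing order.

CREs are assembled by merging overlapping or bookended segments of the
active chromatin states {2–5, 8–11} (promoter, enhancer and insulator
states of a 14-state segmentation) and annotated by proximity:
`TSS-promoter` if overlapping any TSS ± 2 kb window, else `genic` if
overlapping a gene body, else `intergenic`. The closest gene is the one
whose representative TSS (the 5′-most across its transcripts) is nearest
the CRE midpoint; signed distances are negative when the CRE lies upstream
of the TSS on the gene's strand.

Counts are scaled by TMM (trimmed mean of M-values) normalization factors
times library size before correlation. The TMM implementation follows the
Robinson–Oshlack weighted trimmed mean: reference sample by
75th-percentile count fraction closest to the mean; gene-wise M and A on
genes positive in both sample and reference; double trim (30% of M, 5% of
A); inverse-variance-weighted mean of the surviving M values; factors
rescaled to geometric mean 1. When fewer than 10 genes survive the trims
the untrimmed weighted mean is used, with a warning. Spearman correlation
is rank-based, so the scaling does not change rho; it is kept so the
emitted per-sample tables are interpretable.

Every (CRE, gene) pair whose CRE midpoint and gene TSS fall in the same
merged loop is tested — representative-point containment rather than full
containment, so boundary-spanning CREs are not dropped. Spearman rho uses
average ranks for ties; the two-sided p-value uses the t approximation
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) (sidedness is a choice; two-sided is
conservative). Benjamini–Hochberg adjustment is applied over all tested
pairs jointly and pairs with adjusted p ≤ 0.05 are reported. Linking
requires at least 5 shared samples; the sample layout mirrors a pan-tissue
design of 9 tissues with up to 4 replicates (2 for the gonadal tissues, 32
samples in total) precisely because per-tissue replicate counts are too
small to estimate rank correlations reliably. Whether correlation should
use all samples or per-tissue means is open; per-sample is the default
because it preserves degrees of freedom.

## Long-read transcript QC

Splice-match classification against a reference annotation uses junction
chains: FSM (full-splice match) when the query chain equals a reference
chain; ISM (incomplete-splice match) when it equals a consecutive
sub-chain; NIC (novel in catalog) when all junctions are known but no
chain matches; NNC when at least one junction is novel; intergenic when
the query overlaps no reference gene body. Mono-exonic queries are not
addressed by chain logic, so the package classifies them FSM when fully
contained in a same-strand reference exon, NNC when overlapping a gene,
and intergenic otherwise.

Support filters run sequentially, with removal counts reported per filter
in application order: ≥2 full-length reads; detected in more than one
sample; every junction covered by short-read data; any short-read coverage
at all. Intra-priming candidates are transcripts whose 20 bp genomic window
immediately 3′ of the TTS carries ≥80% adenines on the transcript's sense
strand (genomic T read as sense A for minus-strand transcripts) — the
signature of oligo-dT mispriming; the threshold is inclusive (16 of 20
flags). 5′-degraded transcripts — identical 3′ ends whose junction chain is
a 3′-anchored suffix of a longer transcript's chain — collapse into the
longest member; the TTS tolerance is 0 bp ("identical 3′ ends" read
literally) but configurable. Signed TTS distances are positive when a
query extends 3′ beyond its matched reference, and the TSS-validation
statistic is log2 of (downstream + pseudocount)/(upstream + pseudocount)
coverage in 100 bp windows around the TSS.

## Differential concordance

Differential accessibility and expression arrive as (feature, log2FC,
adjusted p) tables — negative-binomial GLM fitting is deliberately outside
this package's scope. Peaks pair with genes through promoter windows
(TSS ± 2 kb); pairs significant in both tables (adjusted p < 0.05) are
assigned quadrants by fold-change signs: Q1/Q3 concordant (both up / both
down), Q2/Q4 discordant. Zero fold changes are excluded with a log entry.
Genes with several significant promoter peaks are deduplicated by majority
peak sign, ties excluded. The fold-change relationship is summarised by
Pearson correlation with a one-sided test for r > 0.

## The synthetic-data generators

The generators produce every input the pipeline consumes, with
machine-readable truth manifests; downstream tests compare pipeline output
to manifests only. Fixed conditions (chosen once, stated here so the tests'
meaning is clear):

* 2 chromosomes × 2 Mb of uniform-random sequence; 60 genes per chromosome
  on a regular grid, alternating strands, 6 exons of 200 bp with 1.8 kb
  introns. Genes cycle through six isoform roles so FSM, ISM, NIC, NNC,
  mono-exonic-FSM and intergenic queries all occur by construction, with
  the intended class recorded per transcript.
* Intra-priming positives are planted by overwriting the TTS-downstream
  window with poly-A (sense strand) for 10% of distinct TTS groups;
  designation at the TTS-group level keeps transcripts sharing a 3′ end
  consistent. The background rate of accidental flags in random sequence
  is the binomial tail P(≥16 A in 20 bp at p = 0.25) ≈ 4 × 10⁻⁹, so
  recovery can be checked exactly.
* 200 true regulatory elements, 100 repressed decoys and 400 noise peaks
  on a randomized grid; each element is active in a uniformly drawn subset
  of the nine tissues. True elements carry ATAC scores from Normal(100, 5)
  and the activating histone marks; repressed decoys carry Normal(20, 5)
  scores and H3K27me3; noise peaks carry Normal(20, 5) and no marks.
  Histone peaks cover exactly the elements active in that tissue, so a
  tissue's truth sets and its ATAC peaks describe the same underlying
  elements and the score separation drives the ROC. Testis is generated
  without histone data, exercising the quantile fallback.
* 12 loops of 140 kb per chromosome (per-tissue genome coverage ≈ 84%,
  merged ≈ 86%), convergent motif pairs at the anchors, unpaired decoy
  motifs placed where no left-to-right convergent rule can pair them, and
  per-tissue anchor jitter of ±2 kb. Four active-state CRE blocks of
  1.5 kb are planted inside each loop; poised-promoter blocks (state 1,
  deliberately not an active state) mark forward-gene TSSs so
  state-enrichment output is non-trivial without perturbing CRE assembly.
  Because the loop spacing is a multiple of the gene spacing, the planted
  loop CREs all fall between genes — the synthetic CRE catalog is entirely
  intergenic, which mirrors the predominance of intergenic CREs in real
  catalogs but is a grid artifact, not biology.
* Counts: negative binomial with dispersion 0.1 (variance μ + 0.1 μ²), a
  per-(feature, sample) log-normal latent activity with sdlog = log(8)/2
  (±1 sd spans an 8× multiplier range), and 40 planted CRE–gene links
  implemented as a shared latent multiplying both NB means — a mechanism
  chosen because it induces rank correlation robust to NB noise, matching
  the Spearman-based linking. A `link_effect` weight in [0, 1] sets the
  shared fraction of latent variance; 0 gives the null used to verify
  that linked and unlinked rho distributions coincide.
* Differential tables: 5,000 promoter peak–gene pairs with
  bivariate-normal log2 fold changes at planted Pearson r = 0.4 and
  independent 55% significance rates per table, yielding ≈1,500
  both-significant pairs whose realised quadrant counts form the manifest.

Each generator seeds its own RNG stream from the master seed plus a fixed
offset, so outputs are byte-identical under a fixed seed and adding a
generator never perturbs the others.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: realistic sequence composition; read-level noise
(inputs are peak calls and count matrices, not reads); batch and sex
confounding (real pan-tissue panels have them and typically cannot separate
them); tissue-correlated expression structure (samples are exchangeable, so
the linking null is clean in a way real data never is); irregular gene
density; overlapping genes; and genome-scale catalog sizes. Headline counts
from a full mammalian dataset (hundreds of thousands of peaks, thousands of
loops, tens of thousands of links) are functions of data volume and are
not reproduced at desk scale; what is preserved is the behaviour of every
statistic on inputs whose truth is known.

## Numerical choices and degenerate inputs

* Quantile cutoffs use type-7 linear interpolation.
* Precision is undefined (NA) when no retained peak hits either truth set.
* A constant count vector makes Spearman rho undefined; such pairs are
  skipped with a log message rather than imputed.
* Empty RP or RN sets make a tissue uncalibratable; this is an error and
  the caller falls back to the quantile cutoff.
* Greedy-merge ties are broken by (chromosome, start, end), so the
  leftmost peak wins among equals.
* `fc_correlation` requires ≥3 pairs and errors on zero variance rather
  than returning NaN.
* Problem sizes throughout (2 × 2 Mb genome, ≤700 peaks per tissue,
  ≈430 tested CRE–gene pairs, 5,000 differential pairs) were chosen as
  the smallest at which every planted structure is comfortably
  recoverable and sampling noise does not dominate the statistics.

## Known limitations

Mono-exonic splice classification and the 5′-collapse rule are necessarily
conventions; alternatives (SQANTI-style fuzzy junctions, nonzero TTS
tolerance) are accommodated by parameters but not defaults. The loop
scanner is a heuristic over motif orientation, not a chromatin-interaction
caller; nothing here substitutes for Hi-C. TPR/FPR unclamping follows the
calibration statistic faithfully but means ROC values are not strictly
rates. NB-GLM differential fitting, GO enrichment, motif discovery and
track-hub generation are out of scope by design.
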