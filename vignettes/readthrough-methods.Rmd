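---
title: "Detecting transcription read-through from paired RNA-seq coverage"
author: "rtscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcription read-through from paired RNA-seq coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtscan)
```

## The problem

When RNA polymerase II fails to terminate at a gene's 3' end it continues
into the downstream intergenic region, producing "downstream-of-gene" (DoG)
read-through transcripts. In tumors this termination failure is frequent
enough to reshape the transcriptome: read-through can run into the next
gene of a tandem pair, perturb its expression, and generate intergenically
spliced chimeric RNAs. `rtscan` implements the full quantitative analysis
of this phenomenon for matched test/control (for example tumor/normal)
RNA-seq pairs: a per-gene read-through caller, invasion and interference
quantification, a cohort-level correlation screen, junction-based chimera
calling, and survival stratification by read-through burden.

## The caller

For each gene the 4 kb immediately downstream of the annotated TTS is cut
into 40 windows of 100 bp. Window counts are normalized to RPKM with each
sample's total mapped reads, and per-window fold-changes between test and
control are computed with a pseudocount:

$$
\mathrm{fc}_i \;=\; \frac{\mathrm{RPKM}^{\text{test}}_i + c}
                        {\mathrm{RPKM}^{\text{ctrl}}_i + c},
\qquad c = 0.1\ \mathrm{RPKM}.
$$

A gene is called as reading through when **more than six** windows have
$\mathrm{fc}_i \ge 1.5$ (both boundaries taken literally: a call requires at
least seven windows, and a window at exactly 1.5-fold counts). Before
calling, three filters are applied, in order:

1. **Clear zone** — genes with another annotated gene on either strand
   within 5 kb downstream of the TTS are removed; downstream signal there
   could belong to the neighbor. Genes whose bodies overlap another gene
   are removed for the same reason.
2. **Activity** — only genes whose control gene-body RPKM is strictly above
   the 25th percentile of all annotated genes (zeros included; R's default
   linear-interpolation quantile) are tested. The reference distribution is
   configurable because different choices of "all genes" shift the cut.
3. **Overall increase** — genes whose whole-body expression rises at least
   1.5-fold are excluded, since downstream elevation could then reflect
   global upregulation rather than a termination defect. No canonical
   threshold exists for this exclusion; we default to the same 1.5-fold as
   the window rule (symmetric, and recorded in the run metadata).

The **read-through length** used to order heatmaps is the contiguous run of
passing windows starting at the first passing window nearest the TTS
(`length_rule = "contiguous"`). A defensible alternative — the distance to
the distal-most passing window — is exposed as `length_rule = "distal"`.
Genes whose downstream zone is truncated by a chromosome end to fewer than
seven windows are excluded as undecidable (`truncated_zone`).

### Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `downstream_span_bp` | 4000 | bp | extent scanned past the TTS |
| `window_bp` | 100 | bp | window width |
| `fc_threshold` | 1.5 | fold | per-window call threshold (inclusive) |
| `min_windows_above` | 7 | windows | "more than six" |
| `active_percentile` | 25 | percentile | activity filter (strictly above) |
| `clear_zone_bp` | 5000 | bp | downstream eligibility zone |
| `overall_increase_fc` | 1.5 | fold | gene-body exclusion (inclusive) |
| `pseudocount` | 0.1 | RPKM | keeps zero-control windows defined |

The pseudocount is ours: fold-changes on zero-control windows are otherwise
undefined, and there is no canonical choice. 0.1 RPKM is far below any
biologically meaningful window signal, so it only regularizes near-empty
windows.

## Interference and the correlation screen

For a called upstream gene of a tandem pair, the **invaded fraction** of
the downstream gene is the contiguous run of passing 100-bp windows
*starting at the downstream gene's first window*, divided by gene length
(a run covering every window counts as 1). Requiring the run to start at
the 5' edge encodes the physics: invasion is continuous with the
intergenic tail, so isolated internal elevation — alternative promoters,
internal noise — does not count.

The cohort screen correlates, across sample pairs, each upstream gene's
read-through level (log2 fold-change of read counts over the 4 kb
downstream zone — the same quantity the burden heatmaps display) with the
downstream gene's log2 body fold-change. The correlation is Spearman by
default (fold-changes are heavy-tailed; Pearson is an option, recorded in
the output), two-sided p-values are Benjamini–Hochberg adjusted across all
tested pairs, and significance is q < 0.05. Pairs with fewer than
`min_samples` informative sample pairs (default 10) or a constant vector
are flagged and excluded from the BH family rather than diluted into it.

## Chimera calling

Read-through chimeras are called from split-read junction records, not raw
reads: a junction supports a chimera when its donor coordinate matches an
exon 3' boundary of the upstream gene and its acceptor matches an exon 5'
boundary of the downstream gene of a tandem pair, on the pair's strand,
with span ≥ 100 bp. Boundary matching uses a ±3 bp tolerance because
aligner-reported junction coordinates jitter around annotated exon edges.
Reads are deduplicated by read id before support counting and only events
with ≥ 2 supporting reads are emitted. Exon ranks are defined on the merged
gene model (rank 1 from the end = last exon), so the dominant biological
pattern — terminal 3' splice site eviction joining the second-last exon of
the upstream gene to the second exon of the downstream gene — is labelled
`E[last-1]->E2`. Only cis, same-chromosome, same-strand tandem chimeras are
in scope; interchromosomal fusions are a different mechanism and are not
called.

## Cohort statistics

Samples with more than 200 read-through genes form the "high read-through"
stratum (a sample at exactly 200 is low). Survival is compared between
strata with the Kaplan–Meier product-limit estimator and the two-group
log-rank test (hypergeometric variance at tied event times, the standard
treatment). Categorical contrasts (for example mutation status against
stratum) use Fisher's exact test, and metagene region comparisons use a
paired Student's t-test — paired per gene, matching the matched-pair
design. These standard estimators are delegated to `survival` and `stats`;
the test suite cross-checks each against an independent brute-force
implementation (risk-set enumeration for KM, hypergeometric enumeration for
Fisher, step-up recursion for BH).

## Metagene grids

Profiles that average many genes scale each gene body to 60 equal bins
(remainder bases are assigned to the last bin — the rule is arbitrary but
must be deterministic) and flank the body with 40 windows of 100 bp on each
side, so all TSSs and TTSs align at fixed columns of a 140-column matrix.
Minus-strand genes are mirrored so the TSS is always on the left. Heatmap
rows are ordered by descending read-through length, ties broken by gene id
for reproducibility.

## The synthetic-data generator

No public benchmark exists with known per-gene read-through truth, so the
package ships a generator that emulates exactly the structure the analysis
assumes, with machine-readable ground truth:

* **Annotation** — genes packed per chromosome with log-normal lengths
  (median 10 kb), 2–10 exons, strand-biased chains (80% `+`, giving the
  same-strand runs tandem pairs need), and intergenic gaps with median 8 kb
  of which a configurable 20% are drawn below 5 kb so the clear-zone filter
  is genuinely exercised.
* **Coverage** — per-base Poisson noise around per-gene mean depths
  (log-normal, median 20×) with a flat intergenic background of 0.5×.
  The background is deliberately not zero: with per-base Poisson noise a
  100-bp window at mean 50 gives fold-change estimates stable enough that
  the deterministic calling rule has a false-call probability well below
  1% per gene, while staying 40-fold below a typical gene body.
* **Read-through tails** — planted on a sample of eligible, active genes
  with control depth ≥ 30, as an exponential decay from the TTS with
  initial height 0.8 × gene depth and characteristic length 2 kb,
  truncated at the next annotated gene. Gene-body means are left untouched,
  so a planted call is attributable to termination failure alone and the
  overall-increase filter stays silent — mirroring the empirical signature
  of read-through (elevation only downstream of the TTS).
* **Invasion** — for a configurable fraction of planted genes with a tandem
  pair, the tail runs flat across the whole intergenic gap and into the
  leading fraction of the downstream gene. The added depth inside the gene
  is scaled to the *downstream* gene's own depth (2×, i.e. a 3-fold
  change) rather than the upstream gene's, so the planted fraction is
  recoverable whatever the downstream expression level happens to be.
* **Chimeras** — each invaded pair emits Poisson(3) junction reads joining
  exon boundaries sampled with 80% mass on (second-last → second), plus
  unassigned singleton decoys.
* **Survival** — per-sample planted burden spans the stratification cutoff;
  survival is exponential with a 3× hazard for truly high-burden samples,
  administratively censored at 2000 days.

Everything is reproducible from one integer seed; cohort samples use
documented derived substreams (`seed + 7919·i`).

### What the simulation does not capture

Coverage is emitted as per-base depth, not reads: fragment-length
autocorrelation, exon-intron coverage structure, mappability and GC bias,
and duplicate artifacts are all absent. Per-base Poisson noise is *less*
dispersed than real window counts, so passing recovery tests here bounds
algorithmic correctness, not performance on real libraries — on real data
the same thresholds will trade sensitivity against the higher variance.
Annotation truth is exact by construction; mis-annotated TTSs, a major
practical failure mode, are out of scope.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GTF converts at the I/O
  boundary (1-based inclusive), BED is native.
* Fold-changes use `>=` at thresholds, "more than six" is `> 6`; both are
  literal readings and pinned by boundary tests.
* The 25th-percentile activity cut is *strictly above*, so a degenerate
  cohort where all genes tie produces no active genes rather than all.
* Problem sizes in the test and acceptance runs (a 1000-gene pair with 100
  planted tails; 2000 log-rank null replicates at 25 per arm; a 500-pair
  screen over 50 sample pairs; ~90 invaded pairs per planted fraction) were
  chosen to give tight Monte-Carlo error on every reported rate at desk
  scale.
* Sample-level failure isolation in `run_cohort` (skip-and-report) keeps a
  single corrupt track from discarding a cohort.

## Known limitations

Calling is deterministic thresholding, not hypothesis testing: there is no
per-gene error control, by design. Isoform-level
read-through, TTS re-annotation, and unstranded-library deconvolution are
not attempted. The chimera caller consumes junction evidence and cannot
recover events the upstream aligner never reported.
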