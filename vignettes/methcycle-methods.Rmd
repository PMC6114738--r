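---
title: "Methods: two-group WGBS methylome comparison with methcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-group WGBS methylome comparison with methcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Whole-genome bisulfite sequencing (WGBS) measures DNA methylation at
single-base resolution: bisulfite converts unmethylated cytosines to
uracil (read as T) while methylated cytosines are protected, so at each
cytosine the fraction of reads still showing C estimates its methylation
level. `methcycle` compares two groups of WGBS methylomes — its defaults
are labelled `anagen` and `telogen`, the growth and rest phases of the
hair-follicle cycle in skin — and identifies differentially methylated
regions (DMRs), annotates them to genes (DMGs), and intersects those
genes with differentially expressed genes (DEGs) from a precomputed
expression table.

The pipeline starts from per-cytosine count tables (chromosome, position,
strand, context, methylated reads, total reads), not from raw reads;
read alignment is out of scope. Read-level quality filtering utilities
are provided for the pre-alignment step, and a fully seeded synthetic
data generator produces every input with recorded ground truth so that
each stage can be validated against known answers.

# Per-site layer

**Context.** Each cytosine is classified by its 3'-ward sequence on its
own strand: `CG` when the next base is G, `CHG` when the base after next
is G, `CHH` otherwise (H = A, C or T). Minus-strand cytosines appear as
G in the reference and their context is read toward lower coordinates on
the complement; the classification is exactly strand-symmetric, which
the test suite verifies exhaustively over all 64 trinucleotides.
Cytosines with fewer downstream bases than the label requires are
resolved deterministically: a terminal `CG` dinucleotide is still `CG`,
anything undeterminable is `CHH`. These truncation cases are at most two
sites per contig end and the choice has no measurable effect.

**Conversion rate.** An unmethylated spike-in contig (lambda phage DNA
in the emulated design) measures conversion failure: the rate is
`1 - sum(meth)/sum(total)` over its sites, and its complement — the
conversion error — is the per-read probability of falsely reading an
unmethylated cytosine as methylated.

**Methylation calls.** WGBS studies routinely report methylated-cytosine
inventories without stating an operational calling rule, so `methcycle`
adopts the field's convention: a one-sided binomial test of each site's methylated
read count against the conversion error, Benjamini–Hochberg corrected
over all tested sites, called at q < 0.05. For per-group inventories the
group's replicates are pooled before testing (`call_group_matrix()`).

**Levels.** A site's level is `meth/total`; a region's level pools
counts (`sum(meth)/sum(total)`) rather than averaging site levels, which
makes it a coverage-weighted mean, robust to uneven depth. Sites with
pooled coverage below a floor (default 4 reads) are excluded from
level-based summaries; the floor is configurable everywhere it applies.

# DMR detection

The detector follows the BSmooth idea of borrowing strength across
neighbouring cytosines before testing, re-implemented here rather than
bound to an external package:

1. **Smoothing.** Per sample and per chromosome, raw CG site levels are
   fit by kernel-weighted local regression: tricube distance weights
   times coverage weights, degree-1 (local line) by default, evaluated
   at each site. The window spans ±500 bp and expands, nearest site
   first, until it holds at least 10 covered sites; smoothing never
   crosses a chromosome boundary. Fitted values are clamped to [0, 1].
   The degree-0 variant (weighted running mean) is available and is the
   form checked against a brute-force oracle in the tests.
2. **Window scan.** Sliding windows of 1000 bp advance in 100 bp steps.
   Each sample's window summary is the mean smoothed level over its
   covered sites; windows with fewer than 3 sites are skipped. The two
   groups' summaries are compared with a Welch t-test (the unequal
   variance form is the safe reading of "t-test" at n = 3 per group and
   reduces to Student's under equal variances), and p-values are
   Benjamini–Hochberg corrected over all tested windows.
3. **Differential sites.** A cytosine is differential when it lies in at
   least one window with q < 0.05 *and* its own pooled between-group
   difference exceeds 0.25 in absolute value. The FDR rule binds to
   windows and the effect-size rule to sites: the two criteria are
   usually listed without fixing their level, and this binding keeps region
   boundaries sharp (sites carry their own effect) while significance is
   assessed where the smoothing gives it power. Both thresholds are
   arguments.
4. **Merge.** Same-sign differential sites whose consecutive gaps are at
   most 300 bp form runs; runs with at least 3 sites become DMRs,
   spanning first to one past last supporting site. The 300 bp distance
   rule is conventionally phrased as a merge criterion but only
   functions as a split criterion (a gap larger than 300 bp separates
   regions); `methcycle` implements the split reading, and an exhaustive
   brute-force enumeration of maximal gap-bounded runs agrees with the
   implementation on thousands of randomized configurations. Sites of
   opposite sign never co-merge.
5. **Direction.** A DMR's `mean_diff` is the pooled telogen level minus
   the pooled anagen level over its supporting sites; `hyper` means
   higher in telogen, matching the reported convention for hair-cycle
   methylomes. Window boundaries are `[k*step, k*step + window)`, and
   because DMR coordinates derive from supporting sites, the step phase
   cannot move DMR edges.

Only the CG context is analysed by default; other contexts can be passed
through the same machinery but carry no calibration claims.

# Descriptive profiles

* `window_density()` tiles chromosomes (default 300 kb) and reports the
  pooled level per window, context and group; pooled counts over all
  windows conserve the genome-wide totals exactly.
* `metaprofile()` pools levels into bins over promoters (2 kb upstream
  of the TSS, the common convention since promoter profiles are rarely
  given an explicit definition), scaled gene bodies, exons, introns
  and CpG islands (50 bins each), CGI shores (the 2 kb flanking an
  island, excluding positions inside another island) and 3' gene flanks.
  Minus-strand genes are flipped so bin 0 is always 5'.
* `cpg_oe()` is the Gardiner–Garden observed/expected ratio
  `(N_CpG * L) / (N_C * N_G)`, 0 when C or G is absent.
* `chrom_summaries()` + `chrom_feature_correlations()` relate
  per-chromosome mean levels to length, CpG content, CpG o/e, gene and
  repeat counts by Pearson correlation. Per-chromosome means are used
  (per-window values would also be possible but the summaries are the
  stated quantity).
* `sample_correlation()` computes pairwise Pearson correlations of
  per-site CG levels over sites adequately covered in both samples.

# Integration

A DMR annotates to a gene when it overlaps the gene span or its promoter
by at least 1 bp — the simplest defensible reading of "genes within the
DMRs", with promoters included because promoter methylation is analysed
throughout the profile layer; `promoter_width = 0` restricts membership
to spans. Feature class within a gene follows the precedence promoter >
exon > intron; CGI and shore flags are independent. Genes supported by
hyper and hypo DMRs simultaneously are reported in both sets and flagged
ambivalent. DEGs are genes with `q <= 0.05` and `|log2 fold change| > 1`
(boundary q kept, boundary fold change strictly exceeded); positive
`log_fc` means higher expression in telogen
so that methylation/expression concordance is coherent.

# The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of a two-stage
skin WGBS design: 3 replicates × 2 groups on two 1 Mb contigs plus a 48.5 kb
unmethylated lambda spike-in. Expected site levels are built from
context baselines (CG gene body 0.75, CG promoter/CGI 0.15, CHG 0.02,
CHH 0.01), a V-shaped dip of depth 0.10 within ±400 bp of each TSS, a
+0.03 CHG/CHH elevation at CGIs and shores, a +0.03 global CG offset in
telogen, and planted DMRs, then clamped to [0, 1]. Counts are drawn per
sample as negative binomial coverage (mean 20, size 10), a
beta-distributed replicate wobble around the expected level
(concentration 200, giving honest within-group variance for the window
t-test), and binomial methylated reads whose success probability adds
the conversion error (0.005) on the unmethylated fraction. Sequence
composition is GC 0.42 with background CpG depletion (75% of background
CpGs disrupted) and CpG-rich islands, so the CpG o/e ratio is high
inside islands and realistically low outside. Everything is a function
of one integer seed.

Two design points deserve note:

* **Planted effects are split symmetrically** (anagen −delta/2, telogen
  +delta/2 around the local baseline) rather than added wholly to one
  group: at the default CG body baseline of 0.75 a one-sided +0.3 would
  clamp at 1 and silently shrink the planted effect below the 0.25 site
  rule. The realized between-group difference is exactly delta either
  way.
* **Non-CG methylation is uniform, not bimodal.** Real methylomes
  concentrate CHH/CHG methylation in a small fraction of sites; the
  generator follows its stated uniform-baseline model instead. One
  consequence: with deep pooled counts the binomial caller legitimately
  calls many CHH sites (each truly sits slightly above the conversion
  error), so called-mC context proportions are not CG-dominated under
  the defaults even though CHH *levels* are 75-fold below CG. A
  methylome whose genuine methylation is confined to CG context (non-CG
  baselines at the conversion-error floor) does produce the familiar
  CG-dominated inventory, and is exercised in the tests.

What the generator does **not** emulate: read-level bisulfite sequences
(counts are drawn directly), linkage between neighbouring sites beyond
the shared regional baselines, repeat-associated methylation, copy
number or mappability artefacts, and real chromosome-scale
heterogeneity. Passing recovery tests therefore demonstrate the
correctness and calibration of the statistical machinery under the
generative model, not performance on real tissue data.

## Presets and problem sizes

* `small` — two 300 kb contigs, all contexts (~260k sites): structural
  checks (offset recovery, TSS dip, shore elevation) in seconds.
* `null` — one 1 Mb contig, CG only, identical generative parameters in
  both groups: false-positive calibration. Across 20 seeds the pipeline
  is expected to call essentially no DMRs (observed: none).
* `recovery` — two 1 Mb contigs, CG only, 50 planted DMRs of width
  1–3 kb and delta 0.3 in mixed directions, five of them hosted inside
  genes that are simultaneously planted DEGs: sensitivity, base-level
  precision, direction agreement and the end-to-end DMG×DEG overlap.

These sizes keep a full recovery run around ten seconds while each
planted DMR still spans dozens of CG sites, which is the regime the
window statistics are designed for.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere in memory; site tables
  and GTF are 1-based on disk, BED 0-based, with shifts confined to the
  readers/writers (round-trips are byte-identical and tested).
* The read QC N-fraction rule is implemented as *remove when N fraction
  exceeds 10%*; the rule is sometimes written with the comparison
  reversed, which contradicts its purpose and is treated here as a typo.
* Duplicate marking keys on `(chrom, start, strand)`, the standard proxy
  for "aligned to the same region"; the first read per key is kept.
* Zero-variance windows: both groups constant and equal gives t = 0,
  p = 1; constant but different gives p = 0. Windows where a group has
  fewer than two summaries are skipped and counted.
* The smoother falls back to a weighted mean when the local design
  matrix is near-singular, and an isolated site keeps its raw level.
* Empty regions yield `NA`, never 0; uncovered windows are reported as
  missing rather than dropped.
* `merge_dmrs()` on the support sites of already-merged DMRs returns the
  identical regions (idempotence, tested).

# Limitations

CHG/CHH DMR calling is mechanically available but uncalibrated; strand
collapsing of symmetric CpGs is not performed (sites stay
strand-resolved); GO enrichment is intentionally out of scope — DMG/DEG
lists are emitted in formats suitable for external enrichment tools; and
the acceptance-grade numbers quoted anywhere in this package are those
produced by its own tests and acceptance script on synthetic data, not
re-estimates of any published dataset.
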