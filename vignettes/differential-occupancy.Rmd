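---
title: "Differential ChIP-seq occupancy analysis with occupeak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential ChIP-seq occupancy analysis with occupeak}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occupeak)
```

# The problem

Two ChIP-seq experiments — for example a chromatin remodeler and a
mutant derivative of it — each yield a set of occupancy peaks with rpm
(reads-per-million) intensities and a genome-wide signal track.
`occupeak` answers the downstream questions such studies ask:

* which peaks are *unique* to one factor and which are *common* to both,
  judged by signal intensity rather than by peak-caller presence/absence;
* how peaks distribute over a seven-category functional model of the
  genome and over a chromatin-state segmentation, and whether any
  category is enriched or depleted against the genomic background;
* whether a sequence motif (here, the TPA-response element bound by
  AP-1 factors) is associated with a peak subset;
* whether peaks are linked to sets of regulated genes more often than
  random placement would produce;
* the small arithmetic of qPCR follow-up (ΔΔCt fold changes,
  MNase-qPCR enrichment).

Everything runs on synthetic data with planted ground truth, so the
whole pipeline is testable without any external download.

# The statistics

## Unique/common classification

For every peak of set $A$ (and symmetrically of $B$), read counts of
both libraries are collected in a 200 bp window centered on the peak
center, defined as $\lfloor(\mathrm{start}+\mathrm{end})/2\rfloor$.
With window counts $c_A, c_B$ and library sizes $\ell_A, \ell_B$, the
peak is called **unique to A** when both

$$\frac{\mathrm{rpm}_A}{\mathrm{rpm}_B} \ge 4
  \qquad\text{and}\qquad p \le 10^{-4},$$

otherwise **common**. The test behind $p$ is the conditional binomial:
under the null of equal rpm, given $n = c_A + c_B$,

$$c_A \sim \mathrm{Binomial}\!\left(n,\; q\right),\qquad
  q = \frac{\ell_A}{\ell_A + \ell_B},$$

and $p$ doubles the smaller one-sided tail, capped at 1 ($n = 0$ gives
$p = 1$: no evidence). This exact, parameter-free test is the standard
choice for two-library count ratios; the source study names only "the
p-value for that difference", so the test is a package design decision.
Two further numerical choices: the two-sided form (tail doubling) is
used even though the 4-fold criterion is directional, because the rule
is applied from each set's perspective and doubling is conservative;
and both window counts are floored at the equivalent of half a read
before the ratio, so empty windows yield finite folds instead of
division by zero.

Window counts use half-open windows
$[c - w/2,\, c + w/2)$ clipped at chromosome bounds, computed from
per-chromosome cumulative sums.

## Functional categories

The genome is partitioned into seven categories: promoter (1 kb
upstream of the TSS on the transcribed strand), TTS (1 kb downstream of
the transcript end), 5′ UTR, 3′ UTR, (coding) exon, intron, and
intergenic (the remainder). UTRs are strand-aware and exon-restricted;
non-coding transcripts contribute their exons to the exon class and
have no UTRs. Where features of different transcripts overlap, a fixed
precedence resolves the conflict:

promoter > TTS > 5′UTR > 3′UTR > exon > intron > intergenic.

The precedence is a package decision (the upstream tooling never
documents one): the promoter and TTS windows are the smallest,
explicitly defined classes and must not be swallowed by the introns of
overlapping genes. One disjoint category map backs both the per-peak
classifier and the genome-wide bp fractions, so the invariant
"classifying every base reproduces the genome fractions" holds by
construction — and is still tested against an independent per-base
labeling oracle.

Enrichment per category is
$\mathrm{fold} = \hat p / p_0$ (peak-center fraction over genomic bp
fraction) with an exact one-sided binomial tail taken in the direction
of the observed deviation.

## Cross-set category comparison

To compare one category between two peak sets of sizes $m, n$ with
category counts $m', n'$, both sets are pooled under the null into a
combined frequency $f = (m'+n')/(m+n)$, and the reported p-value is the
product of the two one-sided binomial tails of $m'$ against
$\mathrm{Bin}(m, f)$ and $n'$ against $\mathrm{Bin}(n, f)$, capped
at 1. Each tail's direction follows that set's observed deviation from
$f$ (the source formulation is silent on direction; the choice is
logged per category in the output).

## Chromatin states

Peaks are assigned to the chromatin state containing their center
(half-open segments: a center on a boundary belongs to the following
segment). Enrichment is peak-center fraction over genome bp fraction
with one-sided binomial p-values, exactly as for categories. Group rows
(e.g. two promoter states, four enhancer states) pool member counts and
genome fractions. A "top peaks" view filters to rpm strictly above 1.
Peak "% coverage" is implemented as the fraction of peak centers, not
bp overlap, consistent with center-based assignment.

## Motif association

IUPAC motifs are scanned on both strands with matches reported at
forward coordinates and deduplicated per position, since "contains the
motif" is a per-peak binary. `N` in the sequence never matches. The
built-ins are the TPA-response element `TGASTCA` (S = G or C; its
match-word set is closed under reverse complement, so forward-only
planting in the simulator is sufficient) and the AP-1-like `TGAATCA`.
A peak carries the motif when a match lies entirely within the peak
(flank 0 by default). Association of motif-bearing peaks with a peak
subset uses the exact hypergeometric upper tail against the full peak
population.

## Gene-list linkage and the Monte-Carlo null

A peak links a gene when its interval intersects the gene body extended
1 kb upstream (matching the promoter window; wider assignment rules
used by ontology tools are out of scope). List summaries count occupied
genes (% of listed genes, nearest integer), distinct linked binding
sites (% of all peaks, one decimal), and motif-bearing linked sites
(% of linked sites). The significance of a linkage statistic comes from
a Monte-Carlo null: each replicate re-places all peaks uniformly at
random (widths preserved, chromosomes weighted by length, no
GC/mappability matching — the source procedure used none), the
statistic is recomputed, and the observed value is reported as
$z = (x - \bar x_{\mathrm{null}})/s_{\mathrm{null}}$ with the
upper-tail normal p-value, following the z-score formulation; the
empirical rank p-value is reported alongside. A constant statistic
raises an error rather than returning a misleading zero-variance z.

## qPCR arithmetic

$\mathrm{fold} = 2^{-\Delta\Delta C_t}$ with amplification efficiency
fixed at 2 (the classic assumption; efficiency-corrected variants are
out of scope), and MNase-qPCR enrichment $2^{-(C_t^{\mathrm{chromatin}}
- C_t^{\mathrm{naked}})}$ normalized to naked genomic DNA, with mean ±
SEM over replicates.

# The synthetic-data generator

`simulation_config()` fixes the study conditions; every generator seeds
the RNG from `seed` plus a fixed per-stage offset, so each stage and
the full dataset are exactly reproducible.

```{r, eval = FALSE}
cfg <- simulation_config(seed = 1)
ds <- simulate_dataset(cfg)
res <- run_pipeline(ds, outdir = "occupeak_out")
```

Defaults, and why:

* **Genome**: 2 chromosomes × 1 Mb of i.i.d. sequence at GC 0.41
  (human-like). Large enough for stable state fractions, small enough
  that a full run takes seconds.
* **Peaks**: 120 and 80 peaks of width 400 bp, 60 % of the smaller set
  shared. Unique loci exist in *both* tracks at an 8-fold planted
  intensity ratio — twice the 4-fold classification threshold — rather
  than being absent from one library, matching the intensity-ratio
  notion of uniqueness. Reads are Poisson with mean 200 per peak,
  deposited uniformly within the peak: the simplest model that makes
  the ratio test face real sampling noise.
* **Chromatin states**: 15 labels with target fractions patterned on
  fibroblast chromatin (two-thirds heterochromatin, small promoter and
  enhancer states). Each label receives exactly its bp share per
  chromosome (largest-remainder apportionment) split into randomly
  interleaved segments of mean 2 kb, so realized coverage is exact.
* **Motifs**: 15 % of peak loci get a concrete instance of `TGASTCA`
  written at the locus center on the forward strand (sufficient, by
  the motif's reverse-complement closure). The figure mirrors the
  reported ~15 % of occupancy sites containing the element.
* **Genes and lists**: 60 non-overlapping genes placed in disjoint
  slots, 1–5 exons, CDS at exonic positions; gene lists of 20 ids
  drawn so that half overlap peaks. At the default peak density about
  half the genes are peak-occupied, which is what makes a stratified
  draw possible.

What the generator does **not** emulate: read-level artifacts
(fragment-length distributions, GC bias, mappability), background
noise reads outside peaks, peak-width variability, correlated motif
and state placement, and overlapping transcripts. Passing truth
recovery here shows the statistics and bookkeeping are correct under
the stated model, not that the pipeline is robust to every property of
real ChIP-seq data.

# Numerical and edge-case choices

* All internal coordinates are 0-based half-open (BED convention);
  refFlat input is already 0-based. A single convention eliminates
  off-by-one churn; dialect notes sit on each reader.
* The peak *center*, not the summit, drives every assignment; the
  summit is carried for completeness. The center convention also means
  the promoter window `[TSS-1000, TSS)` excludes the TSS base itself,
  which belongs to the transcript.
* Binary (+/−100 bp) peak-set overlap compares **center distance**
  (≤ slack), not padded-interval intersection — both readings of the
  convention are defensible; center distance is implemented and peaks
  pairing multiple partners count once.
* Percentages round half away from zero (`round_half_up`), so
  35.99 % prints as 36 %, matching the published tables' arithmetic.
* Degenerate inputs fail loudly: empty peak sets, gapped or
  overlapping segmentations, out-of-bounds peaks, unresolvable gene
  ids (reported, never dropped), zero-variance Monte-Carlo nulls.

# Problem sizes used by the test suite

The suite exercises: enumeration oracles at $n \le 30$ (ratio test),
$n \le 25$ (binomial), $N \le 12$ (hypergeometric); a 100 kb genome for
the per-base classification oracle; 150×100 peak sets for the
$O(n^2)$ overlap oracles; the default 2 Mb synthetic dataset for truth
recovery; 10,000 draws for ratio-test calibration; 10,000 uniform
centers for fold calibration; and 1,000 Monte-Carlo replicates for the
planted-linkage p-value. These sizes give every statistical check a
3-SE margin while keeping a full run in a few minutes.

# Known limitations

* The count-ratio test conditions on the window total; it does not
  model overdispersion between biological replicates (none are
  modeled upstream either).
* Enrichment folds computed from rounded printed percentages cannot be
  matched exactly by any implementation (the published folds were
  computed from unrounded internals); folds here are exact w.r.t. the
  package's own fractions.
* The product-of-binomials comparison is heuristic — the two tails are
  not independent under the pooled null — and is reported as defined,
  not as a calibrated p-value.
* GREAT-style distal assignment, peak calling, chromHMM training and
  de-novo motif discovery are out of scope.
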