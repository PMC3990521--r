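# occupeak

Differential ChIP-seq occupancy analysis: compare the genomic occupancy
of two chromatin-bound factors (for example a chromatin remodeler and a
remodeling-defective derivative), annotate their peaks against gene
models and chromatin states, associate them with sequence motifs and
regulated gene sets, and test every step against an exact or
Monte-Carlo null.

## What it computes

Given two peak sets (intervals + summit + rpm) with matched per-base
signal tracks, a gene annotation, a chromatin-state segmentation, a
genome sequence and gene lists, `occupeak` provides:

* **Unique/common classification.** For each peak of set *A*, window
  read counts of both libraries over 200 bp around the peak center are
  compared; the peak is unique to *A* iff rpm_A/rpm_B >= 4 **and** the
  conditional-binomial p-value is <= 1e-4 (given n = c_A + c_B, c_A ~
  Binomial(n, l_A/(l_A+l_B)) under equal rpm; two-sided by tail
  doubling). Symmetric for *B*; the rest are common.
* **Functional annotation.** Seven strand-aware categories (promoter
  -1 kb, TTS +1 kb, 5'UTR, 3'UTR, exon, intron, intergenic) with fixed
  precedence, genomic background fractions, exact one-sided binomial
  enrichment, and a product-of-binomials comparison of a category
  between the two sets against their pooled frequency
  f = (m'+n')/(m+n).
* **Chromatin-state enrichment** by peak center, with grouped states
  and a top-peaks (rpm > 1) view.
* **Motif association.** IUPAC scanning (built-ins: TPA-response
  element `TGASTCA`, AP-1-like `TGAATCA`) on both strands with
  positional dedup, per-peak flags, and hypergeometric association
  tests.
* **Binary peak-set overlap** (+/-100 bp center distance) with
  hypergeometric p-values and percentage summaries.
* **Gene-list linkage.** Body-or-promoter overlap of peaks with genes,
  list summaries, and a seeded Monte-Carlo random-peak null reported
  as a z-score with normal upper-tail p.
* **qPCR arithmetic.** Delta-delta-Ct fold changes and MNase-qPCR
  enrichment normalized to naked genomic DNA.
* **A seeded synthetic-data generator** that produces every input with
  planted ground truth (unique/common structure, motif placement,
  gene-list linkage), so the full pipeline runs and is scored without
  external data.

## Worked example

```r
library(occupeak)
cfg <- simulation_config(seed = 1)   # 2 Mb genome, 120 + 80 peaks
ds  <- simulate_dataset(cfg)
res <- run_pipeline(ds, mc_reps = 200)

render_occupancy_summary(res$classification)
#>     set total_peaks unique_peaks common_peaks
#> 1 set_a         120     72 (60%)     48 (40%)
#> 2 set_b          80     32 (40%)     48 (60%)
```

The generator planted 72 loci unique to A, 32 unique to B and 48
common; the classifier recovers exactly that structure from the read
counts alone. Motif and linkage stages:

```r
sum(res$motif$flags)                       # peaks containing TGASTCA
#> [1] 23                                   # 18 planted + chance hits

res$link[, c("name", "n_genes_occupied", "n_sites", "mc_z", "mc_p")]
#>   name n_genes_occupied n_sites  mc_z    mc_p
#> 1   up               10      10 0.465 0.32096
#> 2 down               10      15 2.670 0.00379
```

Both simulated lists were drawn with 10 of 20 genes peak-occupied; the
Monte-Carlo z tells whether the number of linked binding sites exceeds
random placement of the same 120 peaks (at this density, half-occupied
lists sit near the null, as they should). State enrichment rows carry
`peak_fraction`, `genome_fraction`, `fold` and a one-sided binomial
`p_value` per state, e.g. fold 1.01 with p 0.5 for the dominant
heterochromatin-like state of the uniform default genome.

See `vignettes/differential-occupancy.Rmd` for the statistical model,
parameter rationale, and the generator's scope and limits.

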