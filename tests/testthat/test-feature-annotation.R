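# a compact annotation with deliberately colliding features: geneU's
# promoter overlaps geneX's intron, plus a minus-strand multi-exon gene
toy_annotation <- function() {
  layout <- genome_layout(c("chr1", "chr2"), c(100000, 50000))
  genes <- rbind(
    # plus strand, 2 exons, CDS inside exon 2: 5'UTR = exon 1 + exon-2 prefix
    mk_gene("gX", "chr1", "+", 10000, 30000, cds_start = 22000,
            cds_end = 27000,
            exon_starts = list(c(10000, 20000)),
            exon_ends = list(c(12000, 30000))),
    # promoter of gU sits inside gX's intron
    mk_gene("gU", "chr1", "+", 15000, 18000),
    # minus strand, 3 exons with both UTRs
    mk_gene("gM", "chr1", "-", 50000, 70000, cds_start = 52000,
            cds_end = 68000,
            exon_starts = list(c(50000, 56000, 64000)),
            exon_ends = list(c(54000, 60000, 70000))),
    # non-coding single exon gene on chr2
    mk_gene("gN", "chr2", "+", 10000, 14000, cds_start = 10000,
            cds_end = 10000))
  list(layout = layout, genes = gene_annotation(genes, layout))
}

test_that("location classification follows strand-aware precedence", {
  toy <- toy_annotation()
  map <- category_map(toy$genes, toy$layout)
  cl <- function(chrom, pos) as.character(classify_location(chrom, pos, map))
  expect_equal(cl("chr1", 9500), "promoter")    # 500 bp upstream of + TSS
  expect_equal(cl("chr1", 10000), "utr5")       # TSS itself is transcript
  expect_equal(cl("chr1", 30500), "tts")        # downstream of + TTS
  expect_equal(cl("chr1", 21000), "utr5")       # exon-2 prefix before CDS
  expect_equal(cl("chr1", 11000), "utr5")       # exon 1 entirely 5'UTR
  expect_equal(cl("chr1", 25000), "exon")       # coding exon
  expect_equal(cl("chr1", 28000), "utr3")       # exon-2 suffix after CDS
  expect_equal(cl("chr1", 19000), "intron")
  expect_equal(cl("chr1", 14800), "promoter")   # gU promoter wins over intron
  expect_equal(cl("chr1", 40000), "intergenic")
  # minus strand: promoter upstream means right of tx_end
  expect_equal(cl("chr1", 70500), "promoter")
  expect_equal(cl("chr1", 49500), "tts")
  expect_equal(cl("chr1", 69000), "utr5")       # exonic, > cds_end on - strand
  expect_equal(cl("chr1", 51000), "utr3")
  # non-coding transcript: exons are exon, no UTRs
  expect_equal(cl("chr2", 12000), "exon")
})

test_that("classification of every base reproduces genome fractions and
           matches the per-base oracle", {
  toy <- toy_annotation()
  small <- genome_layout("chr1", 100000)
  genes1 <- gene_annotation(toy$genes[toy$genes$chrom == "chr1", ], small)
  map <- category_map(genes1, small)
  want <- oracle_base_categories(genes1, small)$chr1
  got <- classify_location(rep("chr1", 100000), 0:99999, map)
  expect_equal(as.character(got), as.character(want))
  # genome fractions equal the per-base tally exactly
  fr <- genome_category_fractions(genes1, small, map)
  expect_equal(unname(fr), as.vector(table(want) / 100000),
               tolerance = 1e-12)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  # empty annotation: everything intergenic
  empty <- gene_annotation(mk_gene("x", "chr1", "+", 0, 1)[0, ], small)
  fr0 <- genome_category_fractions(empty, small)
  expect_equal(unname(fr0[["intergenic"]]), 1)
})

test_that("one-sided category binomial test matches enumeration", {
  expect_equal(category_binomial_test(0, 10, 0.3, "greater"), 1)
  expect_equal(category_binomial_test(10, 10, 0.3, "greater"), 0.3^10)
  for (n in c(5, 12, 25)) {
    for (p0 in c(0.011, 0.3, 0.77)) {
      for (k in unique(round(seq(0, n, length.out = 4)))) {
        expect_equal(category_binomial_test(k, n, p0, "greater"),
                     enum_binom_ge(k, n, p0), tolerance = 1e-12)
        expect_equal(category_binomial_test(k, n, p0, "less"),
                     enum_binom_le(k, n, p0), tolerance = 1e-12)
      }
    }
  }
  expect_error(category_binomial_test(1, 10, 0), "strictly inside")
})

test_that("product-of-binomials comparison behaves per its arithmetic", {
  # balanced configuration: both tails >= 0.5, product <= 1
  r <- compare_category_between_sets(100, 100, 30, 30)
  expect_true(r$p_m >= 0.5 && r$p_n >= 0.5)
  expect_true(r$p_value <= 1)
  expect_equal(r$f, 0.3)
  # extreme split: p = (0.5^10) * (0.5^10)
  r2 <- compare_category_between_sets(10, 10, 10, 0)
  expect_equal(r2$f, 0.5)
  expect_equal(r2$p_value, 0.5^10 * 0.5^10, tolerance = 1e-12)
  # p decreases monotonically as the sets diverge at fixed totals
  ps <- vapply(0:5, function(d)
    compare_category_between_sets(40, 40, 10 + d, 10 - d)$p_value, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(compare_category_between_sets(0, 0, 0, 0), "both sets empty")
})

test_that("enrichment table uses the deviation direction for each tail", {
  toy <- toy_annotation()
  set.seed(3)
  st <- sample(0:99000, 200)
  peaks <- mk_peaks("chr1", st, st + 200, layout = toy$layout)
  tab <- category_enrichment_table(peaks, toy$genes, toy$layout)
  expect_equal(tab$category, FUNCTIONAL_CATEGORIES)
  expect_equal(sum(tab$n_peaks), nrow(peaks))
  expect_equal(sum(tab$peak_fraction), 1, tolerance = 1e-12)
  expect_true(all(tab$side[tab$peak_fraction >= tab$genome_fraction]
                  == "greater"))
  # fold definition
  nz <- tab$genome_fraction > 0
  expect_equal(tab$fold[nz], tab$peak_fraction[nz] / tab$genome_fraction[nz])
})

test_that("TSS-distance histogram conserves mass and signs distances", {
  toy <- toy_annotation()
  # peak centered exactly on a TSS falls in the [0, 500) bin
  p0 <- mk_peaks("chr1", 9900, 10100, layout = toy$layout)  # center 10000
  h0 <- tss_distance_histogram(p0, toy$genes, bin = 500, range = 5000)
  expect_equal(h0$count[h0$bin_start == 0], 1)
  expect_equal(sum(h0$count), 1)
  # upstream of a minus-strand TSS (to its right) is negative distance
  pm <- mk_peaks("chr1", 70900, 71100, layout = toy$layout)  # center 71000
  hm <- tss_distance_histogram(pm, toy$genes, bin = 500, range = 5000)
  expect_equal(attr(hm, "distances"), -1000)
  # mass conservation: all peaks within range are counted once
  set.seed(8)
  st <- sample(5000:95000, 150)
  pr <- mk_peaks("chr1", st, st + 200, layout = toy$layout)
  hr <- tss_distance_histogram(pr, toy$genes, bin = 500, range = 100000)
  expect_equal(sum(hr$count), 150)
  expect_error(tss_distance_histogram(p0, toy$genes[0, ]), "no genes")
})

test_that("peaks planted symmetrically around a TSS give a symmetric
           histogram and exact signed distances", {
  layout <- genome_layout("chr1", 200000)
  genes <- gene_annotation(mk_gene("g", "chr1", "+", 100000, 120000), layout)
  set.seed(21)
  half <- abs(round(stats::rnorm(200, 0, 2000))) + 1
  offs <- c(half, -half)   # exactly mirror-symmetric planting
  st <- 100000 + offs - 100
  peaks <- mk_peaks("chr1", st, st + 200, layout = layout)
  h <- tss_distance_histogram(peaks, genes, bin = 500, range = 8000)
  d <- attr(h, "distances")
  # the recovered signed distances are exactly the planted offsets
  expect_equal(sort(d), sort(offs))
  expect_equal(sum(d < 0), sum(d > 0))
  # mirrored bins carry equal mass when no offset sits on a bin edge
  inb <- abs(offs) < 8000 & (offs %% 500) != 0
  hs <- tss_distance_histogram(mk_peaks("chr1", 100000 + offs[inb] - 100,
                                        100000 + offs[inb] + 100,
                                        layout = layout),
                               genes, bin = 500, range = 8000)
  expect_equal(hs$count, rev(hs$count))
})
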