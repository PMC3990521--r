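test_that("chrom.sizes parsing validates layout invariants", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t1000", "chr2\t500"), path)
  layout <- read_chrom_sizes(path)
  expect_equal(layout$chrom, c("chr1", "chr2"))
  expect_equal(genome_size(layout), 1500)

  writeLines(character(), path)
  expect_error(read_chrom_sizes(path), "no chromosomes")
  writeLines("chr1\t0", path)
  expect_error(read_chrom_sizes(path), "positive")
  writeLines(c("chr1\t10", "chr1\t20"), path)
  expect_error(read_chrom_sizes(path), "duplicate")
  writeLines("chr1 10", path)
  expect_error(read_chrom_sizes(path), "malformed")
})

test_that("peak tables are bounds-checked and round-trip identically", {
  layout <- genome_layout(c("chr1", "chr2"), c(1000, 500))
  peaks <- mk_peaks(c("chr1", "chr1", "chr2"), c(0, 400, 100),
                    c(100, 600, 300), rpm = c(0.5, 2, 1.25),
                    layout = layout)
  expect_equal(nrow(peaks), 3L)
  expect_equal(peak_centers(peaks), c(50L, 500L, 200L))

  expect_error(mk_peaks("chr1", 10, 10, layout = layout), "end <= start")
  expect_error(mk_peaks("chr1", 900, 1100, layout = layout), "beyond")
  expect_error(mk_peaks("chr3", 0, 10, layout = layout), "unknown")
  expect_error(mk_peaks("chr1", 0, 10, rpm = -1, layout = layout),
               "negative rpm")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(peaks, path)
  back <- read_peak_table(path, layout, name = attr(peaks, "name"))
  expect_equal(as.data.frame(back), as.data.frame(peaks))
})

test_that("refFlat parsing validates exon structure and round-trips", {
  layout <- genome_layout("chr1", 100000)
  path <- withr::local_tempfile()
  # two-exon minus-strand gene, CDS confined to the genomic-left exon
  writeLines(c(
    "geneA\tchr1\t+\t1000\t3000\t1000\t3000\t1\t1000,\t3000,",
    "geneB\tchr1\t-\t5000\t9000\t5200\t5800\t2\t5000,7000,\t6000,9000,"),
    path)
  genes <- read_gene_annotation(path, layout)
  expect_equal(genes$gene_id, c("geneA", "geneB"))
  expect_equal(genes$exon_starts[[2]], c(5000, 7000))

  out <- withr::local_tempfile()
  write_gene_annotation(genes, out)
  expect_equal(as.data.frame(read_gene_annotation(out, layout)),
               as.data.frame(genes))

  writeLines("geneC\tchr1\t+\t0\t100\t0\t100\t2\t0,\t100,", path)
  expect_error(read_gene_annotation(path, layout), "exonCount")
  writeLines("geneD\tchr1\t+\t0\t100\t0\t100\t2\t50,0,\t60,100,", path)
  expect_error(read_gene_annotation(path, layout), "unsorted")
  expect_warning(
    {
      writeLines(character(), path)
      empty <- read_gene_annotation(path, layout)
    }, "no genes")
  expect_equal(nrow(empty), 0L)
})

test_that("single-exon fully-coding gene has empty UTRs", {
  layout <- genome_layout("chr1", 10000)
  genes <- gene_annotation(mk_gene("g", "chr1", "+", 2000, 5000), layout)
  map <- category_map(genes, layout)
  expect_equal(sum(GenomicRanges::width(map$utr5)), 0)
  expect_equal(sum(GenomicRanges::width(map$utr3)), 0)
  expect_equal(sum(GenomicRanges::width(map$exon)), 3000)
})

test_that("segmentation reader enforces exact tiling and caches fractions", {
  layout <- genome_layout("chr1", 1000)
  path <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100\tA", "chr1\t100\t1000\tB"), path)
  seg <- read_state_segmentation(path, layout, labels = c("A", "B"))
  expect_equal(unname(state_fractions(seg)[c("A", "B")]), c(0.1, 0.9))
  expect_equal(sum(state_fractions(seg)), 1, tolerance = 1e-12)

  writeLines(c("chr1\t0\t100\tA", "chr1\t90\t1000\tB"), path)
  expect_error(read_state_segmentation(path, layout, c("A", "B")),
               "overlap")
  writeLines(c("chr1\t0\t100\tA", "chr1\t200\t1000\tB"), path)
  expect_error(read_state_segmentation(path, layout, c("A", "B")), "gap")
  writeLines(c("chr1\t0\t1000\tZ"), path)
  expect_error(read_state_segmentation(path, layout, c("A", "B")),
               "unknown state")
  # one chromosome fully covered by one label
  writeLines("chr1\t0\t1000\tA", path)
  seg1 <- read_state_segmentation(path, layout, c("A", "B"))
  expect_equal(unname(state_fractions(seg1)[["A"]]), 1)
})

test_that("FASTA reading checks layout lengths and BED round-trips", {
  layout <- genome_layout("chr1", 4)
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT"), path)
  expect_equal(unname(read_fasta(path, layout)["chr1"]), "ACGT")
  writeLines(c(">chr1", "ACGTT"), path)
  expect_error(read_fasta(path, layout), "mismatch")

  bed <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 10L),
                    end = c(5L, 20L), name = c("x", "y"),
                    score = c(0L, 1L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(bed, out)
  expect_equal(read_bed(out), bed)
})

test_that("gene lists report unresolved ids instead of dropping them", {
  layout <- genome_layout("chr1", 10000)
  genes <- gene_annotation(mk_gene("g1", "chr1", "+", 0, 1000), layout)
  expect_warning(gl <- gene_list(c("g1", "gX"), "demo", genes),
                 "not in annotation")
  expect_setequal(as.character(gl), c("g1", "gX"))
  expect_equal(attr(gl, "unresolved"), "gX")
  expect_error(gene_list(character(), "empty"), "non-empty")
})

test_that("signal tracks validate counts and layout consistency", {
  layout <- genome_layout("chr1", 100)
  expect_error(signal_track(list(chr1 = rep(-1L, 100)), 10, layout),
               "negative")
  expect_error(signal_track(list(chr1 = integer(50)), 10, layout),
               "length mismatch")
  tr <- mk_track(layout, list(chr1 = c(5L, 5L, 7L)), library_size = 1e6)
  expect_equal(sum(tr$counts$chr1), 3)
})
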