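test_that("generators are deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 5, chrom_length = 100000L,
                           n_peaks_a = 30L, n_peaks_b = 20L,
                           n_genes = 8L, n_list_genes = 3L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(as.data.frame(d1$set_a), as.data.frame(d2$set_a))
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$track_b$counts, d2$track_b$counts)
})

test_that("background sequence composition follows the configured GC", {
  cfg0 <- simulation_config(seed = 2, n_chroms = 1L,
                            chrom_length = 20000L, background_gc = 0)
  g0 <- simulate_genome(cfg0)
  expect_false(grepl("[GC]", g0$sequences[[1]]))
  cfg <- simulation_config(seed = 2, n_chroms = 1L,
                           chrom_length = 1000000L, background_gc = 0.41)
  g <- simulate_genome(cfg)
  gc <- sum(strsplit(g$sequences[[1]], "")[[1]] %in% c("G", "C")) / 1e6
  se <- sqrt(0.41 * 0.59 / 1e6)
  expect_lt(abs(gc - 0.41), 3 * se)
})

test_that("simulated genes validate and are balanced in strand", {
  layout <- genome_layout(paste0("chr", 1:4), rep(4000000, 4))
  cfg <- simulation_config(seed = 8, n_chroms = 4L,
                           chrom_length = 4000000L, n_genes = 1000L)
  genes <- simulate_genes(layout, cfg)
  # constructor revalidation is the oracle for all gene-model invariants
  expect_silent(gene_annotation(genes, layout))
  expect_equal(nrow(genes), 1000L)
  # non-overlap within chromosomes
  for (cn in layout$chrom) {
    g <- genes[genes$chrom == cn, ]
    g <- g[order(g$tx_start), ]
    if (nrow(g) > 1)
      expect_true(all(g$tx_start[-1] >= g$tx_end[-nrow(g)]))
  }
  n_plus <- sum(genes$strand == "+")
  expect_lt(abs(n_plus - 500), 3 * sqrt(1000 * 0.25))
  expect_equal(nrow(simulate_genes(layout, simulation_config(n_genes = 0L))),
               0L)
  tiny <- genome_layout("chr1", 30000)
  expect_error(simulate_genes(tiny, cfg), "cannot place")
})

test_that("simulated segmentation covers exactly at the target fractions", {
  cfg <- simulation_config(seed = 13)
  layout <- genome_layout(paste0("chr", 1:2), rep(1000000, 2))
  seg <- simulate_segmentation(layout, cfg)
  # full coverage with no gaps is enforced by the constructor; fractions
  # land within 2% of target on a >= 1 Mb genome
  fr <- state_fractions(seg)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_true(all(abs(fr - cfg$state_target_fractions) < 0.02))
  # recount coverage independently of the cached fractions
  bp <- tapply(seg$end - seg$start, seg$state, sum)
  expect_equal(unname(bp[cfg$state_labels[1]]) / genome_size(layout),
               unname(fr[cfg$state_labels[1]]))
  # degenerate single-label segmentation: one segment per chromosome
  cfg1 <- simulation_config(seed = 13, state_labels = "only",
                            state_target_fractions = 1)
  seg1 <- simulate_segmentation(layout, cfg1)
  expect_equal(unname(state_fractions(seg1)[["only"]]), 1)
})

test_that("peak simulation plants the configured structure and truth", {
  ds <- get_shared_dataset()
  cfg <- ds$config
  tr <- ds$truth
  # set sizes and shared structure
  expect_equal(nrow(ds$set_a), cfg$n_peaks_a)
  expect_equal(nrow(ds$set_b), cfg$n_peaks_b)
  n_common <- round(cfg$frac_shared * min(cfg$n_peaks_a, cfg$n_peaks_b))
  expect_equal(sum(tr$label == "common"), n_common)
  expect_equal(sum(tr$in_set_a), cfg$n_peaks_a)
  # frac_shared = 1 leaves no unique loci in the smaller set
  ds1 <- simulate_peaksets(ds$layout, ds$sequences,
                           simulation_config(seed = 4, frac_shared = 1,
                                             n_peaks_a = 50L,
                                             n_peaks_b = 50L))
  expect_equal(unique(ds1$truth$label), "common")
  # planted motifs are recoverable by scanning at every flagged locus
  planted <- tr[tr$has_motif, ]
  for (i in seq_len(nrow(planted))) {
    sub <- substr(ds$sequences[[planted$chrom[i]]],
                  planted$start[i] + 1, planted$end[i])
    expect_gt(length(oracle_scan_positions(sub, cfg$motif)), 0)
  }
  expect_equal(sum(tr$has_motif),
               round(cfg$frac_peaks_with_motif * nrow(tr)))
  # reads are deposited inside their peak interval: per-peak track counts
  # reproduce the rpm scale exactly (loci are disjoint by construction)
  for (i in seq(1, nrow(ds$set_a), length.out = 20)) {
    i <- as.integer(i)
    cnt <- sum(ds$track_a$counts[[ds$set_a$chrom[i]]][
      (ds$set_a$start[i] + 1):ds$set_a$end[i]])
    expect_equal(cnt, ds$set_a$rpm[i] * cfg$library_size_a / 1e6)
  }
  expect_error(
    simulate_peaksets(ds$layout, ds$sequences,
                      simulation_config(motif = paste(rep("A", 100),
                                                      collapse = ""),
                                        peak_width = 50L)),
    "motif longer")
})

test_that("planted unique loci carry the intended intensity ratio", {
  ds <- get_shared_dataset()
  tr <- ds$truth
  cfg <- ds$config
  # realized per-locus read ratio (with the same 0.5-count floor used by
  # the classifier) reaches the 4-fold threshold at >= 95% of unique loci
  ra <- vapply(seq_len(nrow(tr)), function(i) {
    w <- window_counts(ds$track_a, tr$chrom[i], tr$center[i], 200)$count
    max(w, 0.5)
  }, 0)
  rb <- vapply(seq_len(nrow(tr)), function(i) {
    w <- window_counts(ds$track_b, tr$chrom[i], tr$center[i], 200)$count
    max(w, 0.5)
  }, 0)
  ua <- tr$label == "unique_a"; ub <- tr$label == "unique_b"
  hit <- c(ra[ua] / rb[ua], rb[ub] / ra[ub]) >= 4
  expect_gte(mean(hit), 0.95)
})

test_that("simulated gene lists hit the configured occupancy fraction", {
  ds <- get_shared_dataset()
  cfg <- ds$config
  occ <- map_peaks_to_genes(ds$set_a, ds$genes)
  for (gl in ds$gene_lists) {
    s <- summarize_gene_list(gl, occ, ds$set_a)
    want <- round(cfg$frac_list_occupied * cfg$n_list_genes)
    expect_lte(abs(s$n_genes_occupied - want), 1)
  }
  expect_error(
    simulate_gene_lists(ds$genes, ds$set_a,
                        simulation_config(n_list_genes = 500L)),
    "unachievable")
})
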