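# Seeded generators for every input the pipeline consumes: genome
# sequence, gene models, a chromatin-state segmentation, two peak sets
# with matched signal tracks, and up/down gene lists -- each with planted
# ground truth (unique/common locus structure, motif placement, gene-list
# linkage) so every downstream stage has a recoverable truth.
#
# Determinism: every generator seeds the RNG from `config$seed` plus a
# fixed per-stage offset, so each stage is reproducible on its own and
# the full dataset is reproducible end to end.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe a compact two-chromosome genome (2 Mb total) with
#' two occupancy experiments of 120 and 80 peaks: unique loci carry an
#' 8-fold planted intensity ratio between the libraries (twice the
#' 4-fold classification threshold, so truth recovery is expected but
#' not trivial), reads are Poisson with mean 200 per peak, 15 chromatin
#' states follow genome fractions patterned on fibroblast chromatin
#' (heterochromatin-dominated), and 15% of peak loci carry a planted
#' TPA-response element.
#'
#' @param seed integer RNG seed
#' @param n_chroms number of chromosomes
#' @param chrom_length chromosome length in bp
#' @param n_genes genes to place (non-overlapping)
#' @param n_peaks_a,n_peaks_b peak counts of the two sets
#' @param frac_shared fraction of loci shared by both sets
#' @param unique_fold planted intensity ratio at unique loci (> 1)
#' @param peak_width peak interval width in bp
#' @param state_labels chromatin-state label set
#' @param state_target_fractions target genome fraction per label
#'   (normalized to sum to 1)
#' @param state_segment_mean mean segment length in bp
#' @param motif IUPAC motif planted at motif-bearing loci
#' @param frac_peaks_with_motif fraction of loci with a planted motif
#' @param background_gc GC fraction of the background sequence
#' @param reads_per_peak Poisson mean read count per peak
#' @param library_size_a,library_size_b library sizes of the two tracks
#' @param n_list_genes genes per simulated expression list
#' @param frac_list_occupied fraction of listed genes that overlap peaks
#' @param gene_length_range min/max transcript length in bp
#' @return a validated `simulation_config` list
#' @export
simulation_config <- function(
    seed = 1L,
    n_chroms = 2L,
    chrom_length = 1000000L,
    n_genes = 60L,
    n_peaks_a = 120L,
    n_peaks_b = 80L,
    frac_shared = 0.6,
    unique_fold = 8,
    peak_width = 400L,
    state_labels = as.character(1:15),
    state_target_fractions = c(0.6, 0.5, 0.1, 0.3, 1.3, 0.8, 1.9, 0.9,
                               0.5, 4.4, 12.8, 6.4, 65.0, 0.1, 0.1),
    state_segment_mean = 2000L,
    motif = TRE_MOTIF,
    frac_peaks_with_motif = 0.15,
    background_gc = 0.41,
    reads_per_peak = 200,
    library_size_a = 1e6,
    library_size_b = 1e6,
    n_list_genes = 20L,
    frac_list_occupied = 0.5,
    gene_length_range = c(2000L, 10000L)) {
  cfg <- as.list(environment())
  fr <- c(frac_shared, frac_peaks_with_motif, frac_list_occupied,
          background_gc)
  stop_if(any(fr < 0 | fr > 1), "fractions must lie in [0, 1]")
  stop_if(unique_fold <= 1, "unique_fold must exceed 1")
  stop_if(length(state_labels) != length(state_target_fractions),
          "state_labels and state_target_fractions lengths differ")
  stop_if(any(state_target_fractions < 0) ||
            sum(state_target_fractions) <= 0,
          "state_target_fractions must be non-negative, not all zero")
  cfg$state_target_fractions <-
    state_target_fractions / sum(state_target_fractions)
  stop_if(nchar(motif) > peak_width,
          "motif longer than peak width")
  stop_if(reads_per_peak <= 0 || library_size_a <= 0 || library_size_b <= 0,
          "read and library parameters must be positive")
  stop_if(gene_length_range[1] < 100 ||
            gene_length_range[2] < gene_length_range[1],
          "invalid gene_length_range")
  structure(cfg, class = "simulation_config")
}

#' Simulate a genome layout and i.i.d. background sequence
#'
#' @param config a [simulation_config()]
#' @return list: `layout` ([genome_layout()]) and `sequences` (named
#'   character vector, bases i.i.d. at `background_gc`)
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed + 0L)
  layout <- genome_layout(paste0("chr", seq_len(config$n_chroms)),
                          rep(config$chrom_length, config$n_chroms))
  gc <- config$background_gc
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sequences <- vapply(layout$chrom, function(cn) {
    paste(sample(names(p), chrom_length(layout, cn), replace = TRUE,
                 prob = p), collapse = "")
  }, "")
  list(layout = layout, sequences = sequences)
}

#' Simulate non-overlapping gene models
#'
#' Genes are placed in disjoint slots (so they can never overlap), with
#' random strand, 1-5 exons tiling the transcript endpoints, and CDS
#' bounds at exonic positions inside the transcript.
#'
#' @param layout a [genome_layout()]
#' @param config a [simulation_config()]
#' @return a [gene_annotation()]
#' @export
simulate_genes <- function(layout, config) {
  set.seed(config$seed + 1L)
  if (config$n_genes == 0L)
    return(gene_annotation(data.frame(
      gene_id = character(), chrom = character(), strand = character(),
      tx_start = numeric(), tx_end = numeric(),
      cds_start = numeric(), cds_end = numeric(),
      exon_starts = I(list()), exon_ends = I(list()))))
  slot_len <- config$gene_length_range[2] + 2000L
  slots <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    k <- floor(layout$length[i] / slot_len)
    data.frame(chrom = layout$chrom[i],
               slot_start = (seq_len(k) - 1L) * slot_len)
  }))
  stop_if(nrow(slots) < config$n_genes,
          "cannot place ", config$n_genes,
          " non-overlapping genes; reduce n_genes or enlarge the genome")
  chosen <- slots[sample.int(nrow(slots), config$n_genes), , drop = FALSE]
  rows <- lapply(seq_len(config$n_genes), function(i) {
    tx_len <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1L)
    tx_start <- chosen$slot_start[i] +
      sample.int(slot_len - tx_len, 1L) - 1L
    tx_end <- tx_start + tx_len
    k <- sample.int(5L, 1L)
    if (k == 1L) {
      es <- tx_start; ee <- tx_end
    } else {
      b <- sort(sample((tx_start + 1L):(tx_end - 1L), 2L * (k - 1L)))
      es <- c(tx_start, b[seq(2L, length(b), by = 2L)])
      ee <- c(b[seq(1L, length(b), by = 2L)], tx_end)
    }
    exonic <- unlist(lapply(seq_along(es), function(j) es[j]:(ee[j] - 1L)))
    cds <- sort(sample(exonic, 2L, replace = TRUE))
    data.frame(gene_id = sprintf("gene%03d", i), chrom = chosen$chrom[i],
               strand = sample(c("+", "-"), 1L),
               tx_start = tx_start, tx_end = tx_end,
               cds_start = cds[1], cds_end = cds[2] + 1L,
               exon_starts = I(list(es)), exon_ends = I(list(ee)),
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  genes <- genes[order(match(genes$chrom, layout$chrom), genes$tx_start), ]
  rownames(genes) <- NULL
  gene_annotation(genes, layout = layout)
}

# split `total` bp into pieces of roughly `mean_len` (all >= 1)
.split_lengths <- function(total, mean_len) {
  n <- max(1L, min(total, round(total / mean_len)))
  if (n == 1L) return(total)
  cuts <- sort(sample.int(total - 1L, n - 1L))
  diff(c(0L, cuts, total))
}

#' Simulate a full-coverage chromatin-state segmentation
#'
#' Per chromosome, each label receives exactly its target share of bp
#' (largest-remainder apportionment), split into randomly interleaved
#' segments with approximately exponential lengths; coverage is exact and
#' gap-free by construction.
#'
#' @param layout a [genome_layout()]
#' @param config a [simulation_config()]
#' @return a [state_segmentation()]
#' @export
simulate_segmentation <- function(layout, config) {
  set.seed(config$seed + 2L)
  labels <- config$state_labels
  target <- config$state_target_fractions
  out <- list()
  for (i in seq_len(nrow(layout))) {
    len <- layout$length[i]
    raw <- target * len
    bp <- floor(raw)
    short <- len - sum(bp)
    if (short > 0) {
      add <- order(raw - bp, decreasing = TRUE)[seq_len(short)]
      bp[add] <- bp[add] + 1L
    }
    piece_len <- integer(); piece_lab <- character()
    for (j in seq_along(labels)) {
      if (bp[j] == 0) next
      pl <- .split_lengths(bp[j], config$state_segment_mean)
      piece_len <- c(piece_len, pl)
      piece_lab <- c(piece_lab, rep(labels[j], length(pl)))
    }
    ord <- sample.int(length(piece_len))
    piece_len <- piece_len[ord]; piece_lab <- piece_lab[ord]
    ends <- cumsum(as.numeric(piece_len))
    out[[i]] <- data.frame(chrom = layout$chrom[i],
                           start = c(0, ends[-length(ends)]),
                           end = ends, state = piece_lab,
                           stringsAsFactors = FALSE)
  }
  state_segmentation(do.call(rbind, out), layout, labels)
}

.IUPAC_EXPANSION <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

# draw one concrete instance of an IUPAC pattern
.instantiate_motif <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- .IUPAC_EXPANSION[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

#' Simulate two peak sets with matched signal tracks and ground truth
#'
#' Loci are placed in disjoint slots. A `frac_shared` share of them carry
#' peaks in both sets with equal expected intensity; the rest are
#' set-specific, present in both tracks but with the planted intensity
#' ratio `unique_fold` between libraries (matching an intensity-ratio
#' rather than presence/absence notion of uniqueness). Reads are Poisson
#' per locus and deposited uniformly within the peak interval. A
#' `frac_peaks_with_motif` share of loci have a concrete instance of the
#' motif written into the sequence at the locus center (forward strand).
#'
#' @param layout a [genome_layout()]
#' @param sequences named character vector from [simulate_genome()]
#' @param config a [simulation_config()]
#' @return list: `set_a`, `set_b` ([peak_set()]s), `track_a`, `track_b`
#'   ([signal_track()]s), `truth` (per-locus data frame: locus, chrom,
#'   start, end, center, label in common/unique_a/unique_b, has_motif,
#'   expected counts), and `sequences` with motifs planted
#' @export
simulate_peaksets <- function(layout, sequences, config) {
  set.seed(config$seed + 3L)
  stop_if(nchar(config$motif) > config$peak_width,
          "motif longer than peak width")
  n_common <- round(config$frac_shared * min(config$n_peaks_a,
                                             config$n_peaks_b))
  n_ua <- config$n_peaks_a - n_common
  n_ub <- config$n_peaks_b - n_common
  n_loci <- n_common + n_ua + n_ub
  w <- config$peak_width
  half <- floor(w / 2)
  slot_len <- 2L * w
  slots <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    k <- floor(layout$length[i] / slot_len)
    data.frame(chrom = layout$chrom[i],
               slot_start = (seq_len(k) - 1L) * slot_len)
  }))
  stop_if(nrow(slots) < n_loci,
          "genome too small for ", n_loci, " separated peak loci")
  chosen <- slots[sample.int(nrow(slots), n_loci), , drop = FALSE]
  center <- chosen$slot_start + w
  truth <- data.frame(
    locus = seq_len(n_loci), chrom = chosen$chrom,
    start = center - half, end = center - half + w, center = center,
    label = c(rep("common", n_common), rep("unique_a", n_ua),
              rep("unique_b", n_ub)),
    has_motif = FALSE, stringsAsFactors = FALSE)
  truth <- truth[order(match(truth$chrom, layout$chrom), truth$start), ]
  truth$locus <- seq_len(n_loci)
  rownames(truth) <- NULL
  # plant motifs at locus centers, forward strand
  n_motif <- round(config$frac_peaks_with_motif * n_loci)
  if (n_motif > 0) {
    mi <- sample.int(n_loci, n_motif)
    truth$has_motif[mi] <- TRUE
    L <- nchar(config$motif)
    for (i in mi) {
      word <- .instantiate_motif(config$motif)
      s0 <- truth$center[i] - floor(L / 2)   # 0-based
      substr(sequences[[truth$chrom[i]]], s0 + 1L, s0 + L) <- word
    }
  }
  # expected read counts per locus and library
  rpp <- config$reads_per_peak
  truth$lambda_a <- ifelse(truth$label == "unique_b",
                           rpp / config$unique_fold, rpp)
  truth$lambda_b <- ifelse(truth$label == "unique_a",
                           rpp / config$unique_fold, rpp)
  deposit <- function(lambda, library_size) {
    counts <- lapply(setNames(layout$length, layout$chrom),
                     function(l) integer(l))
    reads <- rpois(n_loci, lambda)
    for (i in seq_len(n_loci)) {
      if (reads[i] == 0) next
      pos <- truth$start[i] + floor(runif(reads[i]) * w)  # 0-based
      cn <- truth$chrom[i]
      tab <- tabulate(pos + 1L, nbins = length(counts[[cn]]))
      counts[[cn]] <- counts[[cn]] + tab
    }
    list(track = signal_track(counts, library_size, layout), reads = reads)
  }
  da <- deposit(truth$lambda_a, config$library_size_a)
  db <- deposit(truth$lambda_b, config$library_size_b)
  mk_set <- function(keep, reads, library_size, name) {
    df <- data.frame(chrom = truth$chrom[keep], start = truth$start[keep],
                     end = truth$end[keep],
                     summit = truth$center[keep],
                     rpm = 1e6 * reads[keep] / library_size,
                     stringsAsFactors = FALSE)
    peak_set(df, name = name, layout = layout,
             total_mapped_reads = library_size)
  }
  in_a <- truth$label %in% c("common", "unique_a")
  in_b <- truth$label %in% c("common", "unique_b")
  truth$in_set_a <- in_a
  truth$in_set_b <- in_b
  list(set_a = mk_set(in_a, da$reads, config$library_size_a, "set_a"),
       set_b = mk_set(in_b, db$reads, config$library_size_b, "set_b"),
       track_a = da$track, track_b = db$track,
       truth = truth, sequences = sequences)
}

#' Simulate up/down-regulated gene lists with controlled peak linkage
#'
#' Draws two disjoint gene lists in which a configured fraction of the
#' listed genes overlap peaks (body or promoter); which listed genes are
#' truly occupied is recorded in the `occupied` attribute of each list.
#'
#' @param genes a [gene_annotation()]
#' @param peaks the [peak_set()] linkage is measured against
#' @param config a [simulation_config()]
#' @param promoter_up upstream promoter extension in bp
#' @return list of two [gene_list()]s, `up` and `down`
#' @export
simulate_gene_lists <- function(genes, peaks, config, promoter_up = 1000) {
  set.seed(config$seed + 4L)
  occupancy <- map_peaks_to_genes(peaks, genes, promoter_up)
  occ_ids <- occupancy$gene_id[occupancy$n_peaks >= 1]
  un_ids <- occupancy$gene_id[occupancy$n_peaks == 0]
  n <- config$n_list_genes
  n_occ <- round(config$frac_list_occupied * n)
  stop_if(length(occ_ids) < 2 * n_occ || length(un_ids) < 2 * (n - n_occ),
          "requested overlap fraction unachievable: ",
          length(occ_ids), " occupied and ", length(un_ids),
          " unoccupied genes available")
  pick <- function(pool, k) if (k == 0L) character() else sample(pool, k)
  occ_pick <- pick(occ_ids, 2L * n_occ)
  un_pick <- pick(un_ids, 2L * (n - n_occ))
  mk <- function(ids_occ, ids_un, name) {
    gl <- gene_list(c(ids_occ, ids_un), name = name, genes = genes)
    attr(gl, "occupied") <- ids_occ
    gl
  }
  list(up = mk(occ_pick[seq_len(n_occ)], un_pick[seq_len(n - n_occ)], "up"),
       down = mk(occ_pick[seq_len(n_occ) + n_occ],
                 un_pick[seq_len(n - n_occ) + (n - n_occ)], "down"))
}

#' Simulate a complete dataset
#'
#' Runs every generator in order and returns all pipeline inputs plus
#' the planted truth.
#'
#' @param config a [simulation_config()]
#' @return list: config, layout, sequences (with planted motifs), genes,
#'   segmentation, set_a, set_b, track_a, track_b, truth, gene_lists
#' @export
simulate_dataset <- function(config = simulation_config()) {
  g <- simulate_genome(config)
  genes <- simulate_genes(g$layout, config)
  segmentation <- simulate_segmentation(g$layout, config)
  pk <- simulate_peaksets(g$layout, g$sequences, config)
  gene_lists <- simulate_gene_lists(genes, pk$set_a, config)
  list(config = config, layout = g$layout, sequences = pk$sequences,
       genes = genes, segmentation = segmentation,
       set_a = pk$set_a, set_b = pk$set_b,
       track_a = pk$track_a, track_b = pk$track_b,
       truth = pk$truth, gene_lists = gene_lists)
}

#' Write a simulated dataset to a directory
#'
#' Emits every input in its interchange format: chrom.sizes, genome
#' FASTA, refFlat genes, dense BED4 segmentation, peak tables, gene
#' lists and truth.tsv. Signal tracks are not serialized; they are
#' reproducible from the config seed.
#'
#' @param dataset output of [simulate_dataset()]
#' @param outdir output directory (created if needed)
#' @return named vector of written paths, invisibly
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_chrom_sizes(dataset$layout, p("chrom.sizes"))
  write_fasta(dataset$sequences, p("genome.fa"))
  write_gene_annotation(dataset$genes, p("genes.refflat"))
  write_state_segmentation(dataset$segmentation, p("states.bed"))
  write_peak_table(dataset$set_a, p("peaks_a.tsv"))
  write_peak_table(dataset$set_b, p("peaks_b.tsv"))
  truth <- dataset$truth
  utils::write.table(truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(as.character(dataset$gene_lists$up), p("genes_up.txt"))
  writeLines(as.character(dataset$gene_lists$down), p("genes_down.txt"))
  invisible(setNames(
    p(c("chrom.sizes", "genome.fa", "genes.refflat", "states.bed",
        "peaks_a.tsv", "peaks_b.tsv", "truth.tsv", "genes_up.txt",
        "genes_down.txt")),
    c("chrom_sizes", "genome", "genes", "states", "peaks_a", "peaks_b",
      "truth", "genes_up", "genes_down")))
}
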