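# Independent oracles and small fixture builders shared across tests.
# Each oracle is a deliberately naive reimplementation (per-base loops,
# exhaustive enumeration, O(n^2) scans) kept separate from the package's
# own code paths.

# --- fixture builders --------------------------------------------------------

mk_peaks <- function(chrom, start, end, rpm = 1, name = "test",
                     layout = NULL, lib = NULL) {
  peak_set(data.frame(chrom = chrom, start = start, end = end,
                      summit = floor((start + end) / 2), rpm = rpm,
                      stringsAsFactors = FALSE),
           name = name, layout = layout, total_mapped_reads = lib)
}

# track from explicit 0-based read-start positions
mk_track <- function(layout, positions, library_size = 1e6) {
  counts <- lapply(setNames(layout$length, layout$chrom),
                   function(l) integer(l))
  for (cn in names(positions)) {
    if (length(positions[[cn]]))
      counts[[cn]] <- counts[[cn]] +
        tabulate(positions[[cn]] + 1L, nbins = length(counts[[cn]]))
  }
  signal_track(counts, library_size, layout)
}

mk_gene <- function(id, chrom, strand, tx_start, tx_end,
                    cds_start = tx_start, cds_end = tx_end,
                    exon_starts = list(tx_start), exon_ends = list(tx_end)) {
  data.frame(gene_id = id, chrom = chrom, strand = strand,
             tx_start = tx_start, tx_end = tx_end,
             cds_start = cds_start, cds_end = cds_end,
             exon_starts = I(exon_starts), exon_ends = I(exon_ends),
             stringsAsFactors = FALSE)
}

# memoized default synthetic dataset, built once per test run
.shared <- new.env(parent = emptyenv())
get_shared_dataset <- function() {
  if (is.null(.shared$ds))
    .shared$ds <- simulate_dataset(simulation_config(seed = 42))
  .shared$ds
}

# --- per-base functional labeling oracle ------------------------------------

# label every base of every chromosome by looping over genes and marking
# positions with the best (lowest) precedence rank
oracle_base_categories <- function(genes, layout,
                                   promoter_up = 1000, tts_down = 1000) {
  seqr <- function(a, b) if (b > a) a:(b - 1) else integer()
  out <- list()
  for (ci in seq_len(nrow(layout))) {
    L <- layout$length[ci]
    rank <- rep(7L, L)
    mark <- function(pos0, r) {
      pos0 <- pos0[pos0 >= 0 & pos0 < L]
      if (length(pos0)) rank[pos0 + 1L] <<- pmin(rank[pos0 + 1L], r)
    }
    for (gi in which(genes$chrom == layout$chrom[ci])) {
      g <- genes[gi, ]
      es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
      plus <- g$strand == "+"
      prom <- if (plus) seqr(g$tx_start - promoter_up, g$tx_start) else
        seqr(g$tx_end, g$tx_end + promoter_up)
      tts <- if (plus) seqr(g$tx_end, g$tx_end + tts_down) else
        seqr(g$tx_start - tts_down, g$tx_start)
      exonic <- unlist(mapply(seqr, es, ee, SIMPLIFY = FALSE))
      if (g$cds_end > g$cds_start) {
        left <- exonic[exonic < g$cds_start]
        right <- exonic[exonic >= g$cds_end]
        utr5 <- if (plus) left else right
        utr3 <- if (plus) right else left
        cexon <- exonic[exonic >= g$cds_start & exonic < g$cds_end]
      } else {
        utr5 <- utr3 <- integer(); cexon <- exonic
      }
      intron <- setdiff(seqr(g$tx_start, g$tx_end), exonic)
      mark(prom, 1L); mark(tts, 2L); mark(utr5, 3L); mark(utr3, 4L)
      mark(cexon, 5L); mark(intron, 6L)
    }
    out[[layout$chrom[ci]]] <-
      factor(FUNCTIONAL_CATEGORIES[rank], levels = FUNCTIONAL_CATEGORIES)
  }
  out
}

# --- regex IUPAC scanner oracle ----------------------------------------------

iupac_revcomp <- function(motif) {
  rev_chars <- rev(strsplit(motif, "")[[1]])
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev_chars, collapse = ""))
}

oracle_scan_positions <- function(seq, motif) {
  to_re <- function(m) {
    paste(vapply(strsplit(m, "")[[1]], function(ch) {
      opts <- Biostrings::IUPAC_CODE_MAP[[ch]]
      if (nchar(opts) == 1L) opts else paste0("[", opts, "]")
    }, ""), collapse = "")
  }
  find <- function(pat) {
    m <- gregexpr(paste0("(?=", to_re(pat), ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer() else as.integer(m) - 1L
  }
  sort(unique(c(find(motif), find(iupac_revcomp(motif)))))
}

# --- exhaustive enumeration tails -------------------------------------------

enum_binom_ge <- function(k, n, p) {
  if (k > n) return(0)
  j <- k:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}
enum_binom_le <- function(k, n, p) {
  if (k < 0) return(0)
  j <- 0:min(k, n)
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}
enum_ratio_p <- function(ca, cb, la, lb) {
  n <- ca + cb
  if (n == 0) return(1)
  q <- la / (la + lb)
  min(1, 2 * min(enum_binom_le(ca, n, q), enum_binom_ge(ca, n, q)))
}
enum_hyper_ge <- function(k, K, n, N) {
  j <- k:min(K, n)
  j <- j[j >= max(0, n - (N - K))]
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# --- O(n^2) interval oracles -------------------------------------------------

oracle_binary_overlap <- function(set_a, set_b, slack) {
  ca <- peak_centers(set_a); cb <- peak_centers(set_b)
  hit_a <- logical(nrow(set_a)); hit_b <- logical(nrow(set_b))
  for (i in seq_len(nrow(set_a)))
    for (j in seq_len(nrow(set_b)))
      if (set_a$chrom[i] == set_b$chrom[j] &&
          abs(ca[i] - cb[j]) <= slack) {
        hit_a[i] <- TRUE; hit_b[j] <- TRUE
      }
  list(common_a_count = sum(hit_a), common_b_count = sum(hit_b))
}

oracle_map_peaks <- function(peaks, genes, promoter_up = 1000) {
  n_peaks <- integer(nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    ws <- if (g$strand == "+") max(0, g$tx_start - promoter_up) else g$tx_start
    we <- if (g$strand == "+") g$tx_end else g$tx_end + promoter_up
    for (pi in seq_len(nrow(peaks)))
      if (peaks$chrom[pi] == g$chrom &&
          peaks$start[pi] < we && peaks$end[pi] > ws)
        n_peaks[gi] <- n_peaks[gi] + 1L
  }
  n_peaks
}
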