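# Seven-category functional classification of the genome and of peak
# centers, binomial enrichment against the genomic background, a
# product-of-binomials comparison of one category between two peak sets,
# and the TSS-distance histogram.
#
# Categories, in precedence order when features of different genes
# overlap: promoter (-1 kb to the TSS), tts (TTS to +1 kb), utr5, utr3,
# exon (coding exon), intron, intergenic (the remainder). Promoter/TTS
# windows are strand-aware. Non-coding transcripts (cds_start ==
# cds_end) contribute their exons to the exon category and have no UTRs.

#' Functional category labels, in precedence order
#' @export
FUNCTIONAL_CATEGORIES <- c("promoter", "tts", "utr5", "utr3",
                           "exon", "intron", "intergenic")

# raw (pre-precedence) 0-based half-open intervals per category for one
# gene, as a list of two-column matrices (start, end)
.gene_category_intervals <- function(g, promoter_up, tts_down) {
  es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
  plus <- g$strand == "+"
  clip <- function(s, e) {
    keep <- e > s
    cbind(s[keep], e[keep])
  }
  if (plus) {
    promoter <- clip(max(0, g$tx_start - promoter_up), g$tx_start)
    tts <- clip(g$tx_end, g$tx_end + tts_down)
  } else {
    promoter <- clip(g$tx_end, g$tx_end + promoter_up)
    tts <- clip(max(0, g$tx_start - tts_down), g$tx_start)
  }
  coding <- g$cds_end > g$cds_start
  isect <- function(lo, hi) clip(pmax(es, lo), pmin(ee, hi))
  if (coding) {
    left <- isect(g$tx_start, g$cds_start)   # exonic, 5' side in coords
    right <- isect(g$cds_end, g$tx_end)      # exonic, 3' side in coords
    utr5 <- if (plus) left else right
    utr3 <- if (plus) right else left
    exon <- isect(g$cds_start, g$cds_end)
  } else {
    utr5 <- utr3 <- clip(numeric(0), numeric(0))
    exon <- clip(es, ee)
  }
  # introns: transcript span minus exons (exons tile tx endpoints)
  intron <- if (length(es) > 1) clip(ee[-length(ee)], es[-1]) else
    clip(numeric(0), numeric(0))
  list(promoter = promoter, tts = tts, utr5 = utr5, utr3 = utr3,
       exon = exon, intron = intron)
}

#' Build the disjoint functional-category map of a genome
#'
#' Resolves overlapping features of all transcripts by the fixed
#' precedence promoter > tts > utr5 > utr3 > exon > intron; intergenic is
#' the complement. The same map backs both [classify_location()] and
#' [genome_category_fractions()], so the two are consistent by
#' construction.
#'
#' @param genes a [gene_annotation()]
#' @param layout a [genome_layout()]
#' @param promoter_up promoter window upstream of the TSS, bp
#' @param tts_down TTS window downstream of the TTS, bp
#' @return a `category_map`: list of disjoint `GRanges`, one per category
#' @export
category_map <- function(genes, layout, promoter_up = 1000, tts_down = 1000) {
  si <- GenomeInfoDb::Seqinfo(seqnames = layout$chrom,
                              seqlengths = layout$length)
  empty <- GenomicRanges::GRanges(seqinfo = si)
  raw <- setNames(vector("list", 6L), FUNCTIONAL_CATEGORIES[1:6])
  for (nm in names(raw)) raw[[nm]] <- list()
  for (i in seq_len(nrow(genes))) {
    iv <- .gene_category_intervals(genes[i, ], promoter_up, tts_down)
    for (nm in names(iv)) {
      m <- iv[[nm]]
      if (nrow(m) > 0)
        raw[[nm]][[length(raw[[nm]]) + 1L]] <-
          as_gr(genes$chrom[i], pmin(m[, 1], chrom_length(layout, genes$chrom[i])),
                pmin(m[, 2], chrom_length(layout, genes$chrom[i])), layout)
    }
  }
  out <- list()
  taken <- empty
  for (nm in FUNCTIONAL_CATEGORIES[1:6]) {
    gr <- if (length(raw[[nm]])) GenomicRanges::reduce(
      suppressWarnings(do.call(c, raw[[nm]]))) else empty
    out[[nm]] <- GenomicRanges::setdiff(gr, taken)
    taken <- GenomicRanges::union(taken, gr)
  }
  whole <- as_gr(layout$chrom, rep(0, nrow(layout)), layout$length, layout)
  out$intergenic <- GenomicRanges::setdiff(whole, taken)
  structure(out, class = "category_map", layout = layout,
            promoter_up = promoter_up, tts_down = tts_down)
}

#' Classify genomic positions into functional categories
#'
#' Assigns each 0-based position (typically a peak center) the single
#' category of the precedence-resolved map; positions in no gene feature
#' are intergenic.
#'
#' @param chrom chromosome names
#' @param pos 0-based positions
#' @param map a [category_map()] (or pass `genes` + `layout`)
#' @param genes,layout used to build the map when `map` is missing
#' @return factor over [FUNCTIONAL_CATEGORIES]
#' @export
classify_location <- function(chrom, pos, map = NULL, genes = NULL,
                              layout = NULL) {
  if (is.null(map)) map <- category_map(genes, layout)
  pts <- points_gr(chrom, pos, attr(map, "layout"))
  res <- factor(rep("intergenic", length(pos)),
                levels = FUNCTIONAL_CATEGORIES)
  for (nm in FUNCTIONAL_CATEGORIES[1:6]) {
    hits <- GenomicRanges::findOverlaps(pts, map[[nm]])
    res[unique(S4Vectors::queryHits(hits))] <- nm
  }
  res
}

#' Genome-wide base-pair fractions of the functional categories
#'
#' @param genes a [gene_annotation()]
#' @param layout a [genome_layout()]
#' @param map optional precomputed [category_map()]
#' @return named numeric vector over the 7 categories, summing to 1
#' @export
genome_category_fractions <- function(genes, layout, map = NULL) {
  if (is.null(map)) map <- category_map(genes, layout)
  bp <- vapply(map[FUNCTIONAL_CATEGORIES],
               function(gr) sum(as.numeric(GenomicRanges::width(gr))), 0)
  bp / genome_size(attr(map, "layout"))
}

#' One-sided exact binomial category test
#'
#' Tail probability for observing `k` of `n_total` peaks in a category
#' whose genomic background fraction is `p0`.
#'
#' @param k peaks in the category
#' @param n_total total peaks
#' @param p0 background fraction, strictly inside (0, 1)
#' @param side `"greater"` (enrichment) or `"less"` (depletion)
#' @return exact one-sided p-value
#' @export
category_binomial_test <- function(k, n_total, p0,
                                   side = c("greater", "less")) {
  side <- match.arg(side)
  stop_if(any(k < 0 | k > n_total), "k must be in [0, n_total]")
  stop_if(any(p0 <= 0 | p0 >= 1), "p0 must be strictly inside (0, 1)")
  if (side == "greater") stats::pbinom(k - 1, n_total, p0, lower.tail = FALSE)
  else stats::pbinom(k, n_total, p0)
}

#' Functional-category enrichment table for a peak set
#'
#' Peak centers are classified, per-category fractions are compared to
#' the genomic background, and a one-sided binomial p-value is computed
#' in the direction of the observed deviation.
#'
#' @param peaks a [peak_set()]
#' @param genes a [gene_annotation()]
#' @param layout a [genome_layout()]
#' @param map optional precomputed [category_map()]
#' @return data frame: category, n_peaks, peak_fraction, genome_fraction,
#'   fold, side, p_value
#' @export
category_enrichment_table <- function(peaks, genes, layout, map = NULL) {
  stop_if(nrow(peaks) == 0L, "empty peak set")
  if (is.null(map)) map <- category_map(genes, layout)
  cats <- classify_location(peaks$chrom, peak_centers(peaks), map)
  n <- nrow(peaks)
  k <- as.integer(table(cats))
  genome_fr <- genome_category_fractions(genes, layout, map)
  peak_fr <- k / n
  fold <- ifelse(genome_fr > 0, peak_fr / genome_fr, NA_real_)
  side <- ifelse(peak_fr >= genome_fr, "greater", "less")
  p <- vapply(seq_along(k), function(i) {
    if (genome_fr[i] <= 0 || genome_fr[i] >= 1) return(NA_real_)
    category_binomial_test(k[i], n, genome_fr[i], side[i])
  }, 0)
  data.frame(category = FUNCTIONAL_CATEGORIES, n_peaks = k,
             peak_fraction = peak_fr, genome_fraction = unname(genome_fr),
             fold = unname(fold), side = side, p_value = p,
             stringsAsFactors = FALSE)
}

#' Product-of-binomials comparison of one category between two peak sets
#'
#' Under the null that both sets are one population, the pooled category
#' frequency is `f = (m_prime + n_prime) / (m + n)`. The p-value is the
#' product of the two one-sided binomial tails of each set's category
#' count against `f`, each tail taken in the direction of that set's
#' observed deviation, capped at 1.
#'
#' @param m,n total peak counts of the two sets
#' @param m_prime,n_prime peaks of each set in the category
#' @return list: `f`, per-set tails `p_m`, `p_n`, sides, and the combined
#'   `p_value`
#' @export
compare_category_between_sets <- function(m, n, m_prime, n_prime) {
  stop_if(m + n == 0, "both sets empty")
  stop_if(m_prime < 0 || m_prime > m || n_prime < 0 || n_prime > n,
          "category counts must not exceed set totals")
  f <- (m_prime + n_prime) / (m + n)
  tail_p <- function(k, size) {
    if (f <= 0 || f >= 1) return(list(p = 1, side = "greater"))
    if (k / size >= f)
      list(p = stats::pbinom(k - 1, size, f, lower.tail = FALSE),
           side = "greater")
    else list(p = stats::pbinom(k, size, f), side = "less")
  }
  tm <- tail_p(m_prime, m)
  tn <- tail_p(n_prime, n)
  list(f = f, p_m = tm$p, side_m = tm$side, p_n = tn$p, side_n = tn$side,
       p_value = min(1, tm$p * tn$p))
}

#' Category comparison table between two peak sets
#'
#' Applies [compare_category_between_sets()] to every functional category.
#'
#' @param cats_a,cats_b category factors (from [classify_location()]) of
#'   the two sets' peak centers
#' @return data frame: category, m, m_prime, n, n_prime, f, p_value
#' @export
compare_categories <- function(cats_a, cats_b) {
  m <- length(cats_a); n <- length(cats_b)
  ka <- table(factor(cats_a, levels = FUNCTIONAL_CATEGORIES))
  kb <- table(factor(cats_b, levels = FUNCTIONAL_CATEGORIES))
  rows <- lapply(FUNCTIONAL_CATEGORIES, function(cc) {
    r <- compare_category_between_sets(m, n, as.integer(ka[[cc]]),
                                       as.integer(kb[[cc]]))
    data.frame(category = cc, m = m, m_prime = as.integer(ka[[cc]]),
               n = n, n_prime = as.integer(kb[[cc]]),
               f = r$f, p_value = r$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Histogram of peak distances to the nearest TSS
#'
#' Each peak contributes once, at its signed strand-aware distance from
#' the nearest transcription start site (negative = upstream of the TSS).
#' Peaks beyond `range` are excluded; bins are `[lo, lo + bin)`.
#'
#' @param peaks a [peak_set()]
#' @param genes a [gene_annotation()]
#' @param bin bin width in bp (default 500)
#' @param range half-width of the histogram in bp
#' @return data frame: bin_start, bin_end, count; the signed distances
#'   are attached as attribute `distances`
#' @export
tss_distance_histogram <- function(peaks, genes, bin = 500, range = 10000) {
  stop_if(bin <= 0, "bin must be positive")
  stop_if(nrow(genes) == 0L, "no genes in annotation")
  tss_pos <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  centers <- peak_centers(peaks)
  dist <- rep(NA_real_, nrow(peaks))
  for (cn in unique(peaks$chrom)) {
    gi <- which(genes$chrom == cn)
    if (length(gi) == 0L) next
    ord <- order(tss_pos[gi])
    tp <- tss_pos[gi][ord]
    tstr <- genes$strand[gi][ord]
    pi <- which(peaks$chrom == cn)
    idx <- findInterval(centers[pi], tp)
    for (j in seq_along(pi)) {
      cand <- unique(pmax(1L, pmin(length(tp), c(idx[j], idx[j] + 1L))))
      d_abs <- abs(centers[pi[j]] - tp[cand])
      best <- cand[which.min(d_abs)]
      d <- centers[pi[j]] - tp[best]
      dist[pi[j]] <- if (tstr[best] == "+") d else -d
    }
  }
  breaks <- seq(-range, range, by = bin)
  keep <- !is.na(dist) & dist >= -range & dist < range
  bin_idx <- findInterval(dist[keep], breaks)
  counts <- tabulate(bin_idx, nbins = length(breaks) - 1L)
  structure(data.frame(bin_start = breaks[-length(breaks)],
                       bin_end = breaks[-1], count = counts),
            distances = dist)
}
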