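# Peak-to-gene linkage and gene-list occupancy summaries: which genes'
# bodies or promoters overlap peaks, how many binding sites associate
# with a gene list, how many of those sites carry a motif, and a
# Monte-Carlo random-peak null (z-score p-value) for the linkage.

#' Map peaks to genes by body-or-promoter overlap
#'
#' A peak links a gene when its interval intersects the gene body
#' extended upstream by `promoter_up` bp on the transcribed strand. A
#' peak may link several genes.
#'
#' @param peaks a [peak_set()]
#' @param genes a [gene_annotation()]
#' @param promoter_up upstream promoter extension in bp (default 1000,
#'   consistent with the functional-category promoter window)
#' @return data frame, one row per gene: gene_id, n_peaks, has_motif_peak
#'   placeholder FALSE (filled by [summarize_gene_list()] when motif
#'   flags are supplied) and a list column `peak_idx` of peak indices
#' @export
map_peaks_to_genes <- function(peaks, genes, promoter_up = 1000) {
  win_start <- ifelse(genes$strand == "+",
                      pmax(0, genes$tx_start - promoter_up), genes$tx_start)
  win_end <- ifelse(genes$strand == "+",
                    genes$tx_end, genes$tx_end + promoter_up)
  peak_idx <- rep(list(integer()), nrow(genes))
  if (nrow(peaks) > 0 && nrow(genes) > 0) {
    gene_gr <- as_gr(genes$chrom, win_start, win_end)
    peak_gr <- as_gr(peaks$chrom, peaks$start, peaks$end)
    ov <- GenomicRanges::findOverlaps(peak_gr, gene_gr)
    sp <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
    peak_idx[as.integer(names(sp))] <- unname(sp)
  }
  data.frame(gene_id = genes$gene_id,
             n_peaks = lengths(peak_idx),
             peak_idx = I(peak_idx),
             stringsAsFactors = FALSE)
}

#' Summarize peak occupancy of a gene list
#'
#' Reproduces the layout of a transcription-profiling correlation table:
#' listed genes, genes with at least one peak in body or promoter (+
#' nearest-integer %), distinct binding sites linked to listed genes (+ %
#' of all peaks, one decimal), and motif-bearing linked sites (+ % of
#' linked sites, nearest integer).
#'
#' @param glist a [gene_list()]
#' @param occupancy output of [map_peaks_to_genes()] for the full
#'   annotation
#' @param peaks the [peak_set()] the occupancy was computed from
#' @param motif_flags optional logical vector over `peaks` (from
#'   [peaks_with_motif()])
#' @return one-row data frame: name, n_genes, n_genes_occupied,
#'   pct_genes_occupied, n_sites, pct_sites, n_motif_sites,
#'   pct_motif_sites, n_motif_genes
#' @export
summarize_gene_list <- function(glist, occupancy, peaks, motif_flags = NULL) {
  ids <- setdiff(as.character(glist), attr(glist, "unresolved"))
  stop_if(length(ids) == 0L, "empty gene list after resolving ids")
  rows <- occupancy[occupancy$gene_id %in% ids, , drop = FALSE]
  n_genes <- length(ids)
  occupied <- rows$n_peaks >= 1
  n_occ <- sum(occupied)
  site_idx <- sort(unique(unlist(rows$peak_idx)))
  n_sites <- length(site_idx)
  n_motif_sites <- n_motif_genes <- NA_integer_
  pct_motif_sites <- NA_real_
  if (!is.null(motif_flags)) {
    stop_if(length(motif_flags) != nrow(peaks),
            "motif_flags length must match the peak set")
    n_motif_sites <- sum(motif_flags[site_idx])
    n_motif_genes <- sum(vapply(rows$peak_idx, function(ix)
      length(ix) > 0 && any(motif_flags[ix]), TRUE))
    pct_motif_sites <- if (n_sites > 0)
      round_half_up(100 * n_motif_sites / n_sites) else 0
  }
  data.frame(
    name = attr(glist, "name"),
    n_genes = n_genes,
    n_genes_occupied = n_occ,
    pct_genes_occupied = round_half_up(100 * n_occ / n_genes),
    n_sites = n_sites,
    pct_sites = round_half_up(100 * n_sites / nrow(peaks), 1),
    n_motif_sites = n_motif_sites,
    pct_motif_sites = pct_motif_sites,
    n_motif_genes = n_motif_genes,
    stringsAsFactors = FALSE)
}

#' Monte-Carlo random-peak null for a peak-set statistic
#'
#' Re-places the peaks of a set uniformly at random across the genome
#' (widths preserved, chromosomes weighted by length, intervals kept
#' inside chromosome bounds), recomputes a statistic on each replicate,
#' and reports the z-score of the observed value against the null with
#' its upper-tail normal p-value (and the empirical rank p-value).
#'
#' @param stat_fn function taking a [peak_set()] and returning one number
#' @param peaks the observed [peak_set()]
#' @param layout a [genome_layout()]
#' @param n_reps number of replicates (>= 30)
#' @param seed RNG seed; the null is fully reproducible
#' @return list: observed, null_mean, null_sd, z, p_value (normal upper
#'   tail), p_empirical, n_reps, seed
#' @export
random_peak_null <- function(stat_fn, peaks, layout, n_reps = 100,
                             seed = 1) {
  stop_if(n_reps < 30, "n_reps must be at least 30")
  observed <- stat_fn(peaks)
  stop_if(!is.finite(observed), "statistic undefined on the observed set")
  widths <- peaks$end - peaks$start
  set.seed(seed)
  null <- vapply(seq_len(n_reps), function(r) {
    ci <- sample.int(nrow(layout), length(widths), replace = TRUE,
                     prob = layout$length)
    max_start <- pmax(0, layout$length[ci] - widths)
    start <- floor(runif(length(widths)) * (max_start + 1))
    rp <- data.frame(chrom = layout$chrom[ci], start = start,
                     end = start + widths,
                     summit = start + floor(widths / 2),
                     rpm = peaks$rpm, stringsAsFactors = FALSE)
    v <- stat_fn(peak_set(rp, name = "random", layout = layout))
    stop_if(!is.finite(v), "statistic undefined on a null replicate")
    v
  }, 0)
  null_sd <- stats::sd(null)
  stop_if(null_sd == 0, "degenerate null: statistic is constant")
  z <- (observed - mean(null)) / null_sd
  list(observed = observed, null_mean = mean(null), null_sd = null_sd,
       z = z, p_value = stats::pnorm(z, lower.tail = FALSE),
       p_empirical = (1 + sum(null >= observed)) / (n_reps + 1),
       n_reps = n_reps, seed = seed)
}

#' Full linkage analysis of a gene list
#'
#' Convenience wrapper: occupancy summary plus the Monte-Carlo z-score
#' p-value for the number of linked binding sites and the hypergeometric
#' motif p-value against the whole peak population.
#'
#' @param glist a [gene_list()]
#' @param peaks a [peak_set()]
#' @param genes a [gene_annotation()]
#' @param layout a [genome_layout()]
#' @param motif_flags optional logical vector over `peaks`
#' @param n_reps Monte-Carlo replicates
#' @param seed RNG seed for the null
#' @param promoter_up upstream promoter extension in bp
#' @return one-row data frame: the [summarize_gene_list()] columns plus
#'   `mc_z`, `mc_p` and (with motif flags) `hypergeom_motif_p`
#' @export
analyze_gene_list <- function(glist, peaks, genes, layout,
                              motif_flags = NULL, n_reps = 100, seed = 1,
                              promoter_up = 1000) {
  occupancy <- map_peaks_to_genes(peaks, genes, promoter_up)
  res <- summarize_gene_list(glist, occupancy, peaks, motif_flags)
  ids <- setdiff(as.character(glist), attr(glist, "unresolved"))
  n_sites_stat <- function(ps) {
    occ <- map_peaks_to_genes(ps, genes, promoter_up)
    rows <- occ[occ$gene_id %in% ids, , drop = FALSE]
    length(unique(unlist(rows$peak_idx)))
  }
  mc <- random_peak_null(n_sites_stat, peaks, layout, n_reps, seed)
  res$mc_z <- mc$z
  res$mc_p <- mc$p_value
  if (!is.null(motif_flags)) {
    res$hypergeom_motif_p <- motif_hypergeom(
      k = res$n_motif_sites, n = res$n_sites,
      K = sum(motif_flags), N = nrow(peaks))
  }
  res
}
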