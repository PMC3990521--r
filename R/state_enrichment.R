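# Chromatin-state enrichment of peak sets against a dense genome
# segmentation. Peaks are assigned to states by the location of their
# centers; enrichment is the fraction of peak centers in a state divided
# by the state's genome bp fraction, with a one-sided binomial p-value in
# the direction of the deviation. Group rows (e.g. the two transcribing
# promoter states, or all four enhancer states) pool member counts and
# genome fractions.

#' Assign peaks to chromatin states by their centers
#'
#' @param peaks a [peak_set()]
#' @param segmentation a [state_segmentation()]
#' @return character vector of state labels, one per peak
#' @export
assign_state <- function(peaks, segmentation) {
  centers <- peak_centers(peaks)
  out <- character(nrow(peaks))
  for (cn in unique(peaks$chrom)) {
    seg <- segmentation[segmentation$chrom == cn, ]
    stop_if(nrow(seg) == 0L, "segmentation does not cover chromosome ", cn)
    i <- which(peaks$chrom == cn)
    stop_if(any(centers[i] < seg$start[1] | centers[i] >= seg$end[nrow(seg)]),
            "peak center outside segmentation on ", cn)
    # segments are sorted and tile the chromosome; half-open intervals, so
    # a center equal to a boundary belongs to the following segment
    out[i] <- seg$state[findInterval(centers[i], seg$start)]
  }
  out
}

#' Filter a peak set to its top peaks by intensity
#'
#' Retains peaks with rpm strictly above `rpm_min`, preserving order.
#'
#' @param peaks a [peak_set()]
#' @param rpm_min intensity threshold (default 1: "rpm above 1")
#' @return a [peak_set()]
#' @export
filter_top_peaks <- function(peaks, rpm_min = 1) {
  kept <- peaks[peaks$rpm > rpm_min, , drop = FALSE]
  rownames(kept) <- NULL
  peak_set(kept, name = paste0("top_", attr(peaks, "name")),
           total_mapped_reads = attr(peaks, "total_mapped_reads"))
}

#' Chromatin-state enrichment table
#'
#' @param peaks a [peak_set()]
#' @param segmentation a [state_segmentation()]
#' @param groups optional named list of label vectors; each entry adds a
#'   pooled row (e.g. `list("all enhancer" = c("4","5","6","7"))`)
#' @return data frame: state, n_peaks, peak_fraction, genome_fraction,
#'   fold, side, p_value; group rows flagged by `is_group`
#' @export
state_enrichment_table <- function(peaks, segmentation, groups = NULL) {
  stop_if(nrow(peaks) == 0L, "empty peak set")
  labels <- attr(segmentation, "labels")
  states <- assign_state(peaks, segmentation)
  n <- nrow(peaks)
  counts <- table(factor(states, levels = labels))
  genome_fr <- state_fractions(segmentation)
  one_row <- function(label, k, gfr, is_group) {
    pfr <- k / n
    fold <- if (gfr > 0) pfr / gfr else NA_real_
    side <- if (pfr >= gfr) "greater" else "less"
    p <- if (gfr > 0 && gfr < 1)
      category_binomial_test(k, n, gfr, side) else if (gfr >= 1) 1 else NA_real_
    data.frame(state = label, n_peaks = k, peak_fraction = pfr,
               genome_fraction = gfr, fold = fold, side = side,
               p_value = p, is_group = is_group, stringsAsFactors = FALSE)
  }
  rows <- lapply(labels, function(l)
    one_row(l, as.integer(counts[[l]]), unname(genome_fr[[l]]), FALSE))
  if (!is.null(groups)) {
    for (gname in names(groups)) {
      members <- groups[[gname]]
      stop_if(!all(members %in% labels),
              "group '", gname, "' contains unknown labels")
      rows[[length(rows) + 1L]] <- one_row(
        gname, sum(as.integer(counts[members])),
        sum(genome_fr[members]), TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
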