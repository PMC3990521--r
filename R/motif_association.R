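# IUPAC-degenerate motif scanning and hypergeometric association of
# motifs with peak subsets. The built-in motifs are the TPA-response
# element TGASTCA (S = G or C; its reverse complement set equals itself)
# and the AP-1-like variant TGAATCA.

#' TPA-response element (AP-1 / c-Jun binding motif)
#' @export
TRE_MOTIF <- "TGASTCA"

#' AP-1-like motif variant
#' @export
AP1_LIKE_MOTIF <- "TGAATCA"

.IUPAC_CODES <- names(Biostrings::IUPAC_CODE_MAP)

#' Scan sequences for an IUPAC motif
#'
#' Reports all forward-strand matches plus reverse-complement matches at
#' forward coordinates. Ambiguity codes in the motif are expanded; an `N`
#' in the sequence never matches. Positions found on both strands
#' (palindromic patterns) are deduplicated per (chrom, start).
#'
#' @param sequences named character vector of chromosome sequences
#' @param motif IUPAC pattern string
#' @param both_strands also scan the reverse complement (default TRUE)
#' @return data frame of hits: chrom, start (0-based), strand, match
#' @export
scan_motif <- function(sequences, motif, both_strands = TRUE) {
  stop_if(!nzchar(motif), "empty motif")
  chars <- strsplit(toupper(motif), "")[[1]]
  stop_if(!all(chars %in% .IUPAC_CODES),
          "invalid IUPAC character in motif: ",
          paste(unique(chars[!chars %in% .IUPAC_CODES]), collapse = ", "))
  motif <- toupper(motif)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  hits <- list()
  for (cn in names(sequences)) {
    subj <- Biostrings::DNAString(sequences[[cn]])
    # fixed = "subject": ambiguity codes in the pattern are interpreted,
    # letters in the subject are literal (so N never matches A/C/G/T codes)
    fwd <- Biostrings::matchPattern(motif, subj, fixed = "subject")
    h <- data.frame(chrom = rep(cn, length(fwd)),
                    start = IRanges::start(fwd) - 1L,
                    strand = rep("+", length(fwd)),
                    match = as.character(fwd),
                    stringsAsFactors = FALSE)
    if (both_strands) {
      rev <- Biostrings::matchPattern(rc, subj, fixed = "subject")
      h <- rbind(h, data.frame(chrom = rep(cn, length(rev)),
                               start = IRanges::start(rev) - 1L,
                               strand = rep("-", length(rev)),
                               match = as.character(rev),
                               stringsAsFactors = FALSE))
    }
    # dedup palindromic double counts: one hit per position
    h <- h[order(h$start, h$strand), , drop = FALSE]
    h <- h[!duplicated(h$start), , drop = FALSE]
    hits[[cn]] <- h
  }
  out <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      strand = character(), match = character())
  out
}

#' Flag peaks containing a motif
#'
#' A peak is flagged when at least one motif match lies entirely within
#' `[start - flank, end + flank)`.
#'
#' @param peaks a [peak_set()]
#' @param sequences named character vector of chromosome sequences
#' @param motif IUPAC pattern string
#' @param flank extra bp on each side of the peak (default 0: the motif
#'   must lie within the called peak)
#' @return list: `flags` (logical per peak), `subset` (the flagged
#'   [peak_set()]), `hits` (the full genome scan)
#' @export
peaks_with_motif <- function(peaks, sequences, motif, flank = 0) {
  stop_if(!all(unique(peaks$chrom) %in% names(sequences)),
          "sequences missing peak chromosome(s)")
  len <- nchar(sequences[peaks$chrom])
  stop_if(any(peaks$end > len), "peak beyond sequence end")
  hits <- scan_motif(sequences, motif, both_strands = TRUE)
  w <- nchar(motif)
  flags <- logical(nrow(peaks))
  if (nrow(hits) > 0 && nrow(peaks) > 0) {
    hit_gr <- as_gr(hits$chrom, hits$start, hits$start + w)
    win_gr <- as_gr(peaks$chrom, pmax(0, peaks$start - flank),
                    peaks$end + flank)
    ov <- GenomicRanges::findOverlaps(hit_gr, win_gr, type = "within")
    flags[unique(S4Vectors::subjectHits(ov))] <- TRUE
  }
  subset <- peaks[flags, , drop = FALSE]
  rownames(subset) <- NULL
  subset <- peak_set(subset, name = paste0(attr(peaks, "name"), "_", motif),
                     total_mapped_reads = attr(peaks, "total_mapped_reads"))
  list(flags = flags, subset = subset, hits = hits)
}

#' Hypergeometric motif-association test
#'
#' Tests whether motif-bearing peaks are over-represented in a peak
#' subset relative to the whole population of peaks (upper tail).
#'
#' @param k motif-bearing peaks in the subset
#' @param n subset size
#' @param K motif-bearing peaks in the population
#' @param N population size
#' @return exact upper-tail p-value
#' @export
motif_hypergeom <- function(k, n, K, N) {
  hypergeom_overlap_test(k, K, n, N)
}
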