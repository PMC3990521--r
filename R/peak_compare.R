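# Unique/common classification between two peak sets, binary (+/- slack)
# overlap between peak sets, and the exact tests behind both.
#
# The classification rule: for every peak of set A, signal intensities of
# both libraries are compared over a window (default 200 bp) around the
# peak center. If the rpm ratio is >= fold_threshold (default 4) AND the
# count-ratio p-value is <= alpha (default 1e-4), the peak is unique to A;
# otherwise common. Symmetric for B, regardless of whether the other
# library called a peak there.

#' Classification parameters for unique/common peak calling
#'
#' @param window comparison window in bp, centered on the peak center
#' @param fold_threshold minimum rpm ratio for a unique call
#' @param alpha maximum count-ratio p-value for a unique call
#' @return a `classification_params` list
#' @export
classification_params <- function(window = 200, fold_threshold = 4,
                                  alpha = 1e-4) {
  stop_if(window <= 0, "window must be positive")
  stop_if(fold_threshold <= 1, "fold_threshold must exceed 1")
  stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  structure(list(window = window, fold_threshold = fold_threshold,
                 alpha = alpha), class = "classification_params")
}

# vectorised window read count at 0-based centers on one chromosome,
# window [center - w/2, center + w/2) clipped to the chromosome
.window_counts <- function(track, chrom, centers, window) {
  cs <- track$cumulative[[chrom]]
  stop_if(is.null(cs), "track has no chromosome ", chrom)
  len <- length(cs)
  stop_if(any(centers < 0 | centers >= len),
          "window center outside chromosome ", chrom)
  half <- window / 2
  lo <- pmax(0, floor(centers - half))    # 0-based inclusive
  hi <- pmin(len, floor(centers + half))  # 0-based exclusive
  right <- cs[pmax(hi, 1L)]
  right[hi < 1L] <- 0
  left <- ifelse(lo >= 1L, cs[pmax(lo, 1L)], 0)
  as.numeric(right - left)
}

#' Read count and rpm in a window around a position
#'
#' Counts read starts in `[center - window/2, center + window/2)`, clipped
#' to the chromosome, and scales by the track's library size.
#'
#' @param track a [signal_track()]
#' @param chrom chromosome name
#' @param center 0-based position
#' @param window window width in bp
#' @return list with elements `count` and `rpm`
#' @export
window_counts <- function(track, chrom, center, window = 200) {
  count <- .window_counts(track, chrom, center, window)
  list(count = count, rpm = 1e6 * count / track$library_size)
}

#' Conditional binomial test for a two-library count ratio
#'
#' Under the null of equal rpm, given `n = count_a + count_b`, `count_a`
#' is Binomial(n, q) with `q = lib_a / (lib_a + lib_b)`. The two-sided
#' p-value doubles the smaller one-sided tail, capped at 1. `n = 0`
#' returns 1 (no evidence).
#'
#' @param count_a,count_b non-negative window read counts
#' @param lib_a,lib_b positive library sizes
#' @return p-value vector in \[0, 1\]
#' @export
count_ratio_test <- function(count_a, count_b, lib_a, lib_b) {
  stop_if(any(count_a < 0) || any(count_b < 0), "counts must be non-negative")
  stop_if(any(lib_a <= 0) || any(lib_b <= 0), "library sizes must be positive")
  n <- count_a + count_b
  q <- lib_a / (lib_a + lib_b)
  lower <- stats::pbinom(count_a, n, q)
  upper <- stats::pbinom(count_a - 1, n, q, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[n == 0] <- 1
  p
}

# one direction of the classifier: label each peak of `set_self` against
# the two tracks; fold = rpm_self / rpm_other with both counts floored at
# a 0.5-read pseudo-count so zero windows give finite folds
.classify_one <- function(set_self, track_self, track_other, params,
                          label_unique) {
  centers <- peak_centers(set_self)
  n <- nrow(set_self)
  count_self <- count_other <- numeric(n)
  for (cn in unique(set_self$chrom)) {
    i <- which(set_self$chrom == cn)
    count_self[i] <- .window_counts(track_self, cn, centers[i], params$window)
    count_other[i] <- .window_counts(track_other, cn, centers[i], params$window)
  }
  rpm_self <- 1e6 * pmax(count_self, 0.5) / track_self$library_size
  rpm_other <- 1e6 * pmax(count_other, 0.5) / track_other$library_size
  fold <- rpm_self / rpm_other
  p <- count_ratio_test(count_self, count_other,
                        track_self$library_size, track_other$library_size)
  label <- ifelse(fold >= params$fold_threshold & p <= params$alpha,
                  label_unique, "common")
  data.frame(peak = seq_len(n), chrom = set_self$chrom,
             center = centers, count_self = count_self,
             count_other = count_other, fold = fold, p_value = p,
             label = label, stringsAsFactors = FALSE)
}

#' Classify two peak sets into unique and common occupancy
#'
#' Every peak of each set is compared against the other library's signal
#' at its own center, regardless of whether the other set called a peak
#' there. A peak is unique when its rpm ratio reaches
#' `params$fold_threshold` and the count-ratio p-value is at most
#' `params$alpha`; the rest are common.
#'
#' @param set_a,set_b [peak_set()]s on the same layout
#' @param track_a,track_b matching [signal_track()]s
#' @param params a [classification_params()]
#' @return list with per-peak label tables `labels_a`, `labels_b`
#'   (columns: peak, chrom, center, counts, fold, p_value, label) and a
#'   `summary` data frame (set, total, unique, common)
#' @export
classify_peaks <- function(set_a, set_b, track_a, track_b,
                           params = classification_params()) {
  la <- .classify_one(set_a, track_a, track_b, params, "unique_to_a")
  lb <- .classify_one(set_b, track_b, track_a, params, "unique_to_b")
  summary <- data.frame(
    set = c(attr(set_a, "name"), attr(set_b, "name")),
    total = c(nrow(la), nrow(lb)),
    unique = c(sum(la$label == "unique_to_a"), sum(lb$label == "unique_to_b")),
    common = c(sum(la$label == "common"), sum(lb$label == "common")),
    stringsAsFactors = FALSE)
  list(labels_a = la, labels_b = lb, summary = summary)
}

#' Binary peak-set overlap by center distance
#'
#' Two peaks are common when their centers lie within `slack` bp of each
#' other on the same chromosome. Counts report peaks with at least one
#' partner, each peak counted once regardless of multi-pairing.
#'
#' @param set_a,set_b [peak_set()]s
#' @param slack maximum center distance in bp (default 100)
#' @return list with `pairs` (data frame: index_a, index_b, chrom,
#'   center_a, center_b, distance), `common_a_count`, `common_b_count`
#' @export
binary_overlap <- function(set_a, set_b, slack = 100) {
  ca <- peak_centers(set_a)
  cb <- peak_centers(set_b)
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) {
    return(list(pairs = data.frame(index_a = integer(), index_b = integer(),
                                   chrom = character(), center_a = integer(),
                                   center_b = integer(), distance = integer()),
                common_a_count = 0L, common_b_count = 0L))
  }
  gra <- GenomicRanges::GRanges(set_a$chrom, IRanges::IRanges(ca + 1L, ca + 1L))
  # expand B centers by slack on both sides: overlap <=> |ca - cb| <= slack
  grb <- GenomicRanges::GRanges(set_b$chrom,
                                IRanges::IRanges(cb + 1L - slack, cb + 1L + slack))
  hits <- GenomicRanges::findOverlaps(gra, grb)
  ia <- S4Vectors::queryHits(hits); ib <- S4Vectors::subjectHits(hits)
  pairs <- data.frame(index_a = ia, index_b = ib,
                      chrom = set_a$chrom[ia],
                      center_a = ca[ia], center_b = cb[ib],
                      distance = abs(ca[ia] - cb[ib]),
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       common_a_count = length(unique(ia)),
       common_b_count = length(unique(ib)))
}

#' Percentage of a peak set involved in an overlap
#'
#' @param common number of peaks with a partner
#' @param total set size (> 0)
#' @param digits decimal places of the reported percentage (0 for
#'   nearest-integer, 1 for one-decimal reporting)
#' @return `100 * common / total`, rounded half up to `digits`
#' @export
overlap_summary <- function(common, total, digits = 0) {
  stop_if(any(total <= 0), "total must be positive")
  stop_if(any(common < 0 | common > total), "common must be in [0, total]")
  round_half_up(100 * common / total, digits)
}

#' Upper-tail hypergeometric overlap test
#'
#' P(X >= k) where X ~ Hypergeometric(N, K, n): drawing `n` items from a
#' population of `N` containing `K` successes.
#'
#' @param k successes drawn
#' @param K successes in the population
#' @param n draws
#' @param N population size
#' @return exact upper-tail p-value
#' @export
hypergeom_overlap_test <- function(k, K, n, N) {
  stop_if(any(K > N) || any(n > N), "K and n must not exceed N")
  stop_if(any(k > pmin(K, n)) || any(k < 0), "k must be in [0, min(K, n)]")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
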