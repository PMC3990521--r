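# qPCR arithmetic: relative expression by the ddCt method (amplification
# efficiency fixed at 2, the classic assumption) and MNase-qPCR
# nucleosome-occupancy enrichment normalized to naked genomic DNA.

#' Fold change by the delta-delta-Ct method
#'
#' `fold = 2^-[(ct_target_sample - ct_ref_sample) -
#' (ct_target_control - ct_ref_control)]`: target expression normalized
#' to a reference gene in each condition, then sample over control.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the sample
#' @param ct_target_control,ct_ref_control Ct values in the control
#' @return positive fold change (1 = no change; each cycle halves/doubles)
#' @export
ddct_fold <- function(ct_target_sample, ct_ref_sample,
                      ct_target_control, ct_ref_control) {
  cts <- c(ct_target_sample, ct_ref_sample,
           ct_target_control, ct_ref_control)
  stop_if(any(!is.finite(cts)), "Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' MNase-qPCR enrichment normalized to naked genomic DNA
#'
#' Per replicate, `enrichment = 2^-(ct_chromatin - ct_naked)`: amplicons
#' protected by nucleosomes survive MNase digestion and amplify earlier
#' than in the naked-DNA control. Reports mean and SEM over replicates
#' (SEM is `NA` with fewer than 2 replicates).
#'
#' @param ct_chromatin Ct values from MNase-digested chromatin, one per
#'   replicate
#' @param ct_naked paired Ct values from naked genomic DNA
#' @return list: `enrichment` per replicate, `mean`, `sem`, `n`
#' @export
mnase_enrichment <- function(ct_chromatin, ct_naked) {
  stop_if(length(ct_chromatin) != length(ct_naked),
          "chromatin and naked Ct vectors must be paired")
  stop_if(any(!is.finite(c(ct_chromatin, ct_naked))),
          "Ct values must be finite")
  enr <- 2^(-(ct_chromatin - ct_naked))
  n <- length(enr)
  sem <- if (n >= 2) stats::sd(enr) / sqrt(n) else NA_real_
  list(enrichment = enr, mean = mean(enr), sem = sem, n = n)
}
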