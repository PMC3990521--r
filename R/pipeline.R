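# Orchestration and report rendering: drive every analysis stage over a
# dataset (simulated or read from files), write deterministic TSV
# outputs, and format summary tables the way occupancy studies print
# them ("6,398 (36%)").

#' Format a count with its percentage of a total
#'
#' @param count integer count(s)
#' @param total denominator
#' @param digits decimal places of the percentage (0 = nearest integer,
#'   rounded half up, so 35.99 renders as 36)
#' @return character like `"6,398 (36%)"`
#' @export
format_count_pct <- function(count, total, digits = 0) {
  stop_if(any(total <= 0), "total must be positive")
  pct <- round_half_up(100 * count / total, digits)
  sprintf("%s (%s%%)",
          formatC(count, format = "d", big.mark = ","),
          formatC(pct, format = "f", digits = digits))
}

#' Render an occupancy summary table
#'
#' One row per peak set with unique/common counts and percentages in the
#' layout of a two-experiment occupancy comparison.
#'
#' @param classification output of [classify_peaks()]
#' @return data frame: set, total_peaks, unique_peaks, common_peaks
#'   (formatted)
#' @export
render_occupancy_summary <- function(classification) {
  s <- classification$summary
  data.frame(
    set = s$set,
    total_peaks = formatC(s$total, format = "d", big.mark = ","),
    unique_peaks = format_count_pct(s$unique, s$total),
    common_peaks = format_count_pct(s$common, s$total),
    stringsAsFactors = FALSE)
}

#' Render a binary-overlap summary table
#'
#' @param overlap output of [binary_overlap()]
#' @param total_a,total_b sizes of the two sets
#' @param name_a,name_b set names
#' @return data frame with common counts and cross percentages (one
#'   decimal)
#' @export
render_overlap_summary <- function(overlap, total_a, total_b,
                                   name_a = "A", name_b = "B") {
  data.frame(
    set = c(name_a, name_b),
    common_sites = c(overlap$common_a_count, overlap$common_b_count),
    pct_of_own_set = c(overlap_summary(overlap$common_a_count, total_a, 1),
                       overlap_summary(overlap$common_b_count, total_b, 1)),
    stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline over a dataset
#'
#' Executes classification, functional annotation, state enrichment,
#' motif association and gene-list linkage over a (typically simulated)
#' dataset, writes every stage's TSV output plus a manifest with
#' parameters and file checksums, and returns all results. Re-running
#' with the same config yields byte-identical outputs.
#'
#' @param dataset output of [simulate_dataset()] (or an equivalently
#'   shaped list read from files)
#' @param outdir output directory; `NULL` skips writing
#' @param params a [classification_params()]
#' @param mc_reps Monte-Carlo replicates for the gene-list null
#' @return list of stage results: classification, categories (per set),
#'   category_comparison, states, motif, link, paths
#' @export
run_pipeline <- function(dataset, outdir = NULL,
                         params = classification_params(),
                         mc_reps = 100) {
  layout <- dataset$layout
  cmap <- category_map(dataset$genes, layout)
  classification <- classify_peaks(dataset$set_a, dataset$set_b,
                                   dataset$track_a, dataset$track_b, params)
  cats_a <- classify_location(dataset$set_a$chrom,
                              peak_centers(dataset$set_a), cmap)
  cats_b <- classify_location(dataset$set_b$chrom,
                              peak_centers(dataset$set_b), cmap)
  categories <- list(
    set_a = category_enrichment_table(dataset$set_a, dataset$genes,
                                      layout, cmap),
    set_b = category_enrichment_table(dataset$set_b, dataset$genes,
                                      layout, cmap))
  category_comparison <- compare_categories(cats_a, cats_b)
  states <- list(
    set_a = state_enrichment_table(dataset$set_a, dataset$segmentation),
    top_a = state_enrichment_table(
      filter_top_peaks(dataset$set_a), dataset$segmentation),
    set_b = state_enrichment_table(dataset$set_b, dataset$segmentation))
  motif <- NULL
  motif_flags <- NULL
  if (!is.null(dataset$sequences)) {
    motif <- peaks_with_motif(dataset$set_a, dataset$sequences,
                              dataset$config$motif)
    motif_flags <- motif$flags
  } else {
    warning("no genome sequence in dataset; motif stage skipped")
  }
  link <- NULL
  if (!is.null(dataset$gene_lists)) {
    link <- do.call(rbind, lapply(dataset$gene_lists, function(gl)
      analyze_gene_list(gl, dataset$set_a, dataset$genes, layout,
                        motif_flags = motif_flags, n_reps = mc_reps,
                        seed = dataset$config$seed + 10L)))
    rownames(link) <- NULL
  }
  tss_hist <- tss_distance_histogram(dataset$set_a, dataset$genes)
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)
    wt <- function(df, f) {
      utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p(f)
    }
    paths <- c(
      labels_a = wt(classification$labels_a, "labels_a.tsv"),
      labels_b = wt(classification$labels_b, "labels_b.tsv"),
      summary = wt(render_occupancy_summary(classification), "summary.tsv"),
      categories_a = wt(categories$set_a, "categories_a.tsv"),
      categories_b = wt(categories$set_b, "categories_b.tsv"),
      category_comparison = wt(category_comparison,
                               "category_comparison.tsv"),
      states_a = wt(states$set_a, "states_a.tsv"),
      states_top_a = wt(states$top_a, "states_top_a.tsv"),
      states_b = wt(states$set_b, "states_b.tsv"),
      tss_hist = wt(tss_hist, "tss_histogram.tsv"))
    if (!is.null(motif)) {
      hits <- motif$hits
      paths <- c(paths, motif_hits = {
        write_bed(data.frame(chrom = hits$chrom, start = hits$start,
                             end = hits$start + nchar(dataset$config$motif),
                             name = hits$match, score = 0,
                             strand = hits$strand), p("motif_hits.bed"))
        p("motif_hits.bed")
      })
      paths <- c(paths, motif_flags = wt(
        data.frame(peak = seq_along(motif$flags), has_motif = motif$flags),
        "motif_flags.tsv"))
    }
    if (!is.null(link)) paths <- c(paths, link = wt(link, "link_summary.tsv"))
    manifest <- data.frame(
      file = basename(unname(paths)),
      md5 = unname(tools::md5sum(unname(paths))),
      stringsAsFactors = FALSE)
    manifest_path <- p("manifest.tsv")
    utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, manifest = manifest_path)
  }
  list(classification = classification, categories = categories,
       category_comparison = category_comparison, states = states,
       motif = motif, link = link, tss_histogram = tss_hist,
       paths = paths)
}
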