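# Domain containers and readers/writers for every plain-text format the
# pipeline touches. All internal coordinates are 0-based half-open (BED
# convention); refFlat txStart is already 0-based. Every reader validates
# against the genome layout -- no silent clipping.

# genome layout ---------------------------------------------------------------

#' Construct a genome layout
#'
#' An ordered table of chromosome names and lengths, the coordinate frame
#' every other object is validated against.
#'
#' @param chrom character vector of unique chromosome names
#' @param length positive integer lengths in bp
#' @return a `genome_layout` data frame with columns `chrom`, `length`
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  stop_if(length(chrom) == 0L, "no chromosomes")
  stop_if(anyDuplicated(chrom) > 0L, "duplicate chromosome names")
  stop_if(any(is.na(length)) || any(length <= 0) || any(length != floor(length)),
          "chromosome lengths must be positive integers")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' Read a two-column chrom.sizes file
#'
#' @param path tab-separated file with columns name, length (no header)
#' @return a [genome_layout()]
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  stop_if(length(lines) == 0L, "no chromosomes in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stop_if(any(lengths(parts) != 2L), "malformed chrom.sizes line in ", path)
  nm <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  stop_if(any(is.na(len)), "non-numeric chromosome length in ", path)
  genome_layout(nm, len)
}

#' Write a chrom.sizes file
#' @param layout a [genome_layout()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_chrom_sizes <- function(layout, path) {
  writeLines(sprintf("%s\t%d", layout$chrom, as.integer(layout$length)), path)
  invisible(path)
}

#' Total genome length in bp
#' @param layout a [genome_layout()]
#' @return numeric scalar
#' @export
genome_size <- function(layout) sum(layout$length)

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  stop_if(anyNA(i), "unknown chromosome: ",
          paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$length[i]
}

# peak sets --------------------------------------------------------------------

#' Construct a peak set
#'
#' A named collection of peaks. Each peak is a 0-based half-open interval
#' with a summit position inside it and a non-negative rpm (reads per
#' million) intensity.
#'
#' @param peaks data frame with columns `chrom`, `start`, `end`, `summit`,
#'   `rpm`
#' @param name non-empty set name
#' @param layout optional [genome_layout()]; when given, peaks are
#'   bounds-checked against it
#' @param total_mapped_reads optional positive library size
#' @return a `peak_set` data frame
#' @export
peak_set <- function(peaks, name, layout = NULL, total_mapped_reads = NULL) {
  stop_if(!is.character(name) || !nzchar(name), "peak set name must be non-empty")
  need <- c("chrom", "start", "end", "summit", "rpm")
  stop_if(!all(need %in% names(peaks)),
          "peak table must have columns ", paste(need, collapse = ", "))
  peaks <- as.data.frame(peaks)[need]
  peaks$chrom <- as.character(peaks$chrom)
  for (cl in c("start", "end", "summit", "rpm"))
    peaks[[cl]] <- as.numeric(peaks[[cl]])
  if (nrow(peaks) > 0) {
    stop_if(any(peaks$end <= peaks$start), "peak with end <= start")
    stop_if(any(peaks$summit < peaks$start | peaks$summit >= peaks$end),
            "peak summit outside [start, end)")
    stop_if(any(peaks$rpm < 0), "negative rpm")
    stop_if(any(peaks$start < 0), "negative start coordinate")
    if (!is.null(layout)) {
      len <- chrom_length(layout, peaks$chrom)
      stop_if(any(peaks$end > len), "peak beyond chromosome end")
    }
  }
  if (!is.null(total_mapped_reads))
    stop_if(total_mapped_reads <= 0, "total_mapped_reads must be positive")
  structure(peaks, class = c("peak_set", "data.frame"),
            name = name, total_mapped_reads = total_mapped_reads)
}

#' Centers of the peaks in a set
#'
#' The center is `floor((start + end) / 2)`, the coordinate used for all
#' center-based assignments (not the summit).
#' @param peaks a `peak_set` (or any data frame with `start`, `end`)
#' @return integer vector of 0-based positions
#' @export
peak_centers <- function(peaks) as.integer(floor((peaks$start + peaks$end) / 2))

#' Read a peak table
#'
#' Tab-separated with header and columns `chrom`, `start`, `end`, `summit`,
#' `rpm`; coordinates 0-based half-open.
#'
#' @param path input file
#' @param layout a [genome_layout()] used for bounds checks
#' @param name set name (defaults to the file name)
#' @return a [peak_set()]
#' @export
read_peak_table <- function(path, layout,
                            name = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  peak_set(df, name = name, layout = layout)
}

#' Write a peak table
#' @param peaks a [peak_set()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_peak_table <- function(peaks, path) {
  df <- as.data.frame(peaks)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$summit <- as.integer(df$summit)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# gene annotation --------------------------------------------------------------

#' Construct a gene annotation table
#'
#' Transcript models with strand, transcript and CDS bounds, and exon
#' blocks (list columns `exon_starts`, `exon_ends`). UTRs are derivable:
#' the 5' UTR is the exonic sequence between the transcript start side and
#' the CDS start on the coding strand, the 3' UTR symmetric.
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_start`, `cds_end` and list columns
#'   `exon_starts`, `exon_ends`
#' @param layout optional [genome_layout()] for bounds checks
#' @return a `gene_annotation` data frame
#' @export
gene_annotation <- function(genes, layout = NULL) {
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "exon_starts", "exon_ends")
  stop_if(!all(need %in% names(genes)),
          "gene table must have columns ", paste(need, collapse = ", "))
  genes <- as.data.frame(genes)[need]
  genes$strand <- as.character(genes$strand)
  stop_if(nrow(genes) > 0 && !all(genes$strand %in% c("+", "-")),
          "strand must be '+' or '-'")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    stop_if(length(es) != length(ee) || length(es) == 0L,
            g$gene_id, ": exon start/end count mismatch")
    stop_if(any(ee <= es), g$gene_id, ": exon with end <= start")
    stop_if(is.unsorted(es, strictly = TRUE) ||
              any(es[-1] < ee[-length(ee)]),
            g$gene_id, ": exons unsorted or overlapping")
    stop_if(es[1] < g$tx_start || ee[length(ee)] > g$tx_end,
            g$gene_id, ": exons outside transcript bounds")
    stop_if(!(g$tx_start <= g$cds_start && g$cds_start <= g$cds_end &&
                g$cds_end <= g$tx_end),
            g$gene_id, ": CDS bounds outside transcript")
    if (!is.null(layout)) {
      len <- chrom_length(layout, g$chrom)
      stop_if(g$tx_start < 0 || g$tx_end > len,
              g$gene_id, ": transcript outside chromosome bounds")
    }
  }
  structure(genes, class = c("gene_annotation", "data.frame"))
}

#' Read a refFlat-like gene annotation
#'
#' Ten tab-separated columns: geneName, chrom, strand, txStart, txEnd,
#' cdsStart, cdsEnd, exonCount, exonStarts, exonEnds (comma-terminated
#' lists). Coordinates are 0-based half-open, as in UCSC refFlat.
#'
#' @param path input file (no header)
#' @param layout a [genome_layout()]
#' @return a [gene_annotation()]
#' @export
read_gene_annotation <- function(path, layout) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("gene annotation file ", path, " contains no genes")
    return(gene_annotation(data.frame(
      gene_id = character(), chrom = character(), strand = character(),
      tx_start = numeric(), tx_end = numeric(),
      cds_start = numeric(), cds_end = numeric(),
      exon_starts = I(list()), exon_ends = I(list()))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stop_if(any(lengths(parts) != 10L), "malformed refFlat line in ", path)
  f <- function(k) vapply(parts, `[[`, "", k)
  parse_commas <- function(x) lapply(strsplit(x, ",", fixed = TRUE), as.numeric)
  exon_starts <- parse_commas(f(9))
  exon_ends <- parse_commas(f(10))
  n_exons <- as.integer(f(8))
  stop_if(any(lengths(exon_starts) != n_exons | lengths(exon_ends) != n_exons),
          "exonCount does not match exon list length in ", path)
  gene_annotation(data.frame(
    gene_id = f(1), chrom = f(2), strand = f(3),
    tx_start = as.numeric(f(4)), tx_end = as.numeric(f(5)),
    cds_start = as.numeric(f(6)), cds_end = as.numeric(f(7)),
    exon_starts = I(exon_starts), exon_ends = I(exon_ends),
    stringsAsFactors = FALSE), layout = layout)
}

#' Write a refFlat-like gene annotation
#' @param genes a [gene_annotation()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gene_annotation <- function(genes, path) {
  fmt_list <- function(x) vapply(x, function(v)
    paste0(paste(as.integer(v), collapse = ","), ","), "")
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                   genes$gene_id, genes$chrom, genes$strand,
                   as.integer(genes$tx_start), as.integer(genes$tx_end),
                   as.integer(genes$cds_start), as.integer(genes$cds_end),
                   lengths(genes$exon_starts),
                   fmt_list(genes$exon_starts), fmt_list(genes$exon_ends))
  writeLines(lines, path)
  invisible(path)
}

# chromatin-state segmentation -------------------------------------------------

#' Construct a chromatin-state segmentation
#'
#' Non-overlapping labeled segments that tile each chromosome exactly
#' (no gaps), with labels drawn from a declared set (15 states for the
#' standard chromHMM model).
#'
#' @param segments data frame with columns `chrom`, `start`, `end`, `state`
#' @param layout a [genome_layout()]
#' @param labels character vector of allowed state labels
#' @return a `state_segmentation` data frame; per-label genome fractions
#'   are cached in attribute `genome_fractions`
#' @export
state_segmentation <- function(segments, layout, labels) {
  need <- c("chrom", "start", "end", "state")
  stop_if(!all(need %in% names(segments)),
          "segmentation must have columns ", paste(need, collapse = ", "))
  segments <- as.data.frame(segments)[need]
  segments$chrom <- as.character(segments$chrom)
  segments$state <- as.character(segments$state)
  stop_if(!all(segments$state %in% labels),
          "unknown state label: ",
          paste(unique(setdiff(segments$state, labels)), collapse = ", "))
  segments <- segments[order(match(segments$chrom, layout$chrom),
                             segments$start), ]
  rownames(segments) <- NULL
  for (cn in layout$chrom) {
    seg <- segments[segments$chrom == cn, ]
    len <- chrom_length(layout, cn)
    stop_if(nrow(seg) == 0L, "chromosome ", cn, " has no segments")
    stop_if(seg$start[1] != 0, "segmentation does not start at 0 on ", cn)
    stop_if(seg$end[nrow(seg)] != len,
            "segmentation does not reach chromosome end on ", cn)
    if (nrow(seg) > 1) {
      d <- seg$start[-1] - seg$end[-nrow(seg)]
      stop_if(any(d > 0), "gap between segments on ", cn)
      stop_if(any(d < 0), "overlapping segments on ", cn)
    }
  }
  bp <- tapply(segments$end - segments$start, segments$state, sum)
  fr <- setNames(numeric(length(labels)), labels)
  fr[names(bp)] <- bp / genome_size(layout)
  structure(segments, class = c("state_segmentation", "data.frame"),
            labels = labels, genome_fractions = fr)
}

#' Per-label genome coverage fractions of a segmentation
#' @param segmentation a [state_segmentation()]
#' @return named numeric vector summing to 1
#' @export
state_fractions <- function(segmentation) attr(segmentation, "genome_fractions")

#' Read a chromHMM-style dense BED4 segmentation
#' @param path tab-separated chrom, start, end, label (no header)
#' @param layout a [genome_layout()]
#' @param labels allowed state labels
#' @return a [state_segmentation()]
#' @export
read_state_segmentation <- function(path, layout, labels) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stop_if(ncol(df) < 4L, "segmentation BED must have 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "state")
  state_segmentation(df[1:4], layout, labels)
}

#' Write a segmentation as dense BED4
#' @param segmentation a [state_segmentation()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_state_segmentation <- function(segmentation, path) {
  utils::write.table(
    data.frame(segmentation$chrom, as.integer(segmentation$start),
               as.integer(segmentation$end), segmentation$state),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# FASTA and BED ---------------------------------------------------------------

#' Read genome sequence from FASTA
#' @param path FASTA file
#' @param layout optional [genome_layout()]; sequence lengths are checked
#'   against it when given
#' @return named character vector of upper-case sequences
#' @export
read_fasta <- function(path, layout = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(toupper(as.character(ss)),
                   sub("\\s.*$", "", names(ss)))
  if (!is.null(layout)) {
    stop_if(!all(layout$chrom %in% names(seqs)),
            "FASTA missing chromosomes from layout")
    got <- nchar(seqs[layout$chrom])
    stop_if(any(got != layout$length),
            "FASTA/layout length mismatch for ",
            paste(layout$chrom[got != layout$length], collapse = ", "))
    seqs <- seqs[layout$chrom]
  }
  seqs
}

#' Write genome sequence as FASTA
#' @param seqs named character vector of sequences
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write intervals as BED3/BED6
#'
#' @param intervals data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand` (their presence selects BED6)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(intervals$chrom, as.integer(intervals$start),
                   as.integer(intervals$end))
  if (all(c("name", "score", "strand") %in% names(intervals)))
    df <- cbind(df, intervals$name, intervals$score, intervals$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file
#' @param path input file (no header)
#' @return data frame with columns `chrom`, `start`, `end` (+ `name`,
#'   `score`, `strand` for BED6)
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  df
}

# gene lists -------------------------------------------------------------------

#' Construct a named gene list
#'
#' Ids that do not resolve against the annotation are reported in the
#' `unresolved` attribute (and a warning), never silently dropped.
#'
#' @param gene_ids character vector of gene ids
#' @param name list name
#' @param genes optional [gene_annotation()] to resolve ids against
#' @return a `gene_list` object (character vector with attributes)
#' @export
gene_list <- function(gene_ids, name, genes = NULL) {
  gene_ids <- unique(as.character(gene_ids))
  stop_if(length(gene_ids) == 0L || any(!nzchar(gene_ids)),
          "gene list must contain non-empty ids")
  unresolved <- character()
  if (!is.null(genes)) {
    unresolved <- setdiff(gene_ids, genes$gene_id)
    if (length(unresolved))
      warning("gene list '", name, "': ", length(unresolved),
              " id(s) not in annotation: ",
              paste(head(unresolved, 5), collapse = ", "))
  }
  structure(gene_ids, class = "gene_list", name = name,
            unresolved = unresolved)
}

#' Read a gene list (one id per line)
#' @param path input file
#' @param name list name (defaults to file name)
#' @param genes optional [gene_annotation()] to resolve against
#' @return a [gene_list()]
#' @export
read_gene_list <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                           genes = NULL) {
  ids <- readLines(path)
  gene_list(ids[nzchar(ids)], name = name, genes = genes)
}

# signal tracks ----------------------------------------------------------------

#' Construct a per-base signal track
#'
#' Per-chromosome vectors of read-start counts (bin width 1 bp) plus the
#' library size; `rpm(interval) = 1e6 * sum(counts in interval) /
#' library_size`.
#'
#' @param counts named list of non-negative integer vectors, one per
#'   chromosome, each of the chromosome's length
#' @param library_size positive integer total mapped reads
#' @param layout optional [genome_layout()] for length checks
#' @return a `signal_track` object
#' @export
signal_track <- function(counts, library_size, layout = NULL) {
  stop_if(library_size <= 0, "library_size must be positive")
  stop_if(is.null(names(counts)) || any(!nzchar(names(counts))),
          "counts must be a named list")
  stop_if(any(vapply(counts, function(v) any(v < 0), TRUE)),
          "negative counts in signal track")
  if (!is.null(layout)) {
    stop_if(!setequal(names(counts), layout$chrom),
            "track chromosomes do not match layout")
    got <- vapply(counts[layout$chrom], length, 1L)
    stop_if(any(got != layout$length), "track length mismatch with layout")
    counts <- counts[layout$chrom]
  }
  structure(list(counts = counts, library_size = library_size,
                 cumulative = lapply(counts, cumsum)),
            class = "signal_track")
}
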