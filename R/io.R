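# Plain-text readers and writers for the package's tabular interfaces:
# BED intervals, signal tables, library counts, scale factors.

#' Read a BED file of intervals
#'
#' 3- to 6-column BED via [rtracklayer::import()]; coordinates are returned
#' 0-based, half-open (the native BED convention).
#'
#' @param path BED file path.
#' @return Interval data frame (`chrom`, `start`, `end`, `id`, and `score`,
#'   `strand` when present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  out$id <- if (!is.null(mc$name) && !all(is.na(mc$name))) {
    as.character(mc$name)
  } else {
    sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  }
  if (!is.null(mc$score)) out$score <- as.numeric(mc$score)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand != "*")) out$strand <- strand
  out
}

#' Write intervals as BED
#'
#' Emits 6-column BED (chrom, start, end, name, score, strand) with 0-based,
#' half-open coordinates.
#'
#' @param intervals Interval data frame; `score` defaults to 0 and `strand`
#'   to `"."` when absent.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- validate_intervals(intervals)
  score <- if ("score" %in% names(intervals)) intervals$score else 0
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  df <- data.frame(intervals$chrom, intervals$start, intervals$end,
                   intervals$id, score, strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a signal table as TSV
#'
#' One row per interval: `interval_id`, `chrom`, `start`, `end`, then one
#' column per sample.
#'
#' @param table A [signal_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(table, path) {
  stopifnot(inherits(table, "signal_table"))
  df <- data.frame(interval_id = table$intervals$id,
                   chrom = table$intervals$chrom,
                   start = table$intervals$start,
                   end = table$intervals$end,
                   table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signal table TSV
#'
#' @param path TSV written by [write_signal_table()].
#' @param samples Optional sample metadata data frame (`sample_id`, ...).
#' @param calibrated,units Flags restored onto the table (the TSV itself does
#'   not carry them).
#' @return A [signal_table()].
#' @export
read_signal_table <- function(path, samples = NULL, calibrated = FALSE,
                              units = "counts") {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- c("interval_id", "chrom", "start", "end")
  if (!all(meta %in% names(df))) {
    stop("not a signal table TSV (missing coordinate columns)", call. = FALSE)
  }
  intervals <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                          id = df$interval_id, stringsAsFactors = FALSE)
  counts <- as.matrix(df[setdiff(names(df), meta)])
  signal_table(counts, intervals, samples = samples,
               calibrated = calibrated, units = units)
}

#' Write or read per-sample library read totals
#'
#' @param libraries Library counts data frame (see
#'   [simulate_experiment()]).
#' @param path TSV path.
#' @return `write_library_counts()`: `path`, invisibly.
#'   `read_library_counts()`: the library counts data frame.
#' @export
write_library_counts <- function(libraries, path) {
  write.table(libraries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_counts
#' @export
read_library_counts <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write scale factors as TSV
#'
#' @param factors A `scale_factors` object.
#' @param path TSV path (`sample_id`, `alpha`, `mode`).
#' @return `path`, invisibly.
#' @export
write_scale_factors <- function(factors, path) {
  stopifnot(inherits(factors, "scale_factors"))
  write.table(as.data.frame(factors), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
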