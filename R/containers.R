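# Core data containers. Plain data.frame / matrix based S3 classes, in the
# style of count-table packages: a SignalTable couples an intervals-by-samples
# matrix with interval and sample annotation.

#' Construct a signal table
#'
#' A `signal_table` holds an intervals x samples matrix of fragment counts (or
#' derived densities) together with interval coordinates and sample metadata.
#' It is the unit of exchange between calibration, quantitation and
#' differential testing.
#'
#' @param counts Numeric matrix, one row per interval, one column per sample.
#'   Row and column names are taken from `intervals$id` and
#'   `samples$sample_id` when absent.
#' @param intervals Data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open) and `id`; one row per row of `counts`.
#' @param samples Data frame with columns `sample_id` and optionally
#'   `condition`, `replicate`, `library_size`; one row per column of `counts`.
#'   Defaults to bare sample ids from `colnames(counts)`.
#' @param calibrated Logical flag: have the counts been scaled to the spike-in
#'   calibration genome? Required by [nrpk()].
#' @param units Character label for the values held (`"counts"`, `"NRPK"`,
#'   `"RPKM"`).
#'
#' @return An object of class `signal_table`: a list with elements `counts`,
#'   `intervals`, `samples`, `calibrated`, `units`.
#' @examples
#' iv <- data.frame(chrom = "chr1", start = 0, end = 2000, id = "iv1")
#' st <- signal_table(matrix(50, 1, 1, dimnames = list("iv1", "s1")), iv)
#' st
#' @export
signal_table <- function(counts, intervals, samples = NULL,
                         calibrated = FALSE, units = "counts") {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0)) {
    stop("'counts' must be a finite non-negative numeric matrix", call. = FALSE)
  }
  intervals <- validate_intervals(intervals)
  if (nrow(intervals) != nrow(counts)) {
    stop("'intervals' must have one row per row of 'counts'", call. = FALSE)
  }
  if (is.null(samples)) {
    ids <- colnames(counts)
    if (is.null(ids)) ids <- paste0("sample_", seq_len(ncol(counts)))
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(samples)) {
    stop("'samples' must have a 'sample_id' column", call. = FALSE)
  }
  if (nrow(samples) != ncol(counts)) {
    stop("'samples' must have one row per column of 'counts'", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  rownames(counts) <- intervals$id
  colnames(counts) <- samples$sample_id
  structure(
    list(counts = counts, intervals = intervals, samples = samples,
         calibrated = isTRUE(calibrated), units = units),
    class = "signal_table"
  )
}

#' @export
print.signal_table <- function(x, ...) {
  cat(sprintf(
    "signal_table: %d intervals x %d samples [%s%s]\n",
    nrow(x$counts), ncol(x$counts), x$units,
    if (x$calibrated) ", calibrated" else ""
  ))
  invisible(x)
}

#' @export
dim.signal_table <- function(x) dim(x$counts)

#' Interval lengths of a signal table
#'
#' @param table A [signal_table()].
#' @return Numeric vector of interval widths in bp.
#' @export
interval_lengths <- function(table) {
  stopifnot(inherits(table, "signal_table"))
  table$intervals$end - table$intervals$start
}

# Validate a GenomeInterval data.frame: chrom/start/end (0-based half-open),
# unique ids (generated from coordinates when missing).
validate_intervals <- function(intervals, require_id = FALSE) {
  if (!is.data.frame(intervals)) {
    stop("intervals must be a data.frame", call. = FALSE)
  }
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(intervals))
  if (length(miss)) {
    stop("intervals are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(intervals$start)) || any(!is.finite(intervals$end))) {
    stop("interval coordinates must be finite", call. = FALSE)
  }
  if (any(intervals$start < 0)) {
    stop("interval start coordinates must be >= 0 (0-based)", call. = FALSE)
  }
  bad <- which(intervals$start >= intervals$end)
  if (length(bad)) {
    stop(sprintf("malformed interval (start >= end) at row %d", bad[1]),
         call. = FALSE)
  }
  if (!"id" %in% names(intervals)) {
    if (require_id) stop("intervals must carry an 'id' column", call. = FALSE)
    intervals$id <- sprintf("%s:%d-%d", intervals$chrom,
                            intervals$start, intervals$end)
  }
  if (anyDuplicated(intervals$id)) {
    stop("interval ids must be unique", call. = FALSE)
  }
  intervals$chrom <- as.character(intervals$chrom)
  intervals$id <- as.character(intervals$id)
  intervals
}

# 0-based half-open data.frame -> GRanges (1-based closed) and back.
intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end),
    id = intervals$id
  )
}

granges_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    id = if (!is.null(S4Vectors::mcols(gr)$id))
      as.character(S4Vectors::mcols(gr)$id)
    else sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr)),
    stringsAsFactors = FALSE
  )
}

# Validate a LibraryCounts data.frame.
validate_library_counts <- function(libraries, calibrated = TRUE) {
  if (!is.data.frame(libraries) || nrow(libraries) < 1L) {
    stop("'libraries' must be a data.frame with at least one row", call. = FALSE)
  }
  need <- c("sample_id", "n_target_ip", "n_spike_ip")
  if (calibrated) need <- c(need, "n_target_input", "n_spike_input")
  miss <- setdiff(need, names(libraries))
  if (length(miss)) {
    stop("'libraries' is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(libraries$sample_id)) {
    stop("library sample ids must be unique", call. = FALSE)
  }
  counts <- libraries[intersect(names(libraries),
                                c("n_target_ip", "n_spike_ip",
                                  "n_target_input", "n_spike_input"))]
  if (any(sapply(counts, function(x) any(!is.finite(x) | x < 0)))) {
    stop("library read counts must be finite and >= 0", call. = FALSE)
  }
  libraries
}

#' Split a signal table by condition
#'
#' @param table A [signal_table()] whose `samples` carry a `condition`
#'   column.
#' @return Named list of [signal_table()]s, one per condition, in the order
#'   conditions first appear.
#' @export
split_by_condition <- function(table) {
  stopifnot(inherits(table, "signal_table"))
  cond <- table$samples$condition
  if (is.null(cond)) {
    stop("samples carry no 'condition' column", call. = FALSE)
  }
  out <- lapply(unique(cond), function(cc) {
    sel <- cond == cc
    signal_table(table$counts[, sel, drop = FALSE], table$intervals,
                 samples = table$samples[sel, , drop = FALSE],
                 calibrated = table$calibrated, units = table$units)
  })
  names(out) <- unique(cond)
  out
}
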