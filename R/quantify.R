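# Interval bookkeeping and signal quantitation. Interval arithmetic is done
# with GenomicRanges/IRanges; all user-facing coordinates are 0-based,
# half-open (BED convention).

#' Merge nearby genomic intervals
#'
#' Merges intervals on the same chromosome whose gap (`start2 - end1`) is
#' strictly less than `max_gap` bp -- the "closer than" rule used to fuse
#' nearby peaks (5 kb for broad H2AK119ub1 domains, 2 kb for
#' RING1B/SUZ12/H3K27me3 peak sets). Merging is transitive; overlapping and
#' abutting intervals always merge. An exact gap of `max_gap` does not merge.
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based,
#'   half-open) and optionally `id` columns.
#' @param max_gap Non-negative gap threshold in bp.
#' @return A coordinate-sorted, non-overlapping interval data frame. The `id`
#'   of a merged interval is the comma-joined ids of its members in
#'   coordinate order.
#' @examples
#' iv <- data.frame(chrom = "chr1", start = c(0, 4000), end = c(100, 4100),
#'                  id = c("a", "b"))
#' merge_intervals(iv, max_gap = 5000)  # gap 3900 < 5000: one interval
#' @export
merge_intervals <- function(intervals, max_gap) {
  intervals <- validate_intervals(intervals)
  check_scalar_number(max_gap, "max_gap", min = 0)
  gr <- intervals_to_granges(intervals)
  # reduce() merges ranges separated by a gap < min.gapwidth, which is
  # exactly the strict "closer than max_gap" rule in 0-based coordinates.
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  # revmap indexes the (unsorted) input; emit member ids in coordinate order.
  ord_key <- order(intervals$chrom, intervals$start, intervals$end,
                   intervals$id)
  rank_of <- integer(nrow(intervals))
  rank_of[ord_key] <- seq_len(nrow(intervals))
  merged_ids <- vapply(revmap, function(i) {
    paste(intervals$id[i[order(rank_of[i])]], collapse = ",")
  }, character(1))
  out <- granges_to_intervals(red)
  out$id <- merged_ids
  ord <- order(out$chrom, out$start, out$end)
  out[ord, , drop = FALSE]
}

#' Count fragments overlapping intervals
#'
#' A fragment is assigned to an interval iff they overlap by at least 1 bp
#' (half-open coordinates: a fragment ending where an interval starts does
#' not overlap). Each fragment is counted at most once per interval;
#' intervals must be non-overlapping (merge first), so a fragment spanning a
#' gap can still count towards at most the intervals it genuinely overlaps.
#'
#' @param fragments Data frame of fragment spans with columns `chrom`,
#'   `start`, `end` (0-based, half-open) and optionally `sample` (one count
#'   column is produced per sample; absent means a single unnamed sample).
#' @param intervals Non-overlapping interval data frame (see
#'   [merge_intervals()]).
#' @param sample_levels Optional character vector fixing the sample column
#'   order.
#' @return A raw-count [signal_table()]; per-sample library size is the total
#'   number of fragments of that sample (inside or outside intervals).
#' @export
count_fragments <- function(fragments, intervals, sample_levels = NULL) {
  intervals <- validate_intervals(intervals)
  iv_gr <- intervals_to_granges(intervals)
  if (any(GenomicRanges::countOverlaps(iv_gr, iv_gr) > 1L)) {
    stop("intervals overlap; run merge_intervals() first", call. = FALSE)
  }
  if (!is.data.frame(fragments) ||
      !all(c("chrom", "start", "end") %in% names(fragments))) {
    stop("'fragments' must be a data.frame with chrom/start/end", call. = FALSE)
  }
  if (nrow(fragments) && any(fragments$start >= fragments$end)) {
    stop("malformed fragment (start >= end)", call. = FALSE)
  }
  sample <- if ("sample" %in% names(fragments)) {
    as.character(fragments$sample)
  } else {
    rep("sample_1", nrow(fragments))
  }
  levels <- if (is.null(sample_levels)) sort(unique(sample)) else sample_levels
  if (length(levels) == 0L) levels <- "sample_1"
  counts <- matrix(0, nrow = nrow(intervals), ncol = length(levels),
                   dimnames = list(intervals$id, levels))
  lib <- setNames(numeric(length(levels)), levels)
  for (s in levels) {
    fr <- fragments[sample == s, , drop = FALSE]
    lib[s] <- nrow(fr)
    if (nrow(fr) == 0L) next
    fr_gr <- GenomicRanges::GRanges(
      fr$chrom, IRanges::IRanges(fr$start + 1L, fr$end))
    counts[, s] <- GenomicRanges::countOverlaps(iv_gr, fr_gr, minoverlap = 1L)
  }
  signal_table(counts, intervals,
               samples = data.frame(sample_id = levels, library_size = lib,
                                    stringsAsFactors = FALSE, row.names = NULL))
}

#' Normalised reads per kilobase (NRPK)
#'
#' Per-interval signal density for spike-in calibrated samples: the
#' calibrated fragment count divided by interval length in kb. No per-million
#' library scaling is applied -- calibration has already put all samples on a
#' common absolute scale, which is the point of the spike-in.
#'
#' @param table A calibrated [signal_table()] (see [downsample_counts()]).
#' @return A [signal_table()] with `units = "NRPK"`.
#' @examples
#' iv <- data.frame(chrom = "chr1", start = 0, end = 2000, id = "iv1")
#' st <- signal_table(matrix(50, 1, 1), iv, calibrated = TRUE)
#' nrpk(st)$counts  # 50 / 2 = 25
#' @export
nrpk <- function(table) {
  stopifnot(inherits(table, "signal_table"))
  if (!table$calibrated) {
    stop("nrpk() requires spike-in calibrated counts; run ",
         "compute_scale_factors() + downsample_counts() first, or use rpkm() ",
         "for uncalibrated libraries", call. = FALSE)
  }
  out <- table
  out$counts <- table$counts / (interval_lengths(table) / 1000)
  out$units <- "NRPK"
  out
}

#' Reads per kilobase per million mapped reads (RPKM)
#'
#' Depth-normalised density for uncalibrated libraries:
#' `count / (length/1000) / (library_size/1e6)`.
#'
#' @param table A raw-count [signal_table()] whose `samples$library_size` are
#'   all positive.
#' @return A [signal_table()] with `units = "RPKM"`.
#' @export
rpkm <- function(table) {
  stopifnot(inherits(table, "signal_table"))
  lib <- table$samples$library_size
  if (is.null(lib) || any(!is.finite(lib) | lib <= 0)) {
    stop("rpkm() requires positive library sizes for every sample",
         call. = FALSE)
  }
  out <- table
  out$counts <- sweep(table$counts / (interval_lengths(table) / 1000),
                      2L, lib / 1e6, `/`)
  out$units <- "RPKM"
  out
}

#' Binned signal profiles around site centres
#'
#' Extracts per-base coverage in a fixed window around the centre of each
#' site (centre = `floor((start + end) / 2)`), averages it into equal-width
#' bins, and stacks the rows into a sites x bins matrix -- the input for
#' heatmaps, k-means site classification and metaplots. Sites whose window
#' would run past a contig end are dropped with a warning.
#'
#' @param coverage Named list, one numeric vector per chromosome of per-bp
#'   signal (element `p + 1` is the signal at 0-based position `p`).
#' @param sites Interval data frame (`chrom`, `start`, `end`, optional `id`).
#' @param half_width Window half-width in bp; the window is
#'   `[centre - half_width, centre + half_width)`.
#' @param bins Number of bins; must divide `2 * half_width`.
#' @return A `profile_matrix`: numeric matrix (rows = retained sites, columns
#'   = bins) with attributes `half_width` and `bin_width`.
#' @seealso [metaplot()]
#' @export
profile_matrix <- function(coverage, sites, half_width, bins) {
  sites <- validate_intervals(sites)
  half_width <- check_count(half_width, "half_width", min = 1L)
  bins <- check_count(bins, "bins", min = 1L)
  if ((2L * half_width) %% bins != 0L) {
    stop("'bins' must divide the window width (2 * half_width)", call. = FALSE)
  }
  if (!is.list(coverage) || is.null(names(coverage))) {
    stop("'coverage' must be a named list of per-chromosome vectors",
         call. = FALSE)
  }
  bin_width <- (2L * half_width) %/% bins
  centre <- floor((sites$start + sites$end) / 2)
  w0 <- centre - half_width
  w1 <- centre + half_width  # exclusive
  keep <- logical(nrow(sites))
  rows <- matrix(NA_real_, nrow(sites), bins)
  for (i in seq_len(nrow(sites))) {
    vec <- coverage[[sites$chrom[i]]]
    if (is.null(vec) || w0[i] < 0 || w1[i] > length(vec)) next
    seg <- vec[(w0[i] + 1L):w1[i]]
    rows[i, ] <- colMeans(matrix(seg, nrow = bin_width))
    keep[i] <- TRUE
  }
  if (!all(keep)) {
    warning(sum(!keep), " site(s) dropped: window extends past a contig end ",
            "or chromosome has no coverage (",
            paste(utils::head(sites$id[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ..." else "", ")")
  }
  out <- rows[keep, , drop = FALSE]
  dimnames(out) <- list(sites$id[keep], sprintf("bin_%03d", seq_len(bins)))
  structure(out, half_width = half_width, bin_width = bin_width,
            class = c("profile_matrix", "matrix", "array"))
}

#' Average profile across sites (metaplot)
#'
#' @param matrix A `profile_matrix` (or any sites x bins matrix).
#' @return Numeric vector of per-bin means across sites.
#' @export
metaplot <- function(matrix) {
  if (!is.matrix(matrix)) stop("'matrix' must be a matrix", call. = FALSE)
  colMeans(matrix)
}
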