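# Site and gene classification: variant-enriched vs shared PRC1 targets,
# PcG vs non-PcG TSS, and the non-redundant gene-set filter.

#' Classify PRC1 target sites by k-means on RYBP/CBX7 profiles
#'
#' Clusters sites on the concatenation of their binned RYBP (variant PRC1)
#' and CBX7 (canonical PRC1) signal profiles with seeded k-means (k-means++
#' style multiple restarts via `nstart`). The cluster with the lower mean
#' CBX7 signal is labelled `variant_enriched` (RYBP-bound but CBX7-depleted);
#' the other(s) `shared` -- the labelling hinges on CBX7 depletion, which is
#' what defines a variant-enriched site. Rows are clustered in a canonical
#' lexicographic order internally, so permuting the input site order permutes
#' the labels identically.
#'
#' If the fitted clusters explain less than `min_separation` of the total sum
#' of squares the split is arbitrary (e.g. classes simulated with zero
#' separation, or all-identical profiles) and the function refuses to label
#' rather than emit a meaningless partition.
#'
#' @param rybp_profiles,cbx7_profiles Row-aligned sites x bins matrices (see
#'   [profile_matrix()] / [simulate_profiles()]).
#' @param k Number of clusters (default 2).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of random restarts.
#' @param scale_features Z-scale each bin before clustering? Off by default
#'   (raw densities, matching heatmap-tool conventions).
#' @param min_separation Minimum between-cluster fraction of total sum of
#'   squares below which the clustering is rejected as degenerate.
#' @return A `site_class` data frame: `site_id`, `cluster`, `label`
#'   (`"variant_enriched"` / `"shared"`), `mean_rybp`, `mean_cbx7` (per-site
#'   track means). The k-means cluster centres are attached as attribute
#'   `"cluster_cbx7_means"`.
#' @examples
#' pr <- simulate_profiles(n_sites = 60, bins = 10, separation = 10, seed = 2)
#' cls <- classify_sites(pr$rybp, pr$cbx7, seed = 2)
#' table(cls$label, pr$truth$class)
#' @export
classify_sites <- function(rybp_profiles, cbx7_profiles, k = 2, seed = NULL,
                           nstart = 10, scale_features = FALSE,
                           min_separation = 0.2) {
  rybp <- as.matrix(rybp_profiles)
  cbx7 <- as.matrix(cbx7_profiles)
  if (nrow(rybp) != nrow(cbx7)) {
    stop("profile matrices must be row-aligned (same sites)", call. = FALSE)
  }
  k <- check_count(k, "k", min = 2L)
  if (k > nrow(rybp)) {
    stop("k exceeds the number of sites", call. = FALSE)
  }
  features <- cbind(rybp, cbx7)
  if (all(apply(features, 2L, function(col) length(unique(col)) == 1L))) {
    stop("all site profiles are identical: a single effective cluster; ",
         "refusing an arbitrary split", call. = FALSE)
  }
  if (scale_features) features <- scale(features)
  ids <- rownames(rybp)
  if (is.null(ids)) ids <- sprintf("site_%04d", seq_len(nrow(rybp)))
  # canonical row order: clustering is then invariant to input permutation
  ord <- do.call(order, c(unname(as.data.frame(features)), list(ids)))
  # Hartigan-Wong needs k < n; at k == n every site is its own cluster and
  # Lloyd handles that exactly.
  algo <- if (k == nrow(features)) "Lloyd" else "Hartigan-Wong"
  km <- with_seed(seed, kmeans(features[ord, , drop = FALSE], centers = k,
                               nstart = nstart, iter.max = 50L,
                               algorithm = algo))
  sep <- km$betweenss / km$totss
  if (!is.finite(sep) || sep < min_separation) {
    stop(sprintf(
      "degenerate clustering: between-cluster sum of squares is only %.1f%% of total (< %.0f%%); the classes are not separable",
      100 * sep, 100 * min_separation), call. = FALSE)
  }
  cluster <- integer(nrow(features))
  cluster[ord] <- km$cluster
  cbx7_cluster_means <- vapply(
    seq_len(k), function(cl) mean(cbx7[cluster == cl, , drop = FALSE]),
    numeric(1))
  label <- ifelse(cluster == which.min(cbx7_cluster_means),
                  "variant_enriched", "shared")
  out <- data.frame(
    site_id = ids, cluster = cluster, label = label,
    mean_rybp = rowMeans(rybp), mean_cbx7 = rowMeans(cbx7),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("site_class", "data.frame")
  attr(out, "cluster_cbx7_means") <- cbx7_cluster_means
  attr(out, "separation") <- sep
  out
}

#' Classify TSS as Polycomb targets by peak overlap
#'
#' A gene's TSS is called PcG iff the window `[TSS - flank, TSS + flank]`
#' overlaps any peak by at least 1 bp (with `flank = 0` this is the TSS point
#' itself). `flank = 500` reproduces the TSS +/-500 bp window used for
#' promoter occupancy quantitation. The PcG set is monotone in `flank`.
#'
#' @param genes Data frame with `gene_id`, `chrom` and `tss` (0-based bp)
#'   columns.
#' @param peaks Merged, non-overlapping interval data frame.
#' @param flank Half-width of the TSS window in bp.
#' @return `genes` with added logical `pcg` and character `class`
#'   (`"PcG"` / `"non-PcG"`) columns.
#' @export
classify_tss <- function(genes, peaks, flank = 0) {
  if (!is.data.frame(genes) || !all(c("chrom", "tss") %in% names(genes))) {
    stop("'genes' must be a data.frame with 'chrom' and 'tss' columns",
         call. = FALSE)
  }
  flank <- check_count(flank, "flank", min = 0L)
  if (nrow(peaks) > 0) peaks <- validate_intervals(peaks)
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    genes$pcg <- rep(FALSE, nrow(genes))
  } else {
    tss_gr <- GenomicRanges::GRanges(
      genes$chrom,
      IRanges::IRanges(start = pmax(genes$tss - flank, 0) + 1L,
                       end = genes$tss + flank + 1L))
    genes$pcg <- GenomicRanges::countOverlaps(
      tss_gr, intervals_to_granges(peaks), minoverlap = 1L) > 0L
  }
  genes$class <- ifelse(genes$pcg, "PcG", "non-PcG")
  genes
}

#' Non-redundant gene-set filter
#'
#' Builds the bespoke gene set used for nuclear RNA-seq quantitation: a gene
#' is retained iff its length is strictly greater than `min_length` bp, both
#' its gene-body and TSS mappability flags are set, and both its
#' `(chrom, strand, tss)` and `(chrom, strand, tts)` keys are unique in the
#' input -- every member of a duplicated TSS or TTS group is dropped, which
#' removes poorly mappable and highly similar transcripts.
#'
#' @param genes Data frame with columns `chrom`, `strand`, `tss`, `tts`,
#'   `mappable_body`, `mappable_tss` and optionally `length` (computed as
#'   `abs(tts - tss)` when absent).
#' @param min_length Strict lower bound on gene length in bp (default 200).
#' @return The retained subset of `genes`. Idempotent.
#' @export
filter_gene_set <- function(genes, min_length = 200) {
  if (!is.data.frame(genes)) stop("'genes' must be a data.frame", call. = FALSE)
  need <- c("chrom", "strand", "tss", "tts", "mappable_body", "mappable_tss")
  miss <- setdiff(need, names(genes))
  if (length(miss)) {
    stop("'genes' is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (anyNA(genes$mappable_body) || anyNA(genes$mappable_tss)) {
    stop("mappability flags must not be missing", call. = FALSE)
  }
  len <- if ("length" %in% names(genes)) genes$length else abs(genes$tts - genes$tss)
  tss_key <- paste(genes$chrom, genes$strand, genes$tss)
  tts_key <- paste(genes$chrom, genes$strand, genes$tts)
  dup_tss <- tss_key %in% tss_key[duplicated(tss_key)]
  dup_tts <- tts_key %in% tts_key[duplicated(tts_key)]
  keep <- len > min_length &
    as.logical(genes$mappable_body) & as.logical(genes$mappable_tss) &
    !dup_tss & !dup_tts
  genes[keep, , drop = FALSE]
}
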