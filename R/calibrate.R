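# Spike-in calibration: per-sample scale (retention) factors and random
# downsampling of interval counts.

#' Compute spike-in calibration scale factors
#'
#' Implements two-step spike-in calibration for a comparison group of
#' libraries: each sample's spike-genome IP read total is first adjusted by
#' the spike-to-target read ratio of its matched input library (correcting
#' for sample-to-sample variation in the true spike cell ratio), giving an
#' effective spike signal
#' `E_s = n_spike_ip_s * n_target_input_s / n_spike_input_s`.
#' Target-genome reads are then downsampled by
#' `alpha_s = min(E) / E_s`, so the sample with the least effective spike
#' signal is kept whole (`alpha = 1`) and samples with more effective spike
#' signal -- i.e. more recovered material per unit of true signal -- are
#' thinned proportionally. Fold changes between samples are invariant to the
#' choice of the group minimum as the anchor.
#'
#' @param libraries Data frame of per-sample read totals with columns
#'   `sample_id`, `n_target_ip`, `n_spike_ip`, `n_target_input`,
#'   `n_spike_input` (see [simulate_experiment()] for the layout).
#' @return A `scale_factors` data frame: `sample_id`, `alpha` (retention
#'   fraction in (0, 1]), `mode = "calibrated"`.
#' @examples
#' libs <- data.frame(
#'   sample_id = c("A", "B"), n_target_ip = c(1e6, 1e6),
#'   n_spike_ip = c(1000, 2000),
#'   n_target_input = c(1e6, 1e6), n_spike_input = c(2.5e5, 2.5e5)
#' )
#' compute_scale_factors(libs)  # alpha = 1, 0.5
#' @seealso [equalize_depth()] for non-spiked designs, [downsample_counts()]
#' @export
compute_scale_factors <- function(libraries) {
  libraries <- validate_library_counts(libraries, calibrated = TRUE)
  bad <- libraries$sample_id[libraries$n_spike_ip <= 0 |
                               libraries$n_target_input <= 0 |
                               libraries$n_spike_input <= 0]
  if (length(bad)) {
    stop("cannot calibrate sample(s) with zero spike-IP or input counts: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  input_ratio <- libraries$n_spike_input / libraries$n_target_input
  effective_spike <- libraries$n_spike_ip / input_ratio
  alpha <- min(effective_spike) / effective_spike
  out <- data.frame(sample_id = libraries$sample_id,
                    alpha = alpha,
                    mode = "calibrated",
                    stringsAsFactors = FALSE)
  class(out) <- c("scale_factors", "data.frame")
  out
}

#' Depth-equalizing scale factors for non-spiked libraries
#'
#' For designs without an internal spike-in, replicates are randomly
#' downsampled to the read depth of the shallowest library:
#' `alpha_s = min(n_target_ip) / n_target_ip_s`. Spike counts are not
#' consulted.
#'
#' @param libraries Data frame with `sample_id` and `n_target_ip` columns.
#' @return A `scale_factors` data frame with `mode = "depth"`.
#' @examples
#' equalize_depth(data.frame(sample_id = c("a", "b", "c"),
#'                           n_target_ip = c(10, 20, 40),
#'                           n_spike_ip = 0))$alpha  # 1, 0.5, 0.25
#' @export
equalize_depth <- function(libraries) {
  if (!is.data.frame(libraries) || nrow(libraries) < 1L) {
    stop("'libraries' must be a data.frame with at least one row", call. = FALSE)
  }
  if (!all(c("sample_id", "n_target_ip") %in% names(libraries))) {
    stop("'libraries' needs 'sample_id' and 'n_target_ip' columns", call. = FALSE)
  }
  bad <- libraries$sample_id[!is.finite(libraries$n_target_ip) |
                               libraries$n_target_ip <= 0]
  if (length(bad)) {
    stop("zero or invalid target read count for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(sample_id = libraries$sample_id,
                    alpha = min(libraries$n_target_ip) / libraries$n_target_ip,
                    mode = "depth",
                    stringsAsFactors = FALSE)
  class(out) <- c("scale_factors", "data.frame")
  out
}

#' Downsample interval counts by per-sample scale factors
#'
#' Thins each interval count `c` of sample `s` to `Binomial(c, alpha_s)`
#' (statistically identical to retaining each read independently with
#' probability `alpha_s`, but far cheaper than per-read thinning). The
#' deterministic `"expected"` mode returns `alpha_s * c` instead, for exact
#' regression tests and noise-free pipelines.
#'
#' @param table A [signal_table()] of raw integer counts.
#' @param factors A `scale_factors` object covering every sample of `table`.
#' @param seed Integer seed for the binomial thinning (ignored in
#'   `"expected"` mode).
#' @param mode `"random"` (default) or `"expected"`.
#' @return A [signal_table()] with thinned counts; `calibrated` is set to
#'   `TRUE` when the factors were produced by [compute_scale_factors()].
#'   Library sizes are rescaled by `alpha`.
#' @export
downsample_counts <- function(table, factors, seed = NULL,
                              mode = c("random", "expected")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "signal_table"))
  if (!inherits(factors, "scale_factors")) {
    stop("'factors' must come from compute_scale_factors() or equalize_depth()",
         call. = FALSE)
  }
  idx <- match(table$samples$sample_id, factors$sample_id)
  if (anyNA(idx)) {
    stop("factors missing for sample(s): ",
         paste(table$samples$sample_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  alpha <- factors$alpha[idx]
  if (any(!is.finite(alpha) | alpha <= 0 | alpha > 1)) {
    stop("scale factors must lie in (0, 1]", call. = FALSE)
  }
  counts <- table$counts
  if (mode == "random") {
    if (any(counts != round(counts))) {
      stop("random thinning requires integer counts; use mode = 'expected' ",
           "for non-integer tables", call. = FALSE)
    }
    counts <- with_seed(seed, {
      thinned <- counts
      for (s in seq_along(alpha)) {
        thinned[, s] <- rbinom(nrow(counts), size = as.integer(counts[, s]),
                               prob = alpha[s])
      }
      thinned
    })
  } else {
    counts <- sweep(counts, 2L, alpha, `*`)
  }
  out <- table
  out$counts <- counts
  if ("library_size" %in% names(out$samples)) {
    out$samples$library_size <- out$samples$library_size * alpha
  }
  out$calibrated <- any(factors$mode == "calibrated")
  out
}
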