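# Per-interval condition comparison and downstream per-site statistics.

#' Two-sample t-test kernel
#'
#' Two-sided two-sample t-test on replicate values. Welch (unequal variance)
#' by default; set `var_equal = TRUE` for the pooled-variance test. When both
#' groups have zero variance the test statistic is undefined: equal means
#' return `t = 0, p = 1` by convention, unequal means `t = +/-Inf, p = 0`.
#'
#' @param group_a,group_b Numeric vectors of replicate values (>= 2 each,
#'   finite).
#' @param var_equal Pool the variances?
#' @return A list with `t_stat`, `p_value`, `df`.
#' @export
two_sample_t <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(group_a)) || any(!is.finite(group_b))) {
    stop("group values must be finite", call. = FALSE)
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t_stat = 0, p_value = 1, df = NA_real_))
    }
    return(list(t_stat = sign(mean(group_a) - mean(group_b)) * Inf,
                p_value = 0, df = NA_real_))
  }
  ht <- t.test(group_a, group_b, var.equal = var_equal)
  list(t_stat = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

# Vectorised row-wise two-sample t over matching matrices (rows = intervals).
row_t_test <- function(a, b, var_equal) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t_stat <- (mb - ma) / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  # zero-variance-in-both conventions
  degenerate <- se == 0
  if (any(degenerate)) {
    same <- degenerate & (ma == mb)
    t_stat[same] <- 0; p[same] <- 1
    diff <- degenerate & (ma != mb)
    t_stat[diff] <- sign(mb - ma)[diff] * Inf; p[diff] <- 0
  }
  list(mean_a = ma, mean_b = mb, t_stat = t_stat, p_value = p, df = df)
}

#' Per-interval differential enrichment between two conditions
#'
#' Compares replicate NRPK (or RPKM) values interval-by-interval between two
#' conditions with a two-sample t-test and reports means, log2 fold change
#' (mean of replicates, with a pseudocount for stability at zero), raw
#' p-values and a significance call at `p < alpha`. Following the source
#' protocol for per-interval ChIP comparisons, no multiple-testing correction
#' is applied by default; set `p_adjust = "BH"` for Benjamini-Hochberg.
#'
#' The pooled-variance test (`var_equal = TRUE`) is the default here: with
#' the typical three replicates per condition and equal dispersion under the
#' null, it holds the nominal type-I error exactly, whereas Welch is
#' conservative at this sample size (empirical size ~0.035 at alpha = 0.05).
#'
#' @param table_a,table_b [signal_table()]s of replicate values for condition
#'   A (reference, e.g. UNT) and condition B (e.g. OHT); identical interval
#'   sets, >= 2 replicate columns each.
#' @param alpha Significance threshold on the (adjusted) p-value.
#' @param pseudocount Added to both means in the log2 ratio.
#' @param var_equal Pool variances (default) or Welch.
#' @param p_adjust Method passed to [stats::p.adjust()]; `"none"` by default.
#' @return A `diff_result` data frame: `interval_id`, `mean_a`, `mean_b`,
#'   `log2fc`, `t_stat`, `p_value`, `significant`, `direction`
#'   (`"up"`/`"down"`/`"none"`).
#' @seealso [assign_quartiles()], [erosion_groups()]
#' @export
differential_enrichment <- function(table_a, table_b, alpha = 0.05,
                                    pseudocount = 0.5, var_equal = TRUE,
                                    p_adjust = "none") {
  stopifnot(inherits(table_a, "signal_table"), inherits(table_b, "signal_table"))
  if (!identical(table_a$intervals$id, table_b$intervals$id)) {
    stop("interval ids of the two tables do not match", call. = FALSE)
  }
  if (ncol(table_a$counts) < 2L || ncol(table_b$counts) < 2L) {
    stop("need at least 2 replicates per condition", call. = FALSE)
  }
  check_scalar_number(alpha, "alpha", positive = TRUE)
  check_scalar_number(pseudocount, "pseudocount", min = 0)
  tt <- row_t_test(table_a$counts, table_b$counts, var_equal = var_equal)
  p <- p.adjust(tt$p_value, method = p_adjust)
  significant <- p < alpha
  direction <- rep("none", length(p))
  direction[significant & tt$mean_b > tt$mean_a] <- "up"
  direction[significant & tt$mean_b < tt$mean_a] <- "down"
  out <- data.frame(
    interval_id = table_a$intervals$id,
    mean_a = tt$mean_a, mean_b = tt$mean_b,
    log2fc = log2((tt$mean_b + pseudocount) / (tt$mean_a + pseudocount)),
    t_stat = tt$t_stat, p_value = p,
    significant = significant, direction = direction,
    stringsAsFactors = FALSE
  )
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Assign fold-change quartiles
#'
#' Ranks intervals ascending by `key` (most reduced first) and splits the
#' ranking into four contiguous groups whose sizes differ by at most one:
#' `Q1` holds the most-reduced quarter, `Q4` the least. Ties are broken by
#' interval id (lexicographic) so the partition is deterministic.
#'
#' @param results A `diff_result` data frame (>= 4 rows).
#' @param key Column to rank on (default `"log2fc"`).
#' @return `results` with an added `quartile` column (`"Q1"`..`"Q4"`).
#' @export
assign_quartiles <- function(results, key = "log2fc") {
  if (!is.data.frame(results) || !key %in% names(results)) {
    stop("'results' must be a data.frame containing column '", key, "'",
         call. = FALSE)
  }
  n <- nrow(results)
  if (n < 4L) stop("need at least 4 results to form quartiles", call. = FALSE)
  ord <- order(results[[key]], results$interval_id)
  sizes <- diff(floor(n * (0:4) / 4))
  q <- character(n)
  q[ord] <- rep(paste0("Q", 1:4), times = sizes)
  results$quartile <- q
  results
}

#' Per-interval enrichment ratio between two tracks
#'
#' Ratio of per-interval mean densities (e.g. RYBP relative to RING1B), with
#' a pseudocount on both sides.
#'
#' @param numerator,denominator [signal_table()]s over the same intervals.
#' @param pseudocount Stabilising constant added to both means.
#' @return Data frame with `interval_id` and `ratio`.
#' @export
enrichment_ratio <- function(numerator, denominator, pseudocount = 0.5) {
  stopifnot(inherits(numerator, "signal_table"),
            inherits(denominator, "signal_table"))
  if (!identical(numerator$intervals$id, denominator$intervals$id)) {
    stop("interval ids of the two tables do not match", call. = FALSE)
  }
  check_scalar_number(pseudocount, "pseudocount", min = 0)
  data.frame(
    interval_id = numerator$intervals$id,
    ratio = (rowMeans(numerator$counts) + pseudocount) /
      (rowMeans(denominator$counts) + pseudocount),
    stringsAsFactors = FALSE
  )
}

#' Erosion groups from joint occupancy loss
#'
#' Classifies each interval by whether it shows a significant *decrease* of
#' each of two occupancy marks (typically RING1B for PRC1 and SUZ12 for
#' PRC2): no significant loss of either, loss of the first only, loss of the
#' second only, or loss of both. "Loss" means `significant` and
#' `mean_b < mean_a`. The four labels are mutually exclusive and exhaustive.
#'
#' @param diff_a,diff_b `diff_result` data frames over the same interval
#'   universe (e.g. RING1B and SUZ12 differential results).
#' @param names Length-2 character vector naming the two marks, used to build
#'   the group labels.
#' @return Data frame with `interval_id`, `loss_a`, `loss_b` and `group` (a
#'   factor with levels `"No Sig Loss"`, `"Loss <A>"`, `"Loss <B>"`,
#'   `"Loss <A>+<B>"`).
#' @export
erosion_groups <- function(diff_a, diff_b, names = c("RING1B", "SUZ12")) {
  for (d in list(diff_a, diff_b)) {
    if (!is.data.frame(d) ||
        !all(c("interval_id", "mean_a", "mean_b", "significant") %in% base::names(d))) {
      stop("inputs must be diff_result data frames", call. = FALSE)
    }
  }
  if (!setequal(diff_a$interval_id, diff_b$interval_id) ||
      nrow(diff_a) != nrow(diff_b)) {
    stop("interval universes differ between the two inputs", call. = FALSE)
  }
  diff_b <- diff_b[match(diff_a$interval_id, diff_b$interval_id), ]
  loss_a <- diff_a$significant & diff_a$mean_b < diff_a$mean_a
  loss_b <- diff_b$significant & diff_b$mean_b < diff_b$mean_a
  levels <- c("No Sig Loss",
              paste("Loss", names[1]),
              paste("Loss", names[2]),
              paste0("Loss ", names[1], "+", names[2]))
  group <- factor(levels[1 + loss_a + 2 * loss_b], levels = levels)
  data.frame(interval_id = diff_a$interval_id,
             loss_a = loss_a, loss_b = loss_b, group = group,
             stringsAsFactors = FALSE)
}

#' Fold-change correlation and regression
#'
#' Pearson correlation and ordinary least squares of one per-interval log2FC
#' vector on another (e.g. H3K27me3 changes against H2AK119ub1 changes). The
#' coefficient of determination is computed from the regression sums of
#' squares; for simple OLS it equals the squared Pearson correlation.
#'
#' @param fc_x,fc_y Equal-length (>= 3) finite numeric vectors; `fc_y` is
#'   regressed on `fc_x`.
#' @return A list: `pearson_r`, `r_squared`, `slope`, `intercept`, `n`.
#' @export
fc_correlation <- function(fc_x, fc_y) {
  if (length(fc_x) != length(fc_y) || length(fc_x) < 3L) {
    stop("'fc_x' and 'fc_y' must have equal length >= 3", call. = FALSE)
  }
  if (any(!is.finite(fc_x)) || any(!is.finite(fc_y))) {
    stop("fold-change vectors must be finite", call. = FALSE)
  }
  if (var(fc_x) == 0) {
    stop("zero variance in 'fc_x': slope undefined", call. = FALSE)
  }
  fit <- lm(fc_y ~ fc_x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((fc_y - mean(fc_y))^2)
  list(pearson_r = cor(fc_x, fc_y),
       r_squared = 1 - ss_res / ss_tot,
       slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       n = length(fc_x))
}

#' Nonparametric two-group comparison
#'
#' Two-sided Wilcoxon test: signed-rank for paired vectors, rank-sum
#' (Mann-Whitney) otherwise. All paired differences equal to zero return
#' `p = 1` by convention (no evidence of a shift).
#'
#' @param values_a,values_b Numeric vectors; equal lengths when `paired`.
#' @param paired Paired comparison?
#' @return The two-sided p-value.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  if (paired && length(values_a) != length(values_b)) {
    stop("paired comparison requires equal lengths", call. = FALSE)
  }
  if (paired && all(values_a - values_b == 0)) return(1)
  suppressWarnings(
    wilcox.test(values_a, values_b, paired = paired, exact = NULL)$p.value
  )
}
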