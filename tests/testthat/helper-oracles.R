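# Independent brute-force oracles and small fixture builders used across the
# test files. Each oracle deliberately avoids the code path it checks.

# O(n^2) pairwise merge-to-fixpoint; returns sorted chrom/start/end only.
brute_merge <- function(intervals, max_gap) {
  iv <- intervals[c("chrom", "start", "end")]
  repeat {
    merged <- FALSE
    i <- 1L
    while (i <= nrow(iv) && !merged) {
      j <- 1L
      while (j <= nrow(iv) && !merged) {
        if (i != j && iv$chrom[i] == iv$chrom[j]) {
          gap <- max(iv$start[i], iv$start[j]) - min(iv$end[i], iv$end[j])
          if (gap < max_gap) {  # overlap gives negative gap: always merge
            iv$start[i] <- min(iv$start[i], iv$start[j])
            iv$end[i] <- max(iv$end[i], iv$end[j])
            iv <- iv[-j, , drop = FALSE]
            merged <- TRUE
          }
        }
        j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

# All-pairs >= 1 bp overlap counting.
brute_count <- function(fragments, intervals) {
  vapply(seq_len(nrow(intervals)), function(i) {
    sum(fragments$chrom == intervals$chrom[i] &
          pmin(fragments$end, intervals$end[i]) -
          pmax(fragments$start, intervals$start[i]) > 0)
  }, numeric(1))
}

# Hand-coded Welch / pooled two-sample t from the textbook formulas.
t_oracle <- function(a, b, var_equal = FALSE) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign vectors.
signrank_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_ge <- mean(vs >= v)
  p_le <- mean(vs <= v)
  if (v > n * (n + 1) / 4) min(1, 2 * p_ge) else min(1, 2 * p_le)
}

# Exact two-sided rank-sum p by enumerating all choose(n+m, n) labellings.
ranksum_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- combn(n + m, n)
  ws <- apply(combos, 2L, function(idx) sum(r[idx])) - n * (n + 1) / 2
  p_ge <- mean(ws >= w)
  p_le <- mean(ws <= w)
  if (w > n * m / 2) min(1, 2 * p_ge) else min(1, 2 * p_le)
}

# Pearson r and OLS slope/intercept from explicit sums of squares.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(r = sxy / sqrt(sxx * syy), slope = slope,
       intercept = mean(y) - slope * mean(x))
}

# Small signal-table fixture over shared intervals.
make_table <- function(counts, calibrated = FALSE, len = 1000,
                       samples = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  iv <- data.frame(chrom = "chr1",
                   start = seq_len(n) * 10000,
                   end = seq_len(n) * 10000 + len,
                   id = sprintf("iv_%03d", seq_len(n)))
  signal_table(counts, iv, samples = samples, calibrated = calibrated)
}

# Run the calibrated differential pipeline on a simulate_experiment() output.
run_calibrated_diff <- function(sim, seed = 1L, mode = "random", ...) {
  sf <- compute_scale_factors(sim$libraries)
  cal <- downsample_counts(sim$counts, sf, seed = seed, mode = mode)
  parts <- split_by_condition(nrpk(cal))
  differential_enrichment(parts[[1L]], parts[[2L]], ...)
}

random_intervals <- function(n, n_chrom = 2, max_pos = 50000, max_len = 3000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             id = sprintf("r%03d", seq_len(n)))
}
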