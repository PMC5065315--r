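test_that("identical groups give t = 0, p = 1", {
  res <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  # constant but equal groups: zero-variance convention
  res2 <- two_sample_t(c(2, 2, 2), c(2, 2))
  expect_equal(res2$p_value, 1)
  # constant, different means
  res3 <- two_sample_t(c(2, 2), c(5, 5))
  expect_equal(res3$p_value, 0)
  expect_true(is.infinite(res3$t_stat))
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("Welch and pooled t match the textbook formulas on random cases", {
  set.seed(71)
  for (i in 1:100) {
    a <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    for (ve in c(FALSE, TRUE)) {
      got <- two_sample_t(a, b, var_equal = ve)
      want <- t_oracle(a, b, var_equal = ve)
      expect_equal(got$t_stat, want$t, tolerance = 1e-12)
      expect_equal(got$p_value, want$p, tolerance = 1e-12)
    }
  }
  # the known worked case
  got <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  want <- t_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$t_stat, want$t, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
})

test_that("the vectorised per-interval test agrees with the scalar kernel", {
  set.seed(72)
  a <- matrix(rnorm(60, 10, 2), 20, 3)
  b <- matrix(rnorm(60, 9, 3), 20, 3)
  ta <- make_table(abs(a), calibrated = TRUE)
  tb <- make_table(abs(b), calibrated = TRUE)
  for (ve in c(TRUE, FALSE)) {
    d <- differential_enrichment(ta, tb, var_equal = ve)
    for (i in c(1L, 7L, 20L)) {
      want <- two_sample_t(ta$counts[i, ], tb$counts[i, ], var_equal = ve)
      expect_equal(d$t_stat[i], -want$t_stat, tolerance = 1e-12)
      expect_equal(d$p_value[i], want$p_value, tolerance = 1e-12)
    }
  }
})

test_that("exact doubling with no noise gives log2fc = 1 everywhere", {
  counts <- matrix(rep(c(10, 40, 99.5), 3), 3, 3)
  ta <- make_table(counts, calibrated = TRUE)
  tb <- make_table(2 * counts + 0.5, calibrated = TRUE)  # (2c+0.5+0.5)=2(c+0.5)
  d <- differential_enrichment(ta, tb, pseudocount = 0.5)
  expect_equal(d$log2fc, rep(1, 3))
})

test_that("swapping condition labels negates log2fc and preserves p-values", {
  set.seed(73)
  ta <- make_table(matrix(rpois(30, 50), 10, 3), calibrated = TRUE)
  tb <- make_table(matrix(rpois(30, 30), 10, 3), calibrated = TRUE)
  d1 <- differential_enrichment(ta, tb)
  d2 <- differential_enrichment(tb, ta)
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$p_value, d2$p_value)
  expect_equal(d1$t_stat, -d2$t_stat)
})

test_that("mismatched interval sets are refused", {
  ta <- make_table(matrix(1:6, 3, 2), calibrated = TRUE)
  tb <- make_table(matrix(1:4, 2, 2), calibrated = TRUE)
  expect_error(differential_enrichment(ta, tb), "interval ids")
})

test_that("quartiles partition ranked fold changes deterministically", {
  d <- data.frame(interval_id = letters[1:8], log2fc = c(-3, -2, -1, 0, 1, 2, 3, 4))
  q <- assign_quartiles(d)
  expect_equal(unname(table(q$quartile)), rep(2L, 4), ignore_attr = TRUE)
  expect_setequal(q$interval_id[q$quartile == "Q1"], c("a", "b"))
  expect_setequal(q$interval_id[q$quartile == "Q4"], c("g", "h"))
  # all-tied values split purely by id
  d2 <- data.frame(interval_id = letters[8:1], log2fc = 0)
  q2 <- assign_quartiles(d2)
  expect_setequal(q2$interval_id[q2$quartile == "Q1"], c("a", "b"))
  expect_error(assign_quartiles(d[1:3, ]), "at least 4")
})

test_that("quartile sizes at n = 2407 are 601/602/602/602 and cover all", {
  set.seed(74)
  d <- data.frame(interval_id = sprintf("iv%04d", 1:2407),
                  log2fc = rnorm(2407))
  q <- assign_quartiles(d)
  expect_equal(sort(unname(table(q$quartile))), c(601L, 602L, 602L, 602L),
               ignore_attr = TRUE)
  expect_identical(sum(table(q$quartile)), 2407L)
  # Q1 holds the most reduced intervals
  expect_lt(mean(q$log2fc[q$quartile == "Q1"]),
            mean(q$log2fc[q$quartile == "Q4"]))
})

test_that("enrichment ratios respond proportionally to the numerator", {
  set.seed(75)
  counts <- matrix(rpois(30, 100), 10, 3)
  num <- make_table(counts, calibrated = TRUE)
  den <- make_table(counts, calibrated = TRUE)
  expect_equal(enrichment_ratio(num, den)$ratio, rep(1, 10))
  num2 <- make_table(2 * counts + 0.5, calibrated = TRUE)
  expect_equal(enrichment_ratio(num2, den)$ratio, rep(2, 10))
})

test_that("erosion groups reproduce the 2x2 contingency of loss flags", {
  set.seed(76)
  n <- 1000
  mk <- function(sig, down) data.frame(
    interval_id = sprintf("iv%04d", 1:n),
    mean_a = 10, mean_b = ifelse(down, 5, 15),
    significant = sig, stringsAsFactors = FALSE)
  sig_r <- runif(n) < 0.4; down_r <- runif(n) < 0.7
  sig_s <- runif(n) < 0.3; down_s <- runif(n) < 0.6
  eg <- erosion_groups(mk(sig_r, down_r), mk(sig_s, down_s))
  loss_r <- sig_r & down_r
  loss_s <- sig_s & down_s
  want <- table(loss_r, loss_s)
  got <- table(eg$group)
  expect_equal(unname(got[["No Sig Loss"]]), unname(want["FALSE", "FALSE"]))
  expect_equal(unname(got[["Loss RING1B"]]), unname(want["TRUE", "FALSE"]))
  expect_equal(unname(got[["Loss SUZ12"]]), unname(want["FALSE", "TRUE"]))
  expect_equal(unname(got[["Loss RING1B+SUZ12"]]), unname(want["TRUE", "TRUE"]))
  expect_identical(sum(got), as.integer(n))  # exhaustive and exclusive
})

test_that("erosion grouping handles the trivial flag combinations", {
  one <- function(sig, down) data.frame(
    interval_id = "iv1", mean_a = 10, mean_b = if (down) 4 else 12,
    significant = sig, stringsAsFactors = FALSE)
  expect_equal(as.character(erosion_groups(one(FALSE, TRUE),
                                           one(FALSE, TRUE))$group),
               "No Sig Loss")
  expect_equal(as.character(erosion_groups(one(TRUE, TRUE),
                                           one(TRUE, TRUE))$group),
               "Loss RING1B+SUZ12")
  # significant increase is not a loss
  expect_equal(as.character(erosion_groups(one(TRUE, FALSE),
                                           one(FALSE, TRUE))$group),
               "No Sig Loss")
  expect_error(erosion_groups(one(TRUE, TRUE)[0, ], one(TRUE, TRUE)),
               "universe")
})

test_that("fold-change correlation recovers exact linear relations", {
  x <- c(-2, -1, 0, 1, 2, 3)
  r <- fc_correlation(x, 2 * x)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_error(fc_correlation(rep(1, 5), rnorm(5)), "variance")
})

test_that("correlation and regression match explicit sums of squares", {
  set.seed(77)
  for (i in 1:50) {
    x <- rnorm(sample(5:50, 1))
    y <- 0.5 * x + rnorm(length(x))
    got <- fc_correlation(x, y)
    want <- ols_oracle(x, y)
    expect_equal(got$pearson_r, want$r, tolerance = 1e-10)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r^2, tolerance = 1e-12)
  }
})

test_that("r-squared from residuals equals squared Pearson r", {
  set.seed(78)
  x <- rnorm(1000); y <- rnorm(1000)
  r <- fc_correlation(x, y)
  expect_equal(r$r_squared, r$pearson_r^2, tolerance = 1e-12)
})

test_that("nonparametric comparisons follow the stated conventions", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3), paired = TRUE), 1)
  p <- compare_groups(rnorm(50), rnorm(50) + 5)
  expect_lt(p, 1e-6)
  expect_error(compare_groups(1:3, 1:4, paired = TRUE), "equal lengths")
})

test_that("signed-rank and rank-sum p-values match exact enumeration", {
  set.seed(79)
  for (i in 1:50) {
    x <- runif(8); y <- runif(8)
    expect_equal(compare_groups(x, y, paired = TRUE), signrank_oracle(x, y),
                 tolerance = 1e-10)
  }
  for (i in 1:50) {
    x <- runif(sample(4:6, 1)); y <- runif(sample(4:6, 1))
    expect_equal(compare_groups(x, y), ranksum_oracle(x, y),
                 tolerance = 1e-10)
  }
})
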