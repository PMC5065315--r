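test_that("peaks closer than the gap threshold merge; others do not", {
  iv <- data.frame(chrom = "chr1", start = c(0, 4000), end = c(100, 4100),
                   id = c("a", "b"))
  m <- merge_intervals(iv, max_gap = 5000)  # gap 3900 < 5 kb
  expect_identical(nrow(m), 1L)
  expect_identical(m$start, 0L)
  expect_identical(m$end, 4100L)
  expect_identical(m$id, "a,b")
  # different chromosomes never merge
  iv2 <- data.frame(chrom = c("chr1", "chr2"), start = 0, end = 100,
                    id = c("a", "b"))
  expect_identical(nrow(merge_intervals(iv2, max_gap = 1e6)), 2L)
})

test_that("merging is transitive and ids concatenate in coordinate order", {
  iv <- data.frame(chrom = "chr1", start = c(9000, 0, 4500),
                   end = c(9100, 100, 4600),
                   id = c("c", "a", "b"))
  m <- merge_intervals(iv, max_gap = 5000)
  expect_identical(nrow(m), 1L)
  expect_identical(m$id, "a,b,c")
})

test_that("merge matches a brute-force pairwise fixpoint on random intervals", {
  set.seed(61)
  for (rep in 1:5) {
    iv <- random_intervals(200)
    for (gap in c(0, 500, 5000)) {
      got <- merge_intervals(iv, max_gap = gap)
      want <- brute_merge(iv, max_gap = gap)
      expect_equal(got[c("chrom", "start", "end")], want,
                   ignore_attr = TRUE)
    }
  }
})

test_that("merging is idempotent", {
  set.seed(62)
  iv <- random_intervals(150)
  once <- merge_intervals(iv, max_gap = 2000)
  twice <- merge_intervals(once, max_gap = 2000)
  expect_equal(once[c("chrom", "start", "end")],
               twice[c("chrom", "start", "end")], ignore_attr = TRUE)
})

test_that("malformed intervals are rejected", {
  expect_error(merge_intervals(
    data.frame(chrom = "chr1", start = 100, end = 100, id = "x"), 10),
    "start >= end")
  expect_error(merge_intervals(
    data.frame(chrom = "chr1", start = 0, end = 10, id = "x"), -1), "max_gap")
})

test_that("fragments count by >= 1 bp overlap with half-open boundaries", {
  iv <- data.frame(chrom = "chr1", start = 100, end = 200, id = "iv1")
  # 50 bp overlap counts once
  t1 <- count_fragments(data.frame(chrom = "chr1", start = 50, end = 150), iv)
  expect_equal(unname(t1$counts[1, 1]), 1)
  # half-open abutment does not overlap
  t2 <- count_fragments(data.frame(chrom = "chr1", start = 0, end = 100), iv)
  expect_equal(unname(t2$counts[1, 1]), 0)
})

test_that("fragment counting matches the all-pairs oracle", {
  set.seed(63)
  iv <- merge_intervals(random_intervals(50), max_gap = 0)
  fr <- random_intervals(1000, max_len = 400)
  fr$sample <- sample(c("s1", "s2"), 1000, replace = TRUE)
  tab <- count_fragments(fr, iv)
  for (s in c("s1", "s2")) {
    expect_equal(unname(tab$counts[, s]),
                 brute_count(fr[fr$sample == s, ], iv))
  }
  expect_equal(unname(tab$samples$library_size),
               unname(as.numeric(table(fr$sample)[tab$samples$sample_id])))
})

test_that("counting refuses overlapping intervals", {
  iv <- data.frame(chrom = "chr1", start = c(0, 50), end = c(100, 150),
                   id = c("a", "b"))
  expect_error(count_fragments(data.frame(chrom = "chr1", start = 0, end = 10),
                               iv), "merge")
})

test_that("count conservation holds when intervals tile the fragment span", {
  iv <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                   end = c(100, 200, 300), id = c("a", "b", "c"))
  set.seed(64)
  # point-like fragments fully inside the tiling: each counted exactly once
  st <- sample(0:298, 200, replace = TRUE)
  fr <- data.frame(chrom = "chr1", start = st, end = st + 1)
  tab <- count_fragments(fr, iv)
  expect_equal(sum(tab$counts), 200)
})

test_that("NRPK is calibrated count per kb and refuses uncalibrated tables", {
  tab <- make_table(matrix(c(50, 0), 2, 1), calibrated = TRUE, len = 2000)
  out <- nrpk(tab)
  expect_equal(unname(out$counts[, 1]), c(25, 0))
  expect_identical(out$units, "NRPK")
  raw <- make_table(matrix(50, 1, 1), calibrated = FALSE)
  expect_error(nrpk(raw), "rpkm|calibrat")
  # doubling length at fixed count halves NRPK
  tab2 <- make_table(matrix(50, 1, 1), calibrated = TRUE, len = 4000)
  expect_equal(unname(nrpk(tab2)$counts[1, 1]), 12.5)
})

test_that("RPKM normalises by length and library size", {
  tab <- make_table(matrix(100, 1, 1), len = 1000,
                    samples = data.frame(sample_id = "s1", library_size = 1e6))
  expect_equal(unname(rpkm(tab)$counts[1, 1]), 100)
  tab$samples$library_size <- 2e6
  expect_equal(unname(rpkm(tab)$counts[1, 1]), 50)
  tab$samples$library_size <- 0
  expect_error(rpkm(tab), "library size")
})

test_that("RPKM times library-size-per-million equals per-kb density", {
  set.seed(65)
  counts <- matrix(rpois(30, 40), 10, 3)
  tab <- make_table(counts, len = 500,
                    samples = data.frame(sample_id = paste0("s", 1:3),
                                         library_size = c(1e6, 2e6, 5e5)))
  r <- rpkm(tab)
  back <- sweep(r$counts, 2L, tab$samples$library_size / 1e6, `*`)
  expect_equal(back, counts / 0.5, ignore_attr = TRUE)
})

test_that("NRPK and RPKM are linear in counts", {
  counts <- matrix(c(1, 5, 10), 3, 1)
  tab <- make_table(counts, calibrated = TRUE,
                    samples = data.frame(sample_id = "s1", library_size = 1e6))
  expect_equal(nrpk(make_table(3 * counts, calibrated = TRUE,
                               samples = tab$samples))$counts,
               3 * nrpk(tab)$counts)
  expect_equal(rpkm(make_table(3 * counts,
                               samples = tab$samples))$counts,
               3 * rpkm(tab)$counts)
})

test_that("profile matrices average windows and drop out-of-contig sites", {
  cov <- list(chr1 = rep(1, 5000))
  sites <- data.frame(chrom = "chr1", start = c(2000, 100),
                      end = c(2400, 200), id = c("mid", "edge"))
  expect_warning(
    pm <- profile_matrix(cov, sites, half_width = 1000, bins = 10),
    "dropped")
  expect_identical(rownames(pm), "mid")
  expect_true(all(pm == 1))
  expect_true(all(metaplot(pm) == 1))
})

test_that("a single site's metaplot is its own profile", {
  cov <- list(chr1 = seq_len(4000) / 1000)
  site <- data.frame(chrom = "chr1", start = 1800, end = 2200, id = "s")
  pm <- profile_matrix(cov, site, half_width = 500, bins = 5)
  expect_equal(metaplot(pm), pm[1, ])
})

test_that("a triangular peak centred on every site peaks in the central bin", {
  n_sites <- 100
  half <- 500L
  peak <- c(seq_len(half), rev(seq_len(half)))  # triangle over 1 kb
  cov_len <- 200000L
  set.seed(66)
  centres <- sample(seq(2000L, cov_len - 2000L, by = 7L), n_sites)
  cov <- numeric(cov_len)
  for (ct in centres) {
    idx <- (ct - half + 1L):(ct + half)
    cov[idx] <- cov[idx] + peak
  }
  sites <- data.frame(chrom = "chr1", start = centres - 50L,
                      end = centres + 50L, id = sprintf("s%03d", 1:n_sites))
  pm <- profile_matrix(list(chr1 = cov), sites, half_width = 1000, bins = 25)
  mp <- metaplot(pm)
  expect_identical(unname(which.max(mp)), 13L)  # odd bin count: apex centred
})

test_that("window geometry is validated", {
  cov <- list(chr1 = rep(1, 1000))
  site <- data.frame(chrom = "chr1", start = 400, end = 600, id = "s")
  expect_error(profile_matrix(cov, site, half_width = 100, bins = 3), "divide")
})
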