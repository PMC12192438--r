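test_that("q2q3 matches hand-computed trimmed means", {
  expect_equal(q2q3(rep(7, 8)), 7)
  # L = 8, k = 2: keep sorted ranks 3..6
  expect_equal(q2q3(c(0, 0, 1, 2, 3, 10, 50, 100)), 4.0)
  # two covered positions on a 10 bp contig: every kept rank is zero
  d <- numeric(10); d[c(2, 9)] <- 9
  expect_equal(q2q3(d), 0)
  # short contigs fall back to the plain mean
  expect_equal(q2q3(c(1, 5)), 3)
  expect_equal(q2q3(4), 4)
})

test_that("q2q3 rejects degenerate input", {
  expect_error(q2q3(numeric(0)), "empty")
  expect_error(q2q3(c(1, -2, 3)), "non-negative")
  expect_error(q2q3(c(1, NA)), "non-negative|missing")
})

test_that("q2q3 is scale-equivariant and bounded by the depth range", {
  set.seed(42)
  for (i in 1:50) {
    L <- sample(1:400, 1)
    d <- rpois(L, lambda = sample(c(0.2, 2, 20), 1))
    q <- q2q3(d)
    expect_gte(q, min(d))
    expect_lte(q, max(d))
    c0 <- runif(1, 0, 5)
    expect_equal(q2q3(c0 * d), c0 * q)
  }
})

test_that("detection requires breadth above a quarter of the contig", {
  # depth-1 coverage on L = 100: floor(L/4) = 25 covered positions is the
  # last undetected breadth
  d25 <- numeric(100); d25[1:25] <- 1
  d26 <- numeric(100); d26[1:26] <- 1
  expect_equal(q2q3(d25), 0)
  expect_gt(q2q3(d26), 0)
  # property over random positive-depth patterns
  set.seed(99)
  for (i in 1:30) {
    L <- sample(8:200, 1)
    ncov <- sample(0:L, 1)
    d <- numeric(L)
    if (ncov > 0) d[sample(L, ncov)] <- sample(1:50, ncov, replace = TRUE)
    expect_identical(q2q3(d) > 0, ncov > floor(L / 4))
  }
})

test_that("normalization contracts hold and preserve the zero pattern", {
  set.seed(3)
  m <- matrix(rexp(60), nrow = 10)
  m[m < 0.3] <- 0
  m[, 4] <- 0  # an all-zero sample column
  tab <- tab_from_matrix(m)
  s1 <- normalize_coverage(tab, "sum_to_one")
  expect_false(anyNA(s1$values))
  nz <- colSums(m) > 0
  expect_equal(colSums(s1$values)[nz], rep(1, sum(nz)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(s1$values[, !nz] == 0))
  mx <- normalize_coverage(tab, "max_of_sample")
  expect_equal(apply(mx$values, 2, max)[nz], rep(1, sum(nz)),
               ignore_attr = TRUE)
  expect_true(all(mx$values[, !nz] == 0))
  # zero pattern, hence detection, unchanged
  expect_identical(s1$values > 0, detect_coverage(tab))
  expect_identical(mx$values > 0, detect_coverage(tab))
  # explicit vectors
  expect_equal(normalize_coverage(tab_from_matrix(matrix(c(2, 3, 5), 3)),
                                  "sum_to_one")$values[, 1],
               c(0.2, 0.3, 0.5), ignore_attr = TRUE)
  expect_equal(normalize_coverage(tab_from_matrix(matrix(c(2, 4, 8), 3)),
                                  "max_of_sample")$values[, 1],
               c(0.25, 0.5, 1.0), ignore_attr = TRUE)
})

test_that("normalizing an already-normalized table is refused", {
  tab <- tab_from_matrix(matrix(1:4, 2))
  s1 <- normalize_coverage(tab, "sum_to_one")
  expect_error(normalize_coverage(s1, "max_of_sample"), "raw")
  expect_error(detect_coverage(s1), "raw")
})

test_that("coverage_table zero-fills omitted positions and validates rows", {
  dir <- withr::local_tempdir()
  catalog <- data.frame(contig_id = c("cA", "cB", "cC"),
                        length_bp = c(8L, 10L, 6L))
  # cA fully covered at 3; cB covered at 2 positions only; cC absent
  writeLines(c(paste("cA", 1:8, 3, sep = "\t"),
               paste("cB", c(2, 9), 9, sep = "\t")),
             file.path(dir, "s1.depth.tsv"))
  file.create(file.path(dir, "s2.depth.tsv"))  # empty sample
  files <- c(s1 = file.path(dir, "s1.depth.tsv"),
             s2 = file.path(dir, "s2.depth.tsv"))
  tab <- coverage_table(files, catalog)
  expect_equal(tab$values["cA", "s1"], 3)
  expect_equal(tab$values["cB", "s1"], 0)  # breadth 2/10 trims to zero
  expect_equal(tab$values["cC", "s1"], 0)
  expect_true(all(tab$values[, "s2"] == 0))
  # a position beyond the contig length is a named input error
  writeLines("cC\t7\t1", file.path(dir, "bad.depth.tsv"))
  expect_error(coverage_table(c(bad = file.path(dir, "bad.depth.tsv")), catalog),
               "position 7")
  writeLines("unknown\t1\t1", file.path(dir, "unk.depth.tsv"))
  expect_error(coverage_table(c(unk = file.path(dir, "unk.depth.tsv")), catalog),
               "not in catalog")
})

test_that("fraction_reads_mapped computes percentages and validates counts", {
  md <- toy_metadata(c("a", "b", "c"), c(5, 25, 45), rep("planktonic", 3))
  md$total_reads <- c(1e6, 2e6, 1e4)
  md$mapped_reads <- c(5e3, 0, 1e4)
  out <- fraction_reads_mapped(md)
  expect_equal(out$pct_mapped, c(0.5, 0, 100))
  md$mapped_reads[1] <- 2e6
  expect_error(fraction_reads_mapped(md), "exceeds")
})
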