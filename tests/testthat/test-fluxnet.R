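# Build a response vector with an exact Pearson correlation r to x.
vector_with_cor <- function(x, r, seed = 1) {
  set.seed(seed)
  e <- rnorm(length(x))
  e <- residuals(lm(e ~ x))
  xs <- as.numeric(scale(x))
  es <- as.numeric(scale(e))
  r * xs + sqrt(1 - r^2) * es
}

trap_flux <- function(vals) {
  data.frame(sample_id = colnames(vals), flux = seq_len(ncol(vals)) + 0,
             stringsAsFactors = FALSE)
}

test_that("gene_significance reproduces the t-distribution p-value", {
  f <- 1:10 + rnorm(10, 0, 0.1)
  set.seed(2); f <- sample(f)
  y <- vector_with_cor(f, 0.632)
  m <- matrix(pmax(y - min(y) + 0.1, 0), nrow = 1,
              dimnames = list("c1", sprintf("t%02d", 1:10)))
  # shift to non-negative preserves the correlation
  fl <- data.frame(sample_id = colnames(m), flux = f)
  gs <- gene_significance(coverage_table_new(m, "raw"), fl)
  expect_equal(gs$r, 0.632, tolerance = 1e-12)
  t_expect <- 0.632 * sqrt(8) / sqrt(1 - 0.632^2)
  expect_equal(gs$p, 2 * pt(-t_expect, 8), tolerance = 1e-12)
  expect_equal(gs$p, 0.05, tolerance = 1e-3)
})

test_that("gene_significance flags degenerate rows and exact collinearity", {
  m <- rbind(c1 = c(1, 2, 3, 4, 5),
             c2 = rep(2, 5),
             c3 = c(5, 4, 3, 2, 1))
  colnames(m) <- sprintf("t%d", 1:5)
  fl <- data.frame(sample_id = colnames(m), flux = c(1, 2, 3, 4, 5))
  gs <- gene_significance(coverage_table_new(m, "raw"), fl)
  expect_equal(gs$r[1], 1)
  expect_lt(gs$p[1], 1e-10)
  expect_true(gs$flagged_constant[2])
  expect_true(is.na(gs$r[2]))
  expect_equal(gs$r[3], -1)
  # flagged rows are never selected
  expect_false("c2" %in% select_flux_correlated(gs))
  # negative correlation excluded by the positive-only rule
  expect_false("c3" %in% select_flux_correlated(gs))
  expect_true("c1" %in% select_flux_correlated(gs))
  # fewer than 4 paired samples is an input error
  expect_error(gene_significance(
    coverage_table_new(m[, 1:3], "raw"),
    fl[1:3, ]), "at least 4")
})

test_that("gene_significance p agrees with a permutation null", {
  set.seed(10)
  f <- rnorm(10)
  y <- vector_with_cor(f, 0.632, seed = 3)
  m <- matrix(y - min(y) + 0.1, nrow = 1,
              dimnames = list("c1", sprintf("t%02d", 1:10)))
  fl <- data.frame(sample_id = colnames(m), flux = f)
  gs <- gene_significance(coverage_table_new(m, "raw"), fl)
  r_obs <- abs(gs$r)
  B <- 2000
  set.seed(77)
  r_perm <- replicate(B, abs(cor(m[1, ], sample(f))))
  p_perm <- (1 + sum(r_perm >= r_obs)) / (B + 1)
  expect_lt(abs(p_perm - gs$p), 0.02)
})

test_that("selection is nested in alpha and respects BH correction", {
  set.seed(20)
  n <- 12
  m <- matrix(rexp(40 * n), nrow = 40,
              dimnames = list(sprintf("c%02d", 1:40), sprintf("t%02d", 1:n)))
  fl <- trap_flux(m)
  gs <- gene_significance(coverage_table_new(m, "raw"), fl)
  prev <- select_flux_correlated(gs, alpha = 0.2)
  for (a in c(0.1, 0.05, 0.01)) {
    cur <- select_flux_correlated(gs, alpha = a)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # BH-adjusted selection is a subset of the raw selection
  raw <- select_flux_correlated(gs, alpha = 0.1)
  bh <- select_flux_correlated(gs, alpha = 0.1, bh_correction = TRUE)
  expect_true(all(bh %in% raw))
})

test_that("build_modules recovers a planted two-block structure", {
  set.seed(30)
  n <- 20
  base1 <- rexp(n); base2 <- rexp(n)
  mk_block <- function(base, k, pref) {
    out <- t(sapply(seq_len(k), function(i) base * (0.5 + 0.3 * i)))
    rownames(out) <- sprintf("%s%02d", pref, seq_len(k))
    out
  }
  m <- rbind(mk_block(base1, 6, "a"), mk_block(base2, 6, "b"))
  colnames(m) <- sprintf("t%02d", seq_len(n))
  tab <- coverage_table_new(m, "raw")
  mod <- build_modules(tab, beta = 6, min_module_size = 5, cut_height = 0.25)
  asg <- setNames(mod$assignments$module, mod$assignments$contig_id)
  expect_equal(length(unique(asg)), 2L)
  expect_equal(length(unique(asg[sprintf("a%02d", 1:6)])), 1L)
  expect_equal(length(unique(asg[sprintf("b%02d", 1:6)])), 1L)
  expect_false(unique(asg[sprintf("a%02d", 1:6)]) ==
                 unique(asg[sprintf("b%02d", 1:6)]))

  # labels invariant to row order
  perm <- sample(nrow(m))
  mod2 <- build_modules(coverage_table_new(m[perm, ], "raw"),
                        beta = 6, min_module_size = 5, cut_height = 0.25)
  asg2 <- setNames(mod2$assignments$module, mod2$assignments$contig_id)
  expect_identical(asg2[names(asg)], asg)

  # eigengene sign orientation: positively correlated with its members
  for (lab in colnames(mod$eigengenes)) {
    members <- mod$assignments$contig_id[mod$assignments$module == lab]
    cors <- cor(mod$eigengenes[, lab], t(m[members, ]))
    expect_gt(mean(cors), 0)
  }
})

test_that("beta = 1 adjacency for two contigs equals |r|", {
  set.seed(31)
  m <- matrix(rexp(16), nrow = 2,
              dimnames = list(c("c1", "c2"), sprintf("t%d", 1:8)))
  r <- abs(cor(m[1, ], m[2, ]))
  # with two contigs there is one off-diagonal adjacency; verify through the
  # TOM identity at beta = 1: diss(1,2) = 1 - (a + a)/(a + 1 - a) = 1 - 2a/(1)
  # easier: check the clustering height equals 1 - TOM computed by hand
  A <- r
  tom <- (0 + A) / (min(A, A) + 1 - A)
  mod <- build_modules(coverage_table_new(m, "raw"), beta = 1,
                       min_module_size = 1, cut_height = 1.01)
  expect_equal(sort(unique(mod$assignments$module)), "M1")
  expect_true(is.finite(tom))
})

test_that("module eigengene is the best single summary of its members", {
  set.seed(32)
  n <- 15
  base <- rexp(n)
  m <- t(sapply(1:6, function(i) pmax(base * runif(1, 0.5, 2) +
                                        rnorm(n, 0, 0.05), 0.01)))
  rownames(m) <- sprintf("c%02d", 1:6)
  colnames(m) <- sprintf("t%02d", 1:n)
  mod <- build_modules(coverage_table_new(m, "raw"), min_module_size = 5,
                       cut_height = 0.9)
  e <- mod$eigengenes[, 1]
  xm <- scale(t(m))
  ss_e <- sum((t(xm) %*% (e / sqrt(sum(e^2))))^2)
  for (i in 1:20) {
    u <- rnorm(n); u <- u / sqrt(sum(u^2))
    expect_gte(ss_e + 1e-8, sum((t(xm) %*% u)^2))
  }
})

test_that("module gate restricts selection to flux-linked modules", {
  set.seed(33)
  n <- 16
  f <- rnorm(n)
  base_pos <- as.numeric(scale(f)) + 3        # tracks flux
  base_neg <- -as.numeric(scale(f)) + 3       # anti-tracks flux
  mk <- function(base, pref) {
    out <- t(sapply(1:6, function(i) pmax(base * (0.8 + 0.1 * i) +
                                            rnorm(n, 0, 0.05), 0.01)))
    rownames(out) <- sprintf("%s%02d", pref, 1:6); out
  }
  m <- rbind(mk(base_pos, "p"), mk(base_neg, "q"))
  colnames(m) <- sprintf("t%02d", 1:n)
  fl <- data.frame(sample_id = colnames(m), flux = f)
  tab <- coverage_table_new(m, "raw")
  gs <- gene_significance(tab, fl)
  mod <- build_modules(tab, fl, min_module_size = 5, cut_height = 0.25)
  gated <- select_flux_correlated(gs, mod, require_module_gate = TRUE)
  ungated <- select_flux_correlated(gs)
  expect_true(all(grepl("^p", gated)))
  expect_true(all(gated %in% ungated))
  expect_error(select_flux_correlated(gs, NULL, require_module_gate = TRUE),
               "module gate")
})
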