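# TMM normalization, common-dispersion estimation and the exact NB test,
# cross-checked against an independent implementation and brute-force
# oracles.

test_that("TMM factors are 1 for identical columns and compensate scaling", {
  set.seed(71)
  y <- rnbinom(500, mu = 100, size = 5) + 1L
  expect_equal(tmm_factors(cbind(y, y)), c(1, 1))
  # doubling every count in one sample is pure depth: factors stay 1 and
  # effective library sizes equalize the normalized counts
  f <- tmm_factors(cbind(a = y, b = 2L * y))
  expect_equal(f, c(1, 1), tolerance = 1e-12)
  norm1 <- y / (sum(y) * f[1])
  norm2 <- (2 * y) / (sum(2 * y) * f[2])
  expect_equal(norm1, norm2)
})

test_that("TMM factors agree with the reference implementation", {
  set.seed(72)
  for (i in 1:5) {
    m <- matrix(rnbinom(2000 * 4, mu = runif(2000, 5, 500), size = 3),
                ncol = 4)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    expect_equal(tmm_factors(m),
                 edgeR::calcNormFactors(m, method = "TMM"),
                 tolerance = 1e-6)
  }
  expect_error(tmm_factors(cbind(c(1, 2), c(0, 0))), "positive total")
})

test_that("common dispersion recovers Poisson and NB truths", {
  groups <- rep(c("a", "b"), each = 3)
  set.seed(73)
  m_pois <- matrix(rpois(2000 * 6, lambda = runif(2000, 20, 300)), ncol = 6)
  expect_lt(estimate_common_dispersion(m_pois, groups), 0.01)

  m_nb <- matrix(rnbinom(2000 * 6, mu = runif(2000, 20, 300), size = 1 / 0.2),
                 ncol = 6)
  phi <- estimate_common_dispersion(m_nb, groups)
  expect_gt(phi, 0.15)
  expect_lt(phi, 0.25)

  # invariance to gene order
  perm <- sample(nrow(m_nb))
  expect_equal(estimate_common_dispersion(m_nb[perm, ], groups), phi)

  expect_error(estimate_common_dispersion(m_nb[, c(1, 4)], c("a", "b")),
               "replication")
})

test_that("identical counts give p = 1 and all-zero genes are untested", {
  groups <- rep(c("a", "b"), each = 3)
  # balanced column totals so pseudo-counts equal raw counts under unit factors
  m <- rbind(g1 = rep(50L, 6),
             g2 = rep(0L, 6),
             g3 = c(10L, 12L, 9L, 40L, 44L, 38L),
             g4 = c(40L, 38L, 41L, 10L, 6L, 12L))
  res <- nb_exact_test(m, groups, "a", "b", phi = 0.1, factors = rep(1, 6))
  expect_equal(res$PValue[1], 1)
  expect_true(is.na(res$PValue[2]) && is.na(res$QValue[2]))
  expect_lt(res$PValue[3], 0.05)
  expect_gt(res$log2FC[3], 1)
})

test_that("swapping condition labels negates log2FC and keeps p-values", {
  set.seed(74)
  groups <- rep(c("a", "b"), each = 3)
  m <- matrix(rnbinom(500 * 6, mu = 150, size = 8), ncol = 6)
  rownames(m) <- sprintf("g%03d", 1:500)
  fwd <- nb_exact_test(m, groups, "a", "b", phi = 0.1)
  bwd <- nb_exact_test(m, groups, "b", "a", phi = 0.1)
  expect_equal(bwd$log2FC, -fwd$log2FC)
  expect_equal(bwd$PValue, fwd$PValue)
})

test_that("q-values equal a brute-force Benjamini-Hochberg computation", {
  set.seed(75)
  groups <- rep(c("a", "b"), each = 3)
  m <- matrix(rnbinom(800 * 6, mu = 120, size = 6), ncol = 6)
  res <- nb_exact_test(m, groups, phi = 0.15)
  tested <- !is.na(res$PValue)
  expect_equal(res$QValue[tested], oracle_bh(res$PValue[tested]))
})

test_that("the Poisson limit agrees with a conditional binomial test", {
  # at phi = 0 and one replicate per side, the conditional law of s1 given
  # the total is Binomial(t, 1/2); compare on hand-checkable pairs using
  # the same doubled-smaller-tail convention
  pairs <- list(c(3L, 10L), c(0L, 7L), c(12L, 12L), c(20L, 5L))
  for (pr in pairs) {
    # a mirrored second gene balances the column totals so the conditional
    # law is exactly Binomial(t, 1/2)
    m <- rbind(pr, rev(pr))
    res <- nb_exact_test(m, c("a", "b"), "a", "b", phi = 0,
                         factors = c(1, 1))
    t <- sum(pr)
    oracle <- min(1, 2 * min(pbinom(pr[1], t, 0.5),
                             1 - pbinom(pr[1] - 1L, t, 0.5)))
    expect_equal(res$PValue[1], oracle, tolerance = 1e-12,
                 label = paste(pr, collapse = ","))
  }
})

test_that("null simulation is calibrated and planted depletions are found", {
  groups <- rep(c("a", "b"), each = 3)
  set.seed(76)
  m <- matrix(rnbinom(2000 * 6, mu = 200, size = 1 / 0.1), ncol = 6)
  res <- nb_exact_test(m, groups)
  frac <- mean(res$PValue < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)

  set.seed(77)
  dep <- 1:100
  mu2 <- rep(200, 2000); mu2[dep] <- 25
  m1 <- matrix(rnbinom(2000 * 3, mu = 200, size = 10), ncol = 3)
  m2 <- matrix(rnbinom(2000 * 3, mu = mu2, size = 10), ncol = 3)
  res <- nb_exact_test(cbind(m1, m2), groups, "a", "b")
  expect_gte(mean(res$QValue[dep] < 0.05), 0.9)
})

test_that("comparisons run end-to-end from gene-statistics tables", {
  dir <- withr::local_tempdir()
  lib <- simulate_library(tiny_config(seed = 78), include_reads = FALSE)
  base <- lib$truth_gene_stats
  set.seed(79)
  paths <- character(0)
  for (s in 1:4) {
    tab <- base
    tab$read_count <- rnbinom(nrow(tab), mu = pmax(base$read_count, 1),
                              size = 10)
    p <- file.path(dir, sprintf("sample%d.tsv", s))
    write_gene_stats(tab, p)
    paths <- c(paths, p)
  }
  res <- compare_conditions(paths[1:2], paths[3:4])
  expect_equal(nrow(res), nrow(base))
  expect_equal(res$gene_id, base$locus_tag)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_comparison(res, out)
  back <- read.table(out, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  expect_equal(back$PValue, res$PValue)
})
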