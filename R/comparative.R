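## Between-condition fitness comparison: library-size normalization by
## trimmed mean of M-values (TMM), a single common negative-binomial
## dispersion estimated by conditional maximum likelihood on library-size-
## equalized pseudo-counts, and a per-gene exact NB test conditioned on the
## gene's total count, with Benjamini-Hochberg FDR control. The computation
## is self-contained (no runtime dependency on an external count-testing
## package); numerical agreement with the published TMM procedure is
## checked in the test suite against an independent implementation.

#' Build a count matrix from per-sample gene-statistics tables
#'
#' @param paths character vector of gene-statistics TSV paths (one sample
#'   each, as written by [write_gene_stats()]).
#' @param sample_names column names; default the file base names.
#' @param use which per-gene quantity to compare: mutant read counts
#'   (default) or unique insertion counts.
#' @return An integer matrix, genes x samples, with gene ids as row names.
#' @export
count_matrix_from_stats <- function(paths, sample_names = NULL,
                                    use = c("read_count", "ins_count")) {
  use <- match.arg(use)
  tabs <- lapply(paths, read_gene_stats)
  ids <- tabs[[1L]]$locus_tag
  for (t in tabs) {
    if (!identical(t$locus_tag, ids))
      stop("all gene-statistics tables must list the same genes in the same order")
  }
  m <- vapply(tabs, function(t) as.integer(t[[use]]), integer(length(ids)))
  rownames(m) <- ids
  colnames(m) <- sample_names %||% sub("\\.tsv$", "", basename(paths))
  m
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors (30% two-sided trim on the
#' log-ratios M, 5% on the average log-abundances A, inverse-variance
#' weights). The reference sample is the column whose 75th-percentile
#' count-per-library-size is closest to the mean across samples. Factors
#' are normalized so their geometric mean is 1.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return Numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("every sample must have a positive total count")
  f75 <- apply(counts, 2L, function(y) quantile(y, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref])
  }, numeric(1))
  f / exp(mean(log(f)))
}

# one sample against the reference; published TMM defaults
.tmm_pair <- function(obs, ref, n_obs, n_ref,
                      logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) /
    sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

# scale each column to the geometric-mean effective library size, giving
# (continuous) pseudo-counts comparable across samples
.pseudo_counts <- function(counts, factors) {
  lib <- colSums(counts)
  eff <- lib * factors
  geo <- exp(mean(log(eff)))
  list(pseudo = sweep(counts, 2L, geo / eff, `*`), geo_lib = geo)
}

#' Estimate the common negative-binomial dispersion
#'
#' Maximizes the conditional log-likelihood, summed over genes and over all
#' groups with at least two replicates, of the within-group pseudo-counts
#' given their group totals. A dispersion of (numerically) zero is the
#' Poisson limit.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param groups factor or character vector of condition labels, one per
#'   column.
#' @param factors TMM factors; computed with [tmm_factors()] if `NULL`.
#' @return The estimated common dispersion (phi >= 0).
#' @export
estimate_common_dispersion <- function(counts, groups, factors = NULL) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(counts))
  if (all(table(groups) < 2L))
    stop("no condition has replication: supply a dispersion value instead of estimating one")
  factors <- factors %||% tmm_factors(counts)
  pseudo <- .pseudo_counts(counts, factors)$pseudo
  cond_ll <- function(log_phi) {
    r <- exp(-log_phi)  # size = 1/phi
    total <- 0
    for (g in levels(groups)) {
      cols <- which(groups == g)
      n <- length(cols)
      if (n < 2L) next
      y <- pseudo[, cols, drop = FALSE]
      z <- rowSums(y)
      use <- z > 0
      total <- total + sum(rowSums(lgamma(y[use, , drop = FALSE] + r)) +
                             lgamma(n * r) - lgamma(z[use] + n * r) -
                             n * lgamma(r))
    }
    total
  }
  opt <- optimize(cond_ll, interval = c(log(1e-6), log(20)), maximum = TRUE,
                  tol = 1e-6)
  phi <- exp(opt$maximum)
  if (phi <= 1.5e-6) phi <- 0  # boundary: Poisson limit
  phi
}

# two-sided exact NB p-value for group sums s1 (n1 reps) and s2 (n2 reps)
# conditioned on the total, doubling the smaller tail (capped at 1)
.exact_nb_p <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(NA_real_)
  k <- 0:t
  mu1 <- t * n1 / (n1 + n2)
  mu2 <- t - mu1
  if (phi > 0) {
    logp <- dnbinom(k, size = n1 / phi, mu = mu1, log = TRUE) +
      dnbinom(t - k, size = n2 / phi, mu = mu2, log = TRUE)
  } else {
    logp <- dpois(k, mu1, log = TRUE) + dpois(t - k, mu2, log = TRUE)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  lower <- sum(p[k <= s1])
  upper <- sum(p[k >= s1])
  min(1, 2 * min(lower, upper))
}

#' Exact negative-binomial test between two conditions
#'
#' Per-gene two-sided exact test on library-size-equalized pseudo-counts
#' summed within each condition, conditioned on the gene's total, with
#' common dispersion `phi`. Genes with zero counts in both conditions are
#' excluded from testing and reported with `NA` p- and q-values. Q-values
#' are Benjamini-Hochberg adjusted across all tested genes.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param groups condition labels, one per column (exactly two distinct).
#' @param cond1,cond2 the two condition labels to compare; fold changes are
#'   `cond2` relative to `cond1`.
#' @param phi common NB dispersion; estimated with
#'   [estimate_common_dispersion()] if `NULL`.
#' @param factors TMM factors; computed if `NULL`.
#' @return A data frame in input gene order: `gene_id`, `log2FC`, `logCPM`,
#'   `PValue`, `QValue`.
#' @export
nb_exact_test <- function(counts, groups, cond1 = NULL, cond2 = NULL,
                          phi = NULL, factors = NULL) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts))
  levs <- unique(groups)
  cond1 <- cond1 %||% levs[1L]
  cond2 <- cond2 %||% setdiff(levs, cond1)[1L]
  if (!all(c(cond1, cond2) %in% groups))
    stop("both conditions must be present among the sample labels")
  factors <- factors %||% tmm_factors(counts)
  if (is.null(phi)) {
    phi <- estimate_common_dispersion(counts, groups, factors)
  }
  ps <- .pseudo_counts(counts, factors)
  cols1 <- which(groups == cond1)
  cols2 <- which(groups == cond2)
  n1 <- length(cols1); n2 <- length(cols2)
  s1 <- round(rowSums(ps$pseudo[, cols1, drop = FALSE]))
  s2 <- round(rowSums(ps$pseudo[, cols2, drop = FALSE]))
  p <- mapply(.exact_nb_p, s1, s2, MoreArgs = list(n1 = n1, n2 = n2,
                                                   phi = phi))
  q <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  q[tested] <- p.adjust(p[tested], method = "BH")
  data.frame(
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    log2FC = log2((s2 / n2 + 0.5) / (s1 / n1 + 0.5)),
    logCPM = log2(((s1 + s2) / (n1 + n2) + 0.5) / ps$geo_lib * 1e6),
    PValue = p,
    QValue = q,
    stringsAsFactors = FALSE)
}

#' Compare mutant abundance between two conditions
#'
#' High-level wrapper: builds the count matrix from per-sample
#' gene-statistics tables, normalizes, estimates the common dispersion and
#' runs the exact test.
#'
#' @param cond1_paths,cond2_paths gene-statistics TSVs for the replicates
#'   of each condition.
#' @param phi optional fixed common dispersion (required when neither
#'   condition has replication).
#' @param use compare `"read_count"` (default) or `"ins_count"`.
#' @return The [nb_exact_test()] result table.
#' @export
compare_conditions <- function(cond1_paths, cond2_paths, phi = NULL,
                               use = c("read_count", "ins_count")) {
  use <- match.arg(use)
  counts <- count_matrix_from_stats(c(cond1_paths, cond2_paths), use = use)
  groups <- rep(c("condition1", "condition2"),
                c(length(cond1_paths), length(cond2_paths)))
  nb_exact_test(counts, groups, "condition1", "condition2", phi = phi)
}

#' Write a comparison results table
#'
#' @param result table from [nb_exact_test()].
#' @param path output TSV path.
#' @export
write_comparison <- function(result, path) {
  out <- result
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), "NA", sprintf("%.17g", v)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
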