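## Essentiality classification from the insertion-index distribution. In a
## dense transposon library the genome-wide distribution of insertion
## indices is bimodal: essential genes cluster at or near zero (insertions
## are not tolerated) while non-essential genes form a broad positive mode.
## The two modes are modeled as gamma components, fit separately on either
## side of the inter-modal valley, and genes are labeled by the log2 ratio
## of the two component densities at their index.

#' Locate the valley between the two insertion-index modes
#'
#' A kernel density estimate (Silverman bandwidth) of the insertion indices
#' is scanned for local maxima; the pivot is the index value minimizing the
#' smoothed density between the two largest maxima. Input with no interior
#' valley (a unimodal index distribution) is an error: the library is not
#' dense enough for mode-based classification.
#'
#' @param indices numeric vector of per-gene insertion indices (>= 100
#'   genes).
#' @param bw kernel bandwidth; default Silverman (`"nrd0"`).
#' @return The pivot insertion-index value.
#' @export
find_pivot <- function(indices, bw = "nrd0") {
  indices <- indices[!is.na(indices)]
  if (length(indices) < 100L)
    stop("at least 100 gene indices are required to locate the valley")
  if (diff(range(indices)) == 0)
    stop("all insertion indices are identical: no valley; the library is not dense enough for bimodal classification")
  d <- density(indices, bw = bw, n = 1024L)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1L)] > y[1:(n - 2L)] &
                y[2:(n - 1L)] >= y[3:n], FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2L)
    stop("insertion-index distribution is unimodal: no valley; the library is not dense enough for bimodal classification")
  top2 <- peaks[order(y[peaks], decreasing = TRUE)[1:2]]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1L
  d$x[valley]
}

#' Fit the two-gamma essentiality model
#'
#' Indices of zero cannot enter a gamma likelihood; they are replaced by
#' half the smallest positive index for fitting and evaluation. The
#' essential component is fit by maximum likelihood to indices below the
#' pivot, the non-essential component to indices at or above it. When the
#' below-pivot values are (near-)degenerate — e.g. every essential gene has
#' index exactly zero — maximum likelihood diverges and a weakly
#' informative moment fit with the coefficient of variation floored at 0.5
#' is used instead. Changepoints are the index values where the log2
#' density ratio crosses `+threshold` and `-threshold`.
#'
#' @param indices numeric vector of per-gene insertion indices.
#' @param pivot the valley value from [find_pivot()].
#' @param loglik_threshold log2 density-ratio threshold for classification
#'   (default 2, i.e. 4:1 odds).
#' @return A `gamma_mixture_fit` with the two components' shapes and rates,
#'   the pivot, the zero-replacement pseudo index, and the changepoints.
#' @export
fit_components <- function(indices, pivot, loglik_threshold = 2) {
  indices <- indices[!is.na(indices)]
  if (any(indices < 0)) stop("insertion indices must be non-negative")
  positive <- indices[indices > 0]
  if (!length(positive)) stop("all insertion indices are zero; cannot fit")
  pseudo <- min(positive) / 2
  x <- ifelse(indices == 0, pseudo, indices)
  ess <- x[x < pivot]
  non <- x[x >= pivot]
  if (length(ess) < 10L || length(non) < 10L)
    stop(sprintf("need >= 10 observations on each side of the pivot (have %d below, %d at/above)",
                 length(ess), length(non)))
  fe <- .fit_gamma(ess)
  fn <- .fit_gamma(non)
  ## The hard split truncates both components at the pivot and leaks each
  ## component's tail into the other's fit, which biases the recovered
  ## parameters; a few EM iterations on the two-gamma mixture, initialized
  ## from the split fits, remove that bias. Skipped when either side is
  ## degenerate (e.g. every essential gene at the same pseudo index), where
  ## the moment fallback is the model.
  if (!fe$fallback && !fn$fallback) {
    em <- .em_refine(x, fe, fn, w_ess = length(ess) / length(x))
    fe <- em$fe; fn <- em$fn
  }

  log2_ratio <- function(q) {
    (dgamma(q, fe$shape, fe$rate, log = TRUE) -
       dgamma(q, fn$shape, fn$rate, log = TRUE)) / log(2)
  }
  cp <- .find_changepoints(log2_ratio, loglik_threshold,
                           lower = min(x) / 10, upper = max(x) * 2)
  structure(list(shape_ess = fe$shape, rate_ess = fe$rate,
                 shape_non = fn$shape, rate_non = fn$rate,
                 pivot = pivot, pseudo_index = pseudo,
                 changepoint_lo = cp[1L], changepoint_hi = cp[2L],
                 loglik_threshold = loglik_threshold,
                 ess_fallback = fe$fallback, non_fallback = fn$fallback,
                 n_ess = length(ess), n_non = length(non)),
            class = "gamma_mixture_fit")
}

#' @export
print.gamma_mixture_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "two-gamma insertion-index model\n",
    "  essential:     shape %.4g, rate %.4g (n=%d%s)\n",
    "  non-essential: shape %.4g, rate %.4g (n=%d%s)\n",
    "  pivot %.5g, changepoints [%.5g, %.5g] at |log2 ratio| = %g\n"),
    x$shape_ess, x$rate_ess, x$n_ess,
    if (x$ess_fallback) ", moment fallback" else "",
    x$shape_non, x$rate_non, x$n_non,
    if (x$non_fallback) ", moment fallback" else "",
    x$pivot, x$changepoint_lo, x$changepoint_hi, x$loglik_threshold))
  invisible(x)
}

# Gamma ML via MASS::fitdistr with moment starts; falls back to a moment
# fit with CV floored at 0.5 when the data carry (almost) no spread.
.fit_gamma <- function(x) {
  m <- mean(x)
  v <- var(x)
  v_floor <- (m / 2)^2
  degenerate <- !is.finite(v) || v < m^2 * 1e-6
  if (!degenerate) {
    shape0 <- m^2 / v
    fit <- tryCatch(
      MASS::fitdistr(x, "gamma",
                     start = list(shape = shape0, rate = shape0 / m),
                     lower = c(1e-8, 1e-8)),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$estimate)) &&
        all(fit$estimate > 0)) {
      return(list(shape = unname(fit$estimate["shape"]),
                  rate = unname(fit$estimate["rate"]), fallback = FALSE))
    }
  }
  v <- max(v, v_floor, na.rm = TRUE)
  shape <- m^2 / v
  list(shape = shape, rate = shape / m, fallback = TRUE)
}

# weighted gamma ML: solve log(shape) - digamma(shape) = log(wmean) - wmeanlog
# by Newton iteration; falls back like .fit_gamma when the weighted sample is
# degenerate
.fit_gamma_weighted <- function(x, w) {
  W <- sum(w)
  m <- sum(w * x) / W
  v <- sum(w * (x - m)^2) / W
  if (!is.finite(v) || v < m^2 * 1e-6) {
    v <- max(v, (m / 2)^2)
    shape <- m^2 / v
    return(list(shape = shape, rate = shape / m, fallback = TRUE))
  }
  s <- log(m) - sum(w * log(x)) / W
  shape <- m^2 / v
  for (i in 1:50) {
    f <- log(shape) - digamma(shape) - s
    fp <- 1 / shape - trigamma(shape)
    step <- f / fp
    shape_new <- shape - step
    if (shape_new <= 0) shape_new <- shape / 2
    if (abs(shape_new - shape) < 1e-10 * shape) { shape <- shape_new; break }
    shape <- shape_new
  }
  list(shape = shape, rate = shape / m, fallback = FALSE)
}

# EM on the two-component gamma mixture, initialized from the hard-split
# fits; returns the refined components (essential = smaller-mean component)
.em_refine <- function(x, fe, fn, w_ess, max_iter = 200L, tol = 1e-8) {
  p <- min(max(w_ess, 1e-3), 1 - 1e-3)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    le <- dgamma(x, fe$shape, fe$rate, log = TRUE) + log(p)
    ln <- dgamma(x, fn$shape, fn$rate, log = TRUE) + log(1 - p)
    mx <- pmax(le, ln)
    ll <- sum(mx + log(exp(le - mx) + exp(ln - mx)))
    r <- 1 / (1 + exp(ln - le))   # responsibility of the essential component
    fe_new <- .fit_gamma_weighted(x, r)
    fn_new <- .fit_gamma_weighted(x, 1 - r)
    if (fe_new$fallback || fn_new$fallback) break
    fe <- fe_new; fn <- fn_new
    p <- mean(r)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  if (fe$shape / fe$rate > fn$shape / fn$rate) { tmp <- fe; fe <- fn; fn <- tmp }
  list(fe = fe, fn = fn)
}

# the log2 ratio is monotone decreasing over the inter-modal region for any
# sensible fit (lighter-left component); locate the downward crossings of
# +thr and -thr on a fine grid, then polish with uniroot
.find_changepoints <- function(log2_ratio, thr, lower, upper) {
  xs <- exp(seq(log(lower), log(upper), length.out = 4096L))
  g <- log2_ratio(xs)
  cross <- function(level) {
    above <- g >= level
    i <- which(above[-length(above)] & !above[-1L])
    if (!length(i))
      stop(sprintf("log2 density ratio never crosses %g in (%g, %g); components are not separated",
                   level, lower, upper))
    i <- i[1L]
    uniroot(function(q) log2_ratio(q) - level, c(xs[i], xs[i + 1L]),
            tol = 1e-12)$root
  }
  c(cross(thr), cross(-thr))
}

#' Classify genes as essential, ambiguous or non-essential
#'
#' Each gene's insertion index (zeros evaluated at the fit's pseudo index)
#' is scored with the log2 ratio of the essential to the non-essential
#' component density, and labeled by the changepoint interval: `essential`
#' at or below `changepoint_lo`, `non_essential` at or above
#' `changepoint_hi`, `ambiguous` between. Between the two component modes
#' the interval rule coincides with thresholding the log2 ratio at
#' `loglik_threshold`; far above the non-essential mode the raw density
#' ratio can turn non-monotone (both gamma tails are thin), and there the
#' changepoints remain authoritative. Genes with index exactly zero must
#' come out essential; this is asserted.
#'
#' @param stats gene statistics data frame (see [gene_stats()]), or any
#'   data frame with `locus_tag` and `ins_index` columns.
#' @param fit a `gamma_mixture_fit`.
#' @return A data frame with `gene_id`, `ins_index`, `log2_ratio`, `label`.
#' @export
classify_essentiality <- function(stats, fit) {
  stopifnot(inherits(fit, "gamma_mixture_fit"))
  idx <- stats$ins_index
  q <- ifelse(idx == 0, fit$pseudo_index, idx)
  lr <- (dgamma(q, fit$shape_ess, fit$rate_ess, log = TRUE) -
           dgamma(q, fit$shape_non, fit$rate_non, log = TRUE)) / log(2)
  label <- ifelse(q <= fit$changepoint_lo, "essential",
                  ifelse(q >= fit$changepoint_hi, "non_essential",
                         "ambiguous"))
  if (any(idx == 0) && any(label[idx == 0] != "essential"))
    stop("internal inconsistency: a zero-index gene was not labeled essential; the fitted components do not separate at the pseudo index")
  data.frame(gene_id = stats$locus_tag, ins_index = idx,
             log2_ratio = lr, label = label, stringsAsFactors = FALSE)
}

#' Run the full essentiality analysis on a gene-statistics table
#'
#' Convenience wrapper: locates the pivot, fits the two-gamma model
#' (excluding genes shorter than `min_gene_length` from the fit — their
#' indices are too granular — while still classifying them), and classifies
#' every gene.
#'
#' @param stats gene statistics data frame.
#' @param loglik_threshold log2 density-ratio threshold.
#' @param min_gene_length genes shorter than this are excluded from fitting
#'   but still classified.
#' @return A list with `fit` (the `gamma_mixture_fit`) and `calls` (the
#'   per-gene classification merged onto `stats`).
#' @export
essentiality_analysis <- function(stats, loglik_threshold = 2,
                                  min_gene_length = 100L) {
  fit_rows <- stats$gene_length >= min_gene_length
  indices <- stats$ins_index[fit_rows]
  pivot <- find_pivot(indices)
  fit <- fit_components(indices, pivot, loglik_threshold)
  calls <- classify_essentiality(stats, fit)
  out <- stats
  out$log2_ratio <- calls$log2_ratio
  out$label <- calls$label
  list(fit = fit, calls = out)
}

#' Write essentiality calls and a fit-metadata sidecar
#'
#' @param result the list returned by [essentiality_analysis()].
#' @param path output TSV path; the sidecar is written to
#'   `<path>.fit_metadata.txt`.
#' @export
write_essentiality <- function(result, path) {
  out <- result$calls
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  f <- result$fit
  meta <- c(
    "two-gamma insertion-index essentiality fit (deterministic; no RNG)",
    sprintf("shape_ess\t%.17g", f$shape_ess),
    sprintf("rate_ess\t%.17g", f$rate_ess),
    sprintf("shape_non\t%.17g", f$shape_non),
    sprintf("rate_non\t%.17g", f$rate_non),
    sprintf("pivot\t%.17g", f$pivot),
    sprintf("pseudo_index\t%.17g", f$pseudo_index),
    sprintf("changepoint_lo\t%.17g", f$changepoint_lo),
    sprintf("changepoint_hi\t%.17g", f$changepoint_hi),
    sprintf("loglik_threshold\t%g", f$loglik_threshold),
    sprintf("zero_replacement\thalf smallest positive index"))
  writeLines(meta, paste0(path, ".fit_metadata.txt"))
  invisible(path)
}
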