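# Independent brute-force oracles and small fixture builders shared across
# the test files. Oracles deliberately avoid the code paths they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_quals <- function(lens) {
  vapply(lens, function(l)
    intToUtf8(sample(33:73, l, replace = TRUE)), character(1))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# exhaustive all-positions, both-strands Hamming scan over every replicon;
# best hit selected at the lexicographically smallest (replicon, pos,
# strand) among ties, mirroring the mapping contract
oracle_map_read <- function(read, genome_chr, min_identity = 0.96) {
  len <- nchar(read)
  min_matches <- ceiling(min_identity * len)
  cand <- list()
  for (rn in names(genome_chr)) {
    subj <- Biostrings::DNAString(genome_chr[[rn]])
    L <- length(subj)
    if (L < len) next
    starts <- seq_len(L - len + 1L)
    for (st in c("+", "-")) {
      rd <- if (st == "+") read else revcomp_chr(read)
      mism <- Biostrings::neditStartingAt(Biostrings::DNAString(rd), subj,
                                          starting.at = starts,
                                          with.indels = FALSE)
      hit <- which(len - mism >= min_matches)
      if (length(hit))
        cand[[length(cand) + 1L]] <- data.frame(
          rep = rn, pos = hit, strand = st, matches = len - mism[hit],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(list(is_mapped = FALSE, is_unique = FALSE,
                pos = NA, rep = NA, strand = NA, n_best = 0L))
  cand <- do.call(rbind, cand)
  best <- cand[cand$matches == max(cand$matches), , drop = FALSE]
  best <- best[order(best$rep, best$pos, best$strand), , drop = FALSE]
  list(is_mapped = TRUE, is_unique = nrow(best) == 1L,
       pos = best$pos[1L], rep = best$rep[1L], strand = best$strand[1L],
       n_best = nrow(best))
}

# brute-force tag scan: regex-free position-by-position comparison
oracle_match_tag <- function(bases, tag, max_mismatches) {
  vapply(bases, function(b) {
    k <- nchar(tag)
    if (nchar(b) < k) return(FALSE)
    mm <- sum(strsplit(substr(b, 1L, k), "")[[1L]] !=
                strsplit(tag, "")[[1L]])
    mm <= max_mismatches
  }, logical(1), USE.NAMES = FALSE)
}

# Benjamini-Hochberg from the definition: q_i = min over j >= rank(i) of
# p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# small desk-scale simulation configuration used by several test files
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed,
    replicon_lengths = c(chrA = 30000L, plasB = 9000L),
    n_genes = 25L,
    gene_length_range = c(200L, 600L),
    frac_essential = 0.2,
    n_insertions = 700L,
    reads_per_insertion = 3,
    n_reads = 4000L,
    frac_untagged = 0.1,
    base_error_rate = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

plot_arrays <- function(plots) {
  lapply(plots, function(p) list(p$forward, p$reverse))
}
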