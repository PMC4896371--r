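## Intersection of insertion plots with gene annotation: per-gene read
## counts, unique insertion sites and the length-normalized insertion index.

#' Per-gene insertion statistics
#'
#' For each annotated gene, counts reads and unique insertion sites inside
#' the gene span and computes the insertion index (unique sites divided by
#' full gene length). Counts from both strands contribute regardless of the
#' gene's strand: a transposon insertion disrupts the gene either way.
#' Optional terminal trimming removes `floor(trim5 * length)` bases from
#' the translational start end and `floor(trim3 * length)` from the stop
#' end (strand-aware) before counting — insertions at gene termini often do
#' not disrupt function. The insertion-index denominator is always the full
#' gene length.
#'
#' @param plots named list of [insertion_plot()] objects, keyed by replicon.
#' @param genes annotation data frame (see [read_annotation()]).
#' @param trim5,trim3 fractions of the gene length trimmed from the 5' and
#'   3' ends of the coding sequence; `trim5 + trim3` must be < 1.
#' @return A data frame, one row per gene in annotation order, with columns
#'   `locus_tag`, `gene_name`, `ncrna` (1 for non-CDS features), `start`,
#'   `end`, `strand`, `read_count`, `ins_index`, `gene_length`, `ins_count`,
#'   `fcn` (the product annotation).
#' @export
gene_stats <- function(plots, genes, trim5 = 0, trim3 = 0) {
  if (trim5 < 0 || trim3 < 0 || trim5 + trim3 >= 1)
    stop("trim fractions must be non-negative with trim5 + trim3 < 1")
  missing_rep <- setdiff(unique(genes$replicon), names(plots))
  if (length(missing_rep))
    stop(sprintf("no insertion plot for replicon '%s'", missing_rep[1L]))
  n <- nrow(genes)
  read_count <- integer(n)
  ins_count <- integer(n)
  len <- genes$end - genes$start + 1L
  for (i in seq_len(n)) {
    p <- plots[[genes$replicon[i]]]
    if (genes$end[i] > p$length)
      stop(sprintf("gene '%s' extends past the end of replicon '%s'",
                   genes$gene_id[i], genes$replicon[i]))
    t5 <- as.integer(floor(trim5 * len[i]))
    t3 <- as.integer(floor(trim3 * len[i]))
    if (genes$strand[i] == "-") { tmp <- t5; t5 <- t3; t3 <- tmp }
    lo <- genes$start[i] + t5
    hi <- genes$end[i] - t3
    combined <- p$forward[lo:hi] + p$reverse[lo:hi]
    read_count[i] <- sum(combined)
    ins_count[i] <- sum(combined > 0L)
  }
  data.frame(
    locus_tag = genes$gene_id,
    gene_name = genes$gene_name,
    ncrna = as.integer(genes$feature_type != "CDS"),
    start = genes$start,
    end = genes$end,
    strand = genes$strand,
    read_count = read_count,
    ins_index = ins_count / len,
    gene_length = len,
    ins_count = ins_count,
    fcn = genes$product,
    stringsAsFactors = FALSE)
}
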