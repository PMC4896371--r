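## Per-base insertion profiles. The insertion coordinate is the read base
## adjacent to the transposon junction: the transposon tag sits at the
## read's 5' end, so for a forward alignment that base is the leftmost
## reference position, and for a reverse alignment the rightmost. Both
## strands therefore report the same insertion event at (near-)identical
## coordinates.

#' Build per-replicon insertion plots from alignments
#'
#' Only retained alignments — mapped, unique, and with MAPQ at or above the
#' uniqueness threshold — contribute. Each retained alignment increments
#' exactly one count: `forward[pos]` for a `+` alignment, or
#' `reverse[pos + aligned_length - 1]` for a `-` alignment (the
#' junction-proximal base). Set `junction_end = "three_prime"` to flip the
#' convention.
#'
#' @param alignments alignment data frame (see [map_reads()]).
#' @param genome named `DNAStringSet` or named character vector; every
#'   alignment's replicon must be present.
#' @param params `mapping_params` supplying the MAPQ uniqueness threshold.
#' @param junction_end which read end is counted: `"five_prime"` (default,
#'   the tag-proximal end) or `"three_prime"`.
#' @return A named list of [insertion_plot()] objects, one per replicon.
#' @export
build_plots <- function(alignments, genome,
                        params = mapping_params(13L, 2L),
                        junction_end = c("five_prime", "three_prime")) {
  junction_end <- match.arg(junction_end)
  if (methods::is(genome, "DNAStringSet")) {
    lens <- setNames(Biostrings::width(genome), names(genome))
  } else {
    lens <- setNames(nchar(genome), names(genome))
  }
  keep <- alignments$is_mapped & alignments$is_unique &
    alignments$mapq >= params$mapq_unique_threshold
  aln <- alignments[keep, , drop = FALSE]
  if (nrow(aln) && any(!aln$replicon %in% names(lens)))
    stop(sprintf("alignment refers to unknown replicon '%s'",
                 setdiff(aln$replicon, names(lens))[1L]))
  right_end <- aln$pos + aln$aligned_length - 1L
  site <- if (junction_end == "five_prime") {
    ifelse(aln$strand == "+", aln$pos, right_end)
  } else {
    ifelse(aln$strand == "+", right_end, aln$pos)
  }
  site <- as.integer(site)
  if (nrow(aln) && (any(site < 1L) || any(site > lens[aln$replicon])))
    stop("alignment extends past the replicon end")
  plots <- lapply(names(lens), function(rep_name) {
    len <- lens[[rep_name]]
    on_rep <- aln$replicon == rep_name
    fwd <- tabulate(site[on_rep & aln$strand == "+"], nbins = len)
    rev <- tabulate(site[on_rep & aln$strand == "-"], nbins = len)
    insertion_plot(rep_name, fwd, rev)
  })
  setNames(plots, names(lens))
}

#' Summarize an insertion plot
#'
#' @param plot an `insertion_plot`.
#' @return A list with `replicon`, `n_sites` (bases with nonzero combined
#'   count) and `total_reads` (sum over both strand arrays).
#' @export
summarize_plot <- function(plot) {
  stopifnot(inherits(plot, "insertion_plot"))
  combined <- plot$forward + plot$reverse
  list(replicon = plot$replicon,
       n_sites = sum(combined > 0L),
       total_reads = sum(combined))
}

#' Write one plot file per replicon
#'
#' Files are named `<prefix>.<replicon>.insert_site_plot` (plus `.gz` when
#' `gzip = TRUE`).
#'
#' @param plots named list of `insertion_plot` objects.
#' @param prefix output path prefix.
#' @param gzip compress the output files.
#' @return Named character vector of the written paths.
#' @export
write_plots <- function(plots, prefix, gzip = FALSE) {
  paths <- vapply(plots, function(p) {
    path <- sprintf("%s.%s.insert_site_plot%s", prefix, p$replicon,
                    if (gzip) ".gz" else "")
    write_plot(p, path)
    path
  }, character(1))
  invisible(paths)
}
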