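## Transposon-tag detection and trimming. Reads produced by a TraDIS-style
## protocol begin inside the transposon, so a genuine junction read carries
## the tag at its 5' end; matching is anchored at position 1 only and uses
## Hamming distance (no indels, no reverse-complement check).

#' Specify a transposon tag
#'
#' @param tag DNA string (1-20 bases over `A`,`C`,`G`,`T`; transposon tags
#'   are typically 8-12 bases).
#' @param max_mismatches maximum Hamming distance tolerated between the tag
#'   and the read prefix; must be smaller than the tag length. `N` in a read
#'   counts as a mismatch.
#' @return An object of class `tag_spec`.
#' @export
tag_spec <- function(tag, max_mismatches = 0L) {
  tag <- toupper(as.character(tag))
  if (length(tag) != 1L || nchar(tag) < 1L || nchar(tag) > 20L ||
      grepl("[^ACGT]", tag))
    stop("tag must be a single DNA string of 1-20 bases over {A,C,G,T}")
  max_mismatches <- .check_count(max_mismatches, "max_mismatches")
  if (max_mismatches >= nchar(tag))
    stop("max_mismatches must be smaller than the tag length")
  structure(list(tag = tag, max_mismatches = max_mismatches),
            class = "tag_spec")
}

# Hamming distance between the tag and each read's prefix; reads shorter
# than the tag get NA (treated as non-matching).
.prefix_mismatches <- function(bases, tag) {
  k <- nchar(tag)
  n <- length(bases)
  mm <- rep(NA_integer_, n)
  long_enough <- nchar(bases) >= k
  if (!any(long_enough)) return(mm)
  prefix <- substr(bases[long_enough], 1L, k)
  tag_chars <- strsplit(tag, "", fixed = TRUE)[[1L]]
  pm <- matrix(unlist(strsplit(prefix, "", fixed = TRUE), use.names = FALSE),
               nrow = k)
  mm[long_enough] <- colSums(pm != tag_chars)
  mm
}

#' Test reads for the transposon tag
#'
#' `TRUE` iff the read is at least as long as the tag and the Hamming
#' distance between the read's prefix and the tag is at most
#' `spec$max_mismatches`.
#'
#' @param reads a reads data frame (see [sequenced_reads()]) or a character
#'   vector of base strings.
#' @param spec a [tag_spec()].
#' @return Logical vector, one entry per read.
#' @export
match_tag <- function(reads, spec) {
  stopifnot(inherits(spec, "tag_spec"))
  bases <- if (is.data.frame(reads)) reads$bases else as.character(reads)
  if (!length(bases)) return(logical())
  mm <- .prefix_mismatches(toupper(bases), spec$tag)
  !is.na(mm) & mm <= spec$max_mismatches
}

#' Filter reads for the transposon tag and trim it
#'
#' Reads carrying the tag are emitted with the first `nchar(tag)` bases and
#' quality characters removed, in input order; reads without the tag are
#' dropped. A matching read that would be trimmed to length zero cannot be
#' mapped and is dropped and counted as without-tag.
#'
#' @param reads a reads data frame.
#' @param spec a [tag_spec()].
#' @return A list with `reads` (the trimmed matching reads) and `report`, a
#'   `tag_filter_report` list with fields `total_reads`, `reads_with_tag`,
#'   `reads_without_tag` and `fraction_with_tag`.
#' @export
filter_and_trim <- function(reads, spec) {
  stopifnot(inherits(spec, "tag_spec"))
  k <- nchar(spec$tag)
  hit <- match_tag(reads, spec)
  # matching reads that are exactly the tag trim to nothing
  hit <- hit & nchar(reads$bases) > k
  total <- nrow(reads)
  with_tag <- sum(hit)
  trimmed <- reads[hit, , drop = FALSE]
  if (nrow(trimmed)) {
    trimmed$bases <- substring(trimmed$bases, k + 1L)
    trimmed$quals <- substring(trimmed$quals, k + 1L)
  }
  rownames(trimmed) <- NULL
  report <- structure(list(
    total_reads = total,
    reads_with_tag = with_tag,
    reads_without_tag = total - with_tag,
    fraction_with_tag = if (total > 0L) with_tag / total else 0),
    class = "tag_filter_report")
  list(reads = trimmed, report = report)
}

#' @export
print.tag_filter_report <- function(x, ...) {
  cat(sprintf("tag filter: %d/%d reads with tag (%.4f)\n",
              x$reads_with_tag, x$total_reads, x$fraction_with_tag))
  invisible(x)
}

#' Write a tag-filter report as a two-column TSV
#'
#' @param report a `tag_filter_report`.
#' @param path output path.
#' @export
write_tag_report <- function(report, path) {
  stopifnot(inherits(report, "tag_filter_report"))
  con <- .open_out(path)
  on.exit(close(con))
  writeLines(c(
    paste0("total_reads\t", report$total_reads),
    paste0("reads_with_tag\t", report$reads_with_tag),
    paste0("reads_without_tag\t", report$reads_without_tag),
    paste0("fraction_with_tag\t", sprintf("%.17g", report$fraction_with_tag))),
    con)
  invisible(path)
}
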