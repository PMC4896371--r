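## Read mapping against a multi-replicon reference. The built-in mapper is a
## seed-and-extend Hamming-identity mapper (no indels): insertion calling
## needs only the junction coordinate, so ungapped placement is sufficient
## at desk scale and keeps the exhaustive-scan oracle exact. An adapter is
## provided for substituting an external production mapper.

#' Length-banded default mapping parameters
#'
#' Seed length, seed sampling stride and minimum identity are chosen from
#' the read length: reads shorter than 70 nt use `kmer = 13, step = 2`;
#' 70-99 nt use `kmer = 13, step = 4`; 100 nt and longer use
#' `kmer = 20, step = 4`. All bands use `min_identity = 0.96` and a MAPQ
#' uniqueness threshold of 30. Every value can be overridden via
#' [mapping_params()].
#'
#' @param read_length read length in nt (after tag trimming); must be >= 20.
#' @return A `mapping_params` object.
#' @export
default_mapping_params <- function(read_length) {
  read_length <- .check_count(read_length, "read_length")
  if (read_length < 20L)
    stop("reads shorter than 20 nt are too short to map reliably")
  if (read_length < 70L) {
    mapping_params(kmer = 13L, step = 2L)
  } else if (read_length < 100L) {
    mapping_params(kmer = 13L, step = 4L)
  } else {
    mapping_params(kmer = 20L, step = 4L)
  }
}

#' Construct mapping parameters
#'
#' @param kmer seed length (bases).
#' @param step stride at which reference seeds are sampled; `1 <= step <=
#'   kmer`.
#' @param min_identity minimum fraction of matching bases for a location to
#'   count as mapped, in (0, 1].
#' @param mapq_unique_threshold MAPQ at or above which a record is treated
#'   as uniquely mapped downstream.
#' @return A `mapping_params` object.
#' @export
mapping_params <- function(kmer, step, min_identity = 0.96,
                           mapq_unique_threshold = 30L) {
  kmer <- .check_count(kmer, "kmer")
  step <- .check_count(step, "step")
  if (kmer < 1L || kmer > 32L) stop("kmer must be in 1..32")
  if (step < 1L || step > kmer) stop("step must satisfy 1 <= step <= kmer")
  if (!is.numeric(min_identity) || min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0, 1]")
  structure(list(kmer = kmer, step = step,
                 min_identity = as.numeric(min_identity),
                 mapq_unique_threshold = .check_count(mapq_unique_threshold,
                                                     "mapq_unique_threshold")),
            class = "mapping_params")
}

#' @export
print.mapping_params <- function(x, ...) {
  cat(sprintf("mapping params: kmer=%d step=%d min_identity=%.2f mapq>=%d\n",
              x$kmer, x$step, x$min_identity, x$mapq_unique_threshold))
  invisible(x)
}

.genome_as_character <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- toupper(genome)
  } else {
    stop("genome must be a named DNAStringSet or named character vector")
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every replicon must be named")
  if (anyDuplicated(names(seqs))) stop("replicon names must be unique")
  seqs
}

#' Map trimmed reads to a reference genome
#'
#' Each read yields exactly one alignment record. A read is mapped when its
#' best ungapped placement (either strand, any replicon) reaches
#' `min_identity`, and unique when that best placement strictly beats the
#' second best; ties are reported as non-unique at the lexicographically
#' smallest `(replicon, pos, strand)`. `pos` is the leftmost reference
#' coordinate of the alignment on the forward reference strand; `strand`
#' records the read's orientation. Reads shorter than the seed length
#' produce unmapped records.
#'
#' @param reads a reads data frame (tags already trimmed).
#' @param genome named `DNAStringSet` or named character vector of replicon
#'   sequences.
#' @param params a `mapping_params` object; defaults to
#'   [default_mapping_params()] of the shortest read.
#' @return An alignment data frame with columns `read_id`, `replicon`,
#'   `pos`, `strand`, `aligned_length`, `mapq`, `is_unique`, `is_mapped`.
#' @export
map_reads <- function(reads, genome, params = NULL) {
  seqs <- .genome_as_character(genome)
  if (length(seqs) == 0L) stop("genome must contain at least one replicon")
  if (nrow(reads) == 0L) return(.empty_alignments())
  if (is.null(params))
    params <- default_mapping_params(min(nchar(reads$bases)))
  stopifnot(inherits(params, "mapping_params"))
  ord <- order(names(seqs), method = "radix")
  seqs <- seqs[ord]
  hits <- .cpp_map_reads(unname(seqs), reads$bases, params$kmer, params$step,
                         params$min_identity)
  mapped <- hits$is_mapped
  data.frame(
    read_id = reads$read_id,
    replicon = ifelse(mapped, names(seqs)[hits$rep], NA_character_),
    pos = ifelse(mapped, hits$pos, NA_integer_),
    strand = hits$strand,
    aligned_length = nchar(reads$bases),
    mapq = ifelse(mapped & hits$is_unique, 60L, 0L),
    is_unique = mapped & hits$is_unique,
    is_mapped = mapped,
    stringsAsFactors = FALSE)
}

#' Map reads with an external short-read mapper
#'
#' Runs a configured external mapper executable (default `minimap2` with
#' its short-read preset) to produce a SAM file consumable by [read_sam()].
#' If the executable is not available the call degrades gracefully to the
#' built-in mapper with a logged notice.
#'
#' @param reads_path FASTQ of trimmed reads.
#' @param genome_path reference FASTA.
#' @param out_sam output SAM path.
#' @param params `mapping_params` used when falling back to the built-in
#'   mapper; `NULL` for length-based defaults.
#' @param command external mapper executable name or path.
#' @param args argument vector for the external mapper; the default is a
#'   minimap2 short-read invocation writing SAM to stdout.
#' @return The SAM path, invisibly. Attribute `mapper` records whether the
#'   external tool or the built-in mapper produced it.
#' @export
external_mapper_adapter <- function(reads_path, genome_path, out_sam,
                                    params = NULL,
                                    command = getOption("tradisr.external_mapper",
                                                        "minimap2"),
                                    args = NULL) {
  exe <- Sys.which(command)
  if (!nzchar(exe)) {
    message(sprintf("external mapper '%s' not found; using built-in mapper",
                    command))
    reads <- read_fastq(reads_path)
    genome <- read_genome(genome_path)
    aln <- map_reads(reads, genome, params)
    write_sam(aln, setNames(Biostrings::width(genome), names(genome)), out_sam)
    return(invisible(structure(out_sam, mapper = "builtin")))
  }
  if (is.null(args))
    args <- c("-a", "-x", "sr", "--secondary=no", genome_path, reads_path)
  err_file <- tempfile("mapper_stderr_")
  status <- system2(exe, args, stdout = out_sam, stderr = err_file)
  if (!identical(status, 0L)) {
    err <- paste(readLines(err_file, warn = FALSE), collapse = "\n")
    stop(sprintf("external mapper '%s' exited with status %d:\n%s",
                 command, status, err))
  }
  # sanity-check the output parses as SAM
  read_sam(out_sam)
  invisible(structure(out_sam, mapper = "external"))
}
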