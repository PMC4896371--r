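## Readers and writers for every on-disk format the toolkit touches:
## FASTQ, FASTA, EMBL feature tables / GFF3, Artemis userplot insertion plot
## files, SAM alignments and tab-delimited gene-statistics tables.
## Coordinates are 1-based inclusive everywhere user-facing.

# open a connection, sniffing gzip magic bytes on read; ".gz" suffix selects
# compression on write
.open_in <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    gzfile(path, "rt")
  else
    file(path, "rt")
}

.open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Construct a set of sequenced reads
#'
#' Reads are held as a plain data frame with columns `read_id`, `bases`
#' (uppercase DNA over `A`,`C`,`G`,`T`,`N`) and `quals` (Phred+33 encoded
#' quality string, same length as `bases`).
#'
#' @param read_id character vector of read identifiers.
#' @param bases character vector of base strings.
#' @param quals character vector of Phred+33 quality strings.
#' @return A `data.frame` of reads.
#' @export
sequenced_reads <- function(read_id = character(), bases = character(),
                            quals = character()) {
  stopifnot(length(read_id) == length(bases), length(bases) == length(quals))
  if (any(nchar(bases) == 0L)) stop("reads must have non-empty base strings")
  if (any(nchar(bases) != nchar(quals)))
    stop("quality string length must equal base string length")
  if (length(bases) && any(grepl("[^ACGTN]", bases)))
    stop("bases must be over the alphabet {A,C,G,T,N}")
  data.frame(read_id = as.character(read_id), bases = as.character(bases),
             quals = as.character(quals), stringsAsFactors = FALSE)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param quals character vector of quality strings.
#' @return A list of integer vectors of per-base Phred scores.
#' @export
phred_scores <- function(quals) {
  lapply(quals, function(q) utf8ToInt(q) - 33L)
}

#' Read a FASTQ file
#'
#' Reads a plain or gzip-compressed 4-line-per-record FASTQ file with
#' Phred+33 qualities. Malformed records (missing `@`/`+` markers, a quality
#' string whose length differs from the bases, characters outside
#' `{A,C,G,T,N}`) raise a hard error naming the offending line.
#'
#' @param path path to a FASTQ file, optionally gzipped.
#' @return A reads data frame as from [sequenced_reads()], in file order.
#' @export
read_fastq <- function(path) {
  con <- .open_in(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L) return(sequenced_reads())
  if (n %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4 (record truncated near line %d)",
                 path, n, n))
  hdr <- lines[seq.int(1L, n, 4L)]
  seqs <- toupper(lines[seq.int(2L, n, 4L)])
  plus <- lines[seq.int(3L, n, 4L)]
  qual <- lines[seq.int(4L, n, 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': header at line %d does not start with '@'",
                 path, (bad[1L] - 1L) * 4L + 1L))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': separator at line %d does not start with '+'",
                 path, (bad[1L] - 1L) * 4L + 3L))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': quality length differs from read length at line %d",
                 path, (bad[1L] - 1L) * 4L + 4L))
  bad <- which(nchar(seqs) == 0L | grepl("[^ACGTN]", seqs))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': invalid or empty base string at line %d",
                 path, (bad[1L] - 1L) * 4L + 2L))
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  sequenced_reads(ids, seqs, qual)
}

#' Write reads to a FASTQ file
#'
#' Inverse of [read_fastq()]: `read_fastq(write_fastq(x, path))` reproduces
#' `x` exactly. A `.gz` suffix triggers gzip compression.
#'
#' @param reads a reads data frame.
#' @param path output path.
#' @return Invisibly, the number of records written.
#' @export
write_fastq <- function(reads, path) {
  con <- .open_out(path)
  on.exit(close(con))
  n <- nrow(reads)
  if (n > 0L) {
    out <- character(4L * n)
    out[seq.int(1L, 4L * n, 4L)] <- paste0("@", reads$read_id)
    out[seq.int(2L, 4L * n, 4L)] <- reads$bases
    out[seq.int(3L, 4L * n, 4L)] <- "+"
    out[seq.int(4L, 4L * n, 4L)] <- reads$quals
    writeLines(out, con)
  }
  invisible(n)
}

#' Read a multi-replicon reference genome from FASTA
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] (names are replicon
#'   identifiers, first whitespace-delimited token of each header).
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("replicon names must be unique within a genome")
  genome
}

#' Write a genome to FASTA
#'
#' @param genome a named `DNAStringSet` or named character vector.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

## ---- insertion plot files (Artemis userplot dialect) ----

#' Construct an insertion plot
#'
#' Per-replicon, per-base insertion read counts: `forward[i]` and
#' `reverse[i]` count reads whose transposon junction lies at base `i`
#' (1-based) in forward and reverse orientation respectively.
#'
#' @param replicon replicon name.
#' @param forward,reverse integer vectors of equal length, one entry per
#'   reference base, all entries non-negative.
#' @return An object of class `insertion_plot`.
#' @export
insertion_plot <- function(replicon, forward, reverse) {
  forward <- as.integer(forward)
  reverse <- as.integer(reverse)
  if (length(forward) != length(reverse))
    stop("forward and reverse arrays must have the same length")
  if (length(forward) < 1L) stop("replicon length must be >= 1")
  if (anyNA(forward) || anyNA(reverse) || any(forward < 0L) || any(reverse < 0L))
    stop("insertion counts must be non-negative integers")
  structure(list(replicon = as.character(replicon),
                 length = length(forward),
                 forward = forward, reverse = reverse),
            class = "insertion_plot")
}

#' @export
print.insertion_plot <- function(x, ...) {
  s <- summarize_plot(x)
  cat(sprintf("insertion plot: %s (%d bp), %d insertion sites, %d reads\n",
              x$replicon, x$length, s$n_sites, s$total_reads))
  invisible(x)
}

#' Read an Artemis-style insertion plot file
#'
#' One whitespace-separated line per reference base with two non-negative
#' integer columns (forward count, reverse count); optionally gzipped.
#'
#' @param path path to the plot file.
#' @param replicon replicon name to attach; defaults to the file name with
#'   plot suffixes stripped.
#' @param expected_length if supplied, the declared replicon length; a line
#'   count differing from it is a hard error.
#' @return An `insertion_plot`.
#' @export
read_plot <- function(path, replicon = NULL, expected_length = NULL) {
  if (is.null(replicon)) {
    replicon <- sub("\\.(insert_site_plot|plot)(\\.gz)?$", "",
                    basename(path))
  }
  con <- .open_in(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!is.null(expected_length) && length(lines) != expected_length)
    stop(sprintf("plot file '%s' has %d lines but replicon length is %d",
                 path, length(lines), as.integer(expected_length)))
  if (length(lines) == 0L)
    stop(sprintf("plot file '%s' is empty", path))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  if (any(lengths(parts) != 2L))
    stop(sprintf("plot file '%s': every line must have exactly two columns (first bad line: %d)",
                 path, which(lengths(parts) != 2L)[1L]))
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  if (anyNA(m) || any(m < 0L))
    stop(sprintf("plot file '%s': counts must be non-negative integers", path))
  insertion_plot(replicon, m[, 1L], m[, 2L])
}

#' Write an insertion plot file
#'
#' Bit-exact inverse of [read_plot()]. A `.gz` suffix compresses the output.
#'
#' @param plot an `insertion_plot`.
#' @param path output path.
#' @export
write_plot <- function(plot, path) {
  stopifnot(inherits(plot, "insertion_plot"))
  con <- .open_out(path)
  on.exit(close(con))
  writeLines(paste(plot$forward, plot$reverse), con)
  invisible(path)
}

## ---- annotation (EMBL feature table / GFF3) ----

#' Read gene annotation from an EMBL feature table or GFF3 file
#'
#' Only features of the configured keys (default CDS, tRNA, rRNA) are kept.
#' Coordinates are normalized to 1-based inclusive regardless of dialect;
#' compound `join(...)`/`order(...)` locations are reduced to their
#' min-start..max-end envelope. Features extending beyond a supplied
#' replicon length are clamped (with a warning) or skipped.
#'
#' @param path path to the annotation file.
#' @param dialect `"auto"` (by file suffix/content), `"embl"` or `"gff3"`.
#' @param feature_types feature keys to keep.
#' @param replicon_lengths optional named integer vector of replicon lengths
#'   used to validate coordinates.
#' @param out_of_bounds `"clamp"` or `"skip"` for features extending past a
#'   replicon end.
#' @return A data frame with columns `gene_id`, `gene_name`, `feature_type`,
#'   `replicon`, `start`, `end`, `strand`, `product`, in file order.
#' @export
read_annotation <- function(path, dialect = c("auto", "embl", "gff3"),
                            feature_types = c("CDS", "tRNA", "rRNA"),
                            replicon_lengths = NULL,
                            out_of_bounds = c("clamp", "skip")) {
  dialect <- match.arg(dialect)
  out_of_bounds <- match.arg(out_of_bounds)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "embl"
  }
  ann <- switch(dialect,
                embl = .read_embl(path, feature_types),
                gff3 = .read_gff3(path, feature_types))
  if (nrow(ann) && anyDuplicated(ann$gene_id)) {
    dup <- ann$gene_id[duplicated(ann$gene_id)][1L]
    stop(sprintf("duplicate gene identifier in annotation: '%s'", dup))
  }
  if (!is.null(replicon_lengths) && nrow(ann)) {
    lens <- replicon_lengths[ann$replicon]
    if (anyNA(lens))
      stop("annotation refers to replicons absent from 'replicon_lengths'")
    over <- which(ann$end > lens | ann$start < 1L)
    if (length(over)) {
      if (out_of_bounds == "clamp") {
        warning(sprintf("%d feature(s) extend past the replicon end; clamped",
                        length(over)))
        ann$start[over] <- pmax(ann$start[over], 1L)
        ann$end[over] <- pmin(ann$end[over], lens[over])
      } else {
        warning(sprintf("%d feature(s) extend past the replicon end; skipped",
                        length(over)))
        ann <- ann[-over, , drop = FALSE]
      }
    }
  }
  rownames(ann) <- NULL
  ann
}

# EMBL flat-file feature table: FT lines, 'ID' line names the replicon,
# entries separated by '//'. Only locations of the forms n..m,
# complement(...), join(...), order(...) (and partial markers < >) occur in
# bacterial annotation; they are reduced to an envelope.
.read_embl <- function(path, feature_types) {
  con <- .open_in(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  rows <- list()
  replicon <- NA_character_
  cur <- NULL  # list(key, loc, quals)
  flush_feature <- function(cur) {
    if (is.null(cur) || !(cur$key %in% feature_types)) return(NULL)
    loc <- .parse_embl_location(cur$loc)
    q <- cur$quals
    get_q <- function(name) {
      hit <- grep(paste0("^/", name, "="), q, value = TRUE)
      if (!length(hit)) return(NA_character_)
      gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hit[1L]))
    }
    data.frame(gene_id = get_q("locus_tag"),
               gene_name = get_q("gene"),
               feature_type = cur$key,
               replicon = replicon,
               start = loc$start, end = loc$end, strand = loc$strand,
               product = get_q("product"),
               stringsAsFactors = FALSE)
  }
  for (line in lines) {
    tag <- substr(line, 1L, 2L)
    if (tag == "ID") {
      replicon <- sub(";.*$", "", trimws(substring(line, 6L)))
      replicon <- sub("\\s.*$", "", replicon)
    } else if (tag == "FT") {
      key_field <- trimws(substr(line, 6L, 20L))
      rest <- trimws(substring(line, 22L))
      if (nzchar(key_field)) {            # new feature
        rows[[length(rows) + 1L]] <- flush_feature(cur)
        cur <- list(key = key_field, loc = rest, quals = character())
      } else if (!is.null(cur)) {
        if (startsWith(rest, "/")) {
          cur$quals <- c(cur$quals, rest)
        } else if (!length(cur$quals)) {  # location continuation
          cur$loc <- paste0(cur$loc, rest)
        } else {                          # qualifier continuation
          i <- length(cur$quals)
          cur$quals[i] <- paste(cur$quals[i], rest)
        }
      }
    } else if (tag == "//") {
      rows[[length(rows) + 1L]] <- flush_feature(cur)
      cur <- NULL
      replicon <- NA_character_
    }
  }
  rows[[length(rows) + 1L]] <- flush_feature(cur)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.empty_annotation())
  ann <- do.call(rbind, rows)
  # fall back to a positional id when locus_tag is absent
  miss <- is.na(ann$gene_id)
  ann$gene_id[miss] <- sprintf("%s_%d_%d", ann$replicon[miss],
                               ann$start[miss], ann$end[miss])
  ann
}

.parse_embl_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
  if (length(nums) < 1L)
    stop(sprintf("cannot parse EMBL location '%s'", loc))
  list(start = min(nums), end = max(nums), strand = strand)
}

.read_gff3 <- function(path, feature_types) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (!length(gr)) return(.empty_annotation())
  meta <- S4Vectors::mcols(gr)
  pick <- function(col) {
    if (col %in% colnames(meta)) as.character(meta[[col]]) else
      rep(NA_character_, length(gr))
  }
  gene_id <- pick("locus_tag")
  alt <- pick("ID")
  gene_id[is.na(gene_id)] <- alt[is.na(gene_id)]
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  data.frame(gene_id = gene_id,
             gene_name = pick("gene"),
             feature_type = as.character(gr$type),
             replicon = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = strand,
             product = pick("product"),
             stringsAsFactors = FALSE)
}

.empty_annotation <- function() {
  data.frame(gene_id = character(), gene_name = character(),
             feature_type = character(), replicon = character(),
             start = integer(), end = integer(), strand = character(),
             product = character(), stringsAsFactors = FALSE)
}

#' Write gene annotation as an EMBL feature table
#'
#' Emits one entry per replicon (feature table only, no sequence block).
#'
#' @param genes annotation data frame as from [read_annotation()].
#' @param replicon_lengths named integer vector of replicon lengths.
#' @param path output path.
#' @export
write_embl <- function(genes, replicon_lengths, path) {
  con <- .open_out(path)
  on.exit(close(con))
  fmt_ft <- function(key, rest) sprintf("FT   %-15s %s", key, rest)
  for (rep_name in names(replicon_lengths)) {
    len <- replicon_lengths[[rep_name]]
    writeLines(sprintf("ID   %s; SV 1; circular; genomic DNA; STD; PRO; %d BP.",
                       rep_name, len), con)
    writeLines("FH   Key             Location/Qualifiers", con)
    writeLines(fmt_ft("source", sprintf("1..%d", len)), con)
    sub_g <- genes[genes$replicon == rep_name, , drop = FALSE]
    for (i in seq_len(nrow(sub_g))) {
      g <- sub_g[i, ]
      loc <- sprintf("%d..%d", g$start, g$end)
      if (g$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(fmt_ft(g$feature_type, loc), con)
      writeLines(sprintf("FT                   /locus_tag=\"%s\"", g$gene_id), con)
      if (!is.na(g$gene_name))
        writeLines(sprintf("FT                   /gene=\"%s\"", g$gene_name), con)
      if (!is.na(g$product))
        writeLines(sprintf("FT                   /product=\"%s\"", g$product), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write gene annotation as GFF3
#'
#' @param genes annotation data frame as from [read_annotation()].
#' @param replicon_lengths named integer vector of replicon lengths.
#' @param path output path.
#' @export
write_gff3 <- function(genes, replicon_lengths, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    seqlengths = replicon_lengths)
  gr$source <- "tradisr"
  gr$type <- genes$feature_type
  gr$phase <- ifelse(genes$feature_type == "CDS", 0L, NA_integer_)
  gr$locus_tag <- genes$gene_id
  gr$gene <- genes$gene_name
  gr$product <- genes$product
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

## ---- SAM ----

#' Write alignment records as SAM
#'
#' Emits a header with one `@SQ` line per replicon followed by one record
#' per alignment. Unmapped reads get flag 4; reverse-strand alignments flag
#' 16. The CIGAR is a single ungapped match run.
#'
#' @param alignments alignment data frame (see [map_reads()]).
#' @param replicon_lengths named integer vector of replicon lengths.
#' @param path output path.
#' @export
write_sam <- function(alignments, replicon_lengths, path) {
  con <- .open_out(path)
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(replicon_lengths),
                     as.integer(replicon_lengths)), con)
  if (nrow(alignments)) {
    flag <- ifelse(!alignments$is_mapped, 4L,
                   ifelse(alignments$strand == "-", 16L, 0L))
    rname <- ifelse(alignments$is_mapped, alignments$replicon, "*")
    pos <- ifelse(alignments$is_mapped, alignments$pos, 0L)
    cigar <- ifelse(alignments$is_mapped,
                    paste0(alignments$aligned_length, "M"), "*")
    writeLines(paste(alignments$read_id, flag, rname, pos,
                     alignments$mapq, cigar, "*", 0L, 0L, "*", "*",
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read alignment records from SAM
#'
#' Only the fields of the alignment record model are interpreted; reference
#' length consumed is computed from the CIGAR (`M`, `=`, `X`, `D`, `N` ops).
#' Uniqueness is derived from MAPQ.
#'
#' @param path path to a SAM file.
#' @param mapq_unique_threshold MAPQ at or above which a mapped record is
#'   considered uniquely placed.
#' @return An alignment data frame with columns `read_id`, `replicon`,
#'   `pos`, `strand`, `aligned_length`, `mapq`, `is_unique`, `is_mapped`.
#' @export
read_sam <- function(path, mapq_unique_threshold = 30L) {
  con <- .open_in(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(.empty_alignments())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 11L))
    stop(sprintf("malformed SAM '%s': record with fewer than 11 fields", path))
  f <- function(i) vapply(parts, `[[`, character(1), i)
  flag <- as.integer(f(2))
  mapq <- as.integer(f(5))
  cigar <- f(6)
  is_mapped <- bitwAnd(flag, 4L) == 0L
  aligned_length <- vapply(cigar, .cigar_ref_span, integer(1), USE.NAMES = FALSE)
  data.frame(read_id = f(1),
             replicon = ifelse(is_mapped, f(3), NA_character_),
             pos = ifelse(is_mapped, as.integer(f(4)), NA_integer_),
             strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
             aligned_length = aligned_length,
             mapq = mapq,
             is_unique = is_mapped & mapq >= mapq_unique_threshold,
             is_mapped = is_mapped,
             stringsAsFactors = FALSE)
}

.cigar_ref_span <- function(cigar) {
  if (cigar == "*") return(0L)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(ops) || nchar(cigar) != sum(nchar(ops)))
    stop(sprintf("malformed CIGAR string '%s'", cigar))
  n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(n[op %in% c("M", "=", "X", "D", "N")])
}

.empty_alignments <- function() {
  data.frame(read_id = character(), replicon = character(), pos = integer(),
             strand = character(), aligned_length = integer(),
             mapq = integer(), is_unique = logical(), is_mapped = logical(),
             stringsAsFactors = FALSE)
}

## ---- tab-delimited results tables ----

#' Write a per-gene statistics table
#'
#' Tab-delimited with a single header line and fixed column order:
#' `locus_tag, gene_name, ncrna, start, end, strand, read_count, ins_index,
#' gene_length, ins_count, fcn`. Floating-point columns are written with
#' full (round-trippable) precision so that [read_gene_stats()] is a
#' bit-exact inverse.
#'
#' @param stats gene statistics data frame (see [gene_stats()]).
#' @param path output path.
#' @export
write_gene_stats <- function(stats, path) {
  out <- stats
  out$ins_index <- sprintf("%.17g", out$ins_index)
  con <- .open_out(path)
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene statistics table written by [write_gene_stats()]
#'
#' @param path path to the TSV file.
#' @return The gene statistics data frame.
#' @export
read_gene_stats <- function(path) {
  con <- .open_in(path)
  on.exit(close(con))
  df <- read.table(con, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   colClasses = c(locus_tag = "character",
                                  gene_name = "character",
                                  fcn = "character"))
  df$ins_index <- as.numeric(df$ins_index)
  df
}
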