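## Synthetic transposon mutant libraries with complete ground truth. The
## read model follows the TraDIS protocol: sequencing starts inside the
## transposon, so each genuine junction read is the transposon tag followed
## by genomic sequence beginning at the insertion position in the
## insertion's orientation. Essential genes receive zero insertions by
## construction; insertion positions elsewhere are uniform. Contaminant
## reads are random genomic fragments without the tag.

#' Configure a simulated transposon library
#'
#' Defaults describe a dense library in a small bacterial genome: a 450 kb
#' chromosome plus a 150 kb plasmid, 500 non-overlapping genes of 600-1500
#' nt of which 20% are essential, and 25,000 distinct insertion events —
#' about one insertion per 20 bp of permissive sequence, giving
#' non-essential genes a mean insertion index near 0.05. Reads carry a
#' 10-base tag, 10% of reads are untagged contaminants, and the per-base
#' substitution error rate is 0.1%.
#'
#' @param seed RNG seed; the entire library is deterministic given it.
#' @param replicon_lengths named integer vector of replicon lengths (names
#'   auto-generated when absent).
#' @param n_genes number of non-overlapping genes to place.
#' @param gene_length_range min and max gene length (nt).
#' @param frac_essential fraction of genes planted as essential (zero
#'   insertions).
#' @param n_insertions number of distinct insertion positions.
#' @param reads_per_insertion mean of the geometric read-count distribution
#'   per insertion.
#' @param n_reads optional exact total number of reads; when supplied,
#'   tagged reads are multinomially allocated over insertions (weights
#'   geometric) and `round(n_reads * frac_untagged)` contaminants are
#'   added, so read totals and the tagged fraction are exact.
#' @param tag a [tag_spec()].
#' @param read_length genomic bases per read after the tag.
#' @param frac_untagged fraction of contaminant reads lacking the tag.
#' @param base_error_rate per-base substitution probability, applied to the
#'   genomic part of tagged reads only (tag bases come from high-accuracy
#'   early cycles).
#' @return A `sim_config` object.
#' @export
simulation_config <- function(seed = 1L,
                              replicon_lengths = c(chromosome = 450000L,
                                                   plasmid = 150000L),
                              n_genes = 500L,
                              gene_length_range = c(600L, 1500L),
                              frac_essential = 0.2,
                              n_insertions = 25000L,
                              reads_per_insertion = 5,
                              n_reads = NULL,
                              tag = tag_spec("TAAGAGACAG"),
                              read_length = 50L,
                              frac_untagged = 0.1,
                              base_error_rate = 0.001) {
  if (is.null(names(replicon_lengths)))
    names(replicon_lengths) <- sprintf("replicon%02d",
                                       seq_along(replicon_lengths))
  stopifnot(inherits(tag, "tag_spec"),
            all(replicon_lengths >= 1L),
            gene_length_range[1L] <= gene_length_range[2L],
            frac_essential >= 0, frac_essential <= 1,
            frac_untagged >= 0, frac_untagged < 1,
            base_error_rate >= 0, base_error_rate <= 1,
            reads_per_insertion >= 1)
  structure(list(seed = as.integer(seed),
                 replicon_lengths = replicon_lengths,
                 n_genes = .check_count(n_genes, "n_genes"),
                 gene_length_range = as.integer(gene_length_range),
                 frac_essential = frac_essential,
                 n_insertions = .check_count(n_insertions, "n_insertions"),
                 reads_per_insertion = reads_per_insertion,
                 n_reads = if (is.null(n_reads)) NULL else
                   .check_count(n_reads, "n_reads"),
                 tag = tag,
                 read_length = .check_count(read_length, "read_length"),
                 frac_untagged = frac_untagged,
                 base_error_rate = base_error_rate),
            class = "sim_config")
}

# run code under the config's seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulate a transposon mutant library
#'
#' Generates the genome, annotation, planted essential-gene set, insertion
#' sites, per-base and per-gene ground-truth tallies, and (optionally) the
#' tagged and contaminant reads. Deterministic given the config seed; the
#' same config produces byte-identical FASTQ on every run.
#'
#' @param config a [simulation_config()].
#' @param include_reads generate read sequences (set `FALSE` when only the
#'   truth tables are needed, e.g. for essentiality studies).
#' @return A `sim_library` list with elements `config`, `genome`
#'   (`DNAStringSet`), `genes` (annotation data frame), `essential_ids`,
#'   `insertions` (data frame of replicon/pos/strand/read count), `reads`,
#'   `truth_plots` (per-replicon [insertion_plot()]s of the tagged reads),
#'   `truth_gene_stats` (per-gene table in [gene_stats()] layout),
#'   `n_tagged` and `n_untagged`.
#' @export
simulate_library <- function(config, include_reads = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    lens <- config$replicon_lengths
    rl <- config$read_length

    genome_chr <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))

    genes <- .place_genes(lens, config$n_genes, config$gene_length_range)
    n_ess <- round(config$frac_essential * config$n_genes)
    essential_ids <- sort(sample(genes$gene_id, n_ess))

    ## permissive insertion positions: far enough from replicon ends for a
    ## read in either orientation, and outside essential genes
    allowed <- lapply(names(lens), function(rn) {
      L <- lens[[rn]]
      ok <- rep(FALSE, L)
      if (L >= 2L * rl) ok[rl:(L - rl + 1L)] <- TRUE
      ess <- genes[genes$replicon == rn & genes$gene_id %in% essential_ids, ,
                   drop = FALSE]
      for (i in seq_len(nrow(ess))) ok[ess$start[i]:ess$end[i]] <- FALSE
      which(ok)
    })
    names(allowed) <- names(lens)
    pool_sizes <- lengths(allowed)
    total_allowed <- sum(pool_sizes)
    if (config$n_insertions > total_allowed)
      stop(sprintf("cannot place %d distinct insertions in %d permissive bases",
                   config$n_insertions, total_allowed))
    picks <- sort(sample.int(total_allowed, config$n_insertions))
    rep_idx <- findInterval(picks - 1L, cumsum(c(0L, pool_sizes)),
                            rightmost.closed = FALSE)
    offset <- picks - cumsum(c(0L, pool_sizes))[rep_idx]
    ins <- data.frame(
      replicon = names(lens)[rep_idx],
      pos = vapply(seq_along(picks),
                   function(i) allowed[[rep_idx[i]]][offset[i]], integer(1)),
      strand = sample(c("+", "-"), config$n_insertions, replace = TRUE),
      stringsAsFactors = FALSE)

    ## reads per insertion: geometric weights with the configured mean
    weights <- rgeom(config$n_insertions, 1 / config$reads_per_insertion) + 1L
    if (!is.null(config$n_reads)) {
      n_untagged <- round(config$n_reads * config$frac_untagged)
      n_tagged <- config$n_reads - n_untagged
      ins$count <- as.integer(rmultinom(1L, n_tagged,
                                        weights / sum(weights)))
    } else {
      ins$count <- weights
      n_tagged <- sum(ins$count)
      n_untagged <- round(n_tagged * config$frac_untagged /
                            (1 - config$frac_untagged))
    }

    truth_plots <- .truth_plots(ins, lens)
    truth_gene_stats <- .truth_gene_stats(ins, genes)

    reads <- NULL
    if (include_reads) {
      reads <- .build_reads(config, genome_chr, ins, n_untagged)
    }

    structure(list(config = config,
                   genome = Biostrings::DNAStringSet(genome_chr),
                   genes = genes,
                   essential_ids = essential_ids,
                   insertions = ins,
                   reads = reads,
                   truth_plots = truth_plots,
                   truth_gene_stats = truth_gene_stats,
                   n_tagged = as.integer(n_tagged),
                   n_untagged = as.integer(n_untagged)),
              class = "sim_library")
  })
}

# non-overlapping genes placed left to right with multinomially distributed
# gaps; genes are allocated to replicons proportionally to length
.place_genes <- function(lens, n_genes, length_range) {
  n_per <- round(n_genes * lens / sum(lens))
  n_per[1L] <- n_genes - sum(n_per[-1L])
  rows <- list()
  gid <- 0L
  for (r in seq_along(lens)) {
    n <- n_per[r]
    if (n == 0L) next
    L <- lens[[r]]
    glen <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
    free <- L - sum(glen)
    if (free < n + 1L)
      stop(sprintf("replicon '%s' (%d bp) cannot hold %d genes of %d-%d nt",
                   names(lens)[r], L, n, length_range[1L], length_range[2L]))
    gaps <- as.integer(rmultinom(1L, free, rep(1, n + 1L)))
    starts <- cumsum(gaps[-(n + 1L)] + c(0L, glen[-n])) + 1L
    feature_type <- sample(c("CDS", "tRNA", "rRNA"), n, replace = TRUE,
                           prob = c(0.96, 0.02, 0.02))
    rows[[r]] <- data.frame(
      gene_id = sprintf("SIM_%05d", gid + seq_len(n)),
      gene_name = NA_character_,
      feature_type = feature_type,
      replicon = names(lens)[r],
      start = starts,
      end = starts + glen - 1L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      product = ifelse(feature_type == "CDS", "hypothetical protein",
                       "structural RNA"),
      stringsAsFactors = FALSE)
    gid <- gid + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.truth_plots <- function(ins, lens) {
  plots <- lapply(names(lens), function(rn) {
    L <- lens[[rn]]
    on_rep <- ins$replicon == rn & ins$count > 0L
    fwd <- integer(L); rev <- integer(L)
    f <- ins[on_rep & ins$strand == "+", ]
    r <- ins[on_rep & ins$strand == "-", ]
    fwd[f$pos] <- f$count
    rev[r$pos] <- r$count
    insertion_plot(rn, fwd, rev)
  })
  setNames(plots, names(lens))
}

# independent per-gene tally straight from the insertion list
.truth_gene_stats <- function(ins, genes) {
  by_rep <- split(ins[ins$count > 0L, ], ins$replicon[ins$count > 0L])
  n <- nrow(genes)
  read_count <- integer(n)
  ins_count <- integer(n)
  for (i in seq_len(n)) {
    sub <- by_rep[[genes$replicon[i]]]
    if (is.null(sub)) next
    inside <- sub$pos >= genes$start[i] & sub$pos <= genes$end[i]
    read_count[i] <- sum(sub$count[inside])
    ins_count[i] <- sum(inside)
  }
  len <- genes$end - genes$start + 1L
  data.frame(locus_tag = genes$gene_id,
             gene_name = genes$gene_name,
             ncrna = as.integer(genes$feature_type != "CDS"),
             start = genes$start, end = genes$end, strand = genes$strand,
             read_count = read_count,
             ins_index = ins_count / len,
             gene_length = len,
             ins_count = ins_count,
             fcn = genes$product,
             stringsAsFactors = FALSE)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.build_reads <- function(config, genome_chr, ins, n_untagged) {
  rl <- config$read_length
  tag <- config$tag$tag
  expanded <- ins[rep.int(seq_len(nrow(ins)), ins$count), , drop = FALSE]
  n_tagged <- nrow(expanded)

  genomic <- character(n_tagged)
  for (rn in unique(expanded$replicon)) {
    on_rep <- expanded$replicon == rn
    s <- genome_chr[[rn]]
    fwd <- on_rep & expanded$strand == "+"
    rev <- on_rep & expanded$strand == "-"
    genomic[fwd] <- substring(s, expanded$pos[fwd],
                              expanded$pos[fwd] + rl - 1L)
    genomic[rev] <- .revcomp(substring(s, expanded$pos[rev] - rl + 1L,
                                       expanded$pos[rev]))
  }
  if (config$base_error_rate > 0 && n_tagged > 0L) {
    n_err <- rbinom(n_tagged, rl, config$base_error_rate)
    for (i in which(n_err > 0L)) {
      at <- sample.int(rl, n_err[i])
      for (p in at) {
        orig <- substr(genomic[i], p, p)
        substr(genomic[i], p, p) <-
          sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
      }
    }
  }
  tagged <- sequenced_reads(
    read_id = sprintf("t%07d", seq_len(n_tagged)),
    bases = paste0(tag, genomic),
    quals = rep(strrep("I", nchar(tag) + rl), n_tagged))

  untagged <- .contaminant_reads(config, genome_chr, n_untagged)
  reads <- rbind(tagged, untagged)
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
  rownames(reads) <- NULL
  reads
}

# random genomic fragments of full read length that do not begin with the
# tag (within the configured mismatch tolerance)
.contaminant_reads <- function(config, genome_chr, n_untagged) {
  if (n_untagged == 0L)
    return(sequenced_reads())
  frag_len <- nchar(config$tag$tag) + config$read_length
  lens <- nchar(genome_chr)
  bases <- character(n_untagged)
  todo <- seq_len(n_untagged)
  while (length(todo)) {
    rep_pick <- sample(seq_along(lens), length(todo), replace = TRUE,
                       prob = lens)
    pos <- vapply(rep_pick, function(r)
      sample.int(lens[r] - frag_len + 1L, 1L), integer(1))
    frag <- vapply(seq_along(todo), function(i)
      substring(genome_chr[[rep_pick[i]]], pos[i], pos[i] + frag_len - 1L),
      character(1))
    flip <- runif(length(todo)) < 0.5
    frag[flip] <- .revcomp(frag[flip])
    bases[todo] <- frag
    todo <- todo[match_tag(bases[todo], config$tag)]
  }
  sequenced_reads(read_id = sprintf("u%07d", seq_len(n_untagged)),
                  bases = bases,
                  quals = rep(strrep("I", frag_len), n_untagged))
}

#' Write a simulated library to disk as a pipeline-ready fixture
#'
#' Writes the genome FASTA, annotation (EMBL feature table and GFF3),
#' reads FASTQ, ground-truth plot files, the ground-truth per-gene table,
#' the insertion list and a flat key-value manifest from which the library
#' regenerates bit-identically (see [simulate_from_manifest()]).
#'
#' @param lib a `sim_library` (simulated with reads).
#' @param dir output directory; must be empty or absent unless `force`.
#' @param force overwrite a non-empty directory.
#' @return The manifest path, invisibly.
#' @export
write_fixture <- function(lib, dir, force = FALSE) {
  stopifnot(inherits(lib, "sim_library"))
  if (is.null(lib$reads))
    stop("library was simulated without reads; re-run with include_reads = TRUE")
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop(sprintf("directory '%s' is not empty; use force = TRUE to overwrite", dir))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lens <- setNames(Biostrings::width(lib$genome), names(lib$genome))
  write_genome(lib$genome, file.path(dir, "genome.fasta"))
  write_embl(lib$genes, lens, file.path(dir, "annotation.embl"))
  write_gff3(lib$genes, lens, file.path(dir, "annotation.gff3"))
  write_fastq(lib$reads, file.path(dir, "reads.fastq"))
  write_plots(lib$truth_plots, file.path(dir, "truth"))
  write_gene_stats(lib$truth_gene_stats, file.path(dir, "truth_gene_stats.tsv"))
  write.table(lib$insertions, file.path(dir, "truth_insertions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(lib$essential_ids, file.path(dir, "truth_essential_ids.txt"))
  cfg <- lib$config
  manifest <- c(
    sprintf("seed=%d", cfg$seed),
    sprintf("replicon_names=%s", paste(names(cfg$replicon_lengths),
                                       collapse = ",")),
    sprintf("replicon_lengths=%s", paste(cfg$replicon_lengths,
                                         collapse = ",")),
    sprintf("n_genes=%d", cfg$n_genes),
    sprintf("gene_length_range=%d,%d", cfg$gene_length_range[1L],
            cfg$gene_length_range[2L]),
    sprintf("frac_essential=%.17g", cfg$frac_essential),
    sprintf("n_insertions=%d", cfg$n_insertions),
    sprintf("reads_per_insertion=%.17g", cfg$reads_per_insertion),
    sprintf("n_reads=%s", if (is.null(cfg$n_reads)) "" else cfg$n_reads),
    sprintf("tag=%s", cfg$tag$tag),
    sprintf("tag_max_mismatches=%d", cfg$tag$max_mismatches),
    sprintf("read_length=%d", cfg$read_length),
    sprintf("frac_untagged=%.17g", cfg$frac_untagged),
    sprintf("base_error_rate=%.17g", cfg$base_error_rate))
  manifest_path <- file.path(dir, "manifest.txt")
  writeLines(manifest, manifest_path)
  invisible(manifest_path)
}

#' Regenerate a simulated library from a fixture manifest
#'
#' @param manifest_path path to a `manifest.txt` written by
#'   [write_fixture()].
#' @param include_reads see [simulate_library()].
#' @return The regenerated `sim_library`.
#' @export
simulate_from_manifest <- function(manifest_path, include_reads = TRUE) {
  kv <- strsplit(readLines(manifest_path), "=", fixed = TRUE)
  vals <- setNames(vapply(kv, function(x)
    if (length(x) > 1L) x[[2L]] else "", character(1)),
    vapply(kv, `[[`, character(1), 1L))
  lens <- setNames(
    as.integer(strsplit(vals[["replicon_lengths"]], ",")[[1L]]),
    strsplit(vals[["replicon_names"]], ",")[[1L]])
  glr <- as.integer(strsplit(vals[["gene_length_range"]], ",")[[1L]])
  config <- simulation_config(
    seed = as.integer(vals[["seed"]]),
    replicon_lengths = lens,
    n_genes = as.integer(vals[["n_genes"]]),
    gene_length_range = glr,
    frac_essential = as.numeric(vals[["frac_essential"]]),
    n_insertions = as.integer(vals[["n_insertions"]]),
    reads_per_insertion = as.numeric(vals[["reads_per_insertion"]]),
    n_reads = if (nzchar(vals[["n_reads"]]))
      as.integer(vals[["n_reads"]]) else NULL,
    tag = tag_spec(vals[["tag"]],
                   as.integer(vals[["tag_max_mismatches"]])),
    read_length = as.integer(vals[["read_length"]]),
    frac_untagged = as.numeric(vals[["frac_untagged"]]),
    base_error_rate = as.numeric(vals[["base_error_rate"]]))
  simulate_library(config, include_reads = include_reads)
}
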