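# Built-in seed-and-extend mapper: length-banded defaults, ground-truth
# placement, ambiguity handling, and equivalence with the exhaustive
# both-strand Hamming scan oracle.

test_that("default parameters follow the length bands and are monotone", {
  p50 <- default_mapping_params(50)
  expect_equal(c(p50$kmer, p50$step), c(13L, 2L))
  expect_equal(p50$min_identity, 0.96)
  p80 <- default_mapping_params(80)
  expect_equal(c(p80$kmer, p80$step), c(13L, 4L))
  p120 <- default_mapping_params(120)
  expect_equal(c(p120$kmer, p120$step), c(20L, 4L))
  lens <- seq(20, 300, by = 5)
  kmers <- vapply(lens, function(l) default_mapping_params(l)$kmer, integer(1))
  expect_true(all(diff(kmers) >= 0))
  expect_error(default_mapping_params(19), "short")
})

test_that("error-free extracts map uniquely to their source coordinate", {
  set.seed(31)
  g <- c(repA = random_dna(50000))
  pos <- sample(50000 - 49, 40)
  fwd <- substring(g[["repA"]], pos, pos + 49)
  reads <- sequenced_reads(sprintf("r%02d", 1:40), fwd,
                           rep(strrep("I", 50), 40))
  aln <- map_reads(reads, g)
  expect_true(all(aln$is_mapped & aln$is_unique))
  expect_equal(aln$pos, pos)
  expect_true(all(aln$strand == "+"))
  expect_true(all(aln$mapq == 60L))
})

test_that("reverse-complemented extracts map to the - strand at the leftmost base", {
  set.seed(32)
  g <- c(repA = random_dna(20000))
  pos <- sample(20000 - 49, 20)
  rc <- revcomp_chr(substring(g[["repA"]], pos, pos + 49))
  reads <- sequenced_reads(sprintf("r%02d", 1:20), rc,
                           rep(strrep("I", 50), 20))
  aln <- map_reads(reads, g)
  expect_true(all(aln$is_mapped & aln$is_unique))
  expect_true(all(aln$strand == "-"))
  expect_equal(aln$pos, pos)  # leftmost base of the covered interval
})

test_that("a repeated sequence is reported as non-unique", {
  set.seed(33)
  left <- random_dna(3000); mid <- random_dna(2000)
  tract <- strrep("A", 60)
  g <- c(chr = paste0(left, tract, mid, tract, random_dna(1000)))
  reads <- sequenced_reads("polyA", strrep("A", 50), strrep("I", 50))
  aln <- map_reads(reads, g, mapping_params(13, 2))
  expect_true(aln$is_mapped)
  expect_false(aln$is_unique)
  expect_equal(aln$mapq, 0L)
  # reported position is the leftmost of the tied best locations
  expect_equal(aln$pos, 3001L)
})

test_that("reads shorter than the seed give unmapped records, conserved", {
  g <- c(chr = random_dna(1000))
  reads <- sequenced_reads(c("tiny", "ok"),
                           c("ACGTACGT", substring(g[["chr"]], 100, 149)),
                           c(strrep("I", 8), strrep("I", 50)))
  aln <- map_reads(reads, g, mapping_params(13, 2))
  expect_equal(nrow(aln), 2L)  # one record per input read
  expect_false(aln$is_mapped[1])
  expect_true(aln$is_mapped[2])
})

test_that("mapper equals the exhaustive oracle on mutated and random reads", {
  set.seed(34)
  genome_chr <- c(c1 = random_dna(6000), c2 = random_dna(3000))
  mk_extract <- function(n_mut) {
    rn <- sample(names(genome_chr), 1)
    L <- nchar(genome_chr[[rn]])
    p <- sample(L - 49, 1)
    r <- substring(genome_chr[[rn]], p, p + 49)
    if (n_mut > 0)
      for (q in sample(50, n_mut))
        substr(r, q, q) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(r, q, q)), 1)
    if (runif(1) < 0.5) r <- revcomp_chr(r)
    r
  }
  bases <- c(vapply(rep(0, 40), mk_extract, character(1)),
             vapply(rep(2, 40), mk_extract, character(1)),
             vapply(rep(4, 20), mk_extract, character(1)),
             vapply(rep(50, 20), function(i) random_dna(50), character(1)))
  reads <- sequenced_reads(sprintf("r%03d", seq_along(bases)), bases,
                           rep(strrep("I", 50), length(bases)))
  aln <- map_reads(reads, genome_chr, mapping_params(13, 2))
  for (i in seq_along(bases)) {
    o <- oracle_map_read(bases[i], genome_chr)
    expect_equal(aln$is_mapped[i], o$is_mapped, label = paste("read", i))
    if (o$is_mapped) {
      expect_equal(aln$is_unique[i], o$is_unique, label = paste("read", i))
      expect_equal(aln$pos[i], o$pos, label = paste("read", i))
      expect_equal(aln$replicon[i], o$rep, label = paste("read", i))
      expect_equal(aln$strand[i], o$strand, label = paste("read", i))
    }
  }
})

test_that("mapping is deterministic", {
  set.seed(35)
  g <- c(chr = random_dna(8000))
  bases <- vapply(1:50, function(i) {
    p <- sample(7950, 1); substring(g[["chr"]], p, p + 49)
  }, character(1))
  reads <- sequenced_reads(sprintf("r%02d", 1:50), bases,
                           rep(strrep("I", 50), 50))
  expect_identical(map_reads(reads, g), map_reads(reads, g))
})

test_that("the external-mapper adapter falls back gracefully and cross-checks", {
  cfg <- tiny_config(seed = 17, replicon_lengths = c(chr = 12000L),
                     n_genes = 10L, n_insertions = 150L, n_reads = 600L)
  lib <- simulate_library(cfg)
  trimmed <- filter_and_trim(lib$reads, cfg$tag)$reads
  fq <- withr::local_tempfile(fileext = ".fastq")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fastq(trimmed, fq)
  write_genome(lib$genome, fa)

  # a missing executable degrades to the built-in mapper with a notice
  sam1 <- withr::local_tempfile(fileext = ".sam")
  expect_message(
    external_mapper_adapter(fq, fa, sam1, command = "no_such_mapper_xyz"),
    "built-in")
  builtin <- read_sam(sam1)
  expect_equal(nrow(builtin), nrow(trimmed))

  # when the external tool is present, it must agree on is_mapped for
  # error-free unique reads
  if (nzchar(Sys.which("minimap2"))) {
    sam2 <- withr::local_tempfile(fileext = ".sam")
    out <- external_mapper_adapter(fq, fa, sam2)
    ext <- read_sam(sam2)
    ext <- ext[!duplicated(ext$read_id), ]
    common <- intersect(builtin$read_id, ext$read_id)
    b <- builtin[match(common, builtin$read_id), ]
    e <- ext[match(common, ext$read_id), ]
    expect_gt(mean(b$is_mapped == e$is_mapped), 0.99)
  }
})
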