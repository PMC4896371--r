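# Readers and writers must be mutually inverse (bit-exact) on valid input
# and fail loudly, naming the offending line, on malformed input.

test_that("FASTQ reader handles empty files and single records", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(), f)
  expect_equal(nrow(read_fastq(f)), 0L)

  b <- random_dna(50)
  writeLines(c("@r1 some description", b, "+", strrep("I", 50)), f)
  reads <- read_fastq(f)
  expect_equal(nrow(reads), 1L)
  expect_equal(reads$read_id, "r1")
  expect_equal(nchar(reads$bases), 50L)
  expect_equal(phred_scores(reads$quals)[[1L]], rep(40L, 50))
})

test_that("FASTQ write/read round-trips exactly, plain and gzipped", {
  set.seed(101)
  for (ext in c(".fastq", ".fastq.gz")) {
    lens <- sample(20:80, 50, replace = TRUE)
    reads <- sequenced_reads(sprintf("read_%02d", 1:50),
                             vapply(lens, random_dna, character(1)),
                             random_quals(lens))
    f <- withr::local_tempfile(fileext = ext)
    expect_equal(write_fastq(reads, f), 50L)
    expect_identical(read_fastq(f), reads)
  }
})

test_that("malformed FASTQ errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), f)
  expect_error(read_fastq(f), "line 5")
  writeLines(c("@r1", "ACGT", "+", "III"), f)
  expect_error(read_fastq(f), "line 4")
  writeLines(c("@r1", "ACGT", "x", "IIII"), f)
  expect_error(read_fastq(f), "line 3")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACG"), f)
  expect_error(read_fastq(f), "multiple of 4")
})

test_that("plot files write and read exactly, with gzip sniffing", {
  zero <- insertion_plot("rep", integer(10), integer(10))
  f <- withr::local_tempfile(fileext = ".plot")
  write_plot(zero, f)
  expect_identical(readLines(f), rep("0 0", 10))

  fwd <- integer(10); fwd[7] <- 3L
  p <- insertion_plot("rep", fwd, integer(10))
  write_plot(p, f)
  expect_identical(readLines(f)[7], "3 0")

  set.seed(7)
  for (ext in c(".plot", ".plot.gz")) {
    p <- insertion_plot("chr", rpois(500, 0.3), rpois(500, 0.3))
    f2 <- withr::local_tempfile(fileext = ext)
    write_plot(p, f2)
    back <- read_plot(f2, replicon = "chr", expected_length = 500)
    expect_identical(back$forward, p$forward)
    expect_identical(back$reverse, p$reverse)
  }
  expect_error(read_plot(f, expected_length = 11), "11")
})

test_that("EMBL parsing handles complement locations and join envelopes", {
  f <- withr::local_tempfile(fileext = ".embl")
  writeLines(c(
    "ID   chr1; SV 1; circular; genomic DNA; STD; PRO; 1000 BP.",
    "FH   Key             Location/Qualifiers",
    "FT   source          1..1000",
    "FT   CDS             complement(101..400)",
    "FT                   /locus_tag=\"g1\"",
    "FT                   /product=\"a protein with a long description",
    "FT                   continued on the next line\"",
    "FT   CDS             join(500..600,650..700)",
    "FT                   /locus_tag=\"g2\"",
    "FT   misc_feature    10..20",
    "//"), f)
  ann <- read_annotation(f, dialect = "embl")
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$start, c(101L, 500L))
  expect_equal(ann$end, c(400L, 700L))
  expect_equal(ann$strand, c("-", "+"))
  expect_equal(ann$replicon, c("chr1", "chr1"))
  expect_match(ann$product[1], "continued on the next line")
})

test_that("annotation with zero gene features yields an empty table", {
  f <- withr::local_tempfile(fileext = ".embl")
  writeLines(c("ID   chr1; SV 1; circular; genomic DNA; STD; PRO; 100 BP.",
               "FT   source          1..100", "//"), f)
  expect_equal(nrow(read_annotation(f, dialect = "embl")), 0L)
})

test_that("simulator annotation round-trips through both dialects", {
  lib <- simulate_library(tiny_config(seed = 3), include_reads = FALSE)
  lens <- stats::setNames(Biostrings::width(lib$genome), names(lib$genome))
  core <- c("gene_id", "replicon", "start", "end", "strand", "feature_type")

  fe <- withr::local_tempfile(fileext = ".embl")
  write_embl(lib$genes, lens, fe)
  expect_equal(read_annotation(fe, replicon_lengths = lens)[core],
               lib$genes[core])

  fg <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(lib$genes, lens, fg)
  back <- read_annotation(fg, replicon_lengths = lens)
  back <- back[order(match(back$gene_id, lib$genes$gene_id)), ]
  rownames(back) <- NULL
  expect_equal(back[core], lib$genes[core])
})

test_that("feature coordinates select the ground-truth gene sequence", {
  lib <- simulate_library(tiny_config(seed = 9), include_reads = FALSE)
  g <- lib$genes[5, ]
  extracted <- substring(as.character(lib$genome[[g$replicon]]),
                         g$start, g$end)
  expect_equal(nchar(extracted), g$end - g$start + 1L)
  # same sequence recovered through the written FASTA
  f <- withr::local_tempfile(fileext = ".fasta")
  write_genome(lib$genome, f)
  genome2 <- read_genome(f)
  expect_identical(substring(as.character(genome2[[g$replicon]]),
                             g$start, g$end), extracted)
})

test_that("SAM records round-trip through write_sam/read_sam", {
  aln <- data.frame(
    read_id = c("a", "b", "c"),
    replicon = c("chr", "chr", NA),
    pos = c(10L, 100L, NA),
    strand = c("+", "-", "+"),
    aligned_length = c(50L, 50L, 50L),
    mapq = c(60L, 0L, 0L),
    is_unique = c(TRUE, FALSE, FALSE),
    is_mapped = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, c(chr = 1000L), f)
  back <- read_sam(f)
  expect_equal(back$read_id, aln$read_id)
  expect_equal(back$pos, aln$pos)
  expect_equal(back$strand, aln$strand)
  expect_equal(back$is_mapped, aln$is_mapped)
  expect_equal(back$is_unique, aln$is_unique)
  expect_equal(back$aligned_length[back$is_mapped],
               aln$aligned_length[aln$is_mapped])
})

test_that("gene-statistics tables round-trip bit-exactly", {
  lib <- simulate_library(tiny_config(seed = 5), include_reads = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_stats(lib$truth_gene_stats, f)
  expect_equal(read_gene_stats(f), lib$truth_gene_stats)
})
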