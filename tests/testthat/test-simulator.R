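# The library simulator: determinism, ground-truth bookkeeping, fixture
# round trips and the end-to-end identity with the analysis modules.

test_that("the same seed reproduces the library byte-identically", {
  cfg <- tiny_config(seed = 81)
  lib1 <- simulate_library(cfg)
  lib2 <- simulate_library(cfg)
  expect_identical(lib1$reads, lib2$reads)
  expect_identical(lib1$insertions, lib2$insertions)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fastq(lib1$reads, f1); write_fastq(lib2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different library
  expect_false(identical(simulate_library(tiny_config(seed = 82))$reads,
                         lib1$reads))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(999)
  a <- runif(3)
  set.seed(999)
  invisible(simulate_library(tiny_config(seed = 81), include_reads = FALSE))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("essential genes receive exactly zero insertions", {
  cfg <- tiny_config(seed = 83, n_genes = 50L, frac_essential = 0.2,
                     replicon_lengths = c(chr = 40000L))
  lib <- simulate_library(cfg, include_reads = FALSE)
  expect_equal(length(lib$essential_ids), 10L)
  truth <- lib$truth_gene_stats
  ess <- truth$locus_tag %in% lib$essential_ids
  expect_true(all(truth$ins_count[ess] == 0L))
  expect_true(all(truth$read_count[ess] == 0L))
  # and insertion positions are genuinely outside essential spans
  for (gid in lib$essential_ids) {
    g <- lib$genes[lib$genes$gene_id == gid, ]
    hit <- lib$insertions$replicon == g$replicon &
      lib$insertions$pos >= g$start & lib$insertions$pos <= g$end
    expect_equal(sum(hit), 0L)
  }
})

test_that("ground-truth conservation: plot totals equal tagged reads", {
  lib <- simulate_library(tiny_config(seed = 84))
  total <- sum(vapply(lib$truth_plots, function(p)
    summarize_plot(p)$total_reads, numeric(1)))
  expect_equal(total, lib$n_tagged)
  expect_equal(lib$n_tagged + lib$n_untagged, nrow(lib$reads))
  # exact read sizing under n_reads
  expect_equal(nrow(lib$reads), 4000L)
  expect_equal(lib$n_untagged, 400L)
})

test_that("tagged reads reproduce tag + genomic flank at the insertion", {
  cfg <- tiny_config(seed = 85, frac_untagged = 0, base_error_rate = 0)
  lib <- simulate_library(cfg)
  res <- filter_and_trim(lib$reads, cfg$tag)
  expect_equal(res$report$fraction_with_tag, 1)
  aln <- map_reads(res$reads, lib$genome)
  expect_true(all(aln$is_mapped & aln$is_unique))
  # junction coordinates recover the planted insertion multiset exactly
  junction <- ifelse(aln$strand == "+", aln$pos,
                     aln$pos + aln$aligned_length - 1L)
  got <- sort(paste(aln$replicon, junction, aln$strand))
  ins <- lib$insertions[lib$insertions$count > 0, ]
  want <- sort(paste(rep(ins$replicon, ins$count),
                     rep(ins$pos, ins$count),
                     rep(ins$strand, ins$count)))
  expect_identical(got, want)
})

test_that("sequencing errors hit only the genomic part at the set rate", {
  cfg <- tiny_config(seed = 86, frac_untagged = 0, base_error_rate = 0.02)
  lib <- simulate_library(cfg)
  # the tag region is error-free: every read still carries an intact tag
  expect_equal(filter_and_trim(lib$reads, cfg$tag)$report$fraction_with_tag, 1)
  # error rate in the genomic part is near the configured value
  err_free <- simulate_library(tiny_config(seed = 86, frac_untagged = 0,
                                           base_error_rate = 0))
  a <- substring(lib$reads$bases, 11)
  b <- substring(err_free$reads$bases[match(lib$reads$read_id,
                                            err_free$reads$read_id)], 11)
  mm <- mapply(function(x, y)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), a, b)
  rate <- sum(mm) / sum(nchar(a))
  expect_gt(rate, 0.012)
  expect_lt(rate, 0.028)
})

test_that("untagged contaminants never match the tag", {
  cfg <- tiny_config(seed = 87, frac_untagged = 0.3)
  lib <- simulate_library(cfg)
  untagged <- lib$reads[startsWith(lib$reads$read_id, "u"), ]
  expect_equal(nrow(untagged), lib$n_untagged)
  expect_false(any(match_tag(untagged, cfg$tag)))
})

test_that("fixtures round-trip through the manifest", {
  cfg <- tiny_config(seed = 88)
  lib <- simulate_library(cfg)
  dir <- file.path(withr::local_tempdir(), "fixture")
  write_fixture(lib, dir)
  expect_error(write_fixture(lib, dir), "not empty")
  lib2 <- simulate_from_manifest(file.path(dir, "manifest.txt"))
  expect_identical(lib2$reads, lib$reads)
  expect_identical(lib2$insertions, lib$insertions)
  expect_equal(lib2$truth_gene_stats, lib$truth_gene_stats)
  # written truth table equals the recomputed per-gene statistics
  expect_equal(read_gene_stats(file.path(dir, "truth_gene_stats.tsv")),
               gene_stats(lib$truth_plots, lib$genes))
})

test_that("truth insertion indices are bimodal in the default conditions", {
  sens <- vapply(1:3, function(s) {
    lib <- simulate_library(simulation_config(seed = s),
                            include_reads = FALSE)
    truth <- lib$truth_gene_stats
    ess <- truth$locus_tag %in% lib$essential_ids
    expect_equal(mean(truth$ins_index[!ess]), 0.05, tolerance = 0.1)
    expect_true(all(truth$ins_index[ess] == 0))
    mean(truth$ins_index[!ess] > 0.01)
  }, numeric(1))
  expect_true(all(sens > 0.99))
})
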