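## Orchestration of the full analysis: filter -> map -> plot -> gene stats,
## with a machine-readable run report. Orchestrated output is byte-identical
## to running the stages one at a time with the same parameters.

#' Run the full TraDIS processing pipeline
#'
#' Filters and trims tagged reads, maps them, builds per-replicon insertion
#' plots and the per-gene statistics table, and writes every intermediate
#' (`filtered.fastq`, `mapped.sam`, `<prefix>.<replicon>.insert_site_plot`,
#' `gene_stats.tsv`) plus a run report (`report.tsv` and `report.txt`) into
#' `outdir`. Any stage error aborts with the stage name.
#'
#' @param fastq_path input FASTQ (optionally gzipped).
#' @param reference_path reference genome FASTA.
#' @param annotation_path gene annotation (EMBL feature table or GFF3);
#'   `NULL` skips the gene-statistics stage.
#' @param tag a [tag_spec()].
#' @param outdir output directory (created if absent).
#' @param params `mapping_params`, or `NULL` for read-length defaults.
#' @param trim5,trim3 terminal trim fractions passed to [gene_stats()].
#' @param gzip_plots write gzipped plot files.
#' @param quiet suppress stage log lines (written to `stderr`).
#' @return A list with `plots`, `stats` (or `NULL` without annotation) and
#'   `report` (per-stage read counts, parameters and wall times).
#' @export
run_pipeline <- function(fastq_path, reference_path, annotation_path, tag,
                         outdir, params = NULL, trim5 = 0, trim3 = 0,
                         gzip_plots = FALSE, quiet = FALSE) {
  stopifnot(inherits(tag, "tag_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, msg) {
    if (!quiet) message(sprintf("[tradis %s] %s", stage, msg))
  }
  stage_times <- c()
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline failed at stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE))
    stage_times[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  filt <- run_stage("filter", {
    reads <- read_fastq(fastq_path)
    res <- filter_and_trim(reads, tag)
    write_fastq(res$reads, file.path(outdir, "filtered.fastq"))
    write_tag_report(res$report, file.path(outdir, "tag_report.tsv"))
    log_line("filter", sprintf("%d/%d reads with tag",
                               res$report$reads_with_tag,
                               res$report$total_reads))
    res
  })

  genome <- read_genome(reference_path)
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (is.null(params) && nrow(filt$reads) > 0L)
    params <- default_mapping_params(min(nchar(filt$reads$bases)))
  if (is.null(params)) params <- mapping_params(13L, 2L)

  aln <- run_stage("map", {
    aln <- map_reads(filt$reads, genome, params)
    write_sam(aln, lens, file.path(outdir, "mapped.sam"))
    log_line("map", sprintf("%d/%d reads mapped (%d uniquely)",
                            sum(aln$is_mapped), nrow(aln),
                            sum(aln$is_unique)))
    aln
  })

  plots <- run_stage("plot", {
    plots <- build_plots(aln, genome, params)
    write_plots(plots, file.path(outdir, "tradis"), gzip = gzip_plots)
    plots
  })

  stats <- NULL
  if (!is.null(annotation_path)) {
    stats <- run_stage("genestats", {
      genes <- read_annotation(annotation_path, replicon_lengths = lens)
      stats <- gene_stats(plots, genes, trim5 = trim5, trim3 = trim3)
      write_gene_stats(stats, file.path(outdir, "gene_stats.tsv"))
      log_line("genestats", sprintf("%d genes", nrow(stats)))
      stats
    })
  }

  retained <- sum(aln$is_mapped & aln$is_unique &
                    aln$mapq >= params$mapq_unique_threshold)
  total <- filt$report$total_reads
  report <- structure(list(
    total_reads = total,
    reads_with_tag = filt$report$reads_with_tag,
    reads_mapped = sum(aln$is_mapped),
    reads_uniquely_mapped = sum(aln$is_unique),
    reads_retained = retained,
    fraction_tagged_and_unique = if (total > 0L) retained / total else 0,
    params = params,
    tag = tag$tag,
    tag_max_mismatches = tag$max_mismatches,
    trim5 = trim5, trim3 = trim3,
    stage_seconds = stage_times),
    class = "tradis_run_report")
  .write_run_report(report, outdir)
  list(plots = plots, stats = stats, report = report)
}

.write_run_report <- function(report, outdir) {
  p <- report$params
  kv <- c(
    total_reads = report$total_reads,
    reads_with_tag = report$reads_with_tag,
    reads_mapped = report$reads_mapped,
    reads_uniquely_mapped = report$reads_uniquely_mapped,
    reads_retained = report$reads_retained,
    fraction_tagged_and_unique = sprintf("%.17g",
                                         report$fraction_tagged_and_unique),
    tag = report$tag,
    tag_max_mismatches = report$tag_max_mismatches,
    kmer = p$kmer, step = p$step,
    min_identity = sprintf("%.17g", p$min_identity),
    mapq_unique_threshold = p$mapq_unique_threshold,
    trim5 = sprintf("%.17g", report$trim5),
    trim3 = sprintf("%.17g", report$trim3),
    package_version = as.character(utils::packageVersion("tradisr")))
  writeLines(paste(names(kv), kv, sep = "\t"),
             file.path(outdir, "report.tsv"))
  txt <- c("TraDIS pipeline run report",
           sprintf("  %-28s %s", names(kv), kv),
           sprintf("  %-28s %.2f s", paste0("time_", names(report$stage_seconds)),
                   unlist(report$stage_seconds)))
  writeLines(txt, file.path(outdir, "report.txt"))
  invisible(NULL)
}

#' @export
print.tradis_run_report <- function(x, ...) {
  cat(sprintf(paste0(
    "TraDIS run: %d reads; %d tagged, %d mapped, %d unique, %d retained\n",
    "fraction tagged and uniquely mapped: %.4f\n"),
    x$total_reads, x$reads_with_tag, x$reads_mapped,
    x$reads_uniquely_mapped, x$reads_retained,
    x$fraction_tagged_and_unique))
  invisible(x)
}
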