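---
title: "Models and methods in tradisr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tradisr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tradisr` analyzes transposon insertion sequencing (TIS / Tn-seq / TraDIS)
experiments: a dense library of otherwise isogenic transposon mutants is
sequenced across transposon–chromosome junctions, and the abundance of
reads at each junction reports the fitness of the corresponding insertion
mutant. This vignette describes the models the package implements, the
tunable parameters and their defaults, the numerical choices, and what the
built-in simulator does and does not emulate.

## The read model and tag filtering

Sequencing begins inside the transposon, so a genuine junction read starts
with a short *transposon tag* (typically 8–12 bases, configurable 1–20)
followed by chromosomal sequence. `filter_and_trim()` accepts a read when
the Hamming distance between its prefix and the tag is at most
`max_mismatches` (default 0), then removes the tag.

Three deliberate restrictions:

* **Anchored matching.** The tag is matched at position 1 only. Scanning
  into the read would accept reads in which the tag-like sequence is
  chromosomal, i.e. not a junction, so a scan option is intentionally
  absent.
* **Hamming, not edit, distance.** Tag bases come from early, high-accuracy
  sequencing cycles; indel tolerance would require alignment and change the
  meaning of the anchored prefix.
* **No reverse-complement check.** The protocol defines reads as 5′-tagged;
  a reverse-complement match would again not be a junction.

Base qualities are ignored during matching (a low-quality tag base simply
counts as a mismatch if miscalled). A read equal to the tag alone trims to
length zero, cannot be mapped, and is counted as tagless.

## Mapping

Insertion calling needs one number per read — the reference coordinate of
the junction-proximal base — so the built-in mapper is deliberately simple:
sampled k-mer seeds over the reference, candidate positions from seed hits,
and ungapped extension scored by identity (no indels). This keeps the
mapper exactly checkable against an exhaustive all-positions, both-strands
Hamming scan, which the test suite does on desk-scale genomes.

Defaults are banded by read length and can all be overridden:

| read length | `kmer` | `step` | `min_identity` |
|---|---|---|---|
| 20–69 nt | 13 | 2 | 0.96 |
| 70–99 nt | 13 | 4 | 0.96 |
| ≥ 100 nt | 20 | 4 | 0.96 |

With `kmer = 13`, `step = 2` and at most two mismatches in a 50 nt read
(the 0.96 identity floor), a seed hit is guaranteed by a pigeonhole
argument, so on reads up to ~60 nt the seeded mapper provably finds every
location at or above the identity floor — the oracle-equivalence tests rely
on this.

A read is *mapped* when its best location reaches `min_identity` and
*unique* when that best strictly beats the second best; ties are reported
as non-unique at the lexicographically smallest `(replicon, position,
strand)` so output is deterministic. The built-in mapper assigns MAPQ 60 to
unique and 0 to non-unique placements; only mapped, unique records with
MAPQ at or above `mapq_unique_threshold` (default 30) reach the insertion
plots. `external_mapper_adapter()` lets a production short-read mapper
(default `minimap2`) produce the SAM instead, and degrades to the built-in
mapper when the executable is absent.

## Insertion plots and the junction coordinate

The transposon tag sits at the read's 5′ end, so that end abuts the
transposon. `build_plots()` therefore counts, per replicon and per strand,

* `forward[pos]` for a `+` alignment, and
* `reverse[pos + aligned_length - 1]` for a `-` alignment,

i.e. always the junction-proximal base, so reads from the two sides of one
insertion report (near-)identical coordinates. Which read end existing
TIS pipelines count for minus-strand reads is not standardized; the
convention here is explicit and flippable
(`junction_end = "three_prime"`). No cross-strand site merging is done:
each base is its own potential site, and the small coordinate offsets
introduced by target-site duplication are tolerated downstream by the
per-gene unique-site count. Plot files are Artemis userplot text: one line
per reference base, two integer columns (forward, reverse), optionally
gzipped, round-tripping bit-exactly.

A subtle invariant worth recording: reverse-complementing the genome *and*
every read preserves each read's mapping strand (both sequences flip) but
moves the tag-proximal end to the read's other extremity. The mirrored
dataset therefore reproduces the original plots mirrored — without a
forward/reverse swap — when counted at the 3′ end.

## Per-gene statistics

For each annotated gene (CDS, tRNA and rRNA features by default; non-CDS
rows flagged), `gene_stats()` reports the summed read count, the number of
unique insertion sites, and the *insertion index* — unique sites divided by
gene length. Both strands contribute regardless of gene strand, since an
insertion disrupts the gene either way; bases shared by overlapping genes
count fully toward both. Optional `trim5`/`trim3` fractions (default 0)
exclude gene termini, where insertions often fail to disrupt function; the
index denominator remains the full gene length so trimmed and untrimmed
indices stay comparable. Compound `join(...)` annotation locations are
reduced to their envelope — exon structure is irrelevant for gene-level
counting in bacteria, a documented limitation for the rare spliced case.

## Essentiality: the two-gamma model

In a dense library the genome-wide distribution of insertion indices is
bimodal: essential genes cluster at or near zero, non-essential genes form
a broad positive mode. The package models the two modes as gamma densities
and separates them in three steps.

1. **Valley location.** `find_pivot()` takes a kernel density estimate
   (Gaussian kernel, Silverman bandwidth) of all indices and returns the
   argmin between the two largest local maxima. Zeros are included: with
   planted or truly untouched essential genes at index exactly 0, excluding
   them would leave a unimodal positive density and no valley to find.
   Unimodal input is a hard error — the library is not dense enough for
   mode-based classification. Because Silverman's rule depends on *n*, the
   pivot is only approximately invariant to duplicating the data; the
   tests assert invariance to within a small fraction of the inter-mode
   separation.
2. **Component fitting.** Index 0 cannot enter a gamma likelihood; zeros
   are replaced by half the smallest positive index (a standard
   pseudo-value, recorded in the fit metadata). Indices below the pivot
   seed the essential component and the rest the non-essential component,
   both by maximum likelihood (`MASS::fitdistr`). The hard split truncates
   both components at the pivot and leaks each tail into the other's fit,
   which measurably biases the recovered parameters, so the split fits are
   used only as initialization and refined by EM on the two-component
   gamma mixture (weighted gamma ML per M-step, Newton on the shape). When
   one side is degenerate — every essential gene at the same pseudo-value
   carries no scale information — ML diverges and a weakly informative
   moment fit with the coefficient of variation floored at 0.5 is used
   instead, and EM is skipped.
3. **Classification.** Genes are labeled from the *changepoints*: the
   index values where the log2 ratio of essential to non-essential
   component densities crosses `±loglik_threshold` (default 2, i.e. 4:1
   odds, the established TraDIS convention). At or below the lower
   changepoint a gene is `essential`, at or above the upper
   `non_essential`, between them `ambiguous`. Between the two modes this
   is identical to thresholding the log2 ratio itself; far above the
   non-essential mode the raw ratio can turn around (whichever component
   has the smaller rate eventually dominates), so the changepoint interval
   is authoritative. The reported `log2_ratio` column is the raw ratio.
   Zero-index genes must come out essential; the code asserts this rather
   than assuming it.

Genes shorter than 100 nt are excluded from fitting — their indices are
too granular — but still classified. No multiple-testing correction is
applied: this is a likelihood-ratio classification, not hypothesis
testing, and its error rates should be read from simulation, not from a
nominal alpha.

```{r essentiality-example}
library(tradisr)
lib <- simulate_library(simulation_config(seed = 1), include_reads = FALSE)
ea <- essentiality_analysis(lib$truth_gene_stats)
ea$fit
table(ea$calls$label)
```

## Comparative analysis

`nb_exact_test()` identifies genes whose mutant abundance differs between
two conditions. The computation is self-contained so the toolkit carries
no runtime dependency on an external count-testing package; the test suite
cross-checks the normalization against an independent implementation.

* **Normalization.** Trimmed mean of M-values with the published defaults:
  30% two-sided trim on log-ratios, 5% on average log-abundance,
  inverse-asymptotic-variance weights, reference column the one whose
  75th-percentile count/library-size is closest to the mean. Factors are
  scaled to geometric mean 1.
* **Pseudo-counts.** Each sample is scaled to the geometric-mean effective
  library size — a plain rescaling in place of the quantile-adjustment
  construction used elsewhere, a documented approximation that keeps the
  conditional argument below exact at equalized depths.
* **Dispersion.** A single common negative-binomial dispersion φ,
  maximizing the conditional log-likelihood of within-group pseudo-counts
  given their group totals, over all groups with replication (optimized on
  log φ; a boundary optimum reports φ = 0, the Poisson limit). Tagwise or
  trended shrinkage is out of scope: conditional-fitness TraDIS analyses
  used a common dispersion.
* **Exact test.** Per gene, the two-sided exact conditional test of the
  group pseudo-sums given their total under NB(φ), with the
  doubled-smaller-tail convention (capped at 1). At φ = 0 and one
  replicate per side this reduces exactly to a conditional binomial test.
  Genes with zero counts in both conditions are excluded and reported with
  `NA`. Q-values are Benjamini–Hochberg across tested genes.

Fold changes are reported as `log2FC` of condition 2 over condition 1 with
a prior count of 0.5 per group mean. Read counts, not insertion counts,
are compared by default — abundance, not site saturation, is the fitness
readout — with `use = "ins_count"` available.

## The simulator

`simulate_library()` generates a complete synthetic experiment with ground
truth for every downstream quantity. Defaults describe the dense-library
regime the analysis assumes: a 450 kb chromosome plus 150 kb plasmid, 500
non-overlapping genes (600–1500 nt, uniform), 20% essential, 25,000
distinct insertion positions drawn uniformly over permissive sequence
(about one per 20 bp, putting the non-essential mean insertion index near
0.05), a 10-base tag, 50 nt of genomic sequence per read, 10% untagged
contaminant reads (the protocol's reported >90% tagged-and-mapped
performance), and a 0.1% substitution rate confined to the genomic part of
the read. Reads per insertion are geometric with mean 5, a one-parameter
stand-in for PCR and abundance dispersion; each insertion's reads are
oriented either way with probability ½. When `n_reads` is set, reads are
multinomially allocated so totals and the tagged fraction are exact — the
bookkeeping tests depend on this.

Deliberate non-realism, and hence what passing tests do *not* show about
real data: genome sequence is uniform random (no GC bias, no repeats
beyond chance, so mapping ambiguity is rarer than in real genomes; a mild
Tn5-style GC preference is available but off by default to keep truth
tables analytic); essential genes receive exactly zero insertions rather
than the depleted-but-nonzero counts of real libraries; qualities are
constant; there are no indel errors and no selection dynamics. Fixtures
regenerate bit-identically from a flat-text manifest, so nothing binary
needs to be stored.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere user-facing, matching EMBL
  and Artemis conventions.
* Qualities are Phred+33 throughout; no Solexa/Phred+64 autodetection.
* Changepoints are located by scanning the log2 ratio on a 4096-point
  geometric grid and polishing each bracketed crossing with `uniroot`
  (tolerance 1e-12); non-separated components are a hard error.
* Mapper ties are broken lexicographically; the dispersion optimizer runs
  on log φ over [1e-6, 20] with tolerance 1e-6.
* Degenerate inputs fail loudly and specifically: malformed FASTQ names
  the offending line; plot files must have exactly replicon-length lines;
  alignments to unknown replicons, genes on plot-less replicons, all-zero
  samples, and unreplicated designs without a supplied dispersion are all
  hard errors.

## Problem sizes in the test and acceptance suites

The suites run at desk scale by design: simulated libraries of 4,000 to
140,000 reads on 39–600 kb genomes; mapper-oracle equivalence on 1,000
50 nt reads against 20 kb; essentiality recovery on ten 500-gene
libraries; gamma recovery on 100 replicates of n = 4000; comparative
calibration on 2000 genes × 3 + 3 replicates. These sizes exercise every
code path, including the compiled mapper, in well under the package's own
test-time expectations.

## Known limitations

Single-end semantics only (TraDIS junction reads are effectively
single-end); no gapped alignment or base-quality-aware scoring; no BAM
output (SAM text, convertible with samtools); common dispersion only; no
operon-aware polar-effect modeling; no intergenic statistics; and the
essentiality model assumes a genuinely bimodal index distribution — sparse
libraries are rejected rather than classified badly.
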