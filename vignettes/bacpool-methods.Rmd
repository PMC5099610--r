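---
title: "Methods: simulating MTP-based BAC-pool targeted sequencing"
author: "bacpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating MTP-based BAC-pool targeted sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem the package addresses

Before cheap long-read genomes, a common way to sequence a QTL-bearing
chromosomal region in a non-model species was *targeted* BAC sequencing: a
large-insert clone library is screened by PCR for clones carrying markers
from the region, a minimum tiling path (MTP) of overlapping clones is chosen
from a fingerprint-based physical map, small pools of MTP clones are shotgun
sequenced, and the resulting assemblies are anchored back to the genetic map
for gene discovery and association work. `bacpool` re-implements that whole
strategy as a simulation-backed pipeline: every stage runs on a synthetic,
fully ground-truthed genome, so each algorithmic step can be tested against
the truth that generated its input.

The package emulates a study design built around a growth QTL on one linkage
group of a farmed marine fish: a ~700 Mb genome, a 49,152-clone HindIII
library with ~98 kb inserts (6.9 genome equivalents), a 3D pool set of
16 row + 24 column + 100 plate pools addressing 38,400 clones, SSR-marker
PCR screening, 22 MTP pools sequenced at 2 × 250 bp, hybrid scaffolding
with corrected long reads at 24×, and SNP–growth-trait association in a
96-individual family plus a 570-offspring multi-family batch.

# The synthetic genome

`generate_genome()` draws a random sequence at a configurable AT fraction
(default 59.4%, the composition reported for the assembled target region),
plants interspersed repeats to a target fraction (default 5.6%) and places
genes, SSR markers and trait SNPs:

* **Repeats** come from a small number of families (default 5); each copy
  diverges from its family consensus by 1–5% substitutions and may be
  reverse-complemented. Copies are 300–1500 bp, i.e. longer than a short
  read but far shorter than a long read — so short-read assemblies break at
  repeats *organically* and long reads rescue them, which is the central
  dynamic the pipeline demonstrates.
* **Markers** are loci whose ~300 bp amplicon template occurs exactly once
  in the genome, enforced by rejection sampling; a PCR screen must have a
  single true template. Genetic positions are assigned by a constant
  recombination rate (default 3.4 cM/Mb), making the map a linear,
  order-preserving function of physical position.
* **SNPs** are bi-allelic positions inside a few candidate genes with
  additive per-allele effects on three growth traits (body weight in g,
  total and standard length in cm); about half the SNPs carry no effect so
  association analyses see both nulls and signals.

Coordinates are 0-based half-open throughout; columns suffixed `_1based`
in TSV exports are the only 1-based values. One global seed drives derived
per-stage seeds (`stage_seed()`), so any stage can be re-run independently
and reruns are byte-identical.

The defaults mirror composition figures that were *reported for a 10 Mb
assembled region*, not a generative model of the full genome; they are used
as plausible desk-scale conditions, not as claims about any real genome.

# Library, fingerprints, contigs, tiling paths

`digest_and_clone()` models the clone library as a partial restriction
digest (every HindIII site cut independently with probability
`partial_prob`, default 0.03) followed by size selection (default
80–120 kb window); clone ends therefore sit on genuine cut sites. Clones
receive sequential plate/row/column addresses.

`fingerprint_clone()` abstracts HICF fingerprinting to the multiset of
complete-digest fragment sizes of the insert, binned at a 3 bp tolerance.
The fingerprint motif default (`GACGT`) was chosen so that, at the default
AT-rich composition, its expected spacing is ~1.36 kb — the physical map's
consensus-band calibration (1.36 kb/CB). A contig's `cb_units` is its count
of distinct bands, so `cb_to_kb()` tracks true spans; binning collisions
between near-equal fragments bias the count low by roughly 15–20%, which is
why the span-recovery contract is stated at ±25%.

`build_fpc_contigs()` joins clones by single-linkage on shared-band count
(default threshold 10 bands). Within-contig clone order uses the truth
coordinates (simulation mode); a band-based seriation is deliberately out
of scope since no stage depends on recovering order blind.
`select_mtp()` is a greedy left-to-right interval cover; among clones
reaching equally far right it prefers the leftmost start, maximizing
overlap redundancy for later BES validation. On every instance small enough
to enumerate exhaustively, the greedy cover size equals the brute-force
minimum (this is one of the package's acceptance properties).

# 3D pools, screening, deconvolution

`build_pools()` places each clone in exactly three pools. `screen_marker()`
calls a pool positive iff some member clone's insert fully contains the
marker amplicon, then applies independent per-pool false-negative /
false-positive flips — pools are presence/absence, because the emulated
screen is a binary PCR call. `deconvolve()` intersects the Cartesian
product of positive index sets with the occupied addresses; a 1×1×1
product is confirmed directly, anything larger goes to a confirmation
round ordered by `confirmation_plan()` (candidates sharing the most
indices with other candidates first — a package addition; the emulated
protocol does not state a prioritization). Inconsistent screens (a
positive row with no positive plate, say) warn and return an empty result
rather than erroring, mirroring markers that simply fail to amplify.
With no noise, deconvolution plus confirmation provably recovers the exact
positive set; the test suite verifies this exhaustively for up to three
positives on a 4×4×4 design.

# Reads, preprocessing, assembly

`simulate_short_reads()` produces inward 2 × 250 bp pairs from ~475 bp
fragments (SD 60 bp) with uniform substitution errors (default 0.2%, a
plausible MiSeq rate) and a declining quality profile; qualities and
planted errors are independent, so trimming is exercised without
conflating the two. `simulate_long_reads()` models *corrected* long reads:
log-normal lengths clipped to 0.5–31.4 kb and substitution-only residual
error (default 1%). Because no simulated read contains indels, all
internal alignment is gapless (k-mer seeded diagonal voting plus ungapped
verification) — a deliberate simplification that keeps the toolkit
self-contained; `count_mismatches()` still performs a full global affine
alignment so the Sanger-vs-NGS comparison does not inherit it.

`trim_reads()` reproduces LEADING:3 TRAILING:6 SLIDINGWINDOW:4:15
MINLEN:150 semantics; a read whose mate is dropped survives as unpaired.
`kmer_normalize()` is streaming (diginorm-style) normalization to a
*k-mer* coverage target of 100× at k = 25. Note the unit: a read's k-mers
are covered by reads starting in a window of `L − k + 1` of `L` positions,
so base coverage settles near `target × L/(L − k + 1)` — about 1.1× the
target at 250 bp, within the stated ≤1.2× contract, but substantially
higher for much shorter reads.

`greedy_assemble()` is a greedy overlap-layout-consensus assembler.
A contig is seeded from the first unused read and extended at both ends;
candidate reads are found by stride-indexed seed k-mers (k = 15), verified
gaplessly against the running consensus at ≥97% identity over ≥40 bp, and
the longest verified overlap wins (ties: lexicographically smaller read
id). Reads contained in the contig are absorbed into a per-column vote
matrix; the consensus is the column majority, which is what lifts the
contig identity far above the raw read error rate. Extension stops at
*branch points* — when a second extension base is supported by at least
two reads and ≥30% of the extenders — so exact repeats longer than the
read span break contigs instead of silently producing chimeras. The
procedure is deterministic for a fixed input order.

# Hybrid scaffolding and validation

`hybrid_scaffold()` mines long reads by mapping them to the contigs
(length fraction 0.2, similarity 0.9 — the workflow's mining thresholds).
A read aligned to two or more contigs contributes edges between
consecutive hits along the read, carrying relative orientation and a gap
estimate; junction evidence additionally requires ≥300 aligned bases on
both sides, which filters reads lying entirely inside diverged repeat
copies. Edges join the layout in decreasing support order, Kruskal-style;
an edge whose implied orientation or position contradicts the layout built
from better-supported edges is dropped and logged. Gaps are filled with
the column-majority consensus of the supporting reads' gap bases (a single
read contributes its bases verbatim; conflicting reads vote; ties give
`N`), otherwise with an `N` run of the estimated size. A final
co-assembly pass end-merges any remaining dovetails at ≥99% identity over
≥20 bp, the workflow's merge parameters.

`validate_and_split()` maps *all* relevant reads back at the validation
thresholds (length fraction 0.95, similarity 0.95), computes per-base
coverage from accepted mappings only, splits scaffolds at internal
zero-coverage runs and trims uncovered ends. Every surviving base is
covered, and the operation is idempotent. `anchor_sequences()` places
marker amplicons and BAC-end sequences with full/partial/absent status and
strand; `bes_pair_spans()` converts convergent same-scaffold BES pairs
into implied clone spans.

# Synteny and association

`detect_microsynteny()` chains genes that are adjacent in the query gene
order within one FPC contig (query-rank gap ≤ 1 by default) and co-locate
on one target chromosome (target-rank gap ≤ 5 and ≤ 1 Mb by default —
declared defaults; the emulated study states none). Order *within* a block
is free, matching the definition of conserved synteny as co-localization
regardless of gene order. `count_hits_per_chromosome()` calls homologous
chromosomes as the argmax plus everything ≥25% of it, an operationalization
of "a significant number of hits" that captures species where the region
maps to two chromosomes. The planted-block generator
(`simulate_homology_table()`) uses 24 target chromosomes of 40 Mb
(teleost-scale), 5-gene blocks in 500 kb windows, and a 5% best-hit noise
rate. The recovery property is evaluated at `min_genes = 3`: at
`min_genes = 2` a simple birthday computation over the noise-gene
adjacencies predicts a fraction of a chance block per table, so "zero
false blocks" is only a meaningful claim from three genes up. The
function's default stays 2, the minimal definition of "a set of adjacent
genes".

`simulate_cross()` emulates a mass-cross batch: parents receive alleles at
the population frequency, families are sire × dam pairs with uneven
contributions (defaults 62.1%/27.3% for the two major families), offspring
genotypes are Mendelian, and traits are
`mean + family effect + additive SNP effects + noise`.
`associate()` uses a pooled-variance t-test for two genotype classes (the
classical Prism-era default; Welch sits behind `var_equal = FALSE`) and
one-way ANOVA with Tukey HSD for three, summarized as a compact letter
display computed by sweep-and-split (groups share a letter iff no
significant pairwise difference separates them — verified against the
pairwise Tukey outcomes in the tests). No multiple-testing correction is
applied across SNP × trait tests, matching the emulated analysis; the
report prints the uncorrected test count so users can correct themselves.
`per_family_replication()` re-runs the test within families above a size
threshold and flags whether the genotype-mean ordering matches the pooled
analysis. `pfaffl_ratio()` implements the efficiency-corrected expression
ratio `E_t^dCt_t / E_r^dCt_r` with `dCt = Ct(calibrator) − Ct(sample)`
(the sign convention is fixed here because it is ambiguous in common
usage), and `expression_contrast()` t-tests log-ratios between groups.

# Problem sizes and what passing means

The test suite and `scripts/acceptance.R` run at desk scale, chosen so the
full suite completes in minutes on one core: a 200–400 kb genome, one
simulated FPC pool of three ~100 kb clones (~300 kb span) sequenced at the
study's 130× short / 24× long coverage, 1,000–2,000 association
simulations, and 10–20 synteny seeds. At these sizes the pipeline's
acceptance properties are: ≥95% of the truth span reconstructed at ≥99.5%
identity with hybrid scaffold count ≤ short-read contig count; exhaustive
zero-noise deconvolution; greedy-equals-brute-force tiling; calibrated
type-I error (0.05 ± 0.015) and >95% power for a 1-SD additive effect at
n = 570.

Passing these says the *algorithms* are correct under the generator's
assumptions. The generator does not model indels or structural variation,
PCR chimeras, cloning bias against AT-rich or unstable inserts, fragment
GC bias, quality-dependent error rates, or heterozygosity within the
sequenced individual — so real-data scaffold counts and alignment rates
(which depend on real repeat structure and external databases) are *not*
reproduced, only the arithmetic the original report prints and the
qualitative short-read-to-hybrid improvement.

# Known limitations

* Gapless internal alignment is only valid because simulated errors are
  substitutions; applying the mapper to real indel-rich reads would
  require banded extension.
* The greedy assembler is desk-scale (BAC pools, not genomes); its
  all-candidate verification would not scale to whole-genome read sets.
* Band-based clone ordering within FPC contigs is not implemented; truth
  coordinates stand in (simulation mode).
* The confirmation-plan ordering is a heuristic addition, not part of the
  emulated protocol.
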