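---
title: "Evaluating de novo transcriptome assemblies with txeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating de novo transcriptome assemblies with txeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txeval)
```

## Scope and model

When a transcriptome is assembled de novo — no reference genome, reads from
a non-model organism — the central quality question is not how long the
contigs are but how much of the organism's coding repertoire they actually
reconstruct. `txeval` implements the computations such a characterization
needs, as reusable, tested functions:

1. **digital normalization** of reads by median k-mer abundance, the
   streaming pre-assembly step that discards redundant coverage;
2. **assembly descriptive statistics** (length summaries, length-bin
   histograms, isoforms per assembly component);
3. **CDS reconstruction evaluation**: from tabular protein-homology hits,
   the fraction of each reference protein covered, classified at
   reconstruction levels and aggregated to genes through an
   ortholog-derived protein-to-gene map;
4. **expression core sets**: gene-level TPM per library, the top expressed
   fraction of each library, and the genes common to all libraries'
   top fractions, with hypergeometric fold-enrichment for annotating them.

Every stage can be exercised on synthetic inputs whose correct answer is
planted by construction, which is how the package validates itself.

## Digital normalization

A unit (a read pair by default) is judged by the median abundance of its
canonical k-mers — each k-mer collapsed with its reverse complement —
counted over the units *kept so far*. If the median is below the coverage
cutoff `C` the unit is kept and its k-mers are counted; otherwise it is
discarded and contributes nothing. Counting only kept units is essential:
it is what makes the exact-duplicate law hold (of `D` identical reads,
copy `i` sees median `i − 1`, so exactly `C` survive whenever `C < D`),
and it is the property the replay checker
(`replay_normalization()`) verifies decision by decision.

Parameter defaults follow common practice for Illumina RNA-seq input to a
de Bruijn assembler: `k = 25` bp, `C = 30`, 3′ quality trimming at
Phred `Q < 24`, minimum read length 25 bp, and an abundance cutoff of 2
for the post-pass trim of likely-erroneous k-mers
(`filter_low_abundance()`, which keeps each read's longest prefix whose
k-mers are all trusted). The median of `m` counts is defined as the
element at 0-based index `⌊m/2⌋` of the ascending sort — integer-valued
and deterministic, at the cost of being the upper-middle element for even
`m`. Two points were genuinely open and are exposed as parameters rather
than guessed: whether pairs are judged jointly (`paired_policy`, default
keep-if-either, which preserves pairing) and whether the stream is
shuffled first (`shuffle_seed`; the decision rule is order-dependent).

The counter is an exact hash of canonical k-mers. At the scales this
package targets that is affordable and makes every decision reproducible;
a probabilistic counter honoring the same query/increment contract could
be substituted without changing any downstream logic.

## CDS reconstruction evaluation

The evaluation frame is a reference proteome with a protein-to-gene map
(`protein_db()`). Hits arrive as standard 12-column tabular alignment
rows; `parse_blast_table()` keeps rows with `evalue < 1e-10` (the
conventional stringent annotation cutoff; filtering is per HSP) and
converts subject coordinates to 0-based half-open form.

For each (contig, protein) pair, all its HSP subject intervals are merged
by union — overlapping segments are never double-counted — and coverage is
the united length divided by the protein length (`subject_coverage()`,
`coverage_table()`). The union rule is the most faithful reading of
"overlapping the protein over a fraction of its length" and is testable
against a per-residue bitmap oracle, which the test suite does
exhaustively on random instances.

`reconstruction_report()` classifies at levels 0.99, 0.90, 0.80 and 0.50,
applied as `coverage ≥ level` so that an exactly-full-length
reconstruction (1.00) and an exact boundary value remain countable. Per
level it counts distinct proteins (CDS), genes (a gene counts if its
best-covered isoform counts — always the best, never an average), and
distinct contigs; totals count everything with any significant hit. Counts
are by construction non-decreasing from the strictest level to the totals,
and `union_reports()` — which namespaces contig ids as
`<library>:<contig>` because assembler ids restart per assembly — can only
grow any count (dominance). Both structural properties are asserted on
random inputs. `coverage_histogram()` bins each gene's best coverage
(default width 0.01, last bin closed at 1.0).

## Expression core sets

`tpm()` implements the closed form
`TPM_i = (c_i/l_i) / Σ_j (c_j/l_j) × 10^6` on supplied gene-level counts
and effective lengths; multi-mapping-aware estimation of those counts is
deliberately out of scope, so any upstream quantifier can feed it. Each
library's top fraction (`top_fraction()`, default `q = 0.05`) is taken
over genes with `TPM > 0` — the strict-positivity filter is stated
explicitly because "the top 5% of genes" is ambiguous between annotated
and expressed universes — ranked descending with boundary ties broken by
gene id, taking `⌈qG⌉` genes. `core_set()` intersects the per-library top
sets and sorts members by unweighted mean TPM across libraries.
`enrich()` annotates a study set against a background with fold enrichment
`(k/n)/(K/N)`, an upper-tail hypergeometric p-value and
Benjamini–Hochberg adjustment across terms (`p_adj < 0.05` flags
enrichment); the classical EASE-style deflation of `k` used by some web
tools is intentionally not replicated.

## The synthetic-data generator

`simulate_reference()` builds a multi-isoform proteome from uniformly
drawn sense codons, so each CDS translates exactly to its protein and is
exactly 3× its length. `simulate_contigs()` plants, per requested gene,
one contig whose coverage of one isoform falls strictly inside a requested
band — \[0.99, 1\], \[0.90, 0.99), \[0.80, 0.90), \[0.50, 0.80), or the
sub-threshold band \[0.10, 0.50) — with the exact fraction recorded. The
bands are half-open below the next level so every planted gene lands in
exactly one report row, making recovery checks unambiguous; the
sub-threshold floor of 0.10 keeps even sub-level alignments long enough
(≥ 12 residues on the default ≥ 120-aa proteins) to clear the e-value
cutoff, so totals are recoverable too. `simulate_alignments()` emits one
tabular row per contig piece with subject coordinates equal to the planted
interval; its e-value model is any decreasing function of alignment length
(default `max(10^-len, 1e-180)` — only the ordering relative to the cutoff
matters), and optional spurious hits are kept under 0.50 coverage so they
perturb only the totals rows, with a truth flag marking them.

`simulate_reads()` draws uniformly placed fragments at a requested mean
depth (101 bp reads by default, matching common Illumina output; per-base
substitution errors at 1% by default) and returns the true fragment layout
alongside the reads so the depth of any retained subset can be recomputed
exactly. `simulate_expression()` uses a deliberately minimal overdispersed
model: negative-binomial counts with `size = 1/dispersion` (Poisson at 0)
around a scalar baseline mean scaled by gene effective length, with core
genes at `core_multiplier ×` baseline in every library. Minimality is a
design choice with a consequence worth stating: if a per-gene baseline
spread shared across libraries is enabled (`baseline_sdlog > 0`),
persistently high-expressed non-core genes enter every library's top
fraction and the cross-library intersection becomes a strict superset of
the planted core — as it would in real data, where the observed core is
not a controlled quantity. Exact planted-core recovery is therefore a
property of the minimal model with the planted core comfortably smaller
than the top fraction; the package's recovery checks run 13 libraries,
1000-or-fewer genes, an 8-to-20-gene core at 10× baseline and dispersion
0.1, where recovery is essentially certain.

What the generator does **not** emulate: isoforms share no sequence
(every isoform gets independent codons), quality strings are uniform
high-quality rather than instrument-shaped, fragment lengths are fixed
rather than drawn, and expression has no library-size or batch structure.
Passing tests therefore demonstrate the correctness of the computations,
not robustness to those real-data complications.

## Numerical and degenerate-input choices

* Band edges and level thresholds are compared after computing fractions
  as integer length ratios, so boundary cases (`99/100 ≥ 0.99`) behave
  identically in planting and reporting.
* An empty contig set yields a zero-total summary, not an error; an empty
  core intersection is a valid result; an empty hit file parses to an
  empty record set.
* Reads shorter than `max(k, min_read_length)` are skipped and logged; a
  pair with no usable mate is counted as skipped, and the log identity
  `in = kept + discarded + skipped` always holds.
* `contig_stats()` reports the even-set median as the mean of the two
  middle lengths and rounds the mean to whole base pairs.
* Ties at a top-fraction boundary are broken by ascending gene id, making
  every set deterministic.

## Problem sizes used in validation

The shipped checks run at desk scale, chosen to finish in minutes while
leaving the properties sharp: 100 random reconstruction plans of up to 200
genes × 3 isoforms, 1000 random coverage instances against the bitmap
oracle, a 10 kb transcript at depth 100 for the normalization depth-bound
check, 100 random TPM matrices, 100 seeded 13-library recovery runs, and
an exhaustive hypergeometric comparison for all backgrounds up to N = 60.
The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Limitations

The k-mer counter holds exact counts in memory, so inputs in the
hundreds-of-millions-of-reads range need a drop-in probabilistic counter;
normalization decisions depend on stream order (hence the seeded shuffle
option and the replay checker rather than any claim of order
invariance); and the enrichment stand-in is a plain hypergeometric test —
results will differ from web services that deflate the overlap count.
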