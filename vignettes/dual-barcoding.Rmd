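---
title: "Dual-barcoded amplicon multiplexing: models, layouts and crosstalk evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-barcoded amplicon multiplexing: models, layouts and crosstalk evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodemux)
```

## The problem

Marker-gene (e.g. 16S rRNA) amplicon sequencing profiles hundreds of samples
per run by tagging each sample's amplicons with short DNA barcodes before
pooling. In a two-step PCR workflow the first PCR amplifies the target region
with primers carrying a constant 16-nt *head* (linker) sequence; the second
(barcoding) PCR anneals to that head and prepends a sample barcode. Every
read therefore starts with

```
[barcode][16-nt head][target primer][biological insert]
```

Pooling creates a failure mode: *crosstalk* (index hopping, barcode
contamination, or barcode sequencing errors) moves reads between samples.
With a single barcode per sample such misassignments are undetectable. Dual
barcoding attaches a barcode to both amplicon ends, and the way the two
barcodes are allocated across samples decides whether crosstalk is
*detectable* (the observed pair is not assigned to any sample) or silently
*misassigned* (the observed pair happens to belong to another sample).

## Barcoding schemes and capacity

`barcodemux` implements four layouts. With a set of `k` barcodes, the number
of samples that one amplicon pool can hold for a single primer pair is:

| scheme    | heads (fwd/rev) | allocation                               | capacity       |
|-----------|-----------------|------------------------------------------|----------------|
| `SB`      | H1 / H1         | one barcode, same on both ends           | `k`            |
| `UDB_H11` | H1 / H1         | unordered pair, both barcodes exclusive  | `floor(k/2)`   |
| `UDB_H12` | H1 / H2         | one exclusive barcode per head side      | `k`            |
| `CDB_H12` | H1 / H2         | unique *ordered* pair, barcodes reused   | `k * (k - 1)`  |

```{r capacities}
sapply(schemes(), capacity, k = 548)
```

With the 548-barcode 12-nt set, combinatorial dual barcoding reaches
`548 * 547 = 299756` samples per pool — at the cost of losing crosstalk
detectability, which is exactly the trade-off the evaluation half of this
package quantifies. `total_capacity()` multiplies by the number of primer
pairs and pooled libraries per run.

The combinatorial capacity excludes pairs that use the same barcode on both
sides (`k*(k-1)`, not `k^2`): the printed maximum 299,756 equals `548 * 547`.
For consistency, the default `UDB_H12` layout pairs barcode `i` on the H1
side with barcode `i+1 (mod k)` on the H2 side ("circular offset"), so the
two barcodes of a sample always differ. No pairing rule is canonical for
UDB-H12; the circular offset was chosen because it reaches the full capacity
`k` while keeping within-sample barcodes distinct, and it is deterministic.

## Barcode-set design

Two properties make a barcode set robust:

* **Minimum pairwise Hamming distance** `d_min >= 4`: demultiplexing with
  tolerance `t` is provably unambiguous when `d_min > 2 t`, so one tolerated
  mismatch needs distance >= 3 and the default design target of 4 leaves
  margin.
* **Per-position base-composition uniformity**: barcodes are sequenced in
  the first cycles, where Illumina cluster calibration needs base diversity.
  We summarize composition as `uniformity_score = max |freq - 0.25|` over
  all positions and bases (0 = perfectly uniform, 0.75 = degenerate).

`select_barcodes()` treats distance as a hard constraint and uniformity as
an objective: a seeded shuffle, a greedy packing pass that keeps every
candidate at distance `>= d_min` from the kept set, then local swap
refinement that replaces kept barcodes by unused candidates whenever this
lowers the uniformity score without breaking the constraint. The published
sets were selected by unstated means, so no attempt is made to reproduce
their exact identity — only their stated properties. Ties are broken by
post-shuffle candidate order, making runs reproducible from the seed.

```{r design}
pool <- random_barcodes(200, 12, seed = 1)
sel <- select_barcodes(pool, k = 24, d_min = 4, seed = 1)
distance_profile(sel)[c("min", "median")]
composition_profile(sel)$uniformity_score
```

## Demultiplexing model

Matching is *anchored* and *indel-free*: barcode at positions `1..L`, head
at the next 16 nt, primer next, all compared positionally (Hamming mode;
degenerate primer bases expanded per IUPAC). Amplicon constructs have fixed
geometry and Illumina substitution errors dominate indels, so positional
matching is both faster and stricter than alignment. Default tolerances are
1 mismatch in the barcode and 2 in head and primer.

Each pair is classified into exactly one category:
`assigned`, `unknown_barcode` (a barcode matches nothing),
`ambiguous` (a barcode matches two set members, or both read orientations
assign to different samples — ties are rejected, never guessed),
`invalid_combination` (both barcodes known, pair not on the sheet — the
crosstalk-candidate signal), `head_mismatch`, `primer_mismatch`, and
`structural` for reads too short to contain the construct. The category
enum deliberately includes `structural` as its own class rather than
folding truncated reads into a mismatch category.

Both orientations (mate 1 = H1 side, and the swap) are attempted because
ligation-based library prep randomizes orientation. If only one orientation
assigns, it wins; if both assign to different samples the pair is
`ambiguous`; if neither assigns, the reported failure comes from the
orientation that progressed furthest through the anatomy
(structural < head < primer < barcode < combination), ties toward
orientation A.

For `SB`, both ends carry the same barcode; the demultiplexer requires both
mates' barcodes to match and to agree, reporting disagreement as
`invalid_combination`. Whether the original single-barcode pipelines read
one or both ends is not documented; using both is the stricter choice and
is symmetric with the dual schemes.

Qualities are trimmed alongside sequences but never filtered on — quality
filtering and denoising belong to downstream tools and are out of scope.

## The simulator: a stated world

`simulate_reads()` / `simulate_run()` generate ground-truthed multiplexed
runs. Defaults encode the reference evaluation conditions:

* **Library size 2438 read pairs** per sample and **100 replicates** for
  composition simulation (`simulate_mock_counts()`), drawn with
  `stats::rmultinom` from the reference per-variant probabilities.
* **Mock community**: `synthetic_zymo_mock()` is a *synthetic* stand-in for
  a log-distributed DNA standard — eight bacterial species at
  89.1 / 8.9 / 0.89 / 0.089 / 0.089 / 0.0089 / 0.00089 / 0.000089 %
  (renormalized), each with 1–5 intragenomic 16S variants of random
  sequence differing at a few positions. The real per-variant abundance
  table ships with the commercial standard and is supplied to
  `read_mock_reference()` when available; per-variant weights are an input
  by design, never inferred.
* **Substitution errors**: each base independently mutates to a uniformly
  chosen different base with probability `error_rate` (default 0; typical
  Illumina-like values 0.001–0.01). Indels, chimeras, quality decay and
  PCR amplification bias are deliberately not modelled.
* **Barcode swaps (index hopping)**: with probability `crosstalk_rate` per
  pair, the barcode on one uniformly chosen side is replaced by a barcode
  in use *on that side* by a different sample (excluding the current
  sequence, so every event is a real change). Swaps are applied before
  substitution errors, mirroring the physical order (hopping happens on the
  flowcell, base-calling errors afterwards). One side per event; double
  swaps can be composed by calling `inject_crosstalk()` twice.
* Degenerate primer positions are expanded uniformly at random per read.
* All randomness derives from one master seed through named substreams, so
  compositions, orientations, errors and swaps are independently
  reproducible.

A green simulation-based test therefore establishes the *combinatorial*
behaviour of the schemes — which observed pairs decode where, and how
hopped reads are classified — under substitution-only noise. It does not
establish robustness to indels, chimeras, primer-site biology, or real
error-rate profiles, and it cannot validate the identity of any published
barcode list.

What the simulated contrast shows (and the test suite asserts): under
unique dual barcoding every single-side swap produces an
`invalid_combination` — misassignment is structurally zero — while on a
fully-used combinatorial sheet a swapped pair is almost always another
sample's valid pair and is silently misassigned. Downstream, those
misassigned reads appear as spurious sequences in mock libraries and in
negative controls, inflate Chao1 richness, and raise between-replicate
Bray–Curtis dissimilarity; filtering sequences that never exceed 0.25%
relative abundance shrinks (but does not eliminate) that gap.

## Evaluation metrics: numerical choices

* **Reference matching** uses Hamming distance on equal-length sequences
  with a one-mismatch tolerance; length-mismatched sequences are spurious.
  Synthetic inserts are fixed-length, so no local alignment is needed; a
  BLAST-style backend is a pluggable extension for real data.
* **Chao1** uses the bias-corrected form
  `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`, defined even without doubletons and
  always `>= S_obs` (the common ecology-package default; the classical
  `f1^2 / (2 f2)` form is undefined at `f2 = 0`).
* **Abundance filtering** drops sequences that *never strictly exceed* the
  threshold (default 0.25%) in any sample; the boundary case (exactly at
  threshold everywhere) is dropped. Behaviour at the boundary is a
  convention, fixed here as strict.
* **Rarefaction** subsamples without replacement (multivariate
  hypergeometric), seeded.
* **Expected-vs-measured correlation** aggregates variants into species,
  excludes members undetected in a pool (no pseudocount — zeros carry no
  log abundance), requires at least two shared members per pool, and
  averages per-pool Pearson r of log relative abundances. The log base is
  irrelevant to Pearson r. Suspected external contaminants can be excluded
  via `exclude_members`, mirroring the manual curation such comparisons
  need in practice.
* **Bray–Curtis** is computed on counts as `sum|x-y| / sum(x+y)` and errors
  on two all-zero vectors rather than returning a conventional value.

## Known limitations

* The selection heuristic is greedy: it guarantees the distance constraint
  but not a maximum-size or maximum-uniformity subset.
* Anchored matching cannot rescue reads with indels in the technical
  region; such reads fail as head/primer mismatches.
* The simulator's mock is synthetic; conclusions about real mock standards
  require loading the vendor's reference sequences and weights.
* Library-index (pool-level) demultiplexing, PhiX removal, denoising,
  chimera removal and ordination are out of scope; the package hands off
  trimmed per-sample FASTQ files and count tables.
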