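---
title: "Clade-specific degenerate primer design and clone-library analysis with PrimerClade"
author: "PrimerClade authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade-specific degenerate primer design and clone-library analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PrimerClade)
```

## The problem

Universal 16S rRNA primers sample a community in proportion to abundance,
so clades present at a percent or less — *Deinococcus–Thermus* in desert
sand or hot-spring sediments being the motivating case — are barely
represented in the resulting clone libraries. The remedy is a
group-specific primer pair: oligonucleotides matching a region conserved
within the target clade but divergent outside it, used either directly or
as the inner pair of a nested PCR. PrimerClade implements the in-silico
half of that strategy: designing such pairs from a clade alignment,
quantifying their coverage and specificity against a taxonomically
labelled database, and analysing the clone libraries they produce.

## Threshold IUPAC consensus

The design input is a multiple alignment of the target clade. For each
column, base frequencies are computed over **non-gap residues only** —
indels carry no information for an ungapped primer and are ignored in the
counting. A column is encoded as the IUPAC code of the *smallest* base set
whose cumulative frequency reaches the threshold $t$ (default $t = 0.90$);
among equal-cardinality sets the one with the highest cumulative frequency
wins, and remaining ties go to the lexicographically smallest symbol, so
builds are deterministic. Frequencies are compared with a $10^{-9}$
tolerance so that exact-threshold columns are not lost to floating-point
noise.

Two decisions here were genuinely open and are worth recording:

* **What "a 90% consensus" means.** Besides the minimal-set reading we
  default to, one can read it as "include every base whose own frequency
  is at least $1 - t$". Both are implemented (`mode = "minimal"` /
  `"inclusion"` in `buildConsensus()`); the minimal-set reading is the
  default because it yields the least degenerate primer compatible with
  the threshold.
* **Ambiguity codes in the input rows** contribute fractionally,
  $1/|B|$ to each base of their set $B$, rather than being discarded —
  real reference alignments contain them and dropping residues biases
  columns with low coverage. Setting `ambiguityWeights = FALSE` drops
  them instead.

All-gap columns are unusable and dropped; columns whose gap fraction
exceeds `maxGapFraction` (default 0.5) are treated as alignment artifacts
and dropped too. The profile's `columnMap` records every retained column,
so consensus coordinates can always be traced back to alignment columns.

## Windows, domains, candidates

A sliding window of `windowLength` = 15 nt keeps every start whose window
contains at most `maxDegeneracies` = 2 degenerate positions ("fewer than
three"). Overlapping *or abutting* windows are merged into maximal
domains — abutting windows delimit one contiguous low-degeneracy region,
and merging is conservative because every candidate is re-filtered anyway.
Candidates are all substrings of domains with length 20–30 nt and at most
2 degeneracies; the filter is re-applied per candidate because a 30-mer
can span two valid 15 nt windows yet contain three degeneracies in total.
Reverse-orientation candidates are emitted as the reverse complement of
the consensus substring (the oligo as synthesised) with coordinates kept
on the consensus. Deduplication is by (sequence, start, orientation):
identical sequences at different loci are retained separately so reports
can state where each candidate binds.

## The mismatch-tolerant scanner

Primer–template comparison is ungapped and degenerate-aware: a primer
position matches a template position when the two IUPAC base sets
intersect. This symmetric intersection semantics is our choice — whether
template ambiguity codes should count as matches is not standardized — and
it implies that `N`-rich templates match everything; `coverageTable()`
therefore excludes templates whose `N` fraction exceeds `maxNFraction`
(default 0.05). Matching is implemented on 4-bit base-set encodings, so a
full mismatch profile over all offsets costs one vectorized pass per
primer position.

A template is *recognized at allowance k* when the forward primer binds
the plus strand and the reverse primer the minus strand with at most $k$
mismatches **each**, the forward site lies entirely upstream of the
reverse site, and the implied product length (inclusive span from the
first forward base to the last base of the reverse site) respects the
pair's bounds (defaults 50–2000 nt). The phrase "k mismatches between the
primers and the sequence" could also mean $k$ summed across the pair;
per-primer is the stricter reading and the default, with
`allowance = "summed"` available. Coverage is then, per taxon at a chosen
rank, the percentage of its sequences recognized at each allowance —
non-decreasing in the allowance by construction. Values are kept at full
precision and rounded to one decimal only in the TSV writers. Sequences
are scanned full length rather than within an expected gene region; with
20+ nt primers, spurious sub-allowance hits in unrelated sequence are
rare enough that the simpler rule wins.

Amplicon prediction enumerates *all* site combinations satisfying
orientation and length bounds, reports 1-based inclusive coordinates, and
emits products with primer-derived termini (primers substitute the
template at both ends, as in real PCR); degenerate primer symbols are kept
verbatim unless `resolveTermini = TRUE` resolves them to the matching
template base. Nested PCR applies the inner pair to every outer product
and keeps the provenance.

## Pair selection

"High coverage of the clade, high specificity against everything else"
is made explicit as

$$\mathrm{score} = \mathrm{cov}_{\mathrm{in}}(k_{sel}) -
  \lambda\,\mathrm{cov}_{\mathrm{out}}(k_{spec}),$$

with defaults $k_{sel} = 1$, $k_{spec} = 2$, $\lambda = 1$: coverage is
scored at a tight allowance, leakage at a laxer one. Ties rank by fewer
total degeneracies, then shorter total length, then leftmost coordinates.
Scoring every candidate pair against every database sequence is the
expensive step, so selection is staged: candidates are first screened
individually on a deterministic stride subsample of the database (no RNG,
so seeded pipelines are unaffected), only the best `keepPerSide` = 25 per
orientation enter exact pair scoring, and pairs whose consensus
coordinates already violate the product bounds are pruned unscanned. The
exact stage uses the full recognition semantics above.

## Clone-library analysis

Queries are classified by global Needleman–Wunsch alignment against every
reference. Scoring is match $+1$, mismatch $-1$, gap opening $-2$, gap
extension $-1$ (the alignment engine is Biostrings'
`pairwiseAlignment()`), and *identity* is defined as identities over
alignment columns after stripping terminal-gap columns — the overlap
region — since "similarity" is otherwise ambiguous for sequences of
unequal length. Queries are orientation-normalized (both strands aligned,
better one kept). The 20 best hits at ≥ 80% identity feed a step-wise
consensus taxonomy: starting at 99% the threshold drops in 1-point steps
(the step size is our choice; only "step-wise" is prescribed) until some
hit qualifies, and the assignment is the deepest rank — Domain > Phylum >
Class > Order > Family > Genus — on which **all** qualifying hits agree.
Only hits at or above the current threshold enter the consensus; hits
with shorter lineages cap the achievable depth. Below 80% a query stays
unassigned.

OTUs are built from the pairwise identity matrix by average-linkage
agglomeration, merging while the closest pair of clusters is within
$100 - \mathrm{cutoff}$ (cutoff 97% by default, i.e. 3 distance points).
Equal-distance merges are resolved towards the clusters whose smallest
member ids sort first — average linkage is order-sensitive under ties, and
this rule makes partitions reproducible. The implementation is checked in
the test suite against both a brute-force re-clustering and
`stats::hclust` on tie-free instances.

Rarefaction supports the analytic hypergeometric expectation
$E[S_n] = \sum_i \bigl(1 - \binom{N-N_i}{n}\big/\binom{N}{n}\bigr)$
(computed on log-binomials for numerical stability) and seeded Monte-Carlo
subsampling without replacement; the two agree to within Monte-Carlo
error, which the tests assert at three standard errors.

## Synthetic study conditions

`generateReferenceDatabase()` simulates a root → phylum → genus → strain
hierarchy by substitution-only evolution (the scanner is ungapped, so the
default model plants no indels). Defaults are 3 phyla × 4 genera × 10
sequences of 900 nt with per-level substitution rates 0.16 / 0.06 / 0.04 —
roughly 16S-like divergence between phyla and between genera, with the
strain level representing distinct species within a genus. The
strain-level rate deliberately keeps the non-signature background
*variable*: the planted signature (forward site at 326–350, reverse
binding site at 758–785, hence a 460 bp product) is the only region
conserved across the entire target clade, which is exactly the situation
a group-specific primer exploits. Out-group sequences carry homologs of
both sites degraded by exactly 4 substitutions each, one more than the
usual 3-mismatch scan allowance. Every generator fixes all randomness
from a single seed and returns truth tables (planted coordinates, true
taxonomy) so tests never re-derive ground truth from the output.

What the generator does **not** emulate: indel variation and alignment
uncertainty, rRNA secondary-structure-constrained substitution patterns,
chimeras, compositional bias, and databases orders of magnitude larger
than desk scale. Passing tests therefore demonstrate the correctness of
the algorithms under the stated model, not field performance of any
particular primer pair on a real reference database.

Problem sizes in the tests and the acceptance script are chosen at desk
scale: the design recovery runs on the 120-sequence default database, the
scanner oracle on 500 random instances up to 2 kb, OTU checks on 100
random instances up to $n = 20$ plus a 142-clone, 33-group synthetic
library at 460 nt, and the classifier round trip on 20 amplicon clones
against an 80-sequence database.

## Known limitations

* No thermodynamic screening (melting temperature, hairpins, dimers,
  3′-clamp rules): candidate filtering is purely by length and
  degeneracy, and mismatch counts are unweighted by position.
* The scanner tolerates substitutions only; a primer site disrupted by an
  indel is counted as absent.
* Average-linkage clustering materializes the full identity matrix, so
  clone libraries of thousands of sequences will be slow; the intended
  scale is a few hundred clones.
* The consensus assumes the input alignment is trustworthy; no masking or
  trimming beyond the gap-fraction filter is applied.
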