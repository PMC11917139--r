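---
title: "Alignment-free capture of conserved short linear motifs"
author: "kcapture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free capture of conserved short linear motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcapture)
```

## The problem

Short linear motifs (SLiMs) are 3–10 residue functional peptides that
mediate protein–protein interactions, targeting and post-translational
modification. Most live in intrinsically disordered regions (IDRs),
which evolve fast and align poorly: column-wise conservation in a
multiple sequence alignment is a weak and often misleading signal
there. `kcapture` therefore detects conserved motifs without any
alignment, by asking which short peptides keep re-finding each other —
as mutual nearest neighbours in physicochemical space — across every
pair of related sequences.

## The model

**Per-residue similarity.** Amino-acid dissimilarity is taken from the
Grantham distance matrix $D'$, which combines side-chain composition,
polarity and molecular volume (range 5 for Leu–Ile to 215 for
Cys–Trp). It is rescaled to a similarity
$$D(a,b) = 1 - \frac{D'(a,b)}{\max D'}$$
so identity scores exactly 1 and the most distant pair 0. The exact
normalization is a design choice of this package: min–max scaling is
the simplest map satisfying the two anchors (identity $=1$, maximal
distance $=0$), it preserves the full ranking of all 190 residue pairs
(tested exhaustively), and `distanceToSimilarity()` accepts any
alternative normalization function, so downstream code never depends
on this choice. Any 20×20 symmetric, zero-diagonal, non-negative
matrix can replace Grantham via `readDistanceMatrix()`.

**k-mer similarity.** Each sequence is decomposed into all overlapping
k-mers (`kmerTable()`). Two equal-length k-mers score the mean of
their position-wise residue similarities,
$$w(x,y) = \frac1k \sum_{p=1}^{k} D(x_p, y_p) \in [0,1].$$

**Reciprocal best matches.** For each unordered pair of sequences
(self-pairs included — $n(n+1)/2$ comparisons for $n$ sequences), all
unique k-mers of one sequence are compared with all unique k-mers of
the other, and each k-mer selects its single most similar partner.
Pairs that select each other are *reciprocal best matches*, the unit
of conservation evidence. Ties on $w$ are broken by the lowest
$$LD(q_i, t_j) = \frac{2\,(q_i^2 + t_j^2)}{q_i + t_j},$$
where $q_i$ and $t_j$ are the two k-mers' occurrence frequencies, and
any remaining tie lexicographically on the partner string, so results
are bit-for-bit reproducible.

**Scoring across k.** A k-mer's raw score is the number of reciprocal
events it appears in across all pairs (a k-mer present in $m$
sequences has a floor of $m$ from the self-pairs). Raw counts are not
comparable across k: longer k-mers face a larger pool of potential
partners, so a reciprocal hit is intrinsically rarer. The raw count is
therefore multiplied by a weighting factor in the search space $S_k$,
the number of unique k-mers of that length pooled over the input set.
The default factor is $S_k/2$ — a reciprocal hit's baseline
probability scales roughly as $1/S_k$, so the product is comparable
across k; $S_k^2$ is available via `weighting = "squared"` for a
stronger long-k preference, and the choice is recorded in every run
manifest. Ranking is by descending score with deterministic
tie-breaks: larger k first (longer exact conservation is rarer), then
lexicographic.

**Map-back.** A consensus k-mer is located in each sequence by its
most frequent reciprocal partner among that sequence's k-mers (ties:
higher mean $w$ to the consensus, then lexicographic); *all*
occurrence positions of the chosen partner are reported, and sequences
sharing no reciprocal event with the consensus report nothing.
Coordinates are 1-based inclusive everywhere. Per-consensus position
probability matrices are empirical per-position residue frequencies
over the mapped k-mers.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `kMin`, `kMax` | 3, 10 | k-mer length range; the SLiM length regime |
| `topN` | 10 | consensus k-mers reported (full ranking retained) |
| `similarity` | Grantham | any validated 20×20 distance matrix |
| `weighting` | `"half"` ($S_k/2$) | cross-k weighting factor |
| `scoreBy` | `"count"` | count reciprocal events, or weight each by $w$ |
| extension `threshold` | 0.9 | candidates must score strictly above $0.9\,C$ |
| extension `pool` | 10 | top consensus k-mers eligible as candidates |
| IDR `window` | 15 | pLDDT smoothing window (residues) |
| IDR `threshold` | 65 | smoothed pLDDT ≤ 65 is disordered (inclusive) |
| IDR `maxLen` | 10 | islands up to this length are reassigned |
| IDR `minLen` | 30 | minimal IDR length (residues) |
| proteome `minSeparation` | 2 | required distance to structure (strict) |
| proteome cap | 2/100 | motifs allowed per 100 residues of IDR |

## Extension

Capture reports fixed-length k-mers, but real motifs are often longer
than `kMax` or straddle several high-scoring k-mers. `extendMotifs()`
grows each sequence's top-ranked region by absorbing candidate regions
that (1) overlap it by at least one residue and (2) score strictly
above `threshold` × the top score. Absorption iterates to a fixed
point by default (`chain = TRUE`); a single-pass mode applies the
criterion once against the original seed interval only, for a stricter
reading of the rule. The seed is the first mapped instance of the
rank-1 consensus k-mer; candidates are the mappings of the top `pool`
consensus k-mers. Extension only ever grows intervals, so site-level
recall cannot decrease.

## Benchmark metrics

`siteMetrics()`/`residueMetrics()` implement two evaluation
granularities against annotated motif tables. A *site* is a continuous
stretch of residues; a predicted site sharing ≥ 1 residue with an
annotated site is a true positive, and one prediction overlapping $m$
annotated sites contributes $m$ true positives (unique sequences can
carry several instances of one motif class). True negatives are not
defined at site level. At *residue* level, residues are deduplicated
across overlapping sites and TP/FP/FN/TN tile each sequence exactly.
Per-class counts are summed over sequences before precision and recall
are computed; `aggregateMetrics()` then averages per-class precision,
recall and F1 with equal class weights, so large classes do not bias
the summary. Recall is TP/(TP+FN); a `printedRecall` compatibility
flag provides the TP/(FP+FN) variant found in some descriptions of
this scheme. F1 is defined as 0 when P + R = 0, and an empty
prediction scores precision = recall = 0. The stringent default mode
evaluates only the top-ranked prediction per sequence (first instance
on ties); `combineTopK()` provides the sensitivity mode that unions
the mappings of the top 10 consensus k-mers.

## IDR segmentation and proteome filters

Disorder is called from per-residue pLDDT tracks: a centered
15-residue moving average (shrinking at the termini, so no padding
values are invented), an inclusive ≤ 65 threshold, island
reassignment, and a 30-residue minimum. Island reassignment runs two
passes: ordered islands of ≤ 10 residues flanked by disorder on both
sides are flipped first, then disordered islands flanked by order —
"first reassigned ordered" is read as *the ordered islands are
reassigned first*; the opposite pass order is available via
`first = "disordered"` since the phrase admits both readings.
Terminal segments have a single flank and are never flipped.

Proteome-scale runs keep only motifs fully inside an IDR and more than
2 residues (strict) from any ordered segment of the *reassigned*
tiling (a flag-free design choice: the reassigned mask is what the
segmentation reports, so distances are measured against it). Retained
motifs are capped per protein at $\max(2, \lfloor 2 L_{IDR}/100
\rfloor)$, with $L_{IDR}$ the protein's summed IDR length — the
stated rate of two motifs per 100 IDR residues, floored so the rate is
exact at multiples of 100, with a floor of two so short-IDR proteins
are not silenced. Equal-scoring duplicate positions of one k-mer are
all reported and count once against the cap. `randomControl()` draws
five same-length windows per motif from the same protein as a
composition-matched null.

## The synthetic generator

`simulateOrthologSet()` is the package's test bed: it plants one copy
of each requested motif at random non-overlapping positions in
background sequences and emits exact ground-truth coordinates.
Defaults mirror the validation conditions used throughout the test
suite and the acceptance script: 10 sequences of 150 residues, uniform
background, one planted 5-mer. The planted motif used in the shipped
checks, `DEWFM`, mixes charged, aromatic and hydrophobic chemistry so
its conservation signal is carried by physicochemistry rather than by
background composition. Substitution noise is applied per position;
`conservative` draws uniformly from the 3 residues nearest the
original by Grantham distance, `radical` from the 3 farthest — tying
the fixture to the same matrix the engine scores with, so
conservative noise is *by construction* the noise the similarity
should forgive. An IDR-biased background (P, R, G, Q, S, K, A, E
enriched three-fold) stresses the low-complexity regime where spurious
reciprocal matches are most likely. `simulatePlddtTrack()` builds
high-confidence (~90) tracks with low-confidence (~45) blocks for the
segmentation module.

What the generator does *not* emulate: phylogenetic correlation
between sequences (all copies are independent), rate heterogeneity
along the sequence, indel-rich alignment-breaking evolution beyond
simple per-position indels, and compositional drift between orthologs.
Passing tests therefore demonstrate correctness of the machinery and
recoverability under controlled noise — not performance on real
ortholog sets, which differ in all four respects.

## Numerical choices and degenerate inputs

* Similarities and $w$ values are plain doubles; ties are detected by
  exact equality. Both the vectorized R path and the compiled engine
  accumulate position-wise similarities in the same order before one
  division, so the two paths agree bit for bit and tie-breaks resolve
  identically (this is asserted against an independent nested-loop
  brute-force oracle in the tests).
* Mean-$w$ tie-breaks sort the addends before summing, so results are
  independent of input order and worker count.
* Sequences shorter than k are skipped for that k with a warning; a
  single-sequence input is valid (every unique k-mer scores its
  self-pair); an input with no reciprocal matches anywhere returns an
  empty consensus table, not an error.
* An all-zero distance matrix is rejected as degenerate; non-canonical
  residues are an error by default or skippable by policy.
* Run manifests record configuration, seed, package version and an
  input checksum but deliberately no wall-clock timestamp, so
  identical reruns are byte-identical.

## Problem sizes used in the shipped checks

The test suite verifies the engine against the brute-force oracle on
20 random sets of ≤ 5 sequences × ≤ 30 residues over all k in 3..10,
and measures planted-motif recovery on 100 seeded replicates per noise
condition at the 10 × 150 default scale. These sizes were chosen so
the full suite re-runs in minutes on a laptop while still exercising
every code path at the k-range and sequence-count regime the method
targets.

## Known limitations

* Scores carry no statistical significance; ranks are relative to the
  input set only.
* When a planted motif is partially degraded, its conserved internal
  sub-k-mers can accumulate more reciprocal events than the
  full-length exact string and occupy the top ranks; the motif site is
  still found, but the reported consensus may be shorter than the
  true motif. The extension step exists precisely to reassemble such
  regions.
* Repetitive, low-complexity sequences inflate k-mer frequencies and
  make reciprocal matches less specific; the LD tie-break mitigates
  but does not remove this.
* The IDR module consumes pLDDT tracks as given; it does not predict
  structure or parse coordinate files.
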