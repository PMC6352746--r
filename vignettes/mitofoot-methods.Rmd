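---
title: "Footprint detection and occupancy dynamics on circular mitochondrial genomes"
author: "mitofoot authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footprint detection and occupancy dynamics on circular mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofoot)
```

## The problem

ATAC-seq and DNase-seq report chromatin accessibility: the transposase or
nuclease cuts exposed DNA, so aligned read coverage is high where DNA is
accessible and locally depressed where a bound protein protects it. On the
nuclear genome such depressions ("footprints") mark transcription-factor
occupancy. The mitochondrial genome is a small (~16.3 kb in mouse, ~16.6 kb
in human), circular, multi-copy genome packaged into nucleoids mainly by
TFAM; localized accessibility footprints on mtDNA report nucleoid-level
protein–DNA organization, for example at the D-loop regulatory region, the
light-strand replication origin, tRNA genes and G-quadruplex-prone (GQP)
sequences. mitofoot implements the full computational pipeline for this
analysis: per-base circular coverage, footprint scoring and calling,
replicate concordance, cross-stage merging and occupancy dynamics,
co-localization statistics, and two artifact screens (transposase sequence
bias, NUMT read contamination), together with a synthetic-data generator
that provides planted ground truth for every stage.

## The footprint occupancy score

Every genome position $p$ is scored with a footprint occupancy score (FOS)
computed in a sliding window centered on $p$: a central window of $c$ bases
flanked on each side by windows of equal width $c$,

$$\mathrm{FOS}(p, c) \;=\; \frac{\bar{x}_C + \pi}{\max(\bar{x}_L, \varepsilon)}
\;+\; \frac{\bar{x}_C + \pi}{\max(\bar{x}_R, \varepsilon)},$$

where $\bar{x}_C$, $\bar{x}_L$, $\bar{x}_R$ are mean per-base coverages of
the center and the two flanks, $\pi$ is a pseudocount (default 1) and
$\varepsilon = 0.25$ guards empty flanks. Low scores mean the center is
depleted relative to both flanks — a footprint. The statistic is the
classical center-versus-flanks ratio of digital genomic footprinting,
monotone in protection depth, which is all the downstream logic requires.

Window geometry: the scan varies the center width $c$ over 6–41 bases with
flanks equal to the center, so total windows span 18–123 bases, inside the
18–124 base envelope the method is defined for. Varying center and flank
independently is possible in principle; equal widths are the simplest
geometry consistent with those bounds, and the per-position statistic is
the **minimum** FOS over all scanned configurations, so a footprint of any
width within the envelope is matched by some configuration.

Positions where every configuration has a flank mean below `min_flank_mean`
(default 5 reads/base) are *unscorable*: they can never seed or extend a
candidate site. This prevents calls driven by coverage deserts, where
ratios of near-zero means are meaningless.

## Calling threshold

The calling threshold is empirical: the `call_quantile` (default 0.01) of
the null distribution of per-position best scores, with the null defined by
uniform random circular rotations of the track. Because the best-score
field is exactly equivariant under rotation of a circular track, every
rotation contributes the identical multiset of scores; the pooled null
quantile therefore equals the same quantile of the observed track's own
best-score distribution, and the implementation computes it directly from
the single scan. Candidate sites are maximal circular runs of positions
scoring **strictly** below the threshold; a consequence of the strict
comparison is that a uniform-coverage track (all scores tied) calls
nothing.

Two practical consequences are worth understanding:

* On a pure noise track roughly `call_quantile` of positions fall below
  the threshold, forming many 1–3 bp runs. These false runs are removed by
  the replicate-concordance filter (two independent replicates rarely
  produce overlapping noise runs) — which is exactly why the pipeline
  requires duplicate experiments.
* The quantile is well calibrated when true footprints occupy roughly the
  quantile's share of the genome or more. The shipped example stage
  scripts plant several ~30 bp sites per stage for this reason.

A called run is reported at its full extent even if longer than the 124 bp
window envelope (possible on pathological tracks); truncating it would
fabricate boundaries.

## Replicate concordance, merging, prevalence

Only sites supported by both duplicates are kept: a site is retained iff it
shares at least one base (modular) with a site of the other replicate.
Retained coordinates default to the union of the overlapping pair
(conservative toward later overlap queries; intersection is available via
`mode = "intersection"`). Sites from any collection of stage or sample
sets that overlap by at least one nucleotide are merged transitively;
half-open adjacency (e.g. `[10,30)` next to `[30,50)`) is *not* overlap —
"at least one nucleotide position" is read literally. All interval algebra
is circular: a site may wrap the origin (represented as `end < start`) and
merging, gaps and overlap queries treat the origin like any other base.
`prevalence_filter()` keeps merged reference sites supported by at least
(or, with `strict = TRUE`, more than) a given fraction of samples — the
"shared by at least 10% of cell lines" and "common to more than 90% of
samples" filters.

## Occupancy dynamics

`build_occupancy()` merges all per-stage sites into reference sites and
marks presence of each reference site at each stage by modular overlap.
Each nonzero presence vector falls into exactly one of four trajectory
classes:

| class | pattern |
|---|---|
| `core` | present at every stage |
| `emergent_persistent` | absent early, then present through the final stage |
| `alternating` | present, lost, present again (any internal gap) |
| `transient` | one presence block ending before the final stage |

Boundary cases are resolved as follows: "appeared and persisted" requires
persistence through the final analyzed stage, so a site present only at the
last stage is `emergent_persistent` (suffix of length one), and a
`transient` site ends before the final stage. These four cases exhaust and
partition all nonzero binary vectors, which the test suite verifies
exhaustively for series of 2–8 stages. Gain/loss counts per stage, the
distribution of sites over annotation classes (a site spanning a boundary
counts in every class it touches), and the overlap of adult prevalence-
filtered sites with the embryonic series (with earliest-stage attribution
taken from the embryonic reference site's first presence column) complete
the dynamics module.

## Co-localization and its null models

G-quadruplex-prone sequences are found with the minimal quadparser-style
motif $G_{3+}(N_{1-7}G_{3+})_{3}$ on both strands (the minus strand is
scanned on the reverse complement and mapped back, so reverse-complement
symmetry holds by construction), modular across the origin, with
leftmost-maximal collapsing of overlapping matches. The motif parameters
are exposed because published G4 definitions vary; no claim is made of
matching any particular published motif count.

A feature's status relative to a site set is `overlap` (shared base),
`proximal` (no shared base, circular gap strictly below `max_gap`,
default 40 bp) or `none`. Enrichment is tested two ways:

* a 1-df goodness-of-fit chi-square of the observed co-localized count
  against a null fraction, which defaults to the fraction of genome bases
  within the proximity distance of any site (sites dilated by `max_gap`);
  this makes the null explicit and interpretable;
* a rotation permutation test that rotates the whole feature set by
  uniform random offsets (sites stay fixed, preserving the coverage
  structure the site calls depend on) and recomputes the co-localized
  count, with $p = (1 + \#\{T_{perm} \ge T_{obs}\})/(B+1)$. Internally the
  count is evaluated against the `max_gap`-dilated site bitmap, which is
  provably the same predicate as the status computation and fast enough
  for thousands of rotations. Note the permutation p is exact but
  discrete: with few features the count statistic is heavily tied and the
  test is conservative; with regularly spaced features, rotations genuinely
  re-align the sets and the test correctly reports weak evidence.

## Artifact screens

**Transposase k-mer bias.** Each cut site's centered k-mer (k/2 bases 5' of
the cut, default k = 6) is counted and compared with the binomial
expectation under genome-wide circular k-mer frequencies; per-k-mer
two-sided binomial tests are Benjamini–Hochberg corrected across all 4^k
k-mers, and the screen reports bias only when a k-mer is both significant
(adjusted p < 0.05) and substantially enriched or depleted (outside
[0.5, 2]). The centered anchor and the genome-frequency null are the
conventional choices; flanking-shuffle nulls are out of scope.

**NUMT contamination.** Reads originating from nuclear-mitochondrial
pseudogenes carry diagnostic alleles. At each catalog position the NUMT
read fraction is the share of informative reads (carrying either allele)
that carry the NUMT allele; positions with no informative read are
undefined, not zero. Site versus non-site fractions are compared with a
two-sided Mann–Whitney test on unweighted per-position fractions —
rank-based because the fractions are bounded and strongly skewed. When
both groups are constant and identical the rank statistic has zero
variance; this degenerate case is reported as p = 1 (no evidence of a
difference).

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes and
nothing more:

* counts are negative-binomial (default size 10) around
  `background_mean` × a smooth positional multiplier (a two-component
  sinusoidal mixture, amplitudes 0.3 and 0.15, phases drawn from the
  seed) — real mtDNA coverage is smoothly non-uniform, and a flat Poisson
  null would make footprint calling unrealistically easy;
* footprints are planted as fractional coverage reductions (`protection`)
  over 10–60 bp intervals; replicates share the multiplier and the planted
  sites but draw counts independently, with an extra log-normal
  per-replicate scale (sd 0.05);
* stage series follow a binary site × stage script; shipped example
  scripts cover a 7-stage mouse-style series (all four trajectory classes)
  and a 3-stage human-style series (no transient class — with three
  ordered stages a single block ending before the last stage reduces to
  presence at stage 1 or stages 1–2 only, which the shorter series design
  simply does not include);
* reads are sampled along the circle (multiplier-weighted), a `numt_rate`
  fraction (default 0.002, i.e. 0.2% of reads) carries catalog NUMT
  alleles, and an optional `bias_kmer` gives cut sites a fold preference
  for one k-mer.

Defaults are fixed at the emulated study's scale: a 16,299 bp genome
(mouse mtDNA; 16,569 for human), 50× mean coverage, duplicate design.

What the generator does **not** model: fragment-size distributions,
sequencing errors beyond the NUMT alleles, strand asymmetries,
copy-number heterogeneity between organelles, or locus-specific coverage
structure beyond the smooth multiplier. Passing the planted-recovery and
end-to-end tests therefore demonstrates correctness of the algorithms
under the stated statistical assumptions, not performance on any real
dataset.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; wrap-around
  intervals are single records with `end < start`, never split records.
* Merging uses strict overlap; ties (adjacency) never merge. If the
  overlap closure covers the whole circle the merge is the single full
  circle `[0, L)`.
* `eps = 0.25` bounds FOS denominators; pseudocount 1 bounds numerators
  away from 0; the score is therefore always finite.
* All-zero tracks warn and return an empty site set (not an error);
  empty feature annotations are an error for `region_distribution()`.
* Every stochastic step takes an explicit seed and restores the caller's
  RNG state; identical inputs and seeds give bit-identical outputs.

## Problem sizes used in validation

The test suite validates scorer and interval algebra against brute-force
oracles on tracks up to a few hundred bases (50 tracks, all positions and
window configurations), planted-footprint recovery on 200 full-scale
16,299 bp tracks (background 50×, protection 0.8–1.0, widths 15–60 bp),
the trajectory classifier exhaustively for all nonzero binary vectors of
lengths 2–8, interval merging on 1,000 random circular interval sets,
statistic calibration on 200–400 null simulations, and NUMT recovery at
5,000× coverage on a 600 bp genome (100 runs per rate). The acceptance
script (`scripts/acceptance.R`) recomputes a condensed version of the same
quantities at sizes chosen to finish in a few minutes.
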