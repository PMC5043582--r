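---
title: "Detecting segmental exchange in multigene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting segmental exchange in multigene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segscan)
```

# The inference problem

Closely related paralogs of a multigene family can acquire variation by
point mutation, by repeat-unit copy-number change, or by *segmental
exchange*: the transfer of a short sequence stretch (a "cassette") from one
paralog into another, by gene conversion or double reciprocal
recombination. The two mechanisms cannot be distinguished from alignment
data, and `segscan` makes no attempt to: it reports exchange, donor and
tract, not mechanism.

The diagnostic pattern for exchange into a *recipient* gene, relative to
its closest relatives (the *background*), has three parts:

* the recipient's differences from the background are **clustered**, not
  scattered;
* the alignment fails the **pairwise homoplasy index** (PHI) test, i.e. the
  variation is not compatible with point mutation on a single tree;
* after **excising** the clustered intervals, the recipient's placement in
  a phylogeny snaps back from the putative donor to its true relatives,
  and some candidate donor matches the excised intervals almost exactly.

Each part is a module of this package, and the pipeline
(`run_pipeline()`) chains them into one reproducible report.

# Models and statistics

## Distances and trees

All distances are **p-distances**: the proportion of differing sites among
sites where both sequences are non-missing (gaps `-` and `N` are missing
data, deleted pairwise). No multiple-hit correction is applied, matching
the short, closely related sequences this analysis targets; a correction
could be added upstream of `nj_tree()` without touching anything else.

Trees are built by the Saitou–Nei **neighbour-joining** agglomeration on
the Q-criterion. Two numerical conventions make results reproducible and
auditable:

* ties in the Q minimisation are broken by the smallest (row, column)
  index pair;
* negative intermediate branch lengths are clamped to zero with the
  deficit moved to the partner branch, preserving the joined pair's total
  distance; the clamped total is recorded on the tree.

On additive matrices the output reproduces the input patristic distances
to numerical precision (this is asserted in the tests over random 4–6
taxon trees).

**Bootstrap support** resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, and decorates each internal edge of
the *point-estimate* tree with the fraction of replicates containing the
same bipartition. No consensus tree is formed: supports describe the fixed
topology, the way alignment-viewer phylogenies are usually annotated.
Support values are serialised as integer percents on internal node labels.

## Selection: Nei–Gojobori with a bootstrap Z-test

Synonymous (*S*) and non-synonymous (*N*) **site** counts follow the 1986
counting method: each codon position contributes the fraction of its three
possible substitutions that preserve the amino acid; substitutions
creating stop codons count as non-synonymous; *S + N = 3* per codon
exactly. **Differences** between codons differing at 2 (3) positions are
averaged over the 2 (6) mutational pathways; pathways through stop codons
are excluded and the rest re-weighted, with a documented fallback (stops
counted as non-synonymous steps) when every pathway is excluded.

The *overall average* aggregates over all unordered sequence pairs:
differences are summed, site counts pair-averaged, and the proportions
pooled (`pS = ΣSd / ΣS`). Codons containing a gap, `N`, or a stop in
either member of a pair are skipped for that pair only.

The test statistic is `Z = (pN − pS) / sd_boot(pN − pS)`, with the
standard deviation estimated by bootstrap over codon columns (default 500
replicates) rather than the analytic 1986 variance — the variance of a
pooled ratio under codon resampling is estimated directly instead of
through a delta approximation. The p-value is two-tailed normal. Edge
cases are pinned down: identical proportions give `Z = 0, p = 1`; zero
bootstrap variance with unequal proportions reports infinite `|Z|` with a
warning rather than `NaN`.

## Recombination: the pairwise homoplasy index

For two aligned characters, the **refined incompatibility score** is
`E − V + C` on the bipartite graph whose vertices are the observed states
of each column and whose edges are the observed joint states — the minimum
number of extra state changes the pair forces on any single tree (0 iff
compatible; the classic four-gamete violation scores 1). The test suite
verifies this equals brute-force minimum homoplasy over all trees on up to
six taxa (tree enumeration plus Fitch parsimony, via `phangorn`, used only
as an oracle).

**Φ** is the mean score over pairs of parsimoniously informative sites at
most `window_w` columns apart (default 100 columns, the method's
conventional window). Recombination concentrates compatibility into nearby
pairs, so the test is one-sided towards small Φ. The null permutes the
*order* of the informative sites; the permutation p-value uses the add-one
estimator `(1 + #{Φ_perm ≤ Φ_obs}) / (permutations + 1)` (default 1000
permutations) and therefore never returns exactly 0. An optional analytic
p-value uses a normal approximation whose mean and variance are computed
exactly from the pairwise score matrix by U-statistic algebra (overlap
cases: identical, one shared site, disjoint).

When fewer than three informative sites exist, or no pair falls inside the
window, the test is reported as *not applicable* with `p = 1` and a flag —
never as a spurious rejection.

A calibration caveat that the tests make explicit: with few informative
sites the permutation distribution is coarse and the test is
*conservative* (observed type-I error below nominal). The calibration
property is therefore asserted in a site-rich regime (six sequences, 300
columns, ~20% divergence, ≈65 informative sites), where the rejection rate
at α = 0.05 falls inside the binomial 95% confidence band over 200 clonal
simulations.

## Clustered differences and the cassette scan

`difference_positions()` supports two readings of "the recipient differs
from its family": against the background **consensus** (strict majority,
alphabetical tie-break with an ambiguity mask), or **unanimously** against
every background member. Consensus mode is a superset of unanimous mode;
unanimous mode matches how differences are counted off an alignment figure
when the background genes are nearly identical.

Clusters are maximal runs of difference columns with consecutive spacing
≤ `gap_max` (default 6) and span ≤ `scan_window` (default 30), keeping
runs of at least `min_count` (default 3) members. The defaults are set so
that both of the motivating geometries — 8 differences across ~27 nt and 4
across ~21 nt — are detected without merging. Significance is Monte Carlo:
place the observed number of differences uniformly at random among the L
columns (default 10⁴ replicates) and ask how often any `scan_window`
window holds at least the observed maximum count. The tests cross-check
this against exhaustive placement enumeration at enumerable sizes (k ≤ 5,
L ≤ 24) and against an independently coded Monte Carlo sweep at k = 12,
L = 60; full enumeration at the larger size is combinatorially out of
reach for any implementation (C(60,12) ≈ 10¹²).

Cassette intervals span each cluster from first to last member column
(half-open, 0-based throughout; optional widening to codon boundaries).
The boundary convention is deliberately conservative — a cassette may
extend beyond its outermost observed difference, and adjacent cassettes
may really be one segment; reported boundaries are convention-dependent
and flagged as such in the report.

**Donor attribution** counts Hamming mismatches between recipient and each
candidate inside the cassette union (missing states excluded pairwise).
Ties are reported as ties; the margin to the runner-up quantifies
confidence. **Topology shift** rebuilds bootstrap NJ trees on the full and
the excised alignment with identical settings and seed and reports the
recipient's sister group and support in each, plus the Robinson–Foulds
distance between the point trees. Sister groups require a root: an
explicit outgroup if the user has one, otherwise the leaf farthest from
the recipient (a stated, deterministic fallback — not an inference about
the true root).

## Repeat-unit decomposition

Copy numbers of tandem multi-exon repeats are read by greedy left-to-right
tiling with the best-matching unit (≤ `max_mismatch_per_unit` mismatches,
default 0). The unit library must stay pairwise distinguishable at the
chosen tolerance, ambiguous positions raise an error naming the offset,
and any un-tileable remainder is reported rather than silently dropped. A
hidden-Markov or alignment-based decomposition would handle degenerate
units, but the target systems have easily distinguishable exon units, for
which greedy tiling is exact.

# The simulator and the synthetic study systems

`simulate_family()` evolves sequences by JC69 (single substitution rate)
along a fixed newick or Yule tree; the per-branch substitution probability
is the closed form `(3/4)(1 − exp(−4µt/3))`, which the tests verify
against observed divergences. Conversion events copy the *donor tip's*
tract into the recipient at a stated fraction of the recipient's terminal
branch, after which the remaining branch fraction continues to mutate — so
tracts can accrue post-event mutations, and an event at `time = 1` leaves
the tract identical to the donor. Using the donor's present-day sequence
(rather than its ancestral state at the event time) is a simplification;
for the short branches and recent events simulated here the difference is
a handful of substitutions at most, and the truth table always records
exactly what was copied. JC69 is deliberately minimal: every downstream
statistic is p-distance-based, so richer substitution models would add
parameters without changing any conclusion the pipeline can reach.

`simulate_neutral_coding()` accepts all mutations regardless of
amino-acid effect but redraws stop-creating substitutions, preserving the
frame — the correct null for the selection Z-test, since `pN = pS` in
expectation while the sequence stays translatable.

Three deterministic **stand-in families** (in `fixtures.R`) plant the
variant geometry of the motivating study systems into random background
sequence, because no real sequences ship with the package:

* `cassette_family_fixture()` — five genes, 300 nt: a recipient carrying
  two donor cassettes (27 and 21 nt; 8 and 4 difference columns; one
  post-exchange mismatch against the donor), a nearly identical
  three-gene background, and phylogenetically conflicting scattered
  variation (donor/background-shared sites on both flanks) so that the
  homoplasy test sees realistic long-range incompatibility.
* `monomorphic_family_fixture()` — seven alleles with exactly seven
  isolated SNPs (one 5'UTR, four 3'UTR, two non-synonymous).
* `point_mutation_family_fixture()` — six alleles with 39 non-synonymous,
  9 synonymous and 13 UTR variant positions, most on one divergent
  allele; the few shared variants all carry the same bipartition, so all
  informative sites are mutually compatible and the homoplasy test
  returns p = 1 exactly.

What passing on these systems shows — and what it does not: the pipeline
provably recovers planted geometry (cluster sizes, donor identity, tract
locations, census counts) and its tests are calibrated on its own null
simulations. It does not show robustness to alignment error, indel-rich
histories (the simulator does no indel evolution), rate heterogeneity, or
donors absent from the sampled family — on real data those all degrade
donor attribution before they degrade cluster detection.

# Problem sizes and design choices in the checks

The verification suite runs at sizes chosen to make each property
measurable rather than impressive: type-I calibrations use 200 simulations
of six 300-nt sequences (200 permutations / 100 bootstrap replicates per
test); end-to-end recovery uses 50 families with two tracts of 40 and 35
nt, a nearly identical background (~2% divergence) and a donor at ~30%
local divergence — the density regime in which cassettes are visible as
clusters at all; the topology-shift contract uses a 150-nt tract with the
donor at ~10%, since with a uniform-rate simulator a short weakly diverged
tract cannot move a recipient across the tree (real exchanged cassettes
sit in hypervariable loops, which is why short real cassettes do shift
topology — a structure the planted fixture reproduces and the uniform-rate
simulator cannot).

Everything stochastic is seed-threaded: every public function with
randomness takes a `seed`, restores the caller's RNG state on exit, and
the pipeline derives stage seeds from one master seed via a string hash,
so independent stages stay independently reproducible.

# Known limitations

* PHI is conservative on sparse alignments (few informative sites); treat
  `p = 1` with `applicable = FALSE` as "no power", not "no recombination".
* Cassette boundaries follow the cluster-span convention and will
  under-cover tracts whose edges carry no differences.
* Donor attribution assumes the donor (or a close relative) is in the
  candidate set; it reports a best match, not a statement that exchange
  from that gene occurred.
* The simulator's uniform substitution rate cannot reproduce
  loop-concentrated divergence; planted fixtures cover that structure
  instead.
* Consensus-mode difference counts include columns where the background
  itself is split; unanimous mode is the figure-reading count.
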