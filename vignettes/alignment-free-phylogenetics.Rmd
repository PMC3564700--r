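---
title: "Alignment-free phylogenetics with the relative complexity measure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free phylogenetics with the relative complexity measure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lzphylo)
```

## The problem

Distance- and character-based phylogeny reconstruction normally starts
from a multiple sequence alignment, and alignment errors propagate into
the tree. The relative complexity measure (RCM) sidesteps alignment
entirely: it scores how much of one sequence can be mechanically copied
out of another, using Lempel–Ziv production parsing, and feeds the
resulting pairwise distances to neighbor joining. `lzphylo` implements
that pipeline end to end, together with two ways of interrogating the
resulting trees: a composition-conserving perturbation resampler
(robustness on real data) and a sequence-evolution simulator (accuracy
against a known truth).

## LZ production complexity

The complexity $c(S)$ of a sequence $S$ is the number of steps needed to
generate $S$ from the empty state, where each step copies the longest
substring of the sequence generated so far and then appends one new
symbol. Two conventions matter and are fixed throughout:

* the copy source may **self-overlap** — it can run past the history
  boundary into symbols written during the current step (this is what
  lets `ACA` be produced in one step when the history is `TGATGCGAC`);
* the **final step may be a bare copy** with no appended symbol, when
  the sequence ends mid-copy. It still counts as one step.

```{r}
lz_parse("TGATGCGACACA")
```

The parser is written in C++ and keeps per-character occurrence lists of
the history, extending a candidate copy source only when it already
matches at the current best length; on 4-letter DNA this runs far below
its quadratic worst case (micro-seconds for a kilobase). An intentionally
naive cubic reference parser lives in the test suite and the two are
checked against each other on thousands of random sequences.

Input policy: sequences are uppercased, `U` is mapped to `T` with a
warning, and IUPAC ambiguity codes are rejected by default (parsing over
a silently enlarged alphabet changes complexities without notice);
`ambiguous = "strip"` deletes such positions and reports how many.

## The RCM distance

For two sequences, with $S_1 S_2$ denoting plain concatenation (no
separator symbol),

$$
d(S_1,S_2) \;=\;
\frac{\bigl(c(S_1S_2)-c(S_1)\bigr)+\bigl(c(S_2S_1)-c(S_2)\bigr)}
     {\tfrac12\bigl(c(S_1S_2)+c(S_2S_1)\bigr)} .
$$

$c(S_2S_1)-c(S_2)$ is the number of extra production steps needed to
build $S_1$ when the whole history of $S_2$ is already available —
near-identical sequences need almost none. The measure is symmetric and
bounded by $[0,2]$. Note that the raw self-distance is *positive*:
doubling a sequence always costs one extra whole-copy step, so
$d(S,S) = 2\,(c(SS)-c(S))/c(SS) = 2/(c(S)+1)$ in the
(empirically universal, property-tested) case $c(SS)=c(S)+1$. Distance
matrices written by `rcm_distance_matrix()` put 0 on the diagonal by
convention, as downstream neighbor joining and the PHYLIP interchange
format require.

Only this one normalization of the relative complexity idea is
implemented; alternative normalizations reported in the earlier RCM
literature produced identical topologies, so the package keeps a single
definition and a clear seam (the distance function is an ordinary R
function) for adding others.

## Trees

`nj_tree()` delegates to the standard Saitou–Nei implementation in
**ape**; on additive matrices it provably recovers the generating tree,
which the tests exercise with random trees of 5–20 leaves. Negative
branch lengths, which NJ can produce on non-additive input, are kept as
computed — masking them would hide a property users may need to see — with
an optional PHYLIP-style `clamp_negative` adjustment.

`rf_distance()` is the Robinson–Foulds symmetric distance: the number of
nontrivial bipartitions present in exactly one of the two trees, branch
lengths ignored, partially resolved trees supported (only splits actually
present are counted). The optional normalization divides by $2(n-3)$,
the maximum for two fully resolved unrooted $n$-leaf trees.

`consensus_mre()` is the extended majority rule: all splits in more than
half the input trees, greedily extended with the most frequent remaining
compatible splits until the tree is resolved or nothing compatible
remains. The greedy order for equally frequent splits is frequency
descending, then the canonical split key (sorted leaf labels joined by
`|`, side not containing the alphabetically first leaf) ascending — the
classic consensus programs leave this order unspecified, so it is pinned
down here for determinism. Each retained branch carries its occurrence
count as the node label.

## The perturbation resampler

Classic bootstrap resampling needs equal-length columns, i.e. an
alignment. The pool-based perturbation scheme works directly on
unaligned sequences while conserving each sequence's base composition
exactly: with $n$ mutations requested, $n/3$ bases are deleted into a
pool, $n/3$ positions swap their resident base with a uniform draw from
the pool, and the pool is then reinserted one base at a time at uniform
positions. Because deletions feed the pool, substitutions swap
one-for-one and insertions drain it, both length and base multiset are
invariant — enforced by hard assertions, not just tests.

Choices the scheme's verbal description leaves open, fixed here:

* **Rounding of the three-way split.** $n_\text{total} =
  \operatorname{round}(kL)$ (half-up); $n_\text{del} = n_\text{ins} =
  \operatorname{round}(n_\text{total}/3)$ with the remainder going to
  substitutions. Keeping deletions and insertions exactly equal is what
  preserves length; this rounding also keeps all three counts within one
  of each other. Rates yielding one or two total mutations are rejected
  (each class must occur at least once, or none).
* **Substitution draws are not rejection-sampled**: the pool may return
  the same letter (a silent substitution). Rejection would bias the
  composition bookkeeping.
* **The displaced resident enters the pool.** The alternative reading
  (discard it) would break composition conservation, which is the
  scheme's defining property.
* **Randomness** flows from one master seed through deterministic
  per-(rate, replicate, sequence) substreams, so replicate 837 can be
  regenerated alone and editing one sequence never shifts another's
  replicates.

`run_robustness_experiment()` chains everything: original tree, then per
rate — perturbed datasets, a tree per replicate, MRe consensus with
support counts, RF of the consensus against the original, plus the
per-replicate RF distribution. The canonical design is the seven levels
1–25% with 1000 replicates each; both are parameters.

## The simulator and the accuracy benchmark

`evolve_family()` draws a root sequence from the model's stationary
distribution and evolves it down a tree. Substitution models are K2P
(equal frequencies) and F84 (unequal frequencies), parameterised by the
expected transition/transversion ratio; transition matrices come from
the exact spectral decomposition of the scaled generator, computed on
the $\sqrt{\pi}$-symmetrized matrix so detailed balance holds to machine
precision. The closed-form checks (Jukes–Cantor as the ts/tv = 0.5
special case of K2P; the single-branch expected p-distance) are in the
test suite as independent cross-checks of the same analytic object.

Indels are optional and deliberately simple: per branch, each site
triggers an event with probability `indel_rate`; an event is a deletion
or insertion with equal odds and geometric length (default mean 2).
Every homology is logged, so the *true* alignment of the leaves is
returned next to the unaligned sequences; the RCM pipeline never reads
it (that is the point of an alignment-free method), but it lets users
benchmark alignment-based competitors on identical data.

The benchmark preset emulates the classic design — the balanced 16-leaf
topology, root length 500 — with divergence calibrated so sister leaves
are about 95% identical at the substitution level: all branches 0.026
expected substitutions/site (two branches separate a sister pair;
$2 \times 0.026$ with multiple-hit correction gives $\approx 5\%$
observed difference), ts/tv 2 (the classic default), F84 frequencies
(0.30, 0.20, 0.20, 0.30) (mildly AT-rich, as in typical plant marker
data), indel rate 0.01. The original benchmark's generator had a
"relatedness" control with no published mapping to branch lengths, so
this calibration is this package's own, stated choice; under it RCM+NJ
recovers the true topology almost always, so mean symmetric distances
reported by `benchmark_rcm()` sit at or near 0 rather than at the small
positive values a harder (unknown) calibration would produce.
`benchmark_rcm()` reports raw and normalized RF per family and, via
`extra_methods`, scores user-supplied reconstructions — externally built
trees included — on exactly the same families.

## Problem sizes and numerical choices

The shipped tests run the benchmark at 200 families per model and the
robustness experiment at 100 replicates per rate over 5 seeds — sizes
chosen so the full suite completes in minutes on one core while keeping
Monte-Carlo noise well below the asserted margins; both scale linearly
if users want the classic 1000-replicate design. Other fixed choices:
distance matrices are validated symmetric to $10^{-12}$ and written with
0 diagonal; NJ tie-breaks follow the deterministic behaviour of the
underlying implementation; consensus tie-breaks are as above; all
experiment drivers are bit-reproducible from their master seed.

## What the synthetic data do and do not show

The simulator is site-homogeneous (no rate variation across sites, no
codon structure, no GTR), its indel model is geometric and
branch-local, and the perturbation resampler conserves composition by
construction — real markers (ITS, chloroplast spacers) violate all three
in various ways. Green tests therefore demonstrate correctness of the
algorithms and calibrated-regime accuracy, not that RCM will resolve any
particular real clade; on real data the robustness experiment, not the
benchmark, is the relevant instrument.

## Limitations

* Complexity parsing is exact but the RCM distance is not additive, so
  NJ on RCM matrices has no consistency guarantee; the benchmark
  quantifies accuracy empirically instead.
* The perturbation scheme requires at least three mutations per
  sequence at nonzero rates; very short sequences at 1% are rejected
  rather than silently under-mutated.
* Consensus support counts are occurrence counts (as in the classic
  display), not posterior probabilities.
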