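# lzphylo

Alignment-free phylogeny reconstruction for unaligned nucleotide
sequences, built on the **relative complexity measure (RCM)**: a
pairwise distance derived from Lempel–Ziv (LZ76) production complexity.
Aimed at people working with markers that are awkward to align —
length-variable spacers like nuclear ITS or chloroplast trnL–trnF across
related species, or any dataset where alignment uncertainty should not
be allowed to shape the tree.

## The method

The LZ production complexity `c(S)` is the number of steps needed to
generate `S` from nothing when each step copies the longest substring of
what has been generated so far (self-overlapping copies allowed) and
appends one new symbol; the final step may be a bare copy. For example
`TGATGCGACACA` parses as `T.G.A.TGC.GAC.ACA`, so `c = 6`.

The RCM distance between two sequences, with `S1S2` plain concatenation,
is

    d(S1,S2) = [ (c(S1S2) − c(S1)) + (c(S2S1) − c(S2)) ]
               / [ ½ (c(S1S2) + c(S2S1)) ]

`c(S2S1) − c(S2)` is the cost of producing `S1` when the history of `S2`
is already available, so closely related sequences score near 0. The
pipeline is: RCM distance matrix → neighbor-joining tree →
(optionally) extended-majority-rule consensus over resampled replicates,
scored with the Robinson–Foulds symmetric topology distance.

Because bootstrap resampling needs aligned columns, tree robustness is
assessed instead with a **pool-based perturbation resampler**: `k%` of
each sequence's bases are mutated through equal numbers of deletions,
substitutions and insertions mediated by a base pool, which conserves
each sequence's length and exact base composition. A built-in
**sequence-evolution simulator** (K2P / F84, optional indels, true
alignment logged) benchmarks reconstruction accuracy against a known
topology.

## Worked example

Simulate a 16-taxon family on the balanced benchmark tree, reconstruct
it alignment-free, and probe robustness by perturbation:

```r
library(lzphylo)

lz_parse("TGATGCGACACA")
#> LZ76 exhaustive-history parse
#>   components: T.G.A.TGC.GAC.ACA
#>   complexity: 6

fam <- evolve_family(balanced_tree(16, 0.026), subst_model("K2P"),
                     root_length = 500, indel_rate = 0.01, seed = 11)
complexity_table(fam$sequences[1:4, ])
#> # A tibble: 4 × 3
#>   id    length lz_complexity
#> 1 t1       494           112
#> 2 t2       498           110
#> 3 t3       483           108
#> 4 t4       489           110

d <- rcm_distance_matrix(fam$sequences)
round(d[1:4, 1:4], 3)
#>       t1    t2    t3    t4
#> t1 0.000 0.458 0.667 0.655
#> t2 0.458 0.000 0.654 0.667
#> t3 0.667 0.654 0.000 0.448
#> t4 0.655 0.667 0.448 0.000

tr <- nj_tree(d)
rf_distance(tr, fam$tree)
#> [1] 0

res <- run_robustness_experiment(fam$sequences,
                                 rates = c(0.02, 0.10, 0.25),
                                 n_replicates = 50, seed = 1)
glance(res)
#> # A tibble: 3 × 5
#>    rate n_replicates rf_consensus rf_consensus_normalized mean_replicate_rf
#> 1  0.02           50            0                  0                    0
#> 2  0.1            50            0                  0                    0.6
#> 3  0.25           50            2                  0.0769              20.2
```

Sister taxa at this divergence are ~95% identical; RCM+NJ recovers the
true topology exactly (RF 0). Under perturbation the consensus topology
is unchanged through 10% mutation and only starts to drift at 25% —
individual replicate trees wobble (mean per-replicate RF 20.2 at 25%)
long before the consensus does. `autoplot(res)` draws the curve;
`tidy()`/`glance()` give per-replicate and per-rate tables.

A command-line front end with the same operations (`complexity`,
`distmat`, `perturb`, `tree`, `consensus`, `treedist`, `simulate`,
`robustness`) is installed at `inst/scripts/lzphylo`.

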