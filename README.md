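# tomexo

Tree-structured mutual-exclusivity models of cancer progression, inferred
from cross-sectional binary mutation data.

## The problem

Cohorts of tumors profiled for somatic mutations show two recurring kinds of
structure among cancer driver genes: *mutual exclusivity* (genes in the same
pathway rarely mutate together, because either mutation exhausts the shared
selective advantage) and *progression order* (some drivers tend to mutate
only after others). `tomexo` infers both at once from an `M × N` binary
matrix `B` (`B[m, n] = 1` if tumor `m` has a non-silent mutation in gene
`n`), for users analysing cohort-level mutation calls — including datasets
with hundreds of genes and thousands of tumors.

## The model

A progression model is `T = (V, E, {f_v}, {D_v}, P)`: a rooted tree whose
non-root nodes carry disjoint, non-empty driver-gene sets `D_v` (driver
pathways), a firing probability `f_v ∈ (0,1)` per edge, and a passenger set
`P`. A tumor evolves from the root: a node may fire only if its parent
fired, and each fired node mutates exactly one of its genes (categorically,
weights proportional to overall gene mutation rates). The observed matrix is
the latent noise-free matrix corrupted by global false-positive (`ε`) and
false-negative (`δ`) flips.

The package provides:

* an exact `O(MN)` dynamic-programming likelihood `p(B | T, ε, δ)`
  marginalising all latent node states in one post-order traversal;
* Metropolis–Hastings structure search (`fit()`) with fourteen paired move
  kernels (node merges/splits, passenger and simple-node attach/detach,
  single-gene moves, gene swap, SPR), starting from the star tree, with
  `ε̂, δ̂, f̂_v` tied to each structure by fast empirical estimators and the
  prior `p(T) ∝ |S_B*(T)|^(-ζ)` penalising models with many reachable
  noise-free states;
* gradient fine-tuning of `(ε, δ)` on the selected structure;
* a generative simulator and benchmark fixtures (`simulate_cohort()`,
  `make_fixture()`, `run_experiment_grid()`);
* method-independent validation: progression scores
  `λ_PR(u,v) = (p(v|u) − p(v|ū)) / (p(v|u) + p(v|ū))`, symmetrised
  mutual-exclusivity scores `λ_ME`, and binomial tail p-values for both
  (`score_report()`), plus model-vs-truth F-scores (`f_scores()`).

See the methods vignette (`vignettes/tomexo-methods.Rmd`) for the formulas,
estimators, move kernels and numerical choices.

## Worked example

```r
library(tomexo)

truth <- make_fixture("linear", n_nodes = 3, genes_per_node = 2, n_passengers = 2)
set.seed(11)
B <- simulate_cohort(truth, 300, eps = 0.02, delta = 0.02)

result <- fit(B, chains = 2, iterations = 5000, seed = 42)
result
#> tomexo fit: 300 tumors x 8 genes, 2 chain(s) x 5000 iteration(s)
#> log-posterior -909.821 (star tree -1146.725, per-tumor ratio 2.203)
#> error rates: eps = 0.0184, delta = 0.0012; minimal tally: 27 FP, 0 FN
#> Progression model: 3 driver node(s), 8 gene(s), 2 passenger(s)
#>   [root] -> {g2,g1}  f = 0.909
#>   [g2,g1] -> {g4,g3}  f = 0.639
#>   [g4,g3] -> {g5,g6}  f = 0.549
#>   passengers: {p2,p1}

f_scores(result$model, truth)
#>      F_ME      F_PR F_overall
#>         1         1         1

score_report(B, result$model)$nodes
#>    node lambda_me         p_me
#> 1 g2,g1 0.9656357 4.290291e-33
#> 2 g4,g3 0.8086408 5.998480e-10
#> 3 g5,g6 0.5624517 1.041635e-02
```

Reading the output: the chain recovered the generating chain of three
two-gene pathways exactly (`F_overall = 1`; gene order within a node is
arbitrary). The fitted false-positive rate 0.018 is close to the simulating
0.02; the whole 2400-bit matrix conforms with the structure assuming only 27
false positives. The per-tumor posterior ratio 2.203 says each tumor is, on
average, 2.2 times better explained by the model than by the structureless
star tree. In the score report, each multi-gene node shows a strong
mutual-exclusivity signal (`λ_ME` near 1) with small binomial p-values —
the same statistics the package computes for models fitted to real cohorts,
where they serve as a method-independent sanity check.

The same pipeline is scriptable:

```sh
Rscript inst/cli/tomexo.R simulate --model truth.json --tumors 300 --eps 0.02 --delta 0.02 --seed 3 --out m.tsv
Rscript inst/cli/tomexo.R fit      --matrix m.tsv --chains 10 --iterations 100000 --zeta 5 --seed 1 --out fit/
Rscript inst/cli/tomexo.R score    --matrix m.tsv --model fit/model.json --out report.json --dot tree.dot
Rscript inst/cli/tomexo.R evaluate --predicted fit/model.json --truth truth.json
```

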