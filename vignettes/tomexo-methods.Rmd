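---
title: "Tree-structured mutual-exclusivity models of cancer progression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-structured mutual-exclusivity models of cancer progression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

tomexo analyses a binary matrix $B$ of $M$ tumors by $N$ genes, where
$B_{m,n} = 1$ means tumor $m$ carries at least one non-silent mutation in gene
$n$. The progression model is a tuple $T = (V, E, \{f_v\}, \{D_v\}, P)$:

* a rooted tree $(V, E)$ whose non-root nodes hold non-empty, disjoint sets
  $D_v$ of driver genes (the *driver pathways*);
* a firing probability $f_v \in (0,1)$ on the edge into each non-root node;
* a passenger set $P$ of genes outside the tree.

A tumor evolves top-down: the root is always active, a node can fire only if
its parent fired (with probability $f_v$), and every fired node mutates
*exactly one* of its genes, drawn categorically with weights $\alpha_g$
proportional to the genes' overall mutation rates. Genes sharing a node are
therefore mutually exclusive in the noise-free matrix $B^*$, and an edge
$(u, v)$ means mutations in $D_u$ precede mutations in $D_v$. The observed
matrix $B$ is $B^*$ with every 0 flipped to 1 with probability $\epsilon$
(false positives: background mutations and technical artefacts) and every 1
flipped to 0 with probability $\delta$ (false negatives: e.g. lost coverage).

Key assumptions, which define what the model can and cannot express: tumors
are independent draws from one cohort-level process; error rates are global
(not per gene or per tumor); each node has a single parent (no conjunctive
"AND" parents); and exclusivity within a node is absolute in $B^*$ — observed
co-occurrence inside a node must be explained by noise.

## Exact likelihood in linear time

Marginalising $B^*$ naively sums over $2^N$ vectors. Because only node
states (fired / not fired) couple genes, a single post-order traversal
suffices. With $s_{m,v}$ the latent state of node $v$ in tumor $m$, each
node contributes local terms for its observed bits ($o_{m,v}$ ones,
$z_{m,v}$ zeros, $w_1$ the normalised $\alpha$-mass on the observed ones):

$$\Lambda_{m,v} = p(B_{m,D_v} \mid s_{m,v}{=}1) =
  w_1 (1-\delta)\,\epsilon^{o-1}(1-\epsilon)^{z} +
  (1-w_1)\,\delta\,\epsilon^{o}(1-\epsilon)^{z-1},$$
$$\Gamma_{m,v} = p(B_{m,D_v} \mid s_{m,v}{=}0) = \epsilon^{o}(1-\epsilon)^{z},$$

and subtree quantities combine over children $c$:

$$\Psi_v = \Lambda_v \prod_c \big(f_c \Psi_c + (1-f_c)\Omega_c\big), \qquad
  \Omega_v = \Gamma_v \prod_c \Omega_c,$$

with the root treated as always fired and carrying no genes. The tumor
likelihood is $\Psi_{\text{root}}$ times the passenger background factor
$\epsilon^{o_P}(1-\epsilon)^{z_P}$, and the dataset log-likelihood sums over
tumors: $O(MN)$ overall. All computation is in log space with pairwise
log-sum-exp for the firing mixtures; products over hundreds of genes would
otherwise underflow. The test suite certifies the traversal against full
$2^N$ enumeration (relative error below $10^{-10}$) and checks that row
likelihoods sum to one.

## Prior and noise handling

The structure prior is $p(T) \propto |S_{B^*}(T)|^{-\zeta}$, where
$|S_{B^*}(T)|$ counts the distinct noise-free tumor vectors the model can
generate, via the recursion $c(v) = 1 + |D_v| \prod_{u \in C(v)} c(u)$.
Richer models can imitate more data patterns and are penalised accordingly;
$\zeta = 5$ is the default everywhere. Counts grow multiplicatively, so the
counter uses an exact arbitrary-precision integer helper, while the prior
itself is evaluated through an equivalent log-space recursion that cannot
overflow.

Rather than sampling $(\epsilon, \delta)$, the sampler ties them to the
structure: a second post-order dynamic program finds, per tumor, the
reachable $B^*$ row needing the fewest bit flips (two states per node:
"off" costs all observed ones as FPs; "on" designates one observed-1 gene as
the driver, costing $o-1$ FPs, or a single FN when $o = 0$). Summed FP / FN
tallies over the implied true-zero / true-one positions give plug-in
$\hat\epsilon, \hat\delta$, floored at $10^{-6}$ and capped at $0.5$ (rates
above one half are relabelings). Cost ties prefer fewer false negatives,
then the "off" state, making the distinguished assignment deterministic.

Two properties of these plug-ins matter in practice. They are biased
downward by construction — the minimum-error explanation is the most
charitable one. The bias is mild for $\hat\epsilon$ (passenger and
off-pathway ones must be FPs) but can be severe for $\hat\delta$: a fired
node with no observed mutation costs nothing unless one of its descendants
fired, so most FNs are silently rerouted into "not fired". This is why the
final model's error rates are re-estimated by likelihood ascent (below), and
why $\hat\delta$ inside the chain should be read as a lower bound.

Firing probabilities are likewise tied to the data. With $X$ tumors mutated
in the parent node ($X = M$ at the first layer) and $Y$ mutated in both:

$$\hat f_v = \max\!\Big\{\frac{Y - \epsilon X}{(1-\epsilon-\delta)X},\, 0\Big\},$$

clamped into $[10^{-6}, 1-10^{-6}]$; "node mutated" means at least one of
its genes is observed mutated (the natural OR reduction; the same convention
drives the validation statistics). When no tumor carries the parent, the
clamp floor is returned with a warning.

## MCMC over structures

The chain starts at the star tree (every gene its own first-layer node) and
explores structures with fourteen move kernels: vertical merge/split
(leaf into parent / subset out of a node), horizontal merge/split (sibling
leaves), attach-from-passengers / detach-into-passengers, attach-from-simple
/ detach-into-simple (bundle childless first-layer single-gene nodes),
single-gene moves P2D/D2P and S2D/D2S, gene swap along an edge, and SPR
(regraft a subtree anywhere outside itself, excluding the identity). Each
kernel is paired with its inverse; inner choices are uniform over the
applicable options, attach moves draw a subset size uniformly on
1..min(4, available) and then a uniform subset of that size, and the
Metropolis–Hastings correction is computed exactly from the forward and
backward choice counts, including the uniform choice among applicable move
types at both endpoints. Because the inner proposal distributions are not
dictated by the model, any fixed choice is valid once the Hastings term is
exact; the suite verifies stated proposal probabilities against empirical
frequencies and, end to end, that visit frequencies on the fully enumerable
two-gene space match the exact posterior (chi-square, $10^5$ steps).

Every proposal is evaluated as a full state — empirical
$(\hat\epsilon, \hat\delta)$, empirical $\hat f_v$, likelihood, prior — so a
single iteration costs $O(MN)$. Chains are independent, chain $i$ seeded
with `seed + i - 1`; defaults are 10 chains of $10^5$ iterations,
$\zeta = 5$. The reported model is the maximum-posterior sample over all
visited states (the star tree is always a candidate, so the MAP can never
fall below it). On the selected structure, $(\epsilon, \delta)$ are then
fine-tuned by gradient ascent on the logit scale (rates parameterised as
$0.5\,\mathrm{plogis}(x)$), with central finite differences ($h = 10^{-5}$),
initial step 0.1 backtracked until the likelihood does not decrease, a
200-iteration cap and a $10^{-8}$ gain threshold. Firing probabilities are
re-estimated at every candidate $(\epsilon, \delta)$, so the objective is a
profile likelihood and the reported model stays inside the
empirically-parameterised class. A start sitting at the clamp floor has a
vanishing logit-scale gradient, so the tuner also evaluates an interior
start (rates floored at 0.005) and keeps the better of the two; the
returned likelihood never falls below the starting one.

## The simulator and what passing tests mean

`sample_tumors()` implements the generative process exactly (top-down
firing, one mutated gene per fired node, categorical by $\alpha$ — uniform
within nodes by default, as the generative description fixes no weights),
and `inject_noise()` applies independent flips. `make_fixture()` builds the
three benchmark topologies: a chain of multi-gene nodes (*linear*, a pathway
linear progression model), one seed node with branches below it
(*single-seeded*), and several independent first-layer chains
(*multi-seeded*). Defaults — 3 nodes of 2 genes, firing probabilities
(0.9, 0.7, 0.5) decaying with depth, 2 passengers — are chosen so that deep
nodes still fire in a few hundred tumors, making recovery feasible at
cohort sizes of 100–500; exact benchmark settings are parameters, not
constants.

The simulator emulates cohort-level mutation calls with homogeneous,
independent errors. It does not emulate clonal substructure, per-gene or
per-sample error rates, covarying artefacts (panel composition, coverage),
or drivers outside the tree model class. Passing recovery benchmarks
therefore certifies the inference machinery under the model's own
assumptions — not robustness to their violation on real cohorts.

## Numerical and design choices

* $\alpha_g$ = (number of tumors mutated in $g$) + 1, computed once from the
  input matrix; the pseudocount keeps never-mutated genes proposable.
  $\alpha$ is normalised within each node at evaluation time.
* Error rates are floored at $10^{-6}$ and capped at $0.5$ before any
  likelihood evaluation; firing probabilities are clamped to
  $[10^{-6}, 1-10^{-6}]$.
* Min-error ties: fewer false negatives first, then the "off" state.
* State counting uses exact base-$10^4$ digit arithmetic; the prior uses the
  log-space recursion.
* Gene identifiers are opaque strings; the matrix column order is the
  canonical gene order. Model JSON round-trips firing probabilities at 17
  significant digits (bit-exact).
* Degenerate inputs: a single-gene matrix fits (the move set keeps at least
  one applicable kernel); an empty driver tree (all passengers) is a valid
  state reachable by detach moves and is scored as pure background.

Test problem sizes are deliberate package choices balancing statistical
power against suite runtime: the sampler-correctness check runs $10^5$
steps on a 30-tumor, two-gene cohort with $\zeta = 1$ (a flatter prior
keeps several structures at testable mass) and thins by 25 before the
chi-square; the benchmark reproduction runs three seeds at $M = 500$,
noise 0.01, 20k iterations, plus a 2-by-2 grid (noise
$\{0.01, 0.1\}$ by $M$ \{50, 500\}, three replicates, 10k iterations)
checked for monotone mean scores; error-rate recovery averages ten
replicates at $M = 200$.

## Known limitations

* $F_{\text{overall}}$ is fragile: a single misplaced gene can zero the
  mutual-exclusivity recall of a small truth, so benchmark scores drop
  sharply from small structural mistakes.
* At noise levels around 0.1 the star tree explains the data competitively
  and chains can stall near the initial state; scores there are expected to
  degrade, and the suite only asserts monotone degradation, not recovery.
* Per-replicate $\delta^*$ is weakly identified at moderate cohort sizes
  (the profile likelihood in $\delta$ is flat when deep nodes rarely fire);
  recovery claims are made about replicate means.
* The MAP report carries no uncertainty: no consensus structures or credible
  sets are produced.
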