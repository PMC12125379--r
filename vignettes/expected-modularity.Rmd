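---
title: "Computing expected modularity in probabilistic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing expected modularity in probabilistic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwmod)
```

## The model

A probabilistic network assigns each edge an independent existence
probability $p(e) \in (0,1]$. The package interprets it under possible-world
semantics: the network generates $2^m$ deterministic graphs, world $w$
having probability $\Pr(w)=\prod_{e\in E_w}p(e)\prod_{e\notin E_w}(1-p(e))$.
Given a fixed node clustering (this package computes modularity, it does not
optimise it), modularity becomes a random variable over worlds and the
quantity of interest is its expectation $E(Q)$.

Two assumptions are baked into the data model and should be checked against
any real dataset before use:

* **edge independence** — the world probability factorises; correlated
  evidence (e.g. shared experiments behind several interactions) violates
  this and is not representable;
* **simple undirected graphs** — no self-loops, no multi-edges, no
  direction. The degree terms of modularity and the edge trisection are
  defined here for simple graphs only, so the readers reject violations
  loudly rather than reinterpreting them. Probabilities of exactly 0 are
  likewise rejected: an absent edge is expressed by omitting it, and a
  silent "p = 0 means drop" rule would hide data errors.

## The possible-world partition

For a community $c$, every edge is *within* ($e_c$), *cross*
($e_{c,\bar c}$) or *outside* ($e_{\bar c}$); capacities $T_x,T_y,T_z$ sum
to $m$. A world's contribution for $c$ depends only on its per-part present
counts $(x,y,z)$:
$$Q_c^{xyz} = \frac{x}{x+y+z}-\Big(\frac{2x+y}{2(x+y+z)}\Big)^2 ,$$
so the worlds sharing a signature form a cell on which the contribution is
constant, and
$$E(Q)=\sum_c\sum_{x=0}^{T_x}\sum_{y=0}^{T_y}\sum_{z=0}^{T_z}
Q_c^{xyz}\,\Pr(X{=}x)\Pr(Y{=}y)\Pr(Z{=}z),$$
with each factor the Poisson-binomial pmf of that part's edge
probabilities. The factorisation is exact because the three parts are
disjoint edge sets. Note what is *not* claimed: the per-community cell
probabilities are marginals, and cross parts overlap between communities,
so the joint law of total $Q$ is not recoverable from them. The package
therefore returns the full modularity distribution only from the
brute-force enumerator (`modularity_distribution()`), while the partition
algorithms return the exact expectation and per-community terms.

### Poisson-binomial engines

Three interchangeable engines compute $\Pr(\text{count}=k)$ for independent
non-identical Bernoulli trials:

1. `poisbin_pmf_enum()` — the defining subset sum; $O(2^T)$, guarded at 20
   trials. This is what the enumeration variant (PWP) uses, mirroring the
   formal derivation.
2. `poisbin_pmf_conv()` — the standard dynamic-programming convolution;
   exact, $O(T^2)$. It exists purely as an independent referee between the
   other two engines in the tests; no algorithm path depends on it.
3. `poisbin_pmf_dft()` — the DFT closed form
   $\Pr(X{=}k)=\frac{1}{T+1}\sum_{l=0}^{T}C^{-lk}\prod_i(1+(C^l-1)p_i)$,
   $C=e^{2\pi i/(T+1)}$, evaluated as one complex product per root of unity
   followed by a single FFT; $O(T^2)$ and exact in exact arithmetic. This
   is the production engine behind FPWP.

The closed form is sometimes printed with a stray exponent on $p_i$; the
package implements the standard form (exponents read as trial indices), and
the test suite pins the three engines against each other — enumeration vs
convolution to $10^{-12}$ up to 12 trials, convolution vs DFT to $10^{-8}$
up to 500 trials — so a transcription error in any one engine cannot pass.

### Numerical choices

* **Empty world.** Modularity is $0/0$ on the edgeless world. The package
  defines it as 0 *everywhere*: in the deterministic evaluators, in the
  brute-force enumerator, in the sampler, and in the $x=y=z=0$ cell of the
  partition algorithms. Any single convention works; using one convention
  in all five code paths is what keeps the exactness tests meaningful. Zero
  is chosen because it makes $E(Q)$ continuous as all $p\to 0$.
* **Clamping.** The DFT pmf can produce entries like $-10^{-17}$; they are
  clamped to 0 and the pmf renormalised. If the total mass is off 1 by more
  than $10^{-8}$ the engine raises an error instead of warning — a wrong
  pmf would silently corrupt $E(Q)$.
* **Accumulation.** Cell sums and world sums use R's `sum()`, which
  accumulates in extended (long double) precision; the worst observed
  disagreement between brute force and the partition algorithms on
  hundreds of random instances is below $10^{-15}$.
* **Distribution support merging.** Brute-force distribution atoms are
  merged when equal to 12 decimals, with the exact first-seen value kept as
  the representative, and zero-mass atoms (from deterministic edges) are
  dropped.
* **Entropy inversion.** The binary entropy is inverted by bisection to
  $10^{-12}$ on the requested branch (≥ 0.5 or ≤ 0.5); the entropy ratio
  uses base-2 logarithms, which is what makes its range $[0,1]$ and
  reproduces the canonical pairings $p=0.9 \leftrightarrow 0.47$ and
  $p=0.5 \leftrightarrow 1.00$.

### Cost model and guards

FPWP visits exactly $\sum_c (T_x{+}1)(T_y{+}1)(T_z{+}1)$ cells — the
`cells` diagnostic — regardless of the probability values; its cost is
driven by the clustering (number of communities and size spread), not by
the uncertainty. The implementation loops over $z$ and vectorises each
$(x,y)$ slab, so memory stays at $(T_x{+}1)(T_y{+}1)$ doubles. PWP refuses
any trisection part over 20 edges ($2^{20}$ subsets) and points to FPWP;
the brute-force enumerator similarly refuses more than 25 edges by default.
These caps are scientific statements — beyond them the reference methods
stop being references — not tuning knobs.

## Comparison estimators

* **Sampling** (`sampling_expected_modularity()`): each world is drawn by
  independent per-edge Bernoulli trials, one uniform per edge in canonical
  edge order from a stream seeded by `seed` (run $r$ of a study uses
  `seed + r`), so every estimate is reproducible and distinct seeds give
  independent streams. The estimator is the plain possible-world Monte
  Carlo mean — deliberately the simplest unbiased choice; variance-reduced
  samplers exist but would change none of the qualitative comparisons, and
  the package documents rather than hides that the plain sampler is what
  is evaluated. A time-budget variant draws batches until a monotonic
  clock expires, for time-accuracy studies.
* **Thresholding** (`threshold_modularity()`): keeps edges with $p \ge t$
  (the comparison is inclusive because removal is defined for probabilities
  *lower* than the threshold) and evaluates deterministic modularity once.
  Near-deterministic networks (all $p$ within $\varepsilon$ of 0 or 1) are
  the only regime where this is accurate, since then any threshold between
  $\varepsilon$ and $1-\varepsilon$ changes probabilities by at most
  $\varepsilon$.
* **Weighting** (`weighted_modularity()`): the standard weighted
  modularity with $A_{ij}=p_{ij}$ and node strengths. Weights enter only as
  ratios, so a uniform rescaling of all probabilities cancels — the flat
  line the simulation study exhibits — making the method structurally
  unable to track $E(Q)$ across uncertainty levels.

## What the generators emulate

`generate_planted_partition()` reproduces the planted-partition (stochastic
block model) inputs of the simulation protocol: $k$ communities of $nc$
nodes, within/between densities $p_{in}/p_{out}$. The canonical test
conditions are the CCS network ($k{=}3$, $nc{=}9$, $p_{in}{=}0.99$,
$p_{out}{=}0.01$; nearly three cliques, ~105 edges) and the LCCS network
($p_{in}{=}0.72$, $p_{out}{=}0.12$, ~110 edges), with uniform edge
probabilities $1$, $0.9$, $0.5$ giving entropy ratios $0.00$, $0.47$,
$1.00$.

`generate_topology()` supplies ER, Barabási–Albert, small-world and
forest-fire topologies through igraph's generators (igraph's forest-fire
implementation is used directly rather than re-deriving one: the model only
serves to induce skewed community structure, and a maintained generator is
preferable to a bespoke recursion). igraph's preferential attachment grows
from a single seed vertex, so attachment $a$ yields exactly $a(n-2)$ edges
for $a=3$ — slightly different from constructions that start with $a$
isolated vertices; only approximate agreement with `target_m` is promised.
`random_clustering()` splits nodes over $k$ communities with a symmetric
Dirichlet size split whose concentration controls size variance, for the
cost studies.

`assign_edge_probabilities()` implements the two probability schemes:
`uniform` (one shared $p$) and `entropy_target`, which spreads per-edge
probabilities symmetrically (default half-width 0.05, clipped to $(0,1]$)
around a centre calibrated by root finding so the *realised* entropy ratio
hits the target within 0.005, halving the spread automatically near the
unreachable extremes. The exact distribution behind published
random-probability experiments is not specified anywhere; this scheme is
the package's documented stand-in, and nothing quantitative is asserted
about it beyond the realised entropy ratio.

What the generators do **not** emulate: real probabilistic datasets
(interaction databases, communication networks) have heavy-tailed degree
and probability distributions, correlated probabilities, and clusterings
obtained by optimisation on the observed graph. Passing tests on planted
partitions therefore demonstrates algorithmic correctness and the
qualitative failure modes of the baselines — not that any estimator is
adequate on a particular real dataset. Real data in the supported edge-list
format can be analysed directly with the same functions.

## Problem sizes in the shipped studies

The test-suite and acceptance studies run at desk scale, chosen so the
whole suite completes in minutes while still exercising every regime: the
brute-force certification uses 100 planted-partition networks with 9–21
edges (up to $2^{21}$ worlds each); sampling studies use 50 independent
runs of $\theta{=}1000$ on the ~105-edge CCS network; the scaling study
times FPWP on ER networks of 100–1000 edges with $k{=}5$ communities and
checks the log–log slope against the $O(km^3)$ bound (the observed slope is
≈ 2.2–2.4, below the worst case because the trisection parts are
unbalanced). All study randomness flows from a single master seed, and
every run is reproducible from its logged seed.

## Known limitations

* $E(Q)$ only from the partition algorithms; the joint distribution of $Q$
  requires enumeration (≤ 25 edges) or sampling.
* No directed, overlapping or resolution-parameter modularity variants.
* Edge probabilities must be independent; no correlation model.
* PWP's enumeration cap (20 edges per trisection part) makes it a
  verification tool, not a production path — that is by design.
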