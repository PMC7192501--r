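---
title: "Flux order relations: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux order relations: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxorder)
```

## The model

A metabolic network with stoichiometric matrix $S$ (rows metabolites,
columns reactions) constrains its steady-state fluxes to the polytope

$$P = \{v : S v = 0,\; v_{\min} \le v \le v_{\max}\},$$

after all reversible reactions have been split into forward and backward
copies so that $v \ge 0$. Two reactions are **flux-ordered**, written
$i \ge j$, when $v_i \ge v_j$ for *every* $v \in P$ — a property of the
network structure and bounds alone, independent of kinetics. The relation is
reflexive, antisymmetric and transitive, i.e. a partial order, and therefore
induces a hierarchy: a reaction near the top imposes an upper flux bound on
everything reachable below it.

## Deciding one pair exactly

Whether $i \ge j$ holds everywhere on $P$ is decided through the extrema of
the flux ratio $v_i / v_j$ over the states with $v_j > 0$. The
linear-fractional program for $\rho_{\min}, \rho_{\max}$ becomes a linear
program after the Charnes–Cooper substitution $w = v/v_j$, $t = 1/v_j$:

$$z_{\min}, z_{\max} = \min,\max\; w_i
\quad \text{s.t.}\quad S w = 0,\; w_j = 1,\;
t\,v_{\min} \le w \le t\,v_{\max},\; t \ge 0.$$

The pair is ordered iff $z_{\min} \ge 1$ and $z_{\max} > 1$; it is
*always-equal* iff $z_{\min} = z_{\max} = 1$ (these pairs are collapsed, not
counted as ordered). An equivalent decision — used only as an independent
oracle, never as the main path — extremizes the difference $v_i - v_j$
directly over $P$, or evaluates it on the enumerated vertices of $P$.

Numerical choices:

* `eps = 1e-6` on the ratio scale for all order/equality calls. LP duality
  gaps on genome-scale double-precision models exceed `1e-9`, so a tighter
  threshold would misclassify; a looser one would merge genuinely distinct
  ratios.
* Infinite bounds are capped at 1000 mmol/gDW/h during model reading and
  canonicalization, so every program is bounded.
* The homogenization variable $t$ carries an explicit cap of $10^6$. When
  the true ratio supremum is infinite ($v_j$ can vanish while $v_i$ stays
  positive) the maximization would otherwise be unbounded; the reported
  $z_{\max}$ is then the cap-induced maximum, which is all the order
  decision needs ($z_{\max} > 1$).
* When the $w_j = 1$ system is infeasible ($v_j \equiv 0$), the pair is
  classified unordered. This cannot occur after blocked-reaction removal
  and is handled defensively.
* Pairs whose LPs fail are retried once with the same backend and a larger
  iteration budget, then reported as `undetermined` in the result
  attributes — never silently dropped.

## The two-stage search

Deciding all $n(n-1)$ directed pairs by LP alone is wasteful. The search
therefore runs in two stages:

1. **Sampling prefilter.** A hit-and-run walk draws flux vectors from $P$
   (null-space directions from an interior Chebyshev-style point). Any
   sampled state with $v_i < v_j - 10^{-6}$ is a *counterexample* proving
   $(i, j)$ unordered, so the pair is discarded without an LP. One
   counterexample suffices mathematically; the sample size (default 1000)
   affects only runtime, never the result, which is why the final set is
   seed-independent — a property the test suite asserts.
2. **Coupling shortcut, then verification.** Fully coupled pairs satisfy
   $v_i = \alpha v_j$ everywhere, so their order status follows from
   $\alpha$ directly: ordered if $\alpha > 1$, always-equal if
   $\alpha = 1$. The remaining candidates are verified by the ratio
   program.

Flux coupling itself (full / partial / directional / uncoupled) is
re-implemented from its ratio characterization. Activity implications are
decided by two explicit LPs per pair — the maximum of one flux with the
other fixed to zero — rather than by thresholding $z_{\max}$ against the
$t$-cap, which is exact on the polytope and robust. Directional pairs are
oriented leader $\to$ follower, where the follower's activity forces the
leader's; this matches the ordering convention (the leader sits higher in
the hierarchy). Whether the original analyses ran coupling with or without
the biomass minimum active is not derivable from the sources this package
follows, so coupling uses the same bounds as ordering by default — keeping
the order/coupling overlap internally consistent — and exposes
`unconstrained_biomass = TRUE` for the alternative.

## From pairs to a hierarchy

Always-equal groups (fully coupled with $\alpha = 1$, closed transitively)
collapse into single DAG nodes labelled by their lexicographically smallest
member. Group-level edges are deduplicated and the transitive reduction —
unique for DAGs — removes every edge implied by a longer path, yielding the
Hasse diagram of the poset. The *level* of a node is the longest shortest
path from any root (in-degree-0 node) that reaches it; roots, including
isolated nodes, sit at level 0. Levels are 0-based internally; exports
carry both a `level` and a 1-based `level1` attribute because both
labelling conventions are common.

For level-stratified analyses the levels are partitioned into *first*
(level 0), *middle* (level 1) and *last* (levels $\ge 2$) subsets — the
lowest levels hold most reactions, so this yields comparably sized groups;
the boundaries are configurable arguments.

Reactions ordered above the biomass pseudo-reaction (its DAG ancestors) are
necessarily essential: forcing one to zero propagates a zero upper bound to
biomass. The converse fails — essentiality also arises from binary switches
that are not flux-ordered with biomass — and the essentiality report counts
both sides. Two implementation notes: the ATP maintenance reaction is
excluded from the ancestor subgraph by default when annotated, because its
forced minimum flux makes it an artifactual ancestor; and single-knockout
FBA relaxes the medium's biomass lower bound to zero, since otherwise every
growth-reducing knockout would be infeasible and spuriously essential.

## Concordance with data

Gene-level measurements map to reactions by pooling the values of all genes
appearing anywhere in a reaction's GPR rule, across replicates (genes count
once regardless of repetition in the rule). For an ordered pair with value
multisets $D_i, D_j$ the mean pairwise difference
$\hat\delta_{ij} = \frac{1}{nm}\sum_p\sum_q (d_{ip} - d_{jq})$ collapses
algebraically to $\bar D_i - \bar D_j$. The agreement statistic is the
strictly positive fraction $f_{>0} = \Pr(\hat\delta > 0)$; strictness
guards against pairs whose enzymes share an identical gene set, which would
otherwise match trivially at $\hat\delta = 0$.

Significance comes from a permutation null: values are reassigned at the
data's granularity — per gene for transcript/protein, per reaction for flux
and $k_\mathrm{cat}$ — by drawing from the pool of all available values
*with replacement*, preserving each multiset's size (the without-replacement
variant was considered and rejected as the default because the sources are
silent and with-replacement matches "drawn from the set of all available
values" most literally; sizes are preserved so the recomputed means keep
their sampling variance structure). The empirical p-value is
$(r+1)/(n+1)$ with $r$ the number of rounds whose $f_{>0}$ reaches the
observed value; it therefore lives in $[1/(n+1), 1]$ and is conservative
under ties.

Cost-stratified subsets keep the ordered pairs in which **both** reactions
carry an enzyme cost at or above a percentile of all employed costs. The
"both members" reading was chosen because the economic hypothesis concerns
the cost of violating the order on either side; the percentile uses R's
default linear-interpolation quantile (type 7), fixed for reproducibility.
Mann–Whitney U tests between level subsets are one-sided (earlier levels
expected to carry more regulatory interactions) and use `stats::wilcox.test`,
which applies the exact distribution for small samples without ties and the
tie-corrected normal approximation otherwise.

## What the synthetic data emulate — and what they do not

The generator draws one steady-state flux vector as ground truth, assigns
each gene the mean truth of its reactions plus Gaussian noise, and emits
tables in the package's input formats. With `noise_sd = 0` every ordered
pair with strictly different sampled fluxes is respected ($f_{>0} = 1$);
with noise far above the flux scale the data are effectively exchangeable
and concordance collapses to the null ($f_{>0} \approx 0.5$, p-values
approximately uniform). Passing these tests shows the statistics behave as
their definitions require; it does *not* show that real transcript or
protein data follow flux orders — real data have between-gene variance
structure, measurement batch effects and coverage gaps that the generator
deliberately omits.

## Fixtures, oracles and problem sizes

All tests run on generated networks: named fixtures (chain, branch,
diamond, parallel chains, a growth network with redundant precursor routes,
and a 9-reaction "paperlike" branched network — a structural analogue
built for this package, not a transcription of any published figure) plus
seeded random 8-metabolite × 12-reaction networks grown around a guaranteed
uptake-to-export spine. Two independent oracles cross-check every module:
difference LPs over the polytope, and exhaustive vertex enumeration by
active-bound sets (double-description-style, guarded to small networks).
The correctness gate asserts exact set equality between the main path and
both oracles on all named fixtures and 25 random networks, seed-independence
across sampler seeds, the partial-order axioms, and the coupling/essentiality
consistency properties. These sizes keep the whole suite within a few
minutes on one core while still exercising every code path; the acceptance
script reports the same quantities at the same sizes.

## The LP backend

No dedicated linear-programming package is available in the package's
dependency envelope, and the one general-purpose simplex shipped with R's
recommended packages fails on the highly degenerate programs this domain
produces (equality systems with all-zero right-hand sides are the common
case, not the exception). `fluxorder` therefore includes its own
bounded-variable two-phase revised simplex with Bland's anticycling rule —
small, dense, deterministic, re-factorizing the basis every iteration for
numerical hygiene. It is validated in the test suite against vertex
enumeration on randomized LPs, including the degenerate $b = 0$ family.
The solver contract is deliberately minimal so a faster backend can be
substituted without touching any module above it.

## Known limitations

* Pair iteration is sequential; the per-pair LPs are stateless and could be
  parallelized, but correctness, determinism and order-independence were
  prioritized for this release.
* Vertex enumeration is exponential in the polytope's degrees of freedom
  and guarded accordingly; it is an oracle for small networks, not a tool.
* The SBML reader covers Level 3 core + fbc v2 (bounds via parameters,
  gene-product associations, notes-based subsystems) — the subset used by
  BIGG-distributed genome-scale models — not the full SBML standard.
* Genome-scale runs are supported by the same code paths but are
  compute-bound in R; the dense simplex is the bottleneck well before the
  algorithmics.
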