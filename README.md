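# fluxorder

Exact identification of **flux-ordered reaction pairs** in constraint-based
metabolic models, and analysis of the hierarchy they induce.

## The problem

The steady states of a metabolic network with stoichiometric matrix *S* form
the polytope *P* = {*v* : *S v* = 0, *v*min ≤ *v* ≤ *v*max} (reversible
reactions split so *v* ≥ 0). A reaction pair is *flux-ordered*, *i* ≥ *j*,
when *v*<sub>i</sub> ≥ *v*<sub>j</sub> holds in **every** steady state — a
structural property, independent of kinetics, that makes upstream reactions
hard upper bounds on everything ordered below them. The relation is a partial
order, so it organizes the network into a DAG-shaped hierarchy with direct
uses in metabolic engineering (a root reaction caps the flux of its whole
downstream cone) and in interpreting omics data.

`fluxorder` is for modelers who work with SBML / COBRA-JSON genome-scale or
toy models and want to:

* decide ordering exactly for every reaction pair — each pair's flux-ratio
  extrema come from the **Charnes–Cooper** transformation of the
  linear-fractional program min/max *v*<sub>i</sub>/*v*<sub>j</sub> over *P*
  (*z*min ≥ 1 and *z*max > 1 ⟺ ordered), after a **hit-and-run sampling
  prefilter** discards pairs with sampled counterexamples and **flux
  coupling analysis** (full/partial/directional, re-implemented from the
  ratio characterization) resolves fully coupled pairs from their constant
  ratio α;
* collapse always-equal groups (α = 1) and build the transitively reduced
  **flux order DAG** with hierarchy levels (longest shortest path from a
  root), condition comparisons (Jaccard), biomass-ancestor and reaction
  essentiality analyses;
* test whether transcript, protein, flux or k<sub>cat</sub> profiles respect
  the predicted order: per-pair mean data differences δ̂, the positive
  fraction f<sub>&gt;0</sub>, permutation p-values (*r*+1)/(*n*+1), enzyme-cost
  percentile subsets, and Mann–Whitney tests of regulatory-interaction counts
  across hierarchy levels.

Everything is tibble-first: pair sets, coupling tables, DAG summaries and
concordance results are data frames that compose with dplyr/ggplot2, with
`tidy()`/`glance()`/`autoplot()` methods for the result objects.

## Worked example

The bundled 9-reaction "paperlike" network (two uptakes, a branch point and
a 2:1 stoichiometric step) shows the whole pipeline:

```r
library(fluxorder)

model <- make_fixture("paperlike")
model
#> <metabolic_model> 5 metabolites x 9 reactions
#>   bounds: [0, 10] (irreversible form)

orders <- find_flux_ordered_pairs(model, n_samples = 300, seed = 1)
orders
#> <ordered_pair_set> 6 ordered, 2 equal pair(s)
#> # A tibble: 8 × 6
#>   from  to    relation method   z_min     z_max
#> * <chr> <chr> <chr>    <chr>    <dbl>     <dbl>
#> 1 E1    R1    ordered  lp       1.000 10000000.
#> 2 R1    R3    equal    coupling 1            1
#> 3 E2    R1    ordered  lp       2.00  10000000
#> 4 E1    R2    ordered  lp       1.00   5000001
#> ...
```

Each `ordered` row is a pair proven to satisfy *v*<sub>from</sub> ≥
*v*<sub>to</sub> in every steady state: `z_min` / `z_max` are the flux-ratio
extrema (a `z_max` near 10⁷ is the cap-induced value reported when the true
supremum is infinite), and `method` records whether the pair was decided by
an LP or inferred from a full coupling. `equal` rows (constant ratio 1) are
collapsed into single nodes when building the hierarchy:

```r
dag <- build_order_dag(orders)
generics::tidy(dag)
#> # A tibble: 7 × 4
#>   node  level n_reactions members
#>   <chr> <int>       <int> <chr>
#> 1 E1        0           1 E1
#> 2 E2        0           1 E2
#> 3 E3        0           2 R5,E3
#> 4 E4        0           1 E4
#> 5 R1        1           2 R1,R3
#> 6 R2        1           1 R2
#> 7 R4        1           1 R4
```

Level 0 holds the roots; `R1` sits below because the uptake `E1` bounds it.
Does (synthetic) expression data respect the hierarchy?

```r
omics <- synthetic_omics(model, noise_sd = 0.5, seed = 2)
profile <- map_data_to_reactions(omics$model, omics$gene_data, "transcript")
concordance(orders, profile, n_perm = 999, seed = 3)
#> <concordance_result> transcript: f_pos = 1 over 6 ordered pair(s); permutation p = 0.083 (999 rounds)
```

`f_pos = 1`: every ordered pair has a positive mean expression difference.
The permutation p-value reassigns values to genes at random and asks how
often the null matches the observed f<sub>&gt;0</sub> — with only six
(correlated) pairs the null reaches 1 in ~8% of rounds, a reminder that
small networks carry little evidence even under perfect agreement.

Genome-scale models load the same way (`read_model("iJO1366.xml")`,
`medium_config("EX_glc__D_e", ...)`, then `apply_medium()` +
`find_flux_ordered_pairs()`).

A thin command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","fluxorder.R",package="fluxorder"))') \
    orders --model model.json --carbon-source EX_glc --alpha-b 0.95 --out orders.tsv
```

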