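# netpharm

Quantitative network pharmacology for multi-herb formulas: from raw
interaction and property tables to the minimal set of components that still
covers a formula's disease-relevant target space.

A herbal formula can contain hundreds of small molecules; most contribute
little. `netpharm` implements a component-optimisation pipeline for
researchers in systems pharmacology who want to rank and prune a formula's
chemistry against a disease context:

1. **Lipinski screen** — active components by five literal drug-likeness
   rules (MW < 500 Da, HBD ≤ 5, HBA < 10, −2 ≤ cLogP ≤ 5, rotatable
   bonds ≤ 10);
2. **weighted disease-gene network** — disease genes mapped onto a merged
   PPI, each gene weighted `w(g) = sqrt(relevance(g) × literature(g))`;
3. **C-T network** — the bipartite compound–target graph
   `Net_CT = {N, E}` with its degree statistics;
4. **function response space (FRS)** — a deviation-variable goal program
   `min Z = p1·d1⁻ + p2·d2⁻ + p3·d3⁺` chooses how many maximal-degree
   components to keep; the induced target side defines the *effective
   proteins*;
5. **KGEC** — a genetic 0/1-knapsack algorithm (`max V = Σ vᵢxᵢ` subject
   to `Σ wᵢxᵢ ≤ C`) extracts the *key group of effective components*, the
   smallest-capacity group whose targets cover every effective protein;
6. **validation** — hypergeometric over-representation (BH-adjusted) and a
   pathway-coverage statistic comparing the KGEC's enriched terms with
   those of the disease-shared target set.

Everything is tidyverse-native: readers return tibbles, results carry
`tidy()`/`glance()` methods and `autoplot()`s, and the whole pipeline runs
from a single YAML config. Seeded generators create synthetic inputs with
planted ground truth (exact covers, enriched terms), so the full pipeline
is testable with no database access. Exact oracles — dynamic-programming
knapsack, greedy set cover, exhaustive goal-program enumeration — back
every stochastic component.

## Worked example

Generate a synthetic bundle with a planted 5-component cover and run the
whole pipeline:

```r
library(netpharm)

dir <- tempfile("demo")
m <- make_fixture(dir, seed = 20)          # writes ppi.tsv, components.csv, ...
cfg <- run_config(
  ppi = m$paths$ppi, disease_genes = m$paths$disease_genes,
  components = m$paths$components, ct_edges = m$paths$ct_edges,
  gmt = m$paths$gmt, out_dir = file.path(dir, "out"), seed = 20
)
run_pipeline(cfg)
#> netpharm pipeline run
#> Lipinski screen: 44 of 60 components active
#> C-T network: 44 components, 60 targets, 138 edges
#> Goal program (induced mode): C_com' = 24, C_tar' = 60, Z = 6.4
#> FRS: 84 nodes (24 components + 60 effective proteins), 118 edges
#> KGEC: 5/24 items selected (V = 60, W = 5 <= C = 5, coverage 100.0%)
#> Pathway coverage: 83.33% of reference terms recovered
```

Reading the output: 44 of 60 components pass the screen; the goal program
keeps the 24 highest-degree components (`d2⁻ = 0`: they fully account for
80% of the disease-shared targets, at the price of overshooting the 40%
component cap by `d3⁺ = 6.4`); their induced 60 targets become the
effective proteins; the genetic knapsack then finds that 5 components
(here, exactly the planted cover) suffice for 100% effective-protein
coverage; and the enriched pathways of those 5 components' targets recover
83.33% of the terms enriched in the disease-shared gene set.

Stage outputs (screen report, degree tables, FRS graph as SIF, KGEC table,
enrichment TSVs, `manifest.json` with config + checksums) land in
`out_dir`. Individual stages are plain functions — `screen_components()`,
`build_ct_network()`, `solve_goal_program()`, `select_kgec()`,
`hypergeom_enrich()` — and a thin CLI wraps them
(`Rscript inst/cli/netpharm.R run --config run.yaml`).

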