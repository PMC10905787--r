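---
title: "Methods: component optimisation for multi-herb formulas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: component optimisation for multi-herb formulas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

A multi-herb formula contains hundreds of small molecules, most of which
contribute little to its therapeutic effect. netpharm implements a
quantitative pipeline that narrows a formula down to a *key group of
effective components* (KGEC): the smallest component set whose protein
targets still span the disease-relevant part of the formula's target space.
The pipeline runs entirely on user-supplied tables — PPI edges, disease
genes with evidence scores, component physicochemical properties,
compound–target (C-T) pairs and gene-set annotations — and never queries a
live database.

## Stage 1: drug-likeness screen

Components are filtered by five literal drug-likeness rules: molecular
weight strictly below 500 Da, at most 5 H-bond donors, fewer than 10 H-bond
acceptors, cLogP in $[-2, 5]$, and at most 10 rotatable bonds. The
boundaries are deliberately literal rather than the looser classical
rule-of-five: "below 500" excludes 500.0 exactly. A missing property can
neither pass nor fail a rule; strict mode (the default) refuses to call
such a component active, lenient mode ignores the unknown. Screening is
per-component, so the active set of a union of tables is the union of the
active sets.

Published per-herb screening tables in this field count a component once
per herb it occurs in; `screen_components()$by_herb` follows that
convention, which is why herb-wise totals can exceed the number of distinct
components. (One widely cited formula screen prints per-herb active counts
summing to 276 against a stated text total of 267; the package reproduces
the table arithmetic and leaves such editorial discrepancies to the
reader.)

## Stage 2: weighted disease network and C-T network

Disease genes are mapped onto the merged PPI and the induced subgraph is
kept, each gene weighted by

$$w(g) = \sqrt{\mathrm{relevance}(g) \times \mathrm{literature}(g)},$$

the geometric mean of the two evidence axes. Genes that map but touch no
retained edge are dropped by default. PPI files from several source
databases are unioned with symbol normalisation (uppercase, trimmed; no
alias resolution — aliasing is the user's responsibility), self-loops
removed, and a configurable confidence floor (default 0.7) applied only to
files that carry scores.

The C-T network is the bipartite graph $Net_{C\text{-}T} = \{N, E\}$ of
active components and their targets. Its two headline statistics are the
mean number of targets per component $|E| / C_{com}$ and the mean number of
components per target $|E| / C_{tar}$; both are reported rounded half-up to
two decimals, the convention of printed network summaries. Components that
pass screening but have no targets stay in the network (they belong in
reports) but are excluded from degree rankings, since they can never enter
the response space.

## Stage 3: goal program and the function response space

How many components should be kept? The package answers with a
deviation-variable goal program. With $C_{com}, C_{tar}$ the network
counts, $C_{ov}$ the number of targets shared with the disease genes
(unique symbols — weighting by evidence is deliberately not done here), and
deviation variables $d_i^-, d_i^+ \ge 0$:

$$\min Z = p_1 d_1^- + p_2 d_2^- + p_3 d_3^+$$

subject to

$$C_{com}' + C_{tar}' + d_1^- - d_1^+ = 0.70\,C_{tar}$$
$$C_{com}' + d_2^- - d_2^+ = 0.80\,C_{ov}$$
$$C_{com}' + d_3^- - d_3^+ \le 0.40\,C_{com}.$$

The first goal asks the selection (components plus induced targets) to span
about 70% of the target space; the second asks for enough components to
account for 80% of the disease-shared targets; the third caps the selection
at 40% of the components, with only the overshoot $d_3^+$ penalised — an
inequality with a slack pair whose natural reading, given that $Z$ charges
$d_3^+$ alone, is "stay under the cap, pay for exceeding it".

Priorities are preemptive by default ($p_1 \gg p_2 \gg p_3$, implemented as
lexicographic minimisation; reported $Z$ uses nominal weights $10^6, 10^3,
1$); a weighted mode accepts explicit $p$ values.

In the default *induced* mode the program is coupled to the graph: for each
candidate size $k$ the selection is the top-$k$ maximal-degree component
subset and $C_{tar}'(k)$ is its induced target count, which makes
$C_{tar}'$ a step function of $k$ rather than a free variable. Because
bipartite degrees are independent of co-selection, the size-$k$ subset of
maximal total degree is exactly the top-$k$ by degree (ties broken by
component id ascending, making every run deterministic); the test suite
verifies this against full subset enumeration. The scan covers all $k \in
1..C_{com}$ — the range is small and exactness is free. An *analytic* mode
solves the uncoupled program in closed form for comparison.

The **function response space (FRS)** is the induced bipartite subgraph on
the chosen components; its target side defines the **effective proteins**,
so the effective-protein count always equals $C_{tar}'$.

## Stage 4: genetic knapsack and the KGEC

KGEC selection is a 0/1 knapsack over the FRS components: item $i$ has
value $v_i$ (default: number of effective proteins it targets), weight
$w_i$ (default 1, so capacity $C$ counts components), and

$$\max V = \sum_i v_i x_i, \qquad W = \sum_i w_i x_i \le C,\qquad
x_i \in \{0, 1\}.$$

Because the published result of interest is *full* coverage of the
effective proteins, the pipeline's default fitness is the coverage fraction
of the union of selected target sets; the printed $\max V$ sum-value
fitness is kept as an option.

The solver is a standard genetic algorithm: binary chromosomes, random
initial population, roulette-wheel selection (uniform when all fitnesses
are zero), single-point crossover (rate 0.8), one bit-flip per chromosome
with probability 0.02, elitism of 1. Infeasible chromosomes are *repaired*
by dropping the selected item with the lowest value-per-weight ratio until
$W \le C$ — repair rather than penalty keeps roulette fitness non-negative,
and on cover-style instances it acts as a powerful greedy local move. A
termination rule of "stop when $W = C$" alone can stall when the optimum
does not saturate capacity, so the run also stops after 25 stagnant
generations at saturated capacity, at full coverage (coverage mode), or at
the 500-generation cap. All randomness flows from one integer seed and the
caller's RNG state is restored, so identical configurations reproduce
results bit for bit.

`select_kgec()` searches over the capacity itself: it starts from the
greedy set-cover size and walks the capacity down to the smallest value at
which the GA still certifies full coverage. The greedy-cover chromosome
seeds the GA's initial population (memetic seeding) — the search therefore
starts from a feasible full cover and the GA can only improve on the greedy
baseline; pass `seed_greedy = FALSE` for a fully random population. Whether
the published analyses fixed $C$ a priori or discovered it is not stated in
the literature this design follows; the outer search is this package's
documented choice, and a fixed `capacity` argument reproduces the other
reading. Two exact oracles ship with the package: a dynamic-programming
knapsack (`dp_knapsack()`) and a greedy cover (`greedy_cover()`); the test
suite requires the GA to match the DP optimum on at least 95% of small
random instances and never exceed it.

## Stage 5: enrichment and pathway coverage

Over-representation uses the one-sided hypergeometric tail
$P(X \ge k)$ with Benjamini–Hochberg adjustment across tested terms. The
pathway-coverage statistic is the fraction of the reference selection's
significant terms recovered by the query selection — in the pipeline, KGEC
targets versus the CAP genes (targets shared with the disease genes). The
significance cutoff is applied to raw p at 0.05 by default, matching
common practice in this literature; applying it to adjusted p is one
argument away and recommended when many terms are tested.

## The synthetic generators

Every stage is testable offline because the package generates its own
inputs with the statistical structure the pipeline assumes:

* **PPI** — preferential-attachment graphs (scale-free, heavy-tailed
  degrees), uniform confidences on $[0.4, 1]$;
* **disease genes** — sampled from the PPI nodes with a default 15%
  off-network fraction, mirroring the roughly 15% mapping loss typical of
  curated disease lists landing on a PPI; log-normal relevance scores,
  $1 + \mathrm{Poisson}$ literature counts;
* **components** — each Lipinski rule fails independently with probability
  0.07 by default, giving $\approx 0.93^5 \approx 70\%$ active components,
  the active fraction typical of herbal-formula screens;
* **C-T edges** — power-law target counts (exponent 2.5, capped), plus an
  optional *planted exact cover*: $m$ components whose disjoint target sets
  partition a designated protein set. Planted carriers are chosen among
  screen-passing components so the signal survives ADME filtering. In the
  bundled fixture the planted proteins span the whole target pool, which
  keeps the planted set an exact cover of any induced effective-protein
  set and makes end-to-end recovery well defined;
* **annotations** — random decoy terms plus planted terms drawn from the
  planted proteins, guaranteed enrichable.

What the generators do **not** emulate: correlations between ADME
properties, community structure or pathway topology in the PPI, biased
target promiscuity of particular scaffolds, and literature-count/score
dependence. Passing tests therefore demonstrate algorithmic correctness
and recovery of planted structure, not performance on any particular real
formula.

## Numerical choices and degenerate inputs

* Ties everywhere break lexicographically by identifier; runs are
  deterministic given input and seed.
* Reported network means are rounded half-up (base `round()` is
  half-to-even and would print 7.905 as 7.9).
* Duplicate disease-gene rows merge by max score / summed counts —
  conservative weight, additive evidence.
* Zero-fitness GA populations fall back to uniform selection; capacity 0
  returns the empty selection; a single-item instance degenerates to a
  membership test.
* Goal-program inputs with no component or edge abort early, as does a
  disease list with no PPI overlap or an effective-protein set no item
  combination can cover (the offending proteins are listed).

## Problem sizes in the test suite

The suite exercises exact oracles where exhaustion is feasible: full
subset enumeration for goal programs up to 12 components (50 random
fixtures), DP-verified knapsacks up to $n = 15$ (100 instances),
combinatorial hypergeometric tails for all universes up to $N = 20$, and
planted-cover recovery on 40-component / 200-protein spaces across 10
seeds. End-to-end pipeline checks run on 300-gene PPIs with 60 components.
These sizes were chosen so every expected value is computable by brute
force; the algorithms themselves have no scale-specific logic.

## Known limitations

* No alias/ortholog resolution: symbol mismatches silently shrink
  overlaps.
* The goal coefficients (0.70, 0.80, 0.40) are taken as given; the package
  exposes them but offers no calibration procedure.
* The GA is a single-population algorithm without restarts; for very large
  FRS instances the capacity walk may settle one above the true minimum
  cover (the greedy baseline bounds the error).
* Coverage statistics inherit the annotation quality of the supplied GMT;
  the package never fetches or updates pathway databases.
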