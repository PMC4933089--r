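---
title: "A lattice model of tissue homeostasis, tumour growth and cytotoxic treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lattice model of tissue homeostasis, tumour growth and cytotoxic treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the model it implements: the
rules, the quantities they are built from, the choices made where a rule
could reasonably have been written several ways, and what the test suite
does and does not establish.

## The model in one paragraph

A rectangular grid of *elements* stands in for a tissue. Each element holds
an unordered population of cells, bounded by a carrying capacity, and
receives two kinds of resource every generation: a nutrient (a generic
oxygen/glucose proxy, consumed at a per-cell rate) and one growth factor
per gene of the genome (generic survival/growth signals, assessed but not
consumed). Both are shared among the element's cells in proportion to each
cell's demand — its nutrient target or gene target — so avid cells draw
more. Cells age on a countdown clock and divide when it reaches zero;
ill-adapted cells age faster; overcrowded elements shed their least fit
cells; Malignant cells (and only they) mutate and migrate. Everything else
— homeostatic turnover, tumour expansion, heterogeneity, necrotic cores,
accelerated repopulation after treatment — is emergent.

## Quantities and rules

**Resource shares.** A supply $S$ split over demands $T_1..T_P$ gives cell
$i$ the share $S\,T_i/\sum_p T_p$. Shares conserve the supply exactly
(tested to $10^{-9}$ relative tolerance) and the same transfer function is
used for the nutrient and for each gene factor.

**Expression feedback.** Cells nudge the local factor level towards their
own target through $E = 1 - e^{-(T-F)}$, where $F$ is the factor level the
cell experiences. The element's *available* factor for a gene is the
exogenous supply plus the sum of its cells' expressions, redistributed by
demand. We evaluate each cell's $F$ against its demand share of the
*exogenous* supply. This choice is pinned by the homeostatic equilibrium:
five cells with target 5 under supply 25 each see $F = 5$, express $E = 0$,
and receive exactly their target — the configuration the default parameters
are built around. (Evaluating $F$ against the whole element supply instead
would destabilise that equilibrium.)

**Gene health and ageing.** A gene is healthy iff its received share lies
*strictly* inside (target − tolerance, target + tolerance); a value exactly
on the boundary is unhealthy. A healthy cell's clock decreases by 1 per
generation, plus 1 per unhealthy gene; with the default three-gene genome
the decrement is between 1 and 4. A cell whose nutrient store is exhausted
has its clock forced to 0.

**Division.** At clock zero a cell enters DIVIDING and divides within the
same generation. The daughter starts with a full clock (its genotype's
lifetime) and the configured initial store; a Normal parent proceeds to
APOPTOTIC — Normal division is replacement, so the Normal population can
never grow, only turn over or shrink — while a Malignant parent resets its
clock and keeps dividing. Repeated Malignant division is what makes net
tumour growth possible at all: with one-shot division every birth is offset
by the parent's death, and no parameter choice could grow the population.
The parent-survival rule is still exposed as a configuration switch
(`malignant_parent_survives`) for exploring the alternative.

**Division under starvation.** A cell whose store ran dry enters DIVIDING
through the forced clock, but cloning requires fuel: with an empty store no
daughter is produced and the parent proceeds to APOPTOTIC. This is the one
place the state cycle and resource book-keeping interact, and it is what
makes underfeeding deplete a tissue — cells that cannot meet their
metabolic requirements die without issue, so populations shrink until the
per-cell share again covers the consumption rate. Had starvation produced
fully provisioned daughters, an underfed tissue would sustain itself on
free nutrient indefinitely, which contradicts the starvation behaviour the
stress experiments are built to show.

**Mutation.** With probability `mutation_rate`, a Malignant daughter's
trait vector is perturbed in exactly one uniformly chosen field (each gene
target, each gene tolerance, nutrient target, nutrient rate, lifetime,
mutation rate, invasion rate) by a factor drawn uniformly from
$[1-\delta, 1+\delta]$, $\delta = 0.2$ by default. A multiplicative kernel
is scale-free and sign-symmetric ("increase or decrease") without needing
per-field step sizes; probabilities are clamped to $[0,1]$, tolerances
floored at 0, lifetime rounded to an integer $\ge 1$. Genotype identity is
exact equality of the full trait tuple — mutation magnitudes are generated,
not measured, so exact comparison is safe — and the cumulative count of
Malignant genotypes ever created is the *gene pool*. The Normal base
genotype is not part of the pool: the pool counts clonal sub-populations of
the tumour, which is why a zero-mutation run reports a pool of exactly 1.

**Migration.** A Malignant daughter born into an element at or above
capacity migrates with probability `invasion_rate` to an element chosen
uniformly from the Moore radius-1 neighbourhood (8 neighbours, truncated at
edges). Suspended (necrotic) elements are excluded from the candidates —
nothing may touch a suspended element — and if no candidate remains the
daughter stays put.

**Competition.** An element above capacity recomputes its factor shares and
removes cells from the bottom of the fitness ranking
$F = \frac1N \sum_g e^{-|T_g - A_g|/T_g}$ until it is back at capacity.
Selection is blind to cell type. Ties are broken by age — the older cell
(lower clock) is removed first — and residual ties randomly. The age
tie-break matters: in a freshly invaded element all genomes are identical
and fitness alone cannot order the population.

**Element states and necrosis.** An element is NORMAL (only Normal cells,
or empty), TUMOUR (only Malignant), or a majority state for mixed
populations, with ties classed MAJORITY_NORMAL so that a tumour must have a
strict majority to claim an element's label. A TUMOUR element whose entire
Moore radius-2 neighbourhood (truncated at the grid edge) is TUMOUR or
NECROTIC becomes NECROTIC: it keeps its cells, frozen, and is skipped by
every processing step until the neighbourhood changes, whereupon it reverts
to TUMOUR. The radius is configurable (`necrosis_radius`).

**Treatment.** A cytotoxic strategy, active during a half-open window
$[g, g+d)$ triggered by generation or by malignant count, flags every
HEALTHY cell whose clock is at or below the cut-off for its type; a cell
that reaches clock zero while treatment is active dies instead of dividing.
Flagged cells are removed in the clearance phase of the same tick — before
resources are distributed — so a treated cell consumes nothing in its death
generation. Separate cut-offs for Normal and Malignant cells model
differential toxicity; an absent Normal cut-off is the "magic bullet".

## Anatomy of a generation

Each tick applies, in fixed order: (1) the active treatment strategy;
(2) clearance — APOPTOTIC cells advance to TO_BE_CLEARED and all flagged
cells are removed, so an apoptotic cell is visible for exactly one
generation; (3) resource distribution and ageing of HEALTHY cells;
(4) division, elements in row-major order, cells within an element in
random order; (5) fitness-ranked removal wherever capacity is exceeded;
(6) the element-state and necrosis update.

**Census point.** The per-generation observables are read between steps (3)
and (4): after ageing has settled, before divisions resolve. At that point
every lineage is represented exactly once, which is what makes the
homeostatic census land on the designed value (grid × optimum = 3,125 at
the defaults, with ~1% of cells in DIVIDING at lifetime 100) and keeps the
state partition healthy + dividing + apoptotic + to_be_cleared = total
exact on every row. One observable deviates: **mean cell age**
(lifetime − clock) is censused over viable (HEALTHY) cells at the *end* of
the tick, because the age distribution of a turning-over tissue only reads
correctly when newborn daughters (age 0) are included — ages are then
uniform on {0, …, lifetime−1} and the homeostatic mean sits just below 50,
where the pre-division census, which can never contain an age-0 cell, would
sit just above.

**Randomness.** All stochasticity — initial clock phases, within-element
processing order, mutation draws, migration targets, residual tie-breaks —
comes from one generator seeded per run; identical configuration and seed
reproduce a run bit for bit, and replicate sets derive their seeds as
base + 0, 1, …, n−1.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| grid | 25 × 25 | elements | tissue size; 45×45 and 100×100 in the long-run presets |
| optimum_count | 5 | cells/element | initial Normal population per element |
| carrying_capacity | 10 | cells/element | competition threshold |
| nutrient supply / target / rate | 10 / 10 / 1 | a.u. per generation | per-cell share 2 vs consumption 1 at optimum density |
| initial_store | 10 | a.u. | starting store of initial cells and daughters |
| genome | {(5, 1)} × 3 | a.u. | three identical genes; factor supply 25 per gene gives every cell its target at optimum density |
| lifetime | 100 | generations | cell-cycle length; sets the 1% turnover rate |
| mutation_rate / invasion_rate | 0.05 / 0.10 | probability | seeded Malignant cell's rates; both heritable and mutable |
| mutation_delta | 0.2 | — | multiplicative mutation half-width |
| necrosis_radius | 2 | elements | extended neighbourhood for necrosis |

The defaults are mutually tuned: at optimum density every cell receives
exactly its nutrient and gene-factor targets, so the unstressed tissue is
an exact fixed point of the update rules, and the stress experiments move
one input at a time off that fixed point.

## Numerical and degenerate-input choices

* Share computations refuse an empty population and a zero demand sum
  (degenerate-demand error) rather than returning NaNs.
* Eq-boundary semantics are strict everywhere they matter: the health band
  excludes its endpoints; the treatment window is half-open; a cell exactly
  at the cut-off is treated.
* A gene tolerance of 0 makes the gene permanently unhealthy (even a cell
  receiving its exact target), which is the strict-inequality limit.
* Empty elements are classed NORMAL (vacant tissue) and contribute nothing
  to resource feedback; an element left empty by starvation is never
  recolonised by Normal cells, since Normal division only replaces.
* The clock floors at 0 and never exceeds the genotype's lifetime; ages are
  therefore bounded by construction.
* Lifetime mutations round to the nearest integer ≥ 1; a rounding that
  lands on the old value is a silent non-mutation (the mutation event still
  counts, the genotype does not change).

## Derived statistics

The growth summaries are definitions of convenience over the metrics
series, and their parameters are part of the package's interface rather
than the model:

* **Doubling time** — generations from the first generation the
  (replicate-mean) malignant count reaches 20 cells to the first it reaches
  40. The 20-cell reference clears seeding noise, but sits in the
  *microscopic* phase of growth, where cells in crowded elements cycle
  every ~25 generations (every gene unhealthy, decrement 4); doubling time
  measured this way is therefore much shorter than a value read off the
  macroscopic limb of the growth curve, and grows with the reference level
  as the curve saturates.
* **Repopulation ratio** — mean per-generation malignant increment from the
  end of treatment to the end of the run, divided by the mean over the 200
  generations before onset; > 1 is accelerated repopulation. The
  post-window runs to the end of the run because a deep kill (cut-off 20
  removes ~98% of malignant cells here) is followed by a rebuild lag that a
  short fixed window would mistake for slow growth.
* **Recovery** (treatment-length sweep) — a run recovers iff its mean total
  over the last 100 generations is at least half the pre-treatment baseline
  (mean over the 100 generations before onset). The classification reads
  the state at the observation horizon, deliberately ignoring the trend:
  a population at a few percent of baseline that is still inching upward is
  collapsed at that horizon.

## What the experiments establish — and what they do not

The test suite verifies the closed-form functions against independent
brute-force oracles on 10⁴ random inputs, the conservation, bounds,
monotonicity and boundary properties of each, and the engine's invariants
(capacity, clock bounds, state partition, gene-pool monotonicity,
bit-identical reruns). The full-scale checks run the published
parameterisations: homeostasis (5 × 1,000 generations), the nutrient sweep
(supplies 1–15), the gene-factor stress points, untreated growth
(5 × 2,000), the toxicity and treatment-length experiments, and the
mutation (2.5–30%), invasion (2–20%) and zero-mutation sweeps. Sweep
directions are asserted as rank correlations on replicate-mean endpoints
rather than strict monotonicity, since single points move at SD level.

Two caveats matter when comparing against other implementations of the
same rules. First, the *pace* of tumour growth is sensitive to details the
rules do not pin down — the competition tie-break, the census conventions,
the order of clearance — even when every printed equation and experiment
constraint is honoured; the equations themselves force crowded elements to
be gene-unhealthy (ten cells sharing a supply of 25 cannot receive more
than ~3.5 each, below target − tolerance), so full elements always cycle
~4× faster than the unstressed tissue, and any statistic keyed to an
absolute cell-count threshold inherits that sensitivity. Second, treatment
outcomes at long durations depend on where malignant survivors can hide
(suspended necrotic cores, freshly invaded uncrowded elements), which in
turn depends on how large the tumour has grown by onset; the collapse
threshold of the treatment-length sweep is therefore a function of growth
pace, not an independent constant.

This is also a deliberately minimal model: no pharmacokinetics or
dose–response, no resistance by drug efflux, no stem-cell hierarchy, no
vasculature, diffusion or mechanics, and no real-time calibration — a
generation is a model unit, not a clock time. Conclusions about real
tumours should rest on the *relative* behaviour of scenarios (treated vs
untreated, differential vs uniform toxicity), which is what the model is
for.
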