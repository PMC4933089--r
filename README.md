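# neoplasim

An agent-based, dual-scale stochastic simulator of tissue homeostasis and
tumour growth on a rectangular lattice, written for computational-oncology
work on the population-dynamic side of cancer: clonal evolution and
intra-tumour heterogeneity, fitness-ranked cell competition under a carrying
capacity, necrotic-core formation, and the response of a growing tumour to
cytotoxic treatment schedules — including the counter-intuitive accelerated
repopulation that follows aggressive treatment. The model is deliberately
non-physiological: no oncogenes, pathways, vasculature or immune system,
just cells, resources and a few local rules, so that the emergent behaviours
can be attributed to competition and cell death alone.

## The model

The tissue is a W x H grid of elements, each holding a bounded population of
cells (Normal or Malignant). Every generation each element receives a
nutrient supply *S* and a per-gene growth-factor supply, and shares them
among its P cells by relative demand:

    DN_i = S * T_i / sum_p T_p

where *T_i* is cell *i*'s nutrient target (the same transfer function
distributes each gene factor by the cells' gene targets *G_i*). Each cell
carries a genome of N genes, each a (target, tolerance) pair. A gene is
*healthy* when the factor the cell received lies strictly inside
(target − tolerance, target + tolerance). Cells push back on their local
environment through an expression feedback

    E = 1 − exp(−(T − F))

(positive below target, negative above), and the element's available factor
is the exogenous supply plus the summed expressions, redistributed by
demand. A cell ages on a countdown clock (from its heritable `lifetime`,
default 100 generations): one decrement per generation plus one per
unhealthy gene, and a cell whose nutrient store runs dry drops its clock to
zero outright. At clock zero the cell divides — a Normal parent is replaced
by its daughter and dies; a Malignant parent divides repeatedly. Malignant
daughters mutate with probability `mutation_rate` (one heritable trait
perturbed multiplicatively) and, in a full element, migrate to an adjacent
element with probability `invasion_rate`. When an element exceeds its
carrying capacity, cells are ranked by local fitness

    F = (1/N) * sum_g exp(−|T_g − A_g| / T_g)    in (0, 1]

and the least fit are removed, blind to cell type. Tumour elements whose
whole Moore radius-2 neighbourhood is tumour become necrotic and are
suspended. A cytotoxic treatment strategy, active in a configured window,
flags every cell whose clock is at or below an age cut-off for clearance —
with separate cut-offs for Normal and Malignant cells (equal cut-offs model
non-differential chemotherapy; an absent Normal cut-off is the
Malignant-only "magic bullet").

## Worked example: untreated tumour growth

```r
library(neoplasim)
cfg <- preset("untreated_growth")   # 25x25 grid, one central Malignant seed,
print(cfg)                          # mutation 5%, invasion 10%, 2,000 generations
run <- run_simulation(cfg, seed = 1)
print(run)
#> Simulation run: 25 x 25 grid, 2000 generations (seed 1)
#>   final census: 4295 cells (2060 normal, 2235 malignant), gene pool 1529
#>   element states at end: 374 normal, 49 mixed, 115 tumour, 87 necrotic
run$metrics[c(500, 1000, 1500, 2000),
            c("generation", "normal_cells", "malignant_cells", "gene_pool",
              "active_clones", "dominance", "elems_tumour", "elems_necrotic")]
#>  generation normal_cells malignant_cells gene_pool active_clones dominance elems_tumour elems_necrotic
#>         500         3112              40        10             6      85.0            2              0
#>        1000         2957             382       157            37      66.0           31              0
#>        1500         2636            1047       642           141      53.2           71             24
#>        2000         2060            2235      1529           284      45.5          115             87
```

From a single seeded cell the malignant population expands and displaces the
normal tissue; the cumulative gene pool (every genotype ever created,
extinct clones included) grows with it while the dominance of the largest
clone falls from 100% to ~45% — the signature of increasing intra-tumour
heterogeneity. A necrotic core appears once the tumour mass is deep enough
that interior elements see only tumour around them. Averaging five
replicates,

```r
reps <- run_replicates(cfg, n_replicates = 5, base_seed = 1)
summarise_growth(reps)
#> $doubling_time      75        # generations, from a 20-cell reference
#> $repopulation_ratio NA        # no treatment in this scenario
#> $sigmoid_r2         0.998     # the growth curve is sigmoidal
```

Treatment scenarios are presets too, e.g.
`run_replicates(preset("toxicity_sweep", value = 20), 5, 1)` for the
non-differential cut-off-20 intervention at generations 1,500–1,524, and
`run_sweep("treatment_length_sweep")` for the duration sweep. The
catalogue (`preset_catalogue()`) covers homeostasis, the nutrient and
gene-factor stress sweeps, mutation/invasion-rate sweeps, differential
toxicity, the magic bullet, zero-mutation growth and the scaled long run.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/neoplasim.R preset --preset untreated_growth \
    --replicates 5 --seed 1 --out out/ --snapshot-at 1000,2000
Rscript inst/cli/neoplasim.R sweep --preset invasion_sweep --replicates 2 --out out/
```

writing one CSV per replicate, a mean/SD summary per scenario, and
element-state snapshot matrices (codes: 0 normal, 1 majority-normal,
2 majority-malignant, 3 tumour, 4 necrotic).

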