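#' Run one simulation
#'
#' Advances the model one generation at a time. Each tick applies, in fixed
#' order: (1) the active treatment strategy, if any; (2) clearance
#' (APOPTOTIC cells advance to TO_BE_CLEARED and flagged cells are removed);
#' (3) per-element resource distribution and ageing of HEALTHY cells;
#' (4) division of DIVIDING cells, with mutation and possible migration for
#' Malignant daughters; (5) fitness-ranked removal wherever an element
#' exceeds its carrying capacity; (6) the element-state and necrosis update.
#' The per-generation observables are censused between steps (3) and (4), so
#' `dividing_cells` counts the cells about to divide that generation and the
#' state partition `healthy + dividing + apoptotic + to_be_cleared =
#' total` holds on every row.
#'
#' All randomness comes from a generator seeded with `seed`; identical
#' configuration and seed reproduce the run bit for bit.
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @return object of class `"neoplasim_run"`: a list with `metrics` (one
#'   data.frame row per generation), `snapshots` (element-state matrices at
#'   the requested generations), `final_state`, `gene_pool` (cumulative
#'   Malignant genotypes ever created), `genotypes` (their trait vectors),
#'   `final_clones` (living cells per genotype at the end), plus the `config`
#'   and `seed`.
#' @examples
#' run <- run_simulation(sim_config(width = 5, height = 5, generations = 20), seed = 1)
#' head(run$metrics[, 1:6])
#' @export
run_simulation <- function(cfg, seed = 1L) {
  validate_config(cfg)
  out <- cpp_run_simulation(config_for_engine(cfg), as.integer(seed))
  out$config <- cfg
  out$seed <- as.integer(seed)
  class(out) <- "neoplasim_run"
  out
}

#' @export
print.neoplasim_run <- function(x, ...) {
  m <- x$metrics
  G <- nrow(m)
  cat(sprintf("Simulation run: %d x %d grid, %d generations (seed %d)\n",
              x$config$width, x$config$height, G, x$seed))
  cat(sprintf("  final census: %d cells (%d normal, %d malignant), gene pool %d\n",
              m$total_cells[G], m$normal_cells[G], m$malignant_cells[G],
              x$gene_pool))
  cat(sprintf("  element states at end: %d normal, %d mixed, %d tumour, %d necrotic\n",
              m$elems_normal[G],
              m$elems_majority_normal[G] + m$elems_majority_malignant[G],
              m$elems_tumour[G], m$elems_necrotic[G]))
  invisible(x)
}

#' One ageing step for a healthy cell
#'
#' Applies the per-generation update to a single HEALTHY cell: the nutrient
#' store gains the cell's share and loses its consumption rate; if the store
#' is exhausted the clock drops straight to zero (metabolic failure),
#' otherwise the clock decreases by one plus one per unhealthy gene. A clock
#' of zero moves the cell to DIVIDING, or to TO_BE_CLEARED when an active
#' cytotoxic treatment targets the cell's type.
#'
#' @param clock current countdown value.
#' @param store current nutrient store.
#' @param nutrient_share share received this generation.
#' @param nutrient_rate consumption per generation.
#' @param n_unhealthy number of unhealthy genes this generation.
#' @param treated is an active treatment targeting this cell's type?
#' @param state current cell state; must be `"HEALTHY"`.
#' @return list with updated `clock`, `store` and `state` (one of
#'   `"HEALTHY"`, `"DIVIDING"`, `"TO_BE_CLEARED"`).
#' @export
step_cell <- function(clock, store, nutrient_share, nutrient_rate,
                      n_unhealthy = 0, treated = FALSE, state = "HEALTHY") {
  if (!identical(state, "HEALTHY"))
    stop("contract violation: step_cell() applies only to HEALTHY cells")
  out <- cpp_step_cell(as.integer(clock), as.numeric(store),
                       as.numeric(nutrient_share), as.numeric(nutrient_rate),
                       as.integer(n_unhealthy), isTRUE(treated))
  out$state <- names(CELL_STATES)[match(out$state, CELL_STATES)]
  out
}

#' Gene-factor distribution for one element
#'
#' The full per-gene pipeline: each cell evaluates its expression feedback
#' against its demand-share of the exogenous supply; the available total
#' (exogenous plus the summed expressions) is then redistributed by relative
#' demand. An empty element leaves the supply untouched.
#'
#' @param gene_targets matrix with one row per cell and one column per gene.
#' @param factor_supply exogenous supply, one value per gene.
#' @return list with `available` (per-gene totals) and `shares` (cells x
#'   genes matrix of received amounts).
#' @export
distribute_gene_factors <- function(gene_targets, factor_supply) {
  gene_targets <- as.matrix(gene_targets)
  if (nrow(gene_targets) == 0)
    return(list(available = as.numeric(factor_supply),
                shares = matrix(numeric(0), 0, length(factor_supply))))
  cpp_distribute_factors(gene_targets, as.numeric(factor_supply))
}

#' Perturb one heritable trait
#'
#' A mutation multiplies exactly one uniformly chosen field of the trait
#' vector (a gene target or tolerance, the nutrient target or rate, the
#' lifetime, or the mutation or invasion rate) by a factor drawn uniformly
#' from `[1 - delta, 1 + delta]`. Rates are clamped to \[0, 1\], tolerances
#' floored at zero, and the lifetime rounded to an integer of at least 1.
#'
#' @param traits vector from [make_traits()].
#' @param delta mutation magnitude (default 0.2).
#' @param seed integer seed; the same seed and traits give the same result.
#' @return mutated trait vector.
#' @export
mutate_traits <- function(traits, delta = 0.2, seed = 1L) {
  ng <- n_genes(traits)
  out <- cpp_mutate_traits(as.numeric(traits), ng, as.numeric(delta),
                           as.integer(seed))
  attributes(out) <- attributes(traits)
  out
}

#' Fitness-ranked survivor selection
#'
#' When an element holds more cells than its carrying capacity the excess is
#' removed from the bottom of the fitness ranking; ties are broken by age
#' (lower clock, i.e. older, removed first) and then randomly. Selection is
#' blind to cell type.
#'
#' @param fitness per-cell fitness values.
#' @param clock per-cell clock values.
#' @param capacity carrying capacity.
#' @param seed seed for the random tie-break.
#' @return integer indices of the removed cells (empty when at or below
#'   capacity).
#' @export
rank_select <- function(fitness, clock, capacity, seed = 1L) {
  n_remove <- max(0L, length(fitness) - as.integer(capacity))
  as.integer(cpp_rank_removal(as.numeric(fitness), as.integer(clock),
                              n_remove, as.integer(seed)))
}

#' Element state from its cell composition
#'
#' `NORMAL` when only Normal cells (or none) are present, `TUMOUR` when only
#' Malignant cells are, and a majority state for mixed populations (ties
#' count as `MAJORITY_NORMAL`).
#'
#' @param n_normal,n_malignant cell counts.
#' @return element-state name.
#' @export
element_state <- function(n_normal, n_malignant) {
  code <- mapply(cpp_element_state, as.integer(n_normal), as.integer(n_malignant))
  names(ELEMENT_STATES)[match(code, ELEMENT_STATES)]
}

#' Necrosis update on an element-state matrix
#'
#' A TUMOUR element whose entire Moore neighbourhood of the given radius
#' (truncated at the grid edge) is TUMOUR or NECROTIC becomes NECROTIC and is
#' suspended from processing; a NECROTIC element whose neighbourhood no
#' longer qualifies reverts to TUMOUR.
#'
#' @param states integer matrix of element-state codes (see
#'   [element_state_codes()]).
#' @param radius neighbourhood radius (default 2).
#' @return updated integer matrix.
#' @export
apply_necrosis <- function(states, radius = 2L) {
  cpp_necrosis_update(matrix(as.integer(states), nrow(states), ncol(states)),
                      as.integer(radius))
}

#' Element-state integer codes
#'
#' The fixed code assignment used in snapshots:
#' NORMAL = 0, MAJORITY_NORMAL = 1, MAJORITY_MALIGNANT = 2, TUMOUR = 3,
#' NECROTIC = 4.
#' @return named integer vector.
#' @export
element_state_codes <- function() ELEMENT_STATES
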