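#' Demand-proportional nutrient shares
#'
#' Splits an element's per-generation nutrient supply among its cells in
#' proportion to each cell's nutrient target (its demand weight):
#' \deqn{DN_i = S \, T_i / \sum_p T_p.}
#' Shares always sum to the supply, so the element conserves nutrient.
#'
#' @param nutrient_targets positive numeric vector, one demand weight per cell.
#' @param supply total nutrient delivered to the element this generation
#'   (non-negative).
#' @return numeric vector of per-cell shares, same length as
#'   `nutrient_targets`.
#' @examples
#' nutrient_shares(rep(10, 5), 10)  # five equal cells -> 2 each
#' nutrient_shares(c(10, 30), 10)   # avid cell draws more
#' @export
nutrient_shares <- function(nutrient_targets, supply) {
  stopifnot(is.numeric(nutrient_targets), is.numeric(supply), length(supply) == 1)
  if (length(nutrient_targets) == 0)
    stop("no population: empty demand vector")
  if (supply < 0) stop("supply must be non-negative")
  cpp_nutrient_shares(as.numeric(nutrient_targets), as.numeric(supply))
}

#' Demand-proportional gene-factor shares
#'
#' Distributes the gene factor available in an element for one gene among the
#' element's cells by their gene targets: \eqn{DG_i = A \, G_i / \sum_p G_p}.
#' Unlike the nutrient, the available amount may be negative, because the
#' expression feedback of over-supplied cells can pull the element total below
#' zero; the conservation contract (shares sum to the available amount) holds
#' regardless of sign.
#'
#' @param gene_targets positive numeric vector, one gene target per cell.
#' @param available total factor available for this gene in the element.
#' @return numeric vector of per-cell shares.
#' @export
gene_factor_shares <- function(gene_targets, available) {
  stopifnot(is.numeric(gene_targets), is.numeric(available), length(available) == 1)
  if (length(gene_targets) == 0)
    stop("no population: empty demand vector")
  cpp_gene_factor_shares(as.numeric(gene_targets), as.numeric(available))
}

#' Boolean gene health
#'
#' A gene is healthy when the factor the cell received lies strictly inside
#' the tolerance band around its target: `received > target - tolerance` and
#' `received < target + tolerance`. Values exactly on a boundary are
#' unhealthy. Each unhealthy gene accelerates the cell's ageing by one extra
#' clock decrement per generation.
#'
#' @param target optimum gene-factor level (> 0).
#' @param tolerance half-width of the healthy band (>= 0).
#' @param received factor actually received; may be a vector.
#' @return logical vector.
#' @examples
#' gene_health(5, 1, c(4.5, 5, 6))  # TRUE TRUE FALSE: the boundary is excluded
#' @export
gene_health <- function(target, tolerance, received) {
  stopifnot(length(target) == 1, length(tolerance) == 1, tolerance >= 0)
  cpp_gene_health(as.numeric(target), as.numeric(tolerance), as.numeric(received))
}

#' Gene expression feedback
#'
#' Each cell nudges the element's factor level towards its own target through
#' the expression function \eqn{E = 1 - e^{-(T - F)}}, where `T` is the gene
#' target and `F` the factor the cell experiences. `E` is positive when the
#' factor is below target (the cell raises the local level), negative above
#' target (down-regulation), and zero at equilibrium.
#'
#' @param target gene target(s).
#' @param factor exogenous factor level(s) experienced by the cell.
#' @return numeric vector of expression values.
#' @export
gene_expression <- function(target, factor) {
  cpp_expression(as.numeric(target), as.numeric(factor))
}

#' Cell fitness
#'
#' Local adaptation score in (0, 1]:
#' \deqn{F = \frac{1}{N}\sum_{g=1}^{N} e^{-|T_g - A_g| / T_g}}
#' where \eqn{T_g} is the gene target and \eqn{A_g} the gene-factor share the
#' cell received. Fitness is 1 exactly when every gene receives its target,
#' and decays with relative deviation. It ranks cells during competition when
#' an element exceeds its carrying capacity; ranking is blind to cell type.
#'
#' @param gene_targets numeric vector of targets (length N, all > 0).
#' @param received numeric vector of received shares (length N).
#' @return single fitness value.
#' @examples
#' cell_fitness(c(5, 5, 5), c(5, 5, 5))   # 1
#' cell_fitness(5, 10)                    # exp(-1)
#' @export
cell_fitness <- function(gene_targets, received) {
  cpp_fitness(as.numeric(gene_targets), as.numeric(received))
}

#' Heritable trait vector
#'
#' Builds the flat trait vector that defines a genotype: the genome
#' (per-gene target and tolerance), the nutrient demand and consumption rate,
#' the lifetime (cell-cycle length in generations), and the mutation and
#' invasion probabilities. Every mutation event perturbs exactly one of these
#' fields, and genotype identity is exact equality of the whole vector.
#'
#' @param gene_targets,gene_tolerances numeric vectors of equal length N.
#' @param nutrient_target demand weight (> 0).
#' @param nutrient_rate consumption per generation (>= 0).
#' @param lifetime clock starting value, generations (integer >= 1).
#' @param mutation_rate,invasion_rate probabilities in \[0, 1\]; both 0 for
#'   Normal cells.
#' @return numeric vector of length `2N + 5` with named components, class
#'   `"neoplasim_traits"`.
#' @export
make_traits <- function(gene_targets = c(5, 5, 5), gene_tolerances = c(1, 1, 1),
                        nutrient_target = 10, nutrient_rate = 1, lifetime = 100,
                        mutation_rate = 0, invasion_rate = 0) {
  n <- length(gene_targets)
  stopifnot(
    n >= 1, length(gene_tolerances) == n,
    all(gene_targets > 0), all(gene_tolerances >= 0),
    nutrient_target > 0, nutrient_rate >= 0,
    lifetime >= 1, lifetime == round(lifetime),
    mutation_rate >= 0, mutation_rate <= 1,
    invasion_rate >= 0, invasion_rate <= 1
  )
  v <- c(gene_targets, gene_tolerances, nutrient_target, nutrient_rate,
         lifetime, mutation_rate, invasion_rate)
  names(v) <- c(paste0("target", seq_len(n)), paste0("tolerance", seq_len(n)),
                "nutrient_target", "nutrient_rate", "lifetime",
                "mutation_rate", "invasion_rate")
  class(v) <- "neoplasim_traits"
  v
}

#' @export
print.neoplasim_traits <- function(x, ...) {
  cat("Heritable traits (", (length(x) - 5) / 2, " genes)\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Number of genes in a trait vector
#' @param traits a vector from [make_traits()].
#' @return integer gene count.
#' @export
n_genes <- function(traits) {
  stopifnot((length(traits) - 5) %% 2 == 0)
  as.integer((length(traits) - 5) / 2)
}
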