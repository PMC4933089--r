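#' Simulation configuration
#'
#' Assembles and validates a full run configuration. The defaults are the
#' homeostasis parameterisation: a 25 x 25 grid, 5 cells per element at
#' start (optimum count), carrying capacity 10, nutrient supply and target
#' 10 with consumption rate 1, a three-gene genome of targets 5 and
#' tolerances 1 with factor supply 25 per gene, lifetime 100 generations and
#' an initial nutrient store of 10. At these values each cell of a
#' five-cell element receives exactly its nutrient and gene-factor targets,
#' so the tissue is unstressed.
#'
#' @param width,height grid dimensions (elements).
#' @param optimum_count initial Normal cells per element.
#' @param carrying_capacity maximum cells per element; beyond it the least
#'   fit cells are removed by ranked selection.
#' @param nutrient_supply,nutrient_target,nutrient_rate nutrient input per
#'   element per generation, per-cell demand weight, and per-cell
#'   consumption per generation.
#' @param initial_store nutrient store of cells at instantiation and of
#'   newborn daughters.
#' @param gene_targets,gene_tolerances the genome: per-gene optimum factor
#'   level and healthy-band half-width.
#' @param factor_supply exogenous gene-factor input per element per
#'   generation, one value per gene.
#' @param lifetime cell-cycle length: the clock counts down from this value.
#' @param generations number of ticks to simulate.
#' @param malignant_seed `NULL` for no tumour, or a list with `generation`
#'   (insert before this many ticks have elapsed; 0 = at start), `row`/`col`
#'   (0-based element coordinates, `NULL` = grid centre), `count`,
#'   `mutation_rate` and `invasion_rate` of the seeded cell(s). The seed
#'   carries the Normal genome and a full clock: no genetic head start.
#' @param treatment `NULL`, or a strategy block from
#'   [cytotoxic_treatment()].
#' @param mutation_delta half-width of the multiplicative mutation kernel: a
#'   mutated field is scaled by a factor drawn uniformly from
#'   `[1 - delta, 1 + delta]`.
#' @param malignant_parent_survives if `TRUE` (default) a Malignant parent
#'   resets its clock and stays HEALTHY after division (repeated division);
#'   if `FALSE` it proceeds to APOPTOTIC like a Normal parent.
#' @param necrosis_radius Moore-neighbourhood radius for the necrosis rule.
#' @param snapshot_at generations at which to record an element-state matrix.
#' @return validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(generations = 50)
#' cfg$carrying_capacity
#' @export
sim_config <- function(width = 25, height = 25,
                       optimum_count = 5, carrying_capacity = 10,
                       nutrient_supply = 10, nutrient_target = 10,
                       nutrient_rate = 1, initial_store = 10,
                       gene_targets = c(5, 5, 5), gene_tolerances = c(1, 1, 1),
                       factor_supply = c(25, 25, 25),
                       lifetime = 100, generations = 1000,
                       malignant_seed = NULL, treatment = NULL,
                       mutation_delta = 0.2,
                       malignant_parent_survives = TRUE,
                       necrosis_radius = 2, snapshot_at = integer(0)) {
  seed_defaults <- list(generation = 0L, row = NULL, col = NULL, count = 1L,
                        mutation_rate = 0.05, invasion_rate = 0.1)
  if (!is.null(malignant_seed)) {
    unknown <- setdiff(names(malignant_seed), names(seed_defaults))
    if (length(unknown))
      stop("unknown malignant_seed field(s): ", paste(unknown, collapse = ", "))
    merged <- seed_defaults
    for (nm in names(malignant_seed))
      merged[nm] <- list(malignant_seed[[nm]])  # keeps explicit NULLs
    malignant_seed <- merged
  }
  cfg <- list(
    width = as.integer(width), height = as.integer(height),
    optimum_count = as.integer(optimum_count),
    carrying_capacity = as.integer(carrying_capacity),
    nutrient_supply = as.numeric(nutrient_supply),
    nutrient_target = as.numeric(nutrient_target),
    nutrient_rate = as.numeric(nutrient_rate),
    initial_store = as.numeric(initial_store),
    gene_targets = as.numeric(gene_targets),
    gene_tolerances = as.numeric(gene_tolerances),
    factor_supply = as.numeric(factor_supply),
    lifetime = as.integer(lifetime),
    generations = as.integer(generations),
    malignant_seed = malignant_seed,
    treatment = treatment,
    mutation_delta = as.numeric(mutation_delta),
    malignant_parent_survives = isTRUE(malignant_parent_survives),
    necrosis_radius = as.integer(necrosis_radius),
    snapshot_at = as.integer(snapshot_at)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every field against the model's type invariants and returns the
#' configuration invisibly unchanged; any violation is an error naming the
#' offending field.
#'
#' @param cfg a `"sim_config"` list.
#' @return `cfg`, invisibly usable in a pipeline.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid configuration: ", msg, call. = FALSE)
  chk(cfg$width >= 1 && cfg$height >= 1, "grid dimensions must be >= 1")
  chk(cfg$optimum_count >= 1, "optimum_count must be >= 1")
  chk(cfg$carrying_capacity >= cfg$optimum_count,
      "carrying_capacity must be >= optimum_count")
  chk(cfg$nutrient_supply >= 0, "nutrient_supply must be >= 0")
  chk(cfg$nutrient_target > 0, "nutrient_target must be > 0")
  chk(cfg$nutrient_rate >= 0, "nutrient_rate must be >= 0")
  chk(cfg$initial_store >= 0, "initial_store must be >= 0")
  n <- length(cfg$gene_targets)
  chk(n >= 1, "genome must contain at least one gene")
  chk(all(cfg$gene_targets > 0), "gene_targets must all be > 0")
  chk(length(cfg$gene_tolerances) == n && all(cfg$gene_tolerances >= 0),
      "gene_tolerances must be >= 0 and match the genome length")
  chk(length(cfg$factor_supply) == n,
      "factor_supply must have one value per gene")
  chk(cfg$lifetime >= 1, "lifetime must be >= 1")
  chk(cfg$generations >= 1, "generations must be >= 1")
  chk(cfg$mutation_delta >= 0 && cfg$mutation_delta < 1,
      "mutation_delta must be in [0, 1)")
  chk(cfg$necrosis_radius >= 1, "necrosis_radius must be >= 1")
  ms <- cfg$malignant_seed
  if (!is.null(ms)) {
    chk(ms$generation >= 0, "malignant_seed$generation must be >= 0")
    chk(ms$count >= 1, "malignant_seed$count must be >= 1")
    chk(ms$mutation_rate >= 0 && ms$mutation_rate <= 1,
        "malignant_seed$mutation_rate must be a probability in [0, 1]")
    chk(ms$invasion_rate >= 0 && ms$invasion_rate <= 1,
        "malignant_seed$invasion_rate must be a probability in [0, 1]")
    if (!is.null(ms$row))
      chk(ms$row >= 0 && ms$row < cfg$height, "malignant_seed$row out of range")
    if (!is.null(ms$col))
      chk(ms$col >= 0 && ms$col < cfg$width, "malignant_seed$col out of range")
  }
  tr <- cfg$treatment
  if (!is.null(tr)) {
    chk(tr$trigger %in% c("generation", "malignant_count"),
        "treatment$trigger must be 'generation' or 'malignant_count'")
    chk(is.numeric(tr$trigger_value) && tr$trigger_value >= 0,
        "treatment$trigger_value must be >= 0")
    chk(is.numeric(tr$duration) && tr$duration >= 1,
        "treatment$duration must be >= 1 (Inf for open-ended)")
    for (f in c("cutoff_normal", "cutoff_malignant"))
      chk(is.na(tr[[f]]) || tr[[f]] >= 0, paste0("treatment$", f, " must be >= 0 or NA"))
    chk(!(is.na(tr$cutoff_normal) && is.na(tr$cutoff_malignant)),
        "treatment must target at least one cell type")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation configuration: %d x %d grid, %d generations\n",
              x$width, x$height, x$generations))
  cat(sprintf("  element: optimum %d, capacity %d; lifetime %d\n",
              x$optimum_count, x$carrying_capacity, x$lifetime))
  cat(sprintf("  nutrient: supply %g, target %g, rate %g, initial store %g\n",
              x$nutrient_supply, x$nutrient_target, x$nutrient_rate,
              x$initial_store))
  cat(sprintf("  genome: %d gene(s), targets {%s}, factor supply {%s}\n",
              length(x$gene_targets),
              paste(x$gene_targets, collapse = ", "),
              paste(x$factor_supply, collapse = ", ")))
  if (!is.null(x$malignant_seed))
    cat(sprintf("  malignant seed: %d cell(s) at generation %d, mutation %g, invasion %g\n",
                x$malignant_seed$count, x$malignant_seed$generation,
                x$malignant_seed$mutation_rate, x$malignant_seed$invasion_rate))
  if (!is.null(x$treatment))
    cat(sprintf("  treatment: trigger %s %g, duration %g, cut-offs N=%s M=%s\n",
                x$treatment$trigger, x$treatment$trigger_value,
                x$treatment$duration,
                ifelse(is.na(x$treatment$cutoff_normal), "none", x$treatment$cutoff_normal),
                ifelse(is.na(x$treatment$cutoff_malignant), "none", x$treatment$cutoff_malignant)))
  invisible(x)
}

#' Read or write a configuration file
#'
#' Configurations round-trip through YAML. Unknown keys are rejected;
#' omitted keys take the documented defaults, so an empty file yields the
#' homeostasis configuration.
#'
#' @param path file path.
#' @return `read_config()` returns a validated `"sim_config"`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$treatment)) {
    raw$treatment <- do.call(cytotoxic_treatment, raw$treatment)
  }
  do.call(sim_config, raw)
}

#' @rdname read_config
#' @param cfg a `"sim_config"`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  out <- unclass(cfg)
  out$malignant_parent_survives <- isTRUE(out$malignant_parent_survives)
  if (!is.null(out$treatment)) out$treatment <- unclass(out$treatment)
  out <- Filter(Negate(is.null), out)
  yaml::write_yaml(out, path)
  invisible(path)
}

# flatten config for the C++ engine (internal)
config_for_engine <- function(cfg) {
  ms <- cfg$malignant_seed
  tr <- cfg$treatment
  list(
    width = cfg$width, height = cfg$height,
    optimum_count = cfg$optimum_count,
    carrying_capacity = cfg$carrying_capacity,
    nutrient_supply = cfg$nutrient_supply,
    nutrient_target = cfg$nutrient_target,
    nutrient_rate = cfg$nutrient_rate,
    initial_store = cfg$initial_store,
    gene_targets = cfg$gene_targets,
    gene_tolerances = cfg$gene_tolerances,
    factor_supply = cfg$factor_supply,
    lifetime = cfg$lifetime,
    generations = cfg$generations,
    seed_generation = if (is.null(ms)) 0L else as.integer(ms$generation),
    seed_row = if (is.null(ms) || is.null(ms$row)) -1L else as.integer(ms$row),
    seed_col = if (is.null(ms) || is.null(ms$col)) -1L else as.integer(ms$col),
    seed_count = if (is.null(ms)) 0L else as.integer(ms$count),
    mutation_rate = if (is.null(ms)) 0 else ms$mutation_rate,
    invasion_rate = if (is.null(ms)) 0 else ms$invasion_rate,
    mutation_delta = cfg$mutation_delta,
    malignant_parent_survives = cfg$malignant_parent_survives,
    necrosis_radius = cfg$necrosis_radius,
    snapshot_at = cfg$snapshot_at,
    treatment = if (is.null(tr)) NULL else list(
      trigger = tr$trigger,
      trigger_value = as.numeric(tr$trigger_value),
      duration = as.numeric(tr$duration),
      cutoff_normal = if (is.na(tr$cutoff_normal)) -1L else as.integer(tr$cutoff_normal),
      cutoff_malignant = if (is.na(tr$cutoff_malignant)) -1L else as.integer(tr$cutoff_malignant)
    )
  )
}
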