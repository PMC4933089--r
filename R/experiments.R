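#' Catalogue of experiment presets
#'
#' Named scenario configurations covering the model's standard experiments:
#'
#' * `homeostasis` — unstressed Normal tissue, 25 x 25 grid, 1,000
#'   generations; the population should hold near grid x optimum = 3,125
#'   with ~1% of cells dividing at any time.
#' * `nutrient_sweep` — nutrient supply varied 1-15 in integer steps
#'   (underfeeding below 5 starves cells).
#' * `gene_factor_sweep` — gene-factor supply varied 0-45 in steps of 5
#'   (optimum 25); off-optimum supply speeds cell turnover about four-fold.
#' * `untreated_growth` — a single Malignant cell seeded in the central
#'   element (mutation 5%, invasion 10%), 2,000 generations.
#' * `extended_growth` — the same on a 45 x 45 grid for 6,000 generations
#'   (spatial tendrils and necrotic core).
#' * `mutation_sweep` — mutation rate 2.5%-30% in 2.5% steps.
#' * `invasion_sweep` — invasion rate 2%-20% in 2% steps.
#' * `toxicity_sweep` — non-differential cytotoxic cut-offs 0/10/20,
#'   treatment from generation 1,500 for 25 generations.
#' * `differential_toxicity` — Normal cut-off 10 vs Malignant 15/20/25.
#' * `treatment_length_sweep` — duration 15-60 in steps of 5 (Malignant
#'   cut-off 20, Normal 10).
#' * `magic_bullet` — Malignant-only cut-offs 15/20/25.
#' * `zero_mutation` — mutation rate 0, invasion 0%-8% in 2% steps; the
#'   gene pool must stay at 1 throughout.
#' * `optimum_count_sweep` — optimum cell count varied (capacity fixed at
#'   10); earlier competition speeds tumour growth.
#' * `scaled_run` — 100 x 100 grid, 20,000 generations, for the sigmoidal
#'   long-run growth shape.
#'
#' Sweep presets carry a `sweep` attribute naming the axis and its values;
#' `preset(name, value)` instantiates one point of the sweep.
#'
#' @return named list; each entry is a `"sim_config"` (the sweep presets at
#'   their first axis value).
#' @export
preset_catalogue <- function() {
  lapply(setNames(nm = preset_names()), preset)
}

preset_names <- function() {
  c("homeostasis", "nutrient_sweep", "gene_factor_sweep", "untreated_growth",
    "extended_growth", "mutation_sweep", "invasion_sweep", "toxicity_sweep",
    "differential_toxicity", "treatment_length_sweep", "magic_bullet",
    "zero_mutation", "optimum_count_sweep", "scaled_run")
}

#' @rdname preset_catalogue
#' @param name preset name.
#' @param value for a sweep preset, the axis value to instantiate (default:
#'   the first value of the sweep).
#' @param generations optional override of the preset's run length.
#' @export
preset <- function(name, value = NULL, generations = NULL) {
  name <- match.arg(name, preset_names())
  growth_seed <- list(generation = 0, count = 1,
                      mutation_rate = 0.05, invasion_rate = 0.1)
  sweep <- NULL
  cfg <- switch(name,
    homeostasis = sim_config(generations = 1000),
    nutrient_sweep = {
      sweep <- list(axis = "nutrient_supply", values = 1:15)
      v <- if (is.null(value)) sweep$values[1] else value
      sim_config(nutrient_supply = v, generations = 1000)
    },
    gene_factor_sweep = {
      sweep <- list(axis = "factor_supply", values = seq(0, 45, by = 5))
      v <- if (is.null(value)) sweep$values[1] else value
      sim_config(factor_supply = rep(v, 3), generations = 1000)
    },
    untreated_growth = sim_config(generations = 2000,
                                  malignant_seed = growth_seed),
    extended_growth = sim_config(width = 45, height = 45, generations = 6000,
                                 malignant_seed = growth_seed),
    mutation_sweep = {
      sweep <- list(axis = "mutation_rate", values = seq(0.025, 0.30, by = 0.025))
      v <- if (is.null(value)) sweep$values[1] else value
      seed <- growth_seed; seed$mutation_rate <- v
      sim_config(generations = 2000, malignant_seed = seed)
    },
    invasion_sweep = {
      sweep <- list(axis = "invasion_rate", values = seq(0.02, 0.20, by = 0.02))
      v <- if (is.null(value)) sweep$values[1] else value
      seed <- growth_seed; seed$invasion_rate <- v
      sim_config(generations = 2000, malignant_seed = seed)
    },
    toxicity_sweep = {
      sweep <- list(axis = "cutoff", values = c(0, 10, 20))
      v <- if (is.null(value)) sweep$values[1] else value
      sim_config(generations = 2000, malignant_seed = growth_seed,
                 treatment = cytotoxic_treatment(trigger_value = 1500,
                                                 duration = 25,
                                                 cutoff_normal = v,
                                                 cutoff_malignant = v))
    },
    differential_toxicity = {
      sweep <- list(axis = "cutoff_malignant", values = c(15, 20, 25))
      v <- if (is.null(value)) sweep$values[1] else value
      sim_config(generations = 2000, malignant_seed = growth_seed,
                 treatment = cytotoxic_treatment(trigger_value = 1500,
                                                 duration = 25,
                                                 cutoff_normal = 10,
                                                 cutoff_malignant = v))
    },
    treatment_length_sweep = {
      sweep <- list(axis = "duration", values = seq(15, 60, by = 5))
      v <- if (is.null(value)) sweep$values[1] else value
      sim_config(generations = 2000, malignant_seed = growth_seed,
                 treatment = cytotoxic_treatment(trigger_value = 1500,
                                                 duration = v,
                                                 cutoff_normal = 10,
                                                 cutoff_malignant = 20))
    },
    magic_bullet = {
      sweep <- list(axis = "cutoff_malignant", values = c(15, 20, 25))
      v <- if (is.null(value)) sweep$values[1] else value
      sim_config(generations = 2000, malignant_seed = growth_seed,
                 treatment = cytotoxic_treatment(trigger_value = 1500,
                                                 duration = 25,
                                                 cutoff_normal = NA,
                                                 cutoff_malignant = v))
    },
    zero_mutation = {
      sweep <- list(axis = "invasion_rate", values = seq(0, 0.08, by = 0.02))
      v <- if (is.null(value)) sweep$values[1] else value
      seed <- growth_seed; seed$mutation_rate <- 0; seed$invasion_rate <- v
      sim_config(generations = 2000, malignant_seed = seed)
    },
    optimum_count_sweep = {
      sweep <- list(axis = "optimum_count", values = c(1, 2, 3, 5, 7))
      v <- if (is.null(value)) sweep$values[1] else value
      sim_config(optimum_count = v, generations = 2000,
                 malignant_seed = growth_seed)
    },
    scaled_run = sim_config(width = 100, height = 100, generations = 20000,
                            malignant_seed = growth_seed)
  )
  if (!is.null(generations)) cfg$generations <- as.integer(generations)
  attr(cfg, "preset") <- name
  attr(cfg, "sweep") <- sweep
  validate_config(cfg)
}

#' Run replicate simulations
#'
#' Runs `n_replicates` independent simulations with seeds `base_seed + 0,
#' 1, ..., n - 1` and aggregates the per-generation metrics into mean and SD
#' series. The same base seed reproduces the whole set.
#'
#' @param cfg a [sim_config()] or preset.
#' @param n_replicates number of runs (>= 1).
#' @param base_seed first seed.
#' @return list of class `"neoplasim_replicates"`: `runs` (the individual
#'   run objects), `summary` (from [aggregate_metrics()]), `n_replicates`,
#'   `base_seed`.
#' @export
run_replicates <- function(cfg, n_replicates = 5, base_seed = 1L) {
  stopifnot(n_replicates >= 1)
  runs <- lapply(seq_len(n_replicates) - 1L,
                 function(k) run_simulation(cfg, seed = base_seed + k))
  structure(list(runs = runs, summary = aggregate_metrics(runs),
                 n_replicates = n_replicates, base_seed = as.integer(base_seed),
                 config = cfg),
            class = "neoplasim_replicates")
}

#' @export
print.neoplasim_replicates <- function(x, ...) {
  cat(sprintf("Replicate set: %d run(s) of %d generations (base seed %d)\n",
              x$n_replicates, nrow(x$summary), x$base_seed))
  g <- nrow(x$summary)
  cat(sprintf("  final mean total %.1f (SD %.1f), malignant %.1f\n",
              x$summary$total_cells_mean[g], x$summary$total_cells_sd[g],
              x$summary$malignant_cells_mean[g]))
  invisible(x)
}

#' Run a parameter sweep
#'
#' Instantiates a sweep preset at each axis value and runs replicates at
#' every point.
#'
#' @param name a sweep preset name (see [preset_catalogue()]).
#' @param values axis values (default: the preset's full published range).
#' @param n_replicates replicates per point.
#' @param base_seed first seed (shared across points, so points differ only
#'   in the swept parameter).
#' @param generations optional run-length override.
#' @return list of class `"neoplasim_sweep"`: `axis`, `values`, `points`
#'   (one `"neoplasim_replicates"` per value), and `endpoints`, a data.frame
#'   of final-generation replicate means per value.
#' @export
run_sweep <- function(name, values = NULL, n_replicates = 5, base_seed = 1L,
                      generations = NULL) {
  cfg0 <- preset(name)
  sweep <- attr(cfg0, "sweep")
  if (is.null(sweep)) stop("preset '", name, "' has no sweep axis")
  if (is.null(values)) values <- sweep$values
  points <- lapply(values, function(v) {
    run_replicates(preset(name, value = v, generations = generations),
                   n_replicates = n_replicates, base_seed = base_seed)
  })
  g <- nrow(points[[1]]$summary)
  endpoints <- data.frame(
    value = values,
    malignant_cells = vapply(points, function(p) p$summary$malignant_cells_mean[g], 0),
    normal_cells = vapply(points, function(p) p$summary$normal_cells_mean[g], 0),
    total_cells = vapply(points, function(p) p$summary$total_cells_mean[g], 0),
    gene_pool = vapply(points, function(p) p$summary$gene_pool_mean[g], 0),
    active_clones = vapply(points, function(p) p$summary$active_clones_mean[g], 0),
    dominance = vapply(points, function(p) p$summary$dominance_mean[g], 0)
  )
  structure(list(axis = sweep$axis, values = values, points = points,
                 endpoints = endpoints, preset = name),
            class = "neoplasim_sweep")
}

#' @export
print.neoplasim_sweep <- function(x, ...) {
  cat(sprintf("Sweep of %s over %d value(s) ('%s' preset)\n",
              x$axis, length(x$values), x$preset))
  print(x$endpoints, digits = 4)
  invisible(x)
}

#' Malignant doubling time
#'
#' Generations taken for a malignant count series to grow from a reference
#' level to twice that level; measured from the first generation the series
#' reaches `reference` (20 cells by default, above the seeding noise floor)
#' to the first generation it reaches `2 * reference`. `NA` when the series
#' never doubles.
#'
#' @param malignant per-generation malignant counts (replicate mean).
#' @param reference reference count.
#' @return doubling time in generations, or `NA`.
#' @export
doubling_time <- function(malignant, reference = 20) {
  i0 <- which(malignant >= reference)[1]
  i1 <- which(malignant >= 2 * reference)[1]
  if (is.na(i0) || is.na(i1)) return(NA_real_)
  as.numeric(i1 - i0)
}

#' Accelerated-repopulation statistic
#'
#' Ratio of the mean per-generation malignant growth increment over the
#' post-treatment period (from the end of treatment to the end of the
#' series, by default) to the mean over the `window` generations before
#' treatment starts. A ratio above 1 indicates accelerated repopulation:
#' the post-treatment growth trend is steeper than the pre-treatment trend.
#' A deep cytotoxic kill is followed by a lag while the residual population
#' rebuilds, so the post-treatment trend is assessed over the whole
#' remaining run rather than an arbitrary short window.
#'
#' @param malignant per-generation malignant counts.
#' @param start first active treatment generation.
#' @param duration treatment length in generations.
#' @param window pre-treatment comparison window (default 200 generations).
#' @param post_window generations after treatment to average over; `NULL`
#'   (default) uses everything up to the end of the series.
#' @return the post/pre growth-rate ratio.
#' @export
repopulation_ratio <- function(malignant, start, duration, window = 200,
                               post_window = NULL) {
  g <- length(malignant)
  pre <- max(2, start - window):(start - 1)
  post_start <- min(start + duration, g - 1)
  post_end <- if (is.null(post_window)) g else min(post_start + post_window - 1, g)
  post <- post_start:post_end
  rate <- function(idx) mean(diff(malignant[c(idx[1] - 1, idx)]))
  rate(post) / rate(pre)
}

#' Post-treatment recovery classification
#'
#' A treated run "recovers" when, by the end of the run, its total
#' population has returned to at least `baseline_frac` of the pre-treatment
#' baseline (both measured as means over `window` generations). Otherwise
#' the population is classed as collapsed: still far below its pre-treatment
#' level at the observation horizon, whatever its current trend.
#'
#' @param total per-generation total cell counts.
#' @param start first active treatment generation.
#' @param duration treatment length (unused by the classification but kept
#'   in the signature for clarity of call sites).
#' @param window averaging window (default 100).
#' @param baseline_frac recovery fraction of baseline (default 0.5).
#' @return logical: `TRUE` if recovered.
#' @export
recovered <- function(total, start, duration, window = 100,
                      baseline_frac = 0.5) {
  g <- length(total)
  pre <- mean(total[max(1, start - window):(start - 1)])
  final <- mean(total[max(1, g - window + 1):g])
  final >= baseline_frac * pre
}

#' Treatment-length collapse threshold
#'
#' Runs the treatment-length sweep classification over a set of sweep
#' points: for each duration, the replicate-mean total series is classed
#' with [recovered()]; the threshold reported is the largest duration below
#' the smallest non-recovering duration (`NA` when every duration recovers
#' or none does).
#'
#' @param sweep a `"neoplasim_sweep"` from
#'   `run_sweep("treatment_length_sweep", ...)`.
#' @return list with `durations`, `recovered` (logical per duration) and
#'   `threshold`.
#' @export
collapse_threshold <- function(sweep) {
  durations <- sweep$values
  rec <- vapply(seq_along(durations), function(i) {
    p <- sweep$points[[i]]
    tr <- p$config$treatment
    recovered(p$summary$total_cells_mean, tr$trigger_value, durations[i])
  }, logical(1))
  first_bad <- which(!rec)[1]
  threshold <- if (is.na(first_bad) || first_bad == 1) NA_real_
               else durations[first_bad - 1]
  list(durations = durations, recovered = rec, threshold = threshold)
}

#' Growth summary of a replicate set
#'
#' Headline growth statistics for a tumour-growth run: the malignant
#' doubling time, the accelerated-repopulation ratio when a treatment block
#' is present, and a sigmoid-shape score for long runs — the R-squared of a
#' logistic fit to the malignant count series (close to 1 when growth
#' saturates sigmoidally, lower for sub-exponential or flat series).
#'
#' @param reps a `"neoplasim_replicates"` (or a single run).
#' @param reference doubling-time reference count.
#' @return list with `doubling_time`, `repopulation_ratio` (or `NA` without
#'   treatment) and `sigmoid_r2` (or `NA` when a logistic fit fails).
#' @export
summarise_growth <- function(reps, reference = 20) {
  if (inherits(reps, "neoplasim_run"))
    reps <- structure(list(runs = list(reps), summary = aggregate_metrics(list(reps)),
                           config = reps$config), class = "neoplasim_replicates")
  mal <- reps$summary$malignant_cells_mean
  tot <- reps$summary$total_cells_mean
  cfg <- reps$config
  rr <- NA_real_
  if (!is.null(cfg$treatment) && cfg$treatment$trigger == "generation" &&
      is.finite(cfg$treatment$duration)) {
    rr <- repopulation_ratio(mal, cfg$treatment$trigger_value,
                             cfg$treatment$duration)
  }
  r2 <- NA_real_
  grew <- any(mal >= 2 * reference)
  if (grew) {
    df <- data.frame(t = seq_along(mal), y = mal)
    fit <- tryCatch(nls(y ~ SSlogis(t, Asym, xmid, scal), data = df),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      res <- df$y - predict(fit)
      r2 <- 1 - sum(res^2) / sum((df$y - mean(df$y))^2)
    }
  }
  list(doubling_time = doubling_time(mal, reference),
       repopulation_ratio = rr, sigmoid_r2 = r2)
}
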