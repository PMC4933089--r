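#' Genotype registry
#'
#' Book-keeping for clonal evolution: every distinct heritable trait vector
#' ever observed gets a stable identifier, and the cumulative count of
#' genotypes — the gene pool — includes extinct clones and never decreases.
#' Genotype identity is exact equality of the full trait tuple, so any
#' effective mutation creates a new genotype while re-registering a known
#' tuple returns its existing id.
#'
#' @return an empty registry (environment of class `"genotype_registry"`).
#' @examples
#' reg <- genotype_registry()
#' t1 <- make_traits(mutation_rate = 0.05, invasion_rate = 0.1)
#' register_genotype(reg, t1)             # id 1
#' register_genotype(reg, t1)             # same id, pool unchanged
#' gene_pool_size(reg)
#' @export
genotype_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$ids <- list()      # key string -> id
  reg$count <- 0L
  class(reg) <- "genotype_registry"
  reg
}

#' @rdname genotype_registry
#' @param registry a registry.
#' @param traits trait vector ([make_traits()]).
#' @return `register_genotype()` returns the genotype id (integer).
#' @export
register_genotype <- function(registry, traits) {
  key <- paste(sprintf("%.17g", as.numeric(traits)), collapse = "|")
  id <- registry$ids[[key]]
  if (is.null(id)) {
    registry$count <- registry$count + 1L
    id <- registry$count
    registry$ids[[key]] <- id
  }
  id
}

#' @rdname genotype_registry
#' @return `gene_pool_size()` returns the cumulative genotype count.
#' @export
gene_pool_size <- function(registry) registry$count

#' @export
print.genotype_registry <- function(x, ...) {
  cat("Genotype registry:", x$count, "genotype(s) ever registered\n")
  invisible(x)
}

#' Dominance of the largest clone
#'
#' Percentage of the living malignant population belonging to its most
#' populous clonal sub-population. Extinct clones contribute to the gene
#' pool but not to dominance.
#'
#' @param clone_sizes living cell counts per clone.
#' @return dominance in (0, 100\], or `NA` for an empty population.
#' @examples
#' dominance_fraction(c(60, 40))  # 60
#' @export
dominance_fraction <- function(clone_sizes) {
  clone_sizes <- clone_sizes[clone_sizes > 0]
  if (length(clone_sizes) == 0) return(NA_real_)
  100 * max(clone_sizes) / sum(clone_sizes)
}

#' Aggregate replicate runs
#'
#' Per-generation mean and standard deviation of every metric column across
#' a list of replicate runs. With a single replicate the SD columns are
#' identically zero.
#'
#' @param runs list of `"neoplasim_run"` objects (or of their `metrics`
#'   data frames) with equal generation counts.
#' @return data.frame with `generation`, then `<metric>_mean` and
#'   `<metric>_sd` for every metric.
#' @export
aggregate_metrics <- function(runs) {
  mats <- lapply(runs, function(r) {
    m <- if (inherits(r, "neoplasim_run")) r$metrics else r
    as.matrix(m[, setdiff(names(m), "generation")])
  })
  stopifnot(length(unique(vapply(mats, nrow, 0L))) == 1)
  arr <- simplify2array(mats)                       # gens x metrics x reps
  mu <- apply(arr, c(1, 2), mean)
  sdv <- if (length(mats) > 1) apply(arr, c(1, 2), sd) else mu * 0
  out <- data.frame(generation = seq_len(nrow(mu)))
  for (j in colnames(mu)) {
    out[[paste0(j, "_mean")]] <- mu[, j]
    out[[paste0(j, "_sd")]] <- sdv[, j]
  }
  out
}
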