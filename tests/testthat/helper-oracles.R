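# Independent brute-force oracles for the model's closed-form functions,
# deliberately written element-by-element and kept apart from the package's
# code paths.

oracle_shares <- function(targets, supply) {
  total <- 0
  for (t in targets) total <- total + t
  out <- numeric(length(targets))
  for (i in seq_along(targets)) out[i] <- supply * targets[i] / total
  out
}

oracle_expression <- function(target, factor) 1 - exp(-(target - factor))

oracle_health <- function(target, tolerance, received) {
  (received < target + tolerance) && (received > target - tolerance)
}

oracle_fitness <- function(targets, received) {
  acc <- 0
  for (g in seq_along(targets))
    acc <- acc + exp(-abs(targets[g] - received[g]) / targets[g])
  acc / length(targets)
}

# a small, fast configuration for engine-level property tests
small_config <- function(...) {
  sim_config(width = 8, height = 8, ...)
}

growth_seed <- function(mutation_rate = 0.05, invasion_rate = 0.1) {
  list(generation = 0, count = 1,
       mutation_rate = mutation_rate, invasion_rate = invasion_rate)
}
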