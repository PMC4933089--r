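test_that("the ageing step follows the clock rules", {
  # healthy genes, adequate nutrient: one decrement
  s <- step_cell(clock = 50, store = 10, nutrient_share = 2, nutrient_rate = 1,
                 n_unhealthy = 0)
  expect_equal(s$clock, 49)
  expect_equal(s$state, "HEALTHY")
  # each unhealthy gene adds a decrement
  s <- step_cell(50, 10, 2, 1, n_unhealthy = 2)
  expect_equal(s$clock, 47)
  # metabolic failure drops the clock to zero and triggers the transition
  s <- step_cell(50, 1, 0, 1, n_unhealthy = 0)
  expect_equal(s$store, 0)
  expect_equal(s$clock, 0)
  expect_equal(s$state, "DIVIDING")
  # under active treatment the transition is to clearance, not division
  s <- step_cell(1, 10, 2, 1, n_unhealthy = 0, treated = TRUE)
  expect_equal(s$state, "TO_BE_CLEARED")
  # clock floors at zero
  s <- step_cell(2, 10, 2, 1, n_unhealthy = 3)
  expect_equal(s$clock, 0)
  expect_error(step_cell(50, 10, 2, 1, state = "APOPTOTIC"), "contract")
})

test_that("element factor pipeline matches the worked equilibria", {
  # empty element: supply passes through
  d <- distribute_gene_factors(matrix(numeric(0), 0, 3), c(25, 25, 25))
  expect_equal(d$available, c(25, 25, 25))
  # five on-target cells: zero net expression, every cell gets its target
  tg <- matrix(5, 5, 3)
  d <- distribute_gene_factors(tg, c(25, 25, 25))
  expect_equal(d$available, c(25, 25, 25))
  expect_true(all(abs(d$shares - 5) < 1e-12))
  # a lone cell experiencing the whole supply down-regulates hard
  d <- distribute_gene_factors(matrix(5, 1, 1), 25)
  expect_equal(d$available, 25 + (1 - exp(20)))
  expect_equal(d$shares[1, 1], d$available)
  # conservation: shares sum to the available total per gene
  set.seed(11)
  tg <- matrix(runif(12, 1, 10), 4, 3)
  d <- distribute_gene_factors(tg, c(25, 30, 5))
  expect_equal(colSums(d$shares), d$available, tolerance = 1e-9)
})

test_that("mutation perturbs exactly one field under its constraints", {
  tr <- make_traits(mutation_rate = 0.05, invasion_rate = 0.1)
  any_changed <- FALSE
  for (seed in 1:300) {
    out <- mutate_traits(tr, delta = 0.2, seed = seed)
    diffs <- sum(as.numeric(out) != as.numeric(tr))
    expect_lte(diffs, 1)  # lifetime can round back to its old value
    any_changed <- any_changed || diffs == 1
    expect_true(out["mutation_rate"] >= 0 && out["mutation_rate"] <= 1)
    expect_true(out["invasion_rate"] >= 0 && out["invasion_rate"] <= 1)
    expect_true(out["lifetime"] >= 1 && out["lifetime"] == round(out["lifetime"]))
    expect_true(all(out[grepl("tolerance", names(out))] >= 0))
  }
  expect_true(any_changed)
  # reproducibility
  expect_identical(mutate_traits(tr, seed = 99), mutate_traits(tr, seed = 99))
  # clamping: a rate close to 1 perturbed upward stays at 1
  hot <- make_traits(mutation_rate = 0.99, invasion_rate = 0.99)
  rates <- t(vapply(1:300, function(s) {
    o <- mutate_traits(hot, delta = 0.2, seed = s)
    c(o["mutation_rate"], o["invasion_rate"])
  }, numeric(2)))
  expect_true(all(rates <= 1))
})

test_that("ranked selection removes the least fit, oldest-first on ties", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(11:20, 1)
    fit <- round(runif(n), 3)  # rounding forces occasional ties
    clock <- sample(0:100, n, replace = TRUE)
    removed <- rank_select(fit, clock, capacity = 10, seed = i)
    expect_length(removed, n - 10)
    # oracle: every removed cell is no fitter than every survivor,
    # and among equal fitness the survivor is no older
    kept <- setdiff(seq_len(n), removed)
    worst_kept <- min(fit[kept])
    expect_true(all(fit[removed] <= worst_kept))
    for (r in removed)
      for (k in kept)
        if (fit[r] == fit[k]) expect_lte(clock[r], clock[k])
  }
  # at capacity: nothing removed
  expect_length(rank_select(runif(10), 1:10, capacity = 10), 0)
  # full tie: exactly one removed
  expect_length(rank_select(rep(0.5, 11), rep(50, 11), capacity = 10), 1)
})

test_that("element states classify composition with normal-favouring ties", {
  expect_equal(element_state(5, 0), "NORMAL")
  expect_equal(element_state(0, 8), "TUMOUR")
  expect_equal(element_state(3, 4), "MAJORITY_MALIGNANT")
  expect_equal(element_state(4, 4), "MAJORITY_NORMAL")
  expect_equal(element_state(4, 3), "MAJORITY_NORMAL")
  expect_equal(element_state(0, 0), "NORMAL")  # vacant tissue
})

test_that("necrosis requires an all-tumour extended neighbourhood", {
  codes <- element_state_codes()
  # all-tumour grid: every element necroses (edge neighbourhoods truncate)
  m <- matrix(codes["TUMOUR"], 7, 7)
  expect_true(all(apply_necrosis(m, 2) == codes["NECROTIC"]))
  # one normal corner keeps its radius-2 surroundings alive
  m[1, 1] <- codes["MAJORITY_NORMAL"]
  out <- apply_necrosis(m, 2)
  expect_equal(out[1, 1], unname(codes["MAJORITY_NORMAL"]))
  expect_equal(out[2, 3], unname(codes["TUMOUR"]))     # within radius 2 of the corner
  expect_equal(out[3, 3], unname(codes["TUMOUR"]))
  expect_equal(out[4, 4], unname(codes["NECROTIC"]))   # fully surrounded
  # reversion: a necrotic element with a non-tumour neighbour becomes tumour
  m2 <- matrix(codes["TUMOUR"], 5, 5)
  m2[3, 3] <- codes["NECROTIC"]
  m2[1, 3] <- codes["NORMAL"]
  expect_equal(apply_necrosis(m2, 2)[3, 3], unname(codes["TUMOUR"]))
})

test_that("homeostasis holds the population at the configured optimum", {
  r <- run_simulation(sim_config(width = 10, height = 10, generations = 300),
                      seed = 2)
  m <- r$metrics
  expect_lt(abs(mean(m$total_cells[101:300]) - 500) / 500, 0.02)
  # turnover: ~1/lifetime of the population divides each generation
  expect_lt(abs(mean(m$dividing_cells[101:300]) - 5) / 5, 0.10)
  expect_equal(mean(m$mean_fitness_normal), 1)
  expect_equal(max(m$gene_pool), 0)  # no malignant lineage, empty pool
})

test_that("capacity is never exceeded and the clock stays in range", {
  cfg <- small_config(malignant_seed = growth_seed(), generations = 300)
  r <- run_simulation(cfg, seed = 4)
  expect_true(all(r$metrics$max_element_cells <= cfg$carrying_capacity))
  # ages derived from clocks stay within [0, lifetime]
  expect_true(all(r$metrics$mean_age >= 0 & r$metrics$mean_age <= cfg$lifetime))
})

test_that("identical configuration and seed reproduce a run bit for bit", {
  cfg <- small_config(malignant_seed = growth_seed(), generations = 150)
  a <- run_simulation(cfg, seed = 12)
  b <- run_simulation(cfg, seed = 12)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$final_state, b$final_state)
  c <- run_simulation(cfg, seed = 13)
  expect_false(identical(a$metrics, c$metrics))
})

test_that("the gene pool is cumulative and zero-mutation keeps it at one", {
  cfg <- small_config(malignant_seed = growth_seed(), generations = 400)
  r <- run_simulation(cfg, seed = 6)
  expect_true(all(diff(r$metrics$gene_pool) >= 0))
  expect_true(all(r$metrics$active_clones <= pmax(r$metrics$gene_pool, 1)))

  cfg0 <- small_config(malignant_seed = growth_seed(mutation_rate = 0),
                       generations = 400)
  r0 <- run_simulation(cfg0, seed = 6)
  expect_true(all(r0$metrics$gene_pool == 1))
  expect_true(all(r0$metrics$dominance[r0$metrics$malignant_cells > 0] == 100))
})

test_that("underfeeding shrinks the population; adequate supply does not", {
  starved <- run_simulation(sim_config(width = 10, height = 10,
                                       nutrient_supply = 3, generations = 400),
                            seed = 8)
  fed <- run_simulation(sim_config(width = 10, height = 10,
                                   nutrient_supply = 5, generations = 400),
                        seed = 8)
  n0 <- 10 * 10 * 5
  expect_lt(mean(starved$metrics$total_cells[301:400]), 0.8 * n0)
  expect_gt(mean(fed$metrics$total_cells[301:400]), 0.97 * n0)
})

test_that("zero invasion confines the malignant clone to its seed element", {
  cfg <- small_config(malignant_seed = growth_seed(mutation_rate = 0,
                                                   invasion_rate = 0),
                      generations = 500)
  r <- run_simulation(cfg, seed = 9)
  m <- r$metrics
  # plateau at one element's carrying capacity
  expect_lte(max(m$malignant_cells), cfg$carrying_capacity)
  expect_equal(max(m$malignant_cells[400:500]), cfg$carrying_capacity)
  # at most one element is ever non-normal
  expect_true(all(m$elems_tumour + m$elems_majority_malignant +
                    m$elems_majority_normal + m$elems_necrotic <= 1))
})
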