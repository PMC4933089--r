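test_that("the preset catalogue encodes the published parameterisations", {
  cat <- preset_catalogue()
  expect_setequal(names(cat), c(
    "homeostasis", "nutrient_sweep", "gene_factor_sweep", "untreated_growth",
    "extended_growth", "mutation_sweep", "invasion_sweep", "toxicity_sweep",
    "differential_toxicity", "treatment_length_sweep", "magic_bullet",
    "zero_mutation", "optimum_count_sweep", "scaled_run"))

  h <- cat$homeostasis
  expect_equal(c(h$width, h$height, h$optimum_count, h$carrying_capacity),
               c(25, 25, 5, 10))
  expect_equal(h$gene_targets, c(5, 5, 5))
  expect_equal(h$factor_supply, c(25, 25, 25))
  expect_equal(c(h$lifetime, h$generations), c(100, 1000))

  u <- cat$untreated_growth
  expect_equal(u$malignant_seed$count, 1)
  expect_null(u$malignant_seed$row)  # centre element by default
  expect_equal(u$malignant_seed$mutation_rate, 0.05)
  expect_equal(u$malignant_seed$invasion_rate, 0.1)
  expect_equal(u$generations, 2000)

  tox <- cat$toxicity_sweep
  expect_equal(tox$treatment$trigger_value, 1500)
  expect_equal(tox$treatment$duration, 25)
  expect_true(window_active(tox$treatment, 1500) &&
                !window_active(tox$treatment, 1525))

  z <- cat$zero_mutation
  expect_equal(z$malignant_seed$mutation_rate, 0)
  expect_equal(attr(z, "sweep")$values, seq(0, 0.08, by = 0.02))

  expect_equal(attr(cat$mutation_sweep, "sweep")$values,
               seq(0.025, 0.30, by = 0.025))
  expect_equal(attr(cat$invasion_sweep, "sweep")$values,
               seq(0.02, 0.20, by = 0.02))
  expect_equal(attr(cat$treatment_length_sweep, "sweep")$values,
               seq(15, 60, by = 5))
  expect_true(is.na(cat$magic_bullet$treatment$cutoff_normal))

  x <- cat$extended_growth
  expect_equal(c(x$width, x$height, x$generations), c(45, 45, 6000))
  sc <- cat$scaled_run
  expect_equal(c(sc$width, sc$height, sc$generations), c(100, 100, 20000))
})

test_that("the seeded malignant cell lands in the central element", {
  cfg <- preset("untreated_growth", generations = 1)
  cfg$snapshot_at <- 1L
  r <- run_simulation(cfg, seed = 1)
  snap <- r$snapshots[["1"]]
  nn <- which(snap != element_state_codes()["NORMAL"], arr.ind = TRUE)
  expect_equal(nrow(nn), 1L)
  expect_equal(unname(nn[1, ]), c(13, 13))  # 0-based (12, 12) centre of 25x25
  expect_equal(r$metrics$malignant_cells[1], 1)
})

test_that("doubling time follows its closed-form on constructed series", {
  # exact exponential with rate log(2)/500 doubles in 500 generations
  g <- 0:1999
  series <- 20 * 2^(g / 500)
  expect_equal(doubling_time(series, reference = 20), 500)
  # flat series: no doubling
  expect_true(is.na(doubling_time(rep(10, 1000))))
  expect_true(is.na(doubling_time(rep(30, 1000), reference = 20)))
})

test_that("repopulation ratio compares post- to pre-treatment trends", {
  # piecewise-linear: slope 1 before treatment, slope 3 after
  mal <- c(seq(0, 999), rep(1000, 25), seq(1003, by = 3, length.out = 500))
  rr <- repopulation_ratio(mal, start = 1001, duration = 25)
  expect_equal(rr, 3, tolerance = 0.05)
  # symmetric slopes give ratio 1
  mal2 <- c(seq(0, 999), rep(1000, 25), seq(1001, by = 1, length.out = 500))
  expect_equal(repopulation_ratio(mal2, 1001, 25), 1, tolerance = 0.05)
})

test_that("recovery classification compares the end of run to baseline", {
  pre <- rep(1000, 1000)
  expect_true(recovered(c(pre, rep(200, 25), seq(200, 900, length.out = 475)),
                        start = 1001, duration = 25))
  expect_false(recovered(c(pre, rep(200, 25), seq(200, 350, length.out = 475)),
                         start = 1001, duration = 25))
})

test_that("growth summaries detect sigmoidal saturation", {
  set.seed(31)
  g <- 1:2000
  logistic <- 3000 / (1 + exp(-(g - 1000) / 150)) + rnorm(2000, sd = 10)
  fake_run <- list(summary = data.frame(malignant_cells_mean = logistic,
                                        total_cells_mean = logistic + 100),
                   config = sim_config(generations = 2000))
  class(fake_run) <- "neoplasim_replicates"
  s <- summarise_growth(fake_run)
  expect_gt(s$sigmoid_r2, 0.99)
  expect_true(is.finite(s$doubling_time))
  flat <- fake_run
  flat$summary$malignant_cells_mean <- rep(5, 2000)
  expect_true(is.na(summarise_growth(flat)$doubling_time))
})

test_that("sweeps run each axis point with shared replicate seeds", {
  sw <- run_sweep("invasion_sweep", values = c(0.02, 0.2), n_replicates = 2,
                  base_seed = 3, generations = 120)
  expect_equal(sw$axis, "invasion_rate")
  expect_equal(nrow(sw$endpoints), 2)
  expect_equal(sw$points[[1]]$config$malignant_seed$invasion_rate, 0.02)
  expect_equal(sw$points[[2]]$config$malignant_seed$invasion_rate, 0.2)
  expect_equal(sw$points[[1]]$n_replicates, 2)
})
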