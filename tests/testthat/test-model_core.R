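test_that("resource shares reproduce the worked examples", {
  expect_equal(nutrient_shares(rep(10, 5), 10), rep(2, 5))
  expect_equal(nutrient_shares(7, 10), 10)
  expect_equal(nutrient_shares(c(10, 30), 10), c(2.5, 7.5))

  expect_equal(gene_factor_shares(rep(5, 5), 25), rep(5, 5))
  expect_equal(gene_factor_shares(5, 25), 25)
  expect_equal(gene_factor_shares(c(5, 10, 5), 20), c(5, 10, 5))
})

test_that("degenerate demand and empty populations are rejected", {
  expect_error(nutrient_shares(numeric(0), 10), "no population")
  expect_error(nutrient_shares(c(0, 0), 10), "degenerate")
  expect_error(gene_factor_shares(numeric(0), 10), "no population")
  expect_error(gene_factor_shares(c(0, 0), 5), "degenerate")
})

test_that("gene health band is strict and symmetric", {
  expect_true(gene_health(5, 1, 5.0))
  expect_false(gene_health(5, 1, 6.0))   # upper boundary excluded
  expect_false(gene_health(5, 1, 4.0))   # lower boundary excluded
  expect_true(gene_health(5, 1, 4.5))
  # symmetry: equidistant points agree
  for (d in c(0.1, 0.5, 0.99, 1.0, 1.5)) {
    expect_equal(as.logical(gene_health(5, 1, 5 + d)),
                 as.logical(gene_health(5, 1, 5 - d)))
  }
  # zero tolerance: nothing is healthy, not even the target itself
  expect_false(gene_health(5, 0, 5))
})

test_that("expression feedback has the documented sign and fixed values", {
  expect_equal(gene_expression(5, 5), 0)
  expect_equal(gene_expression(5, 4), 1 - exp(-1))
  expect_equal(gene_expression(5, 6), 1 - exp(1))
  # sign follows target - factor, magnitude monotone on each side
  below <- gene_expression(rep(5, 4), c(4.5, 4, 3, 1))
  above <- gene_expression(rep(5, 4), c(5.5, 6, 7, 9))
  expect_true(all(below > 0) && all(diff(below) > 0))
  expect_true(all(above < 0) && all(diff(above) < 0))
})

test_that("fitness is bounded, maximal at the target, and decays per gene", {
  expect_equal(cell_fitness(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_equal(cell_fitness(5, 10), exp(-1))
  expect_equal(cell_fitness(c(5, 5, 5), c(5, 5, 10)), (2 + exp(-1)) / 3)
  expect_error(cell_fitness(c(5, 5), 5), "dimension")

  set.seed(42)
  for (i in 1:200) {
    targets <- runif(3, 1, 10)
    received <- targets + rnorm(3, sd = 5)
    f <- cell_fitness(targets, received)
    expect_gt(f, 0)
    expect_lte(f, 1)
    # strictly decreasing in |T - A| holding other genes fixed
    worse <- received
    worse[1] <- targets[1] + (received[1] - targets[1]) * 2 + sign(received[1] - targets[1] + 0.1) * 0.5
    expect_lt(cell_fitness(targets, worse), f + 1e-12)
  }
})

test_that("closed-form operations match independent oracles on random inputs", {
  set.seed(7)
  n_cases <- 10000
  share_err <- share_cons <- factor_cons <- fit_err <- expr_err <- numeric(n_cases)
  health_ok <- logical(n_cases)
  for (i in seq_len(n_cases)) {
    k <- sample(1:8, 1)
    targets <- runif(k, 0.1, 50)
    supply <- runif(1, 0, 100)
    got <- nutrient_shares(targets, supply)
    share_err[i] <- max(abs(got - oracle_shares(targets, supply)))
    share_cons[i] <- abs(sum(got) - supply) / max(1, supply)

    avail <- runif(1, -50, 100)
    factor_cons[i] <- abs(sum(gene_factor_shares(targets, avail)) - avail) /
      max(1, abs(avail))

    tg <- runif(1, 0.5, 20); tol <- runif(1, 0, 5); recv <- runif(1, -5, 30)
    health_ok[i] <- identical(as.logical(gene_health(tg, tol, recv)),
                              oracle_health(tg, tol, recv))
    expr_err[i] <- abs(gene_expression(tg, recv) - oracle_expression(tg, recv))

    recvv <- runif(k, -5, 60)
    fit_err[i] <- abs(cell_fitness(targets, recvv) - oracle_fitness(targets, recvv))
  }
  expect_lt(max(share_err), 1e-12)
  expect_lt(max(share_cons), 1e-9)   # conservation, relative
  expect_lt(max(factor_cons), 1e-9)
  expect_true(all(health_ok))
  expect_lt(max(expr_err), 1e-12)
  expect_lt(max(fit_err), 1e-12)
})

test_that("trait constructor enforces the type invariants", {
  tr <- make_traits()
  expect_equal(n_genes(tr), 3L)
  expect_equal(unname(tr["lifetime"]), 100)
  expect_error(make_traits(gene_targets = c(0, 5, 5)), "gene_targets > 0")
  expect_error(make_traits(mutation_rate = 1.5))
  expect_error(make_traits(lifetime = 0))
  expect_error(make_traits(gene_tolerances = c(1, 1)))  # length mismatch
})
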