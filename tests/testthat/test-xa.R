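# X-autosome layer: reparameterization, likelihood invariance, tests.

test_that("xa_to_general applies f_A = 1/r2 and g_A1 = gX1 r2 / r1", {
  p <- xa_params(5.25e-4, 7.5e-4, r1 = 0.65, r2 = 0.75, gX1 = 10, tau1 = 0.1)
  model <- xa_to_general(p, m = c(5e6, 5e6))
  expect_equal(model$loci[[2]]$f, 1 / 0.75, tolerance = 1e-12)   # 1.3333
  expect_equal(model$loci[[2]]$g, 10 * 0.75 / 0.65,
               tolerance = 1e-12)                                # 11.5385
  expect_equal(model$loci[[1]]$g, 10)
  # r1 = r2: both compartments share the size change
  q <- xa_params(1e-3, 1e-3, r1 = 0.8, r2 = 0.8, gX1 = 7, tau1 = 0.2)
  expect_equal(xa_to_general(q)$loci[[2]]$g, 7)
})

test_that("general_to_xa inverts xa_to_general exactly", {
  p <- xa_params(5.25e-4, 7.5e-4, r1 = 0.9, r2 = 0.75, gX1 = 0.2,
                 tau1 = 0.05, epsX = 0.03, epsA = 0.01)
  back <- general_to_xa(xa_to_general(p))
  expect_equal(unclass(back), unclass(p), tolerance = 1e-12)
  expect_error(xa_params(1e-3, 1e-3, r1 = -0.5, r2 = 0.75, gX1 = 1,
                         tau1 = 0.1), "positive|> 0")
})

test_that("reparameterization preserves the likelihood identically", {
  p <- xa_params(5.25e-4, 7.5e-4, r1 = 0.65, r2 = 0.75, gX1 = 10, tau1 = 0.1)
  model <- xa_to_general(p, m = c(1e5, 1e5))
  data <- simulate_dataset(model, 25, seed = 16)
  model2 <- xa_to_general(general_to_xa(model), m = c(1e5, 1e5))
  expect_equal(loglik_full(data, model), loglik_full(data, model2),
               tolerance = 1e-12)
})

test_that("at r1 = r2 = 0.75 with equal theta the diversity ratio is 0.75", {
  # g = 1 in both compartments: equilibrium at relative sizes 1 and 1/r2
  p <- xa_params(1e-3, 1e-3, r1 = 0.75, r2 = 0.75, gX1 = 1, tau1 = 0.5)
  model <- xa_to_general(p, m = c(1e5, 1e5))
  psi <- model_expected_sfs(model, 20)
  expect_equal(sum(psi[1, ]) / sum(psi[2, ]), 0.75, tolerance = 1e-10)
})

test_that("the three named tests carry their degrees of freedom", {
  model <- xa_expansion(m = 2e5)
  data <- simulate_dataset(model, 40, seed = 17)
  res <- xa_tests(data, n_starts = 4, seed = 6)
  expect_named(res, c("mutation_rate", "ne_ratio_075", "ratio_change"))
  expect_equal(vapply(res, `[[`, numeric(1), "df"),
               c(mutation_rate = 1, ne_ratio_075 = 2, ratio_change = 1))
  # full fit shared across the three tests
  expect_identical(res$mutation_rate$full$loglik, res$ratio_change$full$loglik)
  # nulls are nested: statistic non-negative
  expect_true(all(vapply(res, `[[`, numeric(1), "statistic") >= 0))
})
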