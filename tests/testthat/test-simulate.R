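# Simulator: determinism, distributional means, designs, harness.

test_that("simulation is deterministic given the seed", {
  model <- xa_expansion(m = 1e5)
  d1 <- simulate_dataset(model, 30, seed = 5)
  d2 <- simulate_dataset(model, 30, seed = 5)
  d3 <- simulate_dataset(model, 30, seed = 6)
  expect_identical(d1$counts, d2$counts)
  expect_false(identical(d1$counts, d3$counts))
})

test_that("theta = 0 gives all-zero counts; Poisson means match psi and lambda", {
  none <- model_spec(epoch_model(), list(locus_model(0, m = 1000)))
  expect_true(all(simulate_usfs(none, 10, seed = 1)$counts == 0))
  model <- model_spec(epoch_model(0.2),
                      list(locus_model(0.02, 1, 4, 1000)),
                      divergence = list(c = 2, t = 3))
  lam <- expected_divergence(model$loci[[1]], 2, 3)
  x <- vapply(1:4000, function(r) simulate_divergence(model, seed = r)[1],
              numeric(1))
  expect_lt(abs(mean(x) - lam) / lam, 3.5 * sqrt(1 / (lam * 4000)))
  expect_identical(simulate_divergence(
    model_spec(epoch_model(), list(locus_model(0, m = 10)),
               divergence = list(c = 1, t = 1)), seed = 1), 0L)
})

test_that("linear grid designs interpolate the stated endpoints", {
  des <- linear_grid_design(20, theta1 = 0.01, theta_ratio = 5,
                            f1 = 1, f_ratio = 5, m = 5000, g = 10)
  th <- vapply(des, `[[`, numeric(1), "theta")
  f <- vapply(des, `[[`, numeric(1), "f")
  expect_equal(th[1], 0.01)
  expect_equal(th[20], 0.002)        # theta1 / 5
  expect_equal(f[20] / f[1], 5)
  expect_true(all(diff(th) < 0) && all(diff(f) > 0))   # monotone
  des2 <- linear_grid_design(2, theta1 = 0.01, m = 100)
  expect_equal(vapply(des2, `[[`, numeric(1), "theta"), c(0.01, 0.002))
  expect_error(linear_grid_design(1, theta1 = 0.01, m = 10), "K must")
})

test_that("gamma designs have the stated moments and independent draws", {
  des <- gamma_design(4000, m = 100, seed = 8)
  th <- vapply(des, `[[`, numeric(1), "theta")
  f <- vapply(des, `[[`, numeric(1), "f")[-1]
  expect_equal(mean(th), 3 * 0.005, tolerance = 0.05)
  expect_equal(mean(f), 1, tolerance = 0.05)
  expect_equal(des[[1]]$f, 1)        # reference locus
  expect_lt(abs(cor(th[-1], f)), 0.05)
  expect_error(gamma_design(10, a_theta = -1, m = 10), "must be > 0")
})

test_that("the replicate harness summarises estimates and is worker-invariant", {
  model <- model_spec(epoch_model(0.3),
                      lapply(1:3, function(k) locus_model(5e-3, 1, 5, 3000)),
                      shared_g = TRUE)
  r1 <- run_replicates(model, 12, R = 3, seed = 7,
                       fit_args = list(n_starts = 2))
  r2 <- run_replicates(model, 12, R = 3, seed = 7, workers = 2,
                       fit_args = list(n_starts = 2))
  expect_equal(r1$estimates, r2$estimates, tolerance = 1e-10)
  sm <- summary(r1)
  expect_equal(sm$R_used, 3L)
  expect_true(all(c("g.1", "tau.1", "slope.theta") %in% names(sm$mean)))
  # R = 1: SD undefined, reported as absent
  sm1 <- summary(run_replicates(model, 12, R = 1, seed = 7,
                                fit_args = list(n_starts = 2)))
  expect_true(all(is.na(sm1$sd)))
})

test_that("average score at the truth is near zero over replicates", {
  model <- model_spec(epoch_model(0.25), list(locus_model(5e-3, 1, 4, 4000)))
  B <- branch_weights(10)
  g <- rowMeans(vapply(1:300, function(r) {
    d <- simulate_dataset(model, 10, seed = r)
    loglik_gradient(d, model)
  }, numeric(3)))
  # scale: score SD per replicate is O(sqrt(S)); the mean over R replicates
  # should be within a few SD/sqrt(R)
  S <- sum(model_expected_sfs(model, 10))
  expect_lt(max(abs(g)), 4 * sqrt(S) / sqrt(300) * 2)
})
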