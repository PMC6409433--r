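# Expected spectra: equilibrium closed form, limits, continuity, folding,
# polarization error, divergence.

test_that("equilibrium spectrum is m theta f / i", {
  B <- branch_weights(4)
  psi <- expected_sfs(locus_model(0.001, m = 1000), epoch_model(), B)
  expect_equal(psi, c(1, 0.5, 1 / 3), tolerance = 1e-12)
  B2 <- branch_weights(30)
  psi2 <- expected_sfs(locus_model(0.004, f = 1, m = 500), epoch_model(), B2)
  expect_equal(psi2, 2 / seq_len(29), tolerance = 1e-12)
})

test_that("A vanishes when all g = 1 and for very old changes", {
  B <- branch_weights(20)
  eq_g <- locus_model(1e-3, f = 2, g = 1, m = 100)
  expect_equal(epoch_decay_A(1:19, eq_g, epoch_model(0.3), B), rep(0, 19))
  old <- locus_model(1e-3, f = 2, g = 10, m = 100)
  expect_equal(epoch_decay_A(1:19, old, epoch_model(1e6), B), rep(0, 19),
               tolerance = 1e-12)
  # tau -> infinity: equilibrium at the current size f * g1
  psi_old <- expected_sfs(old, epoch_model(1e6), B)
  expect_equal(psi_old, 0.1 * 2 * 10 / seq_len(19), tolerance = 1e-10)
})

test_that("phi is continuous at tau = 0 (reduces to H = 1 with f)", {
  B <- branch_weights(50)
  i <- seq_len(49)
  lo <- locus_model(1e-3, f = 1.7, g = 6, m = 100)
  # analytic limit: A_i -> (1 - g1) / i via sum_j B_i(j) = 1/i
  expect_equal(epoch_decay_A(i, lo, epoch_model(1e-9), B), (1 - 6) / i,
               tolerance = 1e-6)
  expect_equal(phi(lo, epoch_model(1e-9), B), 1.7 / i, tolerance = 1e-6)
})

test_that("Poisson simulation means converge to the expected spectrum", {
  model <- model_spec(epoch_model(0.2),
                      list(locus_model(0.01, f = 1, g = 5, m = 2000)))
  psi <- model_expected_sfs(model, 8)
  R <- 10000
  acc <- matrix(0, R, 7)
  for (r in seq_len(R))
    acc[r, ] <- simulate_usfs(model, 8, seed = r)$counts[1, ]
  se <- sqrt(psi / R)
  expect_true(all(abs(colMeans(acc) - psi) < 3.5 * se))
})

test_that("folding halves the spectrum and conserves the total", {
  expect_equal(fold_expected(c(1, 0.5, 1 / 3), 4), c(1 + 1 / 3, 0.5))
  abcd <- c(4, 3, 2, 1)
  expect_equal(fold_expected(abcd, 5), c(5, 5))
  set.seed(1)
  psi <- rexp(99)
  expect_equal(sum(fold_expected(psi, 100)), sum(psi))
  expect_error(fold_expected(psi, 99), "length")
})

test_that("polarization error mixes mirror classes and conserves the total", {
  expect_equal(apply_polarization_error(c(10, 2), 0), c(10, 2))
  expect_equal(apply_polarization_error(c(10, 2), 0.06), c(9.52, 2.48))
  set.seed(2)
  psi <- rexp(19)
  star <- apply_polarization_error(psi, 0.31)
  expect_equal(sum(star), sum(psi))
  sym <- apply_polarization_error(psi, 0.5)
  expect_equal(sym, rev(sym))
  expect_error(apply_polarization_error(psi, 0.6), "0.5")
  expect_error(apply_polarization_error(psi, -0.1), "0.5")
})

test_that("expected divergence follows lambda = m theta (c f + t)", {
  lo <- locus_model(0.01, f = 1, m = 1000)
  expect_equal(expected_divergence(lo, c = 2, t = 8), 100)  # 0.1 per site
  expect_equal(expected_divergence(lo, c = 1, t = 0), 10)   # = m theta
  lo2 <- locus_model(0.01, f = 1, m = 2000)
  expect_equal(expected_divergence(lo2, c = 2, t = 8), 200) # linear in m
  expect_error(expected_divergence(lo, c = 0, t = 1), "c > 0")
})

test_that("phi rejects invalid parameter regions", {
  B <- branch_weights(10)
  expect_error(locus_model(-1e-3, m = 100), "theta")
  expect_error(locus_model(1e-3, f = 0, m = 100), "f must")
  expect_error(locus_model(1e-3, g = -2, m = 100), "g must")
})
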