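# Fitting: closed forms, nesting, determinism, constraints, pooled fits.

test_that("constant-size fit recovers the Watterson-type closed form", {
  eq <- tiny_eq_model(0.01, 2000)
  data <- simulate_dataset(eq, 20, seed = 4)
  fr <- fit(data, eq, n_starts = 2, seed = 1)
  S <- sum(data$counts)
  hn <- sum(1 / (1:19))
  expect_equal(unname(coef(fr)["theta.1"]), S / (2000 * hn), tolerance = 1e-8)
  # profile route with H = 1 has no free shape parameters
  expect_true(fr$converged)
})

test_that("H = 1 with free f is rejected as unidentifiable", {
  bad <- model_spec(epoch_model(),
                    list(locus_model(1e-3, m = 100),
                         locus_model(1e-3, f = 2, m = 100)))
  data <- sfs_dataset(matrix(1, 2, 3), m = c(100, 100), n = 4)
  expect_error(fit(data, bad), "identifiable")
})

test_that("fits are deterministic given the seed and reproduce their loglik", {
  model <- xa_expansion(m = 1e5)
  data <- simulate_dataset(model, 30, seed = 10)
  f1 <- fit(data, sfsdem:::.xa_template(data), n_starts = 4, seed = 9)
  f2 <- fit(data, sfsdem:::.xa_template(data), n_starts = 4, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loglik, f2$loglik)
  # reported MLE reproduces the reported loglik on re-evaluation
  expect_equal(loglik_full(data, f1$model), f1$loglik, tolerance = 1e-8)
})

test_that("empty constraints reproduce fit(); pinning to truth never beats the MLE", {
  model <- xa_expansion(m = 1e5)
  data <- simulate_dataset(model, 30, seed = 11)
  free <- fit(data, sfsdem:::.xa_template(data), n_starts = 4, seed = 2)
  same <- fit_constrained(data, sfsdem:::.xa_template(data), constraint_set(),
                          n_starts = 4, seed = 2)
  expect_identical(coef(free), coef(same))
  pinned <- fit(data, model,
                constraints = constraint_set(
                  pins = c("f[2]" = 1 / 0.75,
                           "g[1,1]" = 10, "g[2,1]" = 10 * 0.75 / 0.65,
                           "tau[1]" = 0.1)),
                n_starts = 2, seed = 2)
  expect_lte(pinned$loglik, free$loglik + 1e-6)
})

test_that("likelihood ratio machinery floors at zero and uses chi-square tails", {
  model <- xa_expansion(m = 1e5)
  data <- simulate_dataset(model, 30, seed = 12)
  fr <- fit(data, sfsdem:::.xa_template(data), n_starts = 4, seed = 3)
  self <- lrt(fr, fr, df = 1)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_asymptotic, 1)
  tst <- test_ratio_change(data, n_starts = 4, seed = 3)
  expect_gte(tst$statistic, 0)
  expect_equal(tst$df, 1L)
  expect_equal(tst$p_asymptotic,
               pchisq(tst$statistic, 1, lower.tail = FALSE))
})

test_that("pooling one locus is the identity and pooled fits run", {
  model <- model_spec(epoch_model(0.4), list(locus_model(2e-3, 1, 6, 20000)))
  data <- simulate_dataset(model, 40, seed = 13)
  direct <- fit(data, model, n_starts = 4, seed = 5)
  pooled <- fit_pooled(data, n_starts = 4, seed = 5)
  expect_equal(unname(coef(pooled)[c("g.1.1", "tau.1")]),
               unname(coef(direct)[c("g.1.1", "tau.1")]), tolerance = 1e-4)
  expect_error(fit_pooled(fold_dataset(data)), "unfolded")
})

test_that("parametric bootstrap p-values behave at the edges", {
  model <- model_spec(epoch_model(0.4),
                      list(locus_model(2e-3, 1, 6, 5000),
                           locus_model(2e-3, 1.5, 6, 5000)))
  data <- simulate_dataset(model, 15, seed = 14)
  expect_error(bootstrap_pvalue(data, model, constraint_set(), B = 0),
               "B must")
  res <- bootstrap_pvalue(
    data, model, constraint_set(ties = list(c("theta[1]", "theta[2]"))),
    B = 5, seed = 3, n_starts = 2)
  expect_true(res$p_bootstrap > 0 && res$p_bootstrap <= 1)
  expect_lte(res$B, 5L)
})

test_that("bootstrap CIs are percentile intervals within strata", {
  model <- model_spec(epoch_model(0.4),
                      lapply(1:6, function(k)
                        locus_model(2e-3, f = 1, g = 6, m = 4000)),
                      shared_g = TRUE)
  data <- simulate_dataset(model, 15, seed = 15)
  bc <- bootstrap_ci(data, model, B = 8, seed = 4, n_starts = 2,
                     strata = rep(c("a", "b"), each = 3))
  expect_equal(colnames(bc$ci), c("lower", "upper"))
  g1 <- bc$estimates[, "g.1"]
  expect_equal(unname(bc$ci["g.1", ]),
               unname(quantile(g1, c(0.025, 0.975), names = FALSE)))
  expect_true(all(bc$ci[, "lower"] <= bc$ci[, "upper"]))
})
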