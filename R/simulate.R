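# Synthetic data under the Poisson random field model, locus-parameter
# designs, and the replicate harness.
#
# Counts are sampled as independent Poissons per frequency class with means
# given by the (error-perturbed) expected spectrum — exactly the model the
# likelihood assumes (free recombination).  Polarization error is injected
# at the expected-SFS level, which under the PRF is equivalent to flipping
# each site independently with probability epsilon.

#' Simulate unfolded SFS counts
#'
#' Draws `d_{k,i} ~ Poisson(psi*_{k,i})` independently per locus and class.
#'
#' @param model A [model_spec()] (per-locus `epsilon` > 0 injects
#'   polarization error).
#' @param n Sample size (alleles).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return An unfolded [sfs_dataset()].
#' @export
simulate_usfs <- function(model, n, seed = 1L) {
  psi <- model_expected_sfs(model, n, apply_error = TRUE)
  set.seed(seed)
  counts <- matrix(stats::rpois(length(psi), t(psi)), nrow = nrow(psi),
                   byrow = TRUE)
  sfs_dataset(counts, vapply(model$loci, `[[`, numeric(1), "m"), n)
}

#' Simulate substitution counts to the outgroup
#'
#' `x_k ~ Poisson(lambda_k)` with `lambda_k = m_k theta_k (c f_k + t)`.
#'
#' @param model A [model_spec()] with a divergence block.
#' @param seed Integer seed.
#' @return Integer vector of substitution counts, one per locus.
#' @export
simulate_divergence <- function(model, seed = 1L) {
  if (is.null(model$divergence))
    stop("model has no divergence parameters (c, t)")
  lam <- vapply(model$loci, expected_divergence, numeric(1),
                c = model$divergence$c, t = model$divergence$t)
  set.seed(seed)
  stats::rpois(length(lam), lam)
}

#' Simulate a complete dataset (SFS plus optional divergence)
#'
#' @inheritParams simulate_usfs
#' @param divergence Attach Poisson substitution counts (default: yes if the
#'   model has a divergence block).
#' @param folded Return the folded spectra.
#' @return An [sfs_dataset()].
#' @export
simulate_dataset <- function(model, n, seed = 1L,
                             divergence = !is.null(model$divergence),
                             folded = FALSE) {
  data <- simulate_usfs(model, n, seed = .derive_seed(seed, 1L))
  if (divergence)
    data$x <- as.numeric(simulate_divergence(model,
                                             seed = .derive_seed(seed, 2L)))
  if (folded) data <- fold_dataset(data)
  data
}

#' Linear grid of locus parameters
#'
#' Mutation rates decline linearly from `theta1` to `theta1 / theta_ratio`
#' across the `K` loci while the local-size scalars rise from `f1` to
#' `f1 * f_ratio` — the heterogeneous-locus design of the simulation
#' studies.
#'
#' @param K Number of loci (`>= 2`).
#' @param theta1 Mutation rate of locus 1.
#' @param theta_ratio `theta1 / thetaK` (default 5).
#' @param f1 Local-size scalar of locus 1 (reference; default 1).
#' @param f_ratio `fK / f1` (default 5).
#' @param m Locus length in bp (recycled; default 5000).
#' @param g Epoch size multipliers shared by all loci (length `H - 1`).
#' @param epsilon Polarization error (recycled; default 0).
#' @return A list of [locus_model()] objects.
#' @export
linear_grid_design <- function(K, theta1, theta_ratio = 5, f1 = 1,
                               f_ratio = 5, m = 5000, g = numeric(0),
                               epsilon = 0) {
  if (K < 2L) stop("K must be >= 2")
  theta <- seq(theta1, theta1 / theta_ratio, length.out = K)
  f <- seq(f1, f1 * f_ratio, length.out = K)
  m <- rep_len(m, K)
  epsilon <- rep_len(epsilon, K)
  lapply(seq_len(K), function(k)
    locus_model(theta[k], f = f[k], g = g, m = m[k], epsilon = epsilon[k]))
}

#' Gamma-distributed locus parameters
#'
#' Draws `theta_k ~ Gamma(a_theta, scale = b_theta)` for every locus and
#' `f_k ~ Gamma(a_f, scale = b_f)` for every locus except the reference
#' (locus 1, `f = 1`), independently.  Defaults give mean `theta = 0.015`
#' and mean `f = 1`.
#'
#' @param K Number of loci.
#' @param a_theta,b_theta Shape and scale of the mutation-rate gamma
#'   (defaults 3 and 0.005).
#' @param a_f,b_f Shape and scale of the local-size gamma (defaults 5 and
#'   0.2).
#' @param m Locus length in bp (recycled; default 10000).
#' @param g Epoch size multipliers shared by all loci.
#' @param seed Integer seed.
#' @return A list of [locus_model()] objects.
#' @export
gamma_design <- function(K, a_theta = 3, b_theta = 0.005, a_f = 5, b_f = 0.2,
                         m = 10000, g = numeric(0), seed = 1L) {
  if (K < 1L) stop("K must be >= 1")
  if (a_theta <= 0 || b_theta <= 0 || a_f <= 0 || b_f <= 0)
    stop("gamma shapes and scales must be > 0")
  set.seed(seed)
  theta <- stats::rgamma(K, shape = a_theta, scale = b_theta)
  f <- c(1, stats::rgamma(K - 1L, shape = a_f, scale = b_f))
  m <- rep_len(m, K)
  lapply(seq_len(K), function(k)
    locus_model(theta[k], f = f[k], g = g, m = m[k]))
}

#' Replicate simulation-and-refit experiment
#'
#' Simulates `R` datasets under a known truth, refits each (optionally with
#' the X-autosome likelihood ratio tests and/or the naive pooled fit), and
#' collects per-replicate estimates.  Replicate seeds are derived from the
#' master seed by index, so the map is order-independent and worker-count
#' invariant.
#'
#' @param model The true [model_spec()] generating the data.
#' @param n Sample size (alleles).
#' @param R Number of replicates.
#' @param seed Master seed.
#' @param tests Character vector of [xa_tests()] names to run per replicate
#'   (two-locus models only).
#' @param pooled Also run the naive pooled single-SFS fit per replicate.
#' @param workers Parallel workers ([parallel::mclapply()]); results are
#'   identical for any worker count.
#' @param fit_args List of arguments passed to [fit()] (e.g. `n_starts`).
#' @param alpha Significance level used by [summary.sfs_replicates()]
#'   (default 0.05).
#' @return An object of class `"sfs_replicates"`: matrix of per-replicate
#'   estimates (`$estimates`, including XA-parameter columns for two-locus
#'   models, `pooled.*` columns if requested, and `stat_*`/`p_*` columns per
#'   test), the truth (`$truth`), failure count, and regression slopes of
#'   per-locus estimates on their true values (`$slopes`, for `K >= 3`).
#' @export
run_replicates <- function(model, n, R, seed = 1L, tests = character(0),
                           pooled = FALSE, workers = 1L, fit_args = list(),
                           alpha = 0.05) {
  if (R < 1L) stop("R must be >= 1")
  K <- length(model$loci)
  truth <- coef(structure(list(model = model), class = "sfs_fit"))
  theta_true <- vapply(model$loci, `[[`, numeric(1), "theta")
  f_true <- vapply(model$loci, `[[`, numeric(1), "f")
  is_xa <- K == 2L && model$epochs$H == 2L && !model$shared_g
  one <- function(r) {
    data <- simulate_dataset(model, n, seed = .derive_seed(seed, r))
    fa <- c(list(data = data, model = model,
                 seed = .derive_seed(seed, r + 10000L)), fit_args)
    est <- tryCatch({
      if (length(tests)) {
        lrts <- do.call(xa_tests, c(list(data = data, tests = tests),
                                    fit_args,
                                    list(seed = .derive_seed(seed, r + 10000L))))
        fr <- attr(lrts, "full")
      } else {
        lrts <- NULL
        fr <- do.call(fit, fa)
      }
      if (is.na(fr$loglik)) return(NULL)
      out <- coef(fr)
      if (is_xa)
        out <- c(out, unlist(general_to_xa(fr$model)[
          c("thetaX", "thetaA", "r1", "r2", "gX1", "tau1")]))
      if (K >= 3L) {
        th_hat <- out[sprintf("theta.%d", seq_len(K))]
        f_hat <- out[sprintf("f.%d", seq_len(K))]
        out <- c(out,
                 slope.theta = unname(stats::coef(
                   stats::lm(th_hat ~ theta_true))[2L]),
                 slope.f = unname(stats::coef(
                   stats::lm(f_hat[-model$ref] ~ f_true[-model$ref]))[2L]),
                 cor.theta.f = stats::cor(th_hat[-model$ref],
                                          f_hat[-model$ref],
                                          method = "kendall"))
      }
      for (tn in names(lrts))
        out <- c(out,
                 stats::setNames(c(lrts[[tn]]$statistic,
                                   lrts[[tn]]$p_asymptotic),
                                 paste0(c("stat_", "p_"), tn)))
      if (pooled) {
        pf <- do.call(fit_pooled,
                      c(list(data = data,
                             seed = .derive_seed(seed, r + 20000L)),
                        fit_args))
        if (!is.na(pf$loglik)) {
          pc <- coef(pf)
          out <- c(out, pooled.g1 = unname(pc["g.1.1"]),
                   pooled.tau1 = unname(pc["tau.1"]))
        }
      }
      out
    }, error = function(e) NULL)
    est
  }
  ests <- if (workers > 1L)
    parallel::mclapply(seq_len(R), one, mc.cores = workers)
  else lapply(seq_len(R), one)
  failed <- vapply(ests, is.null, logical(1))
  if (sum(failed) > 0.1 * R)
    stop(sprintf("%d/%d replicate fits failed", sum(failed), R))
  est <- do.call(rbind, ests[!failed])
  structure(list(estimates = est, truth = truth, R = R,
                 n_failed = sum(failed), tests = tests, alpha = alpha,
                 theta_true = theta_true, f_true = f_true),
            class = "sfs_replicates")
}

#' @export
summary.sfs_replicates <- function(object, ...) {
  est <- object$estimates
  mean_est <- colMeans(est)
  sd_est <- if (nrow(est) > 1L) apply(est, 2L, stats::sd) else
    rep(NA_real_, ncol(est))
  reject <- sapply(object$tests, function(tn)
    mean(est[, paste0("p_", tn)] < object$alpha))
  out <- list(mean = mean_est, sd = sd_est, reject = reject,
              R_used = nrow(est), n_failed = object$n_failed)
  class(out) <- "summary.sfs_replicates"
  out
}

#' @export
print.summary.sfs_replicates <- function(x, ...) {
  cat(sprintf("Replicate summary (%d replicates used, %d failed)\n",
              x$R_used, x$n_failed))
  tab <- cbind(mean = x$mean, sd = x$sd)
  print(signif(utils::head(tab, 20L), 4))
  if (nrow(tab) > 20L) cat("  ...\n")
  if (length(x$reject)) {
    cat("Rejection rates at the 5% level:\n")
    print(signif(x$reject, 3))
  }
  invisible(x)
}
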