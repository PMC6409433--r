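# Likelihood ratio tests and bootstrap procedures.

#' Likelihood ratio test between nested fits
#'
#' @param full Fit of the larger model (an `"sfs_fit"`).
#' @param null Fit of the nested null model on the same data.
#' @param df Degrees of freedom; defaults to the difference in free-parameter
#'   counts.
#' @return An object of class `"sfs_lrt"` with the statistic
#'   `2 (loglik_full - loglik_null)`, `df`, and the asymptotic chi-square
#'   p-value.  A statistic below `-1e-6` signals an optimization failure and
#'   raises an error; small negative rounding noise is floored at 0.
#' @export
lrt <- function(full, null, df = NULL) {
  if (!inherits(full, "sfs_fit") || !inherits(null, "sfs_fit"))
    stop("full and null must be sfs_fit objects")
  if (is.na(full$loglik) || is.na(null$loglik))
    stop("cannot test with a failed fit")
  if (isTRUE(full$use_divergence) != isTRUE(null$use_divergence))
    stop("fits use different likelihood forms (divergence)")
  stat <- 2 * (full$loglik - null$loglik)
  if (stat < -1e-6)
    stop(sprintf("negative LRT statistic (%.3g): the full-model optimization ",
                 stat), "did not reach the null's likelihood; increase starts")
  stat <- max(stat, 0)
  if (is.null(df)) df <- full$n_free - null$n_free
  if (df < 1) stop("df must be >= 1")
  structure(list(statistic = stat, df = df,
                 p_asymptotic = stats::pchisq(stat, df, lower.tail = FALSE),
                 p_bootstrap = NULL, B = NULL,
                 full = full, null = null),
            class = "sfs_lrt")
}

#' @export
print.sfs_lrt <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: statistic = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_asymptotic))
  if (!is.null(x$p_bootstrap))
    cat(sprintf("  parametric bootstrap: p %s %.4g (B = %d)\n",
                if (attr(x$p_bootstrap, "upper_bound") %||% FALSE) "<" else "=",
                as.numeric(x$p_bootstrap), x$B))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parametric bootstrap p-value for a likelihood ratio test
#'
#' Simulates `B` datasets under the null MLE, refits both models on each and
#' reports the proportion of bootstrap statistics at least as large as the
#' observed one.  If none reaches it, the p-value is reported as the upper
#' bound `1/(B + 1)`.
#'
#' @param data Observed [sfs_dataset()].
#' @param model Template [model_spec()] (as for [fit()]).
#' @param constraints [constraint_set()] defining the null.
#' @param B Number of bootstrap replicates (`>= 1`).
#' @param seed Master seed; replicate seeds are derived by index, so results
#'   do not depend on execution order or worker count.
#' @param df Degrees of freedom passed to [lrt()].
#' @param workers Parallel workers for the refits (forked; result-invariant).
#' @param ... Passed to [fit()] (e.g. `n_starts`, `use_profile`).
#' @return An `"sfs_lrt"` for the observed data with `p_bootstrap` and `B`
#'   filled in.  Bootstrap refits that fail are dropped; more than 10%
#'   failures is an error.
#' @export
bootstrap_pvalue <- function(data, model, constraints, B = 99L, seed = 1L,
                             df = NULL, workers = 1L, ...) {
  if (B < 1) stop("B must be >= 1")
  full_obs <- fit(data, model, seed = .derive_seed(seed, 100000L), ...)
  null_obs <- fit(data, model, constraints = constraints,
                  seed = .derive_seed(seed, 200000L), ...)
  obs <- lrt(full_obs, null_obs, df = df)
  null_model <- null_obs$model
  use_div <- isTRUE(full_obs$use_divergence)
  one <- function(b) {
    sim <- simulate_dataset(null_model, data$n, seed = .derive_seed(seed, b),
                            divergence = use_div, folded = data$folded)
    fb <- tryCatch(fit(sim, model, seed = .derive_seed(seed, b + 300000L), ...),
                   error = function(e) NULL)
    nb <- tryCatch(fit(sim, model, constraints = constraints,
                       seed = .derive_seed(seed, b + 400000L), ...),
                   error = function(e) NULL)
    if (is.null(fb) || is.null(nb) || is.na(fb$loglik) || is.na(nb$loglik))
      return(NA_real_)
    max(2 * (fb$loglik - nb$loglik), 0)
  }
  stats_b <- if (workers > 1L)
    unlist(parallel::mclapply(seq_len(B), one, mc.cores = workers))
  else vapply(seq_len(B), one, numeric(1))
  dropped <- sum(is.na(stats_b))
  if (dropped > 0.1 * B)
    stop(sprintf("%d/%d bootstrap refits failed", dropped, B))
  stats_b <- stats_b[!is.na(stats_b)]
  count <- sum(stats_b >= obs$statistic)
  p <- count / length(stats_b)
  if (count == 0L) {
    p <- 1 / (length(stats_b) + 1)
    attr(p, "upper_bound") <- TRUE
  }
  obs$p_bootstrap <- p
  obs$B <- length(stats_b)
  obs
}

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples loci (resampling blocks) with replacement — within strata if
#' given, keeping each stratum's locus count fixed — refits the model on
#' each resample and reports percentile intervals of the parameter
#' estimates.
#'
#' @param data An [sfs_dataset()]; each locus is one resampling block.
#' @param model Template [model_spec()].
#' @param B Number of bootstrap resamples.
#' @param seed Master seed (per-resample seeds derived by index).
#' @param level Coverage level (default 0.95: the 2.5 and 97.5 percentiles).
#' @param strata Optional factor/vector of length `K`; resampling is done
#'   within each stratum (e.g. X-linked vs autosomal loci).
#' @param workers Parallel workers (forked; result-invariant).
#' @param ... Passed to [fit()].
#' @return An object of class `"sfs_boot"`: matrix of per-resample estimates
#'   (`$estimates`), percentile intervals (`$ci`), and the point fit
#'   (`$fit`).
#' @export
bootstrap_ci <- function(data, model, B = 100L, seed = 1L, level = 0.95,
                         strata = NULL, workers = 1L, ...) {
  if (B < 1) stop("B must be >= 1")
  K <- nrow(data$counts)
  if (is.null(strata)) strata <- rep(1L, K)
  if (length(strata) != K) stop("strata must have one entry per locus")
  groups <- split(seq_len(K), strata)
  point <- fit(data, model, seed = .derive_seed(seed, 500000L), ...)
  one <- function(b) {
    set.seed(.derive_seed(seed, b))
    idx <- unlist(lapply(groups, function(gr)
      gr[sample.int(length(gr), length(gr), replace = TRUE)]))
    resamp <- subset_loci(data, sort(idx))
    fb <- tryCatch(fit(resamp, model, seed = .derive_seed(seed, b + 600000L),
                       ...),
                   error = function(e) NULL)
    if (is.null(fb) || is.na(fb$loglik)) return(NULL)
    coef(fb)
  }
  ests <- if (workers > 1L) parallel::mclapply(seq_len(B), one,
                                               mc.cores = workers)
  else lapply(seq_len(B), one)
  failed <- vapply(ests, is.null, logical(1))
  if (sum(failed) > 0.1 * B)
    stop(sprintf("%d/%d bootstrap refits failed", sum(failed), B))
  est <- do.call(rbind, ests[!failed])
  a <- (1 - level) / 2
  ci <- t(apply(est, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  structure(list(estimates = est, ci = ci, level = level, fit = point,
                 B = nrow(est)),
            class = "sfs_boot")
}

#' @export
print.sfs_boot <- function(x, ...) {
  cat(sprintf("Bootstrap over loci: %d resamples, %.0f%% percentile intervals\n",
              x$B, 100 * x$level))
  print(signif(cbind(estimate = coef(x$fit), x$ci), 4))
  invisible(x)
}
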