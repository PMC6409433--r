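# Multi-start maximum-likelihood fitting.

## deterministic sub-seed derivation (kept below 2^31)
.derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 65011 * 31627 + index * 7919 + 12345) %%
               2147483587 + 1)
}

## Data-driven starts: Watterson-type theta, diversity-ratio f, a mild
## expansion and a mild contraction for g.  Values are clamped to the random
## start boxes so the two routes explore the same region.
.heuristic_starts <- function(template, data) {
  n <- data$n
  S <- rowSums(data$counts)
  hn <- sum(1 / seq_len(n - 1L))
  m <- template$base_state$m
  ref <- template$ref
  div_ref <- max(S[ref] / m[ref], 1e-9)
  clamp <- function(v, kind) {
    box <- .start_box(kind)
    pmin(pmax(v, box[1L]), box[2L])
  }
  mk <- function(g0) {
    st <- template$base_state
    st$theta <- clamp(S / (m * hn), "theta")
    st$f <- clamp(pmax(S / m, 1e-9) / div_ref, "f")
    st$f[ref] <- 1
    if (template$H > 1L) st$g[, ] <- clamp(g0, "g")
    if (length(st$tau)) st$tau[] <- 0.3
    st$eps[template$fit_eps] <- 0.02
    if (template$use_divergence) { st$c <- 1; st$t <- 5 }
    .template_pack(template, st)
  }
  list(mk(3), mk(0.3))
}

#' Fit the stepwise multilocus model by maximum likelihood
#'
#' Maximizes the composite Poisson random field likelihood over the model's
#' free parameters using multi-start quasi-Newton optimization (PORT,
#' [stats::nlminb()]) with analytic gradients in log/logit-transformed
#' coordinates.  By default the mutation rates are concentrated out
#' analytically (profile route) and recovered afterwards as
#' `S_k / (m_k phi_k)` (extended with the substitution counts when
#' divergence data are used), which reduces the dimension of the search by
#' one per locus.
#'
#' Starts comprise two data-driven points (Watterson-type `theta`,
#' diversity-ratio `f`, one mild-expansion and one mild-contraction guess)
#' plus `n_starts` points drawn uniformly in log-space boxes
#' (`theta` in `[1e-5, 0.1]`, `f` in `[0.05, 20]`, `g` in `[0.05, 50]`,
#' `tau` in `[0.001, 10]`, `c` in `[0.1, 10]`, `t` in `[0.1, 50]`).  Ties
#' closer than 1e-6 log-units are broken in favour of the first start found.
#' Results are deterministic given `(data, seed, options)`.
#'
#' @param data An [sfs_dataset()].
#' @param model A [model_spec()] serving as the template: its dimensions,
#'   sharing flags, reference locus and divergence block define which
#'   parameters are free; its numeric values seed nothing unless
#'   `init_from_model = TRUE` adds them as an extra start.
#' @param constraints Optional [constraint_set()] applied by parameter
#'   elimination (substitution, not penalties).
#' @param n_starts Number of random starts (default 20).
#' @param seed Integer seed governing the random starts.
#' @param use_profile Concentrate the mutation rates out analytically
#'   (default TRUE).
#' @param use_divergence Include substitution counts; default: yes whenever
#'   both model and data carry divergence information.
#' @param fit_epsilon Estimate per-locus polarization-error rates.
#' @param init_from_model Also start from the parameter values stored in
#'   `model`.
#' @param control Passed to [stats::nlminb()] (defaults: `rel.tol 1e-12`,
#'   `x.tol 1e-10`, `iter.max 1000`).
#' @return An object of class `"sfs_fit"`: the fitted [model_spec()]
#'   (`$model`), the maximized full-form log-likelihood (`$loglik`), the
#'   per-start record (`$starts`), the number of free parameters including
#'   concentrated mutation rates (`$n_free`), and bookkeeping fields.  If no
#'   start converges the fit is returned with `converged = FALSE` and
#'   `loglik = NA` rather than an error.
#' @export
fit <- function(data, model, constraints = NULL, n_starts = 20L, seed = 1L,
                use_profile = TRUE, use_divergence = NULL,
                fit_epsilon = FALSE, init_from_model = FALSE,
                control = list()) {
  .check_dims(data, model)
  if (model$epochs$H == 1L) {
    anyf <- any(abs(vapply(model$loci, `[[`, numeric(1), "f") - 1) > 1e-12)
    if (anyf)
      stop("under a constant-size model only the composite rates theta* are ",
           "identifiable; f and g cannot be free (set all f = 1)")
  }
  template <- .make_template(model, data, use_profile = use_profile,
                             use_divergence = use_divergence,
                             constraints = constraints,
                             fit_epsilon = fit_epsilon)
  B <- branch_weights(data$n)
  obj <- .make_objective(template, data, B)
  ctrl <- utils::modifyList(
    list(rel.tol = 1e-12, x.tol = 1e-10, iter.max = 1000L, eval.max = 2000L),
    control)

  starts <- .heuristic_starts(template, data)
  if (init_from_model)
    starts <- c(starts, list(.template_pack(template,
                                            .state_from_model(model))))
  if (n_starts > 0L) {
    for (s in seq_len(n_starts)) {
      set.seed(.derive_seed(seed, s))
      starts <- c(starts, list(.random_start(template)))
    }
  }

  if (template$n_free == 0L) {
    ## nothing to optimize (e.g. constant-size profile fit)
    res0 <- obj$evalz(numeric(0))
    rec <- data.frame(start = 1L, converged = TRUE, loglik = res0$loglik,
                      message = "no free parameters")
    return(.finish_fit(template, data, B, numeric(0), rec, 1L, obj))
  }

  rec <- data.frame(start = seq_along(starts), converged = FALSE,
                    loglik = NA_real_, message = "", stringsAsFactors = FALSE)
  best <- NULL; best_obj <- Inf; best_idx <- NA_integer_
  for (s in seq_along(starts)) {
    ans <- tryCatch(
      stats::nlminb(starts[[s]], obj$fn, obj$gr, control = ctrl),
      error = function(e) e)
    if (inherits(ans, "error")) {
      rec$message[s] <- conditionMessage(ans)
      next
    }
    rec$converged[s] <- ans$convergence == 0L
    rec$loglik[s] <- -ans$objective
    rec$message[s] <- ans$message
    if (is.finite(ans$objective) && ans$objective < best_obj - 1e-6) {
      best_obj <- ans$objective
      best <- ans$par
      best_idx <- s
    }
  }
  if (is.null(best) || best_obj >= 1e10) {
    return(structure(list(model = model, loglik = NA_real_,
                          converged = FALSE, starts = rec,
                          n_free = template$n_free_total,
                          best_start = NA_integer_, seed = seed,
                          template = template,
                          use_profile = template$use_profile,
                          use_divergence = template$use_divergence),
                     class = "sfs_fit"))
  }
  .finish_fit(template, data, B, best, rec, best_idx, obj)
}

.finish_fit <- function(template, data, B, z, rec, best_idx, obj) {
  res <- obj$evalz(z)
  state <- res$state
  state$theta <- res$theta            # concentrated thetas, if profile
  ## full-form loglik (divergence terms included iff they were fitted)
  full <- .ll_eval(state, data, B,
                   list(use_divergence = template$use_divergence,
                        profile = FALSE),
                   want_grad = FALSE)
  fitted_model <- .model_from_state(template$model, state)
  structure(list(model = fitted_model, loglik = full$loglik,
                 converged = any(rec$converged), starts = rec,
                 n_free = template$n_free_total, best_start = best_idx,
                 phitot = res$phitot, template = template,
                 use_profile = template$use_profile,
                 use_divergence = template$use_divergence),
            class = "sfs_fit")
}

#' Fit under equality constraints
#'
#' Convenience wrapper: identical to [fit()] with a non-empty
#' [constraint_set()]; an empty constraint set reproduces [fit()] exactly.
#'
#' @inheritParams fit
#' @return An `"sfs_fit"` object.
#' @export
fit_constrained <- function(data, model, constraints, ...) {
  fit(data, model, constraints = constraints, ...)
}

#' Naive pooled fit of a combined spectrum
#'
#' Sums the unfolded spectra of all loci classwise into a single spectrum
#' and fits a one-locus stepwise model (`theta*`, `g`, `tau` free) to it,
#' disregarding between-locus variation in `N_e` and mutation rate.  Used to
#' demonstrate the bias this shortcut induces when loci are heterogeneous.
#'
#' @param data An unfolded [sfs_dataset()].
#' @param H Number of epochs of the pooled model (default 2).
#' @param ... Passed to [fit()].
#' @return An `"sfs_fit"` object for the pooled single-locus dataset.
#' @export
fit_pooled <- function(data, H = 2L, ...) {
  if (data$folded) stop("pooled fits require unfolded data")
  pooled <- pool_dataset(data)
  tau0 <- if (H > 1L) rep(0.5, H - 1L) else numeric(0)
  g0 <- if (H > 1L) rep(2, H - 1L) else numeric(0)
  model <- model_spec(epoch_model(tau0),
                      list(locus_model(theta = 1e-3, f = 1, g = g0,
                                       m = sum(data$m))))
  fit(pooled, model, use_divergence = FALSE, ...)
}

#' @export
print.sfs_fit <- function(x, ...) {
  cat("Maximum-likelihood fit\n")
  if (!isTRUE(x$converged) && is.na(x$loglik)) {
    cat("  all starts failed to converge\n")
    return(invisible(x))
  }
  cat(sprintf("  loglik %.4f (constant omitted), %d free parameters, %d/%d starts converged\n",
              x$loglik, x$n_free, sum(x$starts$converged), nrow(x$starts)))
  print(x$model)
  invisible(x)
}

#' @export
coef.sfs_fit <- function(object, ...) {
  st <- .state_from_model(object$model)
  K <- length(st$theta); H <- length(st$tau) + 1L
  out <- c(stats::setNames(st$theta, sprintf("theta.%d", seq_len(K))),
           stats::setNames(st$f, sprintf("f.%d", seq_len(K))))
  if (H > 1L) {
    if (object$model$shared_g) {
      out <- c(out, stats::setNames(st$g[1L, ], sprintf("g.%d", seq_len(H - 1L))))
    } else {
      gm <- st$g
      nm <- as.vector(outer(seq_len(K), seq_len(H - 1L),
                            function(k, h) sprintf("g.%d.%d", k, h)))
      out <- c(out, stats::setNames(as.vector(gm), nm))
    }
    out <- c(out, stats::setNames(st$tau, sprintf("tau.%d", seq_len(H - 1L))))
  }
  if (any(st$eps > 0))
    out <- c(out, stats::setNames(st$eps, sprintf("eps.%d", seq_len(K))))
  if (!is.na(st$c)) out <- c(out, c = st$c, t = st$t)
  out
}

#' @export
logLik.sfs_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free, class = "logLik")
}
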