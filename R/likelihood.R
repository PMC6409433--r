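# Composite log-likelihoods of the Poisson random field model and their
# analytic gradients.
#
# Counts in frequency class i of locus k are independent Poisson variables
# with mean psi_{k,i} (psi* under polarization error; Psi for folded data);
# substitution counts are Poisson with mean lambda_k.  All reported values
# omit the data-dependent constant (sum of log d! terms), so they are
# comparable only across models on fixed data — exactly what likelihood
# ratio tests need.  The 0 * log 0 = 0 convention is used for empty classes.

## ---- engine ---------------------------------------------------------------
## state: list(theta, f [K], g [K x (H-1)], tau [H-1], eps [K], m [K], c, t)
## opts:  list(use_divergence, profile, theta_groups)
## Returns loglik, per-parameter gradients in natural coordinates, the
## (possibly concentrated) theta vector and per-locus phi totals.
.ll_eval <- function(state, data, B, opts, want_grad = TRUE) {
  K <- length(state$theta)
  n <- data$n
  H <- length(state$tau) + 1L
  i_idx <- seq_len(n - 1L)
  inv_i <- 1 / i_idx
  folded <- data$folded
  use_div <- isTRUE(opts$use_divergence)
  profile <- isTRUE(opts$profile)
  bad <- function() list(loglik = -Inf, feasible = FALSE)
  f <- state$f; th <- state$theta; m <- state$m; eps <- state$eps
  tau <- state$tau; g <- state$g

  ## spectrum pieces, vectorized over loci: one (K x n-1) matrix per epoch
  if (H > 1L) {
    sg <- matrix(0, K, H - 1L)                   # (sum_{l<=h} tau_l/g_l)/f
    acc <- numeric(K)
    for (h in seq_len(H - 1L)) {
      acc <- acc + tau[h] / g[, h]
      sg[, h] <- acc / f
    }
    dg <- cbind(g[, -1L, drop = FALSE], 1) - g   # g_{h+1} - g_h, g_H = 1
    tB <- t(B$B)
    tBN <- B$binom2 * tB                          # row j scaled by choose(j,2)
    Mh <- vector("list", H - 1L); Nh <- vector("list", H - 1L)
    A <- matrix(0, K, n - 1L)
    for (h in seq_len(H - 1L)) {
      Eh <- exp(-sg[, h] %o% B$binom2)
      Mh[[h]] <- Eh %*% tB
      if (want_grad) Nh[[h]] <- Eh %*% tBN
      A <- A + dg[, h] * Mh[[h]]
    }
    phim <- f * (g[, 1L] %o% inv_i + A)
  } else {
    phim <- f %o% inv_i
  }
  if (any(!is.finite(phim)) || any(phim <= 0)) return(bad())
  phitot <- rowSums(phim)

  if (profile) {
    groups <- opts$theta_groups
    if (is.null(groups)) groups <- as.list(seq_len(K))
    S <- rowSums(data$counts)
    for (grp in groups) {
      num <- sum(S[grp])
      den <- sum(m[grp] * phitot[grp])
      if (use_div) {
        num <- num + sum(data$x[grp])
        den <- den + sum(m[grp] * (state$c * f[grp] + state$t))
      }
      if (!is.finite(den) || den <= 0) return(bad())
      th[grp] <- num / den
    }
    state$theta <- th
  }

  psi <- m * th * phim
  any_eps <- any(eps > 0)
  psis <- if (any_eps) (1 - eps) * psi + eps * psi[, rev(i_idx), drop = FALSE]
  else psi
  d <- data$counts
  half <- n %/% 2L
  if (folded) {
    mir <- n - seq_len(half)                    # mirror class of column i
    mu <- psis[, seq_len(half), drop = FALSE]
    addc <- psis[, mir, drop = FALSE]
    addc[, mir == seq_len(half)] <- 0           # central class, n even
    mu <- mu + addc
  } else {
    mu <- psis
  }
  pos <- d > 0
  if (any(pos & mu <= 0)) return(bad())
  ll <- -sum(mu) + sum(d[pos] * log(mu[pos]))
  if (use_div) {
    lam <- m * th * (state$c * f + state$t)
    xk <- data$x
    if (any(xk > 0 & lam <= 0)) return(bad())
    xpos <- xk > 0
    ll <- ll - sum(lam) + sum(xk[xpos] * log(lam[xpos]))
  }
  if (!is.finite(ll)) return(bad())
  if (!want_grad)
    return(list(loglik = ll, feasible = TRUE, theta = th, phitot = phitot))

  P <- -1 + ifelse(mu > 0, d / mu, 0)           # dll/dmu
  q <- if (folded) P[, pmin(i_idx, n - i_idx), drop = FALSE] else P
  r <- if (any_eps) (1 - eps) * q + eps * q[, rev(i_idx), drop = FALSE] else q
  geps <- if (any_eps)
    rowSums(q * (psi[, rev(i_idx), drop = FALSE] - psi)) else numeric(K)
  dphi <- r * (m * th)                          # dll/dphi
  gtheta <- rowSums(q * psis) / th
  gtheta[th == 0] <- 0
  if (H > 1L) {
    vM <- matrix(0, K, H - 1L); vN <- matrix(0, K, H - 1L)
    for (h in seq_len(H - 1L)) {
      vM[, h] <- rowSums(dphi * Mh[[h]])
      vN[, h] <- rowSums(dphi * Nh[[h]])
    }
    dgvN <- dg * vN
    revN <- dgvN
    if (H > 2L)
      for (h in seq.int(H - 2L, 1L)) revN[, h] <- revN[, h] + revN[, h + 1L]
    gf <- rowSums(dphi * phim) / f + rowSums(dg * sg * vN)
    gtau <- -colSums(revN / g)
    ## coefficient part (x f), exponent part (f cancels), g_1/i part (x f)
    gg <- f * (-vM + cbind(0, vM[, -(H - 1L), drop = FALSE])) +
      matrix(tau, K, H - 1L, byrow = TRUE) * revN / g^2
    gg[, 1L] <- gg[, 1L] + f * as.numeric(dphi %*% inv_i)
  } else {
    gf <- rowSums(dphi * phim) / f
    gg <- matrix(0, K, 0L)
    gtau <- numeric(0)
  }
  gc <- 0; gt <- 0
  if (use_div) {
    dlam <- -1 + ifelse(lam > 0, xk / lam, 0)
    gtheta <- gtheta + dlam * (state$c * f + state$t) * m
    gf <- gf + dlam * m * th * state$c
    gc <- sum(dlam * m * th * f)
    gt <- sum(dlam * m * th)
  }

  list(loglik = ll, feasible = TRUE,
       grad = list(theta = gtheta, f = gf, g = gg, tau = gtau,
                   eps = geps, c = gc, t = gt),
       theta = th, phitot = phitot)
}

## options builder with validation shared by exported likelihood functions
.ll_opts <- function(data, model, use_divergence = FALSE, profile = FALSE,
                     theta_groups = NULL) {
  .check_dims(data, model)
  if (data$folded && any(vapply(model$loci, `[[`, numeric(1), "epsilon") > 0))
    stop("polarization error is incompatible with folded spectra: ",
         "the unfolded SFS must be used")
  if (use_divergence) {
    if (is.null(model$divergence))
      stop("model has no divergence parameters (c, t)")
    if (is.null(data$x))
      stop("dataset has no substitution counts")
  }
  list(use_divergence = use_divergence, profile = profile,
       theta_groups = theta_groups)
}

#' Full composite log-likelihood of the SFS
#'
#' `sum_k sum_i [ -psi_{k,i} + d_{k,i} log psi_{k,i} ]`, the Poisson random
#' field log-likelihood with the data-only constant omitted.  Polarization
#' error (per-locus `epsilon`) is applied to the expected spectrum first;
#' folded data use the folded expectation with classes `1..floor(n/2)`.
#'
#' @param data An [sfs_dataset()].
#' @param model A [model_spec()] with matching dimensions.
#' @return Log-likelihood value (may be `-Inf` if the model assigns zero
#'   expectation to an observed class).
#' @export
loglik_full <- function(data, model) {
  opts <- .ll_opts(data, model)
  .ll_eval(.state_from_model(model), data, branch_weights(data$n), opts,
           want_grad = FALSE)$loglik
}

#' Divergence-augmented composite log-likelihood
#'
#' Adds the Poisson substitution terms `-lambda_k + x_k log lambda_k` with
#' `lambda_k = m_k theta_k (c f_k + t)` to [loglik_full()].
#'
#' @inheritParams loglik_full
#' @return Log-likelihood value.
#' @export
loglik_with_divergence <- function(data, model) {
  opts <- .ll_opts(data, model, use_divergence = TRUE)
  .ll_eval(.state_from_model(model), data, branch_weights(data$n), opts,
           want_grad = FALSE)$loglik
}

#' Profile (conditional) log-likelihood of the SFS shape
#'
#' The multinomial log-likelihood of the spectrum conditioned on the numbers
#' of segregating sites: `sum_k sum_i d_{k,i} [log phi*_{k,i} - log phi_k]`,
#' which is free of the per-locus mutation rates `theta_k`.  Its argmax over
#' the shape parameters (`f`, `g`, `tau`, `epsilon`) coincides with that of
#' the full likelihood; `theta_k` is recovered afterwards with
#' [recover_theta()].
#'
#' @inheritParams loglik_full
#' @return Log-likelihood value (theta values in `model` are ignored).
#' @export
loglik_profile <- function(data, model) {
  opts <- .ll_opts(data, model)
  B <- branch_weights(data$n)
  state <- .state_from_model(model)
  n <- data$n
  ll <- 0
  for (k in seq_len(nrow(data$counts))) {
    ph <- .locus_phi(state$f[k],
                     if (ncol(state$g) > 0L) state$g[k, ] else numeric(0),
                     state$tau, B)$phi
    if (any(!is.finite(ph)) || any(ph <= 0))
      stop("phi has non-positive entries: invalid parameter region")
    eps <- state$eps[k]
    if (eps > 0) ph <- (1 - eps) * ph + eps * rev(ph)
    if (data$folded) ph <- fold_expected(ph, n)
    d <- data$counts[k, ]
    pos <- d > 0
    ll <- ll + sum(d[pos] * (log(ph[pos]) - log(sum(ph))))
  }
  ll
}

#' Recover the mutation rate after a profile fit
#'
#' `theta_hat_k = S_k / (m_k phi_k)` where `phi_k = sum_i phi_{k,i}` at the
#' fitted shape parameters (a Watterson-type estimator generalised to the
#' stepwise model).
#'
#' @param S_k Number of segregating sites at the locus.
#' @param m_k Locus length in bp.
#' @param phi_total `sum_i phi_{k,i}` at the fitted shape parameters.
#' @return The conditional MLE of `theta_k`.
#' @export
recover_theta <- function(S_k, m_k, phi_total) {
  if (any(phi_total <= 0) || any(!is.finite(phi_total)))
    stop("phi_total must be positive")
  S_k / (m_k * phi_total)
}

#' Analytic gradient of the composite log-likelihood
#'
#' Gradient with respect to the model's free parameters in the optimizer's
#' transformed coordinates (log for `theta`, `f`, `g`, `tau`, `c`, `t`;
#' scaled logit on `[0, 0.5]` for `epsilon`).  The reference locus' `f` is
#' fixed and therefore absent.  With `profile = TRUE` the mutation rates are
#' concentrated out and do not appear.
#'
#' @inheritParams loglik_full
#' @param use_divergence Include the substitution terms.
#' @param profile Concentrate `theta_k` out analytically.
#' @param fit_epsilon Treat the per-locus polarization errors as free.
#' @return Named numeric vector of partial derivatives.
#' @export
loglik_gradient <- function(data, model, use_divergence = FALSE,
                            profile = FALSE, fit_epsilon = FALSE) {
  template <- .make_template(model, data, use_profile = profile,
                             use_divergence = use_divergence,
                             fit_epsilon = fit_epsilon)
  z <- .template_pack(template, .state_from_model(model))
  obj <- .make_objective(template, data, branch_weights(data$n))
  g <- -obj$gr(z)
  names(g) <- template$free_ids
  g
}
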