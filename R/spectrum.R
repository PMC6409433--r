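# Expected site-frequency spectra under the stepwise model.
#
# phi_{k,i} = f_k [ g_{k,1}/i + A_{k,i} ] is half the expected total length
# of genealogy branches with i descendants; psi_{k,i} = m_k theta_k phi_{k,i}
# is the expected number of segregating sites of derived-allele count i under
# the Poisson random field (free recombination, infinite sites).

## shared helper: the A, M, N pieces for one locus.
## Returns list(phi, A, M, N, sg, dg); M[h,i] = sum_j B_i(j) E_{h,j},
## N[h,i] = sum_j B_i(j) choose(j,2) E_{h,j},
## E_{h,j} = exp(-choose(j,2) sg_h), sg_h = (sum_{l<=h} tau_l / g_l) / f.
.locus_phi <- function(f, g, tau, B) {
  n <- B$n
  i_idx <- seq_len(n - 1L)
  H <- length(tau) + 1L
  if (H == 1L) {
    return(list(phi = f / i_idx, A = numeric(n - 1L),
                M = NULL, N = NULL, sg = numeric(0), dg = numeric(0)))
  }
  sg <- cumsum(tau / g) / f
  E <- exp(-outer(sg, B$binom2))                    # (H-1) x (n-1)
  M <- E %*% t(B$B)
  N <- sweep(E, 2L, B$binom2, "*") %*% t(B$B)
  dg <- diff(c(g, 1))                               # g_{h+1} - g_h, g_H = 1
  A <- as.numeric(crossprod(dg, M))
  list(phi = f * (g[1L] / i_idx + A), A = A, M = M, N = N, sg = sg, dg = dg)
}

#' Nonequilibrium correction term of the expected spectrum
#'
#' Computes `A_{k,i} = sum_{h=1}^{H-1} (g_{k,h+1} - g_{k,h}) sum_j
#' exp(-choose(j,2) sum_{l<=h} tau_l / (f_k g_{k,l})) B_i(j)` (with the
#' implicit `g_{k,H} = 1`).  `A` vanishes when all `g = 1` and decays to 0 as
#' the change recedes into the past.
#'
#' @param i Integer vector of derived-allele counts in `1..n-1`.
#' @param locus A [locus_model()].
#' @param epochs An [epoch_model()] with `H - 1` matching `length(locus$g)`.
#' @param B A [branch_weights()] object for the sample size of interest.
#' @return Numeric vector, one value per element of `i`.
#' @export
epoch_decay_A <- function(i, locus, epochs, B) {
  if (length(locus$g) != epochs$H - 1L)
    stop("locus g length does not match epoch model")
  if (any(i < 1 | i > B$n - 1L)) stop("i out of range 1..n-1")
  .locus_phi(locus$f, locus$g, epochs$tau, B)$A[i]
}

#' Expected per-mutation spectrum shape phi
#'
#' `phi_{k,i} = f_k [g_{k,1}/i + A_{k,i}]`; under the constant-size model
#' this reduces to the equilibrium shape `f_k / i`.
#'
#' @inheritParams epoch_decay_A
#' @return Numeric vector of length `n - 1`.
#' @export
phi <- function(locus, epochs, B) {
  if (length(locus$g) != epochs$H - 1L)
    stop("locus g length does not match epoch model")
  out <- .locus_phi(locus$f, locus$g, epochs$tau, B)$phi
  if (any(!is.finite(out)) || any(out <= 0))
    stop("phi has non-positive or non-finite entries: invalid parameter region")
  out
}

#' Expected unfolded site-frequency spectrum of one locus
#'
#' `psi_{k,i} = m_k theta_k phi_{k,i}`, the expected number of segregating
#' sites with derived-allele count `i` under the Poisson random field.
#'
#' @inheritParams epoch_decay_A
#' @return Numeric vector of length `n - 1`.
#' @export
#' @examples
#' B <- branch_weights(4)
#' expected_sfs(locus_model(theta = 0.001, m = 1000), epoch_model(), B)
expected_sfs <- function(locus, epochs, B) {
  locus$m * locus$theta * phi(locus, epochs, B)
}

#' Expected spectra for all loci of a model
#'
#' @param model A [model_spec()].
#' @param n Sample size (alleles); branch weights are built (or fetched from
#'   cache) internally.
#' @param apply_error Logical; if TRUE (default) each locus' polarization
#'   error `epsilon` is applied to its expected spectrum.
#' @return A `K x (n-1)` matrix of expected counts, rows in locus order.
#' @export
model_expected_sfs <- function(model, n, apply_error = TRUE) {
  B <- branch_weights(n)
  K <- length(model$loci)
  out <- matrix(0, K, n - 1L)
  for (k in seq_len(K)) {
    psi <- expected_sfs(model$loci[[k]], model$epochs, B)
    if (apply_error && model$loci[[k]]$epsilon > 0)
      psi <- apply_polarization_error(psi, model$loci[[k]]$epsilon)
    out[k, ] <- psi
  }
  out
}

#' Fold an expected (or observed) unfolded spectrum
#'
#' `Psi_i = psi_i + psi_{n-i}` for `i < n - i`; the central class (`n` even)
#' is carried over unchanged.  The total is conserved.
#'
#' @param psi Numeric vector of length `n - 1` (unfolded spectrum).
#' @param n Sample size.
#' @return Numeric vector of length `floor(n/2)` (minor-allele classes).
#' @export
fold_expected <- function(psi, n) {
  if (length(psi) != n - 1L) stop("psi must have length n - 1")
  i <- seq_len(n %/% 2L)
  psi[i] + ifelse(i < n - i, psi[n - i], 0)
}

#' Perturb an unfolded spectrum by polarization error
#'
#' With probability `epsilon` the ancestral state of a segregating site is
#' misassigned, mapping frequency class `i` to `n - i`:
#' `psi*_i = (1 - epsilon) psi_i + epsilon psi_{n-i}`.  The total is
#' conserved; at `epsilon = 0.5` the spectrum is symmetric.
#'
#' @param psi Numeric vector of length `n - 1` (unfolded spectrum).
#' @param epsilon Error probability in `[0, 0.5]`.
#' @return Numeric vector of length `n - 1`.
#' @export
apply_polarization_error <- function(psi, epsilon) {
  if (length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon < 0 || epsilon > 0.5)
    stop("epsilon must lie in [0, 0.5]")
  if (epsilon == 0) return(psi)
  (1 - epsilon) * psi + epsilon * rev(psi)
}

#' Expected number of substitutions to the outgroup
#'
#' `lambda_k = m_k theta_k (c f_k + t)`: the first term counts differences
#' accumulated as ancestral polymorphism (ancestral population of size
#' `c f_k N1`), the second changes accrued since the split at scaled time
#' `t`.
#'
#' @param locus A [locus_model()].
#' @param c Ancestral-size scalar, `> 0`.
#' @param t Scaled split time (units of `2 N1` generations), `>= 0`.
#' @return Expected substitution count (numeric scalar).
#' @export
expected_divergence <- function(locus, c, t) {
  if (c <= 0 || t < 0) stop("require c > 0 and t >= 0")
  locus$m * locus$theta * (c * locus$f + t)
}
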