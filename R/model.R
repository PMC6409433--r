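# Model containers: stepwise epoch structure, per-locus parameters, and the
# multilocus model specification.
#
# All scaled parameters are defined against the reference locus in the most
# distant epoch: theta_k = 4 N1 u_k per site, f_k = N_k / N1, tau_h = T_h /
# (2 N1).  Epoch 1 is the most recent; epoch H extends indefinitely into the
# past and carries the implicit size multiplier g_{k,H} = 1 (never stored).
# Absolute quantities (N1, u_k, generations) are deliberately not represented:
# only their scaled composites are estimable.

#' Stepwise epoch structure
#'
#' @param tau Numeric vector of scaled epoch durations `(tau_1, ...,
#'   tau_{H-1})`, most recent first, in units of `2 N1` generations.  An
#'   empty vector gives the constant-size (single-epoch) model.
#' @return An object of class `"epoch_model"` with fields `H` and `tau`.
#' @export
#' @examples
#' epoch_model(0.1)        # two epochs, expansion/contraction at tau = 0.1
#' epoch_model(numeric(0)) # constant size
epoch_model <- function(tau = numeric(0)) {
  tau <- as.numeric(tau)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("all epoch durations tau must be finite and > 0")
  structure(list(H = length(tau) + 1L, tau = tau), class = "epoch_model")
}

#' Per-locus model parameters
#'
#' @param theta Scaled mutation rate per site, `4 N1 u_k` (reference-scaled);
#'   `>= 0`.
#' @param f Local effective-size scalar relative to the reference locus in
#'   the most distant epoch; `> 0`.
#' @param g Numeric vector of epoch size multipliers `(g_{k,1}, ...,
#'   g_{k,H-1})`; the implicit `g_{k,H} = 1` is never stored.  Length must be
#'   `H - 1` for the epoch model the locus is used with.
#' @param m Locus length in basepairs (positive integer).
#' @param epsilon Polarization-error probability in `[0, 0.5]` (default 0).
#' @return An object of class `"locus_model"`.
#' @export
locus_model <- function(theta, f = 1, g = numeric(0), m, epsilon = 0) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta < 0)
    stop("theta must be a single finite number >= 0")
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0)
    stop("f must be a single finite number > 0")
  g <- as.numeric(g)
  if (any(!is.finite(g)) || any(g <= 0))
    stop("all epoch size multipliers g must be finite and > 0")
  if (length(m) != 1L || !is.finite(m) || m <= 0 || m != round(m))
    stop("m must be a single positive integer (locus length in bp)")
  if (length(epsilon) != 1L || !is.finite(epsilon) || epsilon < 0 || epsilon > 0.5)
    stop("epsilon must lie in [0, 0.5]")
  structure(list(theta = theta, f = f, g = g, m = as.numeric(m),
                 epsilon = epsilon),
            class = "locus_model")
}

#' Multilocus model specification
#'
#' Combines a shared stepwise epoch structure with per-locus parameters.
#' The reference locus has `f` fixed at 1 for identifiability.  Under the
#' simplified (shared-g) model all loci respond to the demographic process in
#' the same way: `g_{k,h} = g_h` for all `k`.
#'
#' @param epochs An [epoch_model()].
#' @param loci A list of [locus_model()] objects (length `K >= 1`), each with
#'   `g` of length `H - 1`.
#' @param shared_g Logical; if TRUE the loci share one `g` vector (taken from
#'   the first locus and copied to all).
#' @param divergence Optional list `list(c = ..., t = ...)` with the
#'   ancestral-size scalar `c > 0` and scaled split time `t >= 0` of the
#'   divergence model `lambda_k = m_k theta_k (c f_k + t)`.
#' @param ref Index of the reference locus (default 1); its `f` must be 1.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(epochs, loci, shared_g = FALSE, divergence = NULL,
                       ref = 1L) {
  if (!inherits(epochs, "epoch_model")) stop("epochs must be an epoch_model")
  if (!is.list(loci) || !length(loci) ||
      !all(vapply(loci, inherits, logical(1), "locus_model")))
    stop("loci must be a non-empty list of locus_model objects")
  K <- length(loci)
  ref <- as.integer(ref)
  if (ref < 1L || ref > K) stop("ref must index a locus")
  H <- epochs$H
  for (k in seq_len(K)) {
    if (length(loci[[k]]$g) != H - 1L)
      stop(sprintf("locus %d has g of length %d; epoch model needs %d",
                   k, length(loci[[k]]$g), H - 1L))
  }
  if (abs(loci[[ref]]$f - 1) > 1e-12)
    stop("the reference locus must have f = 1")
  if (isTRUE(shared_g) && H > 1L) {
    gshare <- loci[[1L]]$g
    for (k in seq_len(K)) loci[[k]]$g <- gshare
  }
  if (!is.null(divergence)) {
    if (!is.list(divergence) || is.null(divergence$c) || is.null(divergence$t))
      stop("divergence must be list(c = ..., t = ...)")
    if (divergence$c <= 0 || divergence$t < 0)
      stop("require c > 0 and t >= 0")
    divergence <- list(c = as.numeric(divergence$c),
                       t = as.numeric(divergence$t))
  }
  structure(list(epochs = epochs, loci = loci, shared_g = isTRUE(shared_g),
                 divergence = divergence, ref = ref),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  K <- length(x$loci); H <- x$epochs$H
  cat(sprintf("Stepwise demographic model: %d %s, %d %s%s\n",
              H, if (H == 1) "epoch" else "epochs",
              K, if (K == 1) "locus" else "loci",
              if (x$shared_g) " (shared g)" else ""))
  if (H > 1)
    cat("  tau:", paste(signif(x$epochs$tau, 4), collapse = ", "), "\n")
  if (!is.null(x$divergence))
    cat(sprintf("  divergence: c = %.4g, t = %.4g\n",
                x$divergence$c, x$divergence$t))
  th <- vapply(x$loci, `[[`, numeric(1), "theta")
  f <- vapply(x$loci, `[[`, numeric(1), "f")
  cat(sprintf("  theta in [%.3g, %.3g], f in [%.3g, %.3g], ref locus %d\n",
              min(th), max(th), min(f), max(f), x$ref))
  invisible(x)
}

## internal: flat parameter state used by the likelihood engine
.state_from_model <- function(model) {
  K <- length(model$loci)
  H <- model$epochs$H
  list(
    theta = vapply(model$loci, `[[`, numeric(1), "theta"),
    f     = vapply(model$loci, `[[`, numeric(1), "f"),
    g     = if (H > 1L)
      matrix(unlist(lapply(model$loci, `[[`, "g")), nrow = K, byrow = TRUE)
      else matrix(0, K, 0L),
    tau   = model$epochs$tau,
    eps   = vapply(model$loci, `[[`, numeric(1), "epsilon"),
    m     = vapply(model$loci, `[[`, numeric(1), "m"),
    c     = if (!is.null(model$divergence)) model$divergence$c else NA_real_,
    t     = if (!is.null(model$divergence)) model$divergence$t else NA_real_)
}

## internal: write a flat state back into a model_spec
.model_from_state <- function(model, state) {
  K <- length(model$loci)
  for (k in seq_len(K)) {
    model$loci[[k]]$theta <- state$theta[k]
    model$loci[[k]]$f <- state$f[k]
    if (model$epochs$H > 1L) model$loci[[k]]$g <- as.numeric(state$g[k, ])
    model$loci[[k]]$epsilon <- state$eps[k]
  }
  model$epochs <- epoch_model(state$tau)
  if (!is.na(state$c))
    model$divergence <- list(c = state$c, t = state$t)
  model
}
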