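# X-versus-autosome convenience layer.
#
# A two-locus, two-epoch model with the X chromosome as the reference locus,
# reparameterized in the quantities population geneticists compare:
# r2 = N_X / N_A in the ancient epoch, r1 the same ratio in the current
# epoch, gX1 the X size multiplier, tau1 the scaled time of the change.
# The mapping to the general model is f_A = 1/r2 and g_{A,1} = gX1 * r2 / r1.
# No [9/16, 9/8] clamp is imposed on r1 or r2: deviations from 3/4 may
# reflect sex-ratio bias, variance in reproductive success, or linked
# selection, not only the mode of inheritance.

#' X-autosome parameter set
#'
#' @param thetaX,thetaA Scaled mutation rates of the X-linked and autosomal
#'   compartments, both defined against `N_X` (the reference).
#' @param r1,r2 X/A ratio of `N_e` in the current and the ancient epoch.
#' @param gX1 X epoch-1 size multiplier.
#' @param tau1 Scaled time of the size change (units `2 N_X` generations).
#' @param epsX,epsA Optional polarization-error probabilities.
#' @return An object of class `"xa_params"`.
#' @export
xa_params <- function(thetaX, thetaA, r1, r2, gX1, tau1,
                      epsX = 0, epsA = 0) {
  vals <- c(thetaX = thetaX, thetaA = thetaA, r1 = r1, r2 = r2,
            gX1 = gX1, tau1 = tau1)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all X-autosome parameters must be finite and > 0")
  structure(as.list(c(vals, epsX = epsX, epsA = epsA)), class = "xa_params")
}

#' @export
print.xa_params <- function(x, ...) {
  v <- unlist(x[c("thetaX", "thetaA", "r1", "r2", "gX1", "tau1")])
  cat("X-autosome parameters:\n")
  print(signif(v, 4))
  if (x$epsX > 0 || x$epsA > 0)
    cat(sprintf("  polarization error: epsX = %.3g, epsA = %.3g\n",
                x$epsX, x$epsA))
  invisible(x)
}

#' Map X-autosome parameters to the general two-locus model
#'
#' Locus 1 is the X chromosome (reference, `f = 1`), locus 2 the autosomes
#' with `f_A = 1/r2` and `g_{A,1} = gX1 * r2 / r1`.
#'
#' @param p An [xa_params()].
#' @param m Length-2 vector of compartment lengths in bp (X, A).
#' @param divergence Optional `list(c, t)` passed through to the model.
#' @return A [model_spec()] with two loci and two epochs.
#' @export
xa_to_general <- function(p, m = c(5e6, 5e6), divergence = NULL) {
  if (!inherits(p, "xa_params")) stop("p must be an xa_params object")
  model_spec(
    epoch_model(p$tau1),
    list(locus_model(p$thetaX, f = 1, g = p$gX1, m = m[1L],
                     epsilon = p$epsX),
         locus_model(p$thetaA, f = 1 / p$r2, g = p$gX1 * p$r2 / p$r1,
                     m = m[2L], epsilon = p$epsA)),
    divergence = divergence, ref = 1L)
}

#' Recover X-autosome parameters from a general two-locus model
#'
#' Inverse of [xa_to_general()]; exact round-trip.
#'
#' @param model A two-locus, two-epoch [model_spec()] with locus 1 = X as
#'   reference.
#' @return An [xa_params()].
#' @export
general_to_xa <- function(model) {
  if (length(model$loci) != 2L || model$epochs$H != 2L || model$ref != 1L)
    stop("expected a two-locus, two-epoch model with locus 1 as reference")
  X <- model$loci[[1L]]; A <- model$loci[[2L]]
  r2 <- 1 / A$f
  xa_params(thetaX = X$theta, thetaA = A$theta,
            r1 = X$g[1L] * r2 / A$g[1L], r2 = r2,
            gX1 = X$g[1L], tau1 = model$epochs$tau[1L],
            epsX = X$epsilon, epsA = A$epsilon)
}

## template model for fitting XA data (values are placeholders; fit() draws
## its own starts)
.xa_template <- function(data, fit_epsilon = FALSE) {
  if (nrow(data$counts) != 2L)
    stop("X-autosome analyses need exactly two loci (X first)")
  xa_to_general(xa_params(1e-3, 1e-3, 0.75, 0.75, 2, 0.2), m = data$m)
}

#' X-autosome likelihood ratio tests
#'
#' Fits the full two-locus model once and each requested nested null, and
#' returns the likelihood ratio tests:
#' * `"mutation_rate"`: equal mutation rates, `thetaX = thetaA` (df 1);
#' * `"ne_ratio_075"`: neutral X/A ratio in both epochs, `r1 = r2 = 3/4`
#'   (df 2);
#' * `"ratio_change"`: constant ratio across epochs, `r1 = r2` (df 1).
#'
#' In general-model coordinates the nulls are, respectively, a tie
#' `theta_1 = theta_2`; a pin `f_2 = 4/3` plus tie `g_{2,1} = g_{1,1}`; and
#' the tie `g_{2,1} = g_{1,1}` alone.
#'
#' @param data A two-locus [sfs_dataset()] (X first).
#' @param tests Character vector of test names (default: all three).
#' @param fit_epsilon Estimate per-compartment polarization errors.
#' @param ... Passed to [fit()] (`n_starts`, `seed`, `use_profile`, ...).
#' @return A named list of `"sfs_lrt"` objects sharing one full fit.
#' @export
xa_tests <- function(data, tests = c("mutation_rate", "ne_ratio_075",
                                     "ratio_change"),
                     fit_epsilon = FALSE, ...) {
  tests <- match.arg(tests, several.ok = TRUE)
  model <- .xa_template(data)
  full <- fit(data, model, fit_epsilon = fit_epsilon, ...)
  defs <- list(
    mutation_rate = list(
      cs = constraint_set(ties = list(c("theta[1]", "theta[2]"))), df = 1L),
    ne_ratio_075 = list(
      cs = constraint_set(pins = c("f[2]" = 4 / 3),
                          ties = list(c("g[1,1]", "g[2,1]"))), df = 2L),
    ratio_change = list(
      cs = constraint_set(ties = list(c("g[1,1]", "g[2,1]"))), df = 1L))
  out <- list()
  for (tn in tests) {
    null <- fit(data, model, constraints = defs[[tn]]$cs,
                fit_epsilon = fit_epsilon, ...)
    out[[tn]] <- lrt(full, null, df = defs[[tn]]$df)
  }
  attr(out, "full") <- full
  out
}

#' @rdname xa_tests
#' @export
test_mutation_rate <- function(data, ...)
  xa_tests(data, tests = "mutation_rate", ...)[["mutation_rate"]]

#' @rdname xa_tests
#' @export
test_ne_ratio_075 <- function(data, ...)
  xa_tests(data, tests = "ne_ratio_075", ...)[["ne_ratio_075"]]

#' @rdname xa_tests
#' @export
test_ratio_change <- function(data, ...)
  xa_tests(data, tests = "ratio_change", ...)[["ratio_change"]]
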