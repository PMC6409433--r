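# Study designs used across tests: a two-locus X/A expansion model, a
# two-locus X/A contraction model, the 20-locus heterogeneous shared-g
# design with divergence, and gamma-distributed locus parameters.

xa_expansion <- function(m = 5e6)
  xa_to_general(xa_params(thetaX = 5.25e-4, thetaA = 7.5e-4,
                          r1 = 0.65, r2 = 0.75, gX1 = 10, tau1 = 0.1),
                m = c(m, m))

xa_contraction <- function(m = 5e6)
  xa_to_general(xa_params(thetaX = 5.25e-4, thetaA = 7.5e-4,
                          r1 = 0.9, r2 = 0.75, gX1 = 0.2, tau1 = 0.05),
                m = c(m, m))

grid20_design <- function(divergence = TRUE)
  model_spec(epoch_model(0.5),
             linear_grid_design(20, theta1 = 0.01, theta_ratio = 5,
                                f1 = 1, f_ratio = 5, m = 5000, g = 10),
             shared_g = TRUE,
             divergence = if (divergence) list(c = 2, t = 8) else NULL)

gamma_truth <- function(K, seed, t = 6)
  model_spec(epoch_model(0.5),
             gamma_design(K, m = 10000, g = 10, seed = seed),
             shared_g = TRUE, divergence = list(c = 2, t = t))

## fitting templates (values are placeholders; structure is what matters)
grid20_template <- function(divergence = TRUE)
  model_spec(epoch_model(0.3),
             linear_grid_design(20, theta1 = 1e-3, theta_ratio = 2,
                                f1 = 1, f_ratio = 2, m = 5000, g = 2),
             shared_g = TRUE,
             divergence = if (divergence) list(c = 1, t = 5) else NULL)

gamma_template <- function(K)
  model_spec(epoch_model(0.3), gamma_design(K, m = 10000, g = 2, seed = 1),
             shared_g = TRUE, divergence = list(c = 1, t = 5))

## small equilibrium fixture: one locus, constant size
tiny_eq_model <- function(theta = 0.001, m = 1000)
  model_spec(epoch_model(), list(locus_model(theta, m = m)))
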