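---
title: "Stepwise demography and between-locus heterogeneity from site-frequency spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise demography and between-locus heterogeneity from site-frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfsdem)
```

## The model

`sfsdem` fits multilocus site-frequency-spectrum (SFS) data under a
Poisson random field (PRF) model in which the population size changes in a
stepwise manner while both the effective population size and the mutation
rate vary between loci.

Going backward in time there are $H$ epochs; epoch 1 is the most recent and
epoch $H$ extends indefinitely into the past.  All scaled parameters are
defined against the reference locus (by default locus 1) in the most
distant epoch, whose effective size is $N_1$:

* $\tau_h = T_h / (2 N_1)$ — scaled duration of epoch $h$ ($1 \le h < H$),
  shared by all loci (the demographic events are genome-wide);
* $\theta_k = 4 N_1 u_k$ — scaled mutation rate per site at locus $k$.
  Because every $\theta_k$ is scaled by the same $N_1$, the values are
  directly comparable across loci and carry the mutation-rate signal;
* $f_k$ — the ratio of locus $k$'s effective size to $N_1$ in epoch $H$
  ($f_{\mathrm{ref}} \equiv 1$).  Differences in $f_k$ may reflect the mode
  of inheritance (X vs autosomes) or selection at linked sites;
* $g_{k,h}$ — the size of locus $k$ in epoch $h$ relative to its epoch-$H$
  size ($g_{k,H} \equiv 1$ is implicit and never stored).

Absolute quantities ($N_1$, $u_k$, times in generations) are deliberately
not represented: only their scaled composites are estimable.

The expected number of segregating sites with derived-allele count $i$ in a
sample of $n$ alleles is
$$\psi_{k,i} = m_k\,\theta_k\,\varphi_{k,i}, \qquad
  \varphi_{k,i} = f_k\!\left[\frac{g_{k,1}}{i} + A_{k,i}\right],$$
where $m_k$ is the locus length in bp and $A_{k,i}$ is a sum over epochs of
exponentially decaying corrections,
$$A_{k,i} = \sum_{h=1}^{H-1} (g_{k,h+1} - g_{k,h})
  \sum_{j=2}^{n} e^{-\binom{j}{2} \sum_{l \le h} \tau_l / (f_k g_{k,l})}
  B_i(j).$$
At equilibrium ($H = 1$, or all $g = 1$, or $\tau \to \infty$) this
collapses to the familiar $\psi_i \propto 1/i$ shape.  The PRF assumption
(infinite sites, free recombination) makes the class counts independent
Poisson variables, so the composite log-likelihood is
$\sum_{k,i} [-\psi_{k,i} + d_{k,i} \log \psi_{k,i}]$ up to a data-only
constant that the package always omits — reported log-likelihoods are
comparable only across models on fixed data, which is exactly what
likelihood ratio tests require.

### Branch-length weights

The weights $B_i(j)$ — the probability that a line ancestral to $i$ sample
members existed while $j$ lines were present, divided by $j(j-1)$ — have a
closed-form alternating sum whose terms cancel catastrophically in floating
point (hundreds of significant digits would be needed at $n = 1000$).  The
package therefore evaluates them with the numerically stable
Polanski–Kimmel recursion (`branch_weights()`), which runs in ordinary
double precision, and retains the direct sum (`branch_weight_direct()`) as
an independent oracle implemented in exact big-integer arithmetic over a
common denominator, rounding only in the final conversion to double.  The
two routes agree to better than $10^{-10}$ relative for every weight above
$10^{-8}$ of the spectrum scale at $n \le 40$; entries that decay below the
double-precision absolute resolution ($\sim 10^{-16}$) can carry no
relative guarantee in any double-precision scheme, and contribute nothing
detectable to a spectrum.  The identity $\sum_j B_i(j) = 1/i$ holds to
$10^{-6}$ relative at $n = 1000$.

### Folding, polarization error, divergence

When ancestral states are unavailable the folded spectrum
$\Psi_i = \psi_i + \psi_{n-i}$ ($i < n - i$) is used.  Alternatively,
polarization error is modelled explicitly: with per-locus error probability
$\epsilon_k$, class $i$ is misassigned to $n - i$, giving
$\psi^*_i = (1 - \epsilon_k)\psi_i + \epsilon_k \psi_{n-i}$.  Both
operations conserve the spectrum total; $\epsilon$ is restricted to
$[0, 0.5]$ because beyond $0.5$ the model is a relabelling of
$1 - \epsilon$, and it cannot be estimated from folded data (the folded
spectrum carries no polarization information — the package refuses the
combination).

Divergence to a single outgroup sequence adds Poisson substitution counts
with mean $\lambda_k = m_k \theta_k (c f_k + t)$: the $c f_k$ term is
ancestral polymorphism (ancestral population of size $c f_k N_1$), $t$ the
scaled split time.  This is a deliberately simple divergence model — no
substitution-model corrections, no lineage effects — whose purpose is to
anchor the mutation-rate scale; $c$ and $t$ are informed by
*between-locus variation* in divergence, so they are poorly identified
with few loci.

## Fitting

`fit()` maximizes the likelihood by multi-start quasi-Newton optimization
(`stats::nlminb`, PORT) with analytic gradients.  Positive parameters are
optimized on the log scale and $\epsilon$ on a scaled logit over
$(0, 0.5)$, so all constraints are implicit and the search is smooth and
unconstrained.  Gradient formulas were derived by differentiating
$\psi_{k,i}$ directly; the test suite verifies every variant (full,
profile, folded, polarization-error, divergence) against central finite
differences.

By default the mutation rates are concentrated out analytically.  Because
$\theta_k$ enters both $\psi_k$ and $\lambda_k$ linearly, the conditional
MLE given the shape parameters is available in closed form,
$$\hat\theta_k = \frac{S_k + x_k}{m_k(\varphi_k + c f_k + t)},$$
reducing to the Watterson-type $S_k / (m_k \varphi_k)$ without divergence
($S_k$ = segregating sites, $\varphi_k = \sum_i \varphi_{k,i}$; totals are
conserved by folding and polarization error, so the same formula applies
there).  By the envelope theorem the gradient of the concentrated
likelihood is the partial gradient at $\hat\theta$, so this removes one
dimension per locus at no cost: the 500-locus divergence model drops from
1003 to 502 free parameters.  `loglik_profile()` exposes the equivalent
multinomial (shape-only) form, which differs from the concentrated full
likelihood by a data-only constant.

Starts: 20 points drawn uniformly in log-space boxes ($\theta \in
[10^{-5}, 0.1]$, $f \in [0.05, 20]$, $g \in [0.05, 50]$, $\tau \in
[10^{-3}, 10]$, $c \in [0.1, 10]$, $t \in [0.1, 50]$) plus two data-driven
points (Watterson-type $\theta$, diversity-ratio $f$, one mild-expansion
and one mild-contraction guess for $g$).  The data-driven starts are a
design choice of this package: they make the common case converge in the
first one or two starts while the random starts guard against multimodal
surfaces.  Ties within $10^{-6}$ log-units are broken first-found, all
starts are logged, and fits are bitwise reproducible given `(data, seed)`.
When no start converges, `fit()` returns a failure result rather than
raising.

Constraints (`constraint_set()`) are applied by substitution — tied slots
share one free parameter, pinned slots are eliminated — never by
penalties, so nested-model likelihood comparisons are exact.

## The X-autosome layer

For two-compartment comparisons the package reparameterizes the general
two-locus, two-epoch model in the quantities of interest: $r_2 = N_X/N_A$
in the ancient epoch, $r_1$ the same ratio currently, $g_{X,1}$ and
$\tau_1$ the size change, with $f_A = 1/r_2$ and
$g_{A,1} = g_{X,1} r_2 / r_1$.  Three likelihood ratio tests are built in:
equal mutation rates ($\theta_X = \theta_A$, df 1), neutral ratio in both
epochs ($r_1 = r_2 = 3/4$, df 2), and constant ratio ($r_1 = r_2$, df 1).
No $[9/16, 9/8]$ clamp is imposed on the ratios: linked selection,
sex-biased demography and mate-pairing practices can push $N_X/N_A$
outside the range that sex-ratio distortion alone allows.  Asymptotic
chi-square p-values are the default; `bootstrap_pvalue()` provides a
parametric-bootstrap alternative for small samples.

## The simulator and what passing tests show

`simulate_usfs()` draws each class count as an independent Poisson with
mean $\psi^*_{k,i}$ — exactly the PRF model the likelihood assumes, i.e.
free recombination between sites.  Real data violate this through linkage
(which leaves PRF point estimates consistent but makes the composite
likelihood overconfident), through selection at linked sites beyond what a
locus-specific $f_k$ absorbs, and through non-equilibrium substitution
processes in the outgroup comparison.  Passing the simulation studies
therefore demonstrates correctness of the estimator under its own
assumptions — unbiased recovery, test calibration and power — not
robustness to linked-site effects; for real data, the bootstrap over loci
(`bootstrap_ci()`, resampling within strata such as X vs autosomes) is the
appropriate uncertainty measure because it respects within-locus linkage.

Two locus-parameter designs used throughout the package's studies are
provided: a linear grid ($\theta_1/\theta_K = 5$ falling, $f_K/f_1 = 5$
rising — strong, structured heterogeneity in a small panel) and
independent gamma draws ($\theta_k \sim \Gamma(3, \text{scale } 0.005)$,
$f_k \sim \Gamma(5, \text{scale } 0.2)$, means 0.015 and 1 — genome-scale
heterogeneity).  In the gamma design the reference locus keeps $f_1 = 1$:
drawing it too would redefine the reference scale of every scaled
parameter by a random factor (and bias time-like estimates by
$E[1/f_1] = 1.25$), which is a property of the parameterization, not of
the biology.

### The pooled-fit bias demonstration

Summing the 20 heterogeneous spectra and fitting a single-locus one-step
model (`fit_pooled()`) yields a sharply concentrated but biased answer:
across replicates the pooled $\hat g_1$ averages $\approx 9.3$ (truth 10)
with an interval that excludes the truth, while the joint shared-$g$ model
recovers $g_1 = 10$ without bias.  The pooled fit's time-like parameter
deserves a caution: its time unit is the pooled data's *own* ancestral
size, which the high-$f$ loci inflate roughly threefold relative to the
reference locus, so its $\hat\tau$ is not commensurable with the
reference-scaled truth without an external mutation-rate anchor.  The
package reports the pooled estimator in its own self-contained scale.

## Numerical choices

* Exponentials in $A_{k,i}$ use precomputed cumulative sums
  $\sum_{l \le h} \tau_l/(f_k g_{k,l})$; values underflow harmlessly to 0
  for ancient epochs.
* $0 \log 0 = 0$ for empty classes; $\psi = 0$ with $d > 0$ yields
  $-\infty$ (an impossible-data signal the optimizer treats as an
  infeasible region, not an error).
* Optimizer tolerances: relative function tolerance $10^{-12}$, parameter
  tolerance $10^{-10}$, at most 1000 iterations per start.
* Branch-weight tables are cached per sample size (pure functions of $n$).
* Replicate harnesses and bootstraps derive per-task seeds from the master
  seed by index: results are identical for any worker count
  (`workers > 1` uses forked `parallel::mclapply`).

### Problem sizes of the shipped studies

The packaged tests and the `scripts/acceptance.R` harness run the
simulation studies at desk scale, a choice made once when the studies were
set up: 30–50 replicates for the two-locus X/A models ($n = 100$, 5 Mb per
compartment), 30 replicates of the 20-locus grid design, and 10 replicates
of the gamma design at 100 loci ($n = 50$, 10 kb).  Monte-Carlo tolerances
are three standard errors of a difference of means at these replicate
counts, using the study-reported standard deviations (scaled by
$\sqrt{500/K}$ where the locus count is reduced).  Larger runs only
tighten the comparisons.

## Worked example

```{r example, eval = FALSE}
library(sfsdem)

## truth: X/A comparison with expansion, X mutating 30% slower
truth <- xa_to_general(
  xa_params(thetaX = 5.25e-4, thetaA = 7.5e-4,
            r1 = 0.65, r2 = 0.75, gX1 = 10, tau1 = 0.1),
  m = c(5e6, 5e6))
data <- simulate_dataset(truth, n = 100, seed = 1)

fitted <- fit(data, xa_to_general(xa_params(1e-3, 1e-3, 0.75, 0.75, 2, 0.2),
                                  m = data$m), n_starts = 6, seed = 1)
general_to_xa(fitted$model)

## is the mutation rate different between X and autosomes?
test_mutation_rate(data, n_starts = 6, seed = 1)
```

## Known limitations

* Stepwise size changes only — no continuous growth epochs, migration or
  selection models.
* The composite likelihood ignores linkage: p-values on real data should
  come from the locus bootstrap, not the asymptotic chi-square, whenever
  linkage within loci is non-negligible.
* The divergence model is a single-sequence Poisson count with no
  substitution-model correction; distant outgroups or evolving mutation
  spectra will bias $c$ and $t$.
* Separating $\theta_k$ from $f_k$ needs non-equilibrium information; as
  $1/(f_k g_1) \to 0$ the two parameters form a likelihood ridge and only
  their product is estimable.  Divergence data mitigate but do not remove
  this.
* Estimating the current-epoch size ratio from small samples is fragile
  when very recent events are involved; ancient-epoch quantities and the
  mutation-rate ratio are more robust.
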