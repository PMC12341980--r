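---
title: "Spectral-expansion surrogates for parameter uncertainty in biological models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-expansion surrogates for parameter uncertainty in biological models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectralUQ)
```

## The problem and the model

A deterministic model of a biological system — an ODE network, a
reaction-diffusion lattice, a population balance — maps a parameter
vector to a response $Y$. When the parameters are uncertain, each with a
distribution $P_l(\theta_l)$, the object of interest is the distribution
of $Y$. Monte-Carlo propagation needs thousands of model runs; the
spectral-expansion (SE) surrogate replaces them with a handful.

The response is written in a basis orthonormal with respect to the
parameter distribution,
$$Y^s(\theta) = \sum_{n=0}^{N-1} c_n\,\phi_n(\theta),$$
Legendre polynomials for uniform parameters, probabilists' Hermite for
normal and lognormal (after an isoprobabilistic transform), Charlier for
Poisson counts, or Haar wavelets composed with the parameter's CDF when
the response bifurcates. "Order $N$" throughout means $N$ basis
functions (degrees $0$ to $N-1$), an $N \times N$ operator matrix, $N$
nodes, and $N$ model evaluations per dimension; multivariate responses
use the tensor product, $N^M$ evaluations for $M$ parameters.

Instead of computing the $c_n$ by explicit quadrature, the package
eigendecomposes the symmetric matrix of the multiplication operator,
$$\hat B_{nm} = \int \phi_n(\theta)\,\theta\,\phi_m(\theta)\,P(\theta)\,
  d\theta,$$
which is tridiagonal for the polynomial families (off-diagonals
$n/\sqrt{(2n-1)(2n+1)}$ for Legendre, $\sqrt{n}$ for Hermite; Charlier
has diagonal $n+\lambda$ and off-diagonal $-\sqrt{n\lambda}$). Its
eigenvalues $\lambda^{(l)}$ are the model-evaluation nodes and the
squared first eigenvector components $(u_1^{(l)})^2$ the quadrature
weights — for polynomial bases exactly the classical Gauss rule, which
the test suite verifies against an independent root-finding oracle up to
order 12. The surrogate is then
$$Y^s(\theta) = \sum_{l=1}^{N} Y(\lambda^{(l)})\,u_1^{(l)}\,
  \psi_l^s(\theta), \qquad
  \psi_l^s(\theta) = \sum_{n} u_{n+1}^{(l)} \phi_n(\theta),$$
and the mean and variance of the response are read directly off the
coefficients (mean $= c_0$, variance $= \sum_{n \ne 0} c_n^2$), as are
Sobol sensitivity indices.

```{r decay}
spec <- param_spec("k", "lognormal", mean = 0.5, sd = 0.2)
s <- se_fit(function(p) exp(-p[["k"]]), spec, order = 5)
se_moments(s)
```

## Tunable parameters that matter

* **Expansion order `N`** (unitless, default none — set per study).
  Polynomial exactness holds through per-dimension degree $N-1$; smooth
  responses converge spectrally, responses with bifurcations do not
  (Gibbs oscillation). The worked studies use $N=5$ (exponential decay),
  $N=10$ (glycolytic oscillator), $N=6$ (correlated plasmid counts).
* **Segmentation granularity `M`** (unitless, default 0). The standard
  interval $[-L, L]$ is split into $2M+1$ equal segments by the affine
  map $g_m(\theta) = 2mL/(2M+1) + \theta/(2M+1)$, with an independent
  order-$N$ expansion per segment tuple; fitting costs
  $(2M+1)^K N^K$ model runs and reconstruction sums $N^K$ terms after an
  $O(K)$ segment lookup, against $N^K$ runs but far larger per-query
  sums for one global high-order expansion — `eval_cost()` tabulates
  both. `M = 0` reduces exactly to the unsegmented surrogate.
* **Truncation half-width `L`** (standard-variable units; 1 for uniform
  dims). Unbounded (Hermite) dimensions must be truncated before they
  can be segmented. The package default is the conservative `L = 5`
  (normal tail mass $6\times10^{-7}$). For the dimer-network study
  (order 3, granularity 1) we instead use `L = 3`: the within-segment
  Gauss nodes sit at $\pm\sqrt{3}$ of the compressed variable, so a
  smaller half-width keeps reconstruction interpolatory (queries inside
  the node span) over the range that carries 99.7% of each lognormal
  parameter's mass, where `L = 5` would extrapolate. This choice is a
  property of the method geometry, fixed before any accuracy comparison.
* **Haar resolution level `J`** (unitless). Level $J$ keeps the constant
  plus all wavelets with scale $j \le J$: $2^{J+1}$ basis functions
  (level 3 → 16, level 6 → 128). The Haar expansion on a uniform
  parameter is exactly the piecewise-constant interpolant on $2^{J+1}$
  dyadic cells — robust at bifurcation boundaries where polynomials
  oscillate.
* **QMC sample size and blocks** (`mc_reference`): Sobol-sequence
  sampling with a seeded digital-shift scramble; error bars from the
  blocking method with 16 blocks by default (the block count is a
  convention, not a fitted quantity).
* **KDE bandwidth**: Silverman's robust rule
  $h = 0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$.

## Correlated counts

For two correlated plasmid counts the package uses a bivariate Poisson
with Poisson($\lambda$) marginals and correlation $\xi/\lambda$,
evaluated by the trivariate-reduction series with normalization
$e^{-(2\lambda-\xi)}$. The printed closed form in terms of Kummer's $U$
function circulates with a typographically corrupted exponent; the
series form is taken as primary because it normalizes to 1, has exact
Poisson marginals, and reproduces the correlation identity, and the
corrected $U$-form (via generalized Laguerre polynomials) is kept only
as a cross-validation oracle in the tests.

The correlated expansion transforms the tensor basis by
$\sqrt{P_1 P_2 / P_{12}}$ and weights node responses by
$\omega_{l_1 l_2} = \sum \sqrt{P_1 P_2 P_{12}}\,\psi_{l_1}\psi_{l_2}$
(the expectation of the transformed basis under the joint law). At
$\xi = 0$ this collapses exactly to the independent tensor-product
scheme. Two caveats a user should know:

* the $\sqrt{P_1 P_2/P_{12}}$ prefactor amplifies truncation error
  wherever the joint mass is tiny, so pointwise accuracy is only
  meaningful over the distribution's bulk (compositions with, say,
  $\ge 1\%$ probability, which carry ~90% of the mass at
  $\lambda = 3, \xi = 2.4$);
* convergence in $N$ is slow for strong correlation: at order 6 the
  per-cell reporter expansion agrees with direct solutions to about 7%
  of the response scale over the bulk, improving only gradually with
  order. This is a property of the scheme (the optimal projection onto
  the transformed basis carries a comparable floor), not of the
  implementation, which the tests pin against brute-force evaluation of
  the defining sums.

## The example systems as study conditions

The six fixtures are first-class, deterministic, seed-controlled models;
their defaults are the study conditions and are not adjusted per run.

1. **Exponential decay** $A(t) = A_0 e^{-kt}$,
   $k \sim$ Lognormal(mean 0.5, sd 0.2) — parameterized by arithmetic
   mean and sd. The response PDF is available in closed form by change
   of variables, the reference for the sampled-surrogate KDE.
2. **Dimerization network** — two proteins (production rates $k_1, k_4$)
   bind reversibly ($k_2$, $k_3$) into a dimer, all species degrade at
   $k_5$; lognormal rates, mean 0.1 (sd 0.1) for $k_1, k_4, k_5$ and
   mean 0.4 (sd 0.1) for $k_2, k_3$; zero initial conditions, responses
   on $t \in [0, 40]$ h sampled every 2 h (21 points capture the
   relaxation at rate $k_5 \approx 0.1$). The identity
   $d(x_1+x_3)/dt = k_1 - k_5 (x_1 + x_3)$ is an exact mass-balance test
   of the integrator.
3. **Glycolytic oscillator** (ADP/F6P with negative feedback) —
   $\alpha \sim U(0.1, 0.5)$, $\beta \sim$ Lognormal(0.3, 0.1); a mixed
   Legendre × Hermite expansion straddling the Hopf bifurcation:
   $(\alpha, \beta) = (0.1, 0.46)$ oscillates, $(0.5, 0.46)$ decays to
   the fixed point $(\beta, \beta/(\alpha+\beta^2))$.
4. **Schnakenberg reaction-diffusion line** — 20 cells, zero-flux
   boundaries (the standard choice for a cut-out tissue strip; the
   boundary rule is exposed in code), $\beta = 1$, $\gamma = 5$,
   $d = 20$, $\alpha \sim U(0.001, 0.45)$. Initial condition:
   homogeneous steady state times $(1 + 1\%$ seeded noise$)$; steady
   state declared when the relative $L_\infty$ change over a 10-unit
   window falls below $10^{-6}$. Linear stability on the discrete
   Laplacian spectrum places the Turing boundary between
   $\alpha = 0.23$ and $0.24$; the converged pattern at $\alpha = 0.22$
   has a substrate coefficient of variation of 0.077 across cells
   (activator: 0.18) against under $2\times10^{-7}$ outside — the
   tests assert this four-orders-of-magnitude contrast rather than a
   particular amplitude, which depends on distance to the boundary.
5. **Trichome patterning** — the substrate-depletion model of leaf-hair
   initiation on a periodic 20 × 20 hexagonal lattice (1200 ODEs).
   Only the substrate TTG1 diffuses. The non-dimensional rates other
   than the uncertain basal production $\alpha \sim U(0.4, 0.9)$ are
   not fixed by the source text; we set turnover $\lambda = 0.3$,
   diffusion $\delta = 2$, activation $\beta = 6$ by a numeric
   Turing-space scan so that the patterning boundary
   ($\alpha \approx 0.63$) falls inside the studied range — the
   response distribution then genuinely mixes a no-pattern atom at
   density 0 (~55% of the mass) with a continuous patterned part,
   which is the feature the Haar expansion is meant to handle. The
   trichome density is the fraction of cells whose activating-complex
   level exceeds the field's half-maximum (the biological threshold
   being unknown). Because the offset-row periodic wrap is not a pure
   triangular torus, mode eigenvalues come from the lattice operator
   itself (memoized), not a closed formula.
6. **Plasmid transfection** — per-cell reporter pools
   $x_{nm}, y_{nm}$ driven by $n$ induction and $m$ reporter plasmids
   (production 2 and 6 per plasmid-hour, turnover 2 and 1.5 per hour,
   saturation $\eta$, secretion $\kappa \in \{0, 3\}$), a cell-pool
   tensor $Q_{nm}$ growing logistically with binomial plasmid
   partitioning at division (growth 0.034 h$^{-1}$, equal split
   $q = 0.5$), and bivariate-Poisson uptake. The source text fixes
   $\eta = 0.2$ while its figure captions print $\eta = 0.5$; the
   fixture default follows the captions (0.5) since those label the
   comparisons we reproduce, and the expansion accuracy is insensitive
   to the choice. Division transients of $y_{nm}$ are ignored (steady
   state is reached in ~4 h against a 20 h doubling time).

## What the generators emulate — and what they do not

All fixtures are deterministic ODE/PDE models with parametric
uncertainty only: gene-expression noise, reporter maturation, stochastic
(Gillespie) dynamics, measurement error, and non-stationary parameter
drift are all absent. Passing tests therefore demonstrate that the
surrogate machinery propagates *parameter* uncertainty correctly through
models with the right qualitative difficulties (stiffness, bifurcations,
spatial discontinuity, correlated discrete inputs); they say nothing
about intrinsic-noise regimes, and real data would add observation noise
that none of the acceptance comparisons model.

## Numerical choices

* $\hat B$ by quadrature: continuous weights use Gauss–Legendre on the
  (truncated) support with order-doubling until entries move less than
  $10^{-8}$; discrete weights use tail-extended summation (the Poisson
  tail is extended until the matrix stabilizes, since high-degree
  Charlier polynomials grow polynomially); the Haar matrix integrates
  the quantile function exactly per dyadic cell. Every matrix is
  symmetrized by averaging with its transpose.
* Eigenvectors are sign-fixed so the first component is non-negative; a
  first component below $10^{-12}$ triggers a degeneracy warning (the
  term contributes nothing to the expansion).
* Node tuples iterate column-major (first dimension fastest, ascending
  nodes), the R array convention; the ordering is stored with the
  object.
* Segment boundaries are right-open except the topmost segment, and the
  index formula is clamped so $y = \pm L$ maps to the outer segments.
* Non-finite model output aborts a fit with the offending physical
  parameter values in the error message; bifurcating responses are
  expected to be gated (the trichome density response returns 0 outside
  the Turing space rather than failing).
* The Sobol "first-order" index uses multi-indices exclusive to one
  dimension; `sobol_total_like()` implements the looser
  any-index-active sum so both readings of the variance bookkeeping are
  available. Output components with zero variance (for instance a fixed
  initial condition inside a time course) get `NA` indices; a fully
  constant model is an error.
* No QMC generator exists in the package's R dependency set, so the
  Sobol sequence is implemented directly (Gray-code construction,
  Joe–Kuo direction numbers, up to 10 dimensions) and pinned in the
  tests against externally computed reference points.

## Problem sizes used in the shipped studies

The packaged analyses are sized to the published study conditions:
the dimer comparison runs the full $59{,}049$-evaluation segmented fit
(order 3, granularity 1, five parameters); the reaction-diffusion
budget check runs the actual 126-evaluation segmented Legendre fit of
the 20-cell steady state; the trichome comparison uses resolution
level 3 (16 wavelets) with 1000 surrogate samples, sharing one set of
patterning simulations between the direct and indirect readings; KDE
comparisons use $10^5$ samples.

## Known limitations

* Segmentation of unbounded dimensions inherits the truncation `L`:
  mass outside $[-L, L]$ is clamped to the boundary segment, and
  within-segment Hermite orthonormality is only approximate.
* The correlated-parameter scheme covers the printed bivariate case;
  general $M$-parameter dependence and continuous correlated families
  are out of scope, and its slow convergence under strong correlation
  is documented above.
* Sparse/adaptive bases, leave-one-out stopping rules, and intrusive
  projection are out of scope; expansion order is chosen by the user.
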