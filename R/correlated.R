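#' Bivariate Poisson distribution for correlated plasmid uptake
#'
#' Joint distribution of two plasmid counts `(n, m)` with common mean
#' uptake `lambda`, Poisson(`lambda`) marginals, and Pearson correlation
#' `xi / lambda` (`0 <= xi <= lambda`). Constructed by trivariate
#' reduction: `n = n0 + z`, `m = m0 + z` with independent Poisson
#' components of means `lambda - xi`, `lambda - xi`, `xi`.
#'
#' @param lambda Mean number of plasmids taken up (`> 0`).
#' @param xi Correlation parameter in `[0, lambda]`; `xi = 0` gives
#'   independent marginals.
#' @param tail Truncation tail mass for the stored support (default
#'   `1e-10`).
#' @return An object of class `"se_bvpois"` with elements `lambda`, `xi`,
#'   `n_max`.
#' @examples
#' d <- bivariate_poisson(lambda = 3, xi = 2.4)
#' bvpois_corr(d) # 0.8
#' @export
bivariate_poisson <- function(lambda, xi, tail = 1e-10) {
  stopifnot(lambda > 0)
  if (xi < 0 || xi > lambda)
    stop("correlation parameter xi must lie in [0, lambda]")
  structure(
    list(lambda = lambda, xi = xi,
         n_max = charlier_support_max(lambda, tail)),
    class = "se_bvpois"
  )
}

#' @export
print.se_bvpois <- function(x, ...) {
  cat(sprintf("<se_bvpois> lambda = %g, xi = %g (corr = %g), support 0..%d\n",
              x$lambda, x$xi, x$xi / x$lambda, x$n_max))
  invisible(x)
}

#' Bivariate Poisson probability mass function
#'
#' Evaluated via the trivariate-reduction series
#' \deqn{P(n,m) = e^{-(2\lambda-\xi)} \sum_{i=0}^{\min(n,m)}
#'   \frac{(\lambda-\xi)^{n-i}(\lambda-\xi)^{m-i}\xi^i}{(n-i)!\,(m-i)!\,i!},}
#' which is numerically robust for all admissible parameters; at `xi = 0`
#' it reduces to the product of the two Poisson marginals.
#'
#' @param d An [bivariate_poisson()] object.
#' @param n,m Non-negative integer counts (vectors recycled together).
#' @return Probabilities.
#' @export
bivariate_poisson_pmf <- function(d, n, m) {
  stopifnot(inherits(d, "se_bvpois"))
  ln <- max(length(n), length(m))
  n <- rep_len(n, ln); m <- rep_len(m, ln)
  if (any(n < 0 | m < 0 | n != round(n) | m != round(m)))
    stop("counts n, m must be non-negative integers")
  lam <- d$lambda; xi <- d$xi
  if (xi == 0) return(stats::dpois(n, lam) * stats::dpois(m, lam))
  a <- lam - xi
  vapply(seq_len(ln), function(t) {
    i <- 0:min(n[t], m[t])
    # log-space terms to stay stable for large counts
    lt <- (n[t] - i) * log(a) + (m[t] - i) * log(a) + i * log(xi) -
      lfactorial(n[t] - i) - lfactorial(m[t] - i) - lfactorial(i)
    exp(-(2 * lam - xi)) * sum(exp(lt))
  }, 0)
}

# Kummer-U closed form of the same PMF, used as an independent
# cross-check: P = (-1)^n (lam-xi)^(m-n) xi^n / (n! m!) *
#   U(-n, 1-n+m, -(lam-xi)^2/xi) * exp(-(2 lam - xi)),
# with U(-n, b, z) = (-1)^n n! L_n^{(b-1)}(z) (generalized Laguerre).
bivariate_poisson_pmf_kummer <- function(d, n, m) {
  stopifnot(inherits(d, "se_bvpois"), d$xi > 0)
  lam <- d$lambda; xi <- d$xi
  ln <- max(length(n), length(m))
  n <- rep_len(n, ln); m <- rep_len(m, ln)
  z <- -(lam - xi)^2 / xi
  vapply(seq_len(ln), function(t) {
    U <- (-1)^n[t] * factorial(n[t]) *
      laguerre_gen(n[t], m[t] - n[t], z)
    (-1)^n[t] * (lam - xi)^(m[t] - n[t]) * xi^n[t] /
      (factorial(n[t]) * factorial(m[t])) * U * exp(-(2 * lam - xi))
  }, 0)
}

# generalized Laguerre polynomial L_k^{(alpha)}(z) by recurrence
laguerre_gen <- function(k, alpha, z) {
  if (k == 0) return(1)
  Lm1 <- 1
  L <- 1 + alpha - z
  if (k == 1) return(L)
  for (i in 1:(k - 1)) {
    Lp1 <- ((2 * i + 1 + alpha - z) * L - (i + alpha) * Lm1) / (i + 1)
    Lm1 <- L; L <- Lp1
  }
  L
}

# full truncated PMF matrix over 0..n_max in both arguments
bvpois_pmf_matrix <- function(d) {
  x <- 0:d$n_max
  outer(x, x, function(n, m) bivariate_poisson_pmf(d, n, m))
}

#' Moments and correlation of the truncated bivariate Poisson PMF
#'
#' Computed by direct summation over the truncated support — an
#' independent check of the analytic identity `corr(n, m) = xi / lambda`.
#'
#' @param d An [bivariate_poisson()] object.
#' @return For `bvpois_corr`, the Pearson correlation; for
#'   `bvpois_moments`, a tibble with means, variances, covariance and
#'   correlation.
#' @export
bvpois_corr <- function(d) {
  bvpois_moments(d)$correlation
}

#' @rdname bvpois_corr
#' @export
bvpois_moments <- function(d) {
  P <- bvpois_pmf_matrix(d)
  x <- 0:d$n_max
  pn <- rowSums(P); pm <- colSums(P)
  En <- sum(x * pn); Em <- sum(x * pm)
  Vn <- sum(x^2 * pn) - En^2
  Vm <- sum(x^2 * pm) - Em^2
  Enm <- sum(outer(x, x) * P)
  cov <- Enm - En * Em
  tibble::tibble(mean_n = En, mean_m = Em, var_n = Vn, var_m = Vm,
                 covariance = cov, correlation = cov / sqrt(Vn * Vm))
}

#' Correlated-basis weight matrix
#'
#' For two (discrete) dimensions with joint PMF \eqn{P(\theta_1,\theta_2)}
#' and marginals \eqn{P_1, P_2}, computes
#' \deqn{\omega_{l_1 l_2} = \sum_{\theta_1,\theta_2}
#'   \sqrt{P_1 P_2 P(\theta_1,\theta_2)}\, \psi_{l_1}(\theta_1)\,
#'   \psi_{l_2}(\theta_2),}
#' the projection of the correlated basis onto the independent
#' eigen-combined functions. When the joint factorizes, \eqn{\omega}
#' reduces to the outer product of the first eigenvector components and
#' the correlated expansion collapses to the independent tensor-product
#' expansion.
#'
#' @param nodes1,nodes2 `"se_nodes"` objects for the two marginal bases.
#' @param joint_pmf Function `(n, m) -> probability` (vectorized), or a
#'   matrix over `0..n_max` in both arguments.
#' @param n_max Truncation bound of the summation support.
#' @return An `N x N` weight matrix.
#' @export
correlated_weights <- function(nodes1, nodes2, joint_pmf, n_max) {
  x <- 0:n_max
  P12 <- if (is.matrix(joint_pmf)) joint_pmf
         else outer(x, x, joint_pmf)
  P1 <- rowSums(P12); P2 <- colSums(P12)
  pos <- outer(P1 > 0, P2 > 0)
  if (any(pos & P12 <= 0))
    stop("joint PMF vanishes at a support point of the marginals; the ",
         "correlated-basis construction assumes P(theta1, theta2) > 0 there")
  Psi1 <- psi_matrix(nodes1, x) # (n_max+1) x N
  Psi2 <- psi_matrix(nodes2, x)
  W <- sqrt(outer(P1, P2) * P12)
  t(Psi1) %*% W %*% Psi2
}

#' Fit a spectral expansion under correlated Poisson counts
#'
#' Builds the correlated-basis expansion for a model of two plasmid
#' counts: Charlier bases for both marginals, weight matrix from
#' [correlated_weights()], and model evaluations at the `N^2` pairs of
#' Charlier eigen-nodes (real-valued; the model must accept real count
#' arguments). Evaluation at integer `(n, m)` applies the
#' \eqn{\sqrt{P_1 P_2 / P_{12}}} prefactor of the correlated basis.
#'
#' @param model Function taking a named vector `c(n = , m = )` and
#'   returning a finite numeric scalar or vector.
#' @param joint An [bivariate_poisson()] object.
#' @param order Expansion order `N` (per dimension).
#' @return An object of class `"se_correlated"`.
#' @export
se_fit_correlated <- function(model, joint, order) {
  stopifnot(inherits(joint, "se_bvpois"))
  fam <- basis_family("charlier", order, lambda = joint$lambda)
  nodes <- se_nodes(fam)
  P12 <- bvpois_pmf_matrix(joint)
  omega <- correlated_weights(nodes, nodes, P12, joint$n_max)
  grid <- as.matrix(expand.grid(n = nodes$values, m = nodes$values,
                                KEEP.OUT.ATTRS = FALSE))
  responses <- NULL
  for (i in seq_len(nrow(grid))) {
    y <- as.numeric(model(c(n = unname(grid[i, 1]), m = unname(grid[i, 2]))))
    if (any(!is.finite(y)))
      stop(sprintf("model returned non-finite output at n = %.4g, m = %.4g",
                   grid[i, 1], grid[i, 2]))
    if (is.null(responses))
      responses <- matrix(0, nrow(grid), length(y),
                          dimnames = list(NULL, names(y)))
    responses[i, ] <- y
  }
  structure(
    list(joint = joint, nodes = nodes, omega = omega,
         node_grid = grid, responses = responses, order = order,
         P12 = P12, n_evals = nrow(grid)),
    class = "se_correlated"
  )
}

#' Evaluate a correlated-basis surrogate at integer counts
#'
#' @param object An `"se_correlated"`.
#' @param n,m Non-negative integer counts (vectors recycled together).
#' @param ... Unused.
#' @return Numeric vector (single pair, multi-component output) or matrix
#'   (pairs x components).
#' @export
predict.se_correlated <- function(object, n, m, ...) {
  ln <- max(length(n), length(m))
  n <- rep_len(n, ln); m <- rep_len(m, ln)
  x <- 0:object$joint$n_max
  lam <- object$joint$lambda
  Psi_n <- psi_matrix(object$nodes, n) # ln x N
  Psi_m <- psi_matrix(object$nodes, m)
  N <- object$order
  out <- matrix(0, ln, ncol(object$responses))
  for (t in seq_len(ln)) {
    pref <- sqrt(stats::dpois(n[t], lam) * stats::dpois(m[t], lam) /
                   object$P12[n[t] + 1L, m[t] + 1L])
    # weights over node pairs, grid order: n fastest
    wmat <- (Psi_n[t, ] %o% Psi_m[t, ]) * object$omega
    out[t, ] <- pref * crossprod(object$responses, as.vector(wmat))
  }
  colnames(out) <- colnames(object$responses)
  if (ln == 1) drop(out) else out
}

#' @export
print.se_correlated <- function(x, ...) {
  cat(sprintf(
    "<se_correlated> bivariate Poisson (lambda = %g, xi = %g), order %d, %d model evaluations\n",
    x$joint$lambda, x$joint$xi, x$order, x$n_evals))
  invisible(x)
}
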