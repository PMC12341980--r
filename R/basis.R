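#' Orthonormal basis family for a spectral expansion
#'
#' A basis family bundles everything needed to build a spectral (polynomial
#' chaos) expansion for one uncertain parameter: the kind of orthonormal
#' system, the number of retained basis functions, and (where needed) the
#' hyperparameters of the weight distribution.
#'
#' Supported families and their weight distributions:
#' * `"legendre"` — orthonormal Legendre polynomials, uniform weight on
#'   \eqn{[-1, 1]};
#' * `"hermite"` — orthonormal probabilists' Hermite polynomials, standard
#'   normal weight;
#' * `"charlier"` — orthonormal Charlier polynomials, Poisson(\eqn{\lambda})
#'   weight on the non-negative integers (`lambda` required);
#' * `"haar"` — Haar wavelets composed with a reference CDF `F`, so the
#'   basis is orthonormal with respect to the distribution with that CDF.
#'   Index `n = 0` is the constant function; `n >= 1` is decomposed as
#'   `n = 2^j + k` with `0 <= k < 2^j`. A "resolution level" `J`
#'   corresponds to `order = 2^(J+1)` functions (constant plus all wavelets
#'   with `j = 0..J`).
#'
#' @param kind One of `"legendre"`, `"hermite"`, `"charlier"`, `"haar"`.
#' @param order Number of basis functions retained (indices `0..order-1`).
#'   For the Haar family this must be a power of two.
#' @param lambda Poisson mean, required for `"charlier"`.
#' @param cdf,quantile Reference CDF and its inverse for `"haar"`; default is
#'   the identity on `[0, 1]`. Both must be vectorized.
#' @param support Numeric length-2 support of the Haar reference
#'   distribution (defaults to `c(0, 1)` for the identity CDF).
#'
#' @return An object of class `"se_basis"`.
#' @examples
#' fam <- basis_family("hermite", order = 5)
#' eval_basis(fam, 1, 2.0) # orthonormal Hermite degree 1 is theta
#' @export
basis_family <- function(kind = c("legendre", "hermite", "charlier", "haar"),
                         order,
                         lambda = NULL,
                         cdf = NULL, quantile = NULL, support = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(order), length(order) == 1, order >= 1,
            order == round(order))
  order <- as.integer(order)
  if (kind == "charlier") {
    if (is.null(lambda) || !is.numeric(lambda) || lambda <= 0)
      stop("charlier basis requires lambda > 0 (mean of the Poisson weight)")
  }
  if (kind == "haar") {
    if (bitwAnd(order, order - 1L) != 0L)
      stop("haar basis order must be a power of two (2^(J+1) for level J)")
    if (is.null(cdf)) {
      cdf <- function(x) pmin(pmax(x, 0), 1)
      quantile <- function(p) p
      support <- c(0, 1)
    } else {
      if (is.null(quantile))
        stop("haar basis with a custom cdf also needs its quantile function")
      if (is.null(support))
        stop("haar basis with a custom cdf needs a numeric support = c(lo, hi)")
    }
  }
  structure(
    list(kind = kind, order = order, lambda = lambda,
         cdf = cdf, quantile = quantile, support = support),
    class = "se_basis"
  )
}

#' @export
print.se_basis <- function(x, ...) {
  hp <- if (x$kind == "charlier") sprintf(" (lambda = %g)", x$lambda) else ""
  cat(sprintf("<se_basis> %s, order %d%s\n", x$kind, x$order, hp))
  invisible(x)
}

#' Number of basis functions for a Haar resolution level
#'
#' Level `J` comprises the constant function plus all wavelets with scaling
#' factor `j = 0..J`, i.e. `2^(J+1)` functions in total (level 3 gives 16,
#' level 6 gives 128).
#'
#' @param level Non-negative integer resolution level `J`.
#' @return Integer number of basis functions.
#' @export
haar_count <- function(level) {
  stopifnot(level >= 0, level == round(level))
  as.integer(2^(level + 1))
}

# Haar mother wavelet on [0, 1): +1 on [0, 1/2), -1 on [1/2, 1).
haar_mother <- function(t) {
  ifelse(t >= 0 & t < 0.5, 1, ifelse(t >= 0.5 & t < 1, -1, 0))
}

#' Evaluate one orthonormal basis function
#'
#' Polynomial families are built from their three-term recurrences,
#' normalized to unit norm under the weight distribution (uniform on
#' \eqn{[-1,1]}, standard normal, or Poisson). The Haar family evaluates
#' \eqn{2^{j/2} \psi(2^j F(\theta) - k)} with `n = 2^j + k`.
#'
#' @param family An [basis_family()] object.
#' @param n Basis-function index, `0 <= n < order`.
#' @param theta Evaluation point(s); counts for Charlier, points in the
#'   support of the reference CDF for Haar.
#' @return Numeric vector of basis values, one per element of `theta`.
#' @export
eval_basis <- function(family, n, theta) {
  stopifnot(inherits(family, "se_basis"))
  if (n < 0 || n >= family$order)
    stop(sprintf("basis index n = %d out of range [0, %d]", n, family$order - 1))
  eval_basis_matrix(family, theta)[, n + 1L]
}

#' Evaluate all basis functions at once
#'
#' @param family An [basis_family()] object.
#' @param theta Numeric vector of evaluation points.
#' @return A `length(theta) x order` matrix; column `n + 1` holds
#'   \eqn{\phi_n(\theta)}.
#' @export
eval_basis_matrix <- function(family, theta) {
  N <- family$order
  out <- matrix(0, length(theta), N)
  if (family$kind == "haar") {
    sup <- family$support
    if (any(!is.finite(theta)) ||
        any(theta < sup[1] - 1e-12 | theta > sup[2] + 1e-12))
      stop("haar basis: theta outside the support of the reference CDF")
    y <- family$cdf(theta)
    # right endpoint belongs to the topmost dyadic cell
    y <- pmin(pmax(y, 0), 1 - .Machine$double.eps)
    out[, 1] <- 1
    if (N > 1) {
      for (n in seq_len(N - 1)) {
        j <- floor(log2(n))
        k <- n - 2^j
        out[, n + 1L] <- 2^(j / 2) * haar_mother(2^j * y - k)
      }
    }
    return(out)
  }
  if (family$kind == "charlier" &&
      any(theta < 0 | abs(theta - round(theta)) > 1e-8)) {
    # Charlier polynomials extend to real arguments (used at eigen-nodes);
    # only reject clearly invalid negative inputs.
    if (any(theta < 0))
      stop("charlier basis: theta must be a non-negative count")
  }
  ab <- recurrence_coefs(family)
  out[, 1] <- 1
  if (N > 1) {
    # theta*phi_n = b_n phi_{n-1} + a_n phi_n + b_{n+1} phi_{n+1}
    out[, 2] <- (theta - ab$a[1]) * out[, 1] / ab$b[1]
    if (N > 2) {
      for (n in 2:(N - 1)) {
        out[, n + 1L] <- ((theta - ab$a[n]) * out[, n] -
                            ab$b[n - 1] * out[, n - 1L]) / ab$b[n]
      }
    }
  }
  out
}

# Orthonormal three-term recurrence coefficients:
# a[n+1] = diagonal term for phi_n, b[n+1] = coupling phi_n <-> phi_{n+1}.
recurrence_coefs <- function(family) {
  N <- family$order
  n <- seq_len(max(N - 1, 1))
  switch(family$kind,
    legendre = list(a = rep(0, N), b = n / sqrt((2 * n - 1) * (2 * n + 1))),
    hermite  = list(a = rep(0, N), b = sqrt(n)),
    charlier = list(a = (seq_len(N) - 1) + family$lambda,
                    b = -sqrt(n * family$lambda)),
    stop("no three-term recurrence for the haar family")
  )
}

#' Analytic Jacobi-type matrix of the multiplication operator
#'
#' Builds the symmetric matrix \eqn{\hat B_{nm} = \int \phi_n \theta \phi_m
#' P\, d\theta} from the orthonormal three-term recurrence: tridiagonal with
#' off-diagonal \eqn{n/\sqrt{(2n-1)(2n+1)}} (Legendre), \eqn{\sqrt{n}}
#' (Hermite), or diagonal \eqn{n + \lambda} and off-diagonal
#' \eqn{-\sqrt{n\lambda}} (Charlier).
#'
#' @param family An [basis_family()] object with a polynomial kind.
#' @return Symmetric `order x order` matrix.
#' @export
build_B_analytic <- function(family) {
  stopifnot(inherits(family, "se_basis"))
  if (family$kind == "haar")
    stop("no analytic B for the haar family; use build_B_numeric()")
  N <- family$order
  ab <- recurrence_coefs(family)
  B <- diag(ab$a, nrow = N)
  if (N > 1) {
    idx <- seq_len(N - 1)
    B[cbind(idx, idx + 1)] <- ab$b[idx]
    B[cbind(idx + 1, idx)] <- ab$b[idx]
  }
  B
}

# canonical weight density/pmf and integration support for a family
family_weight <- function(family) {
  switch(family$kind,
    legendre = list(pdf = function(x) stats::dunif(x, -1, 1),
                    lower = -1, upper = 1, discrete = FALSE),
    hermite  = list(pdf = function(x) stats::dnorm(x),
                    lower = -12, upper = 12, discrete = FALSE),
    charlier = list(pdf = function(x) stats::dpois(x, family$lambda),
                    discrete = TRUE),
    haar     = NULL
  )
}

#' Numeric Jacobi-type matrix by quadrature
#'
#' Computes \eqn{\hat B_{nm} = \int \phi_n \theta \phi_m P\, d\theta} by
#' deterministic quadrature (continuous weight), truncated summation with
#' tail mass below `1e-12` (discrete weight), or exact per-cell
#' Gauss–Legendre quadrature in the CDF domain (Haar). The result is
#' symmetrized by averaging with its transpose. Quadrature order is doubled
#' until no entry changes by more than `tol`.
#'
#' @param family An [basis_family()] object.
#' @param pdf Optional weight density/pmf overriding the family's canonical
#'   weight (continuous polynomial families only).
#' @param tol Convergence tolerance for the order-doubling check.
#' @return Symmetric `order x order` matrix.
#' @export
build_B_numeric <- function(family, pdf = NULL, tol = 1e-8) {
  stopifnot(inherits(family, "se_basis"))
  N <- family$order
  if (family$kind == "haar") return(build_B_haar(family))
  w <- family_weight(family)
  if (isTRUE(w$discrete)) {
    # high-degree Charlier polynomials grow polynomially, so the Poisson
    # tail must be extended until the summed entries stabilize
    nmax <- charlier_support_max(family$lambda)
    B_at <- function(nmax) {
      x <- 0:nmax
      P <- stats::dpois(x, family$lambda)
      Phi <- eval_basis_matrix(family, x)
      t(Phi) %*% (Phi * (x * P))
    }
    B <- B_at(nmax)
    repeat {
      nmax <- 2 * nmax
      B2 <- B_at(nmax)
      if (max(abs(B2 - B)) < tol) { B <- B2; break }
      B <- B2
      if (nmax > 1e5)
        stop("Charlier summation for B did not converge")
    }
    return((B + t(B)) / 2)
  }
  dens <- if (is.null(pdf)) w$pdf else pdf
  quad_B <- function(n_nodes) {
    gl <- pracma::gaussLegendre(n_nodes, w$lower, w$upper)
    Phi <- eval_basis_matrix(family, gl$x)
    wt <- gl$w * dens(gl$x) * gl$x
    t(Phi) %*% (Phi * wt)
  }
  n_nodes <- max(4 * N, 64)
  B <- quad_B(n_nodes)
  repeat {
    n_nodes <- 2 * n_nodes
    B2 <- quad_B(n_nodes)
    if (max(abs(B2 - B)) < tol) { B <- B2; break }
    B <- B2
    if (n_nodes > 2^14)
      stop("quadrature for B did not converge (entries still changing > tol)")
  }
  (B + t(B)) / 2
}

# Haar B: in the CDF domain the integrand is piecewise-smooth on the
# dyadic cells of the finest retained level; integrate the quantile
# function exactly per cell with Gauss-Legendre.
build_B_haar <- function(family, n_gl = 32) {
  N <- family$order
  n_cells <- N # order is a power of two = number of finest dyadic cells
  edges <- seq(0, 1, length.out = n_cells + 1)
  gl <- pracma::gaussLegendre(n_gl, 0, 1)
  B <- matrix(0, N, N)
  for (c_i in seq_len(n_cells)) {
    a <- edges[c_i]; b <- edges[c_i + 1]
    y <- a + (b - a) * gl$x
    wt <- (b - a) * gl$w
    theta <- family$quantile(y)
    # basis values are constant on the cell; evaluate at the midpoint
    ymid <- family$quantile((a + b) / 2)
    phi <- eval_basis_matrix(family, ymid)[1, ]
    moment <- sum(wt * theta)
    B <- B + outer(phi, phi) * moment
  }
  (B + t(B)) / 2
}

# smallest n with Poisson(lambda) upper tail mass < 1e-12
charlier_support_max <- function(lambda, tail = 1e-12) {
  n <- stats::qpois(1 - tail, lambda) + 5
  while (stats::ppois(n, lambda, lower.tail = FALSE) >= tail) n <- n + 5
  as.integer(n)
}

#' Spectral nodes and weights from the eigendecomposition of B
#'
#' The eigenvalues of the symmetric matrix `B` are the model-evaluation
#' nodes of the expansion and the squared first components of its
#' orthonormal eigenvectors are the induced quadrature weights (for
#' polynomial families these coincide with the classical Gaussian
#' quadrature rule of the weight distribution). Eigenvalues are returned in
#' ascending order, and each eigenvector is rescaled so that its first
#' component is non-negative.
#'
#' @param B Symmetric matrix from [build_B_analytic()] or
#'   [build_B_numeric()].
#' @param family The [basis_family()] the matrix was built for.
#' @return An object of class `"se_nodes"` with elements `family`, `B`,
#'   `values` (nodes), `vectors` (orthonormal eigenvector columns), and
#'   `w1` (first components \eqn{u_1^{(l)}}).
#' @export
spectral_nodes <- function(B, family) {
  stopifnot(inherits(family, "se_basis"), is.matrix(B),
            nrow(B) == family$order, ncol(B) == family$order)
  if (max(abs(B - t(B))) > 1e-10 * max(1, max(abs(B))))
    stop("B must be symmetric")
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  sgn <- ifelse(vecs[1, ] < 0, -1, 1)
  vecs <- sweep(vecs, 2, sgn, `*`)
  if (any(abs(vecs[1, ]) < 1e-12))
    warning("degenerate node(s): first eigenvector component ~ 0; the ",
            "corresponding expansion term contributes nothing")
  structure(
    list(family = family, B = B, values = vals, vectors = vecs,
         w1 = vecs[1, ]),
    class = "se_nodes"
  )
}

#' @export
print.se_nodes <- function(x, ...) {
  cat(sprintf("<se_nodes> %s basis, %d nodes in [%.4g, %.4g]\n",
              x$family$kind, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

# Evaluate the eigen-combined functions psi_l(theta) = sum_n u_{n+1}^{(l)}
# phi_n(theta) for all l at once; returns length(theta) x N matrix.
psi_matrix <- function(nodes, theta) {
  eval_basis_matrix(nodes$family, theta) %*% nodes$vectors
}

#' Build spectral nodes for a basis family in one call
#'
#' Convenience wrapper: analytic B for polynomial families, numeric B for
#' Haar, then [spectral_nodes()].
#'
#' @inheritParams build_B_analytic
#' @return An `"se_nodes"` object.
#' @export
se_nodes <- function(family) {
  B <- if (family$kind == "haar") build_B_numeric(family)
       else build_B_analytic(family)
  spectral_nodes(B, family)
}
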