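# Independent oracles used across the suite. These deliberately avoid the
# package's eigendecomposition path: nodes come from polynomial
# root-finding on the classical monic three-term recurrences, and
# integrals from closed-form moments or adaptive quadrature.

# monic recurrence coefficients (a_k, b2_k), k = 0, 1, ...
monic_recurrence <- function(kind, N, lambda = NULL) {
  k <- 0:(N - 1)
  switch(kind,
    legendre = list(a = rep(0, N), b2 = c(0, (1:(N - 1))^2 / (4 * (1:(N - 1))^2 - 1))),
    hermite  = list(a = rep(0, N), b2 = c(0, 1:(N - 1))),
    charlier = list(a = k + lambda, b2 = c(0, (1:(N - 1)) * lambda))
  )
}

# classical Gauss nodes as roots of the monic orthogonal polynomial,
# built by explicit polynomial coefficient arithmetic + polyroot()
gauss_nodes_oracle <- function(kind, N, lambda = NULL) {
  rc <- monic_recurrence(kind, N, lambda)
  p_prev <- c(1)            # p_0, ascending coefficients
  p_cur <- c(-rc$a[1], 1)   # p_1 = x - a_0
  if (N > 1) {
    for (k in 1:(N - 1)) {
      x_p <- c(0, p_cur)                       # x * p_k
      t1 <- rc$a[k + 1] * c(p_cur, 0)          # a_k p_k (padded)
      t2 <- rc$b2[k + 1] * c(p_prev, 0, 0)     # b2_k p_{k-1} (padded)
      nxt <- x_p - t1[seq_along(x_p)] - t2[seq_along(x_p)]
      p_prev <- p_cur
      p_cur <- nxt
    }
  }
  sort(Re(polyroot(p_cur)))
}

# raw moments E[theta^k] of the weight distributions, closed form
weight_moment_oracle <- function(kind, k, lambda = NULL) {
  switch(kind,
    legendre = if (k %% 2 == 0) 1 / (k + 1) else 0,
    hermite  = if (k %% 2 == 0) prod(seq(1, max(k - 1, 1), by = 2)) * (k > 0) + (k == 0) else 0,
    charlier = {
      x <- 0:max(200, stats::qpois(1 - 1e-14, lambda) + 20)
      sum(x^k * stats::dpois(x, lambda))
    }
  )
}

# numeric inner product of two basis functions under the family weight
basis_inner_oracle <- function(family, n, m) {
  if (family$kind == "charlier") {
    x <- 0:max(200, stats::qpois(1 - 1e-14, family$lambda) * 4)
    return(sum(eval_basis(family, n, x) * eval_basis(family, m, x) *
                 stats::dpois(x, family$lambda)))
  }
  if (family$kind == "haar") {
    # integrate in the CDF domain on the finest dyadic cells
    nc <- family$order
    mids <- (seq_len(nc) - 0.5) / nc
    th <- family$quantile(mids)
    return(mean(eval_basis(family, n, th) * eval_basis(family, m, th)))
  }
  w <- switch(family$kind,
    legendre = list(d = function(x) stats::dunif(x, -1, 1), lo = -1, hi = 1),
    hermite = list(d = stats::dnorm, lo = -10, hi = 10))
  stats::integrate(function(x)
    eval_basis(family, n, x) * eval_basis(family, m, x) * w$d(x),
    w$lo, w$hi, rel.tol = 1e-11, abs.tol = 1e-12)$value
}

# sup-norm distance between two KDEs on a shared grid
kde_supnorm <- function(x1, x2, grid) {
  max(abs(kde(x1, grid)$density - kde(x2, grid)$density))
}

# memoising wrapper that counts model calls (and caches repeat arguments)
counting_model <- function(f) {
  calls <- 0L
  cache <- new.env(parent = emptyenv())
  g <- function(p) {
    key <- paste(signif(as.numeric(p), 15), collapse = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    calls <<- calls + 1L
    val <- f(p)
    cache[[key]] <- val
    val
  }
  list(model = g, calls = function() calls)
}

# first-order shares plus the pure-interaction share, computed directly
# from the coefficient multi-indices (should sum to one)
sobol_variances_sum <- function(s) {
  td <- generics::tidy(s)
  deg <- as.matrix(td[, seq_len(ncol(td) - 2)])
  c2 <- td$coefficient^2
  nz <- rowSums(deg) > 0
  D <- sum(c2[nz])
  first <- sum(vapply(seq_len(ncol(deg)), function(i)
    sum(c2[deg[, i] > 0 & rowSums(deg[, -i, drop = FALSE]) == 0]), 0))
  inter <- sum(c2[rowSums(deg > 0) > 1])
  (first + inter) / D
}
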