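test_that("basis functions are orthonormal under their weight distributions", {
  fams <- list(
    basis_family("legendre", 6),
    basis_family("hermite", 6),
    basis_family("charlier", 6, lambda = 3),
    basis_family("haar", 8, cdf = function(x) stats::punif(x, -1, 1),
                 quantile = function(p) stats::qunif(p, -1, 1),
                 support = c(-1, 1))
  )
  for (fam in fams) {
    for (n in 0:(fam$order - 1)) {
      for (m in n:(fam$order - 1)) {
        expect_equal(basis_inner_oracle(fam, n, m), as.numeric(n == m),
                     tolerance = 1e-8,
                     label = sprintf("%s <phi_%d, phi_%d>", fam$kind, n, m))
      }
    }
    # constant basis function for all families
    th <- if (fam$kind == "charlier") 2 else 0.37
    expect_equal(eval_basis(fam, 0, th), 1)
  }
})

test_that("first basis functions match known closed forms", {
  expect_equal(eval_basis(basis_family("legendre", 3), 0, 0.7), 1)
  # orthonormal probabilists' Hermite degree 1 is theta itself
  expect_equal(eval_basis(basis_family("hermite", 3), 1, 2.0), 2.0)
  # Haar mother wavelet on the unit interval
  hid <- basis_family("haar", 4)
  expect_equal(eval_basis(hid, 1, 0.25), 1)
  expect_equal(eval_basis(hid, 1, 0.75), -1)
  expect_error(eval_basis(hid, 5, 0.5), "out of range")
  expect_error(eval_basis(hid, 1, 1.5), "outside the support")
})

test_that("analytic B matrices match their recurrence closed forms", {
  expect_equal(build_B_analytic(basis_family("hermite", 2)),
               matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(build_B_analytic(basis_family("legendre", 2)),
               matrix(c(0, 1 / sqrt(3), 1 / sqrt(3), 0), 2, 2))
  # Charlier: diagonal n + lambda, off-diagonal -sqrt(n lambda)
  expect_equal(build_B_analytic(basis_family("charlier", 2, lambda = 3)),
               matrix(c(3, -sqrt(3), -sqrt(3), 4), 2, 2))
  expect_error(build_B_analytic(basis_family("haar", 4)), "numeric")
})

test_that("numeric quadrature B agrees with the analytic matrices", {
  for (fam in list(basis_family("legendre", 10),
                   basis_family("hermite", 10),
                   basis_family("charlier", 10, lambda = 3))) {
    Ba <- build_B_analytic(fam)
    Bn <- build_B_numeric(fam)
    expect_lt(max(abs(Ba - Bn)), 1e-8)
    expect_identical(Bn, t(Bn)) # symmetrized exactly
  }
})

test_that("haar B on a uniform reference reproduces direct cell moments", {
  fam <- basis_family("haar", 2, cdf = function(x) stats::punif(x, -1, 1),
                      quantile = function(p) stats::qunif(p, -1, 1),
                      support = c(-1, 1))
  B <- build_B_numeric(fam)
  # wavelet is +1 on [-1, 0), -1 on [0, 1):
  # c = int theta * W1(theta) /2 dtheta = -1/4 - 1/4 = -1/2
  expect_equal(B, matrix(c(0, -0.5, -0.5, 0), 2, 2), tolerance = 1e-10)
})

test_that("eigen-nodes match classical Gauss quadrature rules", {
  nd <- se_nodes(basis_family("hermite", 2))
  expect_equal(nd$values, c(-1, 1), tolerance = 1e-12)
  expect_equal(nd$w1^2, c(0.5, 0.5), tolerance = 1e-12)
  nd3 <- se_nodes(basis_family("legendre", 3))
  expect_equal(nd3$values, c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
               tolerance = 1e-12)
  # root-finding oracle across orders and families
  for (N in c(2, 5, 8, 12)) {
    for (kind in c("legendre", "hermite")) {
      fam <- basis_family(kind, N)
      nd <- se_nodes(fam)
      expect_equal(nd$values, gauss_nodes_oracle(kind, N),
                   tolerance = 1e-10,
                   label = sprintf("%s N=%d nodes", kind, N))
      expect_equal(sum(nd$w1^2), 1, tolerance = 1e-10)
    }
  }
  ndc <- se_nodes(basis_family("charlier", 6, lambda = 3))
  expect_equal(ndc$values, gauss_nodes_oracle("charlier", 6, lambda = 3),
               tolerance = 1e-9)
})

test_that("eigenvector sign convention and node weights induce a quadrature rule", {
  for (fam in list(basis_family("legendre", 7),
                   basis_family("hermite", 7),
                   basis_family("charlier", 7, lambda = 3))) {
    nd <- se_nodes(fam)
    expect_true(all(nd$w1 >= 0))
    expect_true(all(abs(crossprod(nd$vectors) - diag(fam$order)) < 1e-10))
    # exact for polynomials of degree <= 2N - 1
    N <- fam$order
    set.seed(11)
    for (rep in 1:5) {
      cf <- stats::rnorm(2 * N) # degree 2N - 1
      exact <- sum(vapply(seq_along(cf), function(i)
        cf[i] * weight_moment_oracle(fam$kind, i - 1, fam$lambda), 0))
      quad <- sum(nd$w1^2 * vapply(nd$values, function(x)
        sum(cf * x^(seq_along(cf) - 1)), 0))
      expect_equal(quad, exact, tolerance = 1e-9)
    }
  }
})

test_that("haar level counting gives the printed basis sizes", {
  expect_identical(haar_count(3), 16L)
  expect_identical(haar_count(6), 128L)
})

test_that("haar expansion reproduces piecewise-constant responses exactly", {
  fam <- basis_family("haar", 8, cdf = function(x) stats::punif(x, 0, 1),
                      quantile = function(p) stats::qunif(p, 0, 1),
                      support = c(0, 1))
  nd <- se_nodes(fam)
  # a function constant on the 8 dyadic cells of [0, 1]
  step_fun <- function(x) c(2, -1, 0.5, 3, 7, -2, 1, 4)[pmin(floor(x * 8), 7) + 1]
  spec <- param_spec("u", "uniform", a = 0, b = 1)
  s <- se_fit(function(p) step_fun(p[["u"]]), spec, 8,
              basis = list(basis_family("haar", 8,
                cdf = function(x) stats::punif(x, -1, 1),
                quantile = function(p) stats::qunif(p, -1, 1),
                support = c(-1, 1))))
  # probe away from the dyadic breakpoints
  th <- seq(-0.96, 0.96, length.out = 41)
  u <- (th + 1) / 2
  expect_equal(as.numeric(predict(s, th)), step_fun(u), tolerance = 1e-9)
})
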