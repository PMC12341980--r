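test_that("degree-one and constant models are fit exactly", {
  s <- se_fit(function(p) p[["k"]], param_spec("k", "normal", mean = 0, sd = 1), 2)
  expect_equal(as.numeric(s$coefficients), c(0, 1), tolerance = 1e-12)
  expect_equal(predict(s, 0.7), 0.7, tolerance = 1e-12)
  s0 <- se_fit(function(p) 5, param_spec("k", "normal", mean = 0, sd = 1), 4)
  expect_equal(as.numeric(s0$coefficients), c(5, 0, 0, 0), tolerance = 1e-10)
  expect_equal(predict(s0, c(-2, 0.3, 1.9)), rep(5, 3), tolerance = 1e-10)
})

test_that("the exponential-decay surrogate tracks the analytic solution", {
  spec <- param_spec("k", "lognormal", mean = 0.5, sd = 0.2)
  s <- se_fit(function(p) exp(-p[["k"]]), spec, 5)
  th <- c(-2, -1, 0, 1, 2)
  expect_lt(max(abs(predict(s, th) - exp(-to_physical(spec, th)))), 1e-3)
})

test_that("multivariate polynomials inside the span are reproduced exactly", {
  specs <- list(param_spec("a", "uniform", a = -1, b = 1),
                param_spec("b", "uniform", a = -1, b = 1))
  s <- se_fit(function(p) p[["a"]] * p[["b"]], specs, 3)
  expect_identical(s$n_evals, 9L)
  expect_equal(predict(s, c(0.5, 0.5)), 0.25, tolerance = 1e-12)
  # random polynomial of per-dimension degree <= N - 1 in mixed bases
  specs2 <- list(param_spec("a", "uniform", a = -1, b = 1),
                 param_spec("b", "normal", mean = 0, sd = 1))
  set.seed(5)
  cf <- matrix(stats::rnorm(16), 4, 4)
  poly <- function(t1, t2)
    sum(cf * outer(t1^(0:3), t2^(0:3)))
  s2 <- se_fit(function(p) poly(p[["a"]], p[["b"]]),
               specs2, 4)
  th <- cbind(stats::runif(100, -1, 1), stats::rnorm(100))
  direct <- vapply(seq_len(100), function(i) poly(th[i, 1], th[i, 2]), 0)
  expect_lt(max(abs(predict(s2, th) - direct)), 1e-9)
})

test_that("evaluating at a node tuple returns the stored response", {
  specs <- list(param_spec("a", "uniform", a = 0, b = 2),
                param_spec("b", "lognormal", mean = 0.5, sd = 0.2))
  model <- function(p) c(f = sin(p[["a"]]) + p[["b"]], g = p[["a"]] * p[["b"]])
  s <- se_fit(model, specs, 4)
  for (r in c(1, 7, 16)) {
    expect_equal(as.numeric(predict(s, s$node_grid[r, ])),
                 as.numeric(s$responses[r, ]), tolerance = 1e-8)
  }
})

test_that("coefficients equal the Gaussian-quadrature projection", {
  spec <- param_spec("k", "normal", mean = 0, sd = 1)
  model <- function(p) exp(-p[["k"]]^2 / 3)
  N <- 6
  s <- se_fit(model, spec, N)
  fam <- basis_for(spec, N)
  nd <- se_nodes(fam)
  w <- nd$w1^2
  Y <- vapply(nd$values, function(l) model(c(k = l)), 0)
  c_quad <- vapply(0:(N - 1), function(n)
    sum(w * Y * eval_basis(fam, n, nd$values)), 0)
  expect_equal(as.numeric(s$coefficients), c_quad, tolerance = 1e-10)
})

test_that("moments come from the coefficients and match quadrature oracles", {
  s <- se_fit(function(p) p[["k"]], param_spec("k", "normal", mean = 0, sd = 1), 2)
  m <- se_moments(s)
  expect_equal(m$mean, 0, tolerance = 1e-12)
  expect_equal(m$variance, 1, tolerance = 1e-12)
  spec <- param_spec("k", "lognormal", mean = 0.5, sd = 0.2)
  s2 <- se_fit(function(p) exp(-p[["k"]]), spec, 8)
  al <- spec$hyper$alpha
  exact_mean <- stats::integrate(function(k)
    exp(-k) * stats::dlnorm(k, log(0.5) - al^2 / 2, al), 0, Inf,
    rel.tol = 1e-12)$value
  m2 <- se_moments(s2)
  expect_equal(m2$mean, exact_mean, tolerance = 1e-4)
  expect_gte(m2$variance, 0)
})

test_that("surrogate moments agree with quasi-MC within blocking error bars", {
  spec <- param_spec("k", "lognormal", mean = 0.5, sd = 0.2)
  model <- function(p) exp(-p[["k"]])
  s <- se_fit(model, spec, 8)
  mc <- mc_reference(model, spec, n = 4096, scramble_seed = 11)
  m <- se_moments(s)
  expect_lt(abs(m$mean - mc$moments$mean), 3 * mc$moments$mean_error)
  expect_lt(abs(m$variance - mc$moments$variance),
            3 * mc$moments$variance_error)
})

test_that("Sobol indices recover additive, single-dim and interaction structure", {
  nspec <- function(nm) param_spec(nm, "normal", mean = 0, sd = 1)
  s_add <- se_fit(function(p) p[["a"]] + p[["b"]],
                  list(nspec("a"), nspec("b")), 3)
  expect_equal(sobol_first_order(s_add, 1), 0.5, tolerance = 1e-10)
  expect_equal(sobol_first_order(s_add, 2), 0.5, tolerance = 1e-10)
  s_one <- se_fit(function(p) p[["a"]], list(nspec("a"), nspec("b")), 3)
  expect_equal(sobol_first_order(s_one, 1), 1, tolerance = 1e-10)
  expect_equal(sobol_first_order(s_one, 2), 0, tolerance = 1e-10)
  s_int <- se_fit(function(p) p[["a"]] * p[["b"]],
                  list(nspec("a"), nspec("b")), 3)
  expect_equal(sobol_first_order(s_int, 1), 0, tolerance = 1e-10)
  expect_equal(sobol_first_order(s_int, 2), 0, tolerance = 1e-10)
  expect_equal(sobol_total_like(s_int, 1), 1, tolerance = 1e-10)
  # sum rule: first-order plus interactions account for all variance
  mixed <- se_fit(function(p) p[["a"]] + 0.5 * p[["a"]] * p[["b"]] - p[["b"]]^2,
                  list(nspec("a"), nspec("b")), 4)
  mi_sum <- sobol_first_order(mixed, 1) + sobol_first_order(mixed, 2)
  interaction <- 1 - mi_sum
  v <- se_sobol(mixed)
  expect_equal(sum(v$total_like) - interaction, 1, tolerance = 1e-10)
  expect_error(sobol_first_order(
    se_fit(function(p) 1, list(nspec("a"), nspec("b")), 2), 1), "constant")
})

test_that("non-finite model responses abort the fit with parameter context", {
  spec <- param_spec("k", "normal", mean = 0, sd = 1)
  expect_error(se_fit(function(p) ifelse(p[["k"]] > 0, NaN, 1), spec, 4),
               "non-finite")
  expect_error(se_fit(function(p) stop("boom"), spec, 2), "k = ")
})

test_that("broom-style accessors return tidy tibbles", {
  specs <- list(param_spec("a", "uniform", a = -1, b = 1),
                param_spec("b", "uniform", a = -1, b = 1))
  s <- se_fit(function(p) c(y1 = p[["a"]], y2 = p[["a"]] * p[["b"]]), specs, 3)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 18L) # 9 multi-indices x 2 components
  expect_named(td, c("a", "b", "component", "coefficient"))
  gl <- glance(s)
  expect_identical(gl$n_evals, 9L)
  expect_identical(gl$n_components, 2L)
  p <- autoplot(se_fit(function(p) exp(-p[["k"]]),
                       param_spec("k", "lognormal", mean = 0.5, sd = 0.2), 5))
  expect_s3_class(p, "ggplot")
})
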