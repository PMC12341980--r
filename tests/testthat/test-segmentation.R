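test_that("the scaling function maps the standard interval into each segment", {
  expect_equal(scaling_function(0, M = 1, L = 1, theta = 0), 0)
  # lowest segment's upper endpoint with M = 1, L = 1 is -1/3
  expect_equal(scaling_function(-1, M = 1, L = 1, theta = 1), -1 / 3)
  expect_equal(scaling_function(1, M = 1, L = 1, theta = -1), 1 / 3)
  expect_error(scaling_function(2, M = 1, L = 1, theta = 0), "\\|m\\| <= M")
  expect_error(scaling_function(0, M = 1, L = 1, theta = 2), "outside")
  # round trip through the inverse map
  th <- seq(-1, 1, length.out = 21)
  for (m in -2:2) {
    y <- scaling_function(m, 2, 1.5, th * 1.5)
    expect_lt(max(abs(scaling_function_inv(m, 2, 1.5, y) - th * 1.5)), 1e-12)
  }
})

test_that("segment index function selects the containing segment", {
  expect_identical(segment_index(0, 1, 1), 0)
  expect_identical(segment_index(0.5, 1, 1), 1)
  expect_identical(segment_index(1, 1, 1), 1) # clamped at the endpoint
  expect_identical(segment_index(-1, 1, 1), -1)
  expect_error(segment_index(1.2, 1, 1), "outside")
  # exactly one segment contains each quasi-random point (partition check)
  u <- sobol_sequence(10000, 1, scramble_seed = 3)
  y <- 2 * u[, 1] - 1
  for (M in c(1, 3)) {
    m_star <- segment_index(y, M, 1)
    lower <- (2 * m_star - 1) / (2 * M + 1)
    upper <- (2 * m_star + 1) / (2 * M + 1)
    expect_true(all(y >= lower - 1e-12 & y <= upper + 1e-12))
    # brute-force membership over all segments finds the same single one
    hits <- vapply(seq_along(y), function(i) {
      inside <- vapply(-M:M, function(m) {
        lo <- (2 * m - 1) / (2 * M + 1); hi <- (2 * m + 1) / (2 * M + 1)
        y[i] >= lo & (y[i] < hi | (m == M & y[i] <= hi))
      }, TRUE)
      sum(inside)
    }, 0L)
    expect_true(all(hits == 1L))
  }
})

test_that("granularity zero reduces to the unsegmented surrogate", {
  spec <- param_spec("k", "uniform", a = -2, b = 3)
  model <- function(p) sin(p[["k"]])
  s0 <- se_fit(model, spec, 5)
  sg <- se_fit_segmented(model, spec, 5, M = 0)
  expect_equal(sg$fits[[1]]$coefficients, s0$coefficients, tolerance = 1e-12)
  expect_equal(sg$fits[[1]]$node_grid, s0$node_grid)
  th <- seq(-1, 1, length.out = 17)
  expect_equal(predict(sg, th), as.numeric(predict(s0, th)), tolerance = 1e-12)
})

test_that("segmented and unsegmented expansions agree on polynomials", {
  spec <- param_spec("k", "uniform", a = -1, b = 1)
  poly <- function(p) 2 - p[["k"]] + 0.5 * p[["k"]]^2
  s0 <- se_fit(poly, spec, 3)
  s1 <- se_fit_segmented(poly, spec, 3, M = 2)
  th <- seq(-0.99, 0.99, length.out = 101)
  expect_lt(max(abs(predict(s1, th) - as.numeric(predict(s0, th)))), 1e-9)
})

test_that("reconstruction error of |theta| decreases with granularity", {
  spec <- param_spec("k", "uniform", a = -1, b = 1)
  model <- function(p) abs(p[["k"]])
  th <- seq(-1, 1, length.out = 1001)
  errs <- vapply(c(0, 1, 3), function(M) {
    s <- se_fit_segmented(model, spec, 3, M = M)
    max(abs(predict(s, th) - abs(th)))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("cost accounting reproduces the printed benchmark counts", {
  expect_equal(eval_cost(6, 0, 5, 3),
               list(n_model_evals = 7776, n_sum_terms = 181398528))
  expect_equal(eval_cost(9, 0, 5, 3)$n_model_evals, 59049)
  expect_equal(eval_cost(8, 0, 5, 2)$n_sum_terms, 2147483648)
  expect_equal(eval_cost(3, 1, 5, 2)$n_sum_terms, 118098)
  tab <- se_benchmark_table(data.frame(N = c(6, 9, 2, 3), M = c(0, 0, 1, 1)),
                            K = 5, n_outputs = 3)
  expect_equal(tab$n_evals, c(7776, 59049, 7776, 59049))
  expect_equal(tab$n_terms, c(1.81398528e8, 1.0460353203e10, 3072, 177147))
})

test_that("segmented fits consume exactly the advertised model evaluations", {
  cm <- counting_model(function(p) p[["a"]]^2 + p[["b"]])
  specs <- list(param_spec("a", "uniform", a = -1, b = 1),
                param_spec("b", "uniform", a = -1, b = 1))
  s <- se_fit_segmented(cm$model, specs, 2, M = 1)
  expect_identical(s$n_evals, as.integer((2 * 1 + 1)^2 * 2^2))
})
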