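test_that("decay fixture and its analytic response PDF are consistent", {
  expect_equal(decay_model(A0 = 1, k = 0.5, times = 0), 1)
  spec <- param_spec("k", "lognormal", mean = 0.5, sd = 0.2)
  grid <- seq(1e-4, 1 - 1e-4, length.out = 2001)
  pdf <- decay_pdf_analytic(1, spec, grid)
  expect_lt(abs(sum(pdf$density) * diff(grid)[1] - 1), 1e-4)
  expect_error(decay_pdf_analytic(0, spec, grid), "degenerate")
  # MC histogram oracle
  set.seed(2)
  a <- exp(-to_physical(spec, stats::rnorm(1e6)))
  h <- hist(a, breaks = seq(0, 1, by = 0.02), plot = FALSE)
  approx_pdf <- stats::approx(pdf$a, pdf$density, xout = h$mids)$y
  expect_lt(max(abs(h$density - approx_pdf), na.rm = TRUE), 0.05)
})

test_that("dimer network honours its conservation structure", {
  k <- c(0.1, 0.4, 0.4, 0.1, 0.1)
  times <- seq(0, 40, by = 2)
  x <- dimer_model(k, times)
  expect_identical(colnames(x), c("x1", "x2", "x3"))
  # d(x1 + x3)/dt = k1 - k5 (x1 + x3): solve this 1-D ODE exactly
  z <- x[, 1] + x[, 3]
  z_exact <- k[1] / k[5] * (1 - exp(-k[5] * times))
  expect_lt(max(abs(z - z_exact)), 1e-6)
  # k2 = k3 = 0 decouples into linear birth-death
  x2 <- dimer_model(c(0.2, 1e-12, 1e-12, 0.3, 0.5), seq(0, 60, by = 5))
  expect_equal(unname(x2[13, 1]), 0.2 / 0.5, tolerance = 1e-4)
})

test_that("glycolytic oscillator has the announced fixed point and regimes", {
  a <- 0.3; b <- 0.46
  fp <- c(b, b / (a + b^2))
  rhs <- c(-fp[1] + a * fp[2] + fp[1]^2 * fp[2],
           b - a * fp[2] - fp[1]^2 * fp[2])
  expect_lt(max(abs(rhs)), 1e-12)
  y_osc <- glycolysis_model(0.1, 0.46, seq(0, 100, by = 0.1))[, "y"]
  n <- length(y_osc)
  expect_gt(diff(range(y_osc[(n - 300):n])), 0.1)
  y_fix <- glycolysis_model(0.5, 0.46, seq(0, 100, by = 0.1))[, "y"]
  expect_lt(diff(range(y_fix[(n - 300):n])), 0.01)
})

test_that("Schnakenberg fixture patterns inside and only inside the Turing space", {
  expect_true(turing_space_test(0.22))
  expect_false(turing_space_test(0.24))
  # equal diffusion never gives a Turing instability
  expect_false(any(vapply(seq(0.05, 0.45, by = 0.05), function(a)
    turing_space_test(a, d = 1), TRUE)))
  s_in <- schnakenberg_model(0.22)
  s_out <- schnakenberg_model(0.24)
  cv_in <- stats::sd(s_in$v) / mean(s_in$v)
  cv_out <- stats::sd(s_out$v) / mean(s_out$v)
  expect_gt(cv_in, 0.05)
  expect_lt(cv_out, 1e-3)
  # determinism: same seed, bit-identical fields
  expect_identical(s_in$v, schnakenberg_model(0.22)$v)
})

test_that("trichome density counts cells above the half-maximum threshold", {
  f <- c(10, 1, 1, 6, 1, 1, 1, 1)
  expect_equal(trichome_density(f), 2 / 8)
  expect_true(trichome_turing_test(0.7))
  expect_false(trichome_turing_test(0.5))
  expect_equal(trichome_response(0.5, mode = "direct"), 0)
})

test_that("hexagonal Laplacian is conservative with six neighbours", {
  L <- spectralUQ:::hex_laplacian(6, 6)
  expect_true(all(abs(rowSums(L)) < 1e-12))
  expect_true(all(diag(L) == -6))
  expect_true(all(L[upper.tri(L)] %in% c(0, 1)))
  mu <- spectralUQ:::hex_mode_eigenvalues(6, 6)
  expect_true(all(mu >= -9 - 1e-9 & mu <= 1e-9))
  expect_lt(abs(max(mu)), 1e-9) # uniform mode
})

test_that("plasmid partition probabilities are binomial and normalized", {
  p3 <- partition_probs(3)
  expect_equal(p3, stats::dbinom(0:3, 3, 0.5))
  expect_equal(sum(p3), 1)
  P <- spectralUQ:::partition_matrix(10)
  expect_true(all(abs(colSums(P) - 1) < 1e-12))
})

test_that("per-cell plasmid dynamics reach the closed-form steady state", {
  r <- plasmid_defaults(kappa = 0, eta = 0.5)
  tr <- plasmid_cell_model(3, 2, times = seq(0, 30, by = 0.5), rates = r)
  ss <- plasmid_cell_steady_state(3, 2, rates = r)
  expect_equal(unname(tr[61, "x"]), unname(ss["x"]), tolerance = 1e-6)
  expect_equal(unname(tr[61, "y"]), unname(ss["y"]), tolerance = 1e-5)
})

test_that("population pool grows logistically and the readout histogram normalizes", {
  up <- bivariate_poisson(3, 2.4, tail = 1e-6) # small support for speed
  pop <- plasmid_population_model(up, times = seq(0, 48, by = 2),
                                  rates = plasmid_defaults(kappa = 3),
                                  N0 = 1e4, N_max = 1e5)
  ntot <- apply(pop$Q, 3, sum)
  # logistic growth of the total cell count
  t <- pop$times
  logistic <- 1e5 / (1 + (1e5 / 1e4 - 1) * exp(-0.034 * t))
  expect_lt(max(abs(ntot - logistic) / logistic), 1e-3)
  h <- readout_histogram(pop, t = 6, g = 5)
  expect_equal(sum(h$probability), 1, tolerance = 1e-10)
  expect_true(all(h$z %% 5 == 0))
  expect_gt(utils::tail(pop$S, 1), 0)
})
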