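# run code under a temporary RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Exponential decay fixture
#'
#' One decaying species, \eqn{A(t) = A_0 e^{-kt}}, the simplest test bed
#' for uncertainty propagation: with a lognormal decay rate the response
#' PDF is available in closed form.
#'
#' @param A0 Initial concentration (`> 0`).
#' @param k Decay rate.
#' @param times Time grid (`>= 0`).
#' @return Numeric vector `A(times)`.
#' @export
decay_model <- function(A0 = 1, k, times) {
  stopifnot(A0 > 0, all(times >= 0))
  A0 * exp(-k * times)
}

#' Analytic response PDF of the decay model
#'
#' Change of variables for \eqn{A = A_0 e^{-kt}} with a lognormal rate:
#' \eqn{P_A(a) = P_k(k(a)) / (a t)} with \eqn{k(a) = -\log(a/A_0)/t}.
#'
#' @param t Single positive observation time.
#' @param spec A lognormal [param_spec()] for the rate.
#' @param a_grid Response values in `(0, A0)`.
#' @param A0 Initial concentration.
#' @return A tibble with columns `a` and `density`.
#' @export
decay_pdf_analytic <- function(t, spec, a_grid, A0 = 1) {
  stopifnot(inherits(spec, "se_param"), spec$family == "lognormal")
  if (t <= 0)
    stop("the response distribution is degenerate at t = 0")
  h <- spec$hyper
  meanlog <- log(h$mean) - h$alpha^2 / 2
  k_of_a <- -log(pmax(a_grid, .Machine$double.xmin) / A0) / t
  dens <- ifelse(a_grid > 0 & a_grid < A0, # positive rates only
                 stats::dlnorm(k_of_a, meanlog, h$alpha) / (a_grid * t),
                 0)
  tibble::tibble(a = a_grid, density = dens)
}

#' Dimerization network fixture
#'
#' Two proteins produced at rates `k1`, `k4` bind reversibly (rates `k2`
#' on, `k3` off) into a dimer; all three species degrade at rate `k5`.
#' Integrated from zero initial conditions.
#'
#' @param k Named vector with `k1..k5` (all `> 0`).
#' @param times Time grid starting at 0.
#' @return Matrix `length(times) x 3` with columns `x1`, `x2`, `x3`.
#' @export
dimer_model <- function(k, times = seq(0, 40, by = 2)) {
  stopifnot(all(k > 0), length(k) == 5)
  k <- unname(k)
  rhs <- function(t, x, p) {
    bind <- k[2] * x[1] * x[2] - k[3] * x[3]
    list(c(k[1] - bind - k[5] * x[1],
           k[4] - bind - k[5] * x[2],
           bind - k[5] * x[3]))
  }
  sol <- deSolve::lsoda(c(0, 0, 0), times, rhs, NULL,
                        rtol = 1e-8, atol = 1e-10)
  out <- unname(sol[, 2:4, drop = FALSE])
  colnames(out) <- c("x1", "x2", "x3")
  out
}

#' Parameter specs of the dimer-network study
#'
#' Lognormal rates: mean 0.1, sd 0.1 for `k1`, `k4`, `k5`; mean 0.4,
#' sd 0.1 for `k2`, `k3`.
#'
#' @return A list of five [param_spec()] objects.
#' @export
dimer_specs <- function() {
  list(
    param_spec("k1", "lognormal", mean = 0.1, sd = 0.1),
    param_spec("k2", "lognormal", mean = 0.4, sd = 0.1),
    param_spec("k3", "lognormal", mean = 0.4, sd = 0.1),
    param_spec("k4", "lognormal", mean = 0.1, sd = 0.1),
    param_spec("k5", "lognormal", mean = 0.1, sd = 0.1)
  )
}

#' Glycolytic oscillator fixture
#'
#' Two-component negative-feedback model of oscillatory glycolysis
#' (ADP `x`, F6P `y`): \eqn{\dot x = -x + \alpha y + x^2 y},
#' \eqn{\dot y = \beta - \alpha y - x^2 y}. Depending on
#' \eqn{(\alpha, \beta)} the system settles into a stable limit cycle or
#' the fixed point \eqn{(x^*, y^*) = (\beta, \beta/(\alpha + \beta^2))}.
#'
#' @param alpha,beta Positive kinetic parameters.
#' @param times Time grid.
#' @param init Initial state `c(x, y)`.
#' @return Matrix `length(times) x 2` with columns `x`, `y`.
#' @export
glycolysis_model <- function(alpha, beta, times = seq(0, 20, by = 0.1),
                             init = c(1, 1)) {
  stopifnot(alpha > 0, beta > 0)
  rhs <- function(t, s, p) {
    x <- s[1]; y <- s[2]
    list(c(-x + alpha * y + x^2 * y,
           beta - alpha * y - x^2 * y))
  }
  sol <- deSolve::lsoda(init, times, rhs, NULL, rtol = 1e-8, atol = 1e-10)
  out <- unname(sol[, 2:3, drop = FALSE])
  colnames(out) <- c("x", "y")
  out
}

#' Parameter specs of the glycolytic-oscillator study
#'
#' `alpha ~ U(0.1, 0.5)` (Legendre dim) and `beta ~ Lognormal(0.3, 0.1)`
#' (Hermite dim): a mixed-basis expansion straddling the Hopf bifurcation.
#'
#' @return A list of two [param_spec()] objects.
#' @export
glycolysis_specs <- function() {
  list(
    param_spec("alpha", "uniform", a = 0.1, b = 0.5),
    param_spec("beta", "lognormal", mean = 0.3, sd = 0.1)
  )
}
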