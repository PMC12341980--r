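#' Plasmid partition probabilities at cell division
#'
#' Probability that a daughter cell receives `k` of the mother's `n`
#' plasmids when each plasmid segregates independently with probability
#' `q` (equal division: `q = 0.5`): `Binomial(n, q)`.
#'
#' @param n Number of plasmids in the mother cell.
#' @param q Per-plasmid segregation probability.
#' @return Numeric vector of probabilities over `k = 0..n`.
#' @export
partition_probs <- function(n, q = 0.5) {
  stopifnot(n >= 0, n == round(n), q >= 0, q <= 1)
  stats::dbinom(0:n, n, q)
}

# daughter-from-mother transition matrix P[n+1, k+1] = P(daughter n | mother k)
partition_matrix <- function(n_max, q = 0.5) {
  outer(0:n_max, 0:n_max, function(n, k) stats::dbinom(n, k, q))
}

#' Default rates of the plasmid-transfection fixture
#'
#' Induced production `alpha = 2` per plasmid, mRNA/protein turnover
#' `beta = 2`, reporter production `gamma = 6` with expression-capacity
#' saturation `eta`, reporter turnover `mu = 1.5`, secretion `kappa`
#' (0 for a cell-retained reporter, 3 for a secreted one), bulk decay
#' `delta = 0.01`, volume factor `v = 1e-8`, growth rate
#' `omega = 0.034` per hour (20 h doubling time), division probability
#' `q = 0.5`, induction `I(t) = 1`.
#'
#' @param kappa Secretion rate (default 0).
#' @param eta Saturation parameter (default 0.5).
#' @return Named list of rates.
#' @export
plasmid_defaults <- function(kappa = 0, eta = 0.5) {
  list(alpha = 2, beta = 2, gamma = 6, eta = eta, mu = 1.5, kappa = kappa,
       delta = 0.01, v = 1e-8, omega = 0.034, q = 0.5)
}

#' Per-cell reporter dynamics for a given plasmid composition
#'
#' Solves \eqn{\dot x = n\alpha I(t) - \beta x} and
#' \eqn{\dot y = m\gamma x/(1 + \eta x) - (\mu + \kappa) y} from zero
#' initial conditions with \eqn{I(t) = 1}. The plasmid counts `n`, `m`
#' may be real (the expansion evaluates the model at real-valued
#' Charlier nodes).
#'
#' @param n,m Plasmid counts (induction and reporter construct).
#' @param times Time grid in hours.
#' @param rates Named list from [plasmid_defaults()].
#' @return Matrix `length(times) x 2` with columns `x`, `y`.
#' @export
plasmid_cell_model <- function(n, m, times = seq(0, 6, by = 0.25),
                               rates = plasmid_defaults()) {
  r <- rates
  rhs <- function(t, s, p) {
    x <- s[1]; y <- s[2]
    list(c(n * r$alpha - r$beta * x,
           m * r$gamma * x / (1 + r$eta * x) - (r$mu + r$kappa) * y))
  }
  sol <- deSolve::lsoda(c(0, 0), times, rhs, NULL, rtol = 1e-9, atol = 1e-12)
  out <- unname(sol[, 2:3, drop = FALSE])
  colnames(out) <- c("x", "y")
  out
}

#' Steady state of the per-cell reporter
#'
#' Closed form of the per-cell dynamics at stationarity:
#' \eqn{x^* = n\alpha/\beta} and
#' \eqn{y^* = m\gamma x^*/((1 + \eta x^*)(\mu + \kappa))}.
#'
#' @inheritParams plasmid_cell_model
#' @return Named vector `c(x, y)`.
#' @export
plasmid_cell_steady_state <- function(n, m, rates = plasmid_defaults()) {
  r <- rates
  xs <- n * r$alpha / r$beta
  c(x = xs, y = m * r$gamma * xs / ((1 + r$eta * xs) * (r$mu + r$kappa)))
}

#' Population-level plasmid model
#'
#' Evolves the pool tensor `Q[n, m]` (number of cells carrying `n`
#' induction and `m` reporter plasmids) under logistic growth with
#' binomial plasmid partitioning at division,
#' \deqn{\dot Q = \omega (1 - \|Q\|_1 / N_{max}) (2 P Q P^T - Q),}
#' together with the per-cell reporter levels `y[n, m](t)` and the bulk
#' reporter \eqn{\dot S = v\kappa \sum Q y - \delta S}. The initial pool
#' is the bivariate Poisson uptake distribution scaled to `N0` cells.
#'
#' @param uptake An [bivariate_poisson()] object (initial plasmid
#'   distribution over cells).
#' @param times Time grid in hours.
#' @param rates Named list from [plasmid_defaults()].
#' @param N0 Initial population size.
#' @param N_max Carrying capacity.
#' @param y_fun Optional function `(n, m) -> y trace over times` used for
#'   the reporter levels (e.g. a fitted spectral expansion); default
#'   solves the per-cell ODEs exactly.
#' @return A list with `times`, `Q` (array `n x m x time`), `S` (bulk
#'   reporter trace), `y` (array `n x m x time`), and `n_max`.
#' @export
plasmid_population_model <- function(uptake, times = seq(0, 72, by = 1),
                                     rates = plasmid_defaults(kappa = 3),
                                     N0 = 1e4, N_max = 1e5, y_fun = NULL) {
  stopifnot(inherits(uptake, "se_bvpois"))
  r <- rates
  n_max <- uptake$n_max
  counts <- 0:n_max
  nd <- n_max + 1
  P <- partition_matrix(n_max, r$q)
  Q0 <- bvpois_pmf_matrix(uptake) * N0
  # per-cell y traces at integer compositions; x depends on n only
  y_arr <- array(0, dim = c(nd, nd, length(times)))
  for (i in seq_len(nd)) {
    xs <- counts[i] * r$alpha / r$beta
    x_t <- xs * (1 - exp(-r$beta * times))
    drive <- r$gamma * x_t / (1 + r$eta * x_t)
    # linear ODE y' = m*drive - (mu+kappa) y solved by exact exponential
    # stepping on the (dense) time grid
    y_base <- numeric(length(times))
    for (ti in seq_along(times)[-1]) {
      dt <- times[ti] - times[ti - 1]
      dr <- (drive[ti - 1] + drive[ti]) / 2
      decay <- exp(-(r$mu + r$kappa) * dt)
      y_base[ti] <- y_base[ti - 1] * decay +
        dr / (r$mu + r$kappa) * (1 - decay)
    }
    for (j in seq_len(nd)) y_arr[i, j, ] <- counts[j] * y_base
  }
  if (!is.null(y_fun)) {
    for (i in seq_len(nd)) for (j in seq_len(nd))
      y_arr[i, j, ] <- y_fun(counts[i], counts[j])
  }
  # Q and S integrated together
  rhs <- function(t, s, p) {
    Q <- matrix(s[1:(nd * nd)], nd, nd)
    S <- s[nd * nd + 1]
    growth <- r$omega * (1 - sum(Q) / N_max)
    dQ <- growth * (2 * P %*% Q %*% t(P) - Q)
    ti <- min(max(1, findInterval(t, times)), length(times))
    y_now <- y_arr[, , ti]
    dS <- r$v * r$kappa * sum(Q * y_now) - r$delta * S
    list(c(as.vector(dQ), dS))
  }
  sol <- deSolve::lsoda(c(as.vector(Q0), 0), times, rhs, NULL,
                        rtol = 1e-8, atol = 1e-8)
  Q_arr <- array(t(sol[, 2:(nd * nd + 1)]), dim = c(nd, nd, length(times)))
  list(times = times, Q = Q_arr, S = unname(sol[, nd * nd + 2]),
       y = y_arr, n_max = n_max)
}

#' Binned single-cell readout histogram
#'
#' Distribution of the per-cell reporter level across the population at
#' one time point, binned as \eqn{z = g \lfloor y/g \rfloor} and weighted
#' by the cell pools: \eqn{P(z, t) = \sum \delta_{z, \chi_{nm}(t)}
#' Q_{nm}(t) / \|Q\|_1}.
#'
#' @param pop Result of [plasmid_population_model()].
#' @param t Time point (matched to the nearest grid time).
#' @param g Bin width.
#' @return A tibble with columns `z` and `probability`.
#' @export
readout_histogram <- function(pop, t, g = 5) {
  ti <- which.min(abs(pop$times - t))
  Q <- pop$Q[, , ti]
  y <- pop$y[, , ti]
  z <- g * floor(y / g)
  w <- Q / sum(Q)
  tibble::tibble(z = as.vector(z), w = as.vector(w)) |>
    dplyr::group_by(.data$z) |>
    dplyr::summarise(probability = sum(.data$w), .groups = "drop") |>
    dplyr::arrange(.data$z)
}
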