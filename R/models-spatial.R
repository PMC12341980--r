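# Discrete Laplacian of a 1-D line of n cells with zero-flux (reflecting)
# boundaries; rows sum to zero.
line_laplacian <- function(n) {
  L <- diag(-2, n)
  for (i in seq_len(n - 1)) {
    L[i, i + 1] <- 1
    L[i + 1, i] <- 1
  }
  L[1, 1] <- -1
  L[n, n] <- -1
  L
}

#' Schnakenberg reaction-diffusion fixture on a 1-D line of cells
#'
#' Dimensionless activator-substrate system
#' \eqn{\dot u = \nabla^2 u + \gamma(\alpha - u + u^2 v)},
#' \eqn{\dot v = d \nabla^2 v + \gamma(\beta - u^2 v)} on a line of `n`
#' cells with zero-flux boundaries, integrated from the homogeneous
#' steady state \eqn{(u_0, v_0) = (\alpha + \beta, \beta/(\alpha+\beta)^2)}
#' perturbed by 1% seeded multiplicative noise, until the relative state
#' change over a window of 10 time units drops below `tol`.
#'
#' @param alpha,beta,gamma,d Model parameters (defaults follow the
#'   one-parameter study: `beta = 1`, `gamma = 5`, `d = 20`).
#' @param n Number of cells.
#' @param seed Seed for the initial perturbation.
#' @param tol Steady-state tolerance (relative L-infinity change per
#'   window).
#' @param t_max Maximum integration time.
#' @return A list with `u`, `v` (steady-state profiles), `converged`, and
#'   `time`.
#' @export
schnakenberg_model <- function(alpha, beta = 1, gamma = 5, d = 20, n = 20,
                               seed = 1, tol = 1e-6, t_max = 2000) {
  stopifnot(alpha > 0, beta > 0, gamma > 0, d > 0)
  L <- line_laplacian(n)
  u0 <- alpha + beta
  v0 <- beta / (alpha + beta)^2
  state <- with_local_seed(seed, {
    c(u0 * (1 + 0.01 * stats::rnorm(n)), v0 * (1 + 0.01 * stats::rnorm(n)))
  })
  rhs <- function(t, s, p) {
    u <- s[1:n]; v <- s[(n + 1):(2 * n)]
    uu <- u^2 * v
    list(c(as.vector(L %*% u) + gamma * (alpha - u + uu),
           d * as.vector(L %*% v) + gamma * (beta - uu)))
  }
  t_cur <- 0
  repeat {
    sol <- deSolve::lsodes(state, c(0, 10), rhs, NULL,
                           rtol = 1e-8, atol = 1e-10)
    new_state <- sol[2, -1]
    delta <- max(abs(new_state - state)) / max(abs(new_state), 1e-12)
    state <- new_state
    t_cur <- t_cur + 10
    if (delta < tol)
      return(list(u = unname(state[1:n]), v = unname(state[(n + 1):(2 * n)]),
                  converged = TRUE, time = t_cur))
    if (t_cur >= t_max)
      stop("schnakenberg_model: no steady state reached within t_max")
  }
}

#' Turing-space test for the Schnakenberg fixture
#'
#' Linear stability analysis on the discrete Laplacian spectrum: the
#' homogeneous steady state must be stable without diffusion and at least
#' one non-uniform spatial mode must be unstable with diffusion.
#'
#' @inheritParams schnakenberg_model
#' @return `TRUE` if the parameters lie in the Turing space.
#' @export
turing_space_test <- function(alpha, beta = 1, gamma = 5, d = 20, n = 20) {
  u0 <- alpha + beta
  v0 <- beta / (alpha + beta)^2
  J <- gamma * matrix(c(-1 + 2 * u0 * v0, u0^2,
                        -2 * u0 * v0, -u0^2), 2, 2, byrow = TRUE)
  if (max(Re(eigen(J, only.values = TRUE)$values)) >= 0) return(FALSE)
  mu <- -2 * (1 - cos(pi * seq_len(n - 1) / n)) # Neumann path-graph modes
  any(vapply(mu, function(m)
    max(Re(eigen(J + diag(c(m, d * m)), only.values = TRUE)$values)) > 0,
    TRUE))
}

# 6-neighbour Laplacian of a periodic nr x nc hexagonal (offset) lattice
hex_laplacian <- function(nr = 20, nc = 20) {
  idx <- function(r, c) ((r - 1) %% nr) * nc + ((c - 1) %% nc) + 1
  n <- nr * nc
  L <- matrix(0, n, n)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      i <- idx(r, c)
      off <- if (r %% 2 == 0) 0 else -1 # row-offset hex neighbourhood
      nb <- rbind(
        c(r, c - 1), c(r, c + 1),
        c(r - 1, c + off), c(r - 1, c + off + 1),
        c(r + 1, c + off), c(r + 1, c + off + 1)
      )
      for (q in seq_len(6)) L[i, idx(nb[q, 1], nb[q, 2])] <-
          L[i, idx(nb[q, 1], nb[q, 2])] + 1
      L[i, i] <- L[i, i] - 6
    }
  }
  L
}

# mode eigenvalues of the periodic hex Laplacian (memoized; the offset
# wrap makes the closed triangular-torus formula inexact, so they are
# taken from the operator itself)
hex_mode_cache <- new.env(parent = emptyenv())
hex_mode_eigenvalues <- function(nr = 20, nc = 20) {
  key <- paste(nr, nc, sep = "x")
  if (is.null(hex_mode_cache[[key]])) {
    ev <- eigen(hex_laplacian(nr, nc), symmetric = TRUE,
                only.values = TRUE)$values
    hex_mode_cache[[key]] <- unique(round(ev, 10))
  }
  hex_mode_cache[[key]]
}

#' Default fixed parameters of the trichome fixture
#'
#' The basal TTG1 production `alpha` is the uncertain parameter of the
#' study; the remaining rates are fixed at `lambda = 0.3` (TTG1 turnover),
#' `delta = 2` (TTG1 cell-to-cell diffusion), `beta = 6` (GL3 activation
#' by the activating complex), chosen so that the Turing-space boundary
#' falls inside the studied range `alpha` in `[0.4, 0.9]`.
#'
#' @return Named list of defaults.
#' @export
trichome_defaults <- function() {
  list(lambda = 0.3, delta = 2, beta = 6, nr = 20, nc = 20)
}

# homogeneous steady states of the trichome reaction part: roots T of
# alpha = lambda T + (1 + T)/(beta T), with G = (1+T)/(beta T^2), A = T G
trichome_steady_states <- function(alpha, lambda, beta) {
  f <- function(T) lambda * T + (1 + T) / (beta * T) - alpha
  Ts <- exp(seq(log(1e-4), log(1e3), length.out = 2000))
  v <- vapply(Ts, f, 0)
  roots <- numeric(0)
  for (i in seq_len(length(Ts) - 1)) {
    if (is.finite(v[i]) && is.finite(v[i + 1]) && v[i] * v[i + 1] < 0)
      roots <- c(roots, stats::uniroot(f, c(Ts[i], Ts[i + 1]),
                                       tol = 1e-12)$root)
  }
  lapply(roots, function(T) {
    G <- (1 + T) / (beta * T^2)
    c(T = T, G = G, A = T * G)
  })
}

trichome_reaction_jacobian <- function(ss, lambda, beta) {
  T <- ss[["T"]]; G <- ss[["G"]]; A <- ss[["A"]]
  matrix(c(-lambda - G, -T, 0,
           -G, -1 - T, 2 * beta * A,
           G, T, -1), 3, 3, byrow = TRUE)
}

#' Turing-space test for the trichome fixture
#'
#' A parameter set is in the Turing space if some homogeneous steady
#' state is stable without diffusion but destabilized by TTG1 diffusion on
#' at least one non-uniform mode of the periodic hexagonal lattice.
#'
#' @param alpha Basal TTG1 production.
#' @param lambda,delta,beta Fixed rates (see [trichome_defaults()]).
#' @param nr,nc Lattice dimensions.
#' @return `TRUE` if a diffusion-driven instability exists.
#' @export
trichome_turing_test <- function(alpha, lambda = 0.3, delta = 2, beta = 6,
                                 nr = 20, nc = 20) {
  mu <- hex_mode_eigenvalues(nr, nc)
  mu <- mu[mu < -1e-9]
  for (ss in trichome_steady_states(alpha, lambda, beta)) {
    J <- trichome_reaction_jacobian(ss, lambda, beta)
    if (max(Re(eigen(J, only.values = TRUE)$values)) >= 0) next
    unstable <- any(vapply(mu, function(m)
      max(Re(eigen(J + diag(c(delta * m, 0, 0)),
                   only.values = TRUE)$values)) > 0, TRUE))
    if (unstable) return(TRUE)
  }
  FALSE
}

#' Trichome patterning fixture on a periodic hexagonal lattice
#'
#' Substrate-depletion model of leaf-hair (trichome) initiation: the
#' substrate TTG1 (basal production `alpha`, turnover `lambda`,
#' cell-to-cell diffusion `delta`) binds the transcription factor GL3 to
#' form the activating complex AC, which in turn drives GL3 production
#' (`beta`). 1200 coupled ODEs (3 species x 20 x 20 cells) integrated to
#' steady state from a stable homogeneous state with 1% seeded noise.
#'
#' @inheritParams trichome_turing_test
#' @param seed Seed for the initial perturbation.
#' @param tol Steady-state tolerance (relative L-infinity change per
#'   window of 10 time units).
#' @param t_max Maximum integration time.
#' @return A list with the steady-state `AC` field (length `nr * nc`),
#'   `TTG1`, `GL3`, `converged`, and `time`.
#' @export
trichome_model <- function(alpha, lambda = 0.3, delta = 2, beta = 6,
                           nr = 20, nc = 20, seed = 1, tol = 1e-6,
                           t_max = 3000) {
  n <- nr * nc
  L <- hex_laplacian(nr, nc)
  sss <- trichome_steady_states(alpha, lambda, beta)
  stable <- NULL
  for (ss in sss) {
    J <- trichome_reaction_jacobian(ss, lambda, beta)
    if (max(Re(eigen(J, only.values = TRUE)$values)) < 0) { stable <- ss; break }
  }
  if (is.null(stable)) stable <- sss[[1]]
  state <- with_local_seed(seed, {
    c(stable[["T"]] * (1 + 0.01 * stats::rnorm(n)),
      stable[["G"]] * (1 + 0.01 * stats::rnorm(n)),
      stable[["A"]] * (1 + 0.01 * stats::rnorm(n)))
  })
  rhs <- function(t, s, p) {
    T <- s[1:n]; G <- s[(n + 1):(2 * n)]; A <- s[(2 * n + 1):(3 * n)]
    TG <- T * G
    list(c(alpha - lambda * T - TG + delta * as.vector(L %*% T),
           beta * A^2 - G - TG,
           TG - A))
  }
  t_cur <- 0
  repeat {
    sol <- deSolve::lsodes(state, c(0, 10), rhs, NULL,
                           rtol = 1e-7, atol = 1e-9)
    new_state <- sol[2, -1]
    delta_rel <- max(abs(new_state - state)) / max(abs(new_state), 1e-12)
    state <- new_state
    t_cur <- t_cur + 10
    if (delta_rel < tol)
      return(list(TTG1 = unname(state[1:n]),
                  GL3 = unname(state[(n + 1):(2 * n)]),
                  AC = unname(state[(2 * n + 1):(3 * n)]),
                  converged = TRUE, time = t_cur))
    if (t_cur >= t_max)
      stop("trichome_model: no steady state reached within t_max")
  }
}

#' Trichome density of an AC field
#'
#' Fraction of cells whose activating-complex level exceeds the
#' half-maximum of the field (the half-maximum stands in for the unknown
#' biological commitment threshold).
#'
#' @param field Numeric AC field.
#' @return Density in `[0, 1]` (`count / length(field)`).
#' @export
trichome_density <- function(field) {
  sum(field > max(field) / 2) / length(field)
}

#' Gated trichome-density response
#'
#' The scalar response used in the uncertainty study: the trichome
#' density of the patterned steady state when the parameter lies in the
#' Turing space, and exactly 0 otherwise — in `"direct"` mode the model
#' is not even solved outside the Turing space.
#'
#' @param alpha Basal TTG1 production.
#' @param mode `"direct"` (density is the expanded response) or
#'   `"field"` (return the full AC field, gated to the homogeneous value
#'   outside the Turing space; densities are then extracted from
#'   reconstructed fields in post-processing).
#' @param ... Passed to [trichome_model()] / [trichome_turing_test()].
#' @return Density (direct) or AC field (field mode).
#' @export
trichome_response <- function(alpha, mode = c("direct", "field"), ...) {
  mode <- match.arg(mode)
  in_ts <- trichome_turing_test(alpha, ...)
  if (mode == "direct") {
    if (!in_ts) return(0)
    return(trichome_density(trichome_model(alpha, ...)$AC))
  }
  if (!in_ts) {
    d <- list(...)
    def <- trichome_defaults()
    lambda <- if (!is.null(d$lambda)) d$lambda else def$lambda
    beta <- if (!is.null(d$beta)) d$beta else def$beta
    nr <- if (!is.null(d$nr)) d$nr else def$nr
    nc <- if (!is.null(d$nc)) d$nc else def$nc
    sss <- trichome_steady_states(alpha, lambda, beta)
    return(rep(sss[[1]][["A"]], nr * nc))
  }
  trichome_model(alpha, ...)$AC
}
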