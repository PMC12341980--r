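# Sobol low-discrepancy sequence (Gray-code construction) with Joe-Kuo
# direction numbers for the first 10 dimensions. No QMC generator is
# available in the R dependency stack, so the primitive is implemented
# here and checked against an independent reference in the tests.
sobol_direction_params <- list(
  # dimension 1 is the van der Corput sequence in base 2
  list(s = 1L, a = 0L, m = c(1L)),           # d = 2
  list(s = 2L, a = 1L, m = c(1L, 3L)),       # d = 3
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),   # d = 4
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),   # d = 5
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),    # d = 6
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),   # d = 7
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),  # d = 8
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),   # d = 9
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L))  # d = 10
)

sobol_nbits <- 31L

# direction integers V_k (scaled by 2^(31-k)) for one dimension
sobol_directions <- function(dim_index) {
  V <- integer(sobol_nbits)
  if (dim_index == 1) {
    for (k in seq_len(sobol_nbits)) V[k] <- bitwShiftL(1L, sobol_nbits - k)
    return(V)
  }
  p <- sobol_direction_params[[dim_index - 1L]]
  s <- p$s; a <- p$a; m <- p$m
  for (k in seq_len(min(s, sobol_nbits)))
    V[k] <- bitwShiftL(m[k], sobol_nbits - k)
  if (sobol_nbits > s) {
    for (k in (s + 1L):sobol_nbits) {
      V[k] <- bitwXor(V[k - s], bitwShiftR(V[k - s], s))
      if (s > 1) {
        for (i in seq_len(s - 1L)) {
          if (bitwAnd(bitwShiftR(a, s - 1L - i), 1L) == 1L)
            V[k] <- bitwXor(V[k], V[k - i])
        }
      }
    }
  }
  V
}

#' Sobol low-discrepancy points on the unit hypercube
#'
#' Gray-code Sobol sequence for up to 10 dimensions, optionally scrambled
#' by a seeded random digital shift (XOR of all points with one random
#' bit vector per dimension), which keeps the sequence's equidistribution
#' while removing the deterministic origin point.
#'
#' @param n Number of points.
#' @param dim Number of dimensions (`<= 10`).
#' @param scramble_seed Integer seed for the digital shift; `NULL` leaves
#'   the sequence unscrambled (first point is the origin).
#' @return An `n x dim` matrix of points in `[0, 1)`.
#' @export
sobol_sequence <- function(n, dim, scramble_seed = NULL) {
  stopifnot(n >= 1, dim >= 1)
  if (dim > 10)
    stop("sobol_sequence supports up to 10 dimensions")
  X <- matrix(0L, n, dim)
  for (d in seq_len(dim)) {
    V <- sobol_directions(d)
    x <- 0L
    X[1, d] <- x
    if (n > 1) {
      for (i in 2:n) {
        # Gray code: index of lowest zero bit of i-1
        c_ <- 1L
        v <- i - 2L
        while (bitwAnd(v, 1L) == 1L) { v <- bitwShiftR(v, 1L); c_ <- c_ + 1L }
        x <- bitwXor(x, V[c_])
        X[i, d] <- x
      }
    }
  }
  if (!is.null(scramble_seed)) {
    # digital shift from a small deterministic bit generator so the global
    # RNG stream is left untouched
    state <- as.integer(scramble_seed) %% 2147483647L
    if (state <= 0L) state <- state + 2147483646L
    next_bit <- function() {
      state <<- as.integer((as.double(state) * 16807) %% 2147483647)
      as.integer(state %% 2L)
    }
    for (d in seq_len(dim)) {
      shift <- 0L
      for (b in seq_len(sobol_nbits))
        shift <- bitwOr(shift, bitwShiftL(next_bit(), b - 1L))
      X[, d] <- bitwXor(X[, d], shift)
    }
  }
  X / 2^sobol_nbits
}

#' Quasi-Monte-Carlo sample of standard variables
#'
#' Maps a (scrambled) Sobol sequence through each parameter's standard
#' distribution: affine for uniform dims, inverse normal CDF for
#' normal/lognormal dims, Poisson quantile for count dims. Deterministic
#' given the scramble seed.
#'
#' @param specs A single [param_spec()] or list of them.
#' @param n Number of sample points.
#' @param scramble_seed Integer seed for the Sobol digital shift.
#' @return An `n x length(specs)` matrix of standard-variable samples with
#'   parameter names as column names.
#' @export
qmc_sample <- function(specs, n, scramble_seed = 1L) {
  if (inherits(specs, "se_param")) specs <- list(specs)
  U <- sobol_sequence(n, length(specs), scramble_seed = scramble_seed)
  out <- vapply(seq_along(specs), function(j)
    standard_quantile(specs[[j]])(U[, j]), numeric(n))
  out <- matrix(out, nrow = n)
  colnames(out) <- vapply(specs, `[[`, "", "name")
  out
}

#' Blocking-method error estimate for a Monte-Carlo mean
#'
#' Splits the sample into `n_blocks` consecutive blocks (truncating a
#' non-divisible remainder), takes the mean of each block, and reports the
#' grand mean of the block means together with their standard deviation
#' divided by `sqrt(n_blocks)` — an error bar that is robust to residual
#' correlation within blocks.
#'
#' @param values Numeric sample vector.
#' @param n_blocks Number of blocks (`>= 2`).
#' @return A list with `estimate` and `error`.
#' @export
blocking_error <- function(values, n_blocks = 16) {
  stopifnot(n_blocks >= 2)
  if (length(values) < n_blocks)
    stop("fewer samples than blocks")
  per <- length(values) %/% n_blocks
  values <- values[seq_len(per * n_blocks)]
  bm <- colMeans(matrix(values, nrow = per))
  list(estimate = mean(bm), error = stats::sd(bm) / sqrt(n_blocks))
}

#' Quasi-Monte-Carlo reference moments for a model
#'
#' Runs the model over a QMC sample of the parameter space and reports
#' mean and variance per output component with blocking-method error
#' bars.
#'
#' @param model Function from named physical parameter vector to numeric
#'   output.
#' @param specs A single [param_spec()] or list of them.
#' @param n Number of sample points.
#' @param n_blocks Blocks for the error estimate.
#' @param scramble_seed Sobol scramble seed.
#' @return An object of class `"se_mc"`: list with `samples` (outputs
#'   matrix), `theta` (standard sample), and a `moments` tibble
#'   (`component`, `mean`, `mean_error`, `variance`, `variance_error`).
#' @export
mc_reference <- function(model, specs, n = 1024, n_blocks = 16,
                         scramble_seed = 1L) {
  if (inherits(specs, "se_param")) specs <- list(specs)
  theta <- qmc_sample(specs, n, scramble_seed = scramble_seed)
  out <- NULL
  for (i in seq_len(n)) {
    phys <- vapply(seq_along(specs), function(j)
      to_physical(specs[[j]], theta[i, j]), 0)
    names(phys) <- colnames(theta)
    y <- as.numeric(model(phys))
    if (is.null(out)) out <- matrix(0, n, length(y),
                                    dimnames = list(NULL, names(y)))
    out[i, ] <- y
  }
  moments <- purrr::map_dfr(seq_len(ncol(out)), function(cc) {
    bm <- blocking_error(out[, cc], n_blocks)
    bv <- blocking_error((out[, cc] - mean(out[, cc]))^2, n_blocks)
    tibble::tibble(component = cc,
                   mean = bm$estimate, mean_error = bm$error,
                   variance = bv$estimate, variance_error = bv$error)
  })
  structure(list(samples = out, theta = theta, moments = moments,
                 n = n, n_blocks = n_blocks,
                 scramble_seed = scramble_seed),
            class = "se_mc")
}

#' @export
print.se_mc <- function(x, ...) {
  cat(sprintf("<se_mc> %d QMC samples, %d output component(s)\n",
              x$n, ncol(x$samples)))
  print(x$moments)
  invisible(x)
}

#' Gaussian kernel density estimate on a grid
#'
#' Standard Gaussian-kernel KDE with Silverman's rule-of-thumb bandwidth
#' `h = 0.9 * min(sd, IQR/1.34) * n^(-1/5)`, evaluated on a user-supplied
#' grid.
#'
#' @param samples Numeric sample (at least two distinct values).
#' @param grid Numeric grid to evaluate the density on.
#' @param bw Optional bandwidth override.
#' @return A tibble with columns `grid` and `density`.
#' @export
kde <- function(samples, grid, bw = NULL) {
  samples <- samples[is.finite(samples)]
  if (length(unique(samples)) < 2)
    stop("KDE needs at least two distinct sample values")
  if (is.null(bw)) {
    s <- stats::sd(samples)
    iqr <- stats::IQR(samples) / 1.34
    spread <- if (iqr > 0) min(s, iqr) else s
    bw <- 0.9 * spread * length(samples)^(-1 / 5)
  }
  if (bw <= 0) stop("zero-variance sample: bandwidth is not defined")
  if (length(samples) <= 5000) {
    dens <- vapply(grid, function(g)
      mean(stats::dnorm((g - samples) / bw)) / bw, 0)
  } else {
    lo <- min(min(samples), min(grid)) - 5 * bw
    hi <- max(max(samples), max(grid)) + 5 * bw
    d <- stats::density(samples, bw = bw, kernel = "gaussian",
                        from = lo, to = hi, n = 4096)
    dens <- stats::approx(d$x, d$y, xout = grid, rule = 2)$y
  }
  tibble::tibble(grid = grid, density = dens)
}

#' Plot a KDE curve
#'
#' @param object A tibble from [kde()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_kde <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "response", y = "density")
}
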