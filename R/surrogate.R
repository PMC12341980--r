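#' Fit a spectral-expansion surrogate to a deterministic model
#'
#' Builds a non-intrusive spectral-expansion (polynomial chaos) meta-model:
#' for each uncertain parameter an orthonormal basis of the given order is
#' constructed, the symmetric multiplication-operator matrix is
#' eigendecomposed into evaluation nodes and weights, and the model is run
#' once per tensor-product node tuple (`prod(order)` runs in total). All
#' theta-independent quantities (nodes, eigenvectors, expansion
#' coefficients) are precomputed and cached in the returned object.
#'
#' The model is called with *physical* parameter values: each standard-node
#' coordinate is pushed through the spec's isoprobabilistic transform
#' first. The model may return a scalar or a numeric vector (e.g. a time
#' course or a spatial field); vector outputs are expanded component-wise
#' sharing one node set.
#'
#' @param model A function taking a named numeric vector of physical
#'   parameters and returning a finite numeric scalar or vector of fixed
#'   length.
#' @param specs A single [param_spec()] or a list of them.
#' @param order Expansion order per dimension (number of basis functions =
#'   number of nodes = number of model evaluations per dimension); scalar
#'   or vector of length `length(specs)`.
#' @param basis Optional list of [basis_family()] objects overriding the
#'   default basis per dimension (e.g. a Haar family for a bifurcating
#'   response).
#' @return An object of class `"se_surrogate"`.
#' @examples
#' s <- se_fit(function(p) exp(-p[["k"]]),
#'             param_spec("k", "lognormal", mean = 0.5, sd = 0.2),
#'             order = 5)
#' predict(s, 0)
#' se_moments(s)
#' @export
se_fit <- function(model, specs, order, basis = NULL) {
  if (inherits(specs, "se_param")) specs <- list(specs)
  stopifnot(length(specs) >= 1,
            all(vapply(specs, inherits, TRUE, "se_param")))
  M <- length(specs)
  order <- as.integer(rep_len(order, M))
  dims <- vector("list", M)
  for (j in seq_len(M)) {
    fam <- if (!is.null(basis)) basis[[j]] else basis_for(specs[[j]], order[j])
    stopifnot(inherits(fam, "se_basis"), fam$order == order[j])
    dims[[j]] <- list(spec = specs[[j]], family = fam, nodes = se_nodes(fam))
  }
  node_list <- lapply(dims, function(d) d$nodes$values)
  # node tuples iterated column-major (first dimension fastest), each
  # dimension's nodes ascending; this ordering is part of the object
  grid <- as.matrix(expand.grid(node_list, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- vapply(specs, `[[`, "", "name")
  responses <- eval_model_grid(model, grid, dims)
  structure(
    list(dims = dims, order = order, node_grid = grid,
         responses = responses,
         coefficients = se_coefficients(responses, dims),
         n_evals = nrow(grid)),
    class = "se_surrogate"
  )
}

# run the model at every node tuple; rows of `grid` are standard-variable
# tuples. Returns an (n_tuples x n_out) matrix.
eval_model_grid <- function(model, grid, dims) {
  n <- nrow(grid)
  out <- NULL
  for (i in seq_len(n)) {
    phys <- vapply(seq_along(dims), function(j)
      to_physical(dims[[j]]$spec, grid[i, j]), 0)
    names(phys) <- colnames(grid)
    y <- tryCatch(as.numeric(model(phys)), error = function(e)
      stop(sprintf("model failed at %s: %s",
                   paste(sprintf("%s = %.6g", names(phys), phys),
                         collapse = ", "), conditionMessage(e))))
    if (any(!is.finite(y)))
      stop(sprintf("model returned non-finite output at %s",
                   paste(sprintf("%s = %.6g", names(phys), phys),
                         collapse = ", ")))
    if (is.null(out)) out <- matrix(0, n, length(y),
                                    dimnames = list(NULL, names(y)))
    out[i, ] <- y
  }
  out
}

# tensor-times-matrix along one mode of a column-major response tensor:
# A has dim c(N1..NM, n_out) flattened to (prod(N), n_out); contract mode j
# with t(G): result[.., n_j, ..] = sum_l G[l, n] A[.., l, ..]
mode_multiply <- function(A, G_list) {
  Ns <- vapply(G_list, nrow, 0L)
  n_out <- ncol(A)
  arr <- array(A, dim = c(Ns, n_out))
  Mn <- length(Ns)
  for (j in seq_len(Mn)) {
    perm <- c(j, setdiff(seq_len(Mn + 1), j))
    arr <- aperm(arr, perm)
    d <- dim(arr)
    arr <- t(G_list[[j]]) %*% matrix(arr, nrow = d[1])
    dim(arr) <- d
    arr <- aperm(arr, order(perm))
  }
  matrix(arr, ncol = n_out)
}

# expansion coefficients c_{n1..nM} = sum_l Y_l prod_j u1^{(lj)} u_{nj+1}^{(lj)}
se_coefficients <- function(responses, dims) {
  G_list <- lapply(dims, function(d)
    t(d$nodes$vectors) * d$nodes$w1) # G[l, n] = u1^{(l)} u_{n+1}^{(l)}
  se_struct_names(mode_multiply(responses, G_list), responses)
}

se_struct_names <- function(coef, responses) {
  colnames(coef) <- colnames(responses)
  coef
}

# multi-index matrix matching the coefficient row order (column-major,
# first dimension fastest); entries are basis degrees 0..N-1
se_multi_index <- function(s) {
  as.matrix(expand.grid(lapply(s$order, function(N) 0:(N - 1)),
                        KEEP.OUT.ATTRS = FALSE))
}

#' Evaluate a spectral-expansion surrogate
#'
#' Evaluates the truncated expansion at standard-variable points (use
#' [to_standard()] to convert physical parameter values first).
#'
#' @param object An `"se_surrogate"`.
#' @param theta Numeric vector (one point) or matrix with one point per
#'   row, in standard variables, one column per dimension.
#' @param ... Unused.
#' @return A numeric vector (one point, possibly multi-component output) or
#'   a matrix (points x output components).
#' @export
predict.se_surrogate <- function(object, theta, ...) {
  if (is.null(dim(theta)))
    theta <- matrix(theta, nrow = if (length(object$dims) == 1)
      length(theta) else 1, ncol = length(object$dims),
      byrow = length(object$dims) > 1)
  stopifnot(ncol(theta) == length(object$dims))
  n_q <- nrow(theta)
  n_out <- ncol(object$coefficients)
  out <- matrix(0, n_q, n_out, dimnames = list(NULL, colnames(object$coefficients)))
  # phi_j matrices: (n_q x N_j) basis values per dimension
  phi <- lapply(seq_along(object$dims), function(j)
    eval_basis_matrix(object$dims[[j]]$family, theta[, j]))
  mi <- se_multi_index(object)
  for (q in seq_len(n_q)) {
    wt <- rep(1, nrow(mi))
    for (j in seq_along(object$dims))
      wt <- wt * phi[[j]][q, mi[, j] + 1L]
    out[q, ] <- crossprod(object$coefficients, wt)
  }
  if (n_q == 1 || n_out == 1) drop(out) else out
}

#' Mean and variance of the surrogate response
#'
#' The mean is the zeroth expansion coefficient and the variance the sum of
#' squares of all other coefficients, per output component — no further
#' model evaluations or sampling are needed.
#'
#' @param s An `"se_surrogate"`.
#' @return A tibble with columns `component`, `mean`, `variance`.
#' @export
se_moments <- function(s) {
  stopifnot(inherits(s, "se_surrogate"))
  mi <- se_multi_index(s)
  zero <- rowSums(mi) == 0
  mean_ <- s$coefficients[zero, ]
  var_ <- colSums(s$coefficients[!zero, , drop = FALSE]^2)
  tibble::tibble(
    component = seq_len(ncol(s$coefficients)),
    mean = as.numeric(mean_),
    variance = as.numeric(var_)
  )
}

# partial/total variance sums behind the Sobol indices
sobol_variances <- function(s, i, exclusive = TRUE) {
  mi <- se_multi_index(s)
  nonzero <- rowSums(mi) > 0
  D_hat <- colSums(s$coefficients[nonzero, , drop = FALSE]^2)
  # a numerically constant model has no variance to decompose
  scale0 <- pmax(abs(s$coefficients[!nonzero, ]), 1)
  D_hat[sqrt(D_hat) <= 1e-12 * scale0] <- 0
  sel <- if (exclusive)
    mi[, i] > 0 & rowSums(mi[, -i, drop = FALSE]) == 0
  else
    mi[, i] > 0
  D_i <- colSums(s$coefficients[sel, , drop = FALSE]^2)
  list(D_i = D_i, D_hat = D_hat)
}

#' First-order Sobol sensitivity index
#'
#' Fraction of the output variance attributable to dimension `i` alone:
#' the sum of squared coefficients over multi-indices active *only* in
#' dimension `i`, divided by the total variance.
#'
#' @param s An `"se_surrogate"`.
#' @param i Dimension index.
#' @return Numeric vector, one index in `[0, 1]` per output component.
#' @seealso [sobol_total_like()] for the looser "any multi-index active in
#'   dimension i" sum (a total-effect-like quantity).
#' @export
sobol_first_order <- function(s, i) {
  v <- sobol_variances(s, i, exclusive = TRUE)
  sobol_ratio(v)
}

# indices are undefined where an output component has no variance (e.g. a
# fixed initial condition in a time course); a fully constant model errors
sobol_ratio <- function(v) {
  if (all(v$D_hat <= 0))
    stop("total variance is zero (constant model): Sobol index undefined")
  out <- ifelse(v$D_hat > 0, v$D_i / v$D_hat, NA_real_)
  unname(out)
}

#' Total-effect-like Sobol sum
#'
#' Sums squared coefficients over *all* multi-indices whose `i`-th entry is
#' positive (including interactions), normalized by the total variance.
#' Together with [sobol_first_order()] this brackets the contribution of
#' dimension `i`.
#'
#' @inheritParams sobol_first_order
#' @return Numeric vector, one value per output component.
#' @export
sobol_total_like <- function(s, i) {
  v <- sobol_variances(s, i, exclusive = FALSE)
  sobol_ratio(v)
}

#' Sobol index table for all dimensions
#'
#' @param s An `"se_surrogate"`.
#' @return A tibble with columns `parameter`, `component`, `first_order`,
#'   `total_like`.
#' @export
se_sobol <- function(s) {
  stopifnot(inherits(s, "se_surrogate"))
  purrr::map_dfr(seq_along(s$dims), function(i) {
    tibble::tibble(
      parameter = s$dims[[i]]$spec$name,
      component = seq_len(ncol(s$coefficients)),
      first_order = sobol_first_order(s, i),
      total_like = sobol_total_like(s, i)
    )
  })
}

#' @export
print.se_surrogate <- function(x, ...) {
  cat(sprintf(
    "<se_surrogate> %d dim(s), order %s, %d model evaluations, %d output component(s)\n",
    length(x$dims), paste(x$order, collapse = "x"), x$n_evals,
    ncol(x$coefficients)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the expansion coefficients
#'
#' @param x An `"se_surrogate"`.
#' @param ... Unused.
#' @return A tibble with one row per (multi-index, output component):
#'   degree columns per parameter, `component`, `coefficient`.
#' @exportS3Method generics::tidy
tidy.se_surrogate <- function(x, ...) {
  mi <- se_multi_index(x)
  colnames(mi) <- vapply(x$dims, function(d) d$spec$name, "")
  tibble::as_tibble(mi) |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    tidyr::expand_grid(component = seq_len(ncol(x$coefficients))) |>
    dplyr::mutate(coefficient = x$coefficients[cbind(.data$.row, .data$component)]) |>
    dplyr::select(-".row")
}

#' One-row summary of a fitted surrogate
#'
#' @param x An `"se_surrogate"`.
#' @param ... Unused.
#' @return A tibble with `n_dims`, `order`, `n_evals`, `n_components`, and
#'   the mean/variance of the first output component.
#' @exportS3Method generics::glance
glance.se_surrogate <- function(x, ...) {
  m <- se_moments(x)
  tibble::tibble(
    n_dims = length(x$dims),
    order = paste(x$order, collapse = "x"),
    n_evals = x$n_evals,
    n_components = ncol(x$coefficients),
    mean = m$mean[1],
    variance = m$variance[1]
  )
}

#' Plot a one-dimensional surrogate against its nodes
#'
#' Draws the reconstructed response over the standard variable with the
#' model-evaluation nodes overlaid (first output component).
#'
#' @param object A one-dimensional `"se_surrogate"`.
#' @param n_grid Number of grid points.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.se_surrogate <- function(object, n_grid = 201, ...) {
  stopifnot(length(object$dims) == 1)
  fam <- object$dims[[1]]$family
  rng <- switch(fam$kind,
    legendre = c(-1, 1), hermite = c(-3, 3),
    charlier = c(0, charlier_support_max(fam$lambda, 1e-6)),
    haar = fam$support)
  g <- seq(rng[1], rng[2], length.out = n_grid)
  yfit <- predict(object, g)
  if (is.matrix(yfit)) yfit <- yfit[, 1]
  df <- tibble::tibble(theta = g, value = yfit)
  nodes <- tibble::tibble(theta = object$node_grid[, 1],
                          value = object$responses[, 1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = nodes, colour = "red") +
    ggplot2::labs(x = "standard variable", y = "surrogate response")
}
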