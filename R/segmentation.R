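#' Segment scaling function
#'
#' Affine map \eqn{g_m(\theta) = 2mL/(2M+1) + \theta/(2M+1)} taking the
#' full standard interval \eqn{[-L, L]} into the segment
#' \eqn{I_m = [(2m-1)L/(2M+1),\ (2m+1)L/(2M+1)]}. With granularity `M` the
#' interval is divided into `2M+1` equal segments indexed
#' `m = -M, ..., M`.
#'
#' @param m Segment index, `|m| <= M`.
#' @param M Segmentation granularity (non-negative integer).
#' @param L Half-width of the standard interval (`> 0`).
#' @param theta Point(s) in `[-L, L]`.
#' @return The image point(s) in segment `m`.
#' @examples
#' scaling_function(-1, M = 1, L = 1, theta = 1) # upper end of the lowest segment
#' @export
scaling_function <- function(m, M, L, theta) {
  check_segment_args(m, M, L)
  if (any(abs(theta) > L + 1e-12))
    stop("theta outside [-L, L]")
  2 * m * L / (2 * M + 1) + theta / (2 * M + 1)
}

#' Inverse segment scaling function
#'
#' @inheritParams scaling_function
#' @param y Point(s) in segment `I_m`.
#' @return The preimage in `[-L, L]`.
#' @export
scaling_function_inv <- function(m, M, L, y) {
  check_segment_args(m, M, L)
  (2 * M + 1) * y - 2 * m * L
}

check_segment_args <- function(m, M, L) {
  stopifnot(M >= 0, M == round(M), L > 0)
  if (any(abs(m) > M) || any(m != round(m)))
    stop("segment index m must be an integer with |m| <= M")
  invisible(TRUE)
}

#' Segment index containing a point
#'
#' The index function \eqn{m^* = \lfloor (2M+1)y/(2L) + 1/2 \rfloor},
#' clamped to `[-M, M]` so that the endpoints `y = +-L` map to the outer
#' segments (the floor formula overflows by one at `y = +L` exactly).
#' Segments are right-open except the topmost.
#'
#' @param y Point(s) in `[-L, L]`.
#' @param M Segmentation granularity.
#' @param L Half-width of the standard interval.
#' @return Integer segment index (vector) in `[-M, M]`.
#' @export
segment_index <- function(y, M, L) {
  stopifnot(M >= 0, M == round(M), L > 0)
  if (any(abs(y) > L + 1e-12))
    stop("y outside [-L, L]")
  m <- floor((2 * M + 1) * y / (2 * L) + 0.5)
  pmin(pmax(m, -M), M)
}

#' Fit a segmented (piecewise) spectral-expansion surrogate
#'
#' Divides each dimension's standard interval `[-L, L]` into `2M+1` equal
#' segments and fits an independent order-`N` expansion on every segment
#' tuple, by composing the model with the segment scaling map per
#' dimension. Total model evaluations: `(2M+1)^K * N^K` for `K`
#' dimensions. Evaluation selects the segment tuple via [segment_index()]
#' per dimension and sums the `N^K` terms of that tuple's expansion.
#'
#' Bounded standard variables (uniform dims) use `L = 1`; unbounded ones
#' (normal / lognormal, i.e. Hermite dims) are truncated to `[-L, L]` with
#' default `L = 5` (standard-normal tail mass below `6e-7`).
#'
#' @inheritParams se_fit
#' @param M Segmentation granularity (scalar or per dimension); `M = 0`
#'   reduces exactly to the unsegmented surrogate.
#' @param L Half-width per dimension; default 1 for uniform dims and 5 for
#'   normal/lognormal dims.
#' @return An object of class `"se_segmented"`.
#' @export
se_fit_segmented <- function(model, specs, order, M, L = NULL) {
  if (inherits(specs, "se_param")) specs <- list(specs)
  K <- length(specs)
  order <- as.integer(rep_len(order, K))
  M <- as.integer(rep_len(M, K))
  if (is.null(L))
    L <- vapply(specs, function(sp)
      if (sp$family == "uniform") 1 else 5, 0)
  L <- rep_len(L, K)
  seg_list <- lapply(M, function(Mi) seq.int(-Mi, Mi))
  seg_grid <- as.matrix(expand.grid(seg_list, KEEP.OUT.ATTRS = FALSE))
  fits <- vector("list", nrow(seg_grid))
  for (r in seq_len(nrow(seg_grid)))
    fits[[r]] <- se_fit_on_segment(model, specs, order, seg_grid[r, ], M, L)
  structure(
    list(specs = specs, order = order, M = M, L = L,
         seg_grid = seg_grid, fits = fits,
         n_evals = as.integer(sum(vapply(fits, function(f) f$n_evals, 0)))),
    class = "se_segmented"
  )
}

# fit one segment tuple: standard variable theta in [-L,L] is mapped by
# g_m into the segment before the physical transform is applied
se_fit_on_segment <- function(model, specs, order, mvec, M, L) {
  K <- length(specs)
  dims <- lapply(seq_len(K), function(j) {
    fam <- basis_for(specs[[j]], order[j])
    list(spec = specs[[j]], family = fam, nodes = se_nodes(fam))
  })
  node_list <- lapply(dims, function(d) d$nodes$values)
  grid <- as.matrix(expand.grid(node_list, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- vapply(specs, `[[`, "", "name")
  n <- nrow(grid)
  responses <- NULL
  for (i in seq_len(n)) {
    phys <- vapply(seq_len(K), function(j) {
      th <- scaling_function(mvec[j], M[j], L[j],
                             clamp_to(grid[i, j], L[j]))
      to_physical(specs[[j]], th)
    }, 0)
    names(phys) <- colnames(grid)
    y <- as.numeric(model(phys))
    if (any(!is.finite(y)))
      stop(sprintf("model returned non-finite output at %s",
                   paste(sprintf("%s = %.6g", names(phys), phys),
                         collapse = ", ")))
    if (is.null(responses)) responses <- matrix(0, n, length(y),
                                                dimnames = list(NULL, names(y)))
    responses[i, ] <- y
  }
  structure(
    list(dims = dims, order = order, node_grid = grid,
         responses = responses,
         coefficients = se_coefficients(responses, dims),
         n_evals = n),
    class = "se_surrogate"
  )
}

# nodes of an unbounded (Hermite) basis can exceed the truncation
# half-width for high orders; pull them onto the boundary
clamp_to <- function(x, L) pmin(pmax(x, -L), L)

#' Evaluate a segmented surrogate
#'
#' @param object An `"se_segmented"`.
#' @param y Standard-variable point (vector) or points (matrix, one row
#'   each), each coordinate in `[-L, L]`.
#' @param ... Unused.
#' @return Numeric vector or matrix of surrogate values.
#' @export
predict.se_segmented <- function(object, y, ...) {
  K <- length(object$specs)
  if (is.null(dim(y)))
    y <- matrix(y, nrow = if (K == 1) length(y) else 1, ncol = K,
                byrow = K > 1)
  stopifnot(ncol(y) == K)
  out <- NULL
  for (q in seq_len(nrow(y))) {
    mvec <- vapply(seq_len(K), function(j)
      segment_index(y[q, j], object$M[j], object$L[j]), 0)
    r <- seg_row_index(mvec, object$M)
    theta <- vapply(seq_len(K), function(j)
      scaling_function_inv(mvec[j], object$M[j], object$L[j], y[q, j]), 0)
    val <- predict(object$fits[[r]], theta)
    if (is.null(out)) out <- matrix(0, nrow(y), length(val))
    out[q, ] <- val
  }
  if (nrow(y) == 1 || ncol(out) == 1) drop(out) else out
}

# column-major row index of a segment tuple in the stored segment grid
seg_row_index <- function(mvec, M) {
  sizes <- 2 * M + 1
  idx0 <- mvec + M # 0-based position per dimension
  r <- 0
  mult <- 1
  for (j in seq_along(mvec)) {
    r <- r + idx0[j] * mult
    mult <- mult * sizes[j]
  }
  as.integer(r + 1)
}

#' @export
print.se_segmented <- function(x, ...) {
  cat(sprintf(
    "<se_segmented> %d dim(s), order %s, granularity %s, %d segments, %d model evaluations\n",
    length(x$specs), paste(x$order, collapse = "x"),
    paste(x$M, collapse = "x"), nrow(x$seg_grid), x$n_evals))
  invisible(x)
}

#' Cost accounting for (segmented) spectral expansion
#'
#' Number of deterministic model evaluations required to fit the
#' expansion, `(2M+1)^K * N^K`, and the number of terms summed per
#' reconstruction query (per time point), `n_outputs * N^(2K)`.
#'
#' @param N Expansion order per dimension.
#' @param M Segmentation granularity (`M = 0`: no segmentation).
#' @param K Number of uncertain parameters.
#' @param n_outputs Number of output components (default 1).
#' @return A list with `n_model_evals` and `n_sum_terms`.
#' @examples
#' eval_cost(N = 6, M = 0, K = 5, n_outputs = 3)
#' @export
eval_cost <- function(N, M, K, n_outputs = 1) {
  stopifnot(N >= 1, N == round(N), M >= 0, M == round(M),
            K >= 1, K == round(K), n_outputs >= 1)
  list(
    n_model_evals = (2 * M + 1)^K * as.numeric(N)^K,
    n_sum_terms = n_outputs * as.numeric(N)^(2 * K)
  )
}

#' Benchmark table of expansion costs
#'
#' Tabulates model-evaluation and summation-term counts for a set of
#' (order, granularity) configurations of one problem, in the style of a
#' segmented-vs-unsegmented comparison.
#'
#' @param configs A data frame (or tibble) with columns `N` and `M`.
#' @param K Number of uncertain parameters.
#' @param n_outputs Number of output components.
#' @return A tibble with columns `N`, `M`, `n_evals`, `n_terms`.
#' @export
se_benchmark_table <- function(configs, K, n_outputs = 1) {
  purrr::pmap_dfr(configs[, c("N", "M")], function(N, M) {
    cost <- eval_cost(N, M, K, n_outputs)
    tibble::tibble(N = N, M = M,
                   n_evals = cost$n_model_evals,
                   n_terms = cost$n_sum_terms)
  })
}
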