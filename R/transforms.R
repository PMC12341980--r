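#' Declare an uncertain model parameter
#'
#' A parameter spec ties a physical model parameter to a distribution
#' family, the matching "standard" random variable the expansion is built
#' on, and the isoprobabilistic transform between them:
#'
#' * `uniform(a, b)` — standard variable \eqn{\theta \sim U(-1,1)}, Legendre
#'   basis, \eqn{k = (b+a)/2 + (b-a)\theta/2};
#' * `normal(mean, sd)` — \eqn{\theta \sim N(0,1)}, Hermite basis,
#'   \eqn{k = \mu + \sigma\theta};
#' * `lognormal(mean, sd)` — parameterized by its *arithmetic* mean and
#'   standard deviation; \eqn{\theta \sim N(0,1)}, Hermite basis,
#'   \eqn{k = \mu \exp(\alpha\theta - \alpha^2/2)} with
#'   \eqn{\alpha = \sqrt{\log(1 + \sigma^2/\mu^2)}};
#' * `poisson(lambda)` — counts are already physical (identity transform),
#'   Charlier basis.
#'
#' @param name Parameter name.
#' @param family One of `"uniform"`, `"normal"`, `"lognormal"`, `"poisson"`.
#' @param a,b Uniform bounds (`a < b`).
#' @param mean,sd Mean and standard deviation for normal / lognormal
#'   (`sd > 0`; lognormal additionally `mean > 0`).
#' @param lambda Poisson mean (`> 0`).
#' @return An object of class `"se_param"`.
#' @examples
#' k <- param_spec("k", "lognormal", mean = 0.5, sd = 0.2)
#' to_physical(k, 0)
#' @export
param_spec <- function(name, family = c("uniform", "normal", "lognormal", "poisson"),
                       a = NULL, b = NULL, mean = NULL, sd = NULL,
                       lambda = NULL) {
  family <- match.arg(family)
  hp <- switch(family,
    uniform = {
      stopifnot(is.numeric(a), is.numeric(b))
      if (!(a < b)) stop("uniform spec requires a < b")
      list(a = a, b = b)
    },
    normal = {
      stopifnot(is.numeric(mean), is.numeric(sd))
      if (sd <= 0) stop("normal spec requires sd > 0")
      list(mean = mean, sd = sd)
    },
    lognormal = {
      stopifnot(is.numeric(mean), is.numeric(sd))
      if (sd <= 0) stop("lognormal spec requires sd > 0")
      if (mean <= 0) stop("lognormal spec requires mean > 0")
      list(mean = mean, sd = sd,
           alpha = sqrt(log(1 + sd^2 / mean^2)))
    },
    poisson = {
      stopifnot(is.numeric(lambda))
      if (lambda <= 0) stop("poisson spec requires lambda > 0")
      list(lambda = lambda)
    }
  )
  structure(list(name = name, family = family, hyper = hp),
            class = "se_param")
}

#' @export
print.se_param <- function(x, ...) {
  cat(sprintf("<se_param> %s ~ %s(%s)\n", x$name, x$family,
              paste(sprintf("%s = %g", names(x$hyper), unlist(x$hyper)),
                    collapse = ", ")))
  invisible(x)
}

#' Basis family matching a parameter spec
#'
#' Legendre for uniform, Hermite for normal and lognormal, Charlier for
#' Poisson.
#'
#' @param spec An [param_spec()] object.
#' @param order Number of basis functions.
#' @return An [basis_family()] object.
#' @export
basis_for <- function(spec, order) {
  stopifnot(inherits(spec, "se_param"))
  switch(spec$family,
    uniform   = basis_family("legendre", order),
    normal    = basis_family("hermite", order),
    lognormal = basis_family("hermite", order),
    poisson   = basis_family("charlier", order, lambda = spec$hyper$lambda)
  )
}

#' Map a standard variable to the physical parameter
#'
#' @param spec An [param_spec()] object.
#' @param theta Value(s) of the standard variable (\eqn{U(-1,1)} for
#'   uniform, \eqn{N(0,1)} for normal/lognormal, counts for Poisson).
#' @return Physical parameter value(s).
#' @export
to_physical <- function(spec, theta) {
  stopifnot(inherits(spec, "se_param"))
  h <- spec$hyper
  switch(spec$family,
    uniform   = (h$b + h$a) / 2 + (h$b - h$a) * theta / 2,
    normal    = h$mean + h$sd * theta,
    lognormal = h$mean * exp(h$alpha * theta - h$alpha^2 / 2),
    poisson   = theta
  )
}

#' Map a physical parameter to its standard variable
#'
#' Exact algebraic inverse of [to_physical()].
#'
#' @param spec An [param_spec()] object.
#' @param k Physical parameter value(s); must be positive for lognormal.
#' @return Standard-variable value(s).
#' @export
to_standard <- function(spec, k) {
  stopifnot(inherits(spec, "se_param"))
  h <- spec$hyper
  switch(spec$family,
    uniform   = (2 * k - (h$b + h$a)) / (h$b - h$a),
    normal    = (k - h$mean) / h$sd,
    lognormal = {
      if (any(k <= 0)) stop("lognormal parameter must be positive")
      (log(k / h$mean) + h$alpha^2 / 2) / h$alpha
    },
    poisson   = k
  )
}

# density of the standard variable attached to a spec
standard_density <- function(spec) {
  switch(spec$family,
    uniform   = function(x) stats::dunif(x, -1, 1),
    normal    = function(x) stats::dnorm(x),
    lognormal = function(x) stats::dnorm(x),
    poisson   = function(x) stats::dpois(x, spec$hyper$lambda)
  )
}

# quantile of the standard variable (used by the QMC sampler)
standard_quantile <- function(spec) {
  switch(spec$family,
    uniform   = function(p) stats::qunif(p, -1, 1),
    normal    = ,
    lognormal = function(p) stats::qnorm(p),
    poisson   = function(p) stats::qpois(p, spec$hyper$lambda)
  )
}

#' Serialize / deserialize parameter specs
#'
#' `param_spec_to_list()` turns a spec into a plain named list suitable for
#' a YAML/JSON config block; `param_spec_from_list()` is its inverse.
#'
#' @param spec An [param_spec()] object.
#' @param x A named list with fields `name`, `family`, and hyperparameters.
#' @return A list, or an `"se_param"`.
#' @export
param_spec_to_list <- function(spec) {
  c(list(name = spec$name, family = spec$family),
    spec$hyper[setdiff(names(spec$hyper), "alpha")])
}

#' @rdname param_spec_to_list
#' @export
param_spec_from_list <- function(x) {
  stopifnot(!is.null(x$name), !is.null(x$family))
  do.call(param_spec, x)
}
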