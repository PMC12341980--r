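#' Built-in fixture models for configuration-driven runs
#'
#' Returns a callable `function(named physical parameter vector) ->
#' numeric vector` wrapping one of the built-in example systems, with the
#' response conventions used throughout the package: the decay
#' concentration trace, the three dimer-network species stacked over the
#' time grid, the F6P trace of the glycolytic oscillator, the
#' steady-state substrate profile of the reaction-diffusion line, or the
#' gated trichome density.
#'
#' @param name One of `"decay"`, `"dimer"`, `"glycolysis"`,
#'   `"schnakenberg"`, `"trichome"`.
#' @param times Optional time grid for the dynamic fixtures.
#' @return A function suitable for [se_fit()].
#' @export
fixture_model <- function(name = c("decay", "dimer", "glycolysis",
                                   "schnakenberg", "trichome"),
                          times = NULL) {
  name <- match.arg(name)
  switch(name,
    decay = {
      tg <- if (is.null(times)) seq(0, 6, by = 0.25) else times
      function(p) decay_model(A0 = 1, k = p[["k"]], times = tg)
    },
    dimer = {
      tg <- if (is.null(times)) seq(0, 40, by = 2) else times
      function(p) as.vector(dimer_model(p[c("k1", "k2", "k3", "k4", "k5")], tg))
    },
    glycolysis = {
      tg <- if (is.null(times)) seq(0, 20, by = 0.5) else times
      function(p) glycolysis_model(p[["alpha"]], p[["beta"]], tg)[, "y"]
    },
    schnakenberg = function(p) schnakenberg_model(p[["alpha"]])$v,
    trichome = function(p) trichome_response(p[["alpha"]], mode = "direct")
  )
}

config_error <- function(field, msg) {
  stop(sprintf("config error at `%s`: %s", field, msg), call. = FALSE)
}

validate_config <- function(cfg) {
  if (is.null(cfg$model)) config_error("model", "missing model id")
  if (!cfg$model %in% c("decay", "dimer", "glycolysis", "schnakenberg",
                        "trichome"))
    config_error("model", sprintf("unknown model '%s'", cfg$model))
  if (is.null(cfg$parameters) || length(cfg$parameters) == 0)
    config_error("parameters", "at least one parameter block required")
  for (i in seq_along(cfg$parameters)) {
    p <- cfg$parameters[[i]]
    if (is.null(p$name))
      config_error(sprintf("parameters[%d].name", i), "missing")
    if (is.null(p$family) ||
        !p$family %in% c("uniform", "normal", "lognormal", "poisson"))
      config_error(sprintf("parameters[%d].family", i),
                   sprintf("invalid family '%s'", p$family %||% "<missing>"))
  }
  if (is.null(cfg$method) || is.null(cfg$method$order))
    config_error("method.order", "missing expansion order")
  if (!is.null(cfg$method$basis) &&
      !cfg$method$basis %in% c("auto", "haar"))
    config_error("method.basis",
                 sprintf("invalid basis '%s' (use 'auto' or 'haar')",
                         cfg$method$basis))
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a declarative spectral-expansion configuration
#'
#' Reads a YAML configuration (model id, parameter blocks, method block,
#' optional Monte-Carlo block), fits the requested (segmented) surrogate,
#' and writes coefficients, moments, Sobol tables, a cost report, and the
#' resolved configuration into the output directory as CSV/JSON.
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the fitted surrogate and the tibbles
#'   written to disk.
#' @export
run_config <- function(config, out_dir = "se-run") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
  specs <- lapply(cfg$parameters, param_spec_from_list)
  K <- length(specs)
  N <- cfg$method$order
  M <- cfg$method$granularity %||% 0
  model <- fixture_model(cfg$model, times = cfg$times)
  basis <- NULL
  if (identical(cfg$method$basis, "haar")) {
    if (any(vapply(specs, function(s) s$family, "") != "uniform"))
      config_error("method.basis", "haar basis requires uniform parameters")
    basis <- lapply(specs, function(s)
      basis_family("haar", N,
                   cdf = function(x) stats::punif(x, -1, 1),
                   quantile = function(p) stats::qunif(p, -1, 1),
                   support = c(-1, 1)))
  }
  fit <- if (M > 0) {
    se_fit_segmented(model, specs, N, M = M, L = cfg$method$L %||% NULL)
  } else {
    se_fit(model, specs, N, basis = basis)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(fit = fit)
  if (inherits(fit, "se_surrogate")) {
    utils::write.csv(tidy(fit), file.path(out_dir, "coefficients.csv"),
                     row.names = FALSE)
    moments <- se_moments(fit)
    utils::write.csv(moments, file.path(out_dir, "moments.csv"),
                     row.names = FALSE)
    if (K > 1) {
      sob <- se_sobol(fit)
      utils::write.csv(sob, file.path(out_dir, "sobol.csv"),
                       row.names = FALSE)
      res$sobol <- sob
    }
    res$moments <- moments
  }
  cost <- eval_cost(N, M, K,
                    n_outputs = if (inherits(fit, "se_surrogate"))
                      ncol(fit$coefficients) else 1)
  cost$n_evals_actual <- fit$n_evals
  jsonlite::write_json(cost, file.path(out_dir, "cost.json"),
                       auto_unbox = TRUE, digits = NA)
  res$cost <- cost
  if (!is.null(cfg$mc) && (cfg$mc$nsim %||% 0) > 0) {
    mc <- mc_reference(model, specs, n = cfg$mc$nsim,
                       n_blocks = cfg$mc$blocks %||% 16,
                       scramble_seed = cfg$mc$scramble_seed %||% 1)
    utils::write.csv(mc$moments, file.path(out_dir, "mc_moments.csv"),
                     row.names = FALSE)
    res$mc <- mc
  }
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))
  invisible(res)
}
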