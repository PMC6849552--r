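#' Assemble the fitted path graph
#'
#' Combines the four fitted models with the covariate scaling record into
#' the causal graph of the path analysis: catchment covariates (`NDVI_R`,
#' `NDVI_T`, `WL_T`) feed `DOC`; `WL_C`, `pH` and `DOC` feed the labile
#' metals `NiL` and `CuL`; `NiL`, `CuL`, `DOC`, `depth` and `pH` feed
#' `abund`. Edges are read off each fit's predictor set, so the graph always
#' matches what was actually fitted.
#'
#' @param doc_fit,ni_fit,cu_fit,abund_fit fitted `hier_fit` objects (or
#'   [point_posterior()] stand-ins built from published coefficients).
#' @param scaling scaling record (`variable`, `mean`, `sd`, and for
#'   [range_effect()] also `min`, `max`): from [standardize_covariates()],
#'   the generator truth, or [reference_site_summary()].
#' @return object of class `path_graph`.
#' @export
path_graph <- function(doc_fit, ni_fit, cu_fit, abund_fit, scaling) {
  fits <- list(DOC = doc_fit, NiL = ni_fit, CuL = cu_fit, abund = abund_fit)
  for (f in fits) stopifnot(inherits(f, "hier_fit"))
  edges <- do.call(rbind, lapply(names(fits), function(node) {
    fit <- fits[[node]]
    if (!length(fit$predictors)) return(NULL)
    from <- sub("_z$", "", fit$predictors)
    data.frame(from = from, to = node, coef = paste0("b_", from))
  }))
  # every edge coefficient must exist in its target model's draws
  for (i in seq_len(nrow(edges))) {
    pars <- dimnames(fits[[edges$to[i]]]$draws)[[3]]
    if (!edges$coef[i] %in% pars) {
      stop("coefficient ", edges$coef[i], " missing from the ",
           edges$to[i], " model", call. = FALSE)
    }
  }
  # acyclicity: node order DOC < NiL/CuL < abund must be respected
  rank <- c(DOC = 1, NiL = 2, CuL = 2, abund = 3)
  from_rank <- rank[edges$from]
  from_rank[is.na(from_rank)] <- 0  # exogenous catchment covariates
  if (any(from_rank >= rank[edges$to])) {
    stop("path graph is not acyclic", call. = FALSE)
  }
  structure(list(fits = fits, edges = edges, scaling = scaling),
            class = "path_graph")
}

#' @export
print.path_graph <- function(x, ...) {
  cat("<path_graph> with", nrow(x$edges), "edges\n")
  for (i in seq_len(nrow(x$edges))) {
    cat("  ", x$edges$from[i], "->", x$edges$to[i], "\n")
  }
  invisible(x)
}

#' Degenerate posterior from point estimates
#'
#' Builds a `hier_fit`-compatible object whose every draw equals the
#' supplied point values. Useful for propagating published coefficients
#' through the path graph without refitting, and for closed-form checks.
#'
#' @param response response node name (e.g. `"NiL"`, `"abund"`).
#' @param coefficients named vector of coefficients, named by predictor
#'   (e.g. `c(NiL = -0.914)`).
#' @param alpha intercept value (default 0).
#' @param sigmas optional named vector of SD parameters to include.
#' @param family model family label.
#' @param n_draws number of identical draws to materialize.
#' @return a `hier_fit`.
#' @export
#' @examples
#' ab <- point_posterior("abund", c(NiL = -0.914, depth = -1.227),
#'                       family = "poisson_lognormal")
#' mean(param_draws(ab, "b_NiL"))
point_posterior <- function(response, coefficients, alpha = 0, sigmas = NULL,
                            family = "lognormal", n_draws = 1000) {
  coef_named <- if (length(coefficients)) {
    stats::setNames(coefficients, paste0("b_", names(coefficients)))
  } else {
    NULL
  }
  vals <- c(alpha = alpha, coef_named, sigmas)
  half <- max(1L, n_draws %/% 2L)
  draws <- array(rep(vals, each = 2L * half),
                 dim = c(half, 2L, length(vals)),
                 dimnames = list(NULL, NULL, names(vals)))
  new_hier_fit(draws, family, response,
               predictors = names(coefficients),
               reported = names(vals),
               n_chains = 2L, n_iter = half, n_burnin = 0L, seed = NULL,
               data_info = list(N = 0), sampler = "point estimate")
}

scaling_row <- function(scaling, variable) {
  i <- match(variable, scaling$variable)
  if (is.na(i)) stop("no scaling recorded for ", variable, call. = FALSE)
  scaling[i, ]
}

# seeded subset of n_draws flattened posterior draws per fit
subset_draws <- function(fit, parameter, idx) {
  as.vector(param_draws(fit, parameter))[idx]
}

#' Propagate a covariate perturbation along a path
#'
#' Pushes a standardized perturbation of a catchment covariate (or chemistry
#' variable) through successive fitted models along a route in the path
#' graph, per posterior draw. For the first edge the change in the
#' mediator's log response is `beta * delta_sd`. To feed the next model, the
#' mediator's multiplicative change is converted back to its standardized
#' scale at the observed mean:
#' `delta_z = mean * (exp(delta_log) - 1) / sd`, with mean and SD from the
#' graph's scaling record. The terminal node's multiplicative response is
#' summarized over draws (mean and central 95% interval).
#'
#' @param graph a [path_graph()].
#' @param covariate perturbed variable; must be the first element of
#'   `route`.
#' @param delta_sd perturbation size in SD units of the covariate.
#' @param route character vector of nodes, e.g.
#'   `c("WL_C", "NiL", "abund")`; each consecutive pair must be an edge.
#' @param n_draws posterior draws used (default 1000).
#' @param seed optional seed for the draw subset.
#' @return object of class `propagation_result`: per-node multiplicative
#'   responses with 95% intervals, and the terminal fold change with
#'   percent change and its reciprocal (`suppression_factor`, convenient
#'   when reporting how many times abundance is reduced).
#' @export
#' @examples
#' ab <- point_posterior("abund", c(NiL = -0.914),
#'                       family = "poisson_lognormal")
#' g <- list(fits = list(abund = ab), edges = data.frame(
#'   from = "NiL", to = "abund", coef = "b_NiL"),
#'   scaling = reference_site_summary())
#' class(g) <- "path_graph"
#' propagate_effect(g, "NiL", 1, c("NiL", "abund"))
propagate_effect <- function(graph, covariate, delta_sd, route,
                             n_draws = 1000, seed = NULL) {
  stopifnot(inherits(graph, "path_graph"))
  if (length(route) < 2) stop("route needs at least one edge", call. = FALSE)
  if (route[1] != covariate) {
    stop("`covariate` must be the first node of `route`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  nodes <- vector("list", length(route) - 1)
  delta_z <- delta_sd
  for (s in seq_len(length(route) - 1)) {
    from <- route[s]; to <- route[s + 1]
    hit <- graph$edges$from == from & graph$edges$to == to
    if (!any(hit)) {
      stop("no edge ", from, " -> ", to, " in the path graph", call. = FALSE)
    }
    fit <- graph$fits[[to]]
    n_tot <- dim(fit$draws)[1] * dim(fit$draws)[2]
    idx <- if (n_tot <= n_draws) seq_len(n_tot) else sample.int(n_tot, n_draws)
    beta <- subset_draws(fit, graph$edges$coef[hit][1], idx)
    delta_log <- beta * delta_z
    fold <- exp(delta_log)
    q <- stats::quantile(fold, c(0.025, 0.975), names = FALSE)
    nodes[[s]] <- data.frame(node = to, fold_mean = mean(fold),
                             fold_lower = q[1], fold_upper = q[2])
    if (s < length(route) - 1) {
      sc <- scaling_row(graph$scaling, to)
      delta_z <- sc$mean * (exp(delta_log) - 1) / sc$sd
    }
  }
  nodes <- do.call(rbind, nodes)
  terminal <- nodes[nrow(nodes), ]
  structure(
    list(
      covariate = covariate, delta_sd = delta_sd, route = route,
      nodes = nodes,
      fold_change = terminal$fold_mean,
      fold_lower = terminal$fold_lower, fold_upper = terminal$fold_upper,
      percent_change = 100 * (terminal$fold_mean - 1),
      suppression_factor = 1 / terminal$fold_mean,
      degenerate = FALSE
    ),
    class = "propagation_result"
  )
}

#' @export
print.propagation_result <- function(x, ...) {
  cat("<propagation_result> ", x$covariate,
      sprintf(" %+.2f SD along ", x$delta_sd),
      paste(x$route, collapse = " -> "), "\n", sep = "")
  print(x$nodes, row.names = FALSE)
  cat(sprintf("terminal fold change: %.3g (95%% CI %.3g-%.3g), %+.1f%%\n",
              x$fold_change, x$fold_lower, x$fold_upper, x$percent_change))
  invisible(x)
}

#' Effect of a covariate across its observed range
#'
#' Propagates a perturbation spanning the covariate's observed minimum to
#' maximum (`delta_sd = (max - min) / sd`, from the graph's scaling record)
#' along a route, reporting the terminal response as a max-over-min ratio.
#' A degenerate range (min equal to max) returns a fold change of exactly 1,
#' flagged.
#'
#' @inheritParams propagate_effect
#' @return a `propagation_result` (with `degenerate = TRUE` when the range
#'   collapses).
#' @export
range_effect <- function(graph, covariate, route, n_draws = 1000,
                         seed = NULL) {
  sc <- scaling_row(graph$scaling, covariate)
  if (!all(c("min", "max") %in% names(graph$scaling))) {
    stop("scaling record lacks observed min/max", call. = FALSE)
  }
  span <- sc$max - sc$min
  if (span == 0) {
    res <- structure(
      list(covariate = covariate, delta_sd = 0, route = route,
           nodes = data.frame(node = route[-1], fold_mean = 1,
                              fold_lower = 1, fold_upper = 1),
           fold_change = 1, fold_lower = 1, fold_upper = 1,
           percent_change = 0, suppression_factor = 1, degenerate = TRUE),
      class = "propagation_result")
    warning("degenerate range (min = max): fold change is 1")
    return(res)
  }
  propagate_effect(graph, covariate, span / sc$sd, route,
                   n_draws = n_draws, seed = seed)
}
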