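#' Specification of one path model
#'
#' The four models of the path analysis, by short name:
#' \describe{
#'   \item{doc}{lognormal DOC with riparian forest (`NDVI_R`), total forest
#'     (`NDVI_T`) and total wetland (`WL_T`) predictors; lake random effect.}
#'   \item{ni}{lognormal labile Ni with `pH`, `DOC`, connected wetland
#'     (`WL_C`); lake random effect.}
#'   \item{cu}{lognormal labile Cu, same predictors as `ni`.}
#'   \item{abund}{Poisson-lognormal dendy counts with `NiL`, `CuL`, `DOC`,
#'     `depth`, `pH`; lake and site random effects plus an observation-level
#'     overdispersion term.}
#' }
#' All predictors enter z-scored; priors are Normal(0, sd 10) on intercept
#' and coefficients and Uniform(0, 10) on every SD.
#'
#' @param model one of `"doc"`, `"ni"`, `"cu"`, `"abund"`.
#' @return list with `family`, `response`, `predictors`.
#' @export
model_spec <- function(model = c("doc", "ni", "cu", "abund")) {
  model <- match.arg(model)
  switch(model,
    doc = list(family = "lognormal", response = "DOC",
               predictors = c("NDVI_R", "NDVI_T", "WL_T")),
    ni = list(family = "lognormal", response = "NiL",
              predictors = c("pH", "DOC", "WL_C")),
    cu = list(family = "lognormal", response = "CuL",
              predictors = c("pH", "DOC", "WL_C")),
    abund = list(family = "poisson_lognormal", response = "count",
                 predictors = c("NiL", "CuL", "DOC", "depth", "pH"))
  )
}

# chain-specific RNG initialisations derived from one user seed
chain_inits <- function(seed, n_chains) {
  if (is.null(seed)) return(NULL)
  set.seed(seed)
  rng_seeds <- sample.int(2^31 - 2, n_chains)
  lapply(rng_seeds, function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })
}

# coda mcmc.list -> array [iteration, chain, parameter], beta[i] renamed
as_draws_array <- function(samples, beta_names) {
  mats <- lapply(samples, as.matrix)
  pars <- colnames(mats[[1]])
  if (length(beta_names) == 1L) pars[pars == "beta"] <- beta_names[1]
  for (p in seq_along(beta_names)) {
    pars[pars == sprintf("beta[%d]", p)] <- beta_names[p]
  }
  arr <- array(NA_real_,
               dim = c(nrow(mats[[1]]), length(mats), length(pars)),
               dimnames = list(NULL, NULL, pars))
  for (m in seq_along(mats)) arr[, m, ] <- mats[[m]]
  arr
}

new_hier_fit <- function(draws, family, response, predictors, reported,
                         n_chains, n_iter, n_burnin, seed, data_info,
                         sampler = "jags (glm module)") {
  structure(
    list(draws = draws, family = family, response = response,
         predictors = predictors, reported = reported,
         n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
         seed = seed, data = data_info, sampler = sampler),
    class = "hier_fit"
  )
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("<hier_fit> ", x$family, " model for `", x$response, "`\n", sep = "")
  if (length(x$predictors)) {
    cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  } else {
    cat("  intercept-only (null) model\n")
  }
  cat("  chains:", x$n_chains, " iterations:", x$n_iter,
      " burn-in:", x$n_burnin,
      " kept draws:", dim(x$draws)[1] * dim(x$draws)[2], "\n")
  cat("  sampler:", x$sampler, "\n")
  invisible(x)
}

#' Matrix of posterior draws for one parameter
#'
#' @param fit a `hier_fit`.
#' @param parameter parameter name (e.g. `"alpha"`, `"b_NiL"`,
#'   `"sigma_lake"`).
#' @return matrix of post-burn-in draws, iterations x chains.
#' @export
param_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "hier_fit"))
  pars <- dimnames(fit$draws)[[3]]
  if (!parameter %in% pars) {
    stop("parameter `", parameter, "` not found; available: ",
         paste(utils::head(pars, 20), collapse = ", "),
         if (length(pars) > 20) ", ...", call. = FALSE)
  }
  fit$draws[, , parameter]
}

run_jags <- function(model_string, data, monitors, n_chains, n_iter, n_burnin,
                     seed, quiet = TRUE) {
  if (n_iter <= n_burnin) stop("`n_iter` must exceed `n_burnin`", call. = FALSE)
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = chain_inits(seed, n_chains),
                          n.chains = n_chains, n.adapt = n_burnin,
                          quiet = quiet)
  rjags::coda.samples(jm, monitors, n.iter = n_iter - n_burnin)
}

#' Fit a hierarchical lognormal model
#'
#' Samples the posterior of the model
#' `y_ij ~ lognormal(mu_ij, sigma_resid)` with
#' `mu_ij = alpha + X_ij beta + v_j`, `v_j ~ Normal(0, sigma_lake)`,
#' under Normal(0, sd 10) priors on `alpha` and `beta` and Uniform(0, 10)
#' priors on both SDs, using MCMC (JAGS with the `glm` block-sampling
#' module). Serves the DOC and both labile-metal models; an empty predictor
#' set gives the intercept-only null model used for R-squared.
#'
#' @param data site table (typically the `sites` element of
#'   [standardize_covariates()]).
#' @param response name of the strictly positive response column.
#' @param predictors character vector of predictor columns (usually the
#'   `_z` columns); may be empty.
#' @param lake name of the lake grouping column.
#' @param n_chains,n_iter,n_burnin MCMC settings; defaults are 4 chains of
#'   3500 iterations with 1000 discarded as burn-in (adaptation included).
#' @param seed integer seed controlling all chains.
#' @param monitor_latent also keep draws of the lake effects `v_lake[j]`.
#' @param prior_only sample the prior instead of the posterior (no
#'   likelihood); used to verify prior implementation.
#' @param quiet suppress JAGS progress output.
#' @return a `hier_fit` object.
#' @export
#' @examples
#' \donttest{
#' sim <- generate_catchment_dataset(sim_config(seed = 1))
#' std <- standardize_covariates(sim$sites, sim$dendies)
#' fit <- fit_lognormal_hier(std$sites, "DOC",
#'                           c("NDVI_R_z", "NDVI_T_z", "WL_T_z"),
#'                           n_chains = 2, n_iter = 1200, n_burnin = 400,
#'                           seed = 1)
#' summarize_posterior(fit, seed = 1)
#' }
fit_lognormal_hier <- function(data, response, predictors = character(0),
                               lake = "lake_id",
                               n_chains = 4, n_iter = 3500, n_burnin = 1000,
                               seed = NULL, monitor_latent = TRUE,
                               prior_only = FALSE, quiet = TRUE) {
  P <- length(predictors)
  beta_names <- if (P > 0) paste0("b_", sub("_z$", "", predictors)) else character(0)

  if (prior_only) {
    model_string <- paste0(
      "model {\n",
      "  alpha ~ dnorm(0, 0.01)\n",
      if (P > 0) "  for (p in 1:P) { beta[p] ~ dnorm(0, 0.01) }\n" else "",
      "  sigma_resid ~ dunif(0, 10)\n",
      "  sigma_lake ~ dunif(0, 10)\n",
      "}\n")
    jd <- if (P > 0) list(P = P) else list()
    monitors <- c("alpha", if (P > 0) "beta", "sigma_resid", "sigma_lake")
    samples <- run_jags(model_string, jd, monitors, n_chains, n_iter,
                        n_burnin, seed, quiet)
    draws <- as_draws_array(samples, beta_names)
    return(new_hier_fit(draws, "lognormal", response, predictors,
                        reported = c("alpha", beta_names, "sigma_resid",
                                     "sigma_lake"),
                        n_chains, n_iter, n_burnin, seed,
                        data_info = list(N = 0, J = 0, prior_only = TRUE)))
  }

  stopifnot(response %in% names(data), lake %in% names(data))
  missing_pred <- setdiff(predictors, names(data))
  if (length(missing_pred)) {
    stop("predictor column(s) not in data: ",
         paste(missing_pred, collapse = ", "), call. = FALSE)
  }
  y <- data[[response]]
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("response `", response, "` must be strictly positive and finite",
         call. = FALSE)
  }
  lake_f <- as.integer(factor(data[[lake]]))
  N <- length(y); J <- max(lake_f)

  # order observations by lake so each lake is a contiguous block: the lake
  # effect is marginalized analytically (compound-symmetry covariance per
  # lake), which removes the variance-latent funnel that slows Gibbs-type
  # samplers; v_lake is then drawn from its exact conditional each iteration
  ord <- order(lake_f)
  logy <- log(y)[ord]
  lake_f <- lake_f[ord]
  nj <- as.integer(table(factor(lake_f, levels = seq_len(J))))
  last <- cumsum(nj); first <- c(1L, utils::head(last, -1) + 1L)
  Z <- t(vapply(seq_len(J), function(j) as.numeric(lake_f == j), numeric(N)))

  model_string <- paste0(
    "model {\n",
    "  for (n in 1:N) {\n",
    if (P > 0) {
      "    mu[n] <- alpha + inprod(X[n, ], beta)\n"
    } else {
      "    mu[n] <- alpha\n"
    },
    "    resid[n] <- logy[n] - mu[n]\n",
    "  }\n",
    "  for (j in 1:J) {\n",
    "    for (r in 1:nj[j]) { for (c in 1:nj[j]) {\n",
    "      Omega[r, c, j] <- equals(r, c) / s2 - sl2 / (s2 * (s2 + nj[j] * sl2))\n",
    "    } }\n",
    "    logy[first[j]:last[j]] ~ dmnorm(mu[first[j]:last[j]],",
    " Omega[1:nj[j], 1:nj[j], j])\n",
    "    rbar[j] <- inprod(Z[j, ], resid) / nj[j]\n",
    "    prec_v[j] <- nj[j] / s2 + 1 / sl2\n",
    "    v_lake[j] ~ dnorm((nj[j] / s2) * rbar[j] / prec_v[j], prec_v[j])\n",
    "  }\n",
    "  alpha ~ dnorm(0, 0.01)\n",
    if (P > 0) "  for (p in 1:P) { beta[p] ~ dnorm(0, 0.01) }\n" else "",
    "  sigma_resid ~ dunif(0, 10)\n",
    "  s2 <- pow(sigma_resid, 2)\n",
    "  sigma_lake ~ dunif(0, 10)\n",
    "  sl2 <- pow(sigma_lake, 2)\n",
    "}\n")
  jd <- list(logy = logy, N = N, J = J, nj = nj, first = first, last = last,
             Z = Z)
  if (P > 0) {
    jd$X <- as.matrix(data[, predictors, drop = FALSE])[ord, , drop = FALSE]
    jd$P <- P
  }
  monitors <- c("alpha", if (P > 0) "beta", "sigma_resid", "sigma_lake",
                if (monitor_latent) "v_lake")
  samples <- run_jags(model_string, jd, monitors, n_chains, n_iter, n_burnin,
                      seed, quiet)
  draws <- as_draws_array(samples, beta_names)
  new_hier_fit(draws, "lognormal", response, predictors,
               reported = c("alpha", beta_names, "sigma_resid", "sigma_lake"),
               n_chains, n_iter, n_burnin, seed,
               data_info = list(N = N, J = J))
}

#' Fit the hierarchical Poisson-lognormal abundance model
#'
#' Samples the posterior of
#' `count_ijk ~ Poisson(lambda_ijk)` with
#' `log(lambda_ijk) = alpha + X beta + v_j + v_i + eps_ijk`,
#' where `v_j`, `v_i` are lake- and site-level random effects and `eps_ijk`
#' is an observation-level random effect capturing overdispersion. Priors
#' are Normal(0, sd 10) on `alpha` and `beta` and Uniform(0, 10) on all SDs.
#' The overdispersion term is sampled in non-centered form
#' (`eps = sigma_olre * z`, `z ~ Normal(0, 1)`), which markedly improves
#' mixing of `sigma_olre` under the Gibbs-type sampler.
#'
#' @param dendies dendy table with `site_id`, non-negative integer `count`,
#'   and any dendy-level predictor columns (e.g. `depth_z`).
#' @param sites site table with `lake_id`, `site_id` and site-level
#'   predictor columns.
#' @param predictors predictor columns; each must exist in `dendies` or in
#'   `sites` (site-level values are expanded to observations). May be empty
#'   for the null model.
#' @param response name of the count column.
#' @inheritParams fit_lognormal_hier
#' @param monitor_latent also keep draws of `v_lake`, `v_site` and `eps`.
#' @param engine `"interweaved"` (default): the package's adaptive
#'   Metropolis-within-Gibbs sampler with ancillarity-sufficiency
#'   interweaving, whose SD hyperparameters mix far better than plain
#'   Gibbs-type updates on this model; or `"jags"`: JAGS with a
#'   non-centered overdispersion term, retained as an independent
#'   cross-check engine. Both target the identical posterior; the engine
#'   used is recorded in the fit.
#' @return a `hier_fit` object.
#' @export
fit_poisson_lognormal <- function(dendies, sites,
                                  predictors = c("NiL_z", "CuL_z", "DOC_z",
                                                 "depth_z", "pH_z"),
                                  response = "count", lake = "lake_id",
                                  n_chains = 4, n_iter = 3500,
                                  n_burnin = 1000, seed = NULL,
                                  monitor_latent = TRUE,
                                  engine = c("interweaved", "jags"),
                                  quiet = TRUE) {
  engine <- match.arg(engine)
  stopifnot(response %in% names(dendies),
            all(c("site_id", lake) %in% names(sites)),
            "site_id" %in% names(dendies))
  y <- dendies[[response]]
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (!all(dendies$site_id %in% sites$site_id)) {
    stop("dendy table references sites absent from the site table: ",
         paste(unique(setdiff(dendies$site_id, sites$site_id)), collapse = ", "),
         call. = FALSE)
  }
  site_f <- as.integer(factor(dendies$site_id, levels = sites$site_id))
  lake_f <- as.integer(factor(sites[[lake]]))[site_f]
  N <- length(y); S <- nrow(sites); J <- max(lake_f)

  P <- length(predictors)
  beta_names <- if (P > 0) paste0("b_", sub("_z$", "", predictors)) else character(0)
  X <- NULL
  if (P > 0) {
    X <- matrix(NA_real_, N, P)
    for (p in seq_len(P)) {
      v <- predictors[p]
      if (v %in% names(dendies)) {
        X[, p] <- dendies[[v]]
      } else if (v %in% names(sites)) {
        X[, p] <- sites[[v]][site_f]
      } else {
        stop("predictor `", v, "` found in neither table", call. = FALSE)
      }
    }
    if (any(!is.finite(X))) stop("non-finite predictor values", call. = FALSE)
  }

  if (engine == "interweaved") {
    if (n_iter <= n_burnin) stop("`n_iter` must exceed `n_burnin`", call. = FALSE)
    lake_of_site <- as.integer(factor(sites[[lake]]))
    draws <- pln_fit_interweaved(as.integer(y), X, site_f, lake_of_site,
                                 beta_names, n_chains, n_iter, n_burnin,
                                 seed, monitor_latent)
    return(new_hier_fit(draws, "poisson_lognormal", response, predictors,
                        reported = c("alpha", beta_names, "sigma_olre",
                                     "sigma_site", "sigma_lake"),
                        n_chains, n_iter, n_burnin, seed,
                        data_info = list(N = N, S = S, J = J),
                        sampler = "interweaved Metropolis-within-Gibbs (ASIS)"))
  }

  model_string <- paste0(
    "model {\n",
    "  for (n in 1:N) {\n",
    "    y[n] ~ dpois(lambda[n])\n",
    if (P > 0) {
      paste0("    log(lambda[n]) <- alpha + inprod(X[n, ], beta) +",
             " v_lake[lake[n]] + v_site[site[n]] + sigma_olre * z[n]\n")
    } else {
      paste0("    log(lambda[n]) <- alpha +",
             " v_lake[lake[n]] + v_site[site[n]] + sigma_olre * z[n]\n")
    },
    "    z[n] ~ dnorm(0, 1)\n",
    "    eps[n] <- sigma_olre * z[n]\n",
    "  }\n",
    "  for (i in 1:S) { v_site[i] ~ dnorm(0, tau_site) }\n",
    "  for (j in 1:J) { v_lake[j] ~ dnorm(0, tau_lake) }\n",
    "  alpha ~ dnorm(0, 0.01)\n",
    if (P > 0) "  for (p in 1:P) { beta[p] ~ dnorm(0, 0.01) }\n" else "",
    "  sigma_olre ~ dunif(0, 10)\n",
    "  sigma_site ~ dunif(0, 10)\n",
    "  tau_site <- pow(sigma_site, -2)\n",
    "  sigma_lake ~ dunif(0, 10)\n",
    "  tau_lake <- pow(sigma_lake, -2)\n",
    "}\n")
  jd <- list(y = as.integer(y), lake = lake_f, site = site_f,
             N = N, S = S, J = J)
  if (P > 0) { jd$X <- X; jd$P <- P }
  monitors <- c("alpha", if (P > 0) "beta",
                "sigma_olre", "sigma_site", "sigma_lake",
                if (monitor_latent) c("v_lake", "v_site", "eps"))
  samples <- run_jags(model_string, jd, monitors, n_chains, n_iter, n_burnin,
                      seed, quiet)
  draws <- as_draws_array(samples, beta_names)
  new_hier_fit(draws, "poisson_lognormal", response, predictors,
               reported = c("alpha", beta_names, "sigma_olre", "sigma_site",
                            "sigma_lake"),
               n_chains, n_iter, n_burnin, seed,
               data_info = list(N = N, S = S, J = J))
}

#' Fit one of the four path models by name
#'
#' Convenience wrapper mapping [model_spec()] onto the standardized tables
#' from [standardize_covariates()] (predictors are taken as the `_z`
#' columns) and dispatching to [fit_lognormal_hier()] or
#' [fit_poisson_lognormal()].
#'
#' @param model `"doc"`, `"ni"`, `"cu"` or `"abund"`.
#' @param std list from [standardize_covariates()].
#' @param null fit the intercept-only version (same family and grouping).
#' @param ... passed on to the fitting function (chains, iterations, seed...).
#' @return a `hier_fit`.
#' @export
fit_path_model <- function(model, std, null = FALSE, ...) {
  spec <- model_spec(model)
  preds <- if (null) character(0) else paste0(spec$predictors, "_z")
  if (spec$family == "lognormal") {
    fit_lognormal_hier(std$sites, spec$response, preds, ...)
  } else {
    fit_poisson_lognormal(std$dendies, std$sites, preds,
                          response = spec$response, ...)
  }
}
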