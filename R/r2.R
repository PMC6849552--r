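#' Observation-level residual variance of a fitted model
#'
#' Latent (log-scale) residual variance at posterior means. For the
#' lognormal models this is simply `sigma_resid^2`. For the
#' Poisson-lognormal abundance model it is the sum of the overdispersion
#' variance and the distribution-specific variance,
#' `sigma_olre^2 + ln(1 + 1/lambda_bar)`, following the mixed-model
#' R-squared framework of Nakagawa & Schielzeth. The rate at which the
#' distribution-specific part is evaluated is, by default, the marginal
#' expectation `lambda_bar = exp(alpha + (sigma_lake^2 + sigma_site^2 +
#' sigma_olre^2) / 2)`; the simpler `exp(alpha)` is available via
#' `lambda_bar = "intercept"`.
#'
#' @param fit a `hier_fit`.
#' @param lambda_bar `"marginal"` (default) or `"intercept"`; how to
#'   evaluate the representative Poisson rate.
#' @return residual variance (scalar) with attribute `"components"`.
#' @export
residual_variance <- function(fit, lambda_bar = c("marginal", "intercept")) {
  stopifnot(inherits(fit, "hier_fit"))
  lambda_bar <- match.arg(lambda_bar)
  pm <- function(p) mean(param_draws(fit, p))
  if (fit$family == "lognormal") {
    v <- pm("sigma_resid")^2
    attr(v, "components") <- c(sigma_resid2 = v)
    return(v)
  }
  s_olre <- pm("sigma_olre"); s_site <- pm("sigma_site")
  s_lake <- pm("sigma_lake"); a <- pm("alpha")
  lb <- if (lambda_bar == "marginal") {
    exp(a + 0.5 * (s_lake^2 + s_site^2 + s_olre^2))
  } else {
    exp(a)
  }
  dist_var <- log(1 + 1 / lb)
  v <- s_olre^2 + dist_var
  attr(v, "components") <- c(sigma_olre2 = s_olre^2,
                             distribution_specific = dist_var,
                             lambda_bar = lb)
  v
}

#' Within-lake (observation-level) R-squared
#'
#' The proportional change in observation-level residual variance between
#' the full model and its intercept-only null:
#' `R2 = 1 - V_resid(full) / V_resid(null)`. Both fits must share family and
#' grouping structure. The value can be negative if the full model's
#' residual variance exceeds the null's; such values are returned as-is with
#' a warning.
#'
#' @param full,null fitted `hier_fit` objects (null: same family and
#'   grouping, no predictors).
#' @param lambda_bar passed to [residual_variance()].
#' @return scalar R-squared.
#' @export
within_lake_r2 <- function(full, null, lambda_bar = "marginal") {
  stopifnot(inherits(full, "hier_fit"), inherits(null, "hier_fit"))
  if (full$family != null$family) {
    stop("full and null fits must share the same family", call. = FALSE)
  }
  v_full <- as.numeric(residual_variance(full, lambda_bar))
  v_null <- as.numeric(residual_variance(null, lambda_bar))
  if (v_null == 0) {
    warning("null residual variance is zero: R-squared undefined")
    return(NaN)
  }
  r2 <- 1 - v_full / v_null
  if (r2 < 0) warning("negative within-group R-squared (full residual variance exceeds null's)")
  r2
}

# variance of the fixed-effect linear predictor at posterior means
fixed_effect_variance <- function(fit, data) {
  if (!length(fit$predictors)) return(0)
  missing_pred <- setdiff(fit$predictors, names(data))
  if (length(missing_pred)) {
    stop("design data lack predictor column(s): ",
         paste(missing_pred, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(data[, fit$predictors, drop = FALSE])
  if (nrow(X) == 0) stop("empty design", call. = FALSE)
  beta_hat <- vapply(paste0("b_", sub("_z$", "", fit$predictors)),
                     function(p) mean(param_draws(fit, p)), 0)
  # population variance of the linear predictor over the observed design
  eta <- drop(X %*% beta_hat)
  mean((eta - mean(eta))^2)
}

#' Conditional R-squared
#'
#' Proportion of total latent-scale variance explained jointly by fixed and
#' random effects:
#' `(V_fixed + sum V_random) / (V_fixed + sum V_random + V_resid)`, where
#' `V_fixed` is the variance of the fixed-effect linear predictor over the
#' observed design (at posterior means), the random-effect variances are the
#' squared posterior-mean SDs of the grouping terms (lake; plus site for the
#' abundance model), and `V_resid` is [residual_variance()] (which already
#' contains the overdispersion and distribution-specific parts for the
#' Poisson-lognormal family).
#'
#' @param fit a fitted `hier_fit`.
#' @param data the model-ready data the fit used (site table, or for the
#'   abundance model a data frame holding all predictor columns at
#'   observation level — see [model_design()]).
#' @param lambda_bar passed to [residual_variance()].
#' @return scalar in `[0, 1]`, with attribute `"components"`.
#' @export
conditional_r2 <- function(fit, data, lambda_bar = "marginal") {
  stopifnot(inherits(fit, "hier_fit"))
  v_f <- fixed_effect_variance(fit, data)
  pm <- function(p) mean(param_draws(fit, p))
  v_rand <- pm("sigma_lake")^2
  if (fit$family == "poisson_lognormal") v_rand <- v_rand + pm("sigma_site")^2
  v_res <- as.numeric(residual_variance(fit, lambda_bar))
  r2 <- (v_f + v_rand) / (v_f + v_rand + v_res)
  attr(r2, "components") <- c(fixed = v_f, random = v_rand, residual = v_res)
  r2
}

#' Observation-level design table for a fit
#'
#' Expands site-level predictors to dendy observations so that
#' [conditional_r2()] can evaluate the fixed-effect variance of the
#' abundance model over its true design. For lognormal fits this is just
#' the site table.
#'
#' @param fit a `hier_fit`.
#' @param std list from [standardize_covariates()].
#' @return data frame with one row per model observation.
#' @export
model_design <- function(fit, std) {
  if (fit$family == "lognormal") return(std$sites)
  idx <- match(std$dendies$site_id, std$sites$site_id)
  out <- std$dendies
  for (v in setdiff(fit$predictors, names(out))) {
    out[[v]] <- std$sites[[v]][idx]
  }
  out
}

#' Model-fit summary: within-lake and conditional R-squared
#'
#' Convenience wrapper reporting both fit statistics for a full/null model
#' pair, with the itemized variance components.
#'
#' @param full,null fitted `hier_fit` objects.
#' @param data model-ready design data (see [conditional_r2()]).
#' @param model optional model label.
#' @param lambda_bar passed to [residual_variance()].
#' @return data frame with one row: `model`, `within_lake_r2`,
#'   `conditional_r2`, `v_fixed`, `v_random`, `v_resid_full`, `v_resid_null`.
#' @export
r2_summary <- function(full, null, data, model = full$response,
                       lambda_bar = "marginal") {
  cr2 <- conditional_r2(full, data, lambda_bar)
  comp <- attr(cr2, "components")
  data.frame(
    model = model,
    within_lake_r2 = within_lake_r2(full, null, lambda_bar),
    conditional_r2 = as.numeric(cr2),
    v_fixed = unname(comp["fixed"]),
    v_random = unname(comp["random"]),
    v_resid_full = unname(comp["residual"]),
    v_resid_null = as.numeric(residual_variance(null, lambda_bar))
  )
}
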