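test_that("residual variance closed forms", {
  ln <- point_posterior("DOC", c(WL_T = 0.1),
                        sigmas = c(sigma_resid = 0.5, sigma_lake = 1))
  expect_equal(as.numeric(residual_variance(ln)), 0.25)
  # Poisson-lognormal at lambda_bar = 1 with no overdispersion: ln 2
  pln <- point_posterior("abund", c(depth = 0), alpha = 0,
                         sigmas = c(sigma_olre = 0, sigma_site = 0,
                                    sigma_lake = 0),
                         family = "poisson_lognormal")
  expect_equal(as.numeric(residual_variance(pln)), log(2))
  # distribution-specific part vanishes monotonically as the rate grows
  vals <- sapply(c(0, 1, 3, 6), function(a) {
    f <- point_posterior("abund", c(depth = 0), alpha = a,
                         sigmas = c(sigma_olre = 0, sigma_site = 0,
                                    sigma_lake = 0),
                         family = "poisson_lognormal")
    as.numeric(residual_variance(f))
  })
  expect_true(all(diff(vals) < 0))
  # the intercept-rate flag changes the evaluation point
  pln2 <- point_posterior("abund", c(depth = 0), alpha = 0,
                          sigmas = c(sigma_olre = 0.5, sigma_site = 0.4,
                                     sigma_lake = 0.3),
                          family = "poisson_lognormal")
  v_marg <- residual_variance(pln2, "marginal")
  v_int <- residual_variance(pln2, "intercept")
  expect_equal(attr(v_int, "components")[["lambda_bar"]], 1)
  expect_gt(attr(v_marg, "components")[["lambda_bar"]], 1)
  expect_lt(as.numeric(v_marg), as.numeric(v_int))
})

test_that("Poisson-lognormal residual variance matches a brute-force oracle", {
  # validate the closed form sigma_olre^2 + ln(1 + 1/lambda_bar) by
  # Monte Carlo: empirical OLRE variance, empirical marginal rate, and the
  # empirical squared CV of Poisson noise at that rate, combined by
  # lognormal moment matching
  set.seed(77)
  alpha <- 0.8; s_l <- 0.5; s_s <- 0.4; s_o <- 0.3
  n <- 1e6
  eps <- rnorm(n, 0, s_o)
  lam <- exp(alpha + rnorm(n, 0, s_l) + rnorm(n, 0, s_s) + eps)
  lambda_bar_mc <- mean(lam)
  pois <- rpois(n, lambda_bar_mc)
  cv2 <- var(pois) / mean(pois)^2
  oracle <- var(eps) + log(1 + cv2)
  fit <- point_posterior("abund", c(depth = 0), alpha = alpha,
                         sigmas = c(sigma_olre = s_o, sigma_site = s_s,
                                    sigma_lake = s_l),
                         family = "poisson_lognormal")
  expect_equal(as.numeric(residual_variance(fit)), oracle, tolerance = 0.02)
})

test_that("within-group R2 is the proportional residual-variance change", {
  full <- point_posterior("DOC", c(WL_T = 0.1),
                          sigmas = c(sigma_resid = sqrt(0.71), sigma_lake = 1))
  null <- point_posterior("DOC", character(0),
                          sigmas = c(sigma_resid = 1, sigma_lake = 1))
  expect_equal(within_lake_r2(full, null), 0.29)
  # a model compared with itself explains nothing, exactly
  expect_identical(within_lake_r2(full, full), 0)
  # a worse-than-null model is allowed but flagged
  worse <- point_posterior("DOC", c(WL_T = 0),
                           sigmas = c(sigma_resid = 1.2, sigma_lake = 1))
  expect_warning(r <- within_lake_r2(worse, null), "negative")
  expect_lt(r, 0)
  pln <- point_posterior("abund", c(depth = 0),
                         sigmas = c(sigma_olre = 1, sigma_site = 1,
                                    sigma_lake = 1),
                         family = "poisson_lognormal")
  expect_error(within_lake_r2(pln, null), "family")
})

test_that("conditional R2 decomposes fixed, random and residual variance", {
  dat <- data.frame(WL_T_z = c(-1, 0, 1))
  # no fixed effects: sigma_lake^2 = 1 against V_resid = 1 gives 0.5
  f0 <- point_posterior("DOC", c(WL_T = 0),
                        sigmas = c(sigma_resid = 1, sigma_lake = 1))
  f0$predictors <- "WL_T_z"
  expect_equal(as.numeric(conditional_r2(f0, dat)), 0.5)
  # near-perfect fit limit
  f1 <- point_posterior("DOC", c(WL_T = 2),
                        sigmas = c(sigma_resid = 1e-8, sigma_lake = 0))
  f1$predictors <- "WL_T_z"
  expect_equal(as.numeric(conditional_r2(f1, dat)), 1, tolerance = 1e-6)
  # conditional R2 exceeds the fixed-only share when random variance > 0
  f2 <- point_posterior("DOC", c(WL_T = 1),
                        sigmas = c(sigma_resid = 1, sigma_lake = 1))
  f2$predictors <- "WL_T_z"
  r2 <- conditional_r2(f2, dat)
  comp <- attr(r2, "components")
  fixed_only <- comp[["fixed"]] / sum(comp)
  expect_gt(as.numeric(r2), fixed_only)
  expect_error(conditional_r2(f2, dat[0, , drop = FALSE]), "empty design")
})

test_that("an informative covariate does not reduce expected within-lake R2", {
  # paired comparison over seeds: fit DOC with and without its wetland
  # driver, generated with a deliberately strong wetland effect
  diffs <- vapply(1:3, function(s) {
    cfg <- sim_config(beta_doc = c(NDVI_R = 0.066, NDVI_T = -0.002,
                                   WL_T = 0.4), seed = 200 + s)
    sim <- generate_catchment_dataset(cfg)
    std <- standardize_covariates(sim$sites, sim$dendies)
    args <- list(n_chains = 2, n_iter = 1200, n_burnin = 400)
    full <- do.call(fit_lognormal_hier,
                    c(list(std$sites, "DOC",
                           c("NDVI_R_z", "NDVI_T_z", "WL_T_z"), seed = 1),
                      args))
    reduced <- do.call(fit_lognormal_hier,
                       c(list(std$sites, "DOC", c("NDVI_R_z", "NDVI_T_z"),
                              seed = 1), args))
    null <- do.call(fit_lognormal_hier,
                    c(list(std$sites, "DOC", character(0), seed = 1), args))
    suppressWarnings(within_lake_r2(full, null) - within_lake_r2(reduced, null))
  }, 0)
  expect_gt(mean(diffs), 0)
  expect_gte(sum(diffs > 0), 2)
})

test_that("r2_summary itemizes both statistics with components", {
  full <- fit_quick("doc", seed = 12)
  null <- fit_quick("doc", null = TRUE, seed = 13)
  out <- r2_summary(full, null, model_design(full, default_std))
  expect_equal(nrow(out), 1)
  expect_true(out$within_lake_r2 < 1)
  expect_true(out$conditional_r2 >= 0 && out$conditional_r2 <= 1)
  expect_equal(out$v_resid_full,
               mean(param_draws(full, "sigma_resid"))^2)
})
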