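test_that("model specs encode the path structure", {
  expect_equal(model_spec("doc")$predictors, c("NDVI_R", "NDVI_T", "WL_T"))
  expect_equal(model_spec("ni")$predictors, c("pH", "DOC", "WL_C"))
  expect_equal(model_spec("abund")$family, "poisson_lognormal")
  expect_error(model_spec("nope"))
})

test_that("lognormal intercept recovers the log-scale mean for one lake", {
  set.seed(5)
  n <- 400
  y <- rlnorm(n, meanlog = 1.3, sdlog = 0.4)
  dat <- data.frame(lake_id = "L1", site_id = seq_len(n), y = y)
  f <- fit_lognormal_hier(dat, "y", character(0), n_chains = 2,
                          n_iter = 1200, n_burnin = 400, seed = 2)
  a <- as.vector(param_draws(f, "alpha"))
  # the log-scale MLE of the intercept is mean(log y)
  expect_lt(abs(mean(a) - mean(log(y))), 2 * sd(a))
  s <- as.vector(param_draws(f, "sigma_resid"))
  expect_lt(abs(mean(s) - 0.4), 3 * sd(s))
})

test_that("prior-only run reproduces the stated priors", {
  f <- fit_lognormal_hier(data.frame(), "DOC", c("x_z"), prior_only = TRUE,
                          n_chains = 2, n_iter = 3000, n_burnin = 500,
                          seed = 3)
  b <- as.vector(param_draws(f, "b_x"))
  expect_equal(sd(b), 10, tolerance = 0.6)
  expect_equal(mean(b), 0, tolerance = 0.6)
  sig <- as.vector(param_draws(f, "sigma_lake"))
  expect_true(all(sig >= 0 & sig <= 10))
  expect_equal(mean(sig), 5, tolerance = 0.3)
})

test_that("lognormal fit agrees with lme4 on the log scale", {
  skip_if_not_installed("lme4")
  f <- fit_quick("doc", seed = 8)
  s <- summarize_posterior(f, seed = 1)
  m <- lme4::lmer(log(DOC) ~ NDVI_R_z + NDVI_T_z + WL_T_z + (1 | lake_id),
                  data = default_std$sites, REML = FALSE)
  fe <- lme4::fixef(m)
  expect_equal(s$mean[s$parameter == "alpha"], unname(fe[1]), tolerance = 0.05)
  for (p in c("NDVI_R", "NDVI_T", "WL_T")) {
    expect_equal(s$mean[s$parameter == paste0("b_", p)],
                 unname(fe[paste0(p, "_z")]), tolerance = 0.05)
  }
})

test_that("both abundance engines target the same posterior", {
  fi <- fit_poisson_lognormal(default_std$dendies, default_std$sites,
                              n_chains = 2, n_iter = 1700, n_burnin = 500,
                              seed = 5)
  fj <- fit_poisson_lognormal(default_std$dendies, default_std$sites,
                              n_chains = 2, n_iter = 1700, n_burnin = 500,
                              seed = 5, engine = "jags")
  si <- summarize_posterior(fi, seed = 1)
  sj <- summarize_posterior(fj, seed = 1)
  for (p in c("alpha", "b_NiL", "b_CuL", "b_DOC", "b_depth", "b_pH")) {
    expect_equal(si$mean[si$parameter == p], sj$mean[sj$parameter == p],
                 tolerance = 0.12)
  }
  for (p in c("sigma_olre", "sigma_site")) {
    expect_equal(si$mean[si$parameter == p], sj$mean[sj$parameter == p],
                 tolerance = 0.1)
  }
  expect_match(fi$sampler, "ASIS")
})

test_that("all-zero counts push the abundance intercept far below zero", {
  d0 <- default_std$dendies
  d0$count <- 0L
  f0 <- fit_poisson_lognormal(d0, default_std$sites,
                              predictors = character(0),
                              n_chains = 2, n_iter = 1200, n_burnin = 400,
                              seed = 6)
  a <- as.vector(param_draws(f0, "alpha"))
  expect_lt(quantile(a, 0.975), 0)
})

test_that("overdispersion SD estimates are ordered by their truth", {
  base <- list(n_lakes = 8, sites_per_lake = rep(4L, 8), dendies_per_site = 8)
  cfg0 <- do.call(sim_config, c(base, list(sigma_olre = 0, seed = 21)))
  cfg1 <- do.call(sim_config, c(base, list(sigma_olre = 1, seed = 21)))
  f0 <- fit_quick("abund", standardize_covariates(
    generate_catchment_dataset(cfg0)$sites,
    generate_catchment_dataset(cfg0)$dendies), seed = 4)
  f1 <- fit_quick("abund", standardize_covariates(
    generate_catchment_dataset(cfg1)$sites,
    generate_catchment_dataset(cfg1)$dendies), seed = 4)
  expect_lt(mean(param_draws(f0, "sigma_olre")),
            mean(param_draws(f1, "sigma_olre")))
})

test_that("relabeling lakes leaves fixed-effect posteriors unchanged", {
  sites2 <- default_std$sites
  perm <- setNames(sample(unique(sites2$lake_id)), unique(sites2$lake_id))
  sites2$lake_id <- unname(perm[sites2$lake_id])
  std2 <- list(sites = sites2, dendies = default_std$dendies,
               scaling = default_std$scaling)
  f1 <- fit_quick("doc", seed = 9)
  f2 <- fit_quick("doc", std2, seed = 9)
  s1 <- summarize_posterior(f1, seed = 1)
  s2 <- summarize_posterior(f2, seed = 1)
  for (p in c("alpha", "b_NDVI_R", "b_NDVI_T", "b_WL_T")) {
    expect_equal(s1$mean[s1$parameter == p], s2$mean[s2$parameter == p],
                 tolerance = 0.03)
  }
})

test_that("fits reject invalid inputs before sampling", {
  bad <- default_std$sites
  bad$DOC[1] <- -1
  expect_error(fit_lognormal_hier(bad, "DOC", "WL_T_z"), "positive")
  expect_error(fit_lognormal_hier(default_std$sites, "DOC", "nope_z"),
               "not in data")
  badd <- default_std$dendies
  badd$count[1] <- 0.5
  expect_error(fit_poisson_lognormal(badd, default_std$sites), "integers")
  orphan <- default_std$dendies
  orphan$site_id[1] <- "S99"
  expect_error(fit_poisson_lognormal(orphan, default_std$sites), "absent")
  expect_error(fit_lognormal_hier(default_std$sites, "DOC", "WL_T_z",
                                  n_iter = 100, n_burnin = 400), "exceed")
})

test_that("fixed seeds make fits reproducible end to end", {
  f1 <- fit_quick("doc", seed = 31)
  f2 <- fit_quick("doc", seed = 31)
  expect_identical(f1$draws, f2$draws)
  g1 <- fit_quick("abund", seed = 31, monitor_latent = FALSE)
  g2 <- fit_quick("abund", seed = 31, monitor_latent = FALSE)
  expect_identical(g1$draws, g2$draws)
})
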