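test_that("default survey has the study dimensions and valid structure", {
  sim <- default_sim
  expect_equal(nrow(sim$sites), 43)
  expect_equal(nrow(sim$dendies), 43 * 8)
  expect_equal(length(unique(sim$sites$lake_id)), 11)
  expect_true(all(sim$sites$DOC > 0))
  expect_true(all(sim$sites$NiL >= 0) && all(sim$sites$CuL >= 0))
  expect_false(any(duplicated(sim$sites$site_id)))
  expect_true(all(sim$dendies$count >= 0))
  expect_true(all(sim$dendies$count == round(sim$dendies$count)))
  expect_true(all(sim$dendies$depth > 0))
  expect_true(all(sim$dendies$site_id %in% sim$sites$site_id))
  # truth record carries every latent needed for recovery checks
  expect_named(sim$truth$v_lake, c("doc", "ni", "cu", "abund"))
  expect_length(sim$truth$v_site, 43)
  expect_length(sim$truth$eps, 43 * 8)
})

test_that("regeneration under a fixed seed is bit-identical", {
  a <- generate_catchment_dataset(sim_config(seed = 123))
  b <- generate_catchment_dataset(sim_config(seed = 123))
  expect_identical(a, b)
  st1 <- generate_stream_timeseries(seed = 5)
  st2 <- generate_stream_timeseries(seed = 5)
  expect_identical(st1, st2)
})

test_that("degenerate generator collapses DOC to exp(alpha)", {
  cfg <- sim_config(
    beta_doc = c(NDVI_R = 0, NDVI_T = 0, WL_T = 0),
    beta_ni = c(pH = 0, DOC = 0, WL_C = 0),
    beta_cu = c(pH = 0, DOC = 0, WL_C = 0),
    beta_abund = c(NiL = 0, CuL = 0, DOC = 0, depth = 0, pH = 0),
    sigma_resid = c(doc = 0, ni = 0, cu = 0),
    sigma_lake = c(doc = 0, ni = 0, cu = 0, abund = 0),
    sigma_site = 0, sigma_olre = 0, seed = 1
  )
  sim <- generate_catchment_dataset(cfg)
  expect_equal(sim$sites$DOC, rep(exp(cfg$alpha[["doc"]]), 43))
  expect_equal(sim$sites$NiL, rep(exp(cfg$alpha[["ni"]]), 43))
})

test_that("lognormal mean identity holds at large n (Monte Carlo)", {
  # no covariate effects, no random effects: E[DOC] = exp(alpha + sigma^2/2)
  cfg <- sim_config(
    n_lakes = 1, sites_per_lake = 10000L, dendies_per_site = 1,
    beta_doc = c(NDVI_R = 0, NDVI_T = 0, WL_T = 0),
    sigma_resid = c(doc = 0.5, ni = 0.2, cu = 0.37),
    sigma_lake = c(doc = 0, ni = 0, cu = 0, abund = 0),
    sigma_site = 0, sigma_olre = 0, seed = 11
  )
  sim <- generate_catchment_dataset(cfg)
  target <- exp(cfg$alpha[["doc"]] + 0.5 * 0.5^2)
  mc_se <- sd(sim$sites$DOC) / sqrt(nrow(sim$sites))
  expect_lt(abs(mean(sim$sites$DOC) - target), 2 * mc_se)
})

test_that("count marginal mean matches the mixed-lognormal identity", {
  # with all covariate effects zero,
  # E[count] -> exp(alpha + (sigma_lake^2 + sigma_site^2 + sigma_olre^2)/2)
  cfg <- sim_config(
    n_lakes = 40, sites_per_lake = rep(10L, 40), dendies_per_site = 10,
    beta_abund = c(NiL = 0, CuL = 0, DOC = 0, depth = 0, pH = 0),
    seed = 3
  )
  sim <- generate_catchment_dataset(cfg)
  target <- exp(cfg$alpha[["abund"]] +
                  0.5 * (cfg$sigma_lake[["abund"]]^2 + cfg$sigma_site^2 +
                           cfg$sigma_olre^2))
  # counts are clustered: use lake-level means for the Monte-Carlo SE
  lake_of <- sim$sites$lake_id[match(sim$dendies$site_id, sim$sites$site_id)]
  lake_means <- tapply(sim$dendies$count, lake_of, mean)
  mc_se <- sd(lake_means) / sqrt(length(lake_means))
  expect_lt(abs(mean(sim$dendies$count) - target), 3 * mc_se)
})

test_that("a strongly negative coefficient produces a monotone decline", {
  cfg <- sim_config(
    n_lakes = 10, sites_per_lake = rep(100L, 10), dendies_per_site = 1,
    beta_abund = c(NiL = -3, CuL = 0, DOC = 0, depth = 0, pH = 0),
    seed = 4
  )
  sim <- generate_catchment_dataset(cfg)
  counts <- tapply(sim$dendies$count, sim$dendies$site_id, sum)
  counts <- counts[sim$sites$site_id]
  expect_lt(cor(sim$sites$NiL, counts, method = "spearman"), 0)
})

test_that("generator rejects invalid configurations", {
  expect_error(sim_config(dendies_per_site = 0), "dendies_per_site")
  expect_error(sim_config(sigma_site = -1), "non-negative")
  bad_cov <- default_covariates()
  bad_cov$sd[1] <- 0
  expect_error(sim_config(covariates = bad_cov), "positive")
  expect_error(sim_config(sites_per_lake = c(3, 3)), "sites_per_lake")
})

test_that("stream generator moment-matches its targets", {
  # zero-variance target draws are exact
  tg <- default_stream_targets()
  tg$sd <- 0
  st <- generate_stream_timeseries(tg, seed = 1)
  hi <- st[st$subcatchment_id == "high_wetland" & st$period == "before", ]
  expect_equal(hi$DOC, rep(16.1, 60))
  # lognormal moment matching at large n reproduces mean and SD within 1%
  p <- lognormal_params(16.1, 3.1)
  set.seed(9)
  x <- rlnorm(1e5, p$meanlog, p$sdlog)
  expect_lt(abs(mean(x) - 16.1) / 16.1, 0.01)
  expect_lt(abs(sd(x) - 3.1) / 3.1, 0.01)
})

test_that("stream series covers both subcatchments and periods at 8-h spacing", {
  st <- generate_stream_timeseries(seed = 2)
  tab <- table(st$subcatchment_id, st$period)
  expect_equal(dim(tab), c(2L, 2L))
  expect_true(all(tab == 60))
  expect_equal(diff(st$timestamp[st$subcatchment_id == "high_wetland"][1:2]), 8)
  expect_true(all(st$DOC > 0) && all(st$NiL > 0) && all(st$CuL > 0))
  # the optional onset pulse only raises DOC right after the drought begins
  sp <- generate_stream_timeseries(seed = 2, onset_spike = TRUE,
                                   spike_n = 6, spike_factor = 2)
  first_during <- which(st$subcatchment_id == "high_wetland" &
                          st$period == "during")[1:6]
  expect_equal(sp$DOC[first_during], 2 * st$DOC[first_during])
})

test_that("stream generator rejects invalid targets", {
  tg <- default_stream_targets()
  tg$mean[1] <- 0
  expect_error(generate_stream_timeseries(tg), "positive")
  tg <- default_stream_targets()
  tg$sd[1] <- -1
  expect_error(generate_stream_timeseries(tg), "non-negative")
})
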