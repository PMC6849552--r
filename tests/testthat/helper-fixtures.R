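# Shared fixtures: small enough that every test file stays quick.

# default-sized survey, fixed seed, reused read-only across tests
default_sim <- generate_catchment_dataset(sim_config(seed = 7))
default_std <- standardize_covariates(default_sim$sites, default_sim$dendies)

# quick MCMC settings for module tests (acceptance tests use paper settings)
quick <- list(n_chains = 2, n_iter = 1200, n_burnin = 400)

fit_quick <- function(model, std = default_std, seed = 1, ...) {
  do.call(fit_path_model, c(list(model = model, std = std, seed = seed), quick,
                            list(...)))
}
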