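# catchlink

Hierarchical Bayesian path models of how summer drought disrupts
terrestrial–aquatic linkages — and what that does to littoral
invertebrates.

Lakes rely on their catchments for terrestrial organic matter (tOM,
measured as dissolved organic carbon, DOC) and on organic soils to retain
metal contaminants. During dry summers both linkages can fail at once: tOM
export drops while oxidized wetland soils release stored metals (nickel,
copper) into stream flow. `catchlink` implements the complete analysis
chain for studying these disruptions across littoral-zone sites nested in
lakes, with the amphipod *Hyalella azteca* as the biotic indicator. It is
aimed at freshwater ecologists and biogeochemists who want a tested,
reusable version of this analysis that runs end-to-end on synthetic data.

## The models

Three hierarchical regressions form the path analysis (site *i*, lake *j*,
dendy *k*; all predictors z-scored):

```
DOC_ij   ~ lognormal(a1 + b1 NDVI_R + b2 NDVI_T + b3 WL_T + v_j,  sigma_DOC)
NiL_ij   ~ lognormal(a2 + b4 pH + b5 DOC + b6 WL_C + v_j,         sigma_NiL)   (same form for CuL)
Abund_ijk ~ Poisson(exp(a4 + b10 NiL + b11 CuL + b12 DOC + b13 Depth
                         + b14 pH + v_j + v_i + eps_ijk))
```

with Normal(0, sd 10) priors on intercepts and coefficients and
Uniform(0, 10) priors on all SDs; `eps_ijk` is an observation-level random
effect capturing overdispersion. Models are fitted by MCMC (4 chains ×
3500 iterations, 1000 burn-in): the lognormal models in JAGS with the lake
effect analytically marginalized, the Poisson-lognormal model with the
package's interweaved Metropolis-within-Gibbs sampler (ASIS updates for
the SDs; a JAGS engine is kept as a cross-check). Convergence is assessed
with split-chain R-hat and effective sample size, fit with within-lake and
conditional R², and fitted models compose into a path graph along which
catchment perturbations propagate to abundance, per posterior draw.

The package also includes the surrounding machinery: a synthetic-data
generator for the nested survey and for before/during-drought stream
chemistry, DGT passive-sampler and UV-absorbance chemistry conversions,
and the before/during drought comparison (period summaries, fold changes,
pooled t-tests).

## Worked example

```r
library(catchlink)

# 1. generate the default synthetic survey: 11 lakes, 43 littoral sites,
#    8 Hester-Dendy substrates per site, published coefficients as truth
sim <- generate_catchment_dataset(sim_config(seed = 1))
std <- standardize_covariates(sim$sites, sim$dendies)

# 2. fit the DOC model at the study's chain settings
fit <- fit_path_model("doc", std, seed = 1)
summarize_posterior(fit, seed = 1)
#>     parameter        mean       lower      upper significant
#> 1       alpha 1.056575363  0.76045417 1.35551899        TRUE
#> 2    b_NDVI_R 0.009613316 -0.04438691 0.06296849       FALSE
#> 3    b_NDVI_T 0.018944001 -0.03519022 0.07753981       FALSE
#> 4      b_WL_T 0.080306233  0.01699736 0.14227618        TRUE
#> 5 sigma_resid 0.153859093  0.11764604 0.20219166        TRUE
#> 6  sigma_lake 0.478990244  0.30424463 0.79301723        TRUE

convergence_diagnostics(fit)
#>     parameter      rhat     n_eff
#> 1       alpha 0.9999572  9474.879
#> 2    b_NDVI_R 1.0000304  9763.902
#> 3    b_NDVI_T 1.0001157 10000.000
#> 4      b_WL_T 0.9999845 10000.000
#> 5 sigma_resid 1.0016026  4597.209
#> 6  sigma_lake 1.0010948  1861.965
```

Interpretation: on this realization total wetland influence significantly
increases littoral DOC (its 95% interval excludes zero) while the two
forest-density effects, whose generating values are small, do not reach
significance at 43 sites. All R-hat values sit at 1.00 and effective
sample sizes are in the thousands, so the chains have mixed.

```r
# 3. before/during drought stream comparison
st <- generate_stream_timeseries(seed = 1)
drought_report(st)[, c("subcatchment_id", "analyte", "fold_change_reported",
                       "t_statistic", "p_value")]
#>   subcatchment_id analyte fold_change_reported t_statistic      p_value
#> 1    high_wetland     DOC                  0.6   -7.516403 1.197707e-11
#> 2    high_wetland     NiL                 35.0    8.054775 7.195648e-13
#> 3    high_wetland     CuL                 27.0   10.446312 1.744927e-18
#> 4     low_wetland     DOC                  1.2    5.084689 1.400254e-06
#> 5     low_wetland     NiL                  2.5    6.355712 4.055661e-09
#> 6     low_wetland     CuL                  1.2    1.168071 2.451329e-01

# 4. propagate a +2 SD connected-wetland perturbation to abundance
#    through the Ni linkage, using published point coefficients
g <- path_graph(
  point_posterior("DOC",  c(NDVI_R = 0.066, NDVI_T = -0.002, WL_T = 0.067)),
  point_posterior("NiL",  c(pH = -0.044, DOC = -0.098, WL_C = 0.082)),
  point_posterior("CuL",  c(pH = 0.054, DOC = -0.205, WL_C = -0.003)),
  point_posterior("abund", c(NiL = -0.914, CuL = 0.629, DOC = 0.016,
                             depth = -1.227, pH = -0.149),
                  family = "poisson_lognormal"),
  reference_site_summary())
propagate_effect(g, "WL_C", 2, c("WL_C", "NiL", "abund"))
#> <propagation_result> WL_C +2.00 SD along WL_C -> NiL -> abund
#>   node fold_mean fold_lower fold_upper
#>    NiL 1.1782143  1.1782143  1.1782143
#>  abund 0.6399435  0.6399435  0.6399435
#> terminal fold change: 0.64 (95% CI 0.64-0.64), -36.0%
```

A 2 SD increase in connected wetland area raises labile Ni by ~18% and, at
the observed mean Ni concentration, suppresses expected *H. azteca*
abundance by about a third. With fitted models instead of point
coefficients the same call yields a full posterior interval.

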