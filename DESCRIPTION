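Package: catchlink
Title: Hierarchical Path Models of Drought-Disrupted Terrestrial-Aquatic Linkages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how summer drought disrupts the export of
    terrestrial organic matter and the retention of metal contaminants in
    catchment soils, and what that does to littoral invertebrates. Provides a
    synthetic-data generator for nested lake/littoral-site/artificial-substrate
    surveys and before/during-drought stream chemistry; passive-sampler (DGT)
    and UV-absorbance chemistry conversions; before/during drought comparisons
    (period summaries, fold changes, pooled t-tests); Bayesian hierarchical
    lognormal and Poisson-lognormal path models fitted by MCMC with
    split-chain R-hat and effective-sample-size diagnostics; within-group and
    conditional R-squared decompositions for mixed models; and propagation of
    catchment perturbations through the fitted path to amphipod abundance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    stats,
    utils
Suggests:
    coda,
    lme4,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
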