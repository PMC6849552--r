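#' Standardize covariates for model fitting
#'
#' z-scores every covariate and every chemistry variable that appears as a
#' predictor in the path models, adding `<variable>_z` columns to the site
#' and dendy tables, and records the means, SDs and observed ranges so that
#' effects can be mapped back to raw units and propagated along the path.
#' Responses are left on their raw scale.
#'
#' @param sites site table with columns `lake_id`, `site_id`, the catchment
#'   covariates (`NDVI_T`, `NDVI_R`, `WL_T`, `WL_C`, `pH`) and chemistry
#'   (`DOC`, `NiL`, `CuL`).
#' @param dendies optional dendy table with `site_id`, `depth`, `count`; when
#'   supplied, `depth` is standardized too.
#' @param site_vars,dendy_vars which columns to standardize.
#' @return list with elements `sites`, `dendies` (augmented tables) and
#'   `scaling` (data frame `variable`, `mean`, `sd`, `min`, `max`).
#' @export
#' @examples
#' sim <- generate_catchment_dataset(sim_config(seed = 1))
#' std <- standardize_covariates(sim$sites, sim$dendies)
#' round(colMeans(std$sites[, c("DOC_z", "pH_z")]), 10)
standardize_covariates <- function(sites, dendies = NULL,
                                   site_vars = c("NDVI_T", "NDVI_R", "WL_T",
                                                 "WL_C", "pH", "DOC", "NiL",
                                                 "CuL"),
                                   dendy_vars = "depth") {
  site_vars <- intersect(site_vars, names(sites))
  vars <- lapply(site_vars, function(v) sites[[v]])
  names(vars) <- site_vars
  if (!is.null(dendies)) {
    dendy_vars <- intersect(dendy_vars, names(dendies))
    for (v in dendy_vars) vars[[v]] <- dendies[[v]]
  }
  bad <- names(vars)[vapply(vars, function(x) any(!is.finite(x)), TRUE)]
  if (length(bad)) {
    rows <- unique(unlist(lapply(bad, function(v) {
      if (v %in% names(sites)) sites$site_id[!is.finite(sites[[v]])] else NULL
    })))
    stop("missing or non-finite values in: ", paste(bad, collapse = ", "),
         if (length(rows)) paste0(" (sites ", paste(rows, collapse = ", "), ")"),
         call. = FALSE)
  }
  sds <- vapply(vars, stats::sd, 0)
  if (any(sds == 0)) {
    stop("zero-variance variable(s): ",
         paste(names(sds)[sds == 0], collapse = ", "),
         "; cannot z-score", call. = FALSE)
  }
  scaling <- data.frame(
    variable = names(vars),
    mean = vapply(vars, mean, 0),
    sd = sds,
    min = vapply(vars, min, 0),
    max = vapply(vars, max, 0),
    row.names = NULL
  )
  for (v in site_vars) {
    sites[[paste0(v, "_z")]] <- (sites[[v]] - scaling$mean[scaling$variable == v]) /
      scaling$sd[scaling$variable == v]
  }
  if (!is.null(dendies)) {
    for (v in dendy_vars) {
      dendies[[paste0(v, "_z")]] <- (dendies[[v]] - scaling$mean[scaling$variable == v]) /
        scaling$sd[scaling$variable == v]
    }
  }
  list(sites = sites, dendies = dendies, scaling = scaling)
}

#' Invert a z-score transform
#'
#' Maps standardized values back to raw units using a scaling record.
#'
#' @param z standardized values.
#' @param variable variable name present in `scaling`.
#' @param scaling scaling record from [standardize_covariates()] (or the
#'   generator truth).
#' @return values on the raw scale.
#' @export
unstandardize <- function(z, variable, scaling) {
  i <- match(variable, scaling$variable)
  if (is.na(i)) stop("no scaling recorded for ", variable, call. = FALSE)
  z * scaling$sd[i] + scaling$mean[i]
}

#' Published littoral-site summary statistics
#'
#' Mean, SD and observed range of chemistry and pH across the 43 littoral
#' sites as printed in the study's site-summary table: DOC 3.12 (1.31),
#' range 1.24-6.22 mg/L; labile Ni 22.8 (8.32), range 8.38-47.9 ug/L; labile
#' Cu 1.32 (0.52), range 0.37-3.06 ug/L; pH 6.27 (0.81), range 3.86-7.94.
#' Useful as a scaling record when propagating published coefficients
#' without access to the raw data.
#'
#' @return data frame with columns `variable`, `mean`, `sd`, `min`, `max`.
#' @export
#' @examples
#' reference_site_summary()
reference_site_summary <- function() {
  data.frame(
    variable = c("DOC", "NiL", "CuL", "pH"),
    mean = c(3.12, 22.8, 1.32, 6.27),
    sd = c(1.31, 8.32, 0.52, 0.81),
    min = c(1.24, 8.38, 0.37, 3.86),
    max = c(6.22, 47.9, 3.06, 7.94)
  )
}
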