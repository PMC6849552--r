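#' Accumulated metal mass from a DGT eluate
#'
#' Converts the eluate concentration measured after acid elution of a
#' diffusive-gradients-in-thin-films (DGT) resin gel into the metal mass
#' accumulated over the deployment:
#' `M = C_e * (V_HNO3 + V_gel) / f_e`.
#' With `C_e` in ug/L and volumes in mL the product ug/L x mL = ng, so `M`
#' is returned in ng.
#'
#' @param eluate_conc eluate concentration `C_e` (ug/L), >= 0.
#' @param acid_volume volume of eluting acid `V_HNO3` (mL), > 0.
#' @param gel_volume resin-gel volume `V_gel` (mL), > 0.
#' @param elution_factor elution efficiency `f_e`, in (0, 1].
#' @return accumulated mass in ng (vectorized).
#' @export
#' @examples
#' eluate_to_mass(1, 1.8, 0.2, 0.8)  # 2.5 ng
eluate_to_mass <- function(eluate_conc, acid_volume, gel_volume, elution_factor) {
  if (any(eluate_conc < 0)) stop("eluate concentration must be >= 0", call. = FALSE)
  if (any(acid_volume <= 0) || any(gel_volume <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  if (any(elution_factor <= 0) || any(elution_factor > 1)) {
    stop("elution factor must lie in (0, 1]", call. = FALSE)
  }
  eluate_conc * (acid_volume + gel_volume) / elution_factor
}

#' Time-averaged labile concentration from DGT-accumulated mass
#'
#' The standard DGT equation `C = M * dg / (D * t * A)`: accumulated mass
#' times diffusive-gel thickness over diffusion coefficient, deployment time
#' and exposure-window area. With `M` in ng, `dg` in cm, `D` in cm^2/s, `t`
#' in s and `A` in cm^2 the result is ng/cm^3, numerically equal to ug/L.
#'
#' @param mass accumulated mass `M` (ng), >= 0.
#' @param gel_thickness diffusive-gel thickness `dg` (cm), > 0.
#' @param diffusion_coeff diffusion coefficient `D` (cm^2/s), > 0; metal- and
#'   temperature-specific, from a lookup table such as
#'   [read_diffusion_table()].
#' @param deploy_time deployment time `t` (s), > 0.
#' @param window_area exposure-window area `A` (cm^2), > 0.
#' @return time-averaged labile concentration in ug/L (vectorized).
#' @export
#' @examples
#' dgt_concentration(10, 0.08, 5e-6, 14 * 86400, 3.14)
dgt_concentration <- function(mass, gel_thickness, diffusion_coeff,
                              deploy_time, window_area) {
  if (any(mass < 0)) stop("mass must be >= 0", call. = FALSE)
  if (any(gel_thickness <= 0) || any(diffusion_coeff <= 0) ||
      any(deploy_time <= 0) || any(window_area <= 0)) {
    stop("gel thickness, diffusion coefficient, deployment time and window area must be positive",
         call. = FALSE)
  }
  mass * gel_thickness / (diffusion_coeff * deploy_time * window_area)
}

#' Blank correction of DGT concentrations
#'
#' Subtracts the mean of the laboratory blanks from each measured
#' concentration. Values that would go negative are floored at 0 and flagged
#' rather than dropped, so the site table stays complete.
#'
#' @param concentrations numeric vector of measured concentrations.
#' @param blank_concentrations numeric vector of blank concentrations
#'   (at least one).
#' @return data frame with columns `raw`, `corrected`, `floored`.
#' @export
#' @examples
#' subtract_blanks(c(5, 1), c(1, 3))
subtract_blanks <- function(concentrations, blank_concentrations) {
  if (length(blank_concentrations) < 1) {
    stop("at least one blank concentration is required", call. = FALSE)
  }
  bl <- mean(blank_concentrations)
  corrected <- concentrations - bl
  floored <- corrected < 0
  corrected[floored] <- 0
  data.frame(raw = concentrations, corrected = corrected, floored = floored)
}

#' DOC from UV absorbance at 320 nm
#'
#' Converts decadic absorbance at 320 nm to the absorbance coefficient
#' `K320 = 2.303 * A320 / l` (per metre) and maps K320 to a DOC estimate
#' through a regional linear calibration
#' `DOC = intercept + slope * K320`. The calibration is mandatory: the
#' coefficients are survey-region specific and no default is meaningful.
#' DOC estimates below `doc_min` are floored there and flagged.
#'
#' @param a320 absorbance at 320 nm (unitless, >= 0).
#' @param path_length cuvette path length in metres (> 0).
#' @param calib list with numeric `intercept` and `slope` of the K320 -> DOC
#'   regression (DOC in mg/L).
#' @param doc_min minimum reportable DOC (mg/L), default 0.1.
#' @return data frame with columns `K320` (per m), `DOC` (mg/L), `floored`.
#' @export
#' @examples
#' absorbance_to_doc(0.1, 0.01, calib = list(intercept = 0.5, slope = 0.12))
absorbance_to_doc <- function(a320, path_length, calib, doc_min = 0.1) {
  if (missing(calib) || is.null(calib) ||
      is.null(calib$intercept) || is.null(calib$slope)) {
    stop("a K320 -> DOC calibration (intercept, slope) must be supplied",
         call. = FALSE)
  }
  if (any(a320 < 0)) stop("absorbance must be >= 0", call. = FALSE)
  if (any(path_length <= 0)) stop("path length must be positive", call. = FALSE)
  if (doc_min <= 0) stop("`doc_min` must be positive", call. = FALSE)
  k320 <- 2.303 * a320 / path_length
  doc <- calib$intercept + calib$slope * k320
  floored <- doc < doc_min
  doc[floored] <- doc_min
  data.frame(K320 = k320, DOC = doc, floored = floored)
}

#' Read a diffusion-coefficient lookup table
#'
#' DGT diffusion coefficients depend on metal and water temperature and come
#' from a configuration table, never from hard-coded values. The packaged
#' example file `inst/extdata/dgt_diffusion_coefficients.csv` carries
#' illustrative 20-25 C values from the open literature.
#'
#' @param path CSV with columns `metal`, `temperature_c`, `diffusion_cm2_s`;
#'   defaults to the packaged example table.
#' @return data frame of the table.
#' @export
read_diffusion_table <- function(path = system.file("extdata",
                                                    "dgt_diffusion_coefficients.csv",
                                                    package = "catchlink")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metal", "temperature_c", "diffusion_cm2_s")
  if (!all(need %in% names(tab))) {
    stop("diffusion table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Look up a diffusion coefficient
#'
#' Nearest-temperature lookup in a diffusion-coefficient table.
#'
#' @param metal metal name, e.g. `"Ni"`.
#' @param temperature_c water temperature in Celsius.
#' @param table a table from [read_diffusion_table()].
#' @return diffusion coefficient in cm^2/s.
#' @export
lookup_diffusion_coeff <- function(metal, temperature_c,
                                   table = read_diffusion_table()) {
  rows <- table[table$metal == metal, ]
  if (nrow(rows) == 0) stop("no entries for metal ", metal, call. = FALSE)
  rows$diffusion_cm2_s[which.min(abs(rows$temperature_c - temperature_c))]
}
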