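#' Per-period summaries of a stream chemistry series
#'
#' Arithmetic mean and sample SD (n-1 denominator) of each analyte per
#' subcatchment and period. A cell with a single observation gets `sd = NA`
#' and is flagged.
#'
#' @param stream data frame as returned by [generate_stream_timeseries()]:
#'   columns `subcatchment_id`, `period`, and analyte columns `DOC`, `NiL`,
#'   `CuL` (any subset).
#' @param analytes analyte columns to summarize.
#' @return data frame: `subcatchment_id`, `analyte`, `period`, `n`, `mean`,
#'   `sd`, `sd_missing`.
#' @export
summarize_periods <- function(stream, analytes = intersect(c("DOC", "NiL", "CuL"),
                                                           names(stream))) {
  stopifnot(all(c("subcatchment_id", "period") %in% names(stream)),
            length(analytes) >= 1)
  grid <- unique(stream[, c("subcatchment_id", "period")])
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sub <- stream[stream$subcatchment_id == grid$subcatchment_id[i] &
                    stream$period == grid$period[i], ]
    do.call(rbind, lapply(analytes, function(an) {
      x <- sub[[an]]
      n <- length(x)
      data.frame(
        subcatchment_id = grid$subcatchment_id[i],
        analyte = an,
        period = grid$period[i],
        n = n,
        mean = mean(x),
        sd = if (n >= 2) stats::sd(x) else NA_real_,
        sd_missing = n < 2
      )
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Drought fold change
#'
#' Ratio of the during-drought mean to the before-drought mean, reported both
#' raw and rounded the way such ratios are conventionally printed: to the
#' nearest integer at or above 10, to one decimal below 10.
#'
#' @param mean_during,mean_before period means; `mean_before` must be > 0.
#' @return data frame with columns `ratio` (raw) and `reported` (rounded).
#' @export
#' @examples
#' fold_change(470, 12.9)$reported   # 36
#' fold_change(147, 55.2)$reported   # 2.7
fold_change <- function(mean_during, mean_before) {
  if (any(mean_before <= 0)) {
    stop("`mean_before` must be positive", call. = FALSE)
  }
  ratio <- mean_during / mean_before
  reported <- ifelse(ratio >= 10, round(ratio), round(ratio, 1))
  data.frame(ratio = ratio, reported = reported)
}

#' Two-sample t-test for a before/during contrast
#'
#' Tests the during-minus-before mean difference. The default is the pooled-
#' variance test with `df = n1 + n2 - 2` (the convention behind integer
#' degrees of freedom in reported stream comparisons); Welch's unequal-
#' variance test is available via `method`. Degenerate inputs are handled
#' explicitly: two zero-variance groups with equal means give `t = 0, p = 1`;
#' zero pooled variance with unequal means gives an infinite, flagged
#' statistic.
#'
#' @param before,during numeric vectors, each with at least 2 observations.
#' @param method `"pooled"` (default) or `"welch"`.
#' @return data frame: `t_statistic`, `df`, `p_value`, `method`, `infinite`.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4))
two_sample_t <- function(before, during, method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (length(before) < 2 || length(during) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  v1 <- stats::var(before); v2 <- stats::var(during)
  if (v1 == 0 && v2 == 0) {
    equal <- isTRUE(all.equal(mean(before), mean(during)))
    df <- if (method == "pooled") length(before) + length(during) - 2 else NA_real_
    return(data.frame(
      t_statistic = if (equal) 0 else sign(mean(during) - mean(before)) * Inf,
      df = df,
      p_value = if (equal) 1 else 0,
      method = method,
      infinite = !equal
    ))
  }
  tt <- stats::t.test(during, before, var.equal = (method == "pooled"))
  data.frame(
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    method = method,
    infinite = FALSE
  )
}

#' Full before/during drought comparison report
#'
#' One row per subcatchment and analyte: period means, SDs and sample sizes,
#' the during/before fold change (raw and as conventionally rounded), and the
#' two-sample t-test of the period contrast.
#'
#' @param stream stream table as in [summarize_periods()].
#' @param method t-test flavour, `"pooled"` (default) or `"welch"`.
#' @return data frame with one row per (subcatchment, analyte).
#' @export
#' @examples
#' st <- generate_stream_timeseries(seed = 1)
#' drought_report(st)
drought_report <- function(stream, method = c("pooled", "welch")) {
  method <- match.arg(method)
  sums <- summarize_periods(stream)
  grid <- unique(sums[, c("subcatchment_id", "analyte")])
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sc <- grid$subcatchment_id[i]; an <- grid$analyte[i]
    b <- sums[sums$subcatchment_id == sc & sums$analyte == an &
                sums$period == "before", ]
    d <- sums[sums$subcatchment_id == sc & sums$analyte == an &
                sums$period == "during", ]
    fc <- fold_change(d$mean, b$mean)
    xb <- stream[stream$subcatchment_id == sc & stream$period == "before", an]
    xd <- stream[stream$subcatchment_id == sc & stream$period == "during", an]
    tt <- two_sample_t(xb, xd, method = method)
    data.frame(
      subcatchment_id = sc, analyte = an,
      n_before = b$n, mean_before = b$mean, sd_before = b$sd,
      n_during = d$n, mean_during = d$mean, sd_during = d$sd,
      fold_change = fc$ratio, fold_change_reported = fc$reported,
      t_statistic = tt$t_statistic, df = tt$df, p_value = tt$p_value
    )
  }))
  rownames(out) <- NULL
  out
}
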