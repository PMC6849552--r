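#' @name convergence
#' @title MCMC convergence diagnostics
#' @description Split-chain potential scale reduction factor (R-hat) and
#' autocorrelation-based effective sample size, the two diagnostics used to
#' verify chain mixing (R-hat below 1.1 and effective sample sizes above 700
#' were the convergence bar for the fitted path models). Each chain is split
#' in half before computation, so within-chain drift inflates R-hat as well.
#' The effective sample size uses combined-chain autocorrelation estimates
#' with Geyer's initial-monotone-sequence truncation, capped at the total
#' number of draws.
NULL

# drop last draw if odd, then split every chain in half
split_chains <- function(mat) {
  n <- 2L * (nrow(mat) %/% 2L)
  mat <- mat[seq_len(n), , drop = FALSE]
  h <- n %/% 2L
  out <- matrix(NA_real_, h, 2L * ncol(mat))
  for (m in seq_len(ncol(mat))) {
    out[, 2L * m - 1L] <- mat[seq_len(h), m]
    out[, 2L * m] <- mat[h + seq_len(h), m]
  }
  out
}

as_chain_matrix <- function(x, parameter) {
  if (inherits(x, "hier_fit")) {
    if (is.null(parameter)) {
      stop("supply `parameter` when passing a hier_fit", call. = FALSE)
    }
    return(param_draws(x, parameter))
  }
  mat <- as.matrix(x)
  if (ncol(mat) < 2) stop("at least 2 chains are required", call. = FALSE)
  mat
}

#' @rdname convergence
#' @param x a `hier_fit`, or a numeric matrix of draws (iterations x chains).
#' @param parameter parameter name (required when `x` is a `hier_fit`).
#' @return `rhat()`: the split-chain potential scale reduction factor
#'   (1 for all-constant chains by convention; `Inf`, with a warning, when
#'   chains are constant but disagree).
#' @export
#' @examples
#' draws <- matrix(rnorm(4000), 1000, 4)
#' rhat(draws)
#' effective_sample_size(draws)
rhat <- function(x, parameter = NULL) {
  sims <- split_chains(as_chain_matrix(x, parameter))
  if (nrow(sims) < 2) stop("need at least 4 draws per chain", call. = FALSE)
  n <- nrow(sims)
  chain_var <- apply(sims, 2, stats::var)
  chain_mean <- colMeans(sims)
  w <- mean(chain_var)
  b <- n * stats::var(chain_mean)
  if (w == 0) {
    if (b == 0) return(1)
    warning("constant chains with differing values: R-hat is infinite")
    return(Inf)
  }
  var_plus <- (n - 1) / n * w + b / n
  sqrt(var_plus / w)
}

#' @rdname convergence
#' @return `effective_sample_size()`: the effective number of independent
#'   draws (`NA`, with a warning, for all-constant chains).
#' @export
effective_sample_size <- function(x, parameter = NULL) {
  sims <- split_chains(as_chain_matrix(x, parameter))
  n <- nrow(sims); m <- ncol(sims)
  if (n < 2) stop("need at least 4 draws per chain", call. = FALSE)
  chain_var <- apply(sims, 2, stats::var)
  w <- mean(chain_var)
  if (w == 0) {
    warning("constant chains: effective sample size is undefined")
    return(NA_real_)
  }
  b <- n * stats::var(colMeans(sims))
  var_plus <- (n - 1) / n * w + b / n
  # biased (1/n) autocovariances per chain via FFT, averaged across chains
  fft_acov <- function(x) {
    len <- length(x)
    x <- x - mean(x)
    pad <- 2^ceiling(log2(2 * len))
    f <- stats::fft(c(x, rep(0, pad - len)))
    Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(len)] / (pad * len)
  }
  acov <- vapply(seq_len(m), function(j) fft_acov(sims[, j]), numeric(n))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (w - mean_acov) / var_plus  # rho[1] is lag 0

  # Geyer initial monotone sequence on paired sums
  max_pairs <- floor(n / 2)
  tau <- -rho[1]
  pair_prev <- Inf
  for (k in seq_len(max_pairs)) {
    i <- 2L * k - 1L
    if (i + 1L > length(rho)) break
    p <- rho[i] + rho[i + 1L]
    if (p <= 0) break
    p <- min(p, pair_prev)   # enforce monotone nonincreasing
    tau <- tau + 2 * p
    pair_prev <- p
  }
  tau <- max(tau, 1 / log10(n * m + 10))  # guard against tiny/negative tau
  min(n * m / tau, n * m)
}

#' Diagnostics table for a fitted model
#'
#' Split-chain R-hat and effective sample size for each reported parameter
#' (intercept, coefficients and SD hyperparameters by default).
#'
#' @param fit a `hier_fit`.
#' @param parameters parameters to diagnose; defaults to the fit's reported
#'   set.
#' @return data frame: `parameter`, `rhat`, `n_eff`.
#' @export
convergence_diagnostics <- function(fit, parameters = fit$reported) {
  stopifnot(inherits(fit, "hier_fit"))
  data.frame(
    parameter = parameters,
    rhat = vapply(parameters, function(p) rhat(fit, p), 0),
    n_eff = vapply(parameters, function(p) effective_sample_size(fit, p), 0),
    row.names = NULL
  )
}

#' Posterior summaries from a thinned subset of draws
#'
#' Posterior mean and central 95% interval for each parameter, computed from
#' a subset of (by default) 1000 draws taken evenly across the chains — the
#' same convention used to report the fitted path-model effects. An effect
#' is marked significant when its 95% interval excludes zero.
#'
#' @param fit a `hier_fit`.
#' @param n_subset number of draws to summarize (default 1000). If more than
#'   available, all draws are used with a warning.
#' @param parameters parameters to summarize; defaults to the reported set.
#' @param seed optional seed making the subset reproducible.
#' @return data frame: `parameter`, `mean`, `lower`, `upper`, `significant`.
#' @export
summarize_posterior <- function(fit, n_subset = 1000,
                                parameters = fit$reported, seed = NULL) {
  stopifnot(inherits(fit, "hier_fit"))
  n_tot <- dim(fit$draws)[1] * dim(fit$draws)[2]
  if (n_subset > n_tot) {
    warning("requested ", n_subset, " draws but only ", n_tot,
            " available; using all")
    n_subset <- n_tot
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(n_tot, n_subset))
  out <- do.call(rbind, lapply(parameters, function(p) {
    d <- as.vector(param_draws(fit, p))[idx]
    q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = p, mean = mean(d), lower = q[1], upper = q[2],
               significant = q[1] > 0 || q[2] < 0)
  }))
  rownames(out) <- NULL
  out
}
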