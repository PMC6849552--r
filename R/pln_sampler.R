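# MCMC engine for the Poisson-lognormal abundance model.
#
# Metropolis-within-Gibbs sampler designed so every reported parameter mixes
# close to iid:
#   * each latent effect (eps, v_site, v_lake) has a log-concave univariate
#     conditional; it is refreshed by an independence Metropolis-Hastings
#     step whose proposal is the Laplace (Newton mode + curvature) Gaussian
#     approximation of that conditional, vectorized over units — acceptance
#     is near 1 and successive latent states are nearly independent;
#   * alpha and each beta get a direct slice update against the Poisson
#     likelihood, plus exact Gaussian "sufficient augmentation" updates
#     through the observation layer (m = eps + alpha + X beta), the site
#     layer (site-level coefficients) and the lake layer (alpha) — the
#     interweaving decouples fixed effects from the latent state;
#   * SD hyperparameters are updated twice per sweep: centered (conjugate
#     truncated inverse-gamma on the variance) and ancillary (slice against
#     the Poisson likelihood with the standardized latents held fixed) —
#     ancillarity-sufficiency interweaving (ASIS), which keeps the SDs
#     mixing even when the data carry little information about them.
# The kernel has no tuned proposal scales, so it is identical in and after
# burn-in.

# univariate slice sampler (stepping out + shrinkage), log target `logf`
slice_sample1 <- function(x0, logf, w = 0.5, lower = -Inf, upper = Inf,
                          max_steps = 50) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero density")
  logy <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- max(lower, x0 - u * w)
  R <- min(upper, L + w)
  k <- max_steps
  while (k > 0 && L > lower && logf(L) > logy) { L <- max(lower, L - w); k <- k - 1 }
  k <- max_steps
  while (k > 0 && R < upper && logf(R) > logy) { R <- min(upper, R + w); k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# Vectorized Laplace independence-MH refresh of latents with conditional
# log-density  g(v) = sy*v - A*exp(v) - v^2/(2 s^2)  (log-concave in v).
# `cur` is the current value; sy, A are per-unit sufficient statistics.
laplace_refresh <- function(cur, sy, A, s) {
  mode <- rep(0, length(cur))
  for (k in 1:6) {  # Newton; converges fast for log-concave targets
    eA <- A * exp(mode)
    grad <- sy - eA - mode / s^2
    hess <- -eA - 1 / s^2
    step <- grad / hess
    step <- pmin(pmax(step, -2), 2)
    mode <- mode - step
  }
  sd_prop <- 1 / sqrt(A * exp(mode) + 1 / s^2)
  prop <- mode + sd_prop * stats::rnorm(length(cur))
  logg <- function(v) sy * v - A * exp(v) - v^2 / (2 * s^2)
  logq <- function(v) -(v - mode)^2 / (2 * sd_prop^2)
  logr <- logg(prop) - logg(cur) - logq(prop) + logq(cur)
  acc <- log(stats::runif(length(cur))) < logr
  cur[acc] <- prop[acc]
  cur
}

pln_sample_chain <- function(y, X, site, lake_of_site, n_iter, n_burnin,
                             chain_seed, monitor_latent, prior_sd = 10,
                             sigma_upper = 10) {
  set.seed(chain_seed)
  N <- length(y); S <- length(lake_of_site)
  J <- max(lake_of_site); P <- if (is.null(X)) 0L else ncol(X)
  lake <- lake_of_site[site]
  site_f <- factor(site, levels = seq_len(S))
  lake_f <- factor(lake, levels = seq_len(J))
  sy_site <- as.vector(rowsum(y, site_f))
  sy_lake <- as.vector(rowsum(y, lake_f))
  sy <- sum(y)
  # site-level columns of X (constant within site) get the site-layer
  # interweave
  first_obs <- match(seq_len(S), site)
  site_cols <- integer(0)
  if (P > 0) {
    site_cols <- which(vapply(seq_len(P), function(p) {
      all(abs(X[, p] - X[first_obs, p][site]) < 1e-12)
    }, TRUE))
  }
  Xs <- if (length(site_cols)) X[first_obs, site_cols, drop = FALSE] else NULL
  # observation-layer design: intercept + dendy-level columns only. The
  # eps layer carries no site-level signal (v_site absorbs it), so
  # projecting site-level coefficients through it would clamp them; they
  # get the site-layer interweave instead.
  obs_cols <- setdiff(seq_len(P), site_cols)
  W <- cbind(rep(1, N), if (length(obs_cols)) X[, obs_cols, drop = FALSE])
  # flat-direction designs for the (alpha, site-beta) interweave:
  # within-lake deviations (compensated by v_site) and lake means plus
  # intercept (compensated by v_lake)
  if (length(site_cols)) {
    Lmeans <- apply(Xs, 2, function(x) {
      as.vector(tapply(x, lake_of_site, mean))[lake_of_site]
    })
    Bdev <- cbind(0, Xs - Lmeans)
    Cmean <- cbind(1, rowsum(Xs, lake_of_site) /
                     as.vector(table(lake_of_site)))
  } else {
    Bdev <- matrix(0, S, 1)
    Cmean <- matrix(1, J, 1)
  }

  # state
  alpha <- log(mean(y) + 0.1)
  beta <- rep(0, P)
  vl <- rep(0, J); vs <- rep(0, S); eps <- rep(0, N)
  sl <- 0.5; ss <- 0.5; so <- 0.5
  fix <- as.vector(if (P > 0) X %*% beta else 0) + alpha
  eta <- fix + vl[lake] + vs[site] + eps

  prior_prec <- 1 / prior_sd^2
  keep <- n_iter - n_burnin
  par_names <- c("alpha",
                 if (P > 0) paste0("beta", seq_len(P)),
                 "sigma_olre", "sigma_site", "sigma_lake",
                 if (monitor_latent) c(sprintf("v_lake[%d]", seq_len(J)),
                                       sprintf("v_site[%d]", seq_len(S)),
                                       sprintf("eps[%d]", seq_len(N))))
  out <- matrix(NA_real_, keep, length(par_names),
                dimnames = list(NULL, par_names))

  draw_trunc_sd <- function(x2sum, n) {
    # sigma^2 | x ~ InvGamma((n-1)/2, sum(x^2)/2) truncated to sigma < upper
    for (try in 1:100) {
      g <- stats::rgamma(1, shape = (n - 1) / 2, rate = x2sum / 2)
      s <- 1 / sqrt(g)
      if (s < sigma_upper) return(s)
    }
    stats::runif(1, 0, sigma_upper)
  }

  for (it in seq_len(n_iter)) {
    # -- latent refreshes (Laplace independence MH, vectorized)
    eps <- laplace_refresh(eps, y, exp(eta - eps), so)
    eta <- fix + vl[lake] + vs[site] + eps

    A_site <- as.vector(rowsum(exp(eta - vs[site]), site_f))
    vs <- laplace_refresh(vs, sy_site, A_site, ss)
    eta <- fix + vl[lake] + vs[site] + eps

    A_lake <- as.vector(rowsum(exp(eta - vl[lake]), lake_f))
    vl <- laplace_refresh(vl, sy_lake, A_lake, sl)
    eta <- fix + vl[lake] + vs[site] + eps

    # -- alpha and each beta: direct slice against the Poisson likelihood
    base <- eta - alpha
    alpha <- slice_sample1(alpha, function(a) {
      sy * a - sum(exp(base + a)) - a^2 / (2 * prior_sd^2)
    }, w = 0.3)
    eta <- base + alpha
    if (P > 0) {
      for (p in seq_len(P)) {
        xp <- X[, p]
        base <- eta - xp * beta[p]
        typ <- sum(y * xp)
        beta[p] <- slice_sample1(beta[p], function(b) {
          typ * b - sum(exp(base + xp * b)) - b^2 / (2 * prior_sd^2)
        }, w = 0.3)
        eta <- base + xp * beta[p]
      }
    }
    fix <- as.vector(if (P > 0) X %*% beta else 0) + alpha

    # -- (alpha, dendy-level beta) | observation layer: sufficient
    # augmentation
    theta_old <- c(alpha, beta[obs_cols])
    m <- eps + drop(W %*% theta_old)
    Lam <- crossprod(W) / so^2 + diag(prior_prec, ncol(W))
    ch <- chol(Lam)
    mu_t <- backsolve(ch, backsolve(ch, crossprod(W, m) / so^2,
                                    transpose = TRUE))
    theta <- drop(mu_t + backsolve(ch, stats::rnorm(ncol(W))))
    alpha <- theta[1]
    if (length(obs_cols)) beta[obs_cols] <- theta[-1]
    eps <- m - drop(W %*% theta)
    fix <- as.vector(if (P > 0) X %*% beta else 0) + alpha
    eta <- fix + vl[lake] + vs[site] + eps

    # -- joint flat-direction update of (alpha, site-level beta): shifting
    # them while compensating v_site (within-lake deviations) and v_lake
    # (lake means) leaves the likelihood invariant, so the conditional for
    # the shift is exactly Gaussian (priors only). This is the interweave
    # that lets site-level coefficients and the intercept mix through the
    # random-effect layers.
    theta_sl <- c(alpha, beta[site_cols])
    Q <- diag(prior_prec, 1 + length(site_cols)) +
      crossprod(Bdev) / ss^2 + crossprod(Cmean) / sl^2
    ell <- -prior_prec * theta_sl + crossprod(Bdev, vs) / ss^2 +
      crossprod(Cmean, vl) / sl^2
    ch <- chol(Q)
    mu_d <- backsolve(ch, backsolve(ch, ell, transpose = TRUE))
    delta <- drop(mu_d + backsolve(ch, stats::rnorm(length(theta_sl))))
    alpha <- alpha + delta[1]
    if (length(site_cols)) beta[site_cols] <- beta[site_cols] + delta[-1]
    vs <- vs - drop(Bdev %*% delta)
    vl <- vl - drop(Cmean %*% delta)
    fix <- as.vector(if (P > 0) X %*% beta else 0) + alpha
    eta <- fix + vl[lake] + vs[site] + eps

    # -- SDs, centered (conjugate)
    so <- draw_trunc_sd(sum(eps^2), N)
    ss <- draw_trunc_sd(sum(vs^2), S)
    sl <- draw_trunc_sd(sum(vl^2), J)

    # -- SDs, ancillary (ASIS): slice against the Poisson likelihood
    z <- eps / so
    c_e <- eta - eps
    syz <- sum(y * z)
    so <- slice_sample1(so, function(s) {
      if (s <= 0 || s >= sigma_upper) return(-Inf)
      s * syz - sum(exp(c_e + s * z))
    }, w = 0.2, lower = 1e-10, upper = sigma_upper)
    eps <- so * z
    eta <- c_e + eps

    # site and lake scales are the weakest-identified parameters (few
    # groups, sometimes sparse counts); cycling their refresh + centered +
    # ancillary updates a few times per sweep multiplies their mixing rate
    # at negligible cost (kernel composition)
    for (cycle in 1:3) {
      A_site <- as.vector(rowsum(exp(eta - vs[site]), site_f))
      vs <- laplace_refresh(vs, sy_site, A_site, ss)
      eta <- fix + vl[lake] + vs[site] + eps
      ss <- draw_trunc_sd(sum(vs^2), S)
      u <- vs / ss
      T_site <- as.vector(rowsum(exp(eta - vs[site]), site_f))
      syu <- sum(sy_site * u)
      ss <- slice_sample1(ss, function(s) {
        if (s <= 0 || s >= sigma_upper) return(-Inf)
        s * syu - sum(exp(s * u) * T_site)
      }, w = 0.2, lower = 1e-10, upper = sigma_upper)
      new_vs <- ss * u
      eta <- eta + (new_vs - vs)[site]
      vs <- new_vs

      A_lake <- as.vector(rowsum(exp(eta - vl[lake]), lake_f))
      vl <- laplace_refresh(vl, sy_lake, A_lake, sl)
      eta <- fix + vl[lake] + vs[site] + eps
      sl <- draw_trunc_sd(sum(vl^2), J)
      uL <- vl / sl
      T_lake <- as.vector(rowsum(exp(eta - vl[lake]), lake_f))
      syuL <- sum(sy_lake * uL)
      sl <- slice_sample1(sl, function(s) {
        if (s <= 0 || s >= sigma_upper) return(-Inf)
        s * syuL - sum(exp(s * uL) * T_lake)
      }, w = 0.2, lower = 1e-10, upper = sigma_upper)
      new_vl <- sl * uL
      eta <- eta + (new_vl - vl)[lake]
      vl <- new_vl
    }

    if (it %% 200 == 0) {  # guard against numeric drift in eta
      eta <- fix + vl[lake] + vs[site] + eps
    }

    if (it > n_burnin) {
      out[it - n_burnin, ] <- c(alpha, if (P > 0) beta, so, ss, sl,
                                if (monitor_latent) c(vl, vs, eps))
    }
  }
  out
}

pln_fit_interweaved <- function(y, X, site, lake_of_site, beta_names,
                                n_chains, n_iter, n_burnin, seed,
                                monitor_latent) {
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  set.seed(seed)
  chain_seeds <- sample.int(2^31 - 2, n_chains)
  chains <- lapply(chain_seeds, function(cs) {
    pln_sample_chain(y, X, site, lake_of_site, n_iter, n_burnin, cs,
                     monitor_latent)
  })
  pars <- colnames(chains[[1]])
  for (p in seq_along(beta_names)) {
    pars[pars == paste0("beta", p)] <- beta_names[p]
  }
  arr <- array(NA_real_, dim = c(nrow(chains[[1]]), n_chains, length(pars)),
               dimnames = list(NULL, NULL, pars))
  for (m in seq_len(n_chains)) arr[, m, ] <- chains[[m]]
  arr
}
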