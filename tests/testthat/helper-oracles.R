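# Independent oracles used across the suite. These deliberately avoid the
# package's computational path: the hierarchical-model oracle discretizes the
# full joint posterior over (mu, tau) on a dense 2-D trapezoid grid, and the
# rank-correlation oracle counts concordant/discordant pairs exhaustively.

# trapezoid weights on a (possibly nonuniform) sorted grid
trapz_weights <- function(x) {
  n <- length(x)
  if (n == 1) return(1)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

# quantile function from CDF values at nodes (linear interpolation on the
# strictly increasing part)
quantile_from_cdf <- function(x, cdf) {
  keep <- c(TRUE, diff(cdf) > 1e-15)
  x <- x[keep]; cdf <- cdf[keep]
  function(p) approx(cdf, x, xout = pmin(pmax(p, min(cdf)), max(cdf)),
                     ties = "ordered")$y
}

# shortest interval located by the highest-density (equal endpoint density)
# condition -- the stationarity condition of the width minimization, solved
# as a sign change, which is numerically much better conditioned
oracle_shortest <- function(qfun, dfun, level = 0.95) {
  g <- function(a) dfun(qfun(a + level)) - dfun(qfun(a))
  eps <- 1e-9
  if (g(eps) <= 0) return(c(qfun(0), qfun(level)))
  if (g(1 - level - eps) >= 0) return(c(qfun(1 - level), qfun(1)))
  a <- uniroot(g, c(eps, 1 - level - eps), tol = 1e-9)$root
  c(qfun(a), qfun(a + level))
}

# interpolated density from node masses on a (possibly nonuniform) grid
density_from_masses <- function(x, mass) {
  dens <- mass / trapz_weights(x)
  function(t) approx(x, dens, xout = t, rule = 2, ties = "ordered")$y
}

# density from a CDF sampled on a grid: derivative of a monotone cubic
# spline, far more accurate in the tails than finite differences
density_from_cdf <- function(x, cdf) {
  sf <- splinefun(x, cdf, method = "monoH.FC")
  function(t) pmax(sf(t, deriv = 1), 0)
}

# Full 2-D brute-force posterior for the normal-normal hierarchical model
# with uniform prior on mu and density prior_d on tau. Returns medians and
# shortest intervals for mu, tau, the predictive distribution of a future
# study, and (optionally) one study's shrinkage summary.
oracle_nnhm <- function(y, s, prior_d, tau_max = NULL, level = 0.95,
                        n_mu = 1601, n_tau = 480, shrink_study = NULL) {
  if (is.null(tau_max)) tau_max <- 4 * (max(s) + diff(range(c(y, y[1] + 1))))
  # the mu marginal mixes conditional normals with sd up to
  # sqrt(sigma^2 + tau^2); the grid must cover those heavy tails or the
  # truncated mass biases the tail quantiles
  mu_ext <- 6 * max(s) + 5 * tau_max / 8
  mu_lo <- min(y) - mu_ext; mu_hi <- max(y) + mu_ext
  mu <- seq(mu_lo, mu_hi, length.out = n_mu)
  # denser near zero, geometric extension into the tail
  t1 <- tau_max / 8
  tau <- unique(c(seq(0, t1, length.out = ceiling(n_tau * 0.7)),
                  exp(seq(log(t1), log(tau_max),
                          length.out = floor(n_tau * 0.3)))))
  wmu <- trapz_weights(mu); wtau <- trapz_weights(tau)

  LP <- matrix(NA_real_, length(tau), length(mu))
  for (j in seq_along(tau)) {
    sd_ij <- sqrt(s^2 + tau[j]^2)
    ll <- 0
    for (i in seq_along(y)) ll <- ll + dnorm(y[i], mu, sd_ij[i], log = TRUE)
    LP[j, ] <- log(prior_d(tau[j])) + ll
  }
  P <- exp(LP - max(LP)) * outer(wtau, wmu)
  P <- P / sum(P)

  # midpoint convention: the mass at a node straddles it, so the CDF at the
  # node is the cumulative mass minus half the node's own mass
  d_mu <- colSums(P)
  q_mu <- quantile_from_cdf(mu, cumsum(d_mu) - d_mu / 2)
  d_tau <- rowSums(P)
  q_tau <- quantile_from_cdf(tau, cumsum(d_tau) - d_tau / 2)

  # flatten the joint grid, dropping cells with negligible mass, so the
  # predictive/shrinkage CDF sums stay affordable
  keep <- which(P > 1e-12 * max(P))
  pw <- P[keep] / sum(P[keep])
  ptau <- tau[(keep - 1) %% length(tau) + 1]
  pmu <- mu[(keep - 1) %/% length(tau) + 1]

  # predictive CDF: F(t) = sum_cells w Phi((t - mu)/tau), an exact pointwise
  # evaluation (no normalization), on a uniform grid covering the data range
  # plus the bulk of the heterogeneity scale (medians and 95% HPD endpoints
  # all fall well inside it; the unresolved extreme tails are irrelevant to
  # them)
  tau_hi <- q_tau(0.999)
  cdf_grid <- function(mfun, sdfun) {
    th <- seq(min(y) - 6 * max(s) - 5 * tau_hi,
              max(y) + 6 * max(s) + 5 * tau_hi, length.out = 1201)
    Fth <- vapply(th, function(t) sum(pw * pnorm(t, mfun, sdfun)), numeric(1))
    list(x = th, cdf = Fth)
  }
  pg <- cdf_grid(pmu, ptau)
  q_pred <- quantile_from_cdf(pg$x, pg$cdf)

  d_mu_fun <- density_from_masses(mu, d_mu)
  d_tau_fun <- density_from_masses(tau, d_tau)
  d_pred_fun <- density_from_cdf(pg$x, pg$cdf)
  out <- list(
    mu_median = q_mu(0.5), mu_cri = oracle_shortest(q_mu, d_mu_fun, level),
    tau_median = q_tau(0.5), tau_cri = oracle_shortest(q_tau, d_tau_fun, level),
    pred_median = q_pred(0.5), pred_cri = oracle_shortest(q_pred, d_pred_fun, level)
  )
  if (!is.null(shrink_study)) {
    i <- shrink_study
    b <- ptau^2 / (ptau^2 + s[i]^2)
    m_i <- b * y[i] + (1 - b) * pmu
    sd_i <- sqrt(b * s[i]^2)
    sg <- cdf_grid(m_i, sd_i)
    q_sh <- quantile_from_cdf(sg$x, sg$cdf)
    out$shrink_median <- q_sh(0.5)
    out$shrink_cri <- oracle_shortest(q_sh, density_from_cdf(sg$x, sg$cdf), level)
  }
  out
}

# exhaustive Kendall tau by pairwise concordance counting
kendall_bruteforce <- function(x, y) {
  n <- length(x)
  sc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    sc <- sc + sign(x[j] - x[i]) * sign(y[j] - y[i])
  sc / (n * (n - 1) / 2)
}

# standard error implied by a printed 95% CI
se_from_ci <- function(lo, hi) (hi - lo) / (2 * qnorm(0.975))

# small reusable synthetic effect sets
toy_effects <- function(seed = 42, k = 4, mu = 0.8, tau = 0.4,
                        sigma_range = c(0.25, 1.2)) {
  set.seed(seed)
  s <- runif(k, sigma_range[1], sigma_range[2])
  y <- rnorm(k, mu, sqrt(tau^2 + s^2))
  list(y = y, s = s)
}
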