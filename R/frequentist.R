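#' DerSimonian-Laird estimate of the between-study variance
#'
#' The classic one-step moment estimator
#' `tau2 = max(0, (Q - (k - 1)) / (S1 - S2/S1))` with fixed-effect weights
#' `w_i = 1/sigma_i^2`, `S1 = sum(w_i)`, `S2 = sum(w_i^2)` and Cochran's Q
#' computed about the fixed-effect mean. A single study returns 0.
#'
#' @param x a [comorbidity_dataset()], a `study_effects` data frame, or a
#'   numeric vector of log odds ratios.
#' @param sigma within-study standard errors (when `x` is a plain vector).
#' @return Non-negative scalar `tau2`.
#' @export
dl_tau2 <- function(x, sigma = NULL) {
  eff <- check_effects(resolve_effects(x, sigma), 1, "dl_tau2")
  y <- eff$y
  k <- length(y)
  if (k == 1) return(0)
  w <- 1 / eff$sigma^2
  mu_fe <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu_fe)^2)
  s1 <- sum(w); s2 <- sum(w^2)
  max(0, (q - (k - 1)) / (s1 - s2 / s1))
}

#' Random-effects pooling with DerSimonian-Laird weights
#'
#' Pools per-study log odds ratios under the random-effects model
#' `y_i ~ N(mu, sigma_i^2 + tau2)` with the [dl_tau2()] heterogeneity
#' estimate: `mu_hat = sum(w*_i y_i) / sum(w*_i)` with
#' `w*_i = 1/(sigma_i^2 + tau2)`, a Wald z confidence interval, Cochran's Q
#' with its chi-square p-value, `I2 = max(0, (Q - df)/Q) * 100`, and a
#' Q-profile confidence interval for tau (when `k >= 2`; see [tau_ci()]).
#'
#' @inheritParams dl_tau2
#' @param level confidence level (default 0.95).
#' @return An object of class `dl_meta`: a list with elements `k`, `mu_hat`,
#'   `se_mu`, `mu_ci`, `or`, `or_ci`, `tau2`, `tau_hat`, `tau_ci`, `q`, `df`,
#'   `p_q`, `i2`, `weights` (normalized random-effects weights) and `labels`.
#' @examples
#' fit <- dl_meta(table2_fixture()$diabetes)
#' fit$or          # pooled odds ratio
#' fit$tau_hat     # between-study SD
#' @export
dl_meta <- function(x, sigma = NULL, level = 0.95) {
  eff <- check_effects(resolve_effects(x, sigma), 1, "dl_meta")
  y <- eff$y; s <- eff$sigma
  k <- length(y)
  z <- qnorm(1 - (1 - level) / 2)

  w_fe <- 1 / s^2
  mu_fe <- sum(w_fe * y) / sum(w_fe)
  q <- if (k > 1) sum(w_fe * (y - mu_fe)^2) else 0
  df <- k - 1
  p_q <- if (df > 0) pchisq(q, df, lower.tail = FALSE) else NA_real_
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0

  tau2 <- dl_tau2(y, s)
  w <- 1 / (s^2 + tau2)
  mu_hat <- sum(w * y) / sum(w)
  se_mu <- sqrt(1 / sum(w))
  ci <- mu_hat + c(-1, 1) * z * se_mu
  tci <- if (k >= 2) tau_ci(y, s, level = level) else c(NA_real_, NA_real_)

  structure(list(
    k = k, labels = eff$labels,
    mu_hat = mu_hat, se_mu = se_mu, mu_ci = ci,
    or = exp(mu_hat), or_ci = exp(ci),
    tau2 = tau2, tau_hat = sqrt(tau2), tau_ci = tci,
    q = q, df = df, p_q = p_q, i2 = i2,
    weights = w / sum(w), level = level
  ), class = "dl_meta")
}

#' @export
print.dl_meta <- function(x, digits = 3, ...) {
  cat(sprintf("Random-effects meta-analysis (DerSimonian-Laird), k = %d\n", x$k))
  cat(sprintf("  pooled log-OR %.*f  [%.*f, %.*f]   OR %.*f [%.*f, %.*f]\n",
              digits, x$mu_hat, digits, x$mu_ci[1], digits, x$mu_ci[2],
              digits, x$or, digits, x$or_ci[1], digits, x$or_ci[2]))
  cat(sprintf("  tau %.*f", digits, x$tau_hat))
  if (!anyNA(x$tau_ci))
    cat(sprintf("  [%.*f, %.*f]", digits, x$tau_ci[1], digits, x$tau_ci[2]))
  cat(sprintf("\n  Q = %.2f, df = %d, p = %.4f, I2 = %.2f%%\n",
              x$q, x$df, x$p_q, x$i2))
  invisible(x)
}

# Generalized Q statistic with random-effects weights at a trial value of tau.
generalized_q <- function(y, s, tau) {
  w <- 1 / (s^2 + tau^2)
  mu <- sum(w * y) / sum(w)
  sum(w * (y - mu)^2)
}

#' Q-profile confidence interval for the between-study SD
#'
#' The interval is the set of tau values whose generalized Q statistic
#' `Q(tau) = sum((y_i - mu_hat(tau))^2 / (sigma_i^2 + tau^2))` lies within the
#' central `level` region of a chi-square distribution with `k - 1` degrees of
#' freedom. `Q(tau)` is decreasing in tau, so the endpoints solve
#' `Q(tau) = qchisq(1 - alpha/2, k - 1)` (lower) and
#' `Q(tau) = qchisq(alpha/2, k - 1)` (upper), each truncated at 0.
#'
#' @inheritParams dl_meta
#' @return Numeric vector `c(lower, upper)` for tau (the SD, not variance).
#' @export
tau_ci <- function(x, sigma = NULL, level = 0.95) {
  eff <- check_effects(resolve_effects(x, sigma), 2, "tau_ci")
  y <- eff$y; s <- eff$sigma
  df <- length(y) - 1
  alpha <- 1 - level
  q_hi <- qchisq(1 - alpha / 2, df)
  q_lo <- qchisq(alpha / 2, df)
  q0 <- generalized_q(y, s, 0)

  solve_tau <- function(target) {
    # Q(tau) is monotone decreasing from Q(0) towards 0
    hi <- max(s) + diff(range(y)) + 1
    while (generalized_q(y, s, hi) > target) hi <- hi * 2
    uniroot(function(t) generalized_q(y, s, t) - target,
            c(0, hi), tol = 1e-8)$root
  }

  lower <- if (q0 <= q_hi) 0 else solve_tau(q_hi)
  upper <- if (q0 <= q_lo) 0 else solve_tau(q_lo)
  c(lower, upper)
}
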