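#' Simulation configuration for two-arm binomial meta-analysis data
#'
#' Describes the generative structure the analysis models assume: study
#' effects `theta_i ~ N(mu, tau^2)` on the log-OR scale, comparator-arm risks
#' drawn uniformly from `baseline_risk_range`, exposed-arm risks via
#' `logit(p1) = logit(p0) + theta_i` (or an additive risk difference when
#' `effect_scale = "risk_difference"`, a deliberate misspecification toggle
#' for robustness experiments), and binomial counts in each arm with per-arm
#' sizes drawn uniformly from `group_size_range`.
#'
#' @param k number of studies (>= 1).
#' @param mu true pooled log odds ratio.
#' @param tau true between-study SD (>= 0).
#' @param baseline_risk_range comparator-arm event-probability interval,
#'   inside (0, 1).
#' @param group_size_range per-arm sample-size interval (integers >= 2).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param effect_scale `"log_or"` (model-consistent) or `"risk_difference"`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(k, mu = 0, tau = 0,
                       baseline_risk_range = c(0.05, 0.30),
                       group_size_range = c(50, 500),
                       seed = 1L,
                       effect_scale = c("log_or", "risk_difference")) {
  effect_scale <- match.arg(effect_scale)
  stopifnot(k >= 1, tau >= 0,
            length(baseline_risk_range) == 2,
            all(baseline_risk_range > 0), all(baseline_risk_range < 1),
            baseline_risk_range[1] <= baseline_risk_range[2],
            length(group_size_range) == 2, all(group_size_range >= 2),
            group_size_range[1] <= group_size_range[2])
  structure(list(k = as.integer(k), mu = mu, tau = tau,
                 baseline_risk_range = baseline_risk_range,
                 group_size_range = as.integer(round(group_size_range)),
                 seed = as.integer(seed), effect_scale = effect_scale),
            class = "sim_config")
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring any
# pre-existing global state afterwards.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a two-arm binomial meta-analysis dataset
#'
#' Draws studies from the generative model described in [sim_config()] and
#' converts the resulting 2x2 counts to log odds ratios via
#' [log_odds_ratio()] with the Haldane-Anscombe correction. A study whose
#' table has an all-zero outcome margin (no events at all, or no non-events
#' at all) is redrawn at the same risk parameters up to `max_retries` times,
#' after which generation fails.
#'
#' @param config a [sim_config()].
#' @param name dataset name.
#' @param max_retries per-study redraw budget for degenerate tables.
#' @return A [comorbidity_dataset()] whose studies carry counts
#'   (`a`, `b`, `c`, `d`), plus columns `theta` (the true study effect) and
#'   `p0` (the comparator risk) for calibration experiments.
#' @examples
#' ds <- simulate_dataset(sim_config(k = 5, mu = 1, tau = 0.3, seed = 7))
#' dl_meta(ds)$mu_hat
#' @export
simulate_dataset <- function(config, name = "simulated", max_retries = 100) {
  stopifnot(inherits(config, "sim_config"))
  with_private_seed(config$seed, {
    k <- config$k
    theta <- rnorm(k, config$mu, config$tau)
    p0 <- runif(k, config$baseline_risk_range[1], config$baseline_risk_range[2])
    p1 <- if (config$effect_scale == "log_or") {
      plogis(qlogis(p0) + theta)
    } else {
      pmin(pmax(p0 + theta, 1e-6), 1 - 1e-6)
    }
    n1 <- sample(seq(config$group_size_range[1], config$group_size_range[2]), k,
                 replace = TRUE)
    n0 <- sample(seq(config$group_size_range[1], config$group_size_range[2]), k,
                 replace = TRUE)
    a <- integer(k); c_ <- integer(k)
    for (i in seq_len(k)) {
      for (try in seq_len(max_retries + 1)) {
        ai <- rbinom(1, n1[i], p1[i])
        ci <- rbinom(1, n0[i], p0[i])
        degenerate <- (ai + ci == 0) || (ai == n1[i] && ci == n0[i])
        if (!degenerate) break
        if (try > max_retries)
          stop("degenerate 2x2 margins persisted after ", max_retries,
               " redraws (study ", i, ")", call. = FALSE)
      }
      a[i] <- ai; c_[i] <- ci
    }
    b <- n1 - a; d <- n0 - c_
    eff <- log_odds_ratio(a, b, c_, d, correction = "haldane")
    st <- study_effects(sprintf("sim_%02d", seq_len(k)), eff$y, eff$sigma,
                        sample_size = n1 + n0, a = a, b = b, c = c_, d = d)
    st$theta <- theta
    st$p0 <- p0
    comorbidity_dataset(name, st)
  })
}

#' Simulate per-study effects directly on the log-OR scale
#'
#' Draws `y_i ~ N(mu, tau^2 + sigma_i^2)` with standard errors `sigma_i`
#' uniform in `sigma_range` — the null model of the funnel-asymmetry tests,
#' in which effect size is unrelated to precision. With `suppress = TRUE`
#' a crude one-sided selection mechanism is applied: imprecise studies
#' (`sigma_i` above the range midpoint) are redrawn until their estimate
#' exceeds `mu`, inducing the small-study asymmetry the bias tests look for.
#'
#' @param k number of studies.
#' @param mu true pooled effect.
#' @param tau between-study SD.
#' @param sigma_range interval for the within-study standard errors.
#' @param seed integer seed.
#' @param suppress apply the selection mechanism (default `FALSE`).
#' @return Data frame with columns `y`, `sigma`.
#' @export
simulate_null_effects <- function(k, mu = 0, tau = 0, sigma_range = c(0.2, 1.5),
                                  seed = 1L, suppress = FALSE) {
  stopifnot(k >= 1, tau >= 0, length(sigma_range) == 2,
            all(sigma_range > 0), sigma_range[1] <= sigma_range[2])
  with_private_seed(seed, {
    s <- runif(k, sigma_range[1], sigma_range[2])
    y <- rnorm(k, mu, sqrt(tau^2 + s^2))
    if (isTRUE(suppress)) {
      mid <- mean(sigma_range)
      for (i in which(s > mid)) {
        while (y[i] <= mu) y[i] <- rnorm(1, mu, sqrt(tau^2 + s[i]^2))
      }
    }
    data.frame(y = y, sigma = s)
  })
}
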