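test_that("priors expose correct densities and validation", {
  expect_equal(half_cauchy(0.5)$d(0), 2 / (pi * 0.5))
  expect_equal(half_normal(0.5)$d(0), 2 * dnorm(0, 0, 0.5))
  expect_equal(integrate(half_normal(0.7)$d, 0, Inf)$value, 1, tolerance = 1e-6)
  expect_error(half_normal(0), "scale")
  expect_error(half_cauchy(-1), "scale")
})

test_that("single study: tau posterior reduces to the prior", {
  # with k = 1 the marginal likelihood of tau is flat, so the posterior of
  # tau is the prior; check median and upper quantile against closed forms
  fit <- bayes_meta(0.7, 1.2, prior = half_normal(0.5), shrinkage = FALSE)
  expect_equal(fit$tau$median, qnorm(0.75) * 0.5, tolerance = 2e-3)
  fitc <- bayes_meta(0.7, 1.2, prior = half_cauchy(0.5), shrinkage = FALSE)
  expect_equal(fitc$tau$median, 0.5 * tan(pi / 4), tolerance = 2e-3)
  # grid weights behave like a distribution
  expect_true(all(fit$tau_grid$wts >= 0))
  expect_equal(sum(fit$tau_grid$wts), 1, tolerance = 1e-8)
})

test_that("point-mass prior at tau = 0 gives the conjugate fixed-effect posterior", {
  e <- toy_effects(seed = 13, k = 5)
  fit <- bayes_meta(e$y, e$s, prior = fixed_tau(0))
  w <- 1 / e$s^2
  m <- sum(w * e$y) / sum(w); se <- sqrt(1 / sum(w))
  expect_equal(fit$mu$median, m, tolerance = 1e-7)
  expect_equal(fit$mu$cri, m + c(-1, 1) * qnorm(0.975) * se, tolerance = 1e-6)
  # predictive and every shrinkage posterior collapse onto the mu posterior
  expect_equal(fit$predictive$median, fit$mu$median, tolerance = 1e-7)
  expect_equal(fit$predictive$cri, fit$mu$cri, tolerance = 1e-6)
  for (i in seq_along(e$y)) {
    expect_equal(fit$shrinkage$median[i], fit$mu$median, tolerance = 1e-7)
    expect_equal(fit$shrinkage$cri_low[i], fit$mu$cri[1], tolerance = 1e-6)
  }
})

test_that("a vanishing prior scale approaches the fixed-effect limit", {
  e <- toy_effects(seed = 17, k = 4)
  fit <- bayes_meta(e$y, e$s, prior = half_normal(1e-4), shrinkage = FALSE)
  w <- 1 / e$s^2
  expect_equal(fit$mu$median, sum(w * e$y) / sum(w), tolerance = 1e-4)
  expect_lt(fit$tau$median, 1e-3)
})

test_that("quadrature summaries match the brute-force 2-D joint posterior", {
  set.seed(202)
  shrink_checked <- 0
  for (rep in 1:6) {
    k <- sample(2:4, 1)
    e <- toy_effects(seed = 300 + rep, k = k, mu = runif(1, -1, 2),
                     tau = runif(1, 0, 0.8))
    prior <- if (rep %% 2) half_normal(0.5) else half_normal(1.0)
    fit <- bayes_meta(e$y, e$s, prior = prior, n_grid = 4001)
    orc <- oracle_nnhm(e$y, e$s, prior$d,
                       shrink_study = if (rep <= 2) 1 else NULL)
    expect_equal(fit$mu$median, orc$mu_median, tolerance = 1e-3)
    expect_equal(fit$mu$cri, orc$mu_cri, tolerance = 1e-3)
    expect_equal(fit$tau$median, orc$tau_median, tolerance = 1e-3)
    expect_equal(fit$predictive$median, orc$pred_median, tolerance = 1e-3)
    expect_equal(fit$predictive$cri, orc$pred_cri, tolerance = 1e-3)
    if (!is.null(orc$shrink_median)) {
      expect_equal(fit$shrinkage$median[1], orc$shrink_median,
                   tolerance = 1e-3)
      expect_equal(c(fit$shrinkage$cri_low[1], fit$shrinkage$cri_high[1]),
                   orc$shrink_cri, tolerance = 1e-3)
      shrink_checked <- shrink_checked + 1
    }
  }
  expect_equal(shrink_checked, 2)
})

test_that("grid refinement leaves every summary essentially unchanged", {
  fix <- table2_fixture()$diabetes
  f1 <- bayes_meta(fix, n_grid = 2001)
  f2 <- bayes_meta(fix, n_grid = 4001)
  expect_equal(f1$mu$median, f2$mu$median, tolerance = 1e-4)
  expect_equal(f1$mu$cri, f2$mu$cri, tolerance = 1e-4)
  expect_equal(f1$tau$median, f2$tau$median, tolerance = 1e-4)
  expect_equal(f1$predictive$cri, f2$predictive$cri, tolerance = 1e-4)
  expect_equal(f1$shrinkage$median, f2$shrinkage$median, tolerance = 1e-4)
})

test_that("posterior structure invariants hold on the evidence datasets", {
  for (ds in table2_fixture()) {
    fit <- bayes_meta(ds)
    expect_gte(fit$tau$cri[1], 0)
    expect_true(all(fit$tau_grid$wts >= 0))
    expect_equal(sum(fit$tau_grid$wts), 1, tolerance = 1e-8)
    # predictive interval at least as wide as the mu interval
    expect_gte(diff(fit$predictive$cri), diff(fit$mu$cri))
    # shrinkage intervals stay in a sane envelope around the data
    lo <- min(ds$studies$y - 4 * ds$studies$sigma)
    hi <- max(ds$studies$y + 4 * ds$studies$sigma)
    expect_true(all(fit$shrinkage$cri_low > lo))
    expect_true(all(fit$shrinkage$cri_high < hi))
  }
})

test_that("inflating all sigmas widens the mu credible interval", {
  e <- toy_effects(seed = 31, k = 6)
  f1 <- bayes_meta(e$y, e$s, shrinkage = FALSE)
  f2 <- bayes_meta(e$y, 1.6 * e$s, shrinkage = FALSE)
  expect_gt(diff(f2$mu$cri), diff(f1$mu$cri))
})

test_that("an uninformative study's shrinkage interval approaches the predictive", {
  e <- toy_effects(seed = 37, k = 4)
  fit <- bayes_meta(c(e$y, 0), c(e$s, 1e4))
  k1 <- length(e$y) + 1
  expect_equal(fit$shrinkage$median[k1], fit$predictive$median,
               tolerance = 1e-3)
  expect_equal(c(fit$shrinkage$cri_low[k1], fit$shrinkage$cri_high[k1]),
               fit$predictive$cri, tolerance = 1e-3)
})

test_that("sensitivity analysis is consistent and ordered in prior width", {
  fix <- table2_fixture()$diabetes
  sa <- sensitivity_analysis(fix)
  expect_equal(nrow(sa$summary), 3)
  direct <- mu_posterior(fix)
  expect_equal(sa$fits[["half_normal(0.5)"]]$mu$median, direct$median)
  # wider heterogeneity priors admit more heterogeneity
  expect_lte(sa$summary$tau_median[sa$summary$prior == "half_normal(0.5)"],
             sa$summary$tau_median[sa$summary$prior == "half_normal(1)"])
  # single-prior call degenerates to the direct fits
  sa1 <- sensitivity_analysis(fix, priors = list(half_normal(0.5)))
  expect_equal(sa1$summary$pred_median, predictive_distribution(fix)$median)
  expect_error(sensitivity_analysis(fix, priors = list()), "non-empty")
})

test_that("operation wrappers expose the same fit", {
  e <- toy_effects(seed = 41, k = 3)
  fit <- bayes_meta(e$y, e$s)
  expect_equal(tau_marginal_posterior(e$y, e$s)$median, fit$tau$median)
  expect_equal(mu_posterior(e$y, e$s)$or_median, exp(fit$mu$median))
  expect_equal(shrinkage_intervals(e$y, e$s)$median, fit$shrinkage$median)
  expect_error(bayes_meta(numeric(0), numeric(0)), "at least")
})
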