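test_that("DL tau2 matches the moment formula and its degenerate cases", {
  # hand-rolled formula evaluation, independent of dl_tau2's code path
  e <- toy_effects(seed = 3, k = 3)
  w <- 1 / e$s^2
  q <- sum(w * (e$y - sum(w * e$y) / sum(w))^2)
  expect_equal(dl_tau2(e$y, e$s),
               max(0, (q - 2) / (sum(w) - sum(w^2) / sum(w))))

  expect_equal(dl_tau2(c(0.5, 0.5), c(0.3, 0.4)), 0)  # identical effects
  expect_equal(dl_tau2(1.2, 0.3), 0)                  # single study
  expect_error(dl_tau2(numeric(0), numeric(0)), "at least")
})

test_that("pooling agrees with an independent reference implementation", {
  skip_if_not_installed("metafor")
  sets <- c(table2_fixture(),
            list(toy = do.call(function(y, s)
              comorbidity_dataset("toy", study_effects(letters[seq_along(y)], y, s)),
              toy_effects(seed = 9, k = 6))))
  for (ds in sets) {
    fit <- dl_meta(ds)
    ref <- metafor::rma(yi = ds$studies$y, sei = ds$studies$sigma,
                        method = "DL")
    expect_equal(fit$mu_hat, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(fit$se_mu, ref$se, tolerance = 1e-10)
    expect_equal(fit$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(fit$q, ref$QE, tolerance = 1e-10)
    expect_equal(fit$p_q, ref$QEp, tolerance = 1e-10)
    # the reference profiles tau2 with a coarser convergence tolerance
    ci <- confint(ref)$random
    expect_equal(fit$tau_ci[1], ci["tau", "ci.lb"], tolerance = 1e-3)
    expect_equal(fit$tau_ci[2], ci["tau", "ci.ub"], tolerance = 1e-3)
  }
})

test_that("pooling invariants hold", {
  e <- toy_effects(seed = 21, k = 7)
  fit <- dl_meta(e$y, e$s)
  expect_equal(sum(fit$weights), 1)
  expect_equal(fit$df, 6)
  expect_gte(fit$i2, 0); expect_lte(fit$i2, 100)
  expect_gte(fit$mu_hat, min(e$y)); expect_lte(fit$mu_hat, max(e$y))

  # zero heterogeneity -> identical to fixed-effect inverse-variance pooling
  y0 <- c(0.5, 0.5, 0.5); s0 <- c(0.2, 0.5, 0.9)
  f0 <- dl_meta(y0, s0)
  expect_equal(f0$tau2, 0)
  w <- 1 / s0^2
  expect_equal(f0$mu_hat, sum(w * y0) / sum(w))
  expect_equal(f0$se_mu, sqrt(1 / sum(w)))

  # a near-uninformative study at the pooled mean gets essentially zero
  # weight; the pooled estimate moves only through the re-estimated tau2
  # (its df changes), and not at all when tau2 stays pinned at zero
  f1 <- dl_meta(c(e$y, fit$mu_hat), c(e$s, 1e4))
  expect_lt(f1$weights[length(f1$weights)], 1e-6)
  expect_lt(abs(f1$mu_hat - fit$mu_hat), 0.05)
  f0b <- dl_meta(c(y0, sum(1 / s0^2 * y0) / sum(1 / s0^2)), c(s0, 1e4))
  expect_lt(abs(f0b$mu_hat - f0$mu_hat), 1e-6)

  # Q is invariant under a common shift of all effects
  f2 <- dl_meta(e$y + 3.7, e$s)
  expect_equal(f2$q, fit$q)

  # k = 1 degeneracy
  f3 <- dl_meta(1.1, 0.4)
  expect_equal(f3$mu_hat, 1.1)
  expect_equal(f3$mu_ci, 1.1 + c(-1, 1) * qnorm(0.975) * 0.4)
  expect_equal(f3$q, 0); expect_equal(f3$i2, 0)
})

test_that("Q-profile interval for tau matches a dense grid scan", {
  e <- toy_effects(seed = 5, k = 3, tau = 0.6)
  ci <- tau_ci(e$y, e$s)
  taus <- seq(0, 15, by = 1e-3)
  qs <- vapply(taus, function(t) {
    w <- 1 / (e$s^2 + t^2)
    sum(w * (e$y - sum(w * e$y) / sum(w))^2)
  }, numeric(1))
  inside <- taus[qs >= qchisq(0.025, 2) & qs <= qchisq(0.975, 2)]
  expect_equal(ci[1], min(inside), tolerance = 2e-3)
  expect_equal(ci[2], max(inside), tolerance = 2e-3)

  # homogeneous data pin the lower bound at zero
  expect_equal(tau_ci(c(1, 1, 1), c(0.3, 0.3, 0.3))[1], 0)
  expect_error(tau_ci(1, 0.2), "at least 2")
})
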