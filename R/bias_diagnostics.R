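#' Begg-Mazumdar rank correlation test for funnel-plot asymmetry
#'
#' Standardizes each study's deviation from the fixed-effect pooled estimate
#' using the variance-stabilized variance `sigma_i^2 - 1/sum(1/sigma_j^2)`
#' and computes Kendall's tau between the standardized effects and the
#' sampling variances. The p-value is exact for `k <= 8` (and no ties) and
#' uses the normal approximation otherwise.
#'
#' @inheritParams dl_meta
#' @return List with `tau` (Kendall correlation), `p` (two-sided), `k`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
begg_rank_test <- function(x, sigma = NULL) {
  eff <- check_effects(resolve_effects(x, sigma), 3, "begg_rank_test")
  y <- eff$y; v <- eff$sigma^2
  k <- length(y)
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  vstar <- v - 1 / sum(w)
  t_i <- (y - mu_fe) / sqrt(vstar)
  ties <- anyDuplicated(t_i) > 0 || anyDuplicated(v) > 0
  exact <- k <= 8 && !ties
  ct <- suppressWarnings(cor.test(t_i, v, method = "kendall", exact = exact))
  list(tau = unname(ct$estimate), p = ct$p.value, k = k,
       method = if (exact) "exact" else "normal")
}

#' Mixed-effects regression test for funnel-plot asymmetry
#'
#' Egger-type random-effects meta-regression of the log odds ratios on a
#' precision moderator (by default the standard error), with the
#' between-study variance of the moderated model estimated by the
#' DerSimonian-Laird moment formula. The asymmetry statistic is the
#' moderator coefficient divided by its standard error, referred to a
#' standard normal.
#'
#' @inheritParams dl_meta
#' @param moderator `"se"` (classic Egger choice), `"variance"`, or
#'   `"inverse_n"` (requires `ni`).
#' @param ni per-study sample sizes when `moderator = "inverse_n"`.
#' @return List with `intercept`, `slope`, `se_slope`, `z`, `p` (two-sided)
#'   and `tau2` (moderated-model DL estimate).
#' @export
egger_regression_test <- function(x, sigma = NULL,
                                  moderator = c("se", "variance", "inverse_n"),
                                  ni = NULL) {
  moderator <- match.arg(moderator)
  eff <- check_effects(resolve_effects(x, sigma), 3, "egger_regression_test")
  y <- eff$y; s <- eff$sigma
  k <- length(y)
  mod <- switch(moderator,
                se = s,
                variance = s^2,
                inverse_n = {
                  if (is.null(ni)) stop("`ni` required for inverse_n", call. = FALSE)
                  1 / ni
                })
  if (sd(mod) < 1e-12)
    stop("moderator is constant across studies; asymmetry regression is degenerate",
         call. = FALSE)
  X <- cbind(1, mod)
  p <- ncol(X)

  # DL tau2 for the moderated model: E[Q_E] = (k - p) + tau2 * tr(P) with
  # P = W - W X (X'WX)^-1 X'W under fixed-effect weights W = diag(1/s^2)
  W <- diag(1 / s^2, k)
  XtWX_inv <- solve(t(X) %*% W %*% X)
  P <- W - W %*% X %*% XtWX_inv %*% t(X) %*% W
  q_e <- drop(t(y) %*% P %*% y)
  tau2 <- max(0, (q_e - (k - p)) / sum(diag(P)))

  Ws <- diag(1 / (s^2 + tau2), k)
  V <- solve(t(X) %*% Ws %*% X)
  beta <- drop(V %*% t(X) %*% Ws %*% y)
  se_b <- sqrt(diag(V))
  z <- unname(beta[2] / se_b[2])
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       se_slope = unname(se_b[2]), z = z, p = 2 * pnorm(-abs(z)), tau2 = tau2)
}

#' Funnel-plot data
#'
#' Per-study effect/precision pairs plus the pooled reference line, as plain
#' data ready for CSV export or plotting.
#'
#' @inheritParams dl_meta
#' @return Data frame with columns `study_label`, `log_or`, `se`,
#'   `pooled_log_or` (the DerSimonian-Laird pooled estimate, repeated).
#' @export
funnel_data <- function(x, sigma = NULL) {
  eff <- check_effects(resolve_effects(x, sigma), 1, "funnel_data")
  pooled <- dl_meta(eff$y, eff$sigma)$mu_hat
  data.frame(study_label = eff$labels, log_or = eff$y, se = eff$sigma,
             pooled_log_or = pooled, stringsAsFactors = FALSE)
}

#' Publication-bias report
#'
#' Bundles the funnel data, the Begg-Mazumdar rank correlation test and the
#' mixed-effects regression test for one dataset.
#'
#' @inheritParams egger_regression_test
#' @return An object of class `bias_report`: list with `funnel_points`,
#'   `rank_test`, `regression_test`.
#' @export
bias_report <- function(x, sigma = NULL, moderator = "se", ni = NULL) {
  eff <- check_effects(resolve_effects(x, sigma), 3, "bias_report")
  structure(list(
    funnel_points = funnel_data(eff$y, eff$sigma),
    rank_test = begg_rank_test(eff$y, eff$sigma),
    regression_test = egger_regression_test(eff$y, eff$sigma,
                                            moderator = moderator, ni = ni)
  ), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("Publication-bias diagnostics\n")
  cat(sprintf("  rank correlation: Kendall tau = %.3f, p = %.4f (%s)\n",
              x$rank_test$tau, x$rank_test$p, x$rank_test$method))
  cat(sprintf("  asymmetry regression: slope = %.3f (SE %.3f), z = %.3f, p = %.4f\n",
              x$regression_test$slope, x$regression_test$se_slope,
              x$regression_test$z, x$regression_test$p))
  invisible(x)
}
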