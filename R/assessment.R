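# Per-draw log-likelihood vector and pointwise log-density matrix, computed
# from the stored linear predictors and observation variances.
pointwise_logdens <- function(fit) {
  S <- nrow(fit$mu)
  if (S < 2L) stop("state error: need at least 2 stored draws", call. = FALSE)
  nu2 <- fit$samples$nu2
  sweep_resid2 <- (fit$mu - matrix(fit$y, S, length(fit$y), byrow = TRUE))^2
  -0.5 * log(2 * pi * nu2) - sweep_resid2 / (2 * nu2)
}

draw_logliks <- function(fit) {
  rowSums(pointwise_logdens(fit))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance
#' `mean_s(-2 loglik(theta_s))` and `pD = Dbar - D(theta_hat)`, the plug-in
#' deviance evaluated at the posterior means of the parameters entering the
#' likelihood (the per-draw linear predictor, which is linear in the
#' coefficients and effects, and `nu2`). Lower is better.
#'
#' @param fit An [st_fit] with at least 2 stored draws.
#' @return DIC (scalar) with attribute `pD`.
#' @export
dic <- function(fit) {
  ll <- draw_logliks(fit)
  dbar <- mean(-2 * ll)
  mu_hat <- colMeans(fit$mu)
  nu2_hat <- mean(fit$samples$nu2)
  dhat <- -2 * gaussian_loglik(fit$y, mu_hat, nu2_hat)
  out <- dbar + (dbar - dhat)
  attr(out, "pD") <- dbar - dhat
  out
}

#' Watanabe-Akaike information criterion
#'
#' `WAIC = -2 (lppd - pW)`: the log pointwise predictive density
#' `lppd = sum_i log mean_s f(y_i | theta_s)` penalised by
#' `pW = sum_i var_s log f(y_i | theta_s)` (sample variance, denominator
#' S-1). Lower is better.
#'
#' @inheritParams dic
#' @return WAIC (scalar) with attributes `lppd` and `pW`.
#' @export
waic <- function(fit) {
  lf <- pointwise_logdens(fit)
  S <- nrow(lf)
  lppd_i <- apply(lf, 2L, log_sum_exp) - log(S)
  pw_i <- apply(lf, 2L, stats::var)
  out <- -2 * (sum(lppd_i) - sum(pw_i))
  attr(out, "lppd") <- sum(lppd_i)
  attr(out, "pW") <- sum(pw_i)
  out
}

#' Log marginal predictive likelihood
#'
#' `LMPL = sum_i log CPO_i` with the conditional predictive ordinate
#' estimated by the harmonic mean
#' `CPO_i = 1 / mean_s(1 / f(y_i | theta_s))`. Densities are floored at the
#' smallest positive normal double; affected observations are reported in
#' the `flagged` attribute. Higher is better.
#'
#' @inheritParams dic
#' @return LMPL (scalar) with attribute `flagged` (indices of floored
#'   observations, possibly empty).
#' @export
lmpl <- function(fit) {
  lf <- pointwise_logdens(fit)
  S <- nrow(lf)
  floor_log <- log(.Machine$double.xmin)
  flagged <- which(apply(lf, 2L, min) < floor_log)
  lf[lf < floor_log] <- floor_log
  # log CPO_i = -(logsumexp(-logf_i) - log S)
  log_cpo <- -(apply(-lf, 2L, log_sum_exp) - log(S))
  out <- sum(log_cpo)
  attr(out, "flagged") <- flagged
  out
}

#' Closed-form CRPS of a Gaussian predictive distribution
#'
#' For `Y ~ N(mean, sd^2)` and outcome `y`, with `z = (y - mean)/sd`:
#' `CRPS = sd * (z * (2 * Phi(z) - 1) + 2 * phi(z) - 1/sqrt(pi))`.
#' Lower is better; 0 for a perfect point forecast.
#'
#' @param y Observed values.
#' @param mean,sd Predictive mean(s) and standard deviation(s) (`sd > 0`).
#' @return Numeric vector of CRPS values.
#' @export
crps_gaussian <- function(y, mean, sd) {
  if (any(sd <= 0)) stop("`sd` must be positive", call. = FALSE)
  z <- (y - mean) / sd
  sd * (z * (2 * stats::pnorm(z) - 1) + 2 * stats::dnorm(z) - 1 / sqrt(pi))
}

#' In-sample validation statistics
#'
#' Residuals are taken against the posterior mean fit
#' `e_i = y_i - mean_s(mu_is)`. The per-observation predictive distribution
#' is approximated as Gaussian with mean `m_i = mean_s(mu_is)` and variance
#' `var_s(mu_is) + mean_s(nu2_s)` (posterior spread of the predictive centre
#' plus observation noise in quadrature); CRPS uses the closed form and
#' coverage counts observations inside the central `level` interval of that
#' distribution.
#'
#' @param fit An [st_fit].
#' @param level Interval level for coverage (default 0.95).
#' @return List with `rmse`, `mae`, `crps`, `cvg` (coverage in percent,
#'   0--100).
#' @export
validation_stats <- function(fit, level = 0.95) {
  S <- nrow(fit$mu)
  if (S < 2L) stop("state error: need at least 2 stored draws", call. = FALSE)
  m <- colMeans(fit$mu)
  v <- apply(fit$mu, 2L, stats::var) + mean(fit$samples$nu2)
  s <- sqrt(v)
  e <- fit$y - m
  z <- stats::qnorm((1 + level) / 2)
  list(rmse = sqrt(mean(e^2)),
       mae = mean(abs(e)),
       crps = mean(crps_gaussian(fit$y, m, s)),
       cvg = 100 * mean(fit$y >= m - z * s & fit$y <= m + z * s))
}

#' Model choice and validation criteria for one fit
#'
#' One comparison-table row: DIC, WAIC, LMPL, the plug-in log-likelihood at
#' the posterior mean parameters, and the in-sample validation statistics
#' RMSE, MAE, mean Gaussian CRPS and 95% predictive coverage.
#'
#' @inheritParams validation_stats
#' @return List with `dic`, `waic`, `lmpl`, `loglikelihood`, `rmse`, `mae`,
#'   `crps`, `cvg`.
#' @export
criteria_bundle <- function(fit, level = 0.95) {
  vs <- validation_stats(fit, level)
  list(dic = as.numeric(dic(fit)),
       waic = as.numeric(waic(fit)),
       lmpl = as.numeric(lmpl(fit)),
       loglikelihood = gaussian_loglik(fit$y, colMeans(fit$mu),
                                       mean(fit$samples$nu2)),
       rmse = vs$rmse, mae = vs$mae, crps = vs$crps, cvg = vs$cvg)
}

#' Spatially aggregated residuals
#'
#' Posterior-mean residuals aggregated over the temporal domain: for each
#' area, the mean and standard deviation over years of
#' `y_dt - mean_s(mu_dt,s)` -- the per-area residual map used to check for
#' leftover spatial pattern.
#'
#' @param fit An [st_fit].
#' @return Data frame with `area`, `mean_residual`, `sd_residual` (one row
#'   per area).
#' @export
aggregate_residuals_spatial <- function(fit) {
  r <- matrix(fit$y - colMeans(fit$mu), nrow = fit$D)
  data.frame(area = fit$area_labels,
             mean_residual = rowMeans(r),
             sd_residual = apply(r, 1L, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Temporally aggregated observed and fitted series
#'
#' For each year: the mean over areas of the observed response, the mean of
#' the posterior-mean fitted values, and a pointwise credible band from the
#' posterior draws of the area-averaged fitted value -- the observed-vs-
#' fitted time-series display.
#'
#' @param fit An [st_fit].
#' @param level Band level (default 0.95).
#' @return Data frame with `year`, `observed`, `fitted`, `lower`, `upper`
#'   (one row per year).
#' @export
aggregate_fitted_temporal <- function(fit, level = 0.95) {
  D <- fit$D; T_ <- fit$n_times
  obs <- colMeans(matrix(fit$y, nrow = D))
  # S x T matrix of area-averaged fitted values per draw
  avg <- matrix(0, D * T_, T_)
  for (t in seq_len(T_)) avg[(t - 1L) * D + seq_len(D), t] <- 1 / D
  band <- fit$mu %*% avg
  a <- (1 - level) / 2
  data.frame(year = fit$years,
             observed = obs,
             fitted = colMeans(band),
             lower = apply(band, 2L, stats::quantile, probs = a, type = 7),
             upper = apply(band, 2L, stats::quantile, probs = 1 - a,
                           type = 7),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare fitted models on shared data
#'
#' Assembles the criteria of several fits of the same data into one table
#' and flags the best model per criterion: minimum for DIC, WAIC, RMSE, MAE
#' and CRPS; maximum for LMPL and log-likelihood; closest to the nominal 95
#' for coverage.
#'
#' @param fits Named list of [st_fit] objects fitted to identical data.
#' @param level Coverage level passed to [criteria_bundle()].
#' @return Data frame, one row per model, columns `model`, `dic`, `waic`,
#'   `lmpl`, `loglikelihood`, `rmse`, `mae`, `crps`, `cvg`, plus logical
#'   `best_<criterion>` flags.
#' @export
compare_models <- function(fits, level = 0.95) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1L),
                                           "st_fit")))
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- vapply(fits, function(f) f$model$family, character(1L))
  }
  y0 <- fits[[1L]]$y
  same <- vapply(fits, function(f) {
    length(f$y) == length(y0) && all(f$y == y0)
  }, logical(1L))
  if (!all(same)) {
    stop("comparison error: fits were not made on identical data",
         call. = FALSE)
  }
  rows <- lapply(fits, function(f) as.data.frame(criteria_bundle(f, level)))
  out <- cbind(data.frame(model = names(fits), stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  lower_better <- c("dic", "waic", "rmse", "mae", "crps")
  higher_better <- c("lmpl", "loglikelihood")
  for (cr in lower_better) {
    out[[paste0("best_", cr)]] <- out[[cr]] == min(out[[cr]])
  }
  for (cr in higher_better) {
    out[[paste0("best_", cr)]] <- out[[cr]] == max(out[[cr]])
  }
  out$best_cvg <- abs(out$cvg - 95) == min(abs(out$cvg - 95))
  out
}
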