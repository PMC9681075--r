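# mu values giving prescribed Gaussian densities at y = 0 with nu2 = 1
mu_for_density <- function(f) sqrt(-2 * log(f * sqrt(2 * pi)))

test_that("DIC follows D-bar plus p_D with the plug-in at posterior means", {
  # a single repeated draw: p_D = 0 and DIC = D(theta)
  y <- c(0.2, -0.1, 0.4)
  mu <- matrix(rep(c(0.1, 0, 0.3), each = 2), 2, 3)
  fit <- make_fake_fit(mu, nu2 = c(0.5, 0.5), y = y, D = 3L)
  d <- dic(fit)
  expect_equal(as.numeric(d), -2 * gaussian_loglik(y, mu[1, ], 0.5))
  expect_equal(attr(d, "pD"), 0, tolerance = 1e-12)

  # two-draw toy against hand arithmetic
  mu2 <- rbind(c(0, 0, 0), c(0.2, 0.2, 0.2))
  nu2 <- c(1, 2)
  fit2 <- make_fake_fit(mu2, nu2, y = y, D = 3L)
  dev <- c(-2 * gaussian_loglik(y, mu2[1, ], 1),
           -2 * gaussian_loglik(y, mu2[2, ], 2))
  dhat <- -2 * gaussian_loglik(y, colMeans(mu2), 1.5)
  expect_equal(as.numeric(dic(fit2)), mean(dev) + (mean(dev) - dhat),
               tolerance = 1e-12)
})

test_that("WAIC and LMPL match hand arithmetic on tiny cases", {
  # all draws identical: p_W = 0, WAIC = -2 sum log f, LMPL = sum log f
  y <- c(1, -1)
  mu <- matrix(rep(c(0.5, -0.4), each = 3), 3, 2)
  fit <- make_fake_fit(mu, nu2 = rep(0.8, 3), y = y, D = 2L)
  lf <- sum(dnorm(y, mu[1, ], sqrt(0.8), log = TRUE))
  expect_equal(as.numeric(waic(fit)), -2 * lf, tolerance = 1e-10)
  expect_equal(attr(waic(fit), "pW"), 0, tolerance = 1e-12)
  expect_equal(as.numeric(lmpl(fit)), lf, tolerance = 1e-10)

  # 2 draws, 1 observation with densities (0.1, 0.3)
  mus <- c(mu_for_density(0.1), mu_for_density(0.3))
  fit2 <- make_fake_fit(matrix(mus, 2, 1), nu2 = c(1, 1), y = 0, D = 1L)
  lppd <- log(mean(c(0.1, 0.3)))
  p_w <- var(log(c(0.1, 0.3)))
  expect_equal(as.numeric(waic(fit2)), -2 * (lppd - p_w), tolerance = 1e-8)
  # CPO = 1 / mean(1/0.1, 1/0.3) = 0.15
  expect_equal(exp(as.numeric(lmpl(fit2))), 0.15, tolerance = 1e-8)
})

test_that("LMPL never exceeds the lppd (harmonic <= arithmetic mean)", {
  set.seed(71)
  for (rep in 1:5) {
    S <- 20; n <- 6
    mu <- matrix(rnorm(S * n), S, n)
    fit <- make_fake_fit(mu, nu2 = rexp(S) + 0.2, y = rnorm(n), D = 2L)
    expect_lte(as.numeric(lmpl(fit)), attr(waic(fit), "lppd") + 1e-10)
  }
})

test_that("criteria agree with a brute-force recomputation from draws", {
  inp <- make_sim_fit_inputs(nx = 2, ny = 3, T_ = 4, seed = 77)
  fit <- run_mcmc(inp$panel, inp$lattice, inp$model, st_prior(),
                  mcmc_config(100, 400, 4, seed = 7))
  bf <- brute_force_criteria(fit$mu, fit$samples$nu2, fit$y)
  expect_equal(as.numeric(dic(fit)), bf$dic, tolerance = 1e-8)
  expect_equal(as.numeric(waic(fit)), bf$waic, tolerance = 1e-8)
  expect_equal(as.numeric(lmpl(fit)), bf$lmpl, tolerance = 1e-8)
})

test_that("Gaussian CRPS closed form is correct", {
  expect_equal(crps_gaussian(0, 0, 1), 2 * dnorm(0) - 1 / sqrt(pi),
               tolerance = 1e-12)
  # scale equivariance and positivity: crps(y, mu, s) = s * crps(z, 0, 1)
  expect_equal(crps_gaussian(1.4, 0.2, 3),
               3 * crps_gaussian((1.4 - 0.2) / 3, 0, 1), tolerance = 1e-12)
  expect_true(all(crps_gaussian(c(-2, 0, 2), 0, 1) > 0))
  expect_error(crps_gaussian(0, 0, 0), "positive")
})

test_that("validation statistics behave at the perfect-fit limit", {
  y <- c(1, 2, 3, 4)
  mu <- matrix(rep(y, each = 3), 3, 4)
  fit <- make_fake_fit(mu, nu2 = rep(1e-12, 3), y = y, D = 2L)
  vs <- validation_stats(fit)
  expect_equal(vs$rmse, 0)
  expect_equal(vs$mae, 0)
  expect_equal(vs$cvg, 100)
  # rmse >= mae in general
  set.seed(81)
  mu2 <- matrix(rnorm(60), 10, 6)
  fit2 <- make_fake_fit(mu2, nu2 = rep(0.5, 10), y = rnorm(6), D = 3L)
  vs2 <- validation_stats(fit2)
  expect_gte(vs2$rmse, vs2$mae)
  expect_true(vs2$cvg >= 0 && vs2$cvg <= 100)
})

test_that("spatial residual aggregation matches hand arithmetic", {
  # 2 areas x 3 years with known residuals
  y <- c(1, 2, 3, 4, 5, 6) # canonical order: areas within years
  fitted <- c(0, 0, 1, 1, 2, 2)
  mu <- rbind(fitted, fitted)
  fit <- make_fake_fit(mu, nu2 = c(1, 1), y = y, D = 2L)
  agg <- aggregate_residuals_spatial(fit)
  expect_equal(nrow(agg), 2L)
  # area 1 residuals: 1, 2, 3; area 2: 2, 3, 4
  expect_equal(agg$mean_residual, c(2, 3))
  expect_equal(agg$sd_residual, c(1, 1))

  # constant residuals give zero SD
  fitc <- make_fake_fit(rbind(y - 0.5, y - 0.5), nu2 = c(1, 1), y = y,
                        D = 2L)
  aggc <- aggregate_residuals_spatial(fitc)
  expect_equal(aggc$sd_residual, c(0, 0))
})

test_that("temporal aggregation returns one bracketed row per year", {
  y <- c(1, 2, 3, 4, 5, 6)
  mu <- rbind(y, y) # perfect deterministic fit
  fit <- make_fake_fit(mu, nu2 = c(1e-12, 1e-12), y = y, D = 2L,
                       years = 2004:2006)
  agg <- aggregate_fitted_temporal(fit)
  expect_equal(nrow(agg), 3L)
  expect_equal(agg$observed, c(1.5, 3.5, 5.5))
  expect_equal(agg$fitted, agg$observed)
  expect_equal(agg$upper - agg$lower, rep(0, 3))

  # with posterior spread the band brackets the fitted mean
  inp <- make_sim_fit_inputs(nx = 2, ny = 2, T_ = 5, seed = 83)
  fit2 <- run_mcmc(inp$panel, inp$lattice, inp$model, st_prior(),
                   mcmc_config(100, 400, 4, seed = 3))
  agg2 <- aggregate_fitted_temporal(fit2)
  expect_equal(nrow(agg2), 5L)
  expect_true(all(agg2$lower <= agg2$fitted & agg2$fitted <= agg2$upper))
})

test_that("compare_models builds the criteria table with best flags", {
  inp <- make_sim_fit_inputs(nx = 2, ny = 3, T_ = 4, seed = 85)
  cfg <- function(s) mcmc_config(100, 400, 4, seed = s)
  fits <- list(
    glm = run_mcmc(inp$panel, inp$lattice,
                   st_model("independent_glm", five_covariates),
                   st_prior(), cfg(1)),
    anova = run_mcmc(inp$panel, inp$lattice,
                     st_model("st_anova", five_covariates),
                     st_prior(), cfg(2)),
    linear = run_mcmc(inp$panel, inp$lattice,
                      st_model("st_linear", five_covariates),
                      st_prior(), cfg(3)),
    ar = run_mcmc(inp$panel, inp$lattice,
                  st_model("st_ar", five_covariates),
                  st_prior(), cfg(4)))
  tab <- compare_models(fits)
  expect_equal(nrow(tab), 4L)
  expect_true(all(c("dic", "waic", "lmpl", "loglikelihood", "rmse", "mae",
                    "crps", "cvg") %in% names(tab)))
  # best flags agree with an independent scan
  expect_equal(which(tab$best_dic), which.min(tab$dic))
  expect_equal(which(tab$best_lmpl), which.max(tab$lmpl))
  expect_equal(which(tab$best_cvg),
               which(abs(tab$cvg - 95) == min(abs(tab$cvg - 95))))

  # a single model is trivially best everywhere
  tab1 <- compare_models(fits["glm"])
  expect_true(all(unlist(tab1[grep("^best_", names(tab1))])))

  # mismatched data is a comparison error
  other <- make_sim_fit_inputs(nx = 2, ny = 3, T_ = 4, seed = 86)
  f_other <- run_mcmc(other$panel, other$lattice,
                      st_model("independent_glm", five_covariates),
                      st_prior(), cfg(5))
  expect_error(compare_models(list(a = fits$glm, b = f_other)),
               "comparison error")
})
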