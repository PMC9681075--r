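# Independent oracles: dense multivariate-normal algebra, closed-form
# conjugate posteriors, Monte-Carlo scoring. These never call the code
# paths they check.

# Dense MVN log-density via determinant and solve (no eigenvalue trick).
dense_mvn_logdensity <- function(u, Sigma) {
  n <- length(u)
  -0.5 * n * log(2 * pi) - 0.5 * determinant(Sigma, logarithm = TRUE)$modulus -
    0.5 * drop(u %*% solve(Sigma, u))
}

# Conditional moments of u | y for the linear-Gaussian model
#   u ~ N(0, Sigma_u),  y = m0 + A u + N(0, V)   (V a covariance matrix)
# via the covariance-partition formulas.
dense_conditional_moments <- function(Sigma_u, A, m0, V, y) {
  S_uy <- Sigma_u %*% t(A)
  S_yy <- A %*% Sigma_u %*% t(A) + V
  K <- S_uy %*% solve(S_yy)
  list(mean = drop(K %*% (y - m0)),
       cov = Sigma_u - K %*% t(S_uy))
}

# Moments of a Gaussian full conditional given in canonical (prec, b) form.
canonical_moments <- function(fc) {
  list(mean = drop(solve(fc$prec, fc$b)), cov = solve(fc$prec))
}

# Closed-form normal--inverse-gamma posterior for the Gaussian linear model
# with flat beta prior: beta | y ~ (mean = OLS), nu2 marginal
# IG(a + (n-p)/2, b + RSS/2).
nig_posterior <- function(X, y, a, b) {
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  n <- length(y); p <- ncol(X)
  a_post <- a + (n - p) / 2
  b_post <- b + rss / 2
  list(beta_mean = fit$coefficients,
       nu2_mean = b_post / (a_post - 1),
       # posterior covariance of beta: E[nu2] * (X'X)^{-1} (approximation
       # used only to scale tolerances)
       beta_cov = (b_post / (a_post - 1)) * solve(crossprod(X)))
}

# Monte-Carlo CRPS for a N(mean, sd^2) forecast: E|X - y| - 0.5 E|X - X'|.
mc_crps_gaussian <- function(y, mean, sd, n = 1e6, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n, mean, sd)
  x2 <- rnorm(n, mean, sd)
  mean(abs(x1 - y)) - 0.5 * mean(abs(x1 - x2))
}

# Brute-force recomputation of DIC / WAIC / LMPL from "persisted" draws:
# takes plain matrices (mu draws, nu2 draws) as an independent script would
# read them back from disk, and loops observation by observation.
brute_force_criteria <- function(mu, nu2, y) {
  S <- nrow(mu); n <- length(y)
  logf <- matrix(NA_real_, S, n)
  for (s in seq_len(S)) {
    for (i in seq_len(n)) {
      logf[s, i] <- dnorm(y[i], mu[s, i], sqrt(nu2[s]), log = TRUE)
    }
  }
  dev <- -2 * rowSums(logf)
  mu_hat <- colMeans(mu)
  nu2_hat <- mean(nu2)
  d_hat <- -2 * sum(dnorm(y, mu_hat, sqrt(nu2_hat), log = TRUE))
  dic <- mean(dev) + (mean(dev) - d_hat)
  lppd <- sum(log(colMeans(exp(logf))))
  p_w <- sum(apply(logf, 2, var))
  waic <- -2 * (lppd - p_w)
  cpo <- 1 / colMeans(exp(-logf))
  list(dic = dic, waic = waic, lmpl = sum(log(cpo)), lppd = lppd)
}

# Monte-Carlo standard error of a posterior mean, autocorrelation-adjusted.
mcse <- function(x) sd(x) / sqrt(ess(x))
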