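test_that("linear predictor reduces to X beta with null effects", {
  D <- 2L; T_ <- 3L
  X <- cbind(1, seq_len(D * T_))
  beta <- c(0.5, -1)
  for (fam in c("independent_glm", "st_anova", "st_linear", "st_ar")) {
    state <- list(beta = beta, nu2 = 1)
    if (fam == "st_anova") {
      state$phi <- numeric(D); state$delta <- numeric(T_)
    }
    if (fam == "st_linear") {
      state$phi <- numeric(D); state$delta <- numeric(D); state$alpha <- 0
    }
    if (fam == "st_ar") state$phi <- matrix(0, D, T_)
    mu <- linear_predictor(state, st_model(fam), X, D, T_)
    expect_equal(mu, drop(X %*% beta))
  }
})

test_that("st_anova and st_linear predictors follow their displays", {
  D <- 2L; T_ <- 3L
  X <- matrix(1, D * T_, 1)
  st <- list(beta = 0, phi = rep(1, D), delta = rep(2, T_))
  expect_equal(linear_predictor(st, st_model("st_anova"), X, D, T_),
               rep(3, 6))

  # (alpha + delta_d) * (t - tbar)/T with tbar = (T+1)/2
  st <- list(beta = 0, phi = c(0, 0), alpha = 1, delta = c(0, 1))
  mu <- linear_predictor(st, st_model("st_linear"), X, D, T_)
  expect_equal(mu[(3 - 1) * D + 2], (1 + 1) * (3 - 2) / 3)
  expect_equal(mu[(1 - 1) * D + 1], (1 + 0) * (1 - 2) / 3)

  expect_error(linear_predictor(list(beta = c(1, 2)), st_model("st_ar"),
                                X, D, T_),
               "state error")
})

test_that("gaussian_loglik matches closed forms and a naive oracle", {
  expect_equal(gaussian_loglik(1, 1, 1), -0.5 * log(2 * pi))
  n <- 7
  y <- rep(2, n)
  expect_equal(gaussian_loglik(y, y, 2) - gaussian_loglik(y, y, 1),
               -0.5 * n * log(2))
  set.seed(3)
  y <- rnorm(11); mu <- rnorm(11); nu2 <- 0.7
  expect_equal(gaussian_loglik(y, mu, nu2),
               sum(dnorm(y, mu, sqrt(nu2), log = TRUE)), tolerance = 1e-12)
  expect_error(gaussian_loglik(y, mu, 0), "positive")
})

test_that("beta full conditional matches conjugacy algebra and OLS limit", {
  set.seed(8)
  X <- cbind(1, rnorm(30), rnorm(30))
  y <- drop(X %*% c(1, 2, -1)) + rnorm(30)
  # vague-prior limit: conditional mean -> OLS
  fc <- carpanel:::fc_beta(crossprod(X), crossprod(X, y), nu2 = 1.3,
                           beta_var = 1e12)
  expect_equal(drop(solve(fc$prec, fc$b)),
               unname(lm.fit(X, y)$coefficients), tolerance = 1e-6)
  # scalar case: n = 1, X = 1, y = 5, nu2 = 1, prior var 1e5
  fc1 <- carpanel:::fc_beta(matrix(1), 5, 1, 1e5)
  expect_equal(drop(solve(fc1$prec, fc1$b)), 5 * (1e5 / (1e5 + 1)))
})

test_that("canonical Gaussian draws have the right mean", {
  prec <- rbind(c(2, 0.5), c(0.5, 1))
  b <- c(1, -2)
  m <- solve(prec, b)
  Sg <- solve(prec)
  set.seed(12)
  draws <- replicate(20000, carpanel:::draw_mvn_canonical(prec, b))
  for (j in 1:2) {
    se <- sqrt(Sg[j, j] / 20000)
    expect_lt(abs(mean(draws[j, ]) - m[j]), 3.5 * se)
  }
  expect_equal(unname(cov(t(draws))), Sg, tolerance = 0.05)
})

test_that("variance update draws from the conjugate inverse-gamma", {
  prior <- st_prior(ig_shape = 1, ig_scale = 0.01)
  set.seed(5)
  d0 <- replicate(20000, update_variance(0, 0, prior))
  expect_true(all(d0 > 0))
  # prior IG(1, 0.01) has median 0.01 / qgamma(0.5, 1)
  expect_equal(median(d0), 0.01 / qgamma(0.5, 1), tolerance = 0.05)

  # count = 4, sum_sq = 2 -> IG(3, 1.01), mean 1.01/2
  prior2 <- st_prior(ig_shape = 1, ig_scale = 0.01)
  d1 <- replicate(100000, update_variance(2, 4, prior2))
  se <- sqrt(1.01^2 / (2^2 * 1) / length(d1)) # var = b^2/((a-1)^2 (a-2))
  expect_lt(abs(mean(d1) - 1.01 / 2), 3 * se)
  expect_error(update_variance(-1, 2, prior), "non-negative")
})

test_that("rho Metropolis chain matches a fine-grid numerical posterior", {
  two <- st_lattice(2, rbind(c(1, 2)))
  eigv <- carpanel:::lattice_eigenvalues(two)
  u <- c(0.8, -0.3); tau2 <- 0.5
  lt <- carpanel:::rho_log_target(eigv, carpanel:::edge_diff_ss(u, two),
                                  sum(u^2), tau2)
  # grid oracle
  g <- seq(0.0005, 0.9995, length.out = 2000)
  w <- exp(vapply(g, lt, numeric(1)))
  w <- w / sum(w)
  grid_mean <- sum(g * w)
  # chain
  set.seed(31)
  rho <- 0.5
  chain <- numeric(30000)
  for (i in seq_along(chain)) {
    rho <- carpanel:::update_rho(rho, 0.3, lt)$rho
    chain[i] <- rho
  }
  expect_true(all(chain > 0 & chain < 1))
  expect_lt(abs(mean(chain) - grid_mean), 3 * mcse(chain) + 0.003)
  # central mass agrees too
  expect_lt(abs(mean(chain < 0.5) - sum(w[g < 0.5])), 0.02)
})

# ---- dense-Gaussian conditioning oracles for every full conditional ----

test_that("st_anova full conditionals match dense conditioning (D*T <= 12)", {
  lat <- grid_lattice(2, 2) # D = 4
  D <- 4L; T_ <- 3L; n <- D * T_
  M <- carpanel:::lattice_structure_matrix(lat)
  set.seed(19)
  X <- cbind(1, rnorm(n))
  beta <- c(0.3, 1.2); nu2 <- 0.8
  delta <- c(-0.2, 0.1, 0.4)
  phi_cur <- c(0.5, -0.5, 0.2, -0.2)
  y <- rnorm(n, 2)
  A_phi <- do.call(rbind, replicate(T_, diag(D), simplify = FALSE))
  A_del <- kronecker(diag(T_), matrix(1, D, 1))

  # phi | rest
  rho <- 0.6; tau2 <- 0.5
  m0 <- drop(X %*% beta) + drop(A_del %*% delta)
  got <- canonical_moments(carpanel:::fc_car_main(
    matrix(y - m0, nrow = D), nu2, M, rho, tau2))
  Q <- rho * M + (1 - rho) * diag(D)
  want <- dense_conditional_moments(tau2 * solve(Q), A_phi, m0,
                                    nu2 * diag(n), y)
  expect_equal(got$mean, want$mean, tolerance = 1e-8)
  expect_equal(got$cov, want$cov, tolerance = 1e-8, ignore_attr = TRUE)

  # delta | rest
  M_T <- carpanel:::lattice_structure_matrix(path_lattice(T_))
  rho_t <- 0.3; tau2_t <- 0.7
  m0 <- drop(X %*% beta) + drop(A_phi %*% phi_cur)
  got <- canonical_moments(carpanel:::fc_car_temporal(
    matrix(y - m0, nrow = D), nu2, M_T, rho_t, tau2_t))
  Q_T <- rho_t * M_T + (1 - rho_t) * diag(T_)
  want <- dense_conditional_moments(tau2_t * solve(Q_T), A_del, m0,
                                    nu2 * diag(n), y)
  expect_equal(got$mean, want$mean, tolerance = 1e-8)
  expect_equal(got$cov, want$cov, tolerance = 1e-8, ignore_attr = TRUE)

  # beta | rest (prior N(0, beta_var I))
  beta_var <- 10
  psi <- drop(A_phi %*% phi_cur) + drop(A_del %*% delta)
  got <- canonical_moments(carpanel:::fc_beta(
    crossprod(X), crossprod(X, y - psi), nu2, beta_var))
  got$mean <- unname(got$mean)
  want <- dense_conditional_moments(beta_var * diag(2), X, psi,
                                    nu2 * diag(n), y)
  expect_equal(got$mean, want$mean, tolerance = 1e-8)
  expect_equal(got$cov, want$cov, tolerance = 1e-8, ignore_attr = TRUE)

  # gamma | rest (iid interaction)
  tau2_I <- 0.4
  m0 <- drop(X %*% beta) + psi
  got <- canonical_moments(carpanel:::fc_gamma(y - m0, nu2, tau2_I))
  want <- dense_conditional_moments(tau2_I * diag(n), diag(n), m0,
                                    nu2 * diag(n), y)
  expect_equal(got$mean, want$mean, tolerance = 1e-8)
  expect_equal(got$cov, want$cov, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("st_linear full conditionals match dense conditioning", {
  lat <- grid_lattice(2, 2)
  D <- 4L; T_ <- 3L; n <- D * T_
  M <- carpanel:::lattice_structure_matrix(lat)
  cvec <- carpanel:::trend_covariate(T_)
  crep <- rep(cvec, each = D)
  set.seed(23)
  X <- cbind(1, rnorm(n))
  beta <- c(-0.5, 0.8); nu2 <- 0.6; alpha <- 0.9
  phi_cur <- c(0.3, -0.3, 0.1, -0.1)
  delta_cur <- c(-0.4, 0.2, 0.1, 0.1)
  y <- rnorm(n)
  A_phi <- do.call(rbind, replicate(T_, diag(D), simplify = FALSE))
  A_slo <- kronecker(matrix(cvec, ncol = 1), diag(D))

  # phi (intercept effects)
  rho <- 0.4; tau2 <- 0.5
  m0 <- drop(X %*% beta) + drop(A_slo %*% (alpha + delta_cur))
  got <- canonical_moments(carpanel:::fc_car_main(
    matrix(y - m0, nrow = D), nu2, M, rho, tau2))
  Q <- rho * M + (1 - rho) * diag(D)
  want <- dense_conditional_moments(tau2 * solve(Q), A_phi, m0,
                                    nu2 * diag(n), y)
  expect_equal(got$mean, want$mean, tolerance = 1e-8)
  expect_equal(got$cov, want$cov, tolerance = 1e-8, ignore_attr = TRUE)

  # delta (slope effects)
  rho_s <- 0.7; tau2_s <- 0.3
  m0 <- drop(X %*% beta) + drop(A_phi %*% phi_cur) + alpha * crep
  got <- canonical_moments(carpanel:::fc_car_slope(
    matrix(y - m0, nrow = D), cvec, nu2, M, rho_s, tau2_s))
  Qs <- rho_s * M + (1 - rho_s) * diag(D)
  want <- dense_conditional_moments(tau2_s * solve(Qs), A_slo, m0,
                                    nu2 * diag(n), y)
  expect_equal(got$mean, want$mean, tolerance = 1e-8)
  expect_equal(got$cov, want$cov, tolerance = 1e-8, ignore_attr = TRUE)

  # alpha (overall slope, N(0, beta_var))
  beta_var <- 100
  m0 <- drop(X %*% beta) + drop(A_phi %*% phi_cur) +
    drop(A_slo %*% delta_cur)
  got <- canonical_moments(carpanel:::fc_alpha(
    matrix(y - m0, nrow = D), cvec, nu2, beta_var))
  want <- dense_conditional_moments(beta_var * diag(1),
                                    matrix(crep, ncol = 1), m0,
                                    nu2 * diag(n), y)
  expect_equal(drop(got$mean), want$mean, tolerance = 1e-8)
  expect_equal(drop(got$cov), drop(want$cov), tolerance = 1e-8)
})

test_that("st_ar slice conditionals match dense joint conditioning", {
  lat <- grid_lattice(2, 1) # D = 2
  D <- 2L; T_ <- 3L; n <- D * T_
  M <- carpanel:::lattice_structure_matrix(lat)
  rho_S <- 0.5; rho_T <- 0.6; tau2_T <- 0.4; nu2 <- 0.7
  Q <- rho_S * M + (1 - rho_S) * diag(D)
  K <- Q / tau2_T
  # dense joint precision of vec(phi) under the AR(1)-in-time chain
  P <- matrix(0, n, n)
  blk <- function(t) (t - 1L) * D + seq_len(D)
  for (t in seq_len(T_)) {
    P[blk(t), blk(t)] <- if (t < T_) (1 + rho_T^2) * K else K
    if (t > 1L) {
      P[blk(t), blk(t - 1L)] <- -rho_T * K
      P[blk(t - 1L), blk(t)] <- -rho_T * K
    }
  }
  set.seed(29)
  X <- matrix(1, n, 1)
  beta <- 0.4
  y <- rnorm(n)
  phi_cur <- matrix(rnorm(n, 0, 0.5), D, T_)
  m0 <- drop(X %*% beta)
  # joint conditional of vec(phi) | y, then one slice given the others
  joint <- dense_conditional_moments(solve(P), diag(n), m0,
                                     nu2 * diag(n), y)
  part_mat <- matrix(y - m0, nrow = D)
  for (t in c(1L, 2L, T_)) {
    idx <- blk(t); rest <- setdiff(seq_len(n), idx)
    Scc <- joint$cov[idx, idx]; Scr <- joint$cov[idx, rest]
    Srr <- joint$cov[rest, rest]
    want_mean <- joint$mean[idx] +
      drop(Scr %*% solve(Srr, as.vector(phi_cur)[rest] - joint$mean[rest]))
    want_cov <- Scc - Scr %*% solve(Srr, t(Scr))
    got <- canonical_moments(carpanel:::fc_ar_slice(
      t, part_mat, phi_cur, Q, nu2, tau2_T, rho_T))
    expect_equal(got$mean, want_mean, tolerance = 1e-8)
    expect_equal(got$cov, want_cov, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("AR slices decouple at rho_T = 0 and vanish as tau2 -> 0", {
  lat <- grid_lattice(2, 2)
  D <- 4L; T_ <- 2L
  M <- carpanel:::lattice_structure_matrix(lat)
  Q <- 0.5 * M + 0.5 * diag(D)
  set.seed(33)
  part <- matrix(rnorm(D * T_), D, T_)
  phi <- matrix(rnorm(D * T_), D, T_)
  # rho_T = 0: slice t = T equals an independent single-slice CAR conditional
  got <- carpanel:::fc_ar_slice(T_, part, phi, Q, nu2 = 0.8,
                                tau2_T = 0.3, rho_T = 0)
  ind <- carpanel:::fc_car_main(part[, T_, drop = FALSE], 0.8, M, 0.5, 0.3)
  expect_equal(got$prec, ind$prec, tolerance = 1e-12)
  expect_equal(got$b, ind$b, tolerance = 1e-12)

  # tau2 -> 0: the prior pins the slice at zero
  got0 <- carpanel:::fc_ar_slice(1L, part, phi * 0, Q, nu2 = 0.8,
                                 tau2_T = 1e-12, rho_T = 0.5)
  set.seed(34)
  draw <- carpanel:::draw_mvn_canonical(got0$prec, got0$b)
  expect_lt(max(abs(draw)), 1e-4)
})

test_that("re-centring transfer leaves the linear predictor unchanged", {
  D <- 3L; T_ <- 4L
  set.seed(40)
  X <- cbind(1, rnorm(D * T_))
  st <- list(beta = c(1, 2), phi = rnorm(D), delta = rnorm(T_), nu2 = 1)
  mod <- st_model("st_anova")
  mu1 <- linear_predictor(st, mod, X, D, T_)
  m <- mean(st$phi)
  st$phi <- st$phi - m; st$beta[1] <- st$beta[1] + m
  m2 <- mean(st$delta)
  st$delta <- st$delta - m2; st$beta[1] <- st$beta[1] + m2
  expect_equal(linear_predictor(st, mod, X, D, T_), mu1, tolerance = 1e-10)

  # st_linear: slope-block mean moves into alpha
  stl <- list(beta = c(0.5, -1), phi = rnorm(D), delta = rnorm(D),
              alpha = 0.7)
  modl <- st_model("st_linear")
  mu1 <- linear_predictor(stl, modl, X, D, T_)
  m <- mean(stl$delta)
  stl$delta <- stl$delta - m; stl$alpha <- stl$alpha + m
  expect_equal(linear_predictor(stl, modl, X, D, T_), mu1,
               tolerance = 1e-10)
})
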