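#' Model specification
#'
#' Chooses one of the four Gaussian model families for the linear predictor
#' `mu_dt = x_dt' beta + psi_dt`:
#'
#' * `independent_glm` — `psi = 0` (no structured effects);
#' * `st_anova` — `psi_dt = phi_d + delta_t (+ gamma_dt)`: a spatial CAR main
#'   effect, a temporal CAR main effect on the path graph, and an optional
#'   iid interaction (off by default);
#' * `st_linear` — `psi_dt = phi_d + (alpha + delta_d) * (t - tbar) / T`:
#'   CAR-distributed area intercepts and area slopes around an overall linear
#'   time trend `alpha`, with `tbar = (T + 1) / 2` on the index scale;
#' * `st_ar` — `psi_dt = phi_dt`, a first-order autoregressive chain of
#'   spatial CAR fields: `phi_1 ~ N(0, tau2_T Q(rho_S)^{-1})`,
#'   `phi_t | phi_{t-1} ~ N(rho_T phi_{t-1}, tau2_T Q(rho_S)^{-1})`.
#'
#' @param family One of `"independent_glm"`, `"st_linear"`, `"st_anova"`,
#'   `"st_ar"`.
#' @param covariates Ordered character vector of covariate names entering
#'   the fixed-effects design (an intercept is always included).
#' @param interaction Logical; `st_anova` only. Adds iid
#'   `gamma_dt ~ N(0, tau2_I)` interaction effects.
#' @return Object of class `st_model`.
#' @export
st_model <- function(family = c("independent_glm", "st_linear", "st_anova",
                                "st_ar"),
                     covariates = character(),
                     interaction = FALSE) {
  family <- match.arg(family)
  if (interaction && family != "st_anova") {
    stop("`interaction` is only meaningful for the st_anova family",
         call. = FALSE)
  }
  structure(list(family = family, covariates = as.character(covariates),
                 interaction = isTRUE(interaction)),
            class = "st_model")
}

#' Prior specification
#'
#' Independent `N(0, beta_var)` priors on each regression coefficient (and
#' on the overall slope `alpha` of the st_linear family), a common
#' `InverseGamma(ig_shape, ig_scale)` prior on every variance parameter
#' (`nu2`, `tau2_S`, `tau2_T`, `tau2_int`, `tau2_slo`, `tau2_I`), and
#' `Uniform(0, 1)` priors on every CAR dependence parameter `rho`.
#'
#' @param beta_var Prior variance of each coefficient (default 100000).
#' @param ig_shape,ig_scale Inverse-gamma shape and scale (defaults 1 and
#'   0.01).
#' @return Object of class `st_prior`.
#' @export
st_prior <- function(beta_var = 1e5, ig_shape = 1, ig_scale = 0.01) {
  if (beta_var <= 0 || ig_shape <= 0 || ig_scale <= 0) {
    stop("prior hyperparameters must be positive", call. = FALSE)
  }
  structure(list(beta_var = beta_var, ig_shape = ig_shape,
                 ig_scale = ig_scale),
            class = "st_prior")
}

# Centred time covariate for the st_linear trend: (t - tbar) / T with
# t = 1..T and tbar = (T + 1) / 2.
trend_covariate <- function(n_times) {
  t <- seq_len(n_times)
  (t - (n_times + 1) / 2) / n_times
}

#' Linear predictor mu = X beta + psi
#'
#' Evaluates the family-specific structured effects `psi` and adds the fixed
#' part, in the canonical flattened order (`(t - 1) * D + d`).
#'
#' @param state Parameter state list: always `beta`; family blocks as
#'   produced by the sampler (`phi`, `delta`, `gamma`, `alpha`, ...). For
#'   `st_ar`, `phi` is a `D x T` matrix.
#' @param model An [st_model].
#' @param X Design matrix (n x p, intercept first).
#' @param D,n_times Panel dimensions.
#' @return Numeric vector of length `D * n_times`.
#' @export
linear_predictor <- function(state, model, X, D, n_times) {
  if (length(state$beta) != ncol(X)) {
    stop("state error: beta has length ", length(state$beta),
         " but design has ", ncol(X), " columns", call. = FALSE)
  }
  mu <- drop(X %*% state$beta)
  psi <- switch(model$family,
    independent_glm = 0,
    st_anova = {
      stopifnot(length(state$phi) == D, length(state$delta) == n_times)
      p <- rep(state$phi, times = n_times) + rep(state$delta, each = D)
      if (!is.null(state$gamma)) p <- p + as.vector(state$gamma)
      p
    },
    st_linear = {
      stopifnot(length(state$phi) == D, length(state$delta) == D)
      cvec <- trend_covariate(n_times)
      rep(state$phi, times = n_times) +
        rep(state$alpha + state$delta, times = n_times) *
          rep(cvec, each = D)
    },
    st_ar = {
      stopifnot(length(state$phi) == D * n_times)
      as.vector(state$phi)
    }
  )
  mu + psi
}

#' Gaussian log-likelihood
#'
#' Homoscedastic Gaussian observation model:
#' `sum_dt log N(y_dt | mu_dt, nu2)`.
#'
#' @param y,mu Equal-length numeric vectors.
#' @param nu2 Observation variance (> 0).
#' @return Scalar log-likelihood.
#' @export
gaussian_loglik <- function(y, mu, nu2) {
  if (nu2 <= 0) stop("`nu2` must be positive", call. = FALSE)
  if (length(y) != length(mu)) stop("length mismatch", call. = FALSE)
  n <- length(y)
  -0.5 * n * log(2 * pi * nu2) - sum((y - mu)^2) / (2 * nu2)
}

# ---------------------------------------------------------------------------
# Full-conditional (precision, linear-term) builders. Each returns
# list(prec, b) such that the conditional is N(prec^{-1} b, prec^{-1}).
# The MCMC sweeps draw from these; oracle tests condition the dense joint
# Gaussian instead and compare moments.
# ---------------------------------------------------------------------------

# beta | rest: prec = X'X / nu2 + I / beta_var, b = X'(y - psi) / nu2
fc_beta <- function(XtX, Xt_resid, nu2, beta_var) {
  p <- nrow(XtX)
  list(prec = XtX / nu2 + diag(1 / beta_var, p), b = Xt_resid / nu2)
}

# Spatial main effect (st_anova phi; st_linear phi). partial: D x T matrix of
# y - (everything except this block), canonical reshape matrix(r, nrow = D).
fc_car_main <- function(partial_mat, nu2, M, rho, tau2) {
  D <- nrow(partial_mat); T_ <- ncol(partial_mat)
  Q <- rho * M + (1 - rho) * diag(D)
  list(prec = diag(T_ / nu2, D) + Q / tau2,
       b = rowSums(partial_mat) / nu2)
}

# Temporal main effect (st_anova delta): transpose roles of D and T.
fc_car_temporal <- function(partial_mat, nu2, M_T, rho, tau2) {
  D <- nrow(partial_mat); T_ <- ncol(partial_mat)
  Q <- rho * M_T + (1 - rho) * diag(T_)
  list(prec = diag(D / nu2, T_) + Q / tau2,
       b = colSums(partial_mat) / nu2)
}

# st_linear slope effects delta_d multiplying the trend covariate c_t.
fc_car_slope <- function(partial_mat, cvec, nu2, M, rho, tau2) {
  D <- nrow(partial_mat)
  Q <- rho * M + (1 - rho) * diag(D)
  list(prec = diag(sum(cvec^2) / nu2, D) + Q / tau2,
       b = drop(partial_mat %*% cvec) / nu2)
}

# st_linear overall slope alpha (scalar, N(0, beta_var) prior).
fc_alpha <- function(partial_mat, cvec, nu2, beta_var) {
  D <- nrow(partial_mat)
  list(prec = matrix(D * sum(cvec^2) / nu2 + 1 / beta_var, 1, 1),
       b = sum(drop(partial_mat %*% cvec)) / nu2)
}

# iid interaction gamma (st_anova): diagonal conditional, returned dense for
# interface uniformity with small fixtures; the sweep uses the scalar form.
fc_gamma <- function(partial_vec, nu2, tau2_I) {
  n <- length(partial_vec)
  list(prec = diag(1 / nu2 + 1 / tau2_I, n), b = partial_vec / nu2)
}

# st_ar time-slice phi_t | phi_{-t}, y_t. phi is D x T; Q is the unit-scale
# Leroux precision of the spatial lattice.
fc_ar_slice <- function(t, partial_mat, phi, Q, nu2, tau2_T, rho_T) {
  D <- nrow(phi); T_ <- ncol(phi)
  K <- Q / tau2_T
  if (t < T_) {
    prec <- diag(1 / nu2, D) + (1 + rho_T^2) * K
  } else {
    prec <- diag(1 / nu2, D) + K
  }
  nb <- numeric(D)
  if (t > 1L) nb <- nb + rho_T * phi[, t - 1L]
  if (t < T_) nb <- nb + rho_T * phi[, t + 1L]
  list(prec = prec, b = partial_mat[, t] / nu2 + drop(K %*% nb))
}

# Exact draw from N(prec^{-1} b, prec^{-1}) via Cholesky of the precision.
draw_mvn_canonical <- function(prec, b) {
  prec <- (prec + t(prec)) / 2
  R <- chol(prec)
  m <- backsolve(R, backsolve(R, b, transpose = TRUE))
  m + backsolve(R, stats::rnorm(length(b)))
}

#' Conjugate inverse-gamma variance draw
#'
#' Draws from `InverseGamma(a + count/2, b + sum_sq/2)`, the full
#' conditional of any variance parameter whose associated quadratic form is
#' `sum_sq` over `count` effective terms (for CAR blocks,
#' `sum_sq = u' Q(rho) u`).
#'
#' @param sum_sq Quadratic form (>= 0).
#' @param count Number of terms (>= 0).
#' @param prior An [st_prior] supplying `ig_shape` and `ig_scale`.
#' @return A single positive draw.
#' @export
update_variance <- function(sum_sq, count, prior) {
  if (sum_sq < 0 || count < 0) {
    stop("`sum_sq` and `count` must be non-negative", call. = FALSE)
  }
  1 / stats::rgamma(1L, shape = prior$ig_shape + count / 2,
                    rate = prior$ig_scale + sum_sq / 2)
}

# Reflect a real proposal into (0, 1) (preserves proposal symmetry).
reflect01 <- function(x) {
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

# Random-walk Metropolis step for a CAR dependence parameter rho under a
# Uniform(0,1) prior. `log_target` must include the 0.5*k*logdet term and
# the quadratic form. Returns list(rho, accepted).
update_rho <- function(rho, scale, log_target) {
  prop <- reflect01(rho + stats::rnorm(1L, 0, scale))
  # keep strictly inside (0,1): the reflected boundary has measure zero but
  # guard against exact hits
  eps <- 1e-12
  prop <- min(max(prop, eps), 1 - eps)
  log_acc <- log_target(prop) - log_target(rho)
  if (is.finite(log_acc) && log(stats::runif(1L)) < log_acc) {
    list(rho = prop, accepted = TRUE)
  } else {
    list(rho = rho, accepted = FALSE)
  }
}

# Log full conditional of rho for a single CAR block with effects u:
# 0.5 * logdet Q(rho) - u'Q(rho)u / (2 tau2), computed from the cached
# eigenvalues and the edge/sum decomposition of the quadratic form.
rho_log_target <- function(eigenvalues, edge_ss, sum_sq, tau2, k = 1) {
  function(rho) {
    0.5 * k * sum(log(rho * eigenvalues + (1 - rho))) -
      (rho * edge_ss + (1 - rho) * sum_sq) / (2 * tau2)
  }
}

# Edge-difference sum of squares sum_edges (u_i - u_j)^2 for a lattice.
edge_diff_ss <- function(u, lattice) {
  e <- lattice$edges
  if (!nrow(e)) return(0)
  sum((u[e[, 1L]] - u[e[, 2L]])^2)
}
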