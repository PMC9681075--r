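# Single Gibbs/Metropolis sweeps, one function per model family.
#
# Each sweep takes the current `state`, the response `y`, the precomputed
# `aux` caches and the named Metropolis `scales`, and returns
# list(state = updated state, acc = named logical acceptance indicators for
# the rho blocks). run_mcmc() loops over these; the Geweke-style
# joint-distribution test interleaves them with re-simulated data.
#
# `aux$center` (default TRUE) controls the sum-to-zero re-centring of the
# random-effect blocks; the removed mean is absorbed into the intercept
# (st_anova / st_ar / st_linear intercept effects) or the overall slope
# (st_linear slope effects), which leaves the linear predictor unchanged.

make_sweep_aux <- function(X, D, T_, lattice, model, prior, center = TRUE) {
  lat_T <- path_lattice(T_)
  list(X = X, XtX = crossprod(X), D = D, T_ = T_, n = D * T_, p = ncol(X),
       lattice = lattice, lat_T = lat_T,
       M_S = lattice_structure_matrix(lattice),
       eig_S = lattice_eigenvalues(lattice),
       M_T = lattice_structure_matrix(lat_T),
       eig_T = lattice_eigenvalues(lat_T),
       cvec = trend_covariate(T_),
       crep = rep(trend_covariate(T_), each = D),
       model = model, prior = prior, center = isTRUE(center))
}

init_sweep_state <- function(y, aux) {
  ls <- stats::lm.fit(aux$X, y)
  beta <- ls$coefficients
  beta[is.na(beta)] <- 0
  nu2 <- max(stats::var(ls$residuals), 1e-6)
  state <- list(beta = beta, nu2 = nu2)
  fam <- aux$model$family
  D <- aux$D; T_ <- aux$T_
  if (fam == "st_anova") {
    state$phi <- numeric(D); state$delta <- numeric(T_)
    state$tau2_S <- 0.1 * nu2; state$tau2_T <- 0.1 * nu2
    state$rho_S <- 0.5; state$rho_T <- 0.5
    if (aux$model$interaction) {
      state$gamma <- numeric(aux$n); state$tau2_I <- 0.1 * nu2
    }
  } else if (fam == "st_linear") {
    state$phi <- numeric(D); state$delta <- numeric(D); state$alpha <- 0
    state$tau2_int <- 0.1 * nu2; state$tau2_slo <- 0.1 * nu2
    state$rho_int <- 0.5; state$rho_slo <- 0.5
  } else if (fam == "st_ar") {
    state$phi <- matrix(0, D, T_)
    state$tau2_T <- 0.1 * nu2
    state$rho_S <- 0.5; state$rho_T <- 0.5
  }
  state
}

rho_block_names <- function(model) {
  switch(model$family,
         independent_glm = character(),
         st_anova = c("rho_S", "rho_T"),
         st_linear = c("rho_int", "rho_slo"),
         st_ar = c("rho_S", "rho_T"))
}

gibbs_sweep <- function(state, y, aux, scales) {
  switch(aux$model$family,
         independent_glm = sweep_glm(state, y, aux),
         st_anova = sweep_anova(state, y, aux, scales),
         st_linear = sweep_linear(state, y, aux, scales),
         st_ar = sweep_ar(state, y, aux, scales))
}

sweep_glm <- function(state, y, aux) {
  prior <- aux$prior
  fc <- fc_beta(aux$XtX, crossprod(aux$X, y), state$nu2, prior$beta_var)
  state$beta <- drop(draw_mvn_canonical(fc$prec, fc$b))
  resid <- y - drop(aux$X %*% state$beta)
  state$nu2 <- update_variance(sum(resid^2), aux$n, prior)
  list(state = state, acc = logical())
}

# Metropolis step for one rho block; returns list(rho, accepted).
sweep_rho <- function(rho, scale, eigenvalues, lattice, u, tau2, k = 1) {
  update_rho(rho, scale,
             rho_log_target(eigenvalues, edge_diff_ss(u, lattice),
                            sum(u^2), tau2, k = k))
}

sweep_anova <- function(state, y, aux, scales) {
  prior <- aux$prior; model <- aux$model
  D <- aux$D; T_ <- aux$T_; n <- aux$n; X <- aux$X
  phi_rep <- rep(state$phi, times = T_)
  del_rep <- rep(state$delta, each = D)
  gam <- if (model$interaction) state$gamma else 0
  # beta
  fc <- fc_beta(aux$XtX, crossprod(X, y - phi_rep - del_rep - gam),
                state$nu2, prior$beta_var)
  state$beta <- drop(draw_mvn_canonical(fc$prec, fc$b))
  xb <- drop(X %*% state$beta)
  # phi
  fc <- fc_car_main(matrix(y - xb - del_rep - gam, nrow = D),
                    state$nu2, aux$M_S, state$rho_S, state$tau2_S)
  phi <- drop(draw_mvn_canonical(fc$prec, fc$b))
  if (aux$center) {
    m <- mean(phi); phi <- phi - m; state$beta[1L] <- state$beta[1L] + m
    xb <- drop(X %*% state$beta)
  }
  state$phi <- phi
  phi_rep <- rep(phi, times = T_)
  # delta
  fc <- fc_car_temporal(matrix(y - xb - phi_rep - gam, nrow = D),
                        state$nu2, aux$M_T, state$rho_T, state$tau2_T)
  delta <- drop(draw_mvn_canonical(fc$prec, fc$b))
  if (aux$center) {
    m <- mean(delta); delta <- delta - m; state$beta[1L] <- state$beta[1L] + m
    xb <- drop(X %*% state$beta)
  }
  state$delta <- delta
  del_rep <- rep(delta, each = D)
  # gamma (optional iid interaction)
  if (model$interaction) {
    part <- y - xb - phi_rep - del_rep
    cprec <- 1 / state$nu2 + 1 / state$tau2_I
    gamma <- part / state$nu2 / cprec + stats::rnorm(n, 0, sqrt(1 / cprec))
    if (aux$center) {
      m <- mean(gamma); gamma <- gamma - m
      state$beta[1L] <- state$beta[1L] + m
      xb <- drop(X %*% state$beta)
    }
    state$gamma <- gamma
    state$tau2_I <- update_variance(sum(gamma^2), n, prior)
    gam <- gamma
  }
  # variances and dependence parameters
  state$tau2_S <- update_variance(
    car_quadform(state$phi, aux$lattice, state$rho_S), D, prior)
  rs <- sweep_rho(state$rho_S, scales[["rho_S"]], aux$eig_S, aux$lattice,
                  state$phi, state$tau2_S)
  state$rho_S <- rs$rho
  state$tau2_T <- update_variance(
    car_quadform(state$delta, aux$lat_T, state$rho_T), T_, prior)
  rt <- sweep_rho(state$rho_T, scales[["rho_T"]], aux$eig_T, aux$lat_T,
                  state$delta, state$tau2_T)
  state$rho_T <- rt$rho
  resid <- y - xb - phi_rep - del_rep - gam
  state$nu2 <- update_variance(sum(resid^2), n, prior)
  list(state = state,
       acc = c(rho_S = rs$accepted, rho_T = rt$accepted))
}

sweep_linear <- function(state, y, aux, scales) {
  prior <- aux$prior
  D <- aux$D; T_ <- aux$T_; n <- aux$n; X <- aux$X
  cvec <- aux$cvec; crep <- aux$crep
  phi_rep <- rep(state$phi, times = T_)
  slope_rep <- rep(state$alpha + state$delta, times = T_) * crep
  # beta
  fc <- fc_beta(aux$XtX, crossprod(X, y - phi_rep - slope_rep),
                state$nu2, prior$beta_var)
  state$beta <- drop(draw_mvn_canonical(fc$prec, fc$b))
  xb <- drop(X %*% state$beta)
  # phi (area intercept effects)
  fc <- fc_car_main(matrix(y - xb - slope_rep, nrow = D),
                    state$nu2, aux$M_S, state$rho_int, state$tau2_int)
  phi <- drop(draw_mvn_canonical(fc$prec, fc$b))
  if (aux$center) {
    m <- mean(phi); phi <- phi - m; state$beta[1L] <- state$beta[1L] + m
    xb <- drop(X %*% state$beta)
  }
  state$phi <- phi
  phi_rep <- rep(phi, times = T_)
  # delta (area slope effects); removed mean absorbed into alpha
  fc <- fc_car_slope(matrix(y - xb - phi_rep - state$alpha * crep, nrow = D),
                     cvec, state$nu2, aux$M_S, state$rho_slo, state$tau2_slo)
  delta <- drop(draw_mvn_canonical(fc$prec, fc$b))
  if (aux$center) {
    m <- mean(delta); delta <- delta - m; state$alpha <- state$alpha + m
  }
  state$delta <- delta
  # alpha (overall slope)
  fc <- fc_alpha(matrix(y - xb - phi_rep - rep(delta, times = T_) * crep,
                        nrow = D),
                 cvec, state$nu2, prior$beta_var)
  state$alpha <- drop(draw_mvn_canonical(fc$prec, fc$b))
  slope_rep <- rep(state$alpha + delta, times = T_) * crep
  # variances and dependence parameters
  state$tau2_int <- update_variance(
    car_quadform(state$phi, aux$lattice, state$rho_int), D, prior)
  ri <- sweep_rho(state$rho_int, scales[["rho_int"]], aux$eig_S,
                  aux$lattice, state$phi, state$tau2_int)
  state$rho_int <- ri$rho
  state$tau2_slo <- update_variance(
    car_quadform(state$delta, aux$lattice, state$rho_slo), D, prior)
  rs <- sweep_rho(state$rho_slo, scales[["rho_slo"]], aux$eig_S,
                  aux$lattice, state$delta, state$tau2_slo)
  state$rho_slo <- rs$rho
  resid <- y - xb - phi_rep - slope_rep
  state$nu2 <- update_variance(sum(resid^2), n, prior)
  list(state = state,
       acc = c(rho_int = ri$accepted, rho_slo = rs$accepted))
}

sweep_ar <- function(state, y, aux, scales) {
  prior <- aux$prior
  D <- aux$D; T_ <- aux$T_; n <- aux$n; X <- aux$X
  lattice <- aux$lattice
  # beta
  fc <- fc_beta(aux$XtX, crossprod(X, y - as.vector(state$phi)),
                state$nu2, prior$beta_var)
  state$beta <- drop(draw_mvn_canonical(fc$prec, fc$b))
  xb <- drop(X %*% state$beta)
  part_mat <- matrix(y - xb, nrow = D)
  # phi slices, sequential full conditionals
  Q <- state$rho_S * aux$M_S + (1 - state$rho_S) * diag(D)
  for (t in seq_len(T_)) {
    fc <- fc_ar_slice(t, part_mat, state$phi, Q, state$nu2,
                      state$tau2_T, state$rho_T)
    state$phi[, t] <- drop(draw_mvn_canonical(fc$prec, fc$b))
  }
  if (aux$center) {
    m <- mean(state$phi); state$phi <- state$phi - m
    state$beta[1L] <- state$beta[1L] + m
    xb <- drop(X %*% state$beta)
  }
  # innovations e_1 = phi_1, e_t = phi_t - rho_T phi_{t-1}
  E <- state$phi
  if (T_ > 1L) {
    E[, -1L] <- state$phi[, -1L, drop = FALSE] -
      state$rho_T * state$phi[, -T_, drop = FALSE]
  }
  quad <- sum(apply(E, 2L, car_quadform, lattice = lattice,
                    rho = state$rho_S))
  state$tau2_T <- update_variance(quad, n, prior)
  # rho_S against the chain's joint density (T log-determinant terms)
  edge_ss <- sum(apply(E, 2L, edge_diff_ss, lattice = lattice))
  rs <- update_rho(state$rho_S, scales[["rho_S"]],
                   rho_log_target(aux$eig_S, edge_ss, sum(E^2),
                                  state$tau2_T, k = T_))
  state$rho_S <- rs$rho
  # rho_T: the transition terms are quadratic in rho_T
  rt <- list(rho = state$rho_T, accepted = FALSE)
  if (T_ > 1L) {
    cur <- state$phi[, -1L, drop = FALSE]
    lag <- state$phi[, -T_, drop = FALSE]
    qf <- function(u, v) car_quadform(u, lattice, state$rho_S, v)
    A <- sum(vapply(seq_len(T_ - 1L), function(j) qf(cur[, j], cur[, j]),
                    numeric(1L)))
    B <- sum(vapply(seq_len(T_ - 1L), function(j) qf(cur[, j], lag[, j]),
                    numeric(1L)))
    C <- sum(vapply(seq_len(T_ - 1L), function(j) qf(lag[, j], lag[, j]),
                    numeric(1L)))
    tt <- state$tau2_T
    rt <- update_rho(state$rho_T, scales[["rho_T"]],
                     function(r) -(A - 2 * r * B + r^2 * C) / (2 * tt))
    state$rho_T <- rt$rho
  }
  resid <- y - xb - as.vector(state$phi)
  state$nu2 <- update_variance(sum(resid^2), n, prior)
  list(state = state,
       acc = c(rho_S = rs$accepted, rho_T = rt$accepted))
}
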