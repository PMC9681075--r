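#' Simulate climate-style covariates on a lattice
#'
#' Generates the five standard covariates (maximum temperature in deg C,
#' rainfall in mm, humidity in %, wind speed in m/s, sunshine in hours) for
#' every area-year cell. Each covariate is built from a smooth spatial base
#' field (a CAR draw on the lattice), a common yearly shift, and cell-level
#' noise, then clamped into a plausible physical range so the default sqrt /
#' log transforms are always well defined (temperature 20--35, rainfall
#' strictly positive, humidity 60--90, wind speed 0.5--3, sunshine 4--9).
#'
#' @param lattice An [st_lattice].
#' @param n_times Number of years T.
#' @param seed Integer seed; the output is a pure function of it.
#' @param start_year First calendar year label (default 2004).
#' @return Data frame in canonical order with columns `area`, `year`,
#'   `temperature`, `rainfall`, `humidity`, `windspeed`, `sunshine`.
#' @export
simulate_covariates <- function(lattice, n_times, seed = 1,
                                start_year = 2004) {
  stopifnot(inherits(lattice, "st_lattice"), n_times >= 1)
  set.seed(seed)
  D <- lattice$n_areas
  T_ <- as.integer(n_times)
  base_struct <- car_structure(lattice, rho = min(0.75, 1 - 1e-6), tau2 = 1)
  spatial <- function() {
    u <- sample_car_field(base_struct)
    if (stats::sd(u) > 0) (u - mean(u)) / stats::sd(u) else u
  }
  cell <- function(sp, yr_sd, cell_sd, centre, sp_amp) {
    yr <- stats::rnorm(T_, 0, yr_sd)
    centre + sp_amp * rep(sp, times = T_) + rep(yr, each = D) +
      stats::rnorm(D * T_, 0, cell_sd)
  }
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  temperature <- clamp(cell(spatial(), 0.8, 0.5, 27.5, 2.0), 20, 35)
  log_rain <- clamp(cell(spatial(), 0.30, 0.25, 7.2, 0.35), 5.5, 8.5)
  humidity <- clamp(cell(spatial(), 2.0, 1.5, 75, 4.0), 60, 90)
  windspeed <- clamp(cell(spatial(), 0.15, 0.10, 1.6, 0.35), 0.5, 3)
  sunshine <- clamp(cell(spatial(), 0.5, 0.3, 6.5, 0.8), 4, 9)
  data.frame(
    area = rep(lattice$labels, times = T_),
    year = rep(seq.int(start_year, length.out = T_), each = D),
    temperature = temperature,
    rainfall = exp(log_rain),
    humidity = humidity,
    windspeed = windspeed,
    sunshine = sunshine,
    stringsAsFactors = FALSE)
}

#' Default ground-truth parameters for synthetic panels
#'
#' Fixture values on the scale of a district-level yield-rate analysis:
#' coefficients on the transformed covariate scale (temperature sqrt,
#' rainfall log), observation variance near 3.4, spatial/temporal CAR
#' variances near 0.2 / 0.4 and dependence near 0.45 / 0.25. The wind-speed
#' coefficient is exactly zero, so its credible interval should cover zero
#' in a correctly calibrated fit.
#'
#' @param family Generating family (see [st_model()]).
#' @return List with `beta` (named), `nu2` and family-specific parameters.
#' @export
default_truth <- function(family = "st_anova") {
  beta <- c("(Intercept)" = -11.2, temperature = 4.8, rainfall = 0.83,
            humidity = -0.078, windspeed = 0, sunshine = -0.86)
  out <- list(beta = beta, nu2 = 3.4)
  if (family == "st_anova") {
    out <- c(out, list(tau2_S = 0.2, tau2_T = 0.4, rho_S = 0.45,
                       rho_T = 0.25))
  } else if (family == "st_linear") {
    out <- c(out, list(alpha = -0.8, tau2_int = 0.2, tau2_slo = 0.3,
                       rho_int = 0.45, rho_slo = 0.4))
  } else if (family == "st_ar") {
    out <- c(out, list(tau2_T = 0.3, rho_S = 0.6, rho_T = 0.25))
  }
  out
}

#' Simulate a panel from a model family with known truth
#'
#' Draws covariates with [simulate_covariates()], forms the design on the
#' transformed scale (sqrt temperature, log rainfall), draws the structured
#' random effects from their priors (CAR fields, iid normals or the AR
#' chain, as the family dictates), sets
#' `y = X beta + psi + N(0, nu2)`, and returns the raw-scale panel together
#' with a full truth record.
#'
#' @param model An [st_model]; its `covariates` default to the five
#'   simulated ones.
#' @param truth Parameter list as from [default_truth()]. `nu2 = 0` and
#'   zero effect variances yield a noiseless `y = X beta`.
#' @param lattice An [st_lattice].
#' @param n_times Number of years.
#' @param seed Integer seed.
#' @return List with `panel` (an [st_panel] carrying raw covariates),
#'   `truth` (class `synthetic_truth`: generating family, parameters,
#'   realised effect vectors, seed) and `lattice`.
#' @export
simulate_panel <- function(model, truth = default_truth(model$family),
                           lattice, n_times, seed = 1) {
  stopifnot(inherits(model, "st_model"), inherits(lattice, "st_lattice"))
  if (truth$nu2 < 0) stop("`nu2` must be non-negative", call. = FALSE)
  for (nm in grep("^tau2", names(truth), value = TRUE)) {
    if (truth[[nm]] < 0) stop("`", nm, "` must be non-negative",
                              call. = FALSE)
  }
  for (nm in grep("^rho", names(truth), value = TRUE)) {
    if (truth[[nm]] < 0 || truth[[nm]] >= 1) {
      stop("`", nm, "` must lie in [0, 1)", call. = FALSE)
    }
  }
  covs <- simulate_covariates(lattice, n_times, seed = seed)
  D <- lattice$n_areas; T_ <- as.integer(n_times); n <- D * T_
  df <- covs
  df$response <- 0
  panel0 <- st_panel(df)
  tpanel <- apply_transforms(panel0, default_transforms())
  cov_names <- if (length(model$covariates)) model$covariates else
    c("temperature", "rainfall", "humidity", "windspeed", "sunshine")
  des <- build_design(tpanel, cov_names)
  beta <- truth$beta
  if (is.null(names(beta))) {
    names(beta) <- colnames(des$X)
  }
  if (!identical(sort(names(beta)), sort(colnames(des$X)))) {
    stop("truth beta names must match the design columns", call. = FALSE)
  }
  beta <- beta[colnames(des$X)]

  # effect draws from the generative priors (continue the seeded stream)
  draw_car <- function(tau2, rho, lat) {
    if (tau2 == 0) return(numeric(lat$n_areas))
    sample_car_field(car_structure(lat, rho, tau2))
  }
  effects <- list()
  psi <- numeric(n)
  if (model$family == "st_anova") {
    phi <- draw_car(truth$tau2_S, truth$rho_S, lattice)
    delta <- draw_car(truth$tau2_T, truth$rho_T, path_lattice(T_))
    effects <- list(phi = phi, delta = delta)
    psi <- rep(phi, times = T_) + rep(delta, each = D)
    if (model$interaction) {
      gamma <- stats::rnorm(n, 0, sqrt(truth$tau2_I))
      effects$gamma <- gamma
      psi <- psi + gamma
    }
  } else if (model$family == "st_linear") {
    phi <- draw_car(truth$tau2_int, truth$rho_int, lattice)
    delta <- draw_car(truth$tau2_slo, truth$rho_slo, lattice)
    effects <- list(phi = phi, delta = delta, alpha = truth$alpha)
    cvec <- trend_covariate(T_)
    psi <- rep(phi, times = T_) +
      rep(truth$alpha + delta, times = T_) * rep(cvec, each = D)
  } else if (model$family == "st_ar") {
    phi <- matrix(0, D, T_)
    if (truth$tau2_T > 0) {
      st <- car_structure(lattice, truth$rho_S, truth$tau2_T)
      phi[, 1L] <- sample_car_field(st)
      for (t in seq_len(T_)[-1L]) {
        phi[, t] <- truth$rho_T * phi[, t - 1L] + sample_car_field(st)
      }
    }
    effects <- list(phi = phi)
    psi <- as.vector(phi)
  }
  mu <- drop(des$X %*% beta) + psi
  y <- mu + if (truth$nu2 > 0) stats::rnorm(n, 0, sqrt(truth$nu2)) else 0

  df$response <- y
  panel <- st_panel(df)
  truth_rec <- structure(
    list(family = model$family, beta = beta, nu2 = truth$nu2,
         params = truth[setdiff(names(truth), c("beta", "nu2"))],
         effects = effects, seed = seed),
    class = "synthetic_truth")
  list(panel = panel, truth = truth_rec, lattice = lattice)
}
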