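#' MCMC configuration
#'
#' Defaults follow the package's reference protocol: 100,000 post-burn-in
#' sweeps after 20,000 burn-in sweeps, thinned by 10, giving 10,000 stored
#' draws. Tests and examples use scaled-down configurations.
#'
#' @param n_burn Burn-in sweeps (discarded; adaptation of the Metropolis
#'   proposal scales happens only here).
#' @param n_keep Post-burn-in sweeps.
#' @param thin Keep every `thin`-th post-burn-in state; the stored draw
#'   count is `floor(n_keep / thin)`.
#' @param seed Integer seed; the whole run is reproducible given it.
#' @param adapt_interval Sweeps between proposal-scale adaptations during
#'   burn-in (target acceptance 40--50%, frozen after burn-in).
#' @param verbose Print progress and final acceptance rates.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burn = 20000, n_keep = 100000, thin = 10,
                        seed = 1, adapt_interval = 50, verbose = FALSE) {
  if (n_burn < 1 || n_keep < 1 || thin < 1 || adapt_interval < 1) {
    stop("configuration error: n_burn, n_keep, thin and adapt_interval ",
         "must be positive", call. = FALSE)
  }
  if (thin > n_keep) {
    stop("configuration error: thin exceeds n_keep", call. = FALSE)
  }
  structure(list(n_burn = as.integer(n_burn), n_keep = as.integer(n_keep),
                 thin = as.integer(thin), seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 verbose = isTRUE(verbose)),
            class = "mcmc_config")
}

#' Fit a spatio-temporal CAR model by MCMC
#'
#' Runs the Gibbs/Metropolis-within-Gibbs sampler for the chosen family.
#' Each sweep updates, in order: the regression coefficients (exact
#' conjugate draw), every random-effect block (exact Gaussian full
#' conditionals, re-centred to sum to zero with the removed mean absorbed
#' into the intercept or overall slope), every variance parameter (conjugate
#' inverse-gamma draw), and every CAR dependence parameter `rho` (reflected
#' random-walk Metropolis whose proposal scale adapts during burn-in toward
#' 40--50% acceptance and is frozen afterwards).
#'
#' @param panel A validated [st_panel] with transforms already applied.
#' @param lattice The [st_lattice] of the panel's areas.
#' @param model An [st_model].
#' @param prior An [st_prior].
#' @param config An [mcmc_config].
#' @return An object of class `st_fit`: a list with `samples` (named draw
#'   arrays, each with `n_stored` rows), `mu` (`n_stored` x n matrix of
#'   per-draw linear predictors), `y`, `X`, `D`, `n_times`, `model`,
#'   `prior`, `config`, `acceptance` (post-burn-in Metropolis acceptance
#'   rates), `area_labels`, `years`.
#' @export
run_mcmc <- function(panel, lattice, model, prior = st_prior(),
                     config = mcmc_config()) {
  stopifnot(inherits(model, "st_model"), inherits(prior, "st_prior"),
            inherits(config, "mcmc_config"))
  report <- validate_panel(panel, lattice)
  if (length(report)) {
    stop(structure(
      class = c("carpanel_validation_error", "error", "condition"),
      list(message = paste0("panel validation failed:\n  ",
                            paste(report, collapse = "\n  ")),
           call = sys.call(), report = report)))
  }
  des <- build_design(panel, model$covariates)
  X <- des$X; y <- des$y
  D <- des$D; T_ <- des$n_times; n <- length(y)
  fam <- model$family

  set.seed(config$seed)
  aux <- make_sweep_aux(X, D, T_, lattice, model, prior)
  state <- init_sweep_state(y, aux)

  rho_names <- rho_block_names(model)
  scales <- stats::setNames(rep(0.1, length(rho_names)), rho_names)
  acc_window <- stats::setNames(integer(length(rho_names)), rho_names)
  acc_post <- stats::setNames(numeric(length(rho_names)), rho_names)

  n_stored <- config$n_keep %/% config$thin
  S <- list(beta = matrix(NA_real_, n_stored, ncol(X),
                          dimnames = list(NULL, colnames(X))),
            nu2 = numeric(n_stored))
  if (fam == "st_anova") {
    S$phi <- matrix(NA_real_, n_stored, D)
    S$delta <- matrix(NA_real_, n_stored, T_)
    S$tau2_S <- numeric(n_stored); S$tau2_T <- numeric(n_stored)
    S$rho_S <- numeric(n_stored); S$rho_T <- numeric(n_stored)
    if (model$interaction) {
      S$gamma <- matrix(NA_real_, n_stored, n)
      S$tau2_I <- numeric(n_stored)
    }
  } else if (fam == "st_linear") {
    S$phi <- matrix(NA_real_, n_stored, D)
    S$delta <- matrix(NA_real_, n_stored, D)
    S$alpha <- numeric(n_stored)
    S$tau2_int <- numeric(n_stored); S$tau2_slo <- numeric(n_stored)
    S$rho_int <- numeric(n_stored); S$rho_slo <- numeric(n_stored)
  } else if (fam == "st_ar") {
    S$phi <- matrix(NA_real_, n_stored, D * T_)
    S$tau2_T <- numeric(n_stored)
    S$rho_S <- numeric(n_stored); S$rho_T <- numeric(n_stored)
  }
  mu_store <- matrix(NA_real_, n_stored, n)

  total <- config$n_burn + config$n_keep
  stored <- 0L
  for (iter in seq_len(total)) {
    sw <- gibbs_sweep(state, y, aux, scales)
    state <- sw$state
    if (length(rho_names)) {
      acc_window <- acc_window + sw$acc[rho_names]
      if (iter > config$n_burn) acc_post <- acc_post + sw$acc[rho_names]
    }
    # adapt Metropolis proposal scales during burn-in only
    if (iter <= config$n_burn && length(rho_names) &&
        iter %% config$adapt_interval == 0L) {
      rate <- acc_window / config$adapt_interval
      scales[rate > 0.5] <- pmin(scales[rate > 0.5] * exp(0.25), 2)
      scales[rate < 0.4] <- pmax(scales[rate < 0.4] * exp(-0.25), 1e-3)
      acc_window[] <- 0L
    }
    if (iter > config$n_burn &&
        (iter - config$n_burn) %% config$thin == 0L &&
        stored < n_stored) {
      stored <- stored + 1L
      S$beta[stored, ] <- state$beta
      S$nu2[stored] <- state$nu2
      if (fam == "st_anova") {
        S$phi[stored, ] <- state$phi; S$delta[stored, ] <- state$delta
        S$tau2_S[stored] <- state$tau2_S; S$tau2_T[stored] <- state$tau2_T
        S$rho_S[stored] <- state$rho_S; S$rho_T[stored] <- state$rho_T
        if (model$interaction) {
          S$gamma[stored, ] <- state$gamma
          S$tau2_I[stored] <- state$tau2_I
        }
      } else if (fam == "st_linear") {
        S$phi[stored, ] <- state$phi; S$delta[stored, ] <- state$delta
        S$alpha[stored] <- state$alpha
        S$tau2_int[stored] <- state$tau2_int
        S$tau2_slo[stored] <- state$tau2_slo
        S$rho_int[stored] <- state$rho_int
        S$rho_slo[stored] <- state$rho_slo
      } else if (fam == "st_ar") {
        S$phi[stored, ] <- as.vector(state$phi)
        S$tau2_T[stored] <- state$tau2_T
        S$rho_S[stored] <- state$rho_S; S$rho_T[stored] <- state$rho_T
      }
      mu_store[stored, ] <- linear_predictor(state, model, X, D, T_)
    }
    if (config$verbose && iter %% max(1L, total %/% 10L) == 0L) {
      message(sprintf("sweep %d / %d", iter, total))
    }
  }

  acceptance <- if (length(rho_names)) acc_post / config$n_keep else numeric()
  if (config$verbose && length(acceptance)) {
    message("acceptance rates: ",
            paste(sprintf("%s=%.2f", names(acceptance), acceptance),
                  collapse = ", "))
  }

  structure(
    list(samples = S, mu = mu_store, y = y, X = X, D = D, n_times = T_,
         model = model, prior = prior, config = config,
         acceptance = acceptance,
         area_labels = attr(panel, "area_labels"),
         years = attr(panel, "years")),
    class = "st_fit")
}

#' @export
print.st_fit <- function(x, ...) {
  cat("st_fit:", x$model$family, "model,", nrow(x$mu), "stored draws,",
      x$D, "areas x", x$n_times, "times\n")
  invisible(x)
}

#' Posterior summary table
#'
#' Posterior mean and equal-tailed credible interval for every scalar
#' parameter (coefficients, variances, dependence parameters, overall
#' slope), in the estimate-plus-interval layout customary for reporting
#' hierarchical spatio-temporal fits. Quantiles use linear interpolation
#' between order statistics (R's default type 7). A parameter is flagged
#' `significant` when its interval excludes zero -- the usual reading under
#' which a covariate whose interval straddles 0 (e.g. wind speed in the
#' motivating crop study) is judged to have no effect.
#'
#' @param fit An [st_fit].
#' @param probs Two probabilities for the interval (default 95% equal-tail).
#' @return Data frame with columns `parameter`, `estimate`, `lower`,
#'   `upper`, `significant`.
#' @export
posterior_summary <- function(fit, probs = c(0.025, 0.975)) {
  stopifnot(inherits(fit, "st_fit"))
  if (nrow(fit$samples$beta) < 2L) {
    stop("state error: need at least 2 stored draws", call. = FALSE)
  }
  if (length(probs) != 2L || any(probs <= 0) || any(probs >= 1) ||
      probs[1L] >= probs[2L]) {
    stop("`probs` must be two increasing values in (0, 1)", call. = FALSE)
  }
  draws <- list()
  bn <- colnames(fit$samples$beta)
  for (j in seq_along(bn)) draws[[bn[j]]] <- fit$samples$beta[, j]
  for (nm in c("alpha", "nu2", "tau2_S", "tau2_T", "tau2_I", "tau2_int",
               "tau2_slo", "rho_S", "rho_T", "rho_int", "rho_slo")) {
    if (!is.null(fit$samples[[nm]]) && !is.matrix(fit$samples[[nm]])) {
      draws[[nm]] <- fit$samples[[nm]]
    }
  }
  est <- vapply(draws, mean, numeric(1L))
  lo <- vapply(draws, stats::quantile, numeric(1L), probs = probs[1L],
               names = FALSE, type = 7)
  hi <- vapply(draws, stats::quantile, numeric(1L), probs = probs[2L],
               names = FALSE, type = 7)
  data.frame(parameter = names(draws), estimate = unname(est),
             lower = unname(lo), upper = unname(hi),
             significant = unname(lo > 0 | hi < 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
summary.st_fit <- function(object, probs = c(0.025, 0.975), ...) {
  out <- posterior_summary(object, probs)
  class(out) <- c("summary.st_fit", "data.frame")
  out
}

#' @export
print.summary.st_fit <- function(x, ...) {
  df <- as.data.frame(x)
  df$estimate <- sprintf("%.3f", df$estimate)
  df$interval <- sprintf("(%.3f, %.3f)", x$lower, x$upper)
  print(df[, c("parameter", "estimate", "interval", "significant")],
        row.names = FALSE)
  invisible(x)
}

#' Effective sample size of a scalar draw sequence
#'
#' Initial-positive-sequence estimator: `n / (1 + 2 * sum(rho_k))` with the
#' autocorrelation sum truncated at the first non-positive adjacent pair.
#' Used for Monte-Carlo standard errors of posterior means.
#'
#' @param x Numeric vector of draws.
#' @return Estimated effective sample size (capped at `length(x)`).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2L, 1000L), plot = FALSE,
                   demean = TRUE)$acf[-1L]
  s <- 0; k <- 1L
  while (k + 1L <= length(ac)) {
    g <- ac[k] + ac[k + 1L]
    if (g < 0) break
    s <- s + g
    k <- k + 2L
  }
  min(n, n / (1 + 2 * s))
}

#' Write a posterior summary as CSV
#'
#' @param summary_df Output of [posterior_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary_df, path) {
  utils::write.csv(summary_df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
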