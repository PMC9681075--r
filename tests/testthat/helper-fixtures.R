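# Small programmatic fixtures shared across test files.

five_covariates <- c("temperature", "rainfall", "humidity", "windspeed",
                     "sunshine")

# Deterministic rectangular panel with simple numeric covariates.
make_toy_panel <- function(D = 2, T_ = 3, covariates = c("x1"),
                           response = NULL) {
  df <- expand.grid(area = sprintf("a%02d", seq_len(D)),
                    year = seq_len(T_) + 2000,
                    stringsAsFactors = FALSE)
  n <- nrow(df)
  for (j in seq_along(covariates)) {
    df[[covariates[j]]] <- seq_len(n) / n + j
  }
  df$response <- if (is.null(response)) seq_len(n) / 2 else response
  st_panel(df, covariates = covariates)
}

# Simulated panel (transformed scale) plus lattice, ready to fit.
make_sim_fit_inputs <- function(family = "st_anova", nx = 3, ny = 3,
                                T_ = 4, seed = 42, truth = NULL) {
  lat <- grid_lattice(nx, ny)
  mod <- st_model(family, covariates = five_covariates)
  if (is.null(truth)) truth <- default_truth(family)
  sim <- simulate_panel(mod, truth, lat, T_, seed = seed)
  list(panel = apply_transforms(sim$panel, default_transforms()),
       raw_panel = sim$panel, lattice = lat, model = mod,
       truth = sim$truth)
}

# Construct a minimal st_fit-like object from draw matrices, for testing
# the assessment module without running a sampler.
make_fake_fit <- function(mu, nu2, y, D = 1L, years = NULL) {
  mu <- as.matrix(mu)
  n <- ncol(mu)
  T_ <- n %/% D
  structure(
    list(samples = list(beta = matrix(0, nrow(mu), 1,
                                      dimnames = list(NULL, "(Intercept)")),
                        nu2 = nu2),
         mu = mu, y = y, X = matrix(1, n, 1), D = D, n_times = T_,
         model = st_model("independent_glm"),
         prior = st_prior(),
         config = NULL, acceptance = numeric(),
         area_labels = sprintf("a%02d", seq_len(D)),
         years = if (is.null(years)) seq_len(T_) else years),
    class = "st_fit")
}
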