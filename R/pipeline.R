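# Read a pipeline config file (JSON or YAML by extension). Recognised keys:
# mcmc: {n_burn, n_keep, thin, adapt_interval}; prior: {beta_var, ig_shape,
# ig_scale}; transforms: named tags; interaction: logical.
read_pipeline_config <- function(path = NULL) {
  if (is.null(path)) return(list())
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

pipeline_settings <- function(config_file, seed, mcmc_override = NULL) {
  cfg <- read_pipeline_config(config_file)
  m <- cfg$mcmc
  mc_args <- list(
    n_burn = if (!is.null(m$n_burn)) m$n_burn else 20000,
    n_keep = if (!is.null(m$n_keep)) m$n_keep else 100000,
    thin = if (!is.null(m$thin)) m$thin else 10,
    adapt_interval = if (!is.null(m$adapt_interval)) m$adapt_interval else 50,
    seed = seed)
  # direct arguments override the config file
  if (!is.null(mcmc_override)) {
    for (nm in intersect(names(mcmc_override),
                         c("n_burn", "n_keep", "thin", "adapt_interval"))) {
      mc_args[[nm]] <- mcmc_override[[nm]]
    }
  }
  pr <- cfg$prior
  prior <- st_prior(
    beta_var = if (!is.null(pr$beta_var)) pr$beta_var else 1e5,
    ig_shape = if (!is.null(pr$ig_shape)) pr$ig_shape else 1,
    ig_scale = if (!is.null(pr$ig_scale)) pr$ig_scale else 0.01)
  transforms <- if (!is.null(cfg$transforms)) {
    do.call(transform_spec, as.list(cfg$transforms))
  } else {
    default_transforms()
  }
  list(config = do.call(mcmc_config, mc_args), prior = prior,
       transforms = transforms,
       interaction = isTRUE(cfg$interaction),
       raw = cfg)
}

model_name_table <- c(glm = "independent_glm", linear = "st_linear",
                      anova = "st_anova", ar = "st_ar")

resolve_family <- function(model_name) {
  if (model_name %in% names(model_name_table)) {
    return(model_name_table[[model_name]])
  }
  if (model_name %in% model_name_table) return(model_name)
  stop("unknown model name '", model_name, "'; use one of {",
       paste(names(model_name_table), collapse = ", "), "}", call. = FALSE)
}

load_inputs <- function(data_path, adjacency_path, transforms) {
  panel <- read_panel(data_path)
  lattice <- read_adjacency(adjacency_path, attr(panel, "area_labels"))
  report <- validate_panel(panel, lattice)
  if (length(report)) {
    stop(structure(
      class = c("carpanel_validation_error", "error", "condition"),
      list(message = paste0("input validation failed:\n  ",
                            paste(report, collapse = "\n  ")),
           call = NULL, report = report)))
  }
  list(panel = apply_transforms(panel, transforms), lattice = lattice,
       raw_panel = panel)
}

run_log <- function(out_dir, seed, settings, inputs = character(),
                    extra = list()) {
  files <- inputs[file.exists(inputs)]
  hashes <- if (length(files)) as.list(tools::md5sum(files)) else list()
  cfg_json <- jsonlite::toJSON(settings$raw, auto_unbox = TRUE, digits = NA)
  log <- c(list(
    package = "carpanel",
    version = as.character(utils::packageVersion("carpanel")),
    seed = seed,
    config = settings$raw,
    config_hash = unname(tools::md5sum(
      local({
        f <- tempfile(fileext = ".json")
        writeLines(as.character(cfg_json), f)
        f
      }))),
    mcmc = unclass(settings$config),
    input_hashes = hashes,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(log)
}

#' Fit one model end to end from files
#'
#' Reads the panel CSV and adjacency edge list, validates, applies the
#' covariate transforms (sqrt temperature, log rainfall unless the config
#' overrides them), runs the sampler, and writes `summary.csv`
#' (parameter/estimate/interval table), `criteria.csv` (one criteria row),
#' `draws.csv` (scalar-parameter draws) and `run_log.json` (version, seed,
#' config hash, input file hashes, acceptance rates) into `out_dir`.
#'
#' @param data_path Panel CSV path.
#' @param adjacency_path Edge-list path.
#' @param model_name One of `"glm"`, `"linear"`, `"anova"`, `"ar"` (or the
#'   full family names).
#' @param config_file Optional JSON/YAML config; direct `mcmc` arguments
#'   override it.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param mcmc Optional named list overriding `n_burn`, `n_keep`, `thin`,
#'   `adapt_interval`.
#' @return The [st_fit], invisibly.
#' @export
pipeline_fit <- function(data_path, adjacency_path, model_name,
                         config_file = NULL, seed = 1, out_dir,
                         mcmc = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  family <- resolve_family(model_name)
  settings <- pipeline_settings(config_file, seed, mcmc)
  inp <- load_inputs(data_path, adjacency_path, settings$transforms)
  covs <- attr(inp$panel, "covariates")
  model <- st_model(family, covariates = covs,
                    interaction = settings$interaction && family == "st_anova")
  fit <- run_mcmc(inp$panel, inp$lattice, model, settings$prior,
                  settings$config)
  write_summary(posterior_summary(fit), file.path(out_dir, "summary.csv"))
  utils::write.csv(as.data.frame(criteria_bundle(fit)),
                   file.path(out_dir, "criteria.csv"), row.names = FALSE)
  scalars <- Filter(function(x) is.numeric(x) && !is.matrix(x), fit$samples)
  draws <- as.data.frame(c(list(), scalars))
  draws <- cbind(as.data.frame(fit$samples$beta), draws)
  utils::write.csv(draws, file.path(out_dir, "draws.csv"), row.names = FALSE)
  run_log(out_dir, seed, settings,
          inputs = c(data_path, adjacency_path,
                     if (!is.null(config_file)) config_file),
          extra = list(model = family,
                       acceptance = as.list(fit$acceptance)))
  invisible(fit)
}

#' Fit and compare all four model families
#'
#' Fits the independent-error GLM and the linear, ANOVA and autoregressive
#' spatio-temporal models to the same data (one seed stream per model,
#' derived from `seed`), writes `comparison.csv` (one criteria row per
#' model, best-model flags included), and, for the best-DIC model,
#' `residuals_spatial.csv` (per-area mean and SD of residuals) and
#' `fitted_temporal.csv` (per-year observed/fitted/interval table).
#'
#' @inheritParams pipeline_fit
#' @return Named list of the four fits, invisibly; the comparison table is
#'   attached as attribute `comparison`.
#' @export
pipeline_compare <- function(data_path, adjacency_path, config_file = NULL,
                             seed = 1, out_dir, mcmc = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  settings <- pipeline_settings(config_file, seed, mcmc)
  inp <- load_inputs(data_path, adjacency_path, settings$transforms)
  covs <- attr(inp$panel, "covariates")
  fams <- c(glm = "independent_glm", linear = "st_linear",
            anova = "st_anova", ar = "st_ar")
  fits <- list()
  for (i in seq_along(fams)) {
    cfg <- settings$config
    cfg$seed <- settings$config$seed + i - 1L
    model <- st_model(fams[[i]], covariates = covs,
                      interaction = settings$interaction &&
                        fams[[i]] == "st_anova")
    fits[[names(fams)[i]]] <- run_mcmc(inp$panel, inp$lattice, model,
                                       settings$prior, cfg)
  }
  comparison <- compare_models(fits)
  utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  best <- fits[[which.min(comparison$dic)]]
  utils::write.csv(aggregate_residuals_spatial(best),
                   file.path(out_dir, "residuals_spatial.csv"),
                   row.names = FALSE)
  utils::write.csv(aggregate_fitted_temporal(best),
                   file.path(out_dir, "fitted_temporal.csv"),
                   row.names = FALSE)
  run_log(out_dir, seed, settings,
          inputs = c(data_path, adjacency_path,
                     if (!is.null(config_file)) config_file),
          extra = list(models = unname(fams),
                       best_dic = comparison$model[which.min(comparison$dic)]))
  attr(fits, "comparison") <- comparison
  invisible(fits)
}

#' Simulate and write a synthetic study scenario
#'
#' Writes `panel.csv`, `adjacency.txt` and `truth.json` for a synthetic
#' panel. The default `"study"` scenario emulates the motivating design: an
#' 8 x 8 rook grid (64 areas) over 17 years, generated from the
#' spatio-temporal ANOVA family at the default truth.
#'
#' @param out_dir Output directory.
#' @param scenario `"study"` or `"custom"`.
#' @param nx,ny,n_times Grid and panel dimensions (used for
#'   `scenario = "custom"`; the study scenario fixes 8, 8, 17).
#' @param family Generating family.
#' @param truth Truth parameter list; default [default_truth()].
#' @param seed Integer seed.
#' @return List with the written `panel`, `truth`, `lattice`, invisibly.
#' @export
pipeline_simulate <- function(out_dir, scenario = c("study", "custom"),
                              nx = 8, ny = 8, n_times = 17,
                              family = "st_anova", truth = NULL, seed = 1) {
  scenario <- match.arg(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (scenario == "study") {
    nx <- 8; ny <- 8; n_times <- 17
  }
  lattice <- grid_lattice(nx, ny)
  model <- st_model(family,
                    covariates = c("temperature", "rainfall", "humidity",
                                   "windspeed", "sunshine"))
  if (is.null(truth)) truth <- default_truth(family)
  sim <- simulate_panel(model, truth, lattice, n_times, seed = seed)
  write_panel(sim$panel, file.path(out_dir, "panel.csv"))
  write_adjacency(lattice, file.path(out_dir, "adjacency.txt"))
  tr <- sim$truth
  jsonlite::write_json(
    list(family = tr$family, beta = as.list(tr$beta), nu2 = tr$nu2,
         params = tr$params, seed = tr$seed,
         effects = lapply(tr$effects, function(e) as.vector(e))),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(sim)
}
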