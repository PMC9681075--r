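#' Construct a rectangular area-by-time panel
#'
#' A space-time panel holds exactly one record per (area, year) combination:
#' the response (e.g. yield rate in tons per acre), an optional exposure
#' (e.g. harvested acres) and named real-valued covariates. Records are
#' stored in a single canonical order -- year-major blocks with areas
#' ascending within each year -- so that every flattened effect vector in
#' the package aligns with row `(t - 1) * D + d`.
#'
#' @param df Data frame with columns `area` (character/factor labels),
#'   `year` (numeric or integer), `response` (numeric), optionally
#'   `exposure`, plus one numeric column per covariate.
#' @param covariates Character vector of covariate column names. Default:
#'   every column other than `area`, `year`, `response`, `exposure`.
#' @return An object of class `st_panel`: the canonically ordered data frame
#'   with attributes `n_areas`, `n_times`, `area_labels`, `years`,
#'   `covariates`.
#' @examples
#' df <- expand.grid(area = c("a", "b"), year = 2004:2006)
#' df$response <- rnorm(6)
#' df$temperature <- 25
#' p <- st_panel(df)
#' attr(p, "n_times") # 3
#' @export
st_panel <- function(df, covariates = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("area", "year", "response")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("panel is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$area <- as.character(df$area)
  if (is.null(covariates)) {
    covariates <- setdiff(names(df), c("area", "year", "response", "exposure"))
  }
  bad <- setdiff(covariates, names(df))
  if (length(bad)) {
    stop("unknown covariate column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  area_labels <- sort(unique(df$area))
  years <- sort(unique(df$year))
  d <- match(df$area, area_labels)
  t <- match(df$year, years)
  ord <- order(t, d)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  keep <- c("area", "year", "response",
            if ("exposure" %in% names(df)) "exposure", covariates)
  df <- df[, keep, drop = FALSE]
  structure(df,
            n_areas = length(area_labels),
            n_times = length(years),
            area_labels = area_labels,
            years = years,
            covariates = covariates,
            class = c("st_panel", "data.frame"))
}

#' Yield rate from production and harvested area
#'
#' The response modelled throughout the package is the yield rate
#' `E = Y / Z`: production (metric tons) divided by harvested area (acres),
#' computed record-wise.
#'
#' @param production Numeric vector of production totals (>= 0).
#' @param area Numeric vector of harvested areas (> 0), recycled if scalar.
#' @return Numeric vector `production / area`.
#' @examples
#' compute_yield_rate(10, 2) # 5
#' @export
compute_yield_rate <- function(production, area) {
  production <- as.numeric(production)
  area <- as.numeric(area)
  if (anyNA(production) || anyNA(area)) {
    stop("missing values in production or area", call. = FALSE)
  }
  if (any(area <= 0)) {
    stop("invalid exposure: harvested area must be strictly positive",
         call. = FALSE)
  }
  if (any(production < 0)) {
    stop("invalid value: production must be non-negative", call. = FALSE)
  }
  production / area
}

#' Per-covariate transform specification
#'
#' Names the transform applied to each covariate before model fitting:
#' `"identity"`, `"sqrt"` or `"log"` (natural log). The study design this
#' package targets puts temperature on the square-root scale and rainfall on
#' the log scale, which [default_transforms()] encodes.
#'
#' @param ... Named transform tags, e.g. `temperature = "sqrt"`.
#' @return Named character vector of class `transform_spec`.
#' @export
transform_spec <- function(...) {
  spec <- c(...)
  if (length(spec)) {
    if (is.null(names(spec)) || any(!nzchar(names(spec)))) {
      stop("every transform must be named by its covariate", call. = FALSE)
    }
    ok <- spec %in% c("identity", "sqrt", "log")
    if (!all(ok)) {
      stop("unknown transform tag(s): ",
           paste(unique(spec[!ok]), collapse = ", "),
           " (use identity, sqrt or log)", call. = FALSE)
    }
  }
  structure(spec, class = "transform_spec")
}

#' @rdname transform_spec
#' @export
default_transforms <- function() {
  transform_spec(temperature = "sqrt", rainfall = "log")
}

#' Apply covariate transforms to a panel
#'
#' Replaces each named covariate column by its transformed values; all other
#' columns are untouched. Domain violations (log of a non-positive value,
#' square root of a negative value) are an error naming the offending
#' record.
#'
#' @param panel An [st_panel].
#' @param spec A [transform_spec]; entries for covariates absent from the
#'   panel are an error.
#' @return The transformed [st_panel].
#' @export
apply_transforms <- function(panel, spec) {
  stopifnot(inherits(panel, "st_panel"))
  covs <- attr(panel, "covariates")
  bad <- setdiff(names(spec), covs)
  if (length(bad)) {
    stop("transform names not covariates of the panel: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (nm in names(spec)) {
    x <- panel[[nm]]
    tag <- spec[[nm]]
    if (tag == "identity") next
    viol <- if (tag == "sqrt") x < 0 else x <= 0
    if (any(viol)) {
      i <- which(viol)[1L]
      stop(sprintf(
        "domain error: %s(%s) undefined at area %s, year %s (value %g)",
        tag, nm, panel$area[i], panel$year[i], x[i]), call. = FALSE)
    }
    panel[[nm]] <- if (tag == "sqrt") sqrt(x) else log(x)
  }
  panel
}

#' Validate a panel against its lattice
#'
#' Report-based validation: confirms rectangular completeness (exactly one
#' record per area-year cell), label agreement with the lattice, contiguous
#' years, and absence of missing values in the response and covariates.
#'
#' @param panel An [st_panel].
#' @param lattice An [st_lattice], or `NULL` to skip the label checks.
#' @return Character vector of violations; `character(0)` means valid.
#' @export
validate_panel <- function(panel, lattice = NULL) {
  out <- character()
  if (!inherits(panel, "st_panel")) {
    return("not an st_panel object")
  }
  D <- attr(panel, "n_areas"); T_ <- attr(panel, "n_times")
  labs <- attr(panel, "area_labels"); years <- attr(panel, "years")
  key <- paste(panel$area, panel$year)
  tab <- table(key)
  if (nrow(panel) != D * T_ || any(tab != 1L)) {
    full <- as.vector(outer(labs, years, paste))
    missing_cells <- setdiff(full, key)
    dup_cells <- names(tab)[tab > 1L]
    for (cell in missing_cells) {
      out <- c(out, paste("missing record for cell:", cell))
    }
    for (cell in dup_cells) {
      out <- c(out, paste("duplicated record for cell:", cell))
    }
  }
  if (length(years) > 1L && !all(diff(sort(years)) == diff(sort(years))[1L])) {
    out <- c(out, "years are not equally spaced/contiguous")
  }
  if (!is.null(lattice)) {
    if (!setequal(lattice$labels, labs)) {
      extra <- setdiff(labs, lattice$labels)
      if (length(extra)) {
        out <- c(out, paste("panel area labels absent from lattice:",
                            paste(utils::head(extra, 5L), collapse = ", ")))
      }
      if (lattice$n_areas != D) {
        out <- c(out, sprintf("lattice has %d areas but panel has %d",
                              lattice$n_areas, D))
      }
    }
  }
  if (anyNA(panel$response)) out <- c(out, "missing values in response")
  for (nm in attr(panel, "covariates")) {
    if (anyNA(panel[[nm]])) {
      out <- c(out, paste("missing values in covariate:", nm))
    }
  }
  out
}

#' Design matrix and response in canonical order
#'
#' Builds the fixed-effects design: an intercept column of ones followed by
#' the requested covariate columns, rows in the canonical year-major order
#' (year 1 block first, areas ascending within each year). The response
#' vector is aligned row-for-row.
#'
#' @param panel A validated [st_panel] (transforms already applied).
#' @param covariates Ordered character vector of covariate names; may be
#'   empty for an intercept-only design.
#' @return List with `X` (n x (p+1) matrix, first column `(Intercept)`),
#'   `y` (length-n response), `D`, `n_times`, `area_index`, `time_index`.
#' @export
build_design <- function(panel, covariates = attr(panel, "covariates")) {
  stopifnot(inherits(panel, "st_panel"))
  bad <- setdiff(covariates, attr(panel, "covariates"))
  if (length(bad)) {
    stop("unknown covariate name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  D <- attr(panel, "n_areas"); T_ <- attr(panel, "n_times")
  X <- cbind(`(Intercept)` = rep(1, nrow(panel)))
  if (length(covariates)) {
    X <- cbind(X, as.matrix(as.data.frame(panel)[, covariates, drop = FALSE]))
  }
  list(X = X,
       y = as.numeric(panel$response),
       D = D,
       n_times = T_,
       area_index = match(panel$area, attr(panel, "area_labels")),
       time_index = match(panel$year, attr(panel, "years")))
}

#' Read / write the standard panel CSV
#'
#' The on-disk format is a UTF-8 CSV with "." decimal and header
#' `area,year,response[,exposure],temperature,rainfall,humidity,windspeed,sunshine`
#' (any covariate set is accepted; `exposure` is optional). Values round-trip
#' to full double precision.
#'
#' @param path File path.
#' @param covariates Passed to [st_panel()]; default auto-detects.
#' @return [read_panel()]: an [st_panel]. [write_panel()]: `path`, invisibly.
#' @export
read_panel <- function(path, covariates = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  st_panel(df, covariates = covariates)
}

#' @rdname read_panel
#' @param panel An [st_panel] to serialise.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "st_panel"))
  df <- as.data.frame(panel)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
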