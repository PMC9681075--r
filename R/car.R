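#' Leroux CAR precision matrix
#'
#' The Leroux parameterisation of the conditional autoregressive (CAR)
#' prior has unit-scale precision
#' \deqn{Q(\rho) = \rho (D_w - W) + (1 - \rho) I,}
#' where `W` is the 0/1 adjacency matrix of the lattice and `D_w` the
#' diagonal matrix of neighbour counts. At `rho = 0` the field is
#' independent (Q = I); as `rho -> 1` it approaches the intrinsic CAR. The
#' full covariance of an effect field with variance parameter `tau2` is
#' `tau2 * solve(Q(rho))`.
#'
#' @param lattice An [st_lattice].
#' @param rho Dependence parameter in `[0, 1]`. `rho = 1` yields the
#'   singular intrinsic structure and is permitted for inspection only;
#'   density evaluation and sampling require `rho < 1`.
#' @return Dense symmetric `n_areas` x `n_areas` matrix.
#' @examples
#' leroux_precision(path_lattice(3), 0.5)
#' @export
leroux_precision <- function(lattice, rho) {
  stopifnot(inherits(lattice, "st_lattice"))
  if (length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1) {
    stop("`rho` must be a single value in [0, 1]", call. = FALSE)
  }
  rho * lattice_structure_matrix(lattice) + (1 - rho) * diag(lattice$n_areas)
}

#' CAR structure: lattice plus (rho, tau2)
#'
#' Bundles a lattice with its dependence and variance parameters and caches
#' the eigenvalues of `D_w - W`, so that the log-determinant
#' `log det Q(rho) = sum(log(rho * lambda_i + 1 - rho))` costs O(n) per
#' `rho` value.
#'
#' @param lattice An [st_lattice] (spatial lattice or [path_lattice()]).
#' @param rho Dependence parameter in `[0, 1)`.
#' @param tau2 Variance parameter (> 0).
#' @return Object of class `car_structure`.
#' @export
car_structure <- function(lattice, rho, tau2) {
  stopifnot(inherits(lattice, "st_lattice"))
  if (rho < 0 || rho >= 1) stop("`rho` must lie in [0, 1)", call. = FALSE)
  if (tau2 <= 0) stop("`tau2` must be positive", call. = FALSE)
  structure(
    list(lattice = lattice, rho = rho, tau2 = tau2,
         eigenvalues = lattice_eigenvalues(lattice)),
    class = "car_structure"
  )
}

# Quadratic form u' Q(rho) v without forming Q:
# rho * sum_edges (u_i - u_j)(v_i - v_j) + (1 - rho) * sum(u * v).
car_quadform <- function(u, lattice, rho, v = u) {
  e <- lattice$edges
  edge_part <- if (nrow(e)) {
    sum((u[e[, 1L]] - u[e[, 2L]]) * (v[e[, 1L]] - v[e[, 2L]]))
  } else 0
  rho * edge_part + (1 - rho) * sum(u * v)
}

# log det Q(rho) from cached eigenvalues of D_w - W
car_logdet <- function(eigenvalues, rho) {
  sum(log(rho * eigenvalues + (1 - rho)))
}

#' Proper CAR log-density
#'
#' Exact log-density of a mean-zero Gaussian field with precision
#' `Q(rho) / tau2`, including the `0.5 * log det` term:
#' \deqn{\log p(u) = -\tfrac{n}{2}\log(2\pi\tau^2)
#'   + \tfrac12 \log\det Q(\rho) - \tfrac{1}{2\tau^2} u'Q(\rho)u.}
#'
#' @param u Numeric effect vector, length `n_areas` of the structure's
#'   lattice.
#' @param structure A [car_structure] with `rho < 1`.
#' @return Log-density (scalar).
#' @export
car_logdensity <- function(u, structure) {
  stopifnot(inherits(structure, "car_structure"))
  lat <- structure$lattice
  if (length(u) != lat$n_areas) {
    stop("`u` must have length ", lat$n_areas, call. = FALSE)
  }
  n <- lat$n_areas
  ld <- car_logdet(structure$eigenvalues, structure$rho)
  if (!is.finite(ld)) stop("singular CAR precision", call. = FALSE)
  -0.5 * n * log(2 * pi * structure$tau2) + 0.5 * ld -
    car_quadform(u, lat, structure$rho) / (2 * structure$tau2)
}

#' Exact draw from a CAR field
#'
#' Samples `u ~ N(0, tau2 * Q(rho)^{-1})` by back-solving the Cholesky
#' factor of `Q(rho) / tau2` against iid standard normals.
#'
#' @param structure A [car_structure].
#' @param seed Optional integer; if given, the draw is a pure function of
#'   it (the global RNG stream is left untouched). If `NULL`, the current
#'   RNG stream is used.
#' @return Numeric vector of length `n_areas`.
#' @export
sample_car_field <- function(structure, seed = NULL) {
  stopifnot(inherits(structure, "car_structure"))
  n <- structure$lattice$n_areas
  z <- if (is.null(seed)) {
    stats::rnorm(n)
  } else {
    withr_seed_rnorm(n, seed)
  }
  Q <- leroux_precision(structure$lattice, structure$rho) / structure$tau2
  R <- tryCatch(chol(Q), error = function(e) {
    stop("singular CAR precision: ", conditionMessage(e), call. = FALSE)
  })
  backsolve(R, z)
}

# rnorm under a local seed, restoring the caller's RNG state
withr_seed_rnorm <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n)
}
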