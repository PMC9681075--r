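#' Construct a spatial lattice of areal units
#'
#' A lattice records the discrete spatial units (districts, grid cells) and a
#' symmetric neighbour structure as an undirected edge set. It is the support
#' of every spatial CAR prior in the package; temporal random effects reuse
#' the same machinery on the path graph returned by [path_lattice()].
#'
#' @param n_areas Number of areal units (positive integer).
#' @param edges Two-column integer matrix of 1-based area indices, one row
#'   per undirected edge. Duplicate and reversed pairs are collapsed;
#'   self-loops are an error. May have zero rows.
#' @param labels Optional character vector of unique area labels (length
#'   `n_areas`); defaults to `area001, area002, ...`. Labels are the join key
#'   used by panel CSV and adjacency files.
#'
#' @return An object of class `st_lattice`: a list with elements `n_areas`,
#'   `edges` (canonicalised two-column matrix, smaller index first, ordered),
#'   `degree` (per-area neighbour count) and `labels`.
#' @examples
#' lat <- st_lattice(3, rbind(c(1, 2), c(2, 3)))
#' lat$degree # 1 2 1
#' @seealso [grid_lattice()], [path_lattice()], [read_adjacency()]
#' @export
st_lattice <- function(n_areas, edges, labels = NULL) {
  if (length(n_areas) != 1L || is.na(n_areas) || n_areas < 1 ||
      n_areas != round(n_areas)) {
    stop("`n_areas` must be a single positive integer", call. = FALSE)
  }
  n_areas <- as.integer(n_areas)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(), ncol = 2L)
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("`edges` must have two columns", call. = FALSE)
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0L) {
    if (anyNA(edges)) stop("`edges` contains missing indices", call. = FALSE)
    if (any(edges < 1L) || any(edges > n_areas)) {
      stop("edge indices must lie in 1..n_areas", call. = FALSE)
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    # canonical undirected form: smaller index first, sorted, deduplicated
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  if (is.null(labels)) {
    labels <- sprintf("area%03d", seq_len(n_areas))
  }
  labels <- as.character(labels)
  if (length(labels) != n_areas || anyDuplicated(labels)) {
    stop("`labels` must be ", n_areas, " unique strings", call. = FALSE)
  }
  degree <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n_areas)
  structure(
    list(n_areas = n_areas, edges = edges, degree = as.integer(degree),
         labels = labels),
    class = "st_lattice"
  )
}

#' @export
print.st_lattice <- function(x, ...) {
  cat("st_lattice:", x$n_areas, "areas,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Rook-adjacency rectangular grid lattice
#'
#' Stand-in for a district contiguity graph: `nx * ny` cells, each adjacent
#' to its horizontal and vertical neighbours.
#'
#' @param nx,ny Grid dimensions (positive integers).
#' @return An [st_lattice] with `nx * ny` areas and `nx*(ny-1) + ny*(nx-1)`
#'   edges.
#' @examples
#' grid_lattice(8, 8) # 64 areas, 112 edges
#' @export
grid_lattice <- function(nx, ny) {
  if (nx < 1 || ny < 1) stop("grid dimensions must be >= 1", call. = FALSE)
  nx <- as.integer(nx); ny <- as.integer(ny)
  idx <- function(i, j) (j - 1L) * nx + i # column-major cells
  e <- list()
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      if (i < nx) e[[length(e) + 1L]] <- c(idx(i, j), idx(i + 1L, j))
      if (j < ny) e[[length(e) + 1L]] <- c(idx(i, j), idx(i, j + 1L))
    }
  }
  edges <- if (length(e)) do.call(rbind, e) else matrix(integer(), ncol = 2L)
  st_lattice(nx * ny, edges)
}

#' Path-graph lattice for temporal random effects
#'
#' The line graph 1 -- 2 -- ... -- T used as the support of temporal CAR
#' priors: endpoints have one neighbour, interior nodes two.
#'
#' @param n_times Number of time points T (positive integer).
#' @return An [st_lattice] with `n_times` nodes and `n_times - 1` edges.
#' @export
path_lattice <- function(n_times) {
  if (length(n_times) != 1L || is.na(n_times) || n_times < 1) {
    stop("`n_times` must be a positive integer", call. = FALSE)
  }
  n_times <- as.integer(n_times)
  edges <- if (n_times > 1L) {
    cbind(seq_len(n_times - 1L), seq_len(n_times - 1L) + 1L)
  } else {
    matrix(integer(), ncol = 2L)
  }
  st_lattice(n_times, edges, labels = sprintf("t%03d", seq_len(n_times)))
}

#' Read a spatial adjacency from a whitespace-separated edge list
#'
#' Each non-empty line holds two area labels, `areaA areaB`. Reversed and
#' duplicated pairs are collapsed to one undirected edge. Labels must match
#' `labels` exactly (the same lexicon as the panel's `area` column).
#'
#' @param path Path to the edge-list text file.
#' @param labels Character vector of all area labels; defines `n_areas` and
#'   the index mapping. Areas with no edges are permitted.
#' @return An [st_lattice].
#' @export
read_adjacency <- function(path, labels) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  labels <- as.character(labels)
  if (length(lines) == 0L) {
    return(st_lattice(length(labels), NULL, labels))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed adjacency line(s): ",
         paste(utils::head(lines[bad], 3L), collapse = "; "), call. = FALSE)
  }
  a <- vapply(parts, `[`, character(1L), 1L)
  b <- vapply(parts, `[`, character(1L), 2L)
  ia <- match(a, labels); ib <- match(b, labels)
  if (anyNA(ia) || anyNA(ib)) {
    unk <- unique(c(a[is.na(ia)], b[is.na(ib)]))
    stop("adjacency labels not present in the panel lexicon: ",
         paste(utils::head(unk, 5L), collapse = ", "), call. = FALSE)
  }
  st_lattice(length(labels), cbind(ia, ib), labels)
}

#' Write a lattice as an edge-list text file
#'
#' @param lattice An [st_lattice].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(lattice, path) {
  stopifnot(inherits(lattice, "st_lattice"))
  e <- lattice$edges
  lines <- if (nrow(e)) {
    paste(lattice$labels[e[, 1L]], lattice$labels[e[, 2L]])
  } else {
    character()
  }
  writeLines(lines, path)
  invisible(path)
}

# Dense M = D_w - W (the ICAR structure matrix) for a lattice.
lattice_structure_matrix <- function(lattice) {
  n <- lattice$n_areas
  M <- diag(lattice$degree, n, n)
  e <- lattice$edges
  if (nrow(e)) {
    M[cbind(e[, 1L], e[, 2L])] <- M[cbind(e[, 1L], e[, 2L])] - 1
    M[cbind(e[, 2L], e[, 1L])] <- M[cbind(e[, 2L], e[, 1L])] - 1
  }
  M
}

# Eigenvalues of M = D_w - W, cached by callers; used for the CAR
# log-determinant log det Q(rho) = sum log(rho*lambda_i + 1 - rho).
lattice_eigenvalues <- function(lattice) {
  eigen(lattice_structure_matrix(lattice), symmetric = TRUE,
        only.values = TRUE)$values
}
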