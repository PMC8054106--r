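#' Build a region adjacency graph
#'
#' The spatial support of the model: an undirected, connected graph whose
#' vertices are the subnational regions (e.g. counties) and whose edges join
#' regions sharing a border. The graph carries the neighbourhood structure of
#' the conditionally autoregressive (CAR) spatial prior, so connectivity is
#' required: on a disconnected graph the proper-CAR correlation is not well
#' defined across components.
#'
#' @param edges A data frame whose first two columns give the region ids at
#'   either end of an undirected edge (one row per edge). Further columns are
#'   ignored. Duplicate and reversed edges are collapsed.
#' @param region_ids Optional character vector fixing the region ordering.
#'   Defaults to the sorted set of ids appearing in `edges`. Ids listed here
#'   but absent from `edges` are only legal in the single-region case.
#'
#' @details A single region (`region_ids` of length 1 and no edges) is
#'   accepted as a degenerate graph: it is trivially connected and its CAR
#'   correlation is the 1 x 1 identity. This supports the conjugate
#'   single-cell model used to check the sampler. Self-edges are an error.
#'
#' @return An object of class `region_graph`: a list with `region_ids`,
#'   `edges` (tibble with columns `from`, `to`), the 0/1 adjacency matrix
#'   `W`, and `n_regions`.
#' @examples
#' g <- region_graph(data.frame(from = c("A", "B"), to = c("B", "C")))
#' g$n_regions
#' @export
region_graph <- function(edges, region_ids = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2 && nrow(edges) > 0) {
    abort("`edges` needs at least two columns (region ids of each edge).")
  }
  if (nrow(edges) > 0) {
    a <- as.character(edges[[1]])
    b <- as.character(edges[[2]])
    if (any(a == b)) {
      abort(paste0(
        "Self-edges are not allowed: ",
        paste(unique(a[a == b]), collapse = ", ")
      ))
    }
    # canonical undirected representation
    from <- pmin(a, b)
    to <- pmax(a, b)
    e <- dplyr::distinct(tibble::tibble(from = from, to = to))
  } else {
    e <- tibble::tibble(from = character(), to = character())
  }

  ids <- region_ids %||% sort(unique(c(e$from, e$to)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) abort("`region_ids` contains duplicates.")
  K <- length(ids)
  if (K < 1) abort("A region graph needs at least one region.")
  missing <- setdiff(c(e$from, e$to), ids)
  if (length(missing) > 0) {
    abort(paste0("Edge regions not in `region_ids`: ",
                 paste(missing, collapse = ", ")))
  }

  W <- matrix(0L, K, K, dimnames = list(ids, ids))
  if (nrow(e) > 0) {
    idx <- cbind(match(e$from, ids), match(e$to, ids))
    W[idx] <- 1L
    W[idx[, 2:1, drop = FALSE]] <- 1L
  }

  if (K > 1) {
    ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected")
    if (!igraph::is_connected(ig)) {
      abort("Region graph is disconnected; the CAR prior requires a connected graph.")
    }
  }

  structure(
    list(region_ids = ids, edges = e, W = W, n_regions = K),
    class = "region_graph"
  )
}

#' @export
print.region_graph <- function(x, ...) {
  cat("<region_graph> ", x$n_regions, " regions, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Read a region adjacency list from a delimited file
#'
#' Expects a header row and two columns (`region_a,region_b`), one row per
#' undirected edge.
#'
#' @param path Path to a delimited text file.
#' @param region_ids Optional fixed region ordering, see [region_graph()].
#' @return A `region_graph`.
#' @export
read_adjacency <- function(path, region_ids = NULL) {
  edges <- readr::read_csv(path, show_col_types = FALSE)
  region_graph(edges, region_ids = region_ids)
}

check_correlation <- function(R, tol = 1e-10) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-12) abort("Correlation matrix is not symmetric.")
  if (max(abs(diag(R) - 1)) > 1e-12) abort("Correlation matrix diagonal is not 1.")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol) abort("Correlation matrix is not positive definite.")
  invisible(R)
}

#' Proper-CAR spatial correlation matrix
#'
#' Builds the spatial correlation implied by a proper conditionally
#' autoregressive model on the region graph: the precision is `D - rho_s W`
#' (`D` the diagonal matrix of neighbour counts, `W` the 0/1 adjacency), its
#' inverse is rescaled to unit diagonal so the result is a genuine
#' correlation matrix, as the separable space-time covariance requires.
#'
#' @param graph A [region_graph()].
#' @param rho_s Spatial dependence parameter, strictly inside (0, 1). Values
#'   near 1 give strong smoothing across neighbouring regions; near 0 the
#'   regions decouple.
#' @return A symmetric positive-definite K x K matrix with unit diagonal and
#'   region ids as dimnames.
#' @examples
#' g <- region_graph(data.frame(from = "A", to = "B"))
#' car_correlation(g, 0.5) # off-diagonal 0.5
#' @export
car_correlation <- function(graph, rho_s) {
  stopifnot(inherits(graph, "region_graph"))
  if (!is.numeric(rho_s) || length(rho_s) != 1 || rho_s <= 0 || rho_s >= 1) {
    abort("`rho_s` must be a single number strictly inside (0, 1).")
  }
  K <- graph$n_regions
  if (K == 1) {
    return(matrix(1, 1, 1, dimnames = list(graph$region_ids, graph$region_ids)))
  }
  W <- graph$W
  Q <- diag(rowSums(W)) - rho_s * W
  V <- solve(Q)
  d <- sqrt(diag(V))
  R <- V / tcrossprod(d)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  dimnames(R) <- list(graph$region_ids, graph$region_ids)
  check_correlation(R)
  R
}

#' AR(1) temporal correlation matrix
#'
#' Correlation between years t and t' is `phi^|t - t'|`.
#'
#' @param n_years Number of consecutive years (T >= 1).
#' @param phi Temporal autocorrelation, |phi| < 1.
#' @return A T x T correlation matrix.
#' @examples
#' ar1_correlation(3, 0.5)
#' @export
ar1_correlation <- function(n_years, phi) {
  if (!is.numeric(n_years) || length(n_years) != 1 || n_years < 1 ||
      n_years != round(n_years)) {
    abort("`n_years` must be a positive integer.")
  }
  if (!is.numeric(phi) || length(phi) != 1 || abs(phi) >= 1) {
    abort("`phi` must satisfy |phi| < 1.")
  }
  lag <- abs(outer(seq_len(n_years), seq_len(n_years), "-"))
  R <- phi^lag
  diag(R) <- 1
  R
}

#' Separable space-time covariance
#'
#' `Sigma = sigma2 * (R_S %x% R_T)`, with the global vectorisation contract:
#' row index `(k - 1) * T + t` (region-major, year-minor). Every module in
#' the package shares this ordering.
#'
#' @param spatial Spatial correlation matrix (K x K).
#' @param temporal Temporal correlation matrix (T x T).
#' @param sigma2 Field variance on the logit scale, > 0.
#' @return A dense KT x KT covariance matrix.
#' @export
kron_covariance <- function(spatial, temporal, sigma2) {
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 <= 0) {
    abort("`sigma2` must be a single positive number.")
  }
  sigma2 * kronecker(spatial, temporal)
}
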