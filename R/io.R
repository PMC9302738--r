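# Plain-text exchange formats: edge lists, dense matrix CSV, GraphML,
# equilibrium JSON.

#' Read / write community graphs as plain edge lists
#'
#' One `"i j"` pair per line, 0-based vertex ids, whitespace separated.
#' Isolated trailing vertices are preserved through the `n_vertices` argument.
#'
#' @param graph a [community_graph].
#' @param path file path.
#' @param n_vertices pool size when reading (defaults to `max(id) + 1`).
#' @return `read_edge_list` returns a [community_graph]; `write_edge_list`
#'   returns `path` invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "community_graph"))
  el <- igraph::as_edgelist(graph$graph, names = FALSE) - 1L
  write.table(el, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, n_vertices = NULL) {
  el <- as.matrix(read.table(path, col.names = c("i", "j")))
  if (nrow(el) == 0) stopf("empty edge list: %s", path)
  n <- n_vertices %||% (max(el) + 1L)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(el + 1L))
  community_graph(g)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "community_graph"))
  igraph::write_graph(graph$graph, path, format = "graphml")
  invisible(path)
}

#' Write an interaction matrix as dense CSV
#'
#' Header row of 0-based vertex ids; symmetric, unit diagonal.
#'
#' @param matrix an `interaction_matrix`.
#' @param path file path.
#' @export
write_interaction_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  M <- as.matrix(matrix$matrix)
  colnames(M) <- seq_len(ncol(M)) - 1L
  write.csv(M, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_interaction_csv
#' @param alpha,sigma ensemble parameters recorded on the reconstructed
#'   object (the CSV itself carries only the matrix entries).
#' @export
read_interaction_csv <- function(path, alpha = NA_real_, sigma = NA_real_) {
  M <- as.matrix(read.csv(path, check.names = FALSE))
  dimnames(M) <- NULL
  if (!isTRUE(all.equal(M, t(M)))) stopf("interaction matrix must be symmetric")
  if (any(abs(diag(M) - 1) > 1e-12)) stopf("interaction matrix must have unit diagonal")
  A <- (M != 0) & !diag(nrow(M))
  g <- community_graph(igraph::graph_from_adjacency_matrix(A, mode = "undirected"))
  el <- igraph::as_edgelist(g$graph, names = FALSE)
  structure(list(matrix = Matrix::Matrix(M, sparse = TRUE), graph = g,
                 alpha = alpha, sigma = sigma,
                 strengths = M[el], edges = el),
            class = "interaction_matrix")
}

#' Serialize an equilibrium to JSON
#'
#' Records abundances, the persistent mask, relative diversity, residual
#' summaries and provenance fields; readable back as a plain list.
#'
#' @param state an `equilibrium_state`.
#' @param path file path.
#' @param ... extra provenance fields (seed, parameters, ...) stored verbatim.
#' @export
write_equilibrium_json <- function(state, path, ...) {
  stopifnot(inherits(state, "equilibrium_state"))
  rec <- list(
    abundances = state$abundances,
    persistent = state$persistent,
    phi = state$phi,
    verified = state$verified,
    converged = state$converged,
    max_persistent_residual = max(c(0, abs(state$residuals$persistent_residual))),
    max_invasion_rate = if (any(!state$persistent))
      max(state$residuals$invasion_rate) else NA,
    time = state$time,
    ...)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
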