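# Observables of assembled equilibria: persistent-subgraph decomposition,
# relative diversity, rank-abundance curves, and tree-catalogue matching.

#' Connected components of the persistent species
#'
#' Decomposes a verified equilibrium into the connected subgraphs of the
#' community graph induced by the persistent species. These components are
#' the basic objects of the theory: each one sits at the fixed point of its
#' own internal interactions, and finite components are trees with
#' probability approaching one on sparse random graphs.
#'
#' @param graph the [community_graph] the equilibrium lives on.
#' @param state an `equilibrium_state`.
#' @param require_verified reject unverified states (default `TRUE`).
#' @return A `component_decomposition`: `components` (list of vertex index
#'   vectors), `sizes`, `largest_fraction` (largest component size over the
#'   pool size `S`), `size_histogram`, `is_tree` flags (edge count equals
#'   size minus one), and `n_persistent`.
#' @export
persistent_components <- function(graph, state, require_verified = TRUE) {
  stopifnot(inherits(graph, "community_graph"),
            inherits(state, "equilibrium_state"))
  if (require_verified && !state$verified)
    stopf("state is not a verified equilibrium")
  pers <- which(state$persistent)
  if (length(pers) == 0) {
    return(structure(list(components = list(), sizes = integer(0),
                          largest_fraction = 0,
                          size_histogram = table(integer(0)),
                          is_tree = logical(0), n_persistent = 0L,
                          S = graph$n_vertices),
                     class = "component_decomposition"))
  }
  sub <- igraph::induced_subgraph(graph$graph, pers)
  comp <- igraph::components(sub)
  components <- lapply(split(seq_along(comp$membership), comp$membership),
                       function(idx) pers[idx])
  sizes <- lengths(components)
  is_tree <- vapply(seq_along(components), function(j) {
    s <- igraph::induced_subgraph(graph$graph, components[[j]])
    igraph::ecount(s) == igraph::vcount(s) - 1L
  }, TRUE)
  structure(list(components = unname(components), sizes = unname(sizes),
                 largest_fraction = max(sizes) / graph$n_vertices,
                 size_histogram = table(sizes),
                 is_tree = unname(is_tree),
                 n_persistent = length(pers), S = graph$n_vertices),
            class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("<component_decomposition> %d persistent species in %d components (largest fraction %.4g)\n",
              x$n_persistent, length(x$components), x$largest_fraction))
  invisible(x)
}

#' Relative diversity of an equilibrium
#'
#' The fraction `phi = S* / S` of pool species that persist.
#'
#' @param state an `equilibrium_state`.
#' @return Number in `[0, 1]`.
#' @export
relative_diversity <- function(state) {
  stopifnot(inherits(state, "equilibrium_state"))
  state$phi
}

#' Rank-abundance curve of an equilibrium
#'
#' Abundances of the persistent species sorted in decreasing order. At
#' homogeneous strengths the curve is a staircase whose plateau values are
#' exactly the fixed-point abundances of the allowed trees (e.g. `1` for
#' singletons and `1 / (1 + alpha)` for pairs).
#'
#' @param state a verified `equilibrium_state`.
#' @return Decreasing numeric vector of persistent abundances.
#' @export
rank_abundance <- function(state) {
  stopifnot(inherits(state, "equilibrium_state"))
  sort(state$abundances[state$persistent], decreasing = TRUE)
}

#' Match observed abundances to subgraph fixed-point predictions
#'
#' For each persistent component, solves the component's own linear system
#' `(I + W) N = 1` and compares the observed equilibrium abundances against
#' this prediction, species by species. Components containing cycles are
#' flagged and skipped (the tree calculus does not cover them); with a
#' homogeneous catalogue supplied, each tree component is additionally
#' checked to be an allowed tree (`alpha < alpha_c`) of the catalogue.
#'
#' @param matrix the `interaction_matrix` of the community.
#' @param state a verified `equilibrium_state`.
#' @param catalogue optional [enumerate_trees()] catalogue for the
#'   homogeneous case.
#' @param tolerance maximum absolute abundance mismatch.
#' @return A list: `table` (per-species data frame with observed, predicted,
#'   matched), `n_mismatch`, `skipped_components` (indices of non-tree
#'   components), `uncatalogued` (tree components missing from the supplied
#'   catalogue), `all_matched`.
#' @export
match_abundances_to_trees <- function(matrix, state, catalogue = NULL,
                                      tolerance = 1e-6) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  decomp <- persistent_components(matrix$graph, state,
                                  require_verified = FALSE)
  Mfull <- as.matrix(matrix$matrix)
  rows <- list()
  skipped <- integer(0)
  uncat <- integer(0)
  for (j in seq_along(decomp$components)) {
    idx <- decomp$components[[j]]
    if (!decomp$is_tree[j]) {
      skipped <- c(skipped, j)
      next
    }
    A <- (Mfull[idx, idx, drop = FALSE] != 0) * 1
    diag(A) <- 0
    W <- Mfull[idx, idx, drop = FALSE]
    diag(W) <- 0
    pred <- subgraph_fixed_point(A, W)
    obs <- state$abundances[idx]
    rows[[length(rows) + 1]] <- data.frame(
      species = idx, component = j, size = length(idx),
      observed = obs, predicted = pred,
      matched = abs(obs - pred) <= tolerance)
    if (!is.null(catalogue)) {
      key <- canonical_key(A)
      hit <- match(key, catalogue$canon)
      if (is.na(hit) || catalogue$alpha_c[hit] <= matrix$alpha)
        uncat <- c(uncat, j)
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = integer(0), component = integer(0), size = integer(0),
               observed = numeric(0), predicted = numeric(0),
               matched = logical(0))
  list(table = table,
       n_mismatch = sum(!table$matched),
       skipped_components = skipped,
       uncatalogued = uncat,
       all_matched = all(table$matched) && length(uncat) == 0)
}

#' Export a component decomposition as a tidy data frame
#'
#' @param decomp a [persistent_components()] result.
#' @return Data frame with one row per component.
#' @export
components_as_data_frame <- function(decomp) {
  stopifnot(inherits(decomp, "component_decomposition"))
  data.frame(component = seq_along(decomp$sizes),
             size = decomp$sizes,
             is_tree = decomp$is_tree,
             fraction_of_pool = decomp$sizes / decomp$S)
}
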