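# Allowed-subgraph calculus: fixed points, feasibility, stability, critical
# interaction strengths, tree catalogue, and the emergence (splitting) rule.

# Per-edge strength matrix W for a connected subgraph: either a scalar alpha
# on every edge of `adjacency`, or a full symmetric matrix of strengths.
strength_matrix <- function(adjacency, strengths) {
  adjacency <- as.matrix(adjacency)
  if (is.matrix(strengths)) {
    W <- strengths * (adjacency != 0)
    if (!isTRUE(all.equal(W, t(W)))) stopf("strengths must be symmetric")
    W
  } else {
    strengths * (adjacency != 0)
  }
}

#' Fixed-point abundances of a connected subgraph
#'
#' At an equilibrium the abundances of a persistent connected subgraph are
#' determined entirely by its internal interactions: they solve the linear
#' system `(I + W) N = 1`, where `W` holds the pairwise strengths. The
#' solution may contain nonpositive entries, in which case the subgraph is
#' infeasible at these strengths.
#'
#' @param adjacency symmetric 0/1 adjacency matrix of the subgraph.
#' @param strengths scalar strength `alpha` (homogeneous case) or a symmetric
#'   matrix of per-edge strengths.
#' @return Numeric abundance vector (one entry per vertex).
#' @export
subgraph_fixed_point <- function(adjacency, strengths) {
  W <- strength_matrix(adjacency, strengths)
  n <- nrow(W)
  M <- diag(n) + W
  N <- tryCatch(solve(M, rep(1, n)), error = function(e) NULL)
  if (is.null(N)) {
    if (!is.matrix(strengths)) {
      ev <- eigen(as.matrix(adjacency), symmetric = TRUE, only.values = TRUE)$values
      crit <- -1 / ev[abs(ev) > 1e-12]
      crit <- min(crit[crit > 0])
      stopf("singular subgraph system: strengths sit at the critical value alpha = %.10g",
            crit)
    }
    stopf("singular subgraph system at the supplied strengths")
  }
  N
}

#' Feasibility and stability of a subgraph fixed point
#'
#' A connected subgraph is *feasible* when all fixed-point abundances are
#' strictly positive (numerical threshold `1e-12`), and *stable* when its
#' interaction matrix `I + W` is positive definite. A subgraph is *allowed*
#' at given strengths when it is both.
#'
#' @param abundances fixed-point abundances from [subgraph_fixed_point()].
#' @param tol strict-positivity threshold.
#' @return Logical.
#' @export
is_feasible <- function(abundances, tol = 1e-12) all(abundances > tol)

#' @rdname is_feasible
#' @inheritParams subgraph_fixed_point
#' @export
is_stable <- function(adjacency, strengths) {
  W <- strength_matrix(adjacency, strengths)
  M <- diag(nrow(W)) + W
  min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) > 0
}

#' @rdname is_feasible
#' @export
subgraph_allowed <- function(adjacency, strengths) {
  W <- strength_matrix(adjacency, strengths)
  n <- nrow(W)
  M <- diag(n) + W
  if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <= 0) return(FALSE)
  N <- tryCatch(solve(M, rep(1, n)), error = function(e) NULL)
  !is.null(N) && is_feasible(N)
}

# strengths as a function of the scanned mean alpha
strength_fun <- function(adjacency, strengths, mode) {
  A <- (as.matrix(adjacency) != 0) * 1
  if (is.null(strengths)) {
    function(a) a * A
  } else {
    W0 <- strength_matrix(adjacency, strengths)
    m0 <- mean(W0[upper.tri(W0) & A == 1])
    if (mode == "shift") function(a) W0 + (a - m0) * A
    else function(a) W0 * (a / m0)
  }
}

#' Critical interaction strength of a connected subgraph, by bisection
#'
#' Locates `alpha_c`, the strength above which the subgraph is no longer
#' allowed (either unstable or infeasible), by bisection on the combined
#' feasibility-and-stability predicate. In the homogeneous case the scanned
#' strength multiplies the adjacency (`W = alpha A`); with heterogeneous
#' strengths the mean is scanned by shifting every edge by a common additive
#' constant (`mode = "shift"`, the default) or by multiplicative scaling
#' (`mode = "scale"`).
#'
#' @inheritParams subgraph_fixed_point
#' @param strengths `NULL` for the homogeneous case, or a symmetric matrix of
#'   per-edge strengths whose mean is scanned.
#' @param alpha_range scan interval; the subgraph must be allowed at its
#'   lower end. No tree is allowed above the two-chain bound `alpha = 1`, so
#'   the default upper bracket 2 is safe.
#' @param tol bisection tolerance on `alpha_c`.
#' @param mode how heterogeneous strengths are scanned.
#' @return A `subgraph_record`: `alpha_c` (possibly `Inf`),
#'   `limiting_condition` (`"feasibility"` or `"stability"`),
#'   `extinction_vertex` (the species whose abundance vanishes at `alpha_c`,
#'   when feasibility-limited), the adjacency and strengths, and the scanned
#'   `mode`.
#' @export
alpha_c_bisection <- function(adjacency, strengths = NULL,
                              alpha_range = c(0.01, 2), tol = 1e-8,
                              mode = c("shift", "scale")) {
  mode <- match.arg(mode)
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  Wf <- strength_fun(adjacency, strengths, mode)
  lo <- alpha_range[1]; hi <- alpha_range[2]
  if (!subgraph_allowed(adjacency, Wf(lo)))
    stopf("subgraph is not allowed at the lower end of alpha_range (%g)", lo)
  rec <- function(alpha_c, limiting, vertex) {
    structure(list(adjacency = adjacency, n = n, strengths = strengths,
                   mode = mode, alpha_c = alpha_c,
                   limiting_condition = limiting, extinction_vertex = vertex,
                   tol = tol),
              class = "subgraph_record")
  }
  if (subgraph_allowed(adjacency, Wf(hi)))
    return(rec(Inf, NA_character_, NA_integer_))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (subgraph_allowed(adjacency, Wf(mid))) lo <- mid else hi <- mid
  }
  alpha_c <- (lo + hi) / 2
  # which condition fails first just above alpha_c, and which species vanishes
  delta <- max(10 * tol, 1e-6)
  Wp <- Wf(alpha_c + delta)
  Mp <- diag(n) + Wp
  stable_above <- min(eigen(Mp, symmetric = TRUE, only.values = TRUE)$values) > 0
  Np <- tryCatch(solve(Mp, rep(1, n)), error = function(e) NULL)
  feasible_above <- !is.null(Np) && is_feasible(Np)
  if (!feasible_above && stable_above) {
    Nb <- subgraph_fixed_point(adjacency, Wf(alpha_c - delta))
    rec(alpha_c, "feasibility", which.min(Nb))
  } else {
    rec(alpha_c, "stability", NA_integer_)
  }
}

#' @export
print.subgraph_record <- function(x, ...) {
  cat(sprintf("<subgraph_record> n = %d, alpha_c = %.8g (%s%s)\n", x$n,
              x$alpha_c, x$limiting_condition %||% "unbounded",
              if (!is.na(x$extinction_vertex))
                sprintf(", vertex %d vanishes", x$extinction_vertex) else ""))
  invisible(x)
}

#' Closed-form critical strength of an n-species chain
#'
#' `alpha_chain(n) = 1 / (2 cos(pi / (n + 1)))` for even `n`, and `1/2` for
#' odd `n >= 3`. A singleton (`n = 1`) is allowed at every strength, so its
#' critical value is infinite. The even-chain sequence decreases strictly
#' towards the odd-chain value `1/2`; every tree that is not a chain has
#' `alpha_c <= 1/2`, so for strengths above one half only even chains (and
#' singletons) can appear in communities.
#'
#' @param n chain length(s), positive integer.
#' @return Numeric vector of critical strengths.
#' @export
chain_alpha_c <- function(n) {
  if (any(n < 1 | n != round(n))) stopf("chain length must be a positive integer")
  ifelse(n == 1, Inf, ifelse(n %% 2 == 0, 1 / (2 * cos(pi / (n + 1))), 0.5))
}

#' Small adjacency constructors
#'
#' Chains (paths), stars and cycles as base 0/1 matrices, for use with the
#' subgraph operations.
#'
#' @param n number of vertices (chain, cycle) or leaves (star).
#' @return Symmetric 0/1 adjacency matrix.
#' @export
adjacency_chain <- function(n) {
  A <- matrix(0, n, n)
  if (n > 1) for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

#' @rdname adjacency_chain
#' @export
adjacency_star <- function(n) {
  A <- matrix(0, n + 1, n + 1)
  A[1, -1] <- A[-1, 1] <- 1
  A
}

#' @rdname adjacency_chain
#' @export
adjacency_cycle <- function(n) {
  A <- adjacency_chain(n)
  A[1, n] <- A[n, 1] <- 1
  A
}

# Canonical string key of a small graph (isomorphism-invariant), via BLISS
# canonical labelling.
canonical_key <- function(adjacency) {
  g <- igraph::graph_from_adjacency_matrix(adjacency != 0, mode = "undirected")
  perm <- igraph::canonical_permutation(g)$labeling
  gc <- igraph::permute(g, perm)
  el <- igraph::as_edgelist(gc, names = FALSE)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste(igraph::vcount(g), paste(t(el), collapse = ","), sep = ":")
}

#' Catalogue of all non-isomorphic trees with their critical strengths
#'
#' Enumerates every free tree with up to `max_size` vertices (grown by leaf
#' addition, de-duplicated by canonical labelling) and computes each tree's
#' homogeneous critical strength `alpha_c` by feasibility/stability
#' bisection. The catalogue is sorted by decreasing `alpha_c`: singleton and
#' even chains first (the only trees allowed above strength one half), then
#' the branched trees.
#'
#' @param max_size largest tree size to enumerate (practical bound ~12).
#' @param tol bisection tolerance passed to [alpha_c_bisection()].
#' @return A `tree_catalogue`: a data frame (one row per isomorphism class
#'   with `id`, `size`, `alpha_c`, `limiting_condition`, `extinction_vertex`,
#'   `is_chain`, `degree_sequence`, `canon`) carrying the adjacency matrices
#'   and records as attributes `adjacency` and `records`.
#' @export
enumerate_trees <- function(max_size, tol = 1e-8) {
  stopifnot(max_size >= 1)
  by_size <- list(list(matrix(0, 1, 1)))
  if (max_size >= 2) {
    for (k in 2:max_size) {
      seen <- character(0)
      out <- list()
      for (adj in by_size[[k - 1]]) {
        for (v in seq_len(k - 1)) {
          A <- matrix(0, k, k)
          A[seq_len(k - 1), seq_len(k - 1)] <- adj
          A[v, k] <- A[k, v] <- 1
          key <- canonical_key(A)
          if (!key %in% seen) {
            seen <- c(seen, key)
            out[[length(out) + 1]] <- A
          }
        }
      }
      by_size[[k]] <- out
    }
  }
  adjs <- do.call(c, by_size)
  records <- lapply(adjs, function(A)
    alpha_c_bisection(A, alpha_range = c(0.01, 2), tol = tol))
  df <- data.frame(
    size = vapply(adjs, nrow, 1L),
    alpha_c = vapply(records, `[[`, 1.0, "alpha_c"),
    limiting_condition = vapply(records, function(r)
      r$limiting_condition %||% NA_character_, ""),
    extinction_vertex = vapply(records, `[[`, 1L, "extinction_vertex"),
    is_chain = vapply(adjs, function(A) all(rowSums(A) <= 2), TRUE),
    degree_sequence = vapply(adjs, function(A)
      paste(sort(rowSums(A)), collapse = "+"), ""),
    canon = vapply(adjs, canonical_key, ""))
  ord <- order(-df$alpha_c, df$size)
  df <- df[ord, , drop = FALSE]
  df$id <- seq_len(nrow(df))
  rownames(df) <- NULL
  df <- df[, c("id", "size", "alpha_c", "limiting_condition",
               "extinction_vertex", "is_chain", "degree_sequence", "canon")]
  attr(df, "adjacency") <- adjs[ord]
  attr(df, "records") <- records[ord]
  class(df) <- c("tree_catalogue", "data.frame")
  df
}

#' Trees allowed at a given homogeneous strength
#'
#' @param catalogue a [enumerate_trees()] catalogue.
#' @param alpha interaction strength.
#' @return The catalogue rows with `alpha_c > alpha`.
#' @export
allowed_trees <- function(catalogue, alpha) {
  stopifnot(inherits(catalogue, "tree_catalogue"))
  keep <- catalogue$alpha_c > alpha
  out <- catalogue[keep, , drop = FALSE]
  attr(out, "adjacency") <- attr(catalogue, "adjacency")[keep]
  out
}

#' Check the subgraph emergence (splitting) rule at a critical strength
#'
#' With heterogeneous strengths, a subgraph generically loses *feasibility*
#' (not stability) at its `alpha_c`: exactly one species' abundance vanishes
#' continuously as `alpha -> alpha_c`, and removing that species splits the
#' subgraph into components that are each still allowed just above
#' `alpha_c`. For a tree with a branching point the vanishing species is a
#' branching point (degree at least 3), so the tree splits into three or
#' more allowed trees; chains, which have no branching point, lose an
#' interior species and split into two. This function verifies all parts
#' numerically for one subgraph.
#'
#' @inheritParams alpha_c_bisection
#' @param strengths symmetric matrix of heterogeneous per-edge strengths.
#' @param eps offset below/above `alpha_c` used for the continuity and
#'   allowedness checks.
#' @return A list with `status` (`"pass"` when exactly one abundance
#'   vanishes continuously and every remaining component is allowed;
#'   `"fail"`; or `"not-feasibility-limited"` when the precondition does
#'   not hold, e.g. for a degenerate homogeneous even chain), `alpha_c`,
#'   `vanishing_vertex`, `vanish_ratio` (how fast the minimal abundance
#'   shrinks as the offset shrinks 100-fold; ~0.01 for linear vanishing),
#'   `component_sizes`, `components_allowed`, `branching_degree`,
#'   `branching_rule_holds` (`NA` when the tree has no branching point),
#'   and, on failure, the offending inputs under `offending`.
#' @export
emergence_split_check <- function(adjacency, strengths,
                                  alpha_range = c(0.01, 2), eps = 1e-6) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  rec <- alpha_c_bisection(adjacency, strengths, alpha_range = alpha_range,
                           tol = 1e-10)
  if (is.infinite(rec$alpha_c) || rec$limiting_condition != "feasibility") {
    return(list(status = "not-feasibility-limited", alpha_c = rec$alpha_c,
                limiting_condition = rec$limiting_condition))
  }
  Wf <- strength_fun(adjacency, strengths, rec$mode)
  N_far <- subgraph_fixed_point(adjacency, Wf(rec$alpha_c - 100 * eps))
  N_near <- subgraph_fixed_point(adjacency, Wf(rec$alpha_c - eps))
  v <- which.min(N_near)
  vanish_ratio <- N_near[v] / N_far[v]
  others_clear <- n == 1 || min(N_near[-v]) > 100 * N_near[v]
  vanishes <- vanish_ratio < 0.1 && others_clear
  # split: components of the subgraph with the vanishing vertex removed,
  # each inspected with its inherited strengths just above alpha_c
  W_above <- Wf(rec$alpha_c + eps)
  keep <- setdiff(seq_len(n), v)
  g_rest <- igraph::graph_from_adjacency_matrix(
    adjacency[keep, keep, drop = FALSE] != 0, mode = "undirected")
  comp <- igraph::components(g_rest)
  comps <- split(keep, comp$membership)
  comp_ok <- vapply(comps, function(idx)
    subgraph_allowed(adjacency[idx, idx, drop = FALSE],
                     W_above[idx, idx, drop = FALSE]), TRUE)
  is_tree <- sum(adjacency) / 2 == n - 1
  branch_deg <- sum(adjacency[v, ])
  # The branching-point rule presupposes a branching point exists (a chain
  # has none: its interior species vanishes, splitting it into two allowed
  # pieces), and holds for narrow strength distributions; at finite width
  # it can be violated, so it is reported rather than folded into `status`.
  branching_applicable <- is_tree && any(rowSums(adjacency) >= 3)
  ok <- vanishes && all(comp_ok)
  out <- list(status = if (ok) "pass" else "fail",
              alpha_c = rec$alpha_c, vanishing_vertex = v,
              vanish_ratio = vanish_ratio,
              component_sizes = lengths(comps),
              components_allowed = unname(comp_ok),
              branching_degree = branch_deg, is_tree = is_tree,
              branching_applicable = branching_applicable,
              branching_rule_holds = if (branching_applicable)
                branch_deg >= 3 else NA)
  if (!ok) out$offending <- list(adjacency = adjacency, strengths = strengths)
  out
}

#' Sample a random free tree with heterogeneous edge strengths
#'
#' Uniform-ish random labelled tree (random attachment) with per-edge
#' strengths drawn from a normal distribution with the given mean and
#' standard deviation; used to probe the emergence rule over an ensemble of
#' heterogeneous trees.
#'
#' @param n number of vertices.
#' @param mean,sd strength distribution parameters.
#' @param seed optional integer seed.
#' @return List with `adjacency` and `strengths` matrices.
#' @export
random_heterogeneous_tree <- function(n, mean = 0.5, sd = 0.05, seed = NULL) {
  set_seed_if(seed)
  A <- matrix(0, n, n)
  if (n > 1) {
    for (k in 2:n) {
      v <- if (k == 2) 1L else sample.int(k - 1, 1)
      A[v, k] <- A[k, v] <- 1
    }
  }
  W <- matrix(0, n, n)
  up <- which(upper.tri(A) & A == 1)
  w <- rnorm(length(up), mean, sd)
  while (any(bad <- w < 0)) w[bad] <- rnorm(sum(bad), mean, sd)
  W[up] <- w
  W <- W + t(W)
  list(adjacency = A, strengths = W)
}
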