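# Ensemble-level experiments: diversity sweeps over the interaction
# strength, jump detection against the tree catalogue, the
# unique-to-multiple-equilibria transition, and the percolation transition
# with its finite-size-scaling estimator.

run_one_realization <- function(spec, alpha, real_seed, params, n_inits) {
  matrix <- sample_ensemble(spec, alpha, seed = real_seed)
  out <- vector("list", n_inits)
  for (k in seq_len(n_inits)) {
    st <- withCallingHandlers(
      integrate_assembly(matrix, params, seed = derive_seed(real_seed, 10L + k)),
      warning = function(w) invokeRestart("muffleWarning"))
    if (st$verified) {
      decomp <- persistent_components(matrix$graph, st)
      n_tree <- sum(decomp$is_tree)
      out[[k]] <- data.frame(
        init = k, phi = st$phi,
        largest_fraction = decomp$largest_fraction,
        n_components = length(decomp$components),
        n_tree_components = n_tree,
        n_small_components = sum(decomp$sizes <= 2),
        converged = TRUE)
    } else {
      out[[k]] <- data.frame(init = k, phi = NA_real_,
                             largest_fraction = NA_real_,
                             n_components = NA_integer_,
                             n_tree_components = NA_integer_,
                             n_small_components = NA_integer_,
                             converged = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Relative diversity (and component observables) over an alpha grid
#'
#' For every interaction strength on the grid, samples `replicates`
#' realizations of the ensemble and assembles each from
#' `inits_per_replicate` random initial conditions to a verified
#' equilibrium, then aggregates the relative diversity `phi`, the
#' largest-component fraction, and the share of small (pair/singleton) tree
#' components. Non-converged runs are excluded from the aggregates and
#' counted.
#'
#' @param spec an [ensemble_spec].
#' @param alpha_grid increasing vector of interaction strengths.
#' @param replicates ensemble realizations per grid point.
#' @param inits_per_replicate initial conditions per realization (default 5).
#' @param seed integer seed; every realization and initial condition uses a
#'   deterministic sub-seed.
#' @param params an [assembly_params].
#' @return A `sweep_result`: `runs` (one row per alpha x replicate x init),
#'   `summary` (one row per alpha with means, standard deviations, standard
#'   errors, pooled pair/singleton percentage among tree components, and
#'   non-convergence counts), plus the spec, grid and seed.
#' @export
diversity_sweep <- function(spec, alpha_grid, replicates,
                            inits_per_replicate = 5, seed = NULL,
                            params = assembly_params()) {
  stopifnot(inherits(spec, "ensemble_spec"), replicates >= 1)
  alpha_grid <- sort(alpha_grid)
  rows <- list()
  cell <- 0L
  for (ai in seq_along(alpha_grid)) {
    for (rep in seq_len(replicates)) {
      cell <- cell + 1L
      real_seed <- derive_seed(seed, cell)
      df <- run_one_realization(spec, alpha_grid[ai], real_seed, params,
                                inits_per_replicate)
      df$alpha <- alpha_grid[ai]
      df$replicate <- rep
      rows[[cell]] <- df
    }
  }
  runs <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(alpha_grid, function(a) {
    d <- runs[runs$alpha == a & runs$converged, , drop = FALSE]
    n <- nrow(d)
    ntree <- sum(d$n_tree_components)
    data.frame(alpha = a, n_runs = n,
               phi_mean = mean(d$phi), phi_sd = sd(d$phi),
               phi_se = sd(d$phi) / sqrt(max(n, 1)),
               largest_mean = mean(d$largest_fraction),
               largest_se = sd(d$largest_fraction) / sqrt(max(n, 1)),
               pairs_singletons_pct = if (ntree > 0)
                 100 * sum(d$n_small_components) / ntree else NA_real_,
               n_nonconverged = sum(runs$alpha == a & !runs$converged))
  }))
  structure(list(runs = runs, summary = summary, spec = spec,
                 alpha_grid = alpha_grid, seed = seed,
                 inits_per_replicate = inits_per_replicate,
                 replicates = replicates),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s ensemble, S = %d, %d alpha values x %d replicates x %d inits\n",
              x$spec$type, x$spec$S, length(x$alpha_grid), x$replicates,
              x$inits_per_replicate))
  print(x$summary, digits = 4)
  invisible(x)
}

#' @rdname diversity_sweep
#' @details `heterogeneity_sweep()` is the same experiment for the
#'   heterogeneous ensembles (per-edge Gaussian strengths, `sigma > 0`, or
#'   Erdos-Renyi degree variation); it additionally requires that the spec
#'   actually carries heterogeneity.
#' @export
heterogeneity_sweep <- function(spec, alpha_grid, replicates,
                                inits_per_replicate = 5, seed = NULL,
                                params = assembly_params()) {
  if (spec$sigma <= 0 && spec$type != "er")
    stopf("heterogeneity_sweep needs sigma > 0 or an Erdos-Renyi topology")
  diversity_sweep(spec, alpha_grid, replicates, inits_per_replicate, seed,
                  params)
}

#' Critical strength of the unique-to-multiple-equilibria transition
#'
#' On random C-regular graphs with all-equal strengths the fully feasible
#' equilibrium (all abundances `1 / (1 + C alpha)`) is the unique
#' equilibrium exactly while the interaction matrix `I + alpha A` stays
#' positive definite. The spectral edge of a large random C-regular graph is
#' `-2 sqrt(C - 1)`, giving the closed form
#' `alpha_UE(C) = 1 / (2 sqrt(C - 1))`.
#'
#' @param C degree, `C >= 2`.
#' @return Critical strength.
#' @export
alpha_UE <- function(C) {
  if (any(C < 2)) stopf("alpha_UE requires C >= 2")
  1 / (2 * sqrt(C - 1))
}

#' Probability of a unique equilibrium over an alpha grid
#'
#' The community has a unique equilibrium exactly when its interaction
#' matrix is positive definite (the Lyapunov function is then concave, so
#' its maximum is global). The probability is the fraction of ensemble
#' realizations whose smallest eigenvalue of `alpha_ij` is positive. For
#' `sigma = 0` the topology eigenvalue is computed once per realization and
#' reused across the grid.
#'
#' @inheritParams diversity_sweep
#' @param replicates ensemble realizations per grid point.
#' @return Data frame with `alpha`, `p_unique`, `n_realizations`; the matrix
#'   of smallest eigenvalues (realization x alpha) is attached as attribute
#'   `"min_eig"`.
#' @export
uniqueness_probability <- function(spec, alpha_grid, replicates, seed = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  min_eig <- matrix(NA_real_, replicates, length(alpha_grid))
  for (rep in seq_len(replicates)) {
    real_seed <- derive_seed(seed, rep)
    if (spec$sigma == 0) {
      g <- switch(spec$type,
        regular = sample_regular_graph(spec$S, spec$C,
                                       seed = derive_seed(real_seed, 1L)),
        er = sample_er_graph(spec$S, spec$C, seed = derive_seed(real_seed, 1L)),
        full = full_graph(spec$S))
      A <- as.matrix(igraph::as_adjacency_matrix(g$graph, sparse = TRUE))
      lam_min <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
      min_eig[rep, ] <- 1 + alpha_grid * lam_min
    } else {
      for (ai in seq_along(alpha_grid)) {
        m <- sample_ensemble(spec, alpha_grid[ai], seed = real_seed)
        min_eig[rep, ai] <- min(eigen(as.matrix(m$matrix), symmetric = TRUE,
                                      only.values = TRUE)$values)
      }
    }
  }
  out <- data.frame(alpha = alpha_grid,
                    p_unique = colMeans(min_eig > 0),
                    n_realizations = replicates)
  attr(out, "min_eig") <- min_eig
  out
}

#' Cross-check the uniqueness criterion against multistart dynamics
#'
#' For each realization near the transition, compares three per-realization
#' statements that the theory says coincide on regular graphs with all-equal
#' strengths: (i) the spectral criterion (interaction matrix positive
#' definite), (ii) multistart dynamics from `n_starts` random initial
#' conditions all converging to one equilibrium, and (iii) that equilibrium
#' being fully feasible (`phi = 1`).
#'
#' @inheritParams diversity_sweep
#' @param alphas strengths to probe (e.g. inside `[0.35, 0.36]` for C = 3).
#' @param replicates realizations per strength.
#' @param n_starts initial conditions per realization (default 30).
#' @return Data frame with one row per (alpha, realization): `spectral`,
#'   `unique_dynamics`, `fully_feasible`, `n_distinct`, `all_converged`.
#' @export
uniqueness_crosscheck <- function(spec, alphas, replicates, n_starts = 30,
                                  seed = NULL, params = assembly_params()) {
  rows <- list()
  cell <- 0L
  for (a in alphas) {
    for (rep in seq_len(replicates)) {
      cell <- cell + 1L
      real_seed <- derive_seed(seed, 5000L + cell)
      m <- sample_ensemble(spec, a, seed = real_seed)
      lam_min <- min(eigen(as.matrix(m$matrix), symmetric = TRUE,
                           only.values = TRUE)$values)
      ms <- withCallingHandlers(
        multistart_assembly(m, params, n_starts = n_starts,
                            seed = derive_seed(real_seed, 3L)),
        warning = function(w) invokeRestart("muffleWarning"))
      ff <- any(vapply(ms$states, function(s) s$verified && s$phi == 1, TRUE))
      rows[[cell]] <- data.frame(
        alpha = a, replicate = rep, spectral = lam_min > 0,
        unique_dynamics = ms$n_distinct == 1 && ms$all_converged,
        fully_feasible = ff, n_distinct = ms$n_distinct,
        all_converged = ms$all_converged)
    }
  }
  do.call(rbind, rows)
}

#' Percolation threshold by finite-size scaling of the largest component
#'
#' At the percolation transition of a random regular graph the relative size
#' of the largest component scales as `S^(-1/3)`, so curves of
#' `f(alpha, S) * S^(1/3)` for different pool sizes cross at `alpha_perc`
#' (below it the rescaled curves rise with `S`, above it they fall). The
#' estimator interpolates each pair of curves linearly in `alpha`, averages
#' the pairwise crossings, and bootstraps over replicates for the
#' uncertainty.
#'
#' @inheritParams diversity_sweep
#' @param S_list pool sizes (at least 3, spanning a factor of ~4).
#' @param replicates realizations per (alpha, S) cell (one initial condition
#'   each).
#' @param n_boot bootstrap resamples for the uncertainty.
#' @return A list: `alpha_perc`, `se`, `crossings` (pairwise), `scaled`
#'   (data frame of `f * S^(1/3)` by alpha and S), `runs`, and `status`
#'   (`"ok"` or `"bracketing-failure"` when no pair of curves crosses inside
#'   the grid).
#' @export
percolation_estimate <- function(spec, alpha_grid, S_list, replicates,
                                 seed = NULL, params = assembly_params(),
                                 n_boot = 200) {
  stopifnot(length(S_list) >= 2)
  alpha_grid <- sort(alpha_grid)
  rows <- list()
  cell <- 0L
  for (S in S_list) {
    spec_S <- ensemble_spec(spec$type, S, spec$C, spec$sigma)
    for (ai in seq_along(alpha_grid)) {
      for (rep in seq_len(replicates)) {
        cell <- cell + 1L
        real_seed <- derive_seed(seed, 90000L + cell)
        df <- run_one_realization(spec_S, alpha_grid[ai], real_seed, params, 1L)
        rows[[cell]] <- data.frame(S = S, alpha = alpha_grid[ai],
                                   replicate = rep, f = df$largest_fraction,
                                   converged = df$converged)
      }
    }
  }
  runs <- do.call(rbind, rows)
  est <- function(d) {
    fm <- tapply(d$f, list(d$alpha, d$S), mean, na.rm = TRUE)
    g <- sweep(fm, 2, as.numeric(colnames(fm))^(1 / 3), `*`)
    a <- as.numeric(rownames(g))
    pairs <- utils::combn(ncol(g), 2)
    cross <- apply(pairs, 2, function(p) {
      h <- g[, p[1]] - g[, p[2]]
      sc <- which(h[-length(h)] * h[-1] < 0)
      if (!length(sc)) return(NA_real_)
      i <- sc[1]
      a[i] + (a[i + 1] - a[i]) * h[i] / (h[i] - h[i + 1])
    })
    list(alpha = mean(cross, na.rm = TRUE), cross = cross, scaled = g)
  }
  ok <- runs[runs$converged, , drop = FALSE]
  point <- est(ok)
  boot <- replicate(n_boot, {
    res <- do.call(rbind, lapply(split(ok, list(ok$alpha, ok$S)), function(cell)
      cell[sample.int(nrow(cell), replace = TRUE), , drop = FALSE]))
    est(res)$alpha
  })
  status <- if (all(is.na(point$cross))) "bracketing-failure" else "ok"
  scaled <- as.data.frame(as.table(point$scaled))
  names(scaled) <- c("alpha", "S", "f_scaled")
  scaled$alpha <- as.numeric(as.character(scaled$alpha))
  scaled$S <- as.integer(as.character(scaled$S))
  list(alpha_perc = point$alpha, se = sd(boot, na.rm = TRUE),
       crossings = point$cross, scaled = scaled, runs = runs, status = status)
}

#' Detect diversity jumps and match them to critical tree strengths
#'
#' The diversity curve `phi(alpha)` is a staircase: plateaus of constant
#' diversity separated by jumps located exactly at the critical strengths of
#' the allowed trees (for strengths above one half, at the even-chain values
#' `alpha_chain(n)`). Detection compares the per-run diversities of adjacent
#' grid points with a Welch test; consecutive significant drops are merged
#' and each detected jump is matched to the nearest catalogue `alpha_c`.
#'
#' @param sweep a [diversity_sweep()] result on a fine grid.
#' @param catalogue an [enumerate_trees()] catalogue providing candidate
#'   critical strengths.
#' @param p_threshold significance level per adjacent-pair test (default
#'   `1e-3`; the within-plateau variability makes the true jumps orders of
#'   magnitude more significant than this).
#' @return A list: `jumps` (data frame with `location` = interval midpoint,
#'   `lower`, `upper`, `magnitude`, `p`, `matched_alpha_c`, `matched_id`,
#'   `matched` = whether the catalogue value lies inside the interval),
#'   `n_jumps`, and `resolution` (largest grid step).
#' @export
detect_jumps <- function(sweep, catalogue, p_threshold = 1e-3) {
  stopifnot(inherits(sweep, "sweep_result"))
  a <- sweep$alpha_grid
  if (length(a) < 2) stopf("grid too coarse: need at least two alpha values")
  runs <- sweep$runs[sweep$runs$converged, , drop = FALSE]
  tests <- lapply(seq_len(length(a) - 1), function(i) {
    x <- runs$phi[runs$alpha == a[i]]
    y <- runs$phi[runs$alpha == a[i + 1]]
    drop <- mean(x) - mean(y)   # phi is non-increasing in alpha
    p <- if (sd(x) == 0 && sd(y) == 0) as.numeric(drop == 0)
         else t.test(x, y)$p.value
    data.frame(lower = a[i], upper = a[i + 1], magnitude = drop, p = p,
               significant = p < p_threshold & drop > 0)
  })
  tests <- do.call(rbind, tests)
  sig <- which(tests$significant)
  jumps <- list()
  if (length(sig)) {
    grp <- cumsum(c(1, diff(sig) != 1))
    for (g in split(sig, grp)) {
      i <- g[which.max(tests$magnitude[g])]
      jumps[[length(jumps) + 1]] <- data.frame(
        location = (tests$lower[i] + tests$upper[i]) / 2,
        lower = tests$lower[min(g)], upper = tests$upper[max(g)],
        magnitude = sum(tests$magnitude[g]), p = min(tests$p[g]))
    }
  }
  jumps <- if (length(jumps)) do.call(rbind, jumps) else
    data.frame(location = numeric(0), lower = numeric(0), upper = numeric(0),
               magnitude = numeric(0), p = numeric(0))
  if (nrow(jumps)) {
    cand <- catalogue$alpha_c[is.finite(catalogue$alpha_c)]
    cand_id <- catalogue$id[is.finite(catalogue$alpha_c)]
    nearest <- vapply(jumps$location, function(x) which.min(abs(cand - x)), 1L)
    jumps$matched_alpha_c <- cand[nearest]
    jumps$matched_id <- cand_id[nearest]
    jumps$matched <- jumps$matched_alpha_c >= jumps$lower &
      jumps$matched_alpha_c <= jumps$upper
  } else {
    jumps$matched_alpha_c <- numeric(0)
    jumps$matched_id <- integer(0)
    jumps$matched <- logical(0)
  }
  list(jumps = jumps, n_jumps = nrow(jumps), resolution = max(diff(a)),
       tests = tests)
}
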