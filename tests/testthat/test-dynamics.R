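test_that("a lone species settles at its logistic fixed point", {
  g <- community_graph(igraph::make_empty_graph(1, directed = FALSE))
  st <- integrate_assembly(build_interactions(g, alpha = 0.5), init = 0.3)
  expect_true(st$verified)
  expect_equal(st$abundances, 1, tolerance = 1e-10)
})

test_that("an interacting pair coexists below strength one and excludes above it", {
  st <- integrate_assembly(im_pair(0.7), init = c(0.2, 0.9))
  expect_true(st$verified)
  expect_equal(st$abundances, rep(1 / 1.7, 2), tolerance = 1e-9)

  st <- integrate_assembly(im_pair(1.1), init = c(0.2, 0.9))
  expect_true(st$verified)
  expect_identical(st$persistent, c(FALSE, TRUE))
  expect_equal(st$abundances[2], 1, tolerance = 1e-10)
  expect_lt(st$abundances[1], 1e-5)
})

test_that("the fully feasible regular equilibrium has all abundances 1/(1 + C alpha)", {
  m <- sample_ensemble(ensemble_spec("regular", 60, 3), 0.3, seed = 13)
  st <- integrate_assembly(m, seed = 14)
  expect_true(st$verified)
  expect_equal(st$phi, 1)
  expect_equal(st$abundances, rep(1 / (1 + 3 * 0.3), 60), tolerance = 1e-9)
  diag <- verify_equilibrium(m, st)
  expect_true(all(abs(diag$persistent_residual) < 1e-10))
})

test_that("verification rejects states that are not true equilibria", {
  # an extinct species with only extinct neighbours can invade
  m <- im_from_adj(adjacency_chain(3), 0.7)
  bad <- structure(list(abundances = c(1, 1e-9, 1e-9),
                        persistent = c(TRUE, FALSE, FALSE)),
                   class = "equilibrium_state")
  diag <- verify_equilibrium(m, bad)
  expect_false(diag$verified)
  expect_gt(max(diag$invasion_rate), 0)  # the far end is unblocked

  # 3-chain with all three persistent is infeasible above alpha = 1/2
  m6 <- im_from_adj(adjacency_chain(3), 0.6)
  N <- solve(as.matrix(m6$matrix), rep(1, 3))
  expect_lt(N[2], 0)  # middle abundance (1 - 2a)/(1 - 2a^2) < 0
  forced <- structure(list(abundances = pmax(N, 0.01),
                           persistent = rep(TRUE, 3)),
                      class = "equilibrium_state")
  expect_false(verify_equilibrium(m6, forced)$verified)
})

test_that("multistart finds a unique equilibrium below alpha_UE and alternatives above 1", {
  m <- sample_ensemble(ensemble_spec("regular", 40, 3), 0.3, seed = 31)
  ms <- multistart_assembly(m, fast_params, n_starts = 8, seed = 5)
  expect_equal(ms$n_distinct, 1)
  expect_equal(ms$states[[1]]$phi, 1)  # the unique equilibrium is fully feasible

  ms2 <- multistart_assembly(im_pair(1.3), fast_params, n_starts = 20, seed = 6)
  expect_equal(ms2$n_distinct, 2)  # either species alone, by symmetry
})

test_that("a fully-interacting pool above strength one keeps a single persistent species per run", {
  m <- full_interaction_matrix(20, 1.1)
  ms <- multistart_assembly(m, fast_params, n_starts = 10, seed = 7)
  for (st in ms$states) {
    expect_true(st$verified)
    expect_equal(sum(st$persistent), 1)
  }
  expect_gt(ms$n_distinct, 1)
})

test_that("Lyapunov values match closed forms and grow along trajectories", {
  m <- im_pair(0.7)
  expect_equal(lyapunov_value(m, c(0, 0)), 0)
  expect_equal(lyapunov_value(m, c(1, 0)), 1)
  Np <- rep(1 / 1.7, 2)
  expect_equal(lyapunov_value(m, Np), 2 / 1.7, tolerance = 1e-12)

  for (seed in 1:3) {
    mt <- sample_ensemble(ensemble_spec("regular", 100, 3), 0.6, seed = seed)
    st <- integrate_assembly(mt, seed = 50 + seed, record_lyapunov = TRUE)
    expect_true(st$verified)
    expect_true(all(diff(st$lyapunov$F) > -1e-7))
  }
})

test_that("strong interactions produce a maximally independent persistent set", {
  m <- sample_ensemble(ensemble_spec("regular", 200, 3), 1.1, seed = 77)
  st <- integrate_assembly(m, seed = 78)
  expect_true(st$verified)
  A <- as.matrix(igraph::as_adjacency_matrix(m$graph$graph))
  pers <- st$persistent
  # no two adjacent species both persist
  expect_equal(sum(A[pers, pers]), 0)
  # every extinct species is blocked by at least one persistent neighbour
  expect_true(all(rowSums(A[!pers, pers, drop = FALSE]) >= 1))
})

test_that("equilibrium abundances depend only on interactions within the persistent subgraph", {
  m <- sample_ensemble(ensemble_spec("regular", 100, 3), 0.7, seed = 41)
  st <- integrate_assembly(m, seed = 42)
  expect_true(st$verified)
  ext <- which(!st$persistent)
  M2 <- as.matrix(m$matrix)
  # perturb a strength between two extinct species
  pair <- NULL
  for (i in ext) {
    js <- intersect(which(M2[i, ] > 0), ext)
    js <- js[js != i]
    if (length(js)) { pair <- c(i, js[1]); break }
  }
  expect_false(is.null(pair))
  M2[pair[1], pair[2]] <- M2[pair[2], pair[1]] <- 0.9
  m2 <- as_interaction_matrix(M2)
  st2 <- integrate_assembly(m2, init = st$abundances)
  expect_true(st2$verified)
  expect_identical(st2$persistent, st$persistent)
  expect_equal(st2$abundances[st$persistent], st$abundances[st$persistent],
               tolerance = 1e-9)
})

test_that("re-integrating from a verified equilibrium returns it unchanged", {
  m <- sample_ensemble(ensemble_spec("regular", 80, 3), 0.55, seed = 61)
  st <- integrate_assembly(m, seed = 62)
  expect_true(st$verified)
  st2 <- integrate_assembly(m, init = st$abundances)
  expect_identical(st2$persistent, st$persistent)
  expect_equal(st2$abundances, st$abundances, tolerance = 1e-9)
})

test_that("extinct species are reported in the vanishing-migration limit", {
  st <- integrate_assembly(im_pair(1.5), init = c(1, 0.999))
  expect_true(all(st$abundances >= 0))
  expect_equal(st$abundances[!st$persistent], 0)
  # at finite migration the excluded species retains a positive remnant
  expect_true(all(st$migration_remnant[!st$persistent] > 0))
  expect_true(all(st$migration_remnant[st$persistent] == 0))
})

test_that("invalid assembly parameters are rejected", {
  expect_error(assembly_params(growth_rates = 0), "positive")
  expect_error(assembly_params(migration = 1e-3), "below")
})
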