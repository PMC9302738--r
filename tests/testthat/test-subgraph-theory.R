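test_that("subgraph fixed points match closed forms", {
  expect_equal(subgraph_fixed_point(matrix(0, 1, 1), 0.7), 1)
  expect_equal(subgraph_fixed_point(adjacency_chain(2), 0.7), rep(1 / 1.7, 2),
               tolerance = 1e-12)
  a <- 0.4
  N <- subgraph_fixed_point(adjacency_chain(3), a)
  expect_equal(N, c((1 - a), (1 - 2 * a), (1 - a)) / (1 - 2 * a^2),
               tolerance = 1e-12)
  # middle abundance crosses zero at alpha = 1/2
  expect_equal(subgraph_fixed_point(adjacency_chain(3), 0.5)[2], 0,
               tolerance = 1e-12)
  expect_error(subgraph_fixed_point(adjacency_chain(2), 1), "singular")
})

test_that("feasibility and stability separate as expected on pairs and stars", {
  # pair: feasible at any alpha > 0, stable only below 1 (eigenvalues 1 +- a)
  expect_true(is_feasible(subgraph_fixed_point(adjacency_chain(2), 0.9)))
  expect_true(is_stable(adjacency_chain(2), 0.9))
  expect_true(is_feasible(subgraph_fixed_point(adjacency_chain(2), 1.1)))
  expect_false(is_stable(adjacency_chain(2), 1.1))
  # 3-star at 0.4: stable (1 - sqrt(3) * 0.4 > 0) but infeasible centre
  A <- adjacency_star(3)
  N <- subgraph_fixed_point(A, 0.4)
  expect_equal(N[1], (1 - 3 * 0.4) / (1 - 3 * 0.4^2), tolerance = 1e-12)
  expect_false(is_feasible(N))
  expect_true(is_stable(A, 0.4))
  # singleton: always allowed
  expect_true(subgraph_allowed(matrix(0, 1, 1), 5))
})

test_that("chain critical strengths follow the closed form", {
  expect_identical(chain_alpha_c(1), Inf)
  expect_equal(chain_alpha_c(2), 1)
  expect_equal(chain_alpha_c(3), 0.5)
  expect_equal(chain_alpha_c(4), 1 / (2 * cos(pi / 5)), tolerance = 1e-12)
  expect_equal(chain_alpha_c(4), 0.6180, tolerance = 1e-4)
  n_even <- seq(2, 20, by = 2)
  vals <- chain_alpha_c(n_even)
  expect_true(all(diff(vals) < 0))     # strictly decreasing
  expect_true(all(vals > 0.5))         # bounded below by the odd-chain value
  expect_equal(chain_alpha_c(seq(3, 19, by = 2)), rep(0.5, 9))
  expect_error(chain_alpha_c(0), "positive")
})

test_that("bisection agrees with the chain closed form to 1e-6 for n = 2..10", {
  for (n in 2:10) {
    rec <- alpha_c_bisection(adjacency_chain(n), tol = 1e-8)
    expect_lt(abs(rec$alpha_c - chain_alpha_c(n)), 1e-6)
    expect_identical(rec$limiting_condition,
                     if (n %% 2 == 0) "stability" else "feasibility")
  }
})

test_that("bisection brackets are sound: allowed just below alpha_c, not above", {
  eps <- 1e-4
  cases <- list(adjacency_chain(2), adjacency_chain(4), adjacency_chain(5),
                adjacency_star(3), adjacency_star(4))
  for (A in cases) {
    rec <- alpha_c_bisection(A)
    expect_true(subgraph_allowed(A, (rec$alpha_c - eps) * (A != 0)))
    expect_false(subgraph_allowed(A, (rec$alpha_c + eps) * (A != 0)))
  }
})

test_that("the 3-star is feasibility-limited at 1/3 with the centre vanishing", {
  rec <- alpha_c_bisection(adjacency_star(3))
  expect_equal(rec$alpha_c, 1 / 3, tolerance = 1e-7)
  expect_identical(rec$limiting_condition, "feasibility")
  expect_equal(rec$extinction_vertex, 1L)  # the centre
})

test_that("the tree catalogue enumerates isomorphism classes with their alpha_c", {
  cat3 <- enumerate_trees(3)
  expect_equal(nrow(cat3), 3)
  expect_equal(cat3$alpha_c, c(Inf, 1, 0.5), tolerance = 1e-7)

  cat4 <- enumerate_trees(4)
  expect_equal(nrow(cat4), 5)  # + 4-chain and 3-star
  expect_equal(sort(cat4$alpha_c[cat4$size == 4]),
               c(1 / 3, 1 / (2 * cos(pi / 5))), tolerance = 1e-7)

  # free-tree counts 1, 1, 1, 2, 3, 6, 11 up to size 7
  cat7 <- enumerate_trees(7)
  expect_equal(as.integer(table(cat7$size)), c(1, 1, 1, 2, 3, 6, 11))
  # sorted by decreasing alpha_c
  expect_true(all(diff(cat7$alpha_c) <= 1e-12))
  # every non-chain tree has alpha_c <= 1/2, the first ones exactly at 1/2
  nonchain <- cat7[!cat7$is_chain, ]
  expect_true(all(nonchain$alpha_c <= 0.5 + 1e-7))
  expect_equal(max(nonchain$alpha_c), 0.5, tolerance = 1e-7)
  # only even chains (and the singleton) are allowed above 1/2
  above <- cat7[cat7$alpha_c > 0.5 + 1e-7, ]
  expect_true(all(above$is_chain))
  expect_true(all(above$size %% 2 == 0 | above$size == 1))
})

test_that("allowed_trees filters the catalogue by strength", {
  cat6 <- enumerate_trees(6)
  at <- allowed_trees(cat6, 0.7)
  expect_true(all(at$alpha_c > 0.7))
  expect_equal(sort(at$size), c(1, 2))  # singleton and pair only
  expect_equal(sort(allowed_trees(cat6, 0.57)$size), c(1, 2, 4))
})

test_that("stability via the spectrum agrees with random quadratic-form probes", {
  set.seed(99)
  for (k in 1:6) {
    tr <- random_heterogeneous_tree(7, mean = 0.45, sd = 0.1, seed = 300 + k)
    a <- runif(1, 0.2, 0.9)
    W <- strength_matrix <- tr$strengths + (a - mean(tr$strengths[tr$adjacency == 1]))
    W <- W * tr$adjacency
    M <- diag(7) + W
    spectral <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) > 0
    v <- matrix(rnorm(7 * 1000), 7)
    probe <- all(colSums(v * (M %*% v)) > 0)
    expect_identical(is_stable(tr$adjacency, W), spectral)
    if (spectral) expect_true(probe)
  }
})

test_that("heterogeneous trees lose feasibility, not stability, at alpha_c", {
  n_fail_stability <- 0
  for (k in 1:60) {
    tr <- random_heterogeneous_tree(sample(4:8, 1), mean = 0.4, sd = 0.05,
                                    seed = 1000 + k)
    rec <- alpha_c_bisection(tr$adjacency, tr$strengths)
    if (is.finite(rec$alpha_c) && rec$limiting_condition != "feasibility")
      n_fail_stability <- n_fail_stability + 1
  }
  expect_equal(n_fail_stability, 0)
})

test_that("the emergence rule holds on random heterogeneous trees", {
  # single species vanishes at alpha_c; the remainder splits into allowed
  # pieces; for trees the vanishing species is a branching point
  statuses <- character(0)
  branch_holds <- logical(0)
  for (k in 1:40) {
    tr <- random_heterogeneous_tree(sample(5:9, 1), mean = 0.45, sd = 0.05,
                                    seed = 2000 + k)
    chk <- emergence_split_check(tr$adjacency, tr$strengths)
    statuses <- c(statuses, chk$status)
    if (chk$status == "pass") {
      expect_true(all(chk$components_allowed))
      if (isTRUE(chk$branching_rule_holds)) {
        # splitting at a branching point yields >= 3 pieces
        expect_gte(length(chk$component_sizes), 3)
      }
      if (!chk$branching_applicable) {
        # chains have no branching point and split into at most two pieces
        expect_lte(length(chk$component_sizes), 2)
      }
      if (chk$branching_applicable)
        branch_holds <- c(branch_holds, chk$branching_rule_holds)
    }
  }
  expect_true(all(statuses %in% c("pass", "not-feasibility-limited")))
  expect_gt(mean(statuses == "pass"), 0.8)
  # the branching-point rule holds for most branched trees at narrow sigma
  expect_gt(mean(branch_holds), 0.9)
})

test_that("a perturbed heterogeneous 3-star splits into three singletons at its alpha_c", {
  set.seed(4)
  A <- adjacency_star(3)
  W <- A * 0.4
  W[1, 2] <- W[2, 1] <- 0.43
  W[1, 3] <- W[3, 1] <- 0.38
  chk <- emergence_split_check(A, W)
  expect_identical(chk$status, "pass")
  expect_equal(chk$vanishing_vertex, 1L)  # the centre
  expect_equal(sort(unname(chk$component_sizes)), c(1, 1, 1))
})

test_that("degenerate homogeneous even chains are reported as not feasibility-limited", {
  A <- adjacency_chain(4)
  chk <- emergence_split_check(A, A * 0.5)
  expect_identical(chk$status, "not-feasibility-limited")
  expect_identical(chk$limiting_condition, "stability")
})
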