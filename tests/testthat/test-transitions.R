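test_that("alpha_UE follows the spectral-edge closed form", {
  expect_equal(alpha_UE(2), 0.5)
  expect_equal(alpha_UE(3), 1 / (2 * sqrt(2)))
  expect_gt(alpha_UE(3), 0.35)
  expect_lt(alpha_UE(3), 0.36)
  expect_lt(alpha_UE(100), 0.06)  # shrinks to zero at large connectivity
  expect_error(alpha_UE(1), "C >= 2")
})

test_that("the spectral uniqueness probability is a sharp step around alpha_UE", {
  spec <- ensemble_spec("regular", 400, 3)
  up <- uniqueness_probability(spec, c(0.30, 0.40), replicates = 12, seed = 3)
  expect_equal(up$p_unique[up$alpha == 0.30], 1)
  expect_equal(up$p_unique[up$alpha == 0.40], 0)
  # spectral edge of large 3-regular graphs: min eig of alpha_ij near 1 - 2 a sqrt(2)
  me <- attr(up, "min_eig")
  expect_lt(abs(mean(me[, 1]) - (1 - 2 * 0.30 * sqrt(2))), 0.02)
})

test_that("the uniqueness transition sharpens with pool size", {
  grid <- seq(0.30, 0.42, by = 0.01)
  width <- sapply(c(100, 400), function(S) {
    up <- uniqueness_probability(ensemble_spec("regular", S, 3), grid,
                                 replicates = 40, seed = 5)
    sum(up$p_unique > 0.05 & up$p_unique < 0.95) # grid cells in the sigmoid
  })
  expect_lte(width[2], width[1])
})

test_that("diversity sweeps reproduce the plateau and the dense baseline", {
  sw <- diversity_sweep(ensemble_spec("regular", 150, 3), c(0.7, 0.9),
                        replicates = 12, inits_per_replicate = 2, seed = 11)
  s <- sw$summary
  # same plateau: means statistically indistinguishable (3 combined SEs)
  expect_lt(abs(s$phi_mean[1] - s$phi_mean[2]),
            3 * sqrt(s$phi_se[1]^2 + s$phi_se[2]^2))
  expect_true(all(s$largest_mean <= s$phi_mean))
  expect_equal(s$n_nonconverged, c(0, 0))

  swf <- diversity_sweep(ensemble_spec("full", 50), 0.5, replicates = 3,
                         inits_per_replicate = 2, seed = 12)
  expect_equal(swf$summary$phi_mean, 1)
  expect_equal(swf$summary$phi_sd, 0)
})

test_that("phi decreases across the two-chain jump at alpha = 1", {
  sw <- diversity_sweep(ensemble_spec("regular", 150, 3), c(0.95, 1.2),
                        replicates = 12, inits_per_replicate = 2, seed = 13)
  s <- sw$summary
  expect_gt(s$phi_mean[1] - s$phi_mean[2],
            3 * sqrt(sum(s$phi_se^2)))
})

test_that("phi estimates are S-independent at large S", {
  phi_by_S <- lapply(c(200, 400), function(S)
    diversity_sweep(ensemble_spec("regular", S, 3), 0.7, replicates = 15,
                    inits_per_replicate = 1, seed = 17)$summary)
  d <- abs(phi_by_S[[1]]$phi_mean - phi_by_S[[2]]$phi_mean)
  se <- sqrt(phi_by_S[[1]]$phi_se^2 + phi_by_S[[2]]$phi_se^2)
  expect_lt(d, 3 * se)
})

test_that("jump detection finds the two-chain jump and stays quiet inside a plateau", {
  cat6 <- enumerate_trees(6)
  sw <- diversity_sweep(ensemble_spec("regular", 150, 3),
                        seq(0.95, 1.05, by = 0.02), replicates = 12,
                        inits_per_replicate = 2, seed = 19)
  res <- detect_jumps(sw, cat6)
  expect_equal(res$n_jumps, 1)
  expect_lt(abs(res$jumps$location[1] - 1), res$resolution)
  expect_equal(res$jumps$matched_alpha_c[1], 1, tolerance = 1e-6)
  expect_true(res$jumps$matched[1])

  sw_plateau <- diversity_sweep(ensemble_spec("regular", 150, 3),
                                seq(0.70, 0.80, by = 0.02), replicates = 12,
                                inits_per_replicate = 2, seed = 23)
  res2 <- detect_jumps(sw_plateau, cat6)
  expect_equal(res2$n_jumps, 0)
})

test_that("heterogeneous sweeps report the small-tree share and broaden the jump", {
  spec <- ensemble_spec("regular", 150, 3, sigma = 0.1)
  sw <- heterogeneity_sweep(spec, 0.7, replicates = 10,
                            inits_per_replicate = 1, seed = 29)
  expect_gt(sw$summary$pairs_singletons_pct, 95)
  expect_error(heterogeneity_sweep(ensemble_spec("regular", 100, 3), 0.7,
                                   replicates = 2, seed = 1),
               "sigma > 0")
})

test_that("with heterogeneity phi drops below one while the equilibrium is still unique", {
  # sigma > 0: loss of full feasibility precedes loss of uniqueness
  spec <- ensemble_spec("regular", 150, 3, sigma = 0.1)
  a_probe <- 0.27  # below the heterogeneous uniqueness transition
  sw <- diversity_sweep(spec, a_probe, replicates = 10,
                        inits_per_replicate = 1, seed = 31)
  up <- uniqueness_probability(spec, a_probe, replicates = 10, seed = 31)
  expect_lt(sw$summary$phi_mean, 1)          # not fully feasible
  expect_gt(up$p_unique, 0.8)                # but still a unique equilibrium
  # whereas at sigma = 0 phi stays exactly 1 below alpha_UE
  sw0 <- diversity_sweep(ensemble_spec("regular", 150, 3), a_probe,
                         replicates = 10, inits_per_replicate = 1, seed = 33)
  expect_equal(sw0$summary$phi_mean, 1)
})

test_that("the percolation estimator recovers a crossing near 0.41 at reduced scale", {
  pe <- percolation_estimate(ensemble_spec("regular", 100, 3),
                             alpha_grid = seq(0.37, 0.45, by = 0.04),
                             S_list = c(50, 100, 200), replicates = 12,
                             seed = 37, n_boot = 50)
  expect_identical(pe$status, "ok")
  expect_gt(pe$alpha_perc, 0.35)
  expect_lt(pe$alpha_perc, 0.47)
  # above the transition the rescaled size falls with S, below it rises
  g <- pe$scaled
  top <- g[g$alpha == 0.45, ]
  expect_gt(top$f_scaled[top$S == 50], top$f_scaled[top$S == 200])
})

test_that("percolation bracketing failure is reported, not invented", {
  pe <- percolation_estimate(ensemble_spec("regular", 100, 3),
                             alpha_grid = c(0.55, 0.60), S_list = c(50, 100),
                             replicates = 6, seed = 41, n_boot = 10)
  expect_identical(pe$status, "bracketing-failure")
  expect_true(is.na(pe$alpha_perc))
})
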