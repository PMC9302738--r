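#' Parameters of the assembly dynamics
#'
#' Controls the Lotka-Volterra assembly integration
#' `dN_i/dt = r_i N_i (1 - sum_j alpha_ij N_j) + lambda_i`.
#' Migration is kept far below the extinction threshold so the dynamics
#' approximates the limit of vanishing migration: every species that can
#' invade eventually does, and equilibria are uninvadable.
#'
#' @param growth_rates per-species growth rates `r_i` (recycled; all positive).
#'   Their values do not affect the set of stable equilibria; default 1.
#' @param migration migration rate `lambda` (default `1e-10`).
#' @param extinction_threshold abundance below which a species counts as
#'   extinct (default `1e-5`).
#' @param convergence_tolerance the integration is considered settled once
#'   `max_i |dN_i/dt|` falls below this (default `1e-10`); an exact Newton
#'   polish of the persistent set is then applied before verification.
#' @param max_time integration horizon; non-convergence within it is reported
#'   explicitly, never returned silently as an equilibrium (default `1e6`).
#' @param residual_tolerance verification tolerance on the persistent-species
#'   linear residual `1 - sum_j alpha_ij N_j` (default `1e-8`).
#' @param rtol,atol relative/absolute local error control of the adaptive
#'   Runge-Kutta stepper.
#' @return An object of class `assembly_params`.
#' @export
assembly_params <- function(growth_rates = 1, migration = 1e-10,
                            extinction_threshold = 1e-5,
                            convergence_tolerance = 1e-10,
                            max_time = 1e6,
                            residual_tolerance = 1e-8,
                            rtol = 1e-6, atol = 1e-12) {
  if (any(growth_rates <= 0)) stopf("all growth rates must be strictly positive")
  if (migration <= 0) stopf("migration must be positive")
  if (migration >= extinction_threshold)
    stopf("migration must be far below the extinction threshold")
  structure(list(growth_rates = growth_rates, migration = migration,
                 extinction_threshold = extinction_threshold,
                 convergence_tolerance = convergence_tolerance,
                 max_time = max_time, residual_tolerance = residual_tolerance,
                 rtol = rtol, atol = atol),
            class = "assembly_params")
}

# Newton polish: classify persistent species by the extinction threshold,
# solve the restricted linear system (migration set to 0) exactly, dropping
# species whose polished abundance falls below threshold, then check
# stability (positive definiteness of the persistent block) and strict
# uninvadability of every extinct species.
polish_equilibrium <- function(M, N, params) {
  S <- length(N)
  th <- params$extinction_threshold
  r <- rep_len(params$growth_rates, S)
  pers <- N >= th
  if (!any(pers)) return(list(ok = FALSE, why = "no persistent species"))
  for (iter in 1:100) {
    idx <- which(pers)
    Mpp <- as.matrix(M[idx, idx, drop = FALSE])
    x <- tryCatch(solve(Mpp, rep(1, length(idx))), error = function(e) NULL)
    if (is.null(x)) return(list(ok = FALSE, why = "singular persistent block"))
    if (any(x < th)) {
      pers[idx[x < th]] <- FALSE
      if (!any(pers)) return(list(ok = FALSE, why = "no persistent species"))
      next
    }
    break
  }
  stable <- !inherits(tryCatch(chol(Mpp), error = function(e) e), "error")
  if (!stable) return(list(ok = FALSE, why = "persistent block not positive definite"))
  Neq <- numeric(S)
  Neq[idx] <- x
  s <- as.numeric(M %*% Neq)
  ext <- which(!pers)
  remnant <- numeric(S)
  if (length(ext)) {
    deficit <- s[ext] - 1           # invasion rate of extinct i is -r_i * deficit_i
    if (any(deficit <= 1e-12))
      return(list(ok = FALSE, why = "invadable extinct species"))
    # abundance a strictly-uninvadable species retains at finite migration;
    # it vanishes in the lambda -> 0+ limit, in which the equilibrium is
    # reported (near-marginal deficits can park the remnant above the
    # extinction threshold even though the species is excluded)
    remnant[ext] <- params$migration / (r[ext] * deficit)
  }
  list(ok = TRUE, N = Neq, persistent = pers, migration_remnant = remnant)
}

new_equilibrium_state <- function(matrix, N, persistent, params, time, steps,
                                  converged, lyap = NULL, remnant = NULL) {
  state <- structure(
    list(abundances = N, persistent = persistent,
         phi = mean(persistent), verified = FALSE, converged = converged,
         residuals = NULL, time = time, steps = steps,
         extinction_threshold = params$extinction_threshold,
         migration_remnant = remnant, lyapunov = lyap),
    class = "equilibrium_state")
  diag <- verify_equilibrium(matrix, state, tolerance = params$residual_tolerance)
  state$residuals <- diag
  state$verified <- diag$verified && converged
  state
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("<equilibrium_state> S = %d, persistent = %d (phi = %.4g), %s\n",
              length(x$abundances), sum(x$persistent), x$phi,
              if (x$verified) "verified" else "NOT verified"))
  invisible(x)
}

#' Integrate the assembly dynamics to a verified equilibrium
#'
#' Runs the symmetric competitive Lotka-Volterra equations with small
#' migration from the given initial abundances, using an adaptive embedded
#' Runge-Kutta stepper (compiled), until abundance changes are negligible;
#' the persistent set is then polished by an exact solve of its linear system
#' and the result verified: persistent species satisfy
#' `1 - sum_j alpha_ij N_j = 0` within tolerance, the persistent block is
#' positive definite, and every extinct species has a strictly negative
#' invasion growth rate.
#'
#' @param matrix an `interaction_matrix` (symmetric, unit diagonal).
#' @param params an [assembly_params] object.
#' @param init initial abundances (nonnegative). Default: uniform on `[0, 1]`
#'   per species, drawn with `seed`.
#' @param seed seed for the default initial condition.
#' @param record_lyapunov keep a (thinned) trace of the Lyapunov function
#'   `F = 2 sum_i N_i - sum_ij N_i alpha_ij N_j` along the trajectory.
#' @return An `equilibrium_state` in the vanishing-migration limit:
#'   `abundances` holds the persistent species at their exact fixed-point
#'   values and the extinct species at 0 (their finite-migration remnants
#'   `lambda / (r_i (sum_j alpha_ij N_j - 1))` are kept in
#'   `migration_remnant`), plus the logical `persistent` mask, relative
#'   diversity `phi`, `verified`/`converged` flags, and per-species
#'   `residuals` diagnostics. Non-convergence within `max_time` yields
#'   `verified = FALSE` plus a warning.
#' @export
integrate_assembly <- function(matrix, params = assembly_params(), init = NULL,
                               seed = NULL, record_lyapunov = FALSE) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  S <- matrix$graph$n_vertices
  if (is.null(init)) {
    set_seed_if(seed)
    init <- runif(S)
  }
  if (length(init) != S || any(init < 0)) stopf("invalid initial abundances")
  csr <- matrix_csr(matrix$matrix)
  r <- rep_len(params$growth_rates, S)
  N <- as.numeric(init)
  t <- 0
  steps <- 0L
  trigger <- max(1e-7, params$convergence_tolerance)
  t_chunk <- 200
  lt <- numeric(0); lv <- numeric(0)
  repeat {
    res <- lv_integrate_cpp(N, csr$row_ptr, csr$col_idx, csr$values, r,
                            params$migration, t, min(t + t_chunk, params$max_time),
                            trigger, params$rtol, params$atol,
                            max_steps = 5000000L,
                            record_lyapunov = as.integer(record_lyapunov))
    N <- res$N; t <- res$t; steps <- steps + res$steps
    if (record_lyapunov) { lt <- c(lt, res$lyapunov_t); lv <- c(lv, res$lyapunov) }
    if (res$converged || res$max_rate < 1e-5) {
      # near-settled: polishing either lands exactly on a verified
      # equilibrium (exact fixed point, stable, strictly uninvadable) or
      # fails, e.g. while a slow invader is still below threshold
      pol <- polish_equilibrium(matrix$matrix, N, params)
      if (pol$ok) {
        lyap <- if (record_lyapunov) data.frame(time = lt, F = lv) else NULL
        return(new_equilibrium_state(matrix, pol$N, pol$persistent, params,
                                     t, steps, converged = TRUE, lyap = lyap,
                                     remnant = pol$migration_remnant))
      }
      if (res$converged) trigger <- max(trigger / 1000, 1e-13)
    }
    if (t >= params$max_time) break
    t_chunk <- min(t_chunk * 2, 2e5)
  }
  warning(sprintf(
    "assembly did not reach a verified equilibrium within max_time = %g (max |dN/dt| = %.3g)",
    params$max_time, res$max_rate), call. = FALSE)
  pers <- N >= params$extinction_threshold
  lyap <- if (record_lyapunov) data.frame(time = lt, F = lv) else NULL
  new_equilibrium_state(matrix, N, pers, params, t, steps, converged = FALSE,
                        lyap = lyap)
}

#' Residual diagnostics for a candidate equilibrium
#'
#' For every persistent species the linear residual
#' `1 - sum_j alpha_ij N_j` (zero at a fixed point); for every extinct
#' species the invasion growth rate `r_i (1 - sum_j alpha_ij N_j)`
#' (strictly negative at an uninvadable equilibrium).
#'
#' @param matrix an `interaction_matrix`.
#' @param state an `equilibrium_state` (or any list with `abundances` and
#'   `persistent`).
#' @param tolerance residual tolerance for the persistent species.
#' @return A list: `residual` (per-species; linear residual for persistent,
#'   invasion rate for extinct), `persistent_residual`, `invasion_rate`,
#'   `verified`.
#' @export
verify_equilibrium <- function(matrix, state, tolerance = 1e-8) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  N <- state$abundances
  pers <- state$persistent
  r <- rep_len(1, length(N))
  # the fixed-point and invasion conditions hold among the present species:
  # in the lambda -> 0+ limit extinct species contribute nothing to the sums
  s <- as.numeric(matrix$matrix %*% (N * pers))
  lin <- 1 - s
  residual <- ifelse(pers, lin, r * lin)
  list(residual = residual,
       persistent_residual = lin[pers],
       invasion_rate = (r * lin)[!pers],
       verified = all(abs(lin[pers]) <= tolerance) && all(lin[!pers] < 0))
}

#' Assembly from many random initial conditions
#'
#' Runs [integrate_assembly()] from `n_starts` initial conditions sampled
#' uniformly from `[0, 1]` per species and groups the resulting equilibria
#' into distinct classes (identical persistent sets and maximum abundance
#' difference below `dist_tol`). Used to decide whether a community has a
#' unique equilibrium.
#'
#' @inheritParams integrate_assembly
#' @param n_starts number of initial conditions (30 for uniqueness checks).
#' @param seed integer seed; start `k` uses a sub-seed derived from it.
#' @param dist_tol abundance distance below which two equilibria are the same.
#' @return A list: `states`, `n_distinct`, `class` (per start), `all_converged`.
#' @export
multistart_assembly <- function(matrix, params = assembly_params(),
                                n_starts = 30, seed = NULL, dist_tol = 1e-6) {
  stopifnot(n_starts >= 1)
  states <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    states[[k]] <- integrate_assembly(matrix, params,
                                      seed = derive_seed(seed, 100L + k))
  }
  cls <- integer(n_starts)
  reps <- list()
  for (k in seq_len(n_starts)) {
    assigned <- FALSE
    for (j in seq_along(reps)) {
      ref <- reps[[j]]
      if (identical(ref$persistent, states[[k]]$persistent) &&
          max(abs(ref$abundances - states[[k]]$abundances)) < dist_tol) {
        cls[k] <- j; assigned <- TRUE; break
      }
    }
    if (!assigned) { reps[[length(reps) + 1]] <- states[[k]]; cls[k] <- length(reps) }
  }
  list(states = states, n_distinct = length(reps), class = cls,
       all_converged = all(vapply(states, `[[`, TRUE, "converged")))
}

#' Lyapunov function of the symmetric Lotka-Volterra dynamics
#'
#' `F = 2 sum_i N_i - sum_ij N_i alpha_ij N_j`; for symmetric interaction
#' matrices F is non-decreasing along trajectories and its local maxima over
#' the nonnegative quadrant are the stable equilibria.
#'
#' @param matrix an `interaction_matrix`.
#' @param abundances nonnegative abundance vector.
#' @return Scalar value of F.
#' @export
lyapunov_value <- function(matrix, abundances) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  N <- as.numeric(abundances)
  2 * sum(N) - as.numeric(N %*% (matrix$matrix %*% N))
}
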