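---
title: "Assembly and equilibria of sparsely interacting competitive communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly and equilibria of sparsely interacting competitive communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparselv)
```

## The model

`sparselv` studies communities assembled from a pool of $S$ species whose
abundances $N_i$ follow the symmetric competitive Lotka--Volterra equations
with small immigration,

$$\frac{dN_i}{dt} = r_i N_i \Big(1 - \sum_j \alpha_{ij} N_j\Big) + \lambda_i,$$

with $\alpha_{ii} = 1$, $\alpha_{ij} = \alpha_{ji} \ge 0$, and $r_i > 0$.
Symmetry guarantees convergence to an equilibrium: the function
$F = 2\sum_i N_i - \sum_{ij} N_i \alpha_{ij} N_j$ is non-decreasing along
trajectories and its local maxima over the nonnegative quadrant are the
stable equilibria. The growth rates do not affect which equilibria exist, so
simulations use $r_i = 1$. Migration is a device for taking the
uninvadable-equilibrium limit: with $\lambda_i \to 0^+$, every species that
can invade eventually does, so an equilibrium consists of a set of
*persistent* species at a feasible, stable fixed point of their own
interactions, with every *extinct* species having a strictly negative
invasion growth rate.

Interactions are sparse: each species interacts appreciably with only a few
others, encoded by a community graph. The package generates the three
ensembles the analysis rests on:

* random $C$-regular graphs with uniform strength $\alpha$ on every edge
  (`sample_regular_graph()`, the core model);
* Erdős--Rényi graphs with edge probability $C/S$, i.e. heterogeneity in
  degree (`sample_er_graph()`);
* per-edge strengths drawn from $\mathcal N(\alpha, \sigma)$, symmetric, i.e.
  heterogeneity in strength (`build_interactions(..., sigma = )`).

## Allowed subgraphs

At an equilibrium the persistent species split into connected subgraphs of
the community graph, and the abundances within a subgraph are determined
entirely by its internal interactions: they solve $(I + W)N = \mathbf 1$
restricted to the subgraph. A subgraph can appear at equilibrium only if
this fixed point is *feasible* (all abundances positive) and *stable*
($I + W$ positive definite). Both conditions depend on the strength alone,
so each subgraph type $\mu$ has a critical value $\alpha_c(\mu)$ above which
it is no longer allowed.

Sparse random graphs are locally tree-like (a random 3-regular graph
carries on average only $4/3$ triangles), so finite components are almost
always trees, and the catalogue of critical values needs to be computed for
trees only. For a chain of $n$ species the critical strength has the closed
form

$$\alpha_{\text{chain}}(n) = \begin{cases}
  1/(2\cos(\pi/(n+1))) & n \text{ even} \\
  1/2 & n \text{ odd},\; n \ge 3,
\end{cases}$$

implemented in `chain_alpha_c()`; a singleton is allowed at every strength
(we define its critical value as infinite — the strong-interaction limit
requires isolated persistent species). The even-chain sequence decreases
strictly to $1/2$, and every other tree has $\alpha_c \le 1/2$, so above one
half only even chains and singletons can persist.

`enumerate_trees()` builds the catalogue: all free trees up to a given size
(grown by leaf addition, de-duplicated with a canonical labelling), each
with its $\alpha_c$ located by bisection on the combined
feasibility-and-stability predicate (`alpha_c_bisection()`). The bisection
discovers rather than assumes which trees attain $\alpha_c = 1/2$ — the
catalogue confirms numerically that the first branched trees sit exactly
there.

```{r catalogue}
cat6 <- enumerate_trees(6)
subset(as.data.frame(cat6), alpha_c > 0.5, c(size, alpha_c, limiting_condition))
```

## Assembly simulations

`integrate_assembly()` runs the dynamics from random initial abundances
(uniform on $[0,1]$ per species) to a verified equilibrium:

1. an adaptive embedded Runge--Kutta (Cash--Karp 4/5) stepper, compiled,
   integrates the equations with $\lambda = 10^{-10}$ until abundance
   changes are negligible;
2. species are classified by the extinction threshold $10^{-5}$, and the
   persistent set is *polished*: its linear system is solved exactly (with
   migration set to zero), iteratively dropping species whose polished
   abundance falls below threshold;
3. the result is verified — persistent species satisfy
   $1 - \sum_j \alpha_{ij} N_j = 0$ among themselves to $10^{-8}$, the
   persistent block is positive definite, and every extinct species has a
   strictly negative invasion rate. Failures (e.g. an invader still below
   threshold) send the integrator back for more time; non-convergence
   within `max_time` is reported explicitly, never silently returned.

Equilibria are reported in the $\lambda \to 0^+$ limit: extinct species at
abundance zero, with their finite-migration remnants
$\lambda / (r_i\,\text{deficit}_i)$ kept as a diagnostic. This matters near
the uniqueness transition, where a strictly excluded species can have an
invasion deficit so small that its remnant at $\lambda = 10^{-10}$ sits
above the extinction cut even though it vanishes in the limit.

```{r pair}
m <- build_interactions(community_graph(igraph::make_graph(c(1, 2),
                                                           directed = FALSE)),
                        alpha = 0.7)
st <- integrate_assembly(m, init = c(0.2, 0.9))
c(phi = st$phi, N = st$abundances[1], expected = 1 / 1.7)
```

## Observables and transitions

`diversity_sweep()` estimates the relative diversity $\phi = S^*/S$ over a
strength grid, together with the largest persistent-component fraction and
the share of pair/singleton components. $\phi(\alpha)$ is a staircase:
plateaus separated by jumps located exactly at the catalogue's critical
values (`detect_jumps()` compares adjacent grid points by Welch tests and
matches significant drops to the catalogue; candidate-based comparison was
chosen over blind change-point search because the smaller jumps below one
half are buried in replicate noise).

Two collective transitions bound the staircase from below:

* **Uniqueness.** The community has a unique equilibrium exactly when the
  interaction matrix is positive definite ($F$ is then concave, so its
  maximum is global) — which on regular graphs with uniform strengths
  coincides with the fully feasible state (all abundances
  $1/(1 + C\alpha)$) being stable. The spectral edge of large $C$-regular
  graphs gives the closed form $\alpha_{UE}(C) = 1/(2\sqrt{C-1})$
  (`alpha_UE()`). `uniqueness_probability()` evaluates the criterion
  spectrally (cheap and exact for this model); `uniqueness_crosscheck()`
  validates it dynamically with 30-start multistart assembly, confirming
  per realization that *unique equilibrium*, *fully feasible*, and
  *positive definite* are the same event.
* **Percolation.** Below $\alpha_{\text{perc}}$ the largest connected
  component of persistent species spans a finite fraction of the pool. At
  the threshold of a random regular graph the largest-component fraction
  scales as $S^{-1/3}$, so curves of $f \cdot S^{1/3}$ against $\alpha$ for
  different $S$ cross at the transition. `percolation_estimate()`
  interpolates each pair of curves linearly, averages the pairwise
  crossings, and bootstraps over replicates for the uncertainty; an absent
  crossing is reported as a bracketing failure rather than extrapolated.

With heterogeneity, degree variation (Erdős--Rényi) leaves the jumps sharp
— a tree's feasibility and stability do not care how many extinct
neighbours it has — while strength variation broadens each jump over a
width proportional to $\sigma$. On the pair/singleton plateau the
homogeneous picture survives mild disorder: at mean strength 0.7 and
$\sigma = 0.1$, pairs and singletons still make up about 99.5% of tree
components.

## The emergence rule

With heterogeneous strengths, `emergence_split_check()` verifies how
subgraphs become allowed as the mean strength decreases (scanned by a
common additive shift of all edge strengths, with multiplicative scaling as
an option): at $\alpha_c$ it is feasibility, not stability, that is lost,
through exactly one abundance vanishing continuously; removing that species
splits the subgraph into components each still allowed just above
$\alpha_c$. For a tree with a branching point the vanishing species is a
branching point, so the tree splits into three or more allowed trees.

Two qualifications, both verified numerically: chains have no branching
point — their interior species vanishes and the chain splits into two
pieces; and the branching-point refinement presumes a narrow strength
distribution, so at $\sigma = 0.05$ a few percent of branched trees
(typically those whose homogeneous limit is the degenerate
$\alpha_c = 1/2$ class) vanish at a degree-2 species instead. The
vanish-and-split property itself holds in every sampled tree; the check
therefore reports the branching rule as a separate field rather than
folding it into pass/fail.

## Numerical choices

* Integrator: Cash--Karp 4(5) with relative tolerance $10^{-6}$ and
  absolute tolerance $10^{-12}$; abundances clamped at zero after each
  accepted step (migration keeps them positive; the clamp guards
  undershoot). The Lyapunov trace, recorded on request, is monotone within
  $10^{-7}$ on every tested trajectory.
* Convergence: derivative criterion $\max_i |dN_i/dt| < 10^{-10}$, with
  polishing attempted whenever the rate falls below $10^{-5}$ — the exact
  solve plus strict verification decides the equilibrium long before the
  softest relaxation modes decay, which matters near the collective
  transitions where those modes are slow. `max_time` defaults to $10^6$.
* Distinct equilibria: identical persistent sets and maximum abundance
  difference below $10^{-6}$.
* Bisection: tolerance $10^{-8}$ on $\alpha_c$, upper bracket 2 (no tree is
  allowed above the two-chain bound of 1); feasibility uses a strict
  positivity threshold of $10^{-12}$.
* Regular graphs are sampled by the pairing (configuration) model with
  whole-graph rejection of self-loops and duplicate edges, which is uniform
  over simple regular graphs. This is deliberate: sequential-rejection
  generators measurably inflate short-cycle counts (mean triangle count
  1.63 instead of the uniform 4/3 at $C = 3$), which would bias the
  locally-tree-like structure the theory relies on.
* Negative draws of heterogeneous strengths are redrawn, keeping the model
  competitive; at the parameter ranges used ($\sigma \le 0.1$,
  $\alpha \ge 0.27$) this is a sub-percent tail event.
* One user seed per realization is split deterministically into topology,
  strength, and initial-condition streams, so topology is held fixed when
  only $\sigma$ or the initial conditions vary.

## What the generator does and does not emulate

The ensembles are the study's own synthetic conditions — there is no
empirical data behind them. They capture sparse competitive interaction
structure with controlled degree and strength heterogeneity; they do not
attempt heavy-tailed degree distributions, asymmetric or mutualistic
interactions, demographic noise, or transient dynamics near unstable fixed
points. Passing tests therefore demonstrate the internal consistency of the
model and the correctness of the implementation, not fidelity to any
particular natural community.

## Problem sizes

Sweeps default to pools of a few hundred species ($S$ = 100--400, where
$\phi$ is already $S$-independent to within sampling error), 10--100
realizations per condition and 1--5 initial conditions per realization;
uniqueness checks use 30 starts as in the published protocol. The
`analysis/` scripts and the acceptance script state their scales
explicitly, and everything is configurable through the function arguments
or a YAML config via `run_experiment()`.

## Limitations

* The $\lambda \to 0^+$ limit is approximated by $\lambda = 10^{-10}$, not
  taken exactly; classification near the extinction threshold is
  threshold-sensitive, and borderline invasion deficits are resolved by the
  exact polish rather than by longer integration.
* Rare uninvadability-driven diversity jumps, if they exist, are below the
  resolution of the sweeps here.
* Components containing cycles are decomposed and reported but excluded
  from tree-catalogue matching; they appear with the expected rarity on
  locally tree-like graphs.
* The possibility of a subgraph switching allowed → disallowed → allowed
  as the strength varies is not modelled; bisection assumes a single
  threshold.
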