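---
title: "Distance-dependent infinite stochastic block models for connectomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-dependent infinite stochastic block models for connectomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dense connectomic reconstructions deliver, for every pair of cells in a
tissue volume, whether (or how strongly) they are connected, together with
each cell's position. Anatomists have long organized such circuits by *cell
type*: cells of a type share a laminar depth, a synaptic density profile,
and — crucially — a characteristic, distance-dependent pattern of
connectivity to cells of other types. `ddsbm` implements a nonparametric
Bayesian model that discovers those types, their number, and the spatial
connectivity rules between them, directly from a connectivity matrix and
pairwise distances, optionally augmented with soma depths and per-cell
synapse depth profiles.

## The model

Each entity (cell, neuron, transistor) $e_i$ carries a latent type
$c_i \in \{1,\dots,K\}$ with $K$ unknown. A Chinese restaurant process
(CRP) prior with concentration $\alpha$ governs the partition, so $K$ is
inferred rather than fixed. Given types $c_i = m$, $c_j = n$ and the
pairwise distance $d_{ij}$, observations are generated by a
distance-dependent link function with per-type-pair parameters
$\eta_{mn}$:

* **Logistic-distance Bernoulli** (binary contact graphs):
  $p^\* = 1/(1 + \exp((d_{ij} - \mu_{mn})/\lambda_{mn}))$, rescaled to
  $p = p^\*(p_{\max} - p_{\min}) + p_{\min}$ with global per-graph ceiling
  and floor. The floor absorbs reconstruction errors: even distant cells
  retain a small base connection probability.
* **Logistic-distance Poisson** (synapse-count graphs): a logistic in
  $d_{ij}$ with global length scale $\lambda$, rescaled between a global
  floor rate $r_{\min}$ and a per-component ceiling $r_{mn}$; counts are
  Poisson at that rate.
* **Per-component-ceiling Bernoulli** (used for circuit netlists): the
  logistic ceiling $p_{mn}$ is itself a per-component parameter with a
  global Beta$(\alpha_{hp}, \beta_{hp})$ prior, while $\lambda$ is tied
  globally to the threshold hyperprior ($\lambda = \mu_{hp}/10$).

Thresholds and scales carry exponential priors parameterized by their
*means* ($\mu_{mn} \sim \mathrm{Exp}(\text{mean} = \mu^{hp})$, etc.), so
the hyperparameter grids live on the same scale as the data's distances.
Hyperparameters take values on finite log10-spaced grids with a uniform
hyperprior; the defaults are the grids used for the three connectome
datasets the model was designed around (micrometre-scale contact graphs:
40 points in $[1, 80]$; normalized body-axis count graphs: 20 points in
$[0.2, 2]$ plus rate scales in $[2, 20]$; circuit netlists: 50 points in
$[10, 500]$).

Several graphs over the same entities (e.g. directed chemical synapses and
undirected gap junctions) share one clustering: their likelihoods multiply.

Two optional per-cell feature models join the product. Soma depth is
Gaussian per type with a conjugate Normal/scaled-inverse-$\chi^2$ prior;
the per-type mean and variance are *collapsed* (integrated out), so the
assignment sweep only ever needs the Student-t posterior predictive.
Synapse depth profiles are mixtures of at most three Gaussians per type
(means, weights, and a gridded global variance scale
$\sigma^2 \in \{0.01, 0.1, 1\}$ in squared normalized-depth units). Depths
are normalized to $[0,1]$ at load time; missing features contribute
nothing. Self-pairs are always excluded from likelihoods, and for
undirected relations $\eta_{mn}$ and $\eta_{nm}$ are one stored parameter.

## Inference

Three composed MCMC kernels, applied once each per iteration:

1. **Assignments** — Gibbs sweep over entities. The likelihood is
   non-conjugate, so each update instantiates `n_aux` ephemeral classes
   with parameters drawn from their priors (a singleton's own class is
   retained as the first ephemeral class); the entity is reassigned with
   weight $m_k \, L_k^{1/T}$ for occupied classes and
   $(\alpha/n_{aux})\, L_k^{1/T}$ for ephemeral ones. Empty classes are
   dropped immediately, keeping labels contiguous.
2. **Component parameters** — univariate slice sampling (stepping out +
   shrinkage) of each $\eta_{mn}$ entry given the assignment; components
   are conditionally independent. The initial slice width is
   `slice_width_fraction` (default 0.1) of the relevant hyperparameter
   grid range, falling back to the grid's own scale for single-point
   grids.
3. **Hyperparameters** — exact discrete Gibbs over the grids. Grids that
   only enter component priors (the exponential-prior means) use closed
   forms; grids that enter the likelihood (ceilings/floors, global length
   scales, the profile variance) are scanned with the tempered likelihood.
   $\alpha$ is resampled from its gridded conditional given the current
   partition.

Synapse-profile means and weights are refreshed by a data-augmented Gibbs
step (latent component indicators, conjugate Normal means with prior
$N(0.5, 0.25)$, Dirichlet(1) weights) rather than slice sampling: with the
shared variance gridded, the augmented conditionals are exact and mix
faster than univariate slices over the simplex.

The assignment and component sweeps are implemented in C++ (identical
algorithms, shared likelihood kernels, R's RNG) and used whenever no
feature models are attached; the R implementations remain the reference
path and the only path for feature-bearing data. Both paths are validated
against exhaustive partition enumeration at small N.

### Annealing, initialization, and what actually mixes

The fitting procedure runs `n_chains` independent chains (default 20),
each annealing the *likelihood only* from `T_start` (default 64) to 1 over
`n_iters_anneal` iterations (default 900) plus `n_iters_post` (default
100) at $T = 1$, pooling each chain's final state as one posterior sample;
the MAP sample is the score maximizer, with ties broken toward the lowest
chain id. Priors — in particular the CRP — are never tempered.

Two behaviors of this sampler, measured on the package's own synthetic
benchmarks, shaped the defaults:

* **Strong tempering destroys structure.** With explicit (non-collapsed)
  $\eta$, the tempered component conditionals revert toward their
  high-variance exponential priors, so at $T \gtrsim 4$ every class's
  likelihood is dominated by prior noise and a single class absorbs all
  entities within a few sweeps. The default schedule is kept for
  compatibility with the procedure the model was published with, but the
  package's validation experiments use a mild schedule
  (`T_start` between 1.5 and 2), which preserves class structure while
  still smoothing the end-phase search. Users fitting connectivity-only
  data are advised to do the same.
* **Consolidation beats nucleation.** Splitting a merged class requires a
  prior-drawn ephemeral class to beat a fitted one across all of an
  entity's pairs — a lottery. Chains therefore start *over-partitioned*:
  the initial assignment is drawn from the CRP at the largest gridded
  $\alpha$ (giving $K \approx \alpha \log N$ initial classes), and
  `n_aux` defaults to 10 rather than a minimal value, multiplying the
  nucleation attempts per sweep. With these defaults, individual chains
  on well-separated data (N = 150) reach the true partition roughly a
  quarter of the time, and the best of 20 chains almost always does —
  which is exactly the role of multi-chain MAP selection in this
  procedure.

## Synthetic data and what the validation shows

`gen_dd_sbm` generates the model's own data: uniform positions in a square
(or interval) of side `side`, balanced round-robin types (CRP-sampled on
request), and edges drawn independently from the chosen link function. The
default truth realizes the *well-separated* regime used in the recovery
experiments: same-type pairs connect out to $\mu = 0.7\,\mathrm{side}$,
cross-type pairs only within $0.1\,\mathrm{side}$, with
$\lambda = 0.05\,\mathrm{side}$, $p_{\max} = 0.95$, $p_{\min} = 0.01$ —
the two connection curves are nearly disjoint over the typical
pairwise-distance range, and edge density stays moderate (~0.1–0.3).
Three mismatch generators (plain SBM, mixed-membership, latent position
cluster) cover the regimes where the model's single-discrete-type
assumption is respectively harmless, over-partitioned, and misspecified.

The validation suite runs at desk scale, chosen to keep the full test run
within tens of minutes on one CPU: recovery at N = 150 with
K ∈ {2, 3, 4, 6, 8}, 20 chains of 300 annealed + 50 flat iterations;
cross-validated link prediction at N = 80 with 10 folds and 3 chains per
fold; exhaustive-enumeration checks at N ≤ 6; edge-effect windowing at
N = 250 over 20 seeds. What passing shows: the sampler targets the right
posterior at small N, recovers well-separated planted structure at
moderate N, and reproduces the qualitative claims (distance-blind fits
over-partition; windowing destroys but never creates distance dependence;
split/merge/distribute hit exactly the metrics they should). What it does
not show: recovery under weak separation, at biological scale (~10³
cells), or robustness to the heavy-tailed contact areas, missing somata,
and annotation noise of real reconstructions.

## Numerical choices

* Probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ before logs;
  Poisson rates are floored at $10^{-10}$. Log scores are finite for any
  valid state.
* The Poisson rate-scale prior is a *shifted* exponential
  ($r_{mn} - r_{\min} \sim \mathrm{Exp}$), so the ceiling always exceeds
  the floor; similarly the per-component Bernoulli ceiling is a Beta draw
  rescaled to $(p_{\min}, 1)$, with the change-of-variables constant in
  its density.
* The annealing schedule is geometric,
  $T(i) = T_{start}^{\,1 - i/n_{anneal}}$ for $T_{end} = 1$: uniform
  multiplicative cooling.
* Contact areas are thresholded with a strict inequality; synapse counts
  divided by 4.0 are rounded half-up. Both conventions are documented at
  the loader.
* MAP ties break toward the lowest chain id; block sorting of the
  coassignment matrix uses average-linkage agglomerative ordering of
  $1 - $coassignment, which is deterministic for a given input.
* Chain c of a run uses seed `seed + 1000 (c - 1)`; every generator takes
  an explicit seed, so the full pipeline is reproducible bit-for-bit.

## Limitations

Link functions are monotone non-increasing in distance by construction;
systems where intermediate distances connect best are outside the model.
The sampler's merged modes are absorbing in practice — inference quality
rests on over-partitioned initialization and multi-chain selection, not on
within-chain ergodicity at realistic run lengths. Feature-bearing data
currently uses the slower reference kernels. The mixed-membership
generator has no single true type per entity, so clustering metrics
against its "truth" (dominant role) are indicative only.
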