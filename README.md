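# ddsbm — distance-dependent infinite stochastic block models for connectomics

Dense connectome reconstructions give, for every pair of cells in a
volume, whether (or how strongly) they connect, plus each cell's position.
`ddsbm` discovers **cell types and their microcircuitry** from such data:
it clusters entities into an *unknown* number of types while jointly
learning how the connection probability between each pair of types decays
with distance, optionally using soma depths and synapse depth profiles as
additional evidence. It is aimed at computational neuroanatomists and
network scientists working with connectivity matrices — neural contact
graphs, synapse-count graphs, or even circuit netlists.

## The model

Entity $e_i$ has a latent type $c_i$; a Chinese restaurant process prior
with concentration $\alpha$ lets the number of types $K$ be inferred.
Given types $c_i = m$, $c_j = n$ and distance $d_{ij}$, a binary
connection is Bernoulli with

$$p^* = \frac{1}{1 + \exp\!\big((d_{ij} - \mu_{mn})/\lambda_{mn}\big)},
\qquad p = p^*\,(p_{\max} - p_{\min}) + p_{\min},$$

with exponential priors on the per-type-pair threshold $\mu_{mn}$ and
scale $\lambda_{mn}$, and gridded global hyperparameters. Synapse-count
graphs use a Poisson variant (a logistic rate between $r_{\min}$ and a
per-component ceiling $r_{mn}$); netlist-style graphs use a variant with a
per-component probability ceiling under a Beta prior. Multiple graphs over
the same entities share one clustering. Inference is MCMC: an
auxiliary-class Gibbs sweep over assignments, slice sampling of the
$\eta_{mn}$, exact Gibbs over the hyperparameter grids, with likelihood
annealing and best-of-`n_chains` MAP selection. Held-out link prediction
(10-fold cross-validated ROC/AUC), posterior coassignment matrices, and
clustering agreement metrics (ARI, homogeneity, completeness) are built
in, as are generators for all the synthetic validation designs.

## Worked example

```r
library(ddsbm)

sim  <- gen_dd_sbm(n = 100, k = 3, seed = 7)   # well-separated planted types
data <- ddsbm_data(sim$relation, sim$geometry)
cfg  <- inference_config(n_iters_anneal = 200, n_iters_post = 50,
                         T_start = 1.5, n_chains = 8, seed = 1)
ss <- run_chains(data, cfg)
mp <- map_sample(ss)
adjusted_rand_index(mp$labels, sim$truth$labels)
```

Output:

```
<ddsbm_data> 100 entities, 1 relation(s)
<ddsbm_samples> 8 samples; K range 3-3; best log score -1060.47
MAP types: K = 3
ARI vs truth: 1.000
homogeneity: 1.000, completeness: 1.000
coassignment: 100 x 100, mean within-truth-type 1.00, between 0.00
per-type spatial extent: 3.44 4.08 4.02
```

All 8 chains land on a 3-type partition identical to the planted one
(ARI = 1); the coassignment matrix — the posterior probability that two
cells share a type — is a clean block matrix, and each recovered type
spans the whole 10 × 10 layout (extent ≈ 3.4–4.1, i.e. global types, not
local cliques). Running the same relation with `distance_blind(geometry)`
reproduces the classic failure of distance-agnostic block models: many
small, spatially local types. A command-line front end
(`inst/cli/ddsbm`, subcommands `simulate`, `fit`, `predict`, `metrics`,
`preprocess`) wraps the same functions for shell pipelines.

See the methods vignette (`vignettes/ddsbm-methods.Rmd`) for the full
model, kernel, and design discussion.

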