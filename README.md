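# metastab

Linear stability analysis of trophic metacommunities with body-size-scaled
dispersal.

## The problem

Food webs rarely exist in isolation: local communities occupy discrete
habitat patches and exchange individuals through dispersal. Body size
structures both halves of this picture. Within a web, larger species sit at
higher trophic positions and turn biomass over more slowly; across the
landscape, movement capacity scales allometrically with body mass, so either
the largest predators or the smallest producers may be the fastest
dispersers. `metastab` is for theoretical ecologists who want to ask how
these two allometric hierarchies interact: does coupling habitat patches by
the movement of large-bodied top consumers stabilize a heterogeneous
metacommunity more than the same total amount of movement distributed
differently among species?

## The model

* **Topology.** Local food webs are niche-model draws with richness `S` and
  connectance `C`: species get niche values `n_i ~ U(0,1)` and feed over an
  interval of width `x·n_i` with `x ~ Beta(1, 1/(2C) − 1)` (so `E[x] = 2C`),
  centred below their own niche value. Webs are retained only if they have a
  basal producer, form a single connected component, and every consumer has
  a directed path to a producer.
* **Allometry.** Trophic position `T_i` is the shortest directed path to a
  producer; mass is `M_i = R^{T_i}` with `R = 42`, and mass-specific
  turnover is `α_i = M_i^{−1/4}`.
* **Local dynamics.** Each patch `k` carries a generalized-model Jacobian
  `J_k` built from branching parameters (`ρ`, `σ`, `β`, `χ`) and
  elasticities (`φ`, `ψ`, `γ`, `μ`, `λ = 1`) drawn independently per patch
  from uniform ranges — spatial environmental heterogeneity without
  committing to specific functional forms.
* **Space.** Patches form a connected random geometric graph (`N = 10`
  patches, radius `0.32` in the unit square) with Laplacian `L`.
* **Coupling.** Species disperse at `δ_i = d·M_i^z`; the metacommunity
  Jacobian is the `SN × SN` matrix

  ```
  J = P − L ⊗ D,   P = blockdiag(J_1, …, J_N),   D = diag(δ_1, …, δ_S)
  ```

  and the system is stable iff every eigenvalue of `J` has a strictly
  negative real part.
* **Permutation analysis.** Each metacommunity is compared against
  counterparts whose dispersal rates are random permutations of the same
  multiset, asking whether stability is driven by *who* disperses fast or
  simply by *how much* total coupling there is.

## Worked example

```r
library(metastab)
set.seed(1)

web    <- niche_web(S = 15, C = 0.15)          # retained niche-model web
net    <- rgg_network()                        # connected RGG, N = 10
params <- sample_patch_params(web, N = net$N)  # per-patch heterogeneity
meta   <- metacommunity(web, net, params)

stability(meta, d = 0.1, z = 0.5)
#> metacommunity stability
#>   leading eigenvalue (Re): -0.078561 -> stable
#>   locally stable patches:  80 %

permutation_analysis(meta, d = 0.1, z = 0.5, n_perm = 100)
#> dispersal permutation analysis (100 permutations)
#>   original leading eigenvalue: -0.078561
#>   median permuted:             -0.0777738
#>   category: stability unaffected
```

Eight of the ten patches are locally stable on their own; the coupled
metacommunity is stable (leading real part −0.079 < 0), and reshuffling
which species carries which dispersal rate leaves the qualitative outcome
unchanged — the "stability unaffected" category.

Ensemble sweeps and the stability attribution GLM:

```r
cfg <- ensemble_config(S_grid = c(10, 20, 30), C_grid = c(0.12, 0.18, 0.24),
                       webs_per_cell = 6, master_seed = 1)
res <- run_ensemble(cfg)
stability_by_local_proportion(res)   # P(stable) vs locally stable fraction
fit_stability_glm(res)               # all-subset AIC, logit-link binomial
```

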