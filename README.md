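# ProfileDMM

Probabilistic clustering of genomic loci characterized by one or more
binned chromatin-feature coverage signals — histone-modification ChIP-seq,
MNase-seq, RNA polymerase II occupancy and the like, counted in fixed-width
bins (e.g. 40 bp) of windows (e.g. 2000 bp) centred at regulatory elements
such as enhancers. It is aimed at epigenomics analysts who want to resolve
the distinct chromatin signatures that a single aggregate heatmap
superimposes.

## The model

Each mixture component k models the M feature profiles of locus i as
independent **Dirichlet-multinomial** (Polya) draws, capturing the
overdispersion of sequencing counts:

    p(x_i* | α*, π) = Σ_k π_k Π_m DM(x_i^(m) | α_k^(m))

Two extensions address the practical pain points of this data type:

- **Latent shift and flip states.** Anchor positions are uncertain and
  profiles can be strand-ambiguous. Component parameter vectors are
  extended from L to L + S − 1 positions (S = 2·maxShift/binSize + 1 shift
  states, e.g. 21 for ±400 bp at 40 bp bins); a latent state picks an
  L-length window, optionally reversed, with per-locus priors ξ
  (uniform or pyramid-shaped) and ζ over the states.
- **Smoothness-regularized MAP estimation.** Every α element has a
  Gamma(η = 1.1, ν = 0.1) prior and the roughness h = Σ_j (α_j − α_{j−1})²
  of each component profile a Gamma(η_h = 10, ν_h = 10) prior (mean 1,
  variance 0.1), which stabilizes profile estimates at low coverage.

Inference is MAP expectation-maximization over the N × K × S × 2
responsibility tensor: closed-form mixture-weight updates and per-block
BFGS updates of λ = log α with analytic gradients. AIC/BIC select the
number of clusters. Simulators (model-based, low-coverage Gaussian,
Skellam shift/flip corruption, prior predictive) and identifiability-aware
evaluation metrics (clustering AUC, shift error in bp, inversion-corrected
flip error) round out the toolkit.

## Worked example

```r
library(ProfileDMM)

sim <- simulateDMM(twoClusterAlpha(L = 50, M = 2), c(0.5, 0.5),
                   coverages = 100, N = 400, seed = 1)
fit <- fitDMM(sim$dataset, K = 2, nRestarts = 2, seed = 1)
fit
#> DMMFit: K=2, converged after 4 iterations (seed 1)
#> log-posterior -59544.3971, log-likelihood -58889.1465
#> cluster
#>   1   2
#> 183 217

clusteringAUC(sim$truth$labels, fit)
#> [1] 1
informationCriteria(fit)[c("aic", "bic")]
#> $aic
#> [1] 118180.3
#> $bic
#> [1] 118982.6
```

The fit recovers the two simulated clusters perfectly (AUC 1) with
weights near the true 50/50 split; `hardAssignments(fit)` lists, per
locus, the cluster, its posterior, the inferred displacement in bp
(positive = pattern downstream of the anchor; realignment translates by
−shiftBp/binSize bins) and the flip state. `realignProfiles()` and
`aggregateProfiles()` produce shift/flip-corrected matrices and
cluster-wise aggregate patterns for visualization; `selectK()` tabulates
AIC/BIC over a K range; `writeResults()` emits assignments, model JSON,
realigned matrices and aggregates. A thin command-line wrapper with
`fit`/`select`/`simulate`/`evaluate`/`realign` subcommands lives at
`inst/scripts/profile-dmm.R`.

See the vignette (`vignettes/chromatin-profile-clustering.Rmd`) for the
model, priors, inference details, conventions and limitations.

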