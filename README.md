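# cortconn

Construction and analysis of whole-cortex structural connectomes from
probabilistic-tractography streamline counts.

Probabilistic diffusion tractography produces, for every ordered pair of
cortical parcels, a raw streamline count. Turning those counts into a
usable connectome and characterizing it involves a fixed chain of steps
that this package implements end to end, for the 360-parcel (180 per
hemisphere) HCP-MMP1.0 parcellation with its 10-network functional
grouping:

- **Normalization.** Counts are *fractionally scaled*,

  $$F_{i,j} = \frac{C_{i,j}}{\sum_{x \ne i} C_{i,x} + \sum_{y \ne j} C_{y,j}},$$

  symmetrized as $F_{i,j} \leftarrow (F_{i,j} + F_{j,i})/2$, and
  log10-transformed (zeros excluded), yielding the log-probability weight
  $F_{pt}$. Three simpler normalizations (per-sample, seed-area,
  both-areas) are provided for concordance checks.
- **Exponential distance decay.** Connectivity falls off with fiber tract
  length $d$ as $10^{F_{pt}} = \alpha e^{-d/\lambda}$; the length constant
  $\lambda$ (mm) is estimated by nonlinear least squares on the linear
  scale, with asymptotic confidence intervals, information-criterion
  comparison against alternative forms, per-hemisphere/callosal subset
  fits, per-subject fits and their relation to head motion.
- **Interindividual variability.** Across-subject coefficients of
  variation per connection, consistency masks, and cross-subject
  correlation of specific connections across hemispheres.
- **Laterality.** The ipsilateral-contralateral differential connectome,
  a bootstrap test of contralateral-homolog hyperconnectivity
  (Bonferroni-corrected percentile CIs over subjects), and the
  distance-binned within/between profile of the combined
  language+auditory network.
- **Cortical hierarchy.** A fractionally scaled |Δ myelination|
  similarity matrix and its correlations with connectivity at hemisphere,
  callosal, network and single-parcel scope.
- **Graph metrics.** Binary undirected network measures (shortest paths,
  clustering, characteristic path length, efficiency, modularity of a
  fixed partition, transitivity, assortativity, density), null-model
  normalization (γ, λ, small-worldness S = γ/λ) and a density-threshold
  sweep with node-order randomization for tied weights.
- **Intermodal comparison.** Renormalization of CCEP- and rs-fMRI-style
  matrices, correlations over shared defined pairs, matched-parcel
  (cross-species) correlation, and a two-component Gaussian-mixture fit
  with midpoint mode splitting for bimodal rs-fMRI weights.
- **Synthetic connectomes.** A generator with known ground truth —
  lognormal weights with exponential distance decay (ipsilateral
  λ = 23.4 mm, callosal 32.8 mm), homolog and ipsilateral boosts, network
  block structure, subject-level and counting noise, myelination
  couplings, a CCEP-like matrix with biased missingness and a bimodal
  rs-fMRI-like matrix — so every stage is testable without downloads.

Undefined entries (the diagonal, missing modality samples, zero-count
pairs after the log) are carried as an explicit mask; every statistic
restricts itself to defined pairs and reports the count it used.

## Worked example

```r
library(cortconn)

cfg <- synthetic_config(n_parcels = 120, n_subjects = 12, seed = 1)
ds  <- generate_dataset(cfg)

fpt <- fpt_chain(group_average(ds$stack))
print(fpt)
#> connectome_matrix: 120 x 120, scale=log10_fractional, symmetric=TRUE, 14280 defined pairs

subset_fit(fpt, ds$lengths, ds$atlas, "all")
#> decay_fit [all]: lambda = 25.89 mm [25.33, 26.45], alpha = 0.129, r2 = 0.634, n = 7140

homolog_test(cv_matrix(ds$stack)$fpt, ds$atlas, iters = 500, seed = 1)
#> homolog_test: 54 hyper / 0 hypo / 6 ns of 60 parcels
```

The decay fit says that at this (reduced) problem size the group
connectome's weights fall off e-fold every ~26 mm of tract length and the
exponential rule explains 63% of the linear-scale variance; the homolog
test finds 54 of the 60 bilateral parcel identities significantly more
strongly connected to their contralateral homolog than to the rest of the
opposite hemisphere. At full size (360 parcels) the same pipeline
recovers the generator's planted structure much more cleanly; see the
reproduction script below.

`run_pipeline()` drives all stages in order on a configuration (an R
object or a YAML file), writes per-stage CSV/JSON outputs and a
reproducibility manifest with input digests and seeds;
`verify_manifest()` re-checks a finished run.

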