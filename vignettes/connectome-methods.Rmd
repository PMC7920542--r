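---
title: "Models and methods for whole-cortex structural connectome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for whole-cortex structural connectome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortconn)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters and the numerical
choices made where the design was genuinely open. The README shows the
user-facing workflow; here we explain *why* each stage is the way it is.

## The parcellation and its bookkeeping

All analyses operate on a 360-parcel cortex: 180 parcels per hemisphere
with one of 10 functional network labels each, a fixed display order, and
a name-based homolog pairing (the right-hemisphere homolog of left parcel
*k* sits at index *k* + 180). `load_atlas()` validates every invariant a
downstream stage relies on — hemisphere balance, within-hemisphere name
uniqueness, network completeness, and the involution property of the
homolog map — and fails with the offending rows rather than propagating a
malformed table. The combined language+auditory super-network used by the
distance-binned laterality profile is derived on demand
(`language_auditory_parcels()`) rather than stored, because it is an
analysis construct, not an atlas fact. Parcel indices are 1-based at
every interface, matching the printed table.

## Normalization: from counts to log-probability weights

Raw streamline counts depend on parcel size, seed voxel count and
sampling depth. Fractional scaling divides each pairwise count by the
total streamlines entering or leaving the two parcels (self-connections
excluded), which removes the overall sampling scale — the result is
invariant to multiplying all counts by a constant, a property the tests
assert. Because A-to-B and B-to-A streamlines are estimated separately,
minor asymmetries are removed by averaging the two directions, and the
heavy-tailed fractional weights are then log10-transformed. The pipeline
order is fixed: group-average the raw counts, then scale, symmetrize and
log; per-subject analyses apply the same chain to each subject's counts.

Zeros are never log-transformed. The default policy marks zero-count
pairs undefined; a floor policy with a user-supplied substitute value is
available. A parcel with no streamlines at all is masked out as an
endpoint entirely (with a warning): literally applying the scaling
formula would leave its entries defined as exact zeros, but a parcel the
tractography never reached carries no information about connectivity.

A subtlety worth stating: log10 of a fractional weight is negative, so
the signed mean of $F_{pt}$ is negative while summaries of
log-probability magnitudes are conventionally printed positive.
`moments()` therefore reports both the signed moments and the moments of
the magnitudes, each with percentile bootstrap 95% CIs (2000 iterations,
seeded). Kurtosis is non-excess (Gaussian = 3).

## The exponential distance rule

The central model is
$$10^{F_{pt}} = \alpha\, e^{-d/\lambda},$$
with $d$ the fiber tract length in mm and $\lambda$ the length constant
in the cable-theory convention (mm, not inverse mm). Fitting happens by
nonlinear least squares *on the linear scale*, not on log weights: the
model is multiplicative and the published convention fits the linear
response with iterative optimization. Initialization uses
$\alpha_0 = \max(y)$ and $\lambda_0 = \mathrm{range}(d)/3$ with a
deterministic ladder of jittered restarts; confidence intervals come from
the asymptotic covariance (QR decomposition of the Jacobian), and $r^2$
is $1 - \mathrm{SSE}/\mathrm{SST}$ on the linear response. The iterative
optimum is checked in the tests against a 0.1-mm grid search over
$\lambda$ with $\alpha$ profiled in closed form.

Two properties of this estimator matter for interpretation. First,
linear-scale least squares is dominated by the strongest (shortest-range)
connections; with multiplicative lognormal scatter the estimate carries a
small finite-sample bias (~2% at realistic noise), which is why the
recovery criteria are stated as medians over replicates. Second, additive
structure that is *not* part of the decay (a homolog boost concentrated
at the shortest callosal distances, an ipsilateral offset) contaminates
subset fits; the package's recovery checks therefore run on
configurations with those boosts disabled, and fits on fully structured
data are reported as what they are — effective, not generative, length
constants.

Candidate-model comparison (`fit_candidates()`) fits a user-extensible
registry (exponential, Gaussian, power, offset-exponential) and ranks by
AICc computed from the Gaussian-error log-likelihood; the parameter count
includes the error variance. The exact alternative set of the original
analysis is not fully enumerable from the available text, hence the
registry design.

Head motion is summarized by the trapezoidal integral of the RMS
displacement series over the scan, and its relation to per-subject
$\lambda$ is a Pearson correlation with a Fisher-z interval (variance
$1/(n-3)$).

## Variability, laterality and the bootstrap conventions

The across-subject coefficient of variation is computed on the
per-subject *log-scale* weights ($F_{pt}$), restricted per pair to the
subjects where the pair is defined, with the contributing count recorded.
On the log scale a global rescaling of counts would shift the mean and
change CV — but fractional scaling has already removed that scale, which
is precisely why CV on $F_{pt}$ is comparable across subjects. The
"most consistent" mask takes the lower quantile of |CV| (default 0.2).
The fold-range of a specific connection is defined here as the ratio of
the 97.5th to the 2.5th percentile of the linear weight across subjects;
the source analyses do not define their fold-variability measure, so this
choice is explicit and configurable.

The contralateral-homolog test compares, per bilateral parcel identity
and subject, the symmetrized homolog weight against the mean of the 179
other callosal weights in that parcel's row. The per-parcel statistic is
bootstrapped over *subjects* (2000 iterations), and percentile CIs are
taken at the Bonferroni-corrected level $1 - \alpha/180$; a parcel is
hyper- (hypo-)connected when the corrected CI lies entirely above
(below) zero. Two facts shape the calibration experiments: mirrored
geometry makes the homolog the nearest callosal target, and
homolog-shared parcel areas leak through the scaling denominator — both
create *true* nonzero homolog differentials. A null simulation for the
test's error rate must therefore flatten the distance rule and remove
fixed pair-level effects; under those conditions the test's family-wise
false-positive count is below one parcel in 180, and a +0.5 log10 boost
at 50 subjects is detected in essentially all parcels.

The distance-binned language profile uses half-open 15-mm bins. Within
each bin and subject, linear weights are averaged *before* the log — the
order matters (by Jensen's inequality the log of the mean dominates the
mean of logs) and is asserted in the tests. Grand averages across
subjects carry Bonferroni-corrected bootstrap CIs, with the correction
count equal to bins × two groups × two hemispheres. Empty bins are
reported as undefined, never as zero.

## Hierarchy

The T1w/T2w myelination index is an inverse proxy for position in the
cortical hierarchy. The hierarchy-similarity matrix applies the same
fractional scaling to |Δ myelination|; because that scaling normalizes by
row and column totals, the matrix is invariant to affine transforms of
the myelination vector (tested), and smaller values mean closer
hierarchical levels — a *negative* correlation with connectivity means
hierarchically close parcels are better connected. Scope correlations are
computed per hemisphere to avoid the collinearity introduced by
hemispheric homology. Parcel-wise correlations (each connectome row
against the myelination vector, self excluded, callosal entries retained
by default with an exclusion flag) use t-distribution p-values multiplied
by 360.

## Binary graph metrics

The metric suite operates on binary undirected graphs: shortest paths by
level-synchronous BFS, triangles from the cube of the adjacency matrix,
clustering with the degree-below-2 convention $C_i = 0$, characteristic
path length and nodal/global efficiency, modularity of a *fixed*
partition (the 20 network-by-hemisphere labels by default; no community
detection is performed), transitivity, degree assortativity over the edge
set, and density $l/\binom{n}{2}$. Two printed-formula ambiguities were
resolved in favour of the standard definitions: global efficiency is the
mean of nodal efficiencies (the printed version would duplicate the path
length), and density is the link count over the possible-pair count. The
modularity normalizer is the total degree sum (twice the undirected link
count), the Brain Connectivity Toolbox convention. Every metric is tested
against brute-force oracles (Floyd–Warshall, triple loops, double-loop
modularity) on hundreds of random small graphs.

Disconnected graphs: the default CPL is computed over reachable pairs
with the disconnected-pair fraction reported alongside; an
infinity-propagating variant is available by flag. Normalized metrics
(γ = MCC/MCC_null, λ = CPL/CPL_null, S = γ/λ exactly) use
degree-preserving rewiring (10 swaps per edge) as the default null, with
an Erdős–Rényi alternative.

The density sweep thresholds the weight matrix to each target binary
density in (0, 0.6] by keeping the top-weight edges, treating missing
entries as non-connections. Tied weights are resolved by a deterministic
hash of the randomized node order, so that ties are exchangeable across
shuffles: with distinct weights the sweep is shuffle-invariant (variance
exactly zero), and with fully tied weights the selected graphs behave
like uniform random edge samples, which is what makes averaging over
shuffles meaningful. The original procedure's "intervals of 0.1" is
ambiguous between weight units and density steps; the sweep is
implemented over a density grid (default 0.05–0.60 by 0.05) realized via
weight-rank thresholds.

## Intermodal comparison

Other modalities pass through the same fractional scaling and
symmetrization; evoked-potential (CCEP) matrices are log10-transformed
like the tractography weights, resting-state fMRI matrices are not
(they are already approximately normal, if bimodal, in linear space).
Missing CCEP entries are excluded from correlations but treated as
non-connections when a density is computed. Correlations between
modalities use upper-triangle shared defined pairs with Fisher-z CIs;
the matched-parcel variant restricts both matrices to a name map first
(the cross-species use case).

The bimodal rs-fMRI distribution is characterized by a two-component
Gaussian mixture (EM, unequal variances, components sorted by mean; for
large inputs the EM is initialized from a seeded subsample). The split
point is defined as the midpoint of the component means — exactly, as a
derived quantity — and values are assigned to modes by that split. A fit
is flagged "unimodal" when the mean separation is under two pooled
standard deviations; in that regime the mixing proportions are poorly
identified and should not be over-read. The printed dispersion of the
reference mixture (8.1e-8, identical for both modes) is interpreted as a
component *variance* (sd ≈ 2.85e-4): as a standard deviation it would
make the modes disjoint spikes, inconsistent with the published density
plot. The generator exposes both interpretations.

## The synthetic generator: what it emulates, and what it does not

`synthetic_config()` defaults define the reference study conditions:
360 parcels on two mirror-image ellipsoidal shells (tract length =
Euclidean distance × 1.3, plus a 20-mm callosal detour, spanning roughly
10–280 mm), exponential decay with ipsilateral λ = 23.4 mm and callosal
λ = 32.8 mm, a +0.5 log10 homolog boost, +0.15 ipsilateral advantage,
+0.1 within-network boost, a +0.3 boost on language/auditory connections
beyond 100 mm, lognormal parcel areas, Poisson counting noise at 5000
samples per seed voxel, 0.12 log10 group-level scatter (plus 0.1 extra on
callosal pairs), 0.25 per-subject pair noise of which 70% is shared with
the mirror-image connection, a myelination vector coupled negatively to a
78-parcel prefrontal set at 0.4 log10 per z-unit, a CCEP-like matrix with
1.7 log10 noise and 30% missingness biased 3:1 toward callosal pairs, and
a bimodal rs-fMRI-like matrix with modes 0.0011/0.0017 mixing 0.63/0.37.

Where the reference analyses print a quantity, the corresponding default
was calibrated once so the synthetic study reproduces it at the reported
order: the group decay fit explains ~0.7–0.8 of the linear variance, the
intermodal correlations sit near 0.42 (CCEP) and 0.08 (rs-fMRI), the
cross-hemisphere correlation of a specific strong connection is ~0.7, and
the parcel-wise myelination analysis recovers ~75 significant parcels.
The default cohort is 24 subjects — large enough for stable bootstrap
CIs, small enough that the full pipeline runs in seconds; the generator
scales to arbitrary cohort sizes.

What the generator does *not* emulate: real geometry (parcels are shell
points, not folded cortex), distance-dependent tractography failure
modes (crossing fibers, gyral bias), non-Poisson overdispersion of
streamline counts, and any genuine functional dynamics behind the
rs-fMRI-like matrix (its mode structure is planted, not emergent).
Passing tests on synthetic data therefore validate the *statistical
machinery* — estimators, masks, bootstrap calibration, classification
logic — not the biological claims.

Determinism: every stage derives its RNG stream from the configuration
seed with fixed offsets; identical configurations reproduce all outputs
bit-exactly, which the manifest machinery (`run_pipeline()`,
`verify_manifest()`) checks via file digests.

## Problem sizes used in the shipped tests

Unit tests run on 40–200-parcel studies with 8–16 subjects; the
calibration and power experiments for the homolog test use the full 360
parcels with 50 subjects; decay recovery uses 100 replicates of ~5000
pairs; the graph-metric oracle battery uses hundreds of exhaustive
small-graph comparisons. The reproduction script
(`scripts/acceptance.R`) runs the full-size default study. These sizes
were chosen so the whole suite completes in about a minute while leaving
every statistical conclusion sampling-stable.

## Known limitations

- The fractional-scaling denominator couples entries within a row and
  column; planted per-row effects are partially redistributed, which is
  visible in the parcel-wise myelination analysis (a planted negative set
  induces a small number of compensatory positive correlations — a
  realistic artifact, but one to keep in mind when reading counts).
- Linear-scale decay fits are dominated by short-range pairs; subset
  length constants on strongly structured data are effective quantities.
- The homolog test's null calibration holds for exchangeable homolog and
  non-homolog weights; on data with real geometry every parcel has a
  nonzero true differential and the test reports that truth, not a false
  positive.
- Mixture proportions from overlapping modes (separation below ~2 sd)
  are ill-identified; the unimodal flag marks this regime.
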