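---
title: "Methods: brain network topology and latent emotion dysregulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain network topology and latent emotion dysregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edsem)
```

## The analysis in one paragraph

`edsem` asks whether the local network integration of individual brain regions
relates to emotion dysregulation, and whether that relation differs between
diagnostic groups (healthy controls, predominantly inattentive ADHD, and ADHD
with hyperactivity-impulsivity). Parcellated resting-state time series become
absolute Fisher-z connectivity matrices, thresholded into binary graphs of
fixed density; six nodal topology measures are computed per graph and averaged
across densities; and for each node × measure a three-group latent-variable
SEM regresses the topology value on a latent emotion-dysregulation factor,
testing group dependence of the slope by a χ² difference against the
shared-slope model under FDR control.

## Graph construction

Pairwise Pearson correlations between parcel time courses are transformed as
`w = |atanh(r)|`. The absolute value treats anti-correlations as connections
(appropriate when preprocessing does not involve global signal regression);
`|atanh(r)| = atanh(|r|)`, so the order of the two operations is immaterial
(asserted numerically in the tests). Correlations are clipped to
`1 - 1e-7` in magnitude before `atanh` so collinear parcels (which synthetic
data can produce) give finite weights.

Each matrix is binarized at seven equally spaced densities 0.10–0.40,
retaining exactly `round(d · n(n-1)/2)` strongest pairs (rounding half away
from zero). Fixing the edge count separates topology from overall connectivity
strength; the low-to-medium density range keeps graphs sparse enough for
meaningful local structure but dense enough to avoid fragmentation. Ties at
the cutoff are broken by node-pair lexicographic order — an arbitrary but
deterministic rule that guarantees reproducibility and makes the graph family
nested across densities (lower-density graphs are edge-subsets of
higher-density ones, which the tests assert under heavy ties). Subjects with
root-mean-square framewise displacement above 0.25 mm are excluded (boundary
values retained; the threshold is a retention bound). Analysis nodes are
parcels whose overlap with the anatomical regions of interest strictly exceeds
0.30.

Two readings of the thresholding scope are supported, because the choice is
genuinely open when only a subset of nodes is analyzed: by default the
connectivity matrix is restricted to the selected nodes *before* thresholding
(`threshold_scope = "selected"`), so the advertised densities hold exactly on
the analysis graph; alternatively the full-parcel matrix is thresholded and
only the reporting is restricted (`"all"`). The default was chosen because it
makes the density guarantee exact for the graphs the metrics actually see.

## Nodal topology measures

For binary undirected graphs: clustering coefficient
`C_i = 2 T_i / (k_i (k_i - 1))` (`T_i` = edges among neighbors, 0 when
`k_i < 2`); local efficiency = global efficiency of the subgraph induced by
the neighbors of `i` (paths may not detour through `i` or non-neighbors;
unreachable pairs contribute 0); nodal efficiency
`(n-1)^{-1} Σ_j 1/d(i,j)`; betweenness with equal weighting over multiple
shortest paths, endpoints not counted, normalized by `(n-1)(n-2)/2`;
component-scaled closeness `((r-1)/(n-1)) · ((r-1)/Σ d)` with `r` the size of
the reachable set (0 for isolates); and eigenvector centrality as the
entrywise-nonnegative, L2-normalized dominant eigenvector of the adjacency
matrix. The verbal gloss sometimes attached to closeness ("how many of the
possible direct connections exist") actually describes degree; the standard
closeness definition is implemented, and since the SEM consumes completely
standardized slopes, per-measure scale conventions do not affect the
inference.

Eigenvector centrality uses power iteration on `A + I` from a uniform start
vector: the identity shift leaves eigenvectors unchanged while making the
dominant eigenvalue strictly largest in magnitude, so the iteration also
converges on bipartite graphs. Tolerance is `1e-12` in max-abs change with a
cap of 50 000 iterations (non-convergence is an error, not a silent result);
the tight tolerance keeps the result within `1e-9` of a dense
eigendecomposition even when the spectral gap is small. On graphs whose
dominant eigenvalue is numerically degenerate (e.g. two disjoint edges) the
centrality is convention-dependent; the uniform start makes the package's
answer deterministic, and the oracle tests skip exactly those cases.

Density integration is the arithmetic mean across the seven levels — the
normalized integral over equally spaced thresholds reduces to this. Tests
verify the six measures against independent brute-force oracles
(Floyd–Warshall distance tables, walk-count shortest-path enumeration, dense
eigendecomposition): exhaustively on all 1 099 labeled graphs with up to 5
nodes, and on seeded random samples of 200 graphs with 6–7 nodes and 200 with
12 nodes — sizes chosen so the exhaustive part is complete where enumeration
is tractable and the random part spans the density range.

## The multi-group SEM

The model family is a one-factor structure: indicators
`x_j = ν_{jg} + λ_j η + ε_j`, outcome `y = ι_g + β_g η + ε_y`, with loadings
`λ` shared across groups, all intercepts and residual variances
group-specific, latent mean 0, and latent variance ψ fixed to 1 in the
reference group (ADHD-I, the group against which the others' variances are
expressed) and free elsewhere. With five observed variables and three groups
this gives 39 free parameters against 60 observed moments — 21 degrees of
freedom, or 23 when the slope is constrained equal — which pins down the
parameterization uniquely among the nearby alternatives (e.g. freeing a
latent mean or variance instead would change the df).

Estimation minimizes the standard multi-group ML discrepancy with
`S_g` the divisor-`n` sample covariance and `T = N·F` the model χ². Because
all intercepts are group-specific and the latent mean is fixed, the implied
means are saturated: the intercepts equal the group means exactly, the mean
term vanishes at the optimum, and the intercepts are profiled out of the
numerical search (they still count in the df; the observed information is
block-diagonal between means and covariance parameters at the optimum, so
standard errors of the structural parameters are unaffected).

Numerics: the optimizer is BFGS with an analytic gradient on an unconstrained
parameterization (residual and latent variances on the log scale, which also
keeps the implied covariance positive definite at every iterate), started from
indicator-variance heuristics, with damped Newton polishing (Hessian by
central differences of the analytic gradient) whenever the quasi-Newton tail
stalls; convergence requires max-abs gradient below `1e-6`. Optimization runs
in a unit-variance metric (each variable divided by its pooled SD) and the
solution is mapped back exactly — the ML fit is equivariant under this linear
rescaling, and it makes convergence independent of raw variable scales
(topology measures can have variances of `1e-3` or less). The loading-vector
sign is fixed by requiring a positive sum. Residual variances approaching the
boundary are flagged as Heywood cases rather than silently truncated.
Standard errors come from the inverse observed information (numeric Hessian of
the discrepancy at the optimum); z = estimate/SE with two-sided normal
p-values. The completely standardized solution rescales loadings and slopes
by the implied standard deviations per group.

Fit indices: CFI against the per-group independence baseline (free variances
and means, df = 30 for five variables and three groups), RMSEA with the
multi-group `sqrt(G)` scaling, SRMR as the average over groups of the RMS of
standardized residual moments (covariances and means; the mean residuals are
zero here by construction). χ² difference tests compare the free and
shared-slope models (`Δdf = 2` for three groups, 1 for the pairwise two-group
post-hoc models).

## The scan and multiple-testing structure

For every node × measure pair the density-integrated value is tested first;
the integrated-level difference-test p-values across all pairs form one
Benjamini–Hochberg FDR family. Only gated pairs (FDR-adjusted p < α = 0.05 by
default; a raw-p gate is available, since which gate the original procedure
used is ambiguous) are followed up: per-density tests, FDR-adjusted across
densities *within* the pair (a second family — the natural reading of
correcting a density profile), and Bonferroni-corrected (×3) two-group
post-hoc models on the integrated value. Failed cells are recorded with a
reason and the scan continues. A Kruskal–Wallis test on per-subject mean
connectivity serves as the robustness check that group differences in
topology are not mere differences in overall connectivity strength; the
omnibus test is rank-based because no distributional form is assumed for mean
connectivity (tests verify its p-value against a permutation distribution of
the same statistic).

Scan model variables are standardized by their overall SD before fitting —
every reported quantity (z, difference-test p, standardized estimates, fit
indices) is invariant to this, and it removes any dependence of optimizer
behavior on the raw scale of a topology measure.

## What the synthetic cohorts emulate — and what they do not

`generate_phenotypes()` draws from exactly the measurement model above, with
defaults set to the study design: group sizes 91/31/25, standardized loadings
0.909/0.603/0.546/0.428, residual variances `1 - λ²` (the completely
standardized metric of the reference group), latent variances 0.300/1/0.340,
and optional topology outcomes with unit implied variance per group so that a
standardized effect pattern (default 0.091/−0.279/0.844 for the effect node)
maps directly onto generating slopes `β_g = β*_g/√ψ_g`, `ζ_g = 1 − β*²_g`.
True latent scores are returned for validation only.

`generate_timeseries_cohort()` builds, per subject, a ground-truth graph — a
background random graph (edge probability 0.15), a target parcel wired to a
fixed 12-neighbor set, and neighbor–neighbor edges drawn with probability
`plogis(qlogis(0.15) + 2·η)` so triangle density around the target rises
monotonically with the latent score — then simulates 266-timepoint Gaussian
series with covariance `c·A + I`. The default `c` is `0.8/|λ_min(A)|`, the
largest scale that safely keeps the covariance positive definite (an explicit
`c` is reduced with a warning when needed). The logistic coupling with slope
2 was fixed by a one-off calibration so that estimated integrated clustering
of the target correlates with the true latent score above 0.5 at realistic
cohort sizes; any monotone coupling would serve the validation purpose.

Deliberate simplifications: noise is Gaussian and white in time (an AR(1)
option exists, off by default) — sufficient because the pipeline consumes
only Pearson correlations; no hemodynamics, motion artifacts, or multi-site
effects; indicators are generated in the standardized metric rather than raw
questionnaire units; and the time-series coupling is identical across groups,
so the time-series route exercises pipeline recovery while group-specific
slope tests are powered through directly generated outcomes. Passing tests
therefore show that the estimator chain is correct and calibrated under the
assumed statistical structure — not that real BOLD data satisfy that
structure.

## Validation design and problem sizes

The test suite's heavier checks, with sizes chosen to balance Monte-Carlo
error against runtime: loading/variance recovery over 100 cohorts of ~5000
subjects in study proportions; slope recovery over 100 cohorts of 2000 per
group; χ²-difference calibration under an exactly shared slope at 150 per
group (comfortably asymptotic for a five-variable model) over 2000
replicates, including a Kolmogorov–Smirnov check of the Δχ² null against
χ²(2); an end-to-end scan with one effect node among 20 null nodes at four
times the study's group sizes over 100 replicates; and 50 zero-discrepancy
fixed-point checks (exact implied moments must reproduce the generating
parameters to `1e-6` with `T < 1e-6`). `scripts/acceptance.R` re-runs the
recovery study from scratch on fresh seeds.

## Known limitations

Only the one-factor model family is supported (no general SEM syntax, no
categorical indicators, no missing-data FIML, no robust corrections, no
mediation structures); graphs are binary and undirected (no weighted-metric
variants, no signed-network analysis); framewise displacement is consumed,
not computed from realignment parameters; and group-level conclusions from
the scan inherit the usual caveats of Wald tests and likelihood-ratio
asymptotics at small group sizes — the package flags Heywood cases and
non-convergence but cannot make 25 subjects asymptotic.
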