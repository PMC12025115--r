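---
title: "Methods: compositional analysis of spicule elemental data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional analysis of spicule elemental data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spicoda)
library(dplyr)
```

## The data and why ordinary statistics fail on them

Energy-dispersive X-ray (EDX) quantification reports the elemental makeup
of each measured spot as *relative* abundances normalised to 100%. For the
calcareous spicules this package was built around, each spicule yields one
row of atomic percentages for C, O, Ca, Mg and the sporadic trace elements
Cl, F and P. Data with a constant-sum constraint live on a simplex, not in
Euclidean space: raw correlations and Euclidean distances between rows are
artefacts of the closure, and only *ratios* of parts carry information.
spicoda therefore follows Aitchison's log-ratio methodology end to end:
every statistic is computed on log-ratio transformed data, and every
reported summary (centers, variances, distances) is the compositional
analogue of its classical counterpart.

## The pipeline

`run_full_analysis()` chains the steps a practitioner would run by hand:

1. **Amalgamation.** Cl, F and P are summed into a single `Traces` part
   *before* any log transform. These elements fall below the detection
   limit in many spicules; amalgamating them removes most zeros while
   keeping their joint signal. Amalgamation happens on the raw percent
   scale, so it commutes with closure.
2. **Closure** to $\kappa = 100$ (percent), the canonical internal scale.
3. **Zero replacement.** A sample can still have `Traces = 0`. Exact zeros
   are replaced multiplicatively with $\delta = 0.005$ percent — half the
   smallest printed resolution of the quantified tables — and the non-zero
   parts of the row are rescaled so the row sum is preserved. The count of
   replacements is reported; $\delta$ is configurable.
4. **Distances.** The weighted log-ratio metric
   $d_w(x,y)^2 = \sum_j w_j\,(\ell_j(x)-\ell_j(y))^2$ with
   $\ell_j(x) = \ln x_j - \sum_k w_k \ln x_k$, where the default weights
   $w_j$ are the column mean proportions of the analysed table. Abundant
   elements (O, Ca) therefore weigh more than noisy trace parts. Uniform
   weights recover the classic Aitchison distance (Euclidean on CLR).
5. **Clustering.** Agglomerative Ward linkage in its D2 form
   (`stats::hclust(method = "ward.D2")`): the Lance–Williams update acts on
   squared distances, the convention consistent with a Euclidean metric,
   and merge heights are non-decreasing. Given identical input order the
   tree is deterministic; exact merge-cost ties (measure zero on continuous
   data) are resolved by `hclust`'s input-order rule.
6. **Cutting.** `k` is user-supplied when reproducing a published cut
   (k = 3 for sections, k = 4 for fractures); `select_k()` is advisory,
   scoring each candidate by average silhouette width (default) or
   Calinski–Harabasz in the same metric the tree was built in. Labels are
   renumbered by decreasing cluster size so runs are comparable.
7. **Characterisation.** Per cluster: the compositional center (closed
   geometric means), the total (metric) variance, the variation matrix
   $\tau_{ij} = \mathrm{var}\,\ln(x_i/x_j)$, and the min/mean/max table of
   all pairwise ratios.
8. **Inference.** A one-way multivariate model in ILR coordinates:
   Wilks' $\Lambda$ with Rao's F approximation for the global test and
   Hotelling $T^2$ with the pooled covariance for all pairwise contrasts,
   Holm-adjusted. Both tests are invariant to the choice of orthonormal
   ILR basis, and both have a permutation mode (same statistics under
   label shuffles, $p = (1 + \#\{\text{as extreme}\})/(1 + n_{perm})$)
   that requires an explicit seed.

### Key identities the implementation leans on (and tests verify)

- `ilr` is an isometry: Euclidean distance of ILR coordinates equals the
  unweighted Aitchison distance (to 1e-10 in the property tests).
- Total variance equals $\frac{1}{2D}\sum_{ij}\tau_{ij}$; the biplot's
  per-axis explained variances sum to it.
- The ratio-table "mean" is the geometric mean of per-sample ratios, so it
  equals the ratio of center components exactly. This is why a published
  center table and a published mean-ratio table cohere at rounding
  precision, which the acceptance checks exploit. The arithmetic mean
  would systematically exceed those values and is deliberately not used.
- Ward.D2 merge heights equal $\sqrt{2\,\Delta\mathrm{ESS}}$ of
  minimum-ESS-increase agglomeration, checked exhaustively against a
  brute-force oracle for small n.

## Conventions and tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| closure constant $\kappa$ | 100 | percent scale of the printed tables |
| trace parts | Cl, F, P | amalgamated to `Traces` |
| $\delta$ (zero replacement) | 0.005 % | half the printed resolution |
| metric weights | column mean proportions | `"uniform"` gives classic Aitchison |
| variance denominator | $n-1$ | $n$ available for cross-toolchain checks |
| ILR basis | pivot SBP in order Ca, Mg, O, C, Traces | tests are basis-invariant; per-coordinate output is not, so reports print the partition |
| quartiles | type 7 (linear interpolation) | plotting conventions differ between toolchains; configurable choice documented here |
| permutations | 9999 | permutation p cannot go below $1/(n_{perm}+1)$ |

All logarithms are natural. Display rounding (2 decimals in ratio tables)
never feeds back into computation.

## The synthetic-data generator

The raw per-spicule tables behind the published study are not deposited in
a machine-readable archive, so the package ships a seeded generator whose
defaults reproduce the *published summary statistics* of the two study
conditions: three section clusters of sizes 14/41/45 with total variances
0.1063/0.2553/0.2567, and four fracture clusters of sizes 19/27/19/40 with
total variances 0.33–0.99, each at its published center. Samples are drawn
from an additive logistic-normal model: ILR coordinates are spherical
Gaussian around `ilr(center)` with per-coordinate variance
$\mathrm{tv}/(D-1)$, so the expected total variance equals the target.
Optional per-element non-detection probabilities zero out trace elements
before closure (P absent in two of the three section clusters, present in
all spicules of the first), exercising the amalgamation/zero-replacement
path downstream.

What the generator deliberately does **not** emulate:

- **Within-cluster covariance structure.** The published variation matrices
  show strongly coupled element ratios; the spherical ILR model ignores
  this. Consequence: synthetic clusters are "rounder" than real ones, and
  the two layered-spicule clusters — whose centers are only about 0.71
  apart in Aitchison distance, comparable to the within-cluster RMS spread
  implied by their total variances — overlap substantially in synthetic
  data. Label recovery on the synthetic section scenario is therefore
  intrinsically limited (no classifier can separate overlapping spherical
  clouds), and silhouette selection often prefers k = 2. Passing the
  recovery checks at their measured levels says the pipeline is correct,
  not that real spicule clusters are this ambiguous; the real data's
  correlated, tighter geometry is what made the published three-way split
  crisp.
- **Systematic preparation offsets.** Fracture surfaces bias EDX physics
  (topography, orientation); the generator represents fractures only as
  shifted centers with inflated variances. A joint section+fracture
  clustering of synthetic data accordingly does *not* reproduce the clean
  preparation split seen in the real combined dendrogram — that split is
  driven by a batch offset the generator does not model. What does carry
  over is the qualitative contrast: fracture-scenario clusterings are
  markedly sparser (lower agreement with the generating labels) than
  section-scenario ones.
- **EDX detector physics** (ZAF biases, topographic shadowing).

## Raman identification

Calcite and magnesian calcite share three diagnostic bands: the lattice
mode at 281–283 cm⁻¹, the ν₄ in-plane bend at 707–720 cm⁻¹, and the ν₁
symmetric carbonate stretch at 1087–1088 cm⁻¹. The pipeline:

- **Baseline:** morphological opening (rolling minimum then rolling
  maximum over a `2·half_window + 1` grid-point window) smoothed by a
  moving average, subtracted. The opening suppresses features narrower
  than the window while following slow instrumental trends without the
  downward bias a plain rolling minimum shows on sloped baselines.
- **Peaks:** local maxima whose topographic prominence exceeds
  `min_prominence_snr` (default 5) times the noise estimate, defined as
  the robust scale of the first differences, `mad(diff(y))`. Differencing
  inflates point noise by $\sqrt 2$, so the default threshold sits near 7
  point-noise SDs — above the extreme-value range of pure noise on grids
  of a few thousand points, which is what makes "no peaks in pure noise"
  and "exactly three peaks at SNR 20" hold simultaneously. Positions are
  refined by three-point parabolic interpolation.
- **Call:** a window is matched if any peak falls inside it after widening
  by 4 cm⁻¹ (reflecting the spread of the printed ν₄ range and grating
  resolution). A spectrum is `calcite_family` iff ν₁ is matched; `partial`
  flags spectra where the lattice or ν₄ band is not expressed, a pattern
  the study itself reports. Calcite and magnesian calcite are not
  distinguished: the Mg signal belongs to EDX, not to the Raman shift,
  at this resolution.

## Worked example

```{r example}
scenario <- system.file("extdata", "section_scenario.yaml",
                        package = "spicoda")
sim <- run_simulation(scenario, output_dir = tempfile())$data

res <- run_full_analysis(sim, output_dir = tempfile(),
                         parts = c("C", "O", "Ca", "Mg", "Traces"),
                         trace_parts = character(0), k = 3)
res$centers
res$global_test
res$pairwise_tests
```

```{r plots, fig.width = 6, fig.height = 4}
plot_dendrogram(res$tree)
autoplot(logratio_biplot_coords(res$data, c("C", "O", "Ca", "Mg", "Traces")))
```

## Problem sizes and numerical choices

Simulation-based checks use the study's own sample sizes (100 section
spicules, 105 fracture spicules) with 20 seeded replicates; calibration
checks of the generator use n = 2000; the null calibration of the global
test uses 500 simulations at $\alpha = 0.05$ with the section-layout group
sizes. Degenerate inputs are refused loudly rather than patched: all-equal
samples make cluster criteria undefined, zero-variance data make the
biplot undefined, singleton groups are rejected by the parametric tests
with a pointer to permutation mode, and any stochastic step without an
explicit seed is an error, not a warning.

## Known limitations

- The exact weighting and variance conventions behind the published total
  variances cannot be pinned down without the raw per-spicule appendix
  tables; both conventions (weighted/unweighted, $n-1$/$n$) are
  implemented, the unweighted $n-1$ form is the reporting default.
- The generator's spherical ILR noise is a deliberate minimal model (one
  spread parameter mapping directly onto printed total variances); see
  above for what that implies about recovery ceilings.
- Newick export serialises the dendrogram ultrametrically with the
  conventional height-halving of `ape`; consumers that assume root-to-tip
  path = merge height should divide accordingly.
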