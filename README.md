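# spicoda

Compositional data analysis (CoDA) of biomineral elemental compositions,
built for EDX measurements of calcareous spicules — the skeletal elements
of dorid nudibranchs and similar invertebrates — but applicable to any
samples-by-elements table of relative abundances.

## The problem and the approach

EDX quantification normalises each measurement to 100%, so the data are
*compositions*: only ratios of parts carry information, and classical
statistics applied to the raw percentages produce closure artefacts. spicoda
implements the Aitchison log-ratio toolbox around that fact:

- **Transforms and statistics**: closure, amalgamation of trace elements
  (Cl + F + P → `Traces`), multiplicative zero replacement, CLR/ILR
  transforms on a sequential-binary-partition basis, compositional centers
  (closed geometric means, so `center_i / center_j` = geometric mean of the
  sample ratios), variation matrices `var ln(x_i/x_j)`, total (metric)
  variance, and (weighted) Aitchison distances.
- **Clustering**: Ward.D2 agglomeration on weighted log-ratio distances
  (default weights = column mean proportions), tree cutting with
  size-ordered labels, silhouette / Calinski–Harabasz k-selection, Newick
  dendrogram export.
- **Inference**: one-way MANOVA in ILR coordinates — Wilks' Λ with Rao's F
  for the global test, pairwise Hotelling T² with pooled covariance and
  Holm adjustment — each with a seeded permutation mode. All results are
  invariant to the choice of orthonormal ILR basis.
- **Descriptive outputs**: per-cluster ratio tables (min / geometric mean /
  max), log-ratio boxplot statistics, centered ternary coordinates against
  the geometric mean of the remaining elements, and log-ratio biplots (SVD
  of the centered log matrix) with ggplot2 helpers.
- **Synthetic data**: a seeded logistic-normal generator parameterised
  directly by published cluster summaries (center, total variance, n,
  trace non-detection probabilities), plus a pseudo-Voigt Raman spectrum
  generator.
- **Raman identification**: morphological-opening baseline correction,
  prominence-based peak detection, and classification against the three
  calcite-family windows (281–283, 707–720, 1087–1088 cm⁻¹).

All user-facing functions take a data frame first and return tibbles, so
analyses chain with the pipe; fitted models support `tidy()`/`glance()`.

## Worked example

Simulate the three-cluster "section" scenario shipped with the package and
run the full pipeline at k = 3:

```r
library(spicoda)

scenario <- system.file("extdata", "section_scenario.yaml", package = "spicoda")
sim <- run_simulation(scenario, output_dir = tempfile())$data

res <- run_full_analysis(sim, output_dir = tempfile(),
                         parts = c("C", "O", "Ca", "Mg", "Traces"),
                         trace_parts = character(0), k = 3)
res$centers
#> # A tibble: 3 × 8
#>   cluster     n     C     O    Ca    Mg Traces total_variance
#>   <chr>   <int> <dbl> <dbl> <dbl> <dbl>  <dbl>          <dbl>
#> 1 1          62  8.96  61.3  24.0  3.41   2.25          0.359
#> 2 2          24  8.48  48.3  38.4  2.91   1.96          0.317
#> 3 3          14 19.4   46.6  19.9  1.63  12.6           0.134
```

The small high-carbon, high-trace cluster (14 spicules, row 3) is recovered
cleanly; the two layered-type clusters overlap under the generator's
spherical noise model (see the methods vignette), so their recovered
centers blend the generating ones. The group tests show the clusters differ
sharply in mean composition:

```r
res$global_test
#> # A tibble: 1 × 8
#>   statistic_name statistic f_value   df1   df2  p_value method    
#> 1 Wilks lambda      0.0717    64.3     8   188 9.36e-50 parametric

res$pairwise_tests[, c("group1", "group2", "statistic", "p_adjusted")]
#> # A tibble: 3 × 4
#>   group1 group2 statistic p_adjusted
#> 1 1      2           111.   6.56e-15
#> 2 1      3           531.   9.12e-37
#> 3 2      3           396.   5.15e-32
```

`run_full_analysis()` also writes the whole report bundle (cluster
assignments, center/ratio/variation tables, Newick dendrogram, test table,
run log) as plain-text files into `output_dir`, and re-running the same
configuration is bit-identical.

For Raman spectra:

```r
sp <- generate_raman_spectrum(
  data.frame(center = c(282, 712, 1087), fwhm = c(8, 10, 6),
             amplitude = c(90, 80, 120)),
  baseline = c(60, 0.03), noise_sd = 5, grid = c(100, 1500, 1), seed = 1)
match_mineral(detect_peaks(subtract_baseline(sp, 50)))
#> Mineral call: calcite_family 
#>   windows matched: nu_lattice, nu4, nu1
```

## Documentation

The methods vignette (`vignettes/spicule-coda-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic-data generator does and does not emulate
about real EDX data, and known limitations.
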