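# clinemorph

Individual-based analysis of secondary contact zones between parapatric
species: geometric morphometrics, discriminant species assignment, phenotypic
covariance (**P**) matrix comparison, maximum-likelihood sigmoid cline
fitting, sliding-window covariance scans, and environmental niche overlap —
plus a synthetic contact-zone simulator with known ground truth so the whole
pipeline can be validated end to end without any field data.

## The scientific problem

When two young species recolonize a region from different glacial refugia
they can meet along a narrow secondary contact zone. Whether such contact
leads to hybridization, reinforcement of reproductive barriers, or stable
mutual exclusion is read off several quantitative signals collected along a
transect through the zone:

* **Geographic clines.** A trait or ancestry score `y`, rescaled to [0, 1],
  is modelled along transect position `x` (km) as

  ```
  E[y | x] = y_L + (y_R - y_L) / (1 + exp(-4 (x - c) / w))
  ```

  with center `c` and width `w` (the factor 4 makes `1/w` the maximum slope
  of a 0-to-1 cline, the conventional width definition). Parameters are
  estimated by Gaussian maximum likelihood over individuals, the sigmoid is
  compared with a constant "no cline" model by AIC, and confidence intervals
  come from the profile likelihood (cutoff `qchisq(0.95, 1)/2 = 1.9207`).
  Coincident, narrow phenotypic and genomic clines indicate a sharp species
  transition.

* **P-matrix comparison.** The phenotypic variance–covariance matrix **P**
  (a surrogate for the genetic **G** matrix) summarizes how trait variation
  is oriented. Two populations are compared by the angle between their
  leading eigenvectors (the "lines of least resistance"),
  `theta = arccos(|p_max,1 · p_max,2|)`, and by the affine-invariant matrix
  distance `sqrt(sum(log^2 lambda_i))` over the generalized eigenvalues of
  the pair. Significance is established by bootstrap: the observed statistic
  must exceed the 95th percentile of both populations' within-population
  resampling null distributions.

* **Species assignment.** Specimens without genotypes are assigned with a
  two-class linear discriminant trained on genotyped individuals
  (`w = S_pooled^-1 (mu_A - mu_B)`), and only specimens inside a per-class
  97% chi-square confidence region of their assigned centroid are retained.

* **F1 detection.** At diagnostic SNPs (allele-frequency difference ≥ 0.9
  between species) an F1 hybrid has hybrid index ≈ 0.5 and is heterozygous
  at essentially every site; backcrosses shift the index toward a parent
  while halving heterozygosity.

* **Niche overlap.** Environmental niches are compared on kernel-density
  surfaces in a PCA ordination via Schoener's `D = 1 - sum|z1 - z2|/2` and
  Warren's `I = 1 - sum(sqrt(z1) - sqrt(z2))^2/2`, with randomization
  similarity tests.

## Worked example

Simulate a 300-specimen transect with the species transition at 9 km, align
the wing landmarks, and fit a cline to the leading shape axis:

```r
library(clinemorph)

cfg <- simulation_config(n_individuals = 300, seed = 42)
sim <- simulate_transect(cfg)
sim
#> <transect_simulation> 300 specimens (187 A, 111 B, 2 hybrid), 118 genotyped, 300 SNPs

gpa   <- generalized_procrustes(sim$wings)
shape <- pca(size_correct(gpa$aligned, sim$specimens$wing_length))
shape
#> <shape_scores> 300 specimens, 46 components; leading var fractions: 0.436 0.362 0.120 0.019 0.011

y   <- rescale01(shape$scores[, 1])
fit <- fit_cline(sim$specimens$distance_km, y, seed = 1)
fit$center_ci <- as.numeric(profile_ci(fit, sim$specimens$distance_km, y, "center_km"))
fit
#> <cline_fit> center = 9.024 km [9.023, 9.024], width = 1 m (at floor), ends 0.264 -> 0.743, AIC -498.1
```

The fitted center (9.024 km) recovers the generating contact at 9.0 km; the
width collapses to the 1 m floor (flagged "at floor") because the simulated
phenotype switches with species identity and carries no intermediate
individuals. Comparing two populations whose leading eigenvectors were
generated 60° apart:

```r
two <- simulate_two_populations(500, pmax_angle_deg = 60, seed = 1)
cmp <- bootstrap_compare(two$XA, two$XB, "theta", n_boot = 1000, seed = 1)
cmp
#> <angle_comparison> theta (deg) = 60.569, p = 0.0000 (significant), null q95 = 4.373 / 4.694, B = 1000
```

The estimated angle (60.6°) matches the generating 60°, and the observed
value far exceeds both populations' resampling nulls (≈ 4.4°/4.7° at the 95th
percentile), so the difference in covariance orientation is significant.

The full pipeline — alignment, assignment with the 97% filter, genotype
filtering, F1 detection, all cline fits, P-matrix comparisons, the
sliding-window scan and niche overlap — runs from one configuration:

```r
report <- run_pipeline(paper_scale_preset(seed = 1))
report_summary(report)   # one line per result; widths below 1 km print in meters
```

A YAML config with an `inputs:` block (TPS landmark files, specimens.csv,
VCF, env.csv) runs the same pipeline on real data; see `?run_pipeline`.

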