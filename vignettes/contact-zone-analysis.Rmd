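---
title: "Methods: individual-based contact-zone analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-based contact-zone analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clinemorph)
```

This vignette documents the statistical models implemented in `clinemorph`,
the assumptions behind them, the design choices that were genuinely open, and
what the synthetic validation data do and do not establish.

## Morphometric preprocessing

Landmark configurations (2-D, read from TPS files) are superimposed by
generalized Procrustes analysis: translation is removed by centering, size by
scaling every configuration to unit centroid size, and orientation by
rotating each configuration onto an iteratively updated consensus
(convergence when the consensus moves by less than `tol = 1e-8`; the fresh
consensus is re-aligned to the previous one so the shared orientation cannot
drift across iterations). Two choices deserve note:

* **No reflections during alignment.** Structures digitized from the other
  side of the body are mirrored explicitly with `reflect_config()` before
  superimposition, mirroring how flipped scans are handled upstream; allowing
  reflections inside the optimizer could silently "fix" digitization errors
  that should be caught.
* **Full scaling to unit centroid size** (rather than partial Procrustes),
  the standard convention of the common morphometrics toolchains, so
  downstream covariance matrices are pure shape covariances.

Size effects on the trait values themselves are removed by regressing each
trait on measured wing length (landmarks 1–4 in raw digitized units) and
keeping the residuals. The same wing-length measure is used for all three
trait blocks — wing shape, the orange-spot landmark subset, and genital
shape — because it is the only body-size proxy carried by the data; the
genital block has no independent size measure.

Which wing landmarks delimit the orange spot is configuration, not a
constant: the landmark scheme does not fix it, so `spot_landmarks` is an
explicit input (default `10:16` in the simulator, chosen arbitrarily as a
contiguous subset of the template outline).

PCA of shape variables uses the covariance matrix (no variable scaling —
Procrustes coordinates share units) with an `n − 1` denominator, and a sign
convention (largest-magnitude loading positive) so score signs, and hence
cline orientations, are reproducible.

## Species assignment and confidence filtering

Ungenotyped specimens are assigned with a two-class linear discriminant
trained on genotype-labeled individuals, under equal-covariance Gaussian
class-conditionals with priors taken from training class frequencies. Because
Procrustes coordinate blocks are rank-deficient (each block loses 4
dimensions to the superimposition), the pooled covariance receives a ridge of
`1e-8 · trace/dim` whenever it is near-singular; in the pipeline the
discriminant instead runs on leading PC scores per block (4 wing + 3 spot +
4 genital by default), which keeps it well-conditioned and makes the trait
space interpretable.

The "97% confidence" retention rule is operationalized as a per-class
multivariate region: a specimen is kept when its squared Mahalanobis distance
to its assigned class centroid is within `qchisq(0.97, d)`. A per-class
(rather than pooled) region was chosen because the two species differ in
covariance orientation — exactly the signal the study quantifies — and a
joint region would preferentially discard members of the more variable
species. A `joint = TRUE` flag provides the alternative.

## P-matrix comparison

Populations are compared by two statistics:

* **theta**, the angle between leading eigenvectors, computed as
  `arccos(|p1 · p2| / (‖p1‖‖p2‖))` in degrees. The absolute value makes the
  statistic invariant to eigenvector sign, which is arbitrary. A
  `literal_sum` flag computes the sum-of-norms variant
  (`arccos(p1 · p2 / (‖p1‖ + ‖p2‖))`) for sensitivity analysis only: that
  expression is not a cosine of anything and is kept purely to quantify how
  much the normalization convention matters.
* **matrix distance**, by default the affine-invariant (log generalized
  eigenvalue) metric `sqrt(Σ ln² λᵢ)`, which is symmetric, zero only for
  equal matrices, and unchanged by any common linear change of trait basis —
  the natural reading of a "distance between two covariance matrices". A
  mean-vector Mahalanobis distance under the pooled covariance is available
  (`method = "mean_mahalanobis"`) since "Mahalanobis distance" between
  populations often denotes that instead; both are reported nowhere as
  interchangeable.

**Bootstrap significance.** Each population is resampled with replacement at
its own size; the observed between-population statistic is called significant
when it exceeds the 95th percentile of *both* within-population null
distributions, and the p-value is the larger exceedance fraction. The null
statistic is, by default, computed **between two independent bootstrap
replicates** of the same population. The superficially simpler alternative —
replicate versus the population's point estimate — carries only one sample's
estimation noise while the observed statistic carries two, and in our
calibration simulations (two samples of n = 200 from the same 5-trait
distribution, 1000 replicates, 200 repeats) it flagged significance in about
a fifth of null cases; the replicate-pair null brings the rate to the nominal
few percent. The point-estimate null remains available via `null = "point"`.

In the sliding-window scan, P matrices are estimated on the leading 10 PC
scores of each species' trait block rather than on the raw 46 Procrustes
coordinates: with 30 individuals per window a 46-dimensional covariance is
badly rank-deficient and its leading eigenvector unstable, while 10
dimensions retain almost all shape variance at these simulation settings and
keep the 10,000-fold resampling loops fast. Windows hold 30 individuals and
step by 10, ordered by distance from the point of contact (the fitted genomic
cline center unless overridden); the reference set is the 30 individuals
furthest from contact on the species' own side, fixed across windows and
disjoint from them. The trend over windows is assessed by OLS of the window
statistic on mean distance from contact, species, and their interaction, with
the bootstrap significance state as an additive fixed covariate (dropped when
constant). A mixed model with a two-level "significance" random effect would
be near-unidentifiable, which is why the fixed-covariate approximation was
preferred.

## Cline fitting

Scores are rescaled to [0, 1] and modelled as Gaussian around
`y_L + (y_R − y_L)/(1 + exp(−4(x − c)/w))`. The `4/w` parameterization makes
`w` the conventional width (inverse of the maximum slope for a 0→1 cline), so
widths are comparable across trait sets. Numerical details:

* For fixed `(c, w)` the end values and residual SD have closed-form MLEs
  (the mean is linear in them), so the search is 2-dimensional. It is run
  from `n_starts = 20` starting points (centers on deciles of `x` with seeded
  jitter, widths log-uniform) because the likelihood is multi-modal in `c`;
  L-BFGS-B bounds keep `c` inside the observed range and `w` in
  `(width_floor, range(x))`.
* `width_floor = 0.001` km (1 m) keeps the likelihood finite for step-like
  data; a fit at the floor carries a `width_boundary` flag. This matters
  because real contact-zone clines can be tens of meters wide on a ~15 km
  transect.
* Residuals are homoscedastic Gaussian. That is a simplification — scores
  near the transition could plausibly be more variable — but with no stated
  error model to the contrary, the 2-parameter noise model keeps AIC
  comparisons (`sigmoid`, k = 5, versus `constant`, k = 2) clean. Only those
  two mean models are in the AIC set; tailed/stepped clines are out of scope.
* Profile-likelihood CIs re-optimize the nuisance member of `(c, w)` at each
  fixed value of the other and cut at `qchisq(level, 1)/2`. The 1-D nuisance
  search is additionally floored at the likelihood evaluated with the
  nuisance held at its joint MLE: near-step fits make the profile surface
  spiky, and a pure golden-section search can miss the spike and collapse the
  interval. Endpoints are located by bisection to `1e-4` km; a profile that
  never crosses the cutoff before the parameter bound yields a one-sided
  interval flagged `boundary`.

## Genotype filtering and F1 detection

Variant filters are applied in a fixed order — non-biallelic sites, sites
with genotype-quality summary ≤ 20, depth (entries outside [5, 30] masked to
missing when per-entry depths exist, otherwise a site-mean rule), sites with
more than 60% missing entries, then minor allele frequency < 0.04. Masking
before the missingness test is the conservative ordering: a site whose
genotypes are unreliable for depth reasons should count as missing data, not
as evidence. In the loss report a site removed at the missingness step is
attributed to the depth rule when it would have survived without masking, so
the per-rule losses always sum to `sites_in − sites_out`.

The hybrid index of a specimen is the mean proportion of B-type alleles over
its non-missing diagnostic sites (allele-frequency difference ≥ 0.9 between
reference groups), and interspecific heterozygosity the fraction of
heterozygous diagnostic genotypes. The F1 call box — index in [0.4, 0.6] and
heterozygosity ≥ 0.85 — is an implementation threshold, not a literature
constant: a true F1 sits at (0.5, 1.0) exactly, first-generation backcrosses
at (0.25 or 0.75, 0.5), so the box cleanly separates them with slack for
missing data and genotyping error; both thresholds are exposed as arguments.

## Niche overlap

Environmental variables are pruned by variance inflation factor (drop the
worst until all VIF ≤ 10), then by pairwise correlation (while any |r| >
`r_max`, drop the member of the worst pair with the higher mean absolute
correlation; ties resolve to the later column). Occurrence densities are
kernel estimates on a shared 100×100 grid spanning the background, with
Silverman bandwidths computed on the background and shared by occurrence and
background densities (so identical inputs give an exactly flat
availability-corrected surface); occurrence density is divided by background
density on occupied cells and renormalized. Schoener's D and Warren's I are
computed cell-wise. The similarity test translates the second group's density
to random background cells, truncating and renormalizing, and uses the
add-one p-value estimator `(1 + k)/(n_rep + 1)` so finite replication never
reports p = 0; both test directions are available because "not more diverged
than expected" (greater) and "more diverged" (lower) are different questions.

## The synthetic transect generator

`simulate_transect()` generates the complete study design with known truth:
positions uniform on a 14.58 km transect; species drawn per individual from a
sigmoid of width `cline_width_km` (default 0.125 km) centered at
`contact_km = 9.0` (a `hard_split` flag gives the deterministic split);
landmark configurations built around fixed wing (23 landmarks) and genital
(11 landmarks) template outlines, with species mean shapes offset by
`shape_divergence` (default 0.02 Procrustes units, about six within-species
SDs along the offset axis — strong enough for reliable discriminant
assignment, weak enough that the leading PC is not pure species separation)
and within-species covariance constructed in the shape tangent space with a
declared eigen-spectrum and a controllable angle between the two species'
leading eigenvectors (default 45°); genotypes with diagnostic sites fixed
between species and background sites at shared Beta(2, 2) frequencies, 2%
missingness, Poisson depths; F1 hybrids at rate `f1_rate` (default 3/464,
i.e. about three expected per study), heterozygous at every diagnostic site,
landmark means at the parental midpoint, placed uniformly within half a cline
width of the contact (capped at 0.25 km) because F1s can only arise where
both parents fly; and environmental variables following logistic spatial
gradients centered at 3.0 km — deliberately west of the species transition —
plus Gaussian noise and three redundant columns that exercise variable
selection.

What the generator does **not** emulate: continuous clinal variation within
species (each individual is fully one species' phenotype plus noise, so
phenotypic clines in the simulation are steps blurred only by sampling —
their fitted widths routinely collapse to the 1 m floor, whereas the genomic
cline, which includes F1s at ancestry 0.5, retains genuine width);
backcrosses and later-generation hybrids; linkage and coalescent structure in
the background SNPs; measurement error in landmark placement beyond isotropic
tangent-space noise; and allopatric reference populations (all simulated
specimens sit on the contact transect, so the pipeline's "interspecific"
P-matrix comparison uses the transect-end reference sets). Passing tests on
this generator therefore validate the estimators and their calibration — not
the biological richness of any particular dataset.

## Validation problem sizes

The test suite exercises: angle recovery at n = 500/population, 50 replicates
per generating angle; bootstrap type-I calibration at n = 200/population,
B = 1000, 200 repeats; cline center accuracy over 100 replicates and profile
CI coverage over 200 replicates at n = 400, width 0.2 km, noise SD 0.1; and a
full paper-scale pipeline run (464 specimens, 300 SNPs, window size 30/step
10, B = 499 for windowed comparisons, 1000 niche randomizations). These sizes
were chosen to give Monte-Carlo error comfortably inside each asserted
tolerance while keeping a full validation run in a few minutes.

## Known limitations

* Cline width estimates from near-binary scores are weakly identified; rely
  on the profile CIs and the `width_boundary` flag rather than point widths.
* The bootstrap comparison assumes within-population exchangeability; spatial
  autocorrelation inside a window would make the null optimistic.
* The niche similarity null translates a density rigidly; it does not reshape
  it, so strongly curved backgrounds may make the null too easy to beat.
* `run_pipeline()` resumes only its most expensive stage (the window scan,
  cached as JSON keyed by seed and window settings); cheaper stages are
  recomputed on every call.
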