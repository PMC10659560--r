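---
title: "chromAge: model, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromAge: model, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromAge)
```

`chromAge` computes an imaging-based chromatin/epigenetic age (ImAge) from
the texture of epigenetic-mark immunostaining in single nuclei. This
vignette is the package's own account of the method: the model behind each
step, the parameters that matter and their defaults, what the synthetic
generators do and do not emulate, and the choices made where the design was
genuinely open. Everything quantitative stated here is computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## 1. From images to features

The pipeline consumes multi-channel images of nuclei together with an
integer label mask from an external segmenter (`loadLabeledImage()`).
Flat-field/illumination correction is expected upstream; the loader only
records whether it was declared (`illumination_corrected`). Nuclei smaller
than a disc/sphere of radius `min_radius_um` are removed
(`filterSmallObjects()`); the default of 4 µm sits mid-range of the
3–7 µm working band that typical mammalian nuclei span across tissues and
microscopes, and the filter runs before feature extraction because the two
orders are equivalent and filtering first is cheaper. Area comparison keeps
records at or above the threshold, so "smaller than r" is what is removed.
Z-stacks can be analyzed as voxels (`mode = "3d"`) or, the default, as a
2D maximum projection over z per channel.

**Band-pass binarization.** For each nucleus and channel, the mean masked
intensity `v_m` defines 28 intervals (`bandIntervals()`): one static
`(v_m, ∞)`, plus three families at width factors `p = 0.1 … 0.9` —
lower-bounded `(v_m − v_m·p, ∞)`, upper-shifted `(v_m + v_m·p, ∞)`, and
symmetric bands `(v_m − v_m·p, v_m + v_m·p]`. The endpoint convention is
`lo < value ≤ hi`: it excludes exactly-mean pixels from the static interval
deterministically, and makes the band family nested (foreground grows
monotonically with `p`, a property the tests assert). Since `p ≤ 0.9`,
lower bounds never go negative. `v_m` is computed per nucleus per channel
over masked pixels only, which makes all features invariant to global
intensity rescaling of a nucleus — an important robustness property under
staining/illumination variation, asserted exactly in the tests.

**Threshold adjacency statistics.** Each binarization is summarized by the
distribution of foreground-neighbor counts over foreground pixels
(`tasStatistics()`): 8-connectivity in 2D (counts 0–8), 26-connectivity in
3D (0–26); out-of-mask and out-of-image neighbors count as background.
Each 9- or 27-bin block is a probability vector (sums to 1), or all zeros
when a binarization has no foreground — zeros rather than NaN, with the
per-block foreground counts kept as a QC attribute. The full vector is
`28 × 9 = 252` per channel in 2D, `28 × 27 = 756` in 3D, concatenated in
the requested channel order with a frozen within-channel ordering
(family, then `p` ascending, then count `k` ascending), so tables are
comparable across runs. The vectorized implementation is verified against
a brute-force per-pixel neighbor scan on random 2D and 3D masks.

## 2. Bootstrap means, z-scoring, and the axis

**Why bootstrap means.** Aging shifts the *composition* of a cell
population more than it shifts individual cells: a T cell from a young and
an old animal can look identical while the type ratios differ. Averaging
200 cells drawn with replacement from one animal (`bootstrapMeans()`,
defaults 200 cells × 1000 bootstraps per animal) turns composition shifts
into mean shifts and equalizes the number of data points per animal.
Sampling strata are always single animals.

**Standardization.** Features are z-scored with parameters fitted on the
training rows only (`zscoreFit()` / `zscoreApply()`); zero-variance
features get scale 1 and become constant 0 (logged via an attribute)
rather than propagating NaN. Held-out rows are always transformed with the
training parameters — the no-leakage property is tested directly.

**The axis.** `fitCentroidAxis()` runs from the young centroid to the old
centroid (origin at the young centroid); `fitSVMAxis()` uses the unit
normal of a linear soft-margin SVM (cost default 1, recorded in the axis
metadata so runs are comparable) with origin at the centroid of all
training rows. Both are oriented so the old group projects higher. The
readout is the scalar projection `p`; the orthogonal distance
`d_o = sqrt(‖x − origin‖² − p²)` (tiny negative radicands from
floating-point cancellation are clamped at 0). The SVM variant is the
robust choice when a reference group is a skewed mixture — the tests show
it beating the centroid axis on exactly such fixtures — while the centroid
axis is parameter-free and easier to interpret. On clean drift fixtures
the two produce rank-equivalent readouts.

**Validation protocol.** `validateAxis()` repeats, 100 times by default:
sample 75% of the young/old rows for training (stratified within each
reference animal so every animal and both classes appear in every training
set; whole-animal splits available via `level = "animal"`), fit the
standardizer and axis on the training rows, project the held-out rows, and
score young/old accuracy. Middle-aged and perturbation groups are
test-only by construction. Per-animal readouts are medians of held-out
projections (mean available; the choice is recorded in the output).
Whether splits should act on bootstrap rows or whole animals is genuinely
open; row-level is the default because reference cohorts are small, and
the animal-level option exists for strict generalization claims — the null
calibration test uses it, since row-level splits share animals between
train and test and therefore inherit an optimistic bias under the null.

`axisVarianceFraction()` reports Var(p) over the summed per-feature
variance; `ageCorrelation()` reports Pearson and Spearman statistics on
per-animal summaries; `organPairSpearman()` flags an organ pair as robust
only if it stays significant (Bonferroni-adjusted over
pairs × channels × subsets) in the full age set *and* every
leave-one-age-group-out subset, so a correlation driven by a single age
group does not qualify. The min-max display normalization sometimes used
for plotting readouts is presentation-layer and intentionally not part of
the computation.

## 3. Information distance and hyperbolic geometry

`informationDistance()` estimates the normalized variation of information
`D = (2H(X,Y) − H(X) − H(Y)) / H(X,Y)` from histograms of the two feature
vectors (bin width `h = 0.1`, ten bins on `[0,1]`, final bin closed) and
the joint histogram of paired values; `D := 0` when the joint entropy is
0. `D` lies in `[0,1]`, is symmetric, and is base-free because it is a
ratio of entropies (asserted by computing it in bases 2, e, 10). Min-max
normalization is computed over the union of the two samples being
compared by default — the two vectors must share a scale for the joint
histogram to be meaningful — and can be disabled when data are already
normalized per dataset.

`emds()` (classical scaling) and `hmds()` embed a distance matrix with
Shepherd-diagram R² and Kruskal stress-1 diagnostics. The hyperbolic
embedding uses the Lorentz/hyperboloid model, numerically stabler for
optimization than the Poincaré ball: points are parameterized by their
spatial coordinates (the timelike coordinate is reconstructed), so the
hyperboloid constraint holds exactly at every step; curvature `−κ` only
scales distances (`d = acosh(−⟨x,y⟩_L)/√κ`). Stress is minimized by BFGS
with an analytic gradient, multi-started (5 starts: a scaled classical-MDS
configuration plus seeded perturbations) keeping the best stress, which
makes the result deterministic given the seed. The stress functional is
unweighted squared stress. `selectGeometry()` grid-searches dimension and
curvature, maximizing Shepherd R² with ties broken toward the smallest
dimension then the smallest curvature; per-dataset fitted κ values are
data properties, not constants of the method.

`hyperbolicCentroid()` is the Karcher mean via iterated log/exp tangent
averaging (tolerance 1e−8). `hyperbolicImAge()` projects points onto the
geodesic through the young and old centroids by a 1-D unimodal search
(distance to a geodesic is convex in a Hadamard space), scaled so `p = 0`
at the young centroid and `p = d_H(a,b)` at the old one. In the
flat-space limit (near-origin points) the geodesic readout converges to
the Euclidean projection — the tests bound the discrepancy. The variance
fraction along the geodesic is defined in the tangent space at the
geodesic midpoint: Var of the tangential component over the total tangent
variance; points on the geodesic give 1, an isotropic d-dimensional cloud
about 1/d.

## 4. Identity erosion

`silhouetteByAge()` computes silhouette scores of cell-type separation per
age group directly on raw data (no embedding bias), under Euclidean or
information distance, with a bootstrap (default 100 replicates) for CIs.
Because the distance matrix is O(n²), cells are subsampled (default 200
per age; the erosion analyses in the tests use 250, where adjacent-age
score differences are resolved reliably). `ksDistanceProfile()` computes
per-feature two-sample KS statistics between type pairs (up to 5000 cells
per type and age, without replacement, seeded; fewer are used, and
recorded, when unavailable) and averages over the `choose(N,2)` pairs —
identical to the single pairwise KS when there are two types.

`significantErosionFeatures()` applies a two-stage gate: the feature must
separate types (all per-pair KS tests at the youngest age significant at
α) with the KS-vs-age Pearson correlation significant and `|r|` above the
first threshold (default 0.85), and the correlation must additionally
clear the stricter second threshold (default 0.95). Whether the first
stage's correlation gate refers to cross-type or per-feature tests is
genuinely ambiguous; the implementation requires per-feature KS test
significance plus both correlation gates and logs all components so either
reading can be audited. Both thresholds are configuration because
different tissue panels warrant different stringency. Negative passing
correlations are the erosion signature; on planted fixtures where type
separation shrinks with age, the passing set is essentially all negative.

## 5. Signature cells and rejuvenation reports

Single cells are projected with the axis and standardizer trained on
bootstrap means (`singleCellReadouts()` — no refitting). Single-cell
distributions are wider than bootstrap-mean distributions and the
young/old accuracy at single-cell level is correspondingly lower; that
residual heterogeneity is the object of interest. `callSignatures()`
labels a cell a young signature if its readout is strictly below the old
group's `q_old`-th percentile and an old signature if strictly above the
young group's `q_young`-th percentile (defaults 5 and 95; 0/100 gives the
purity limit where signatures only occur outside the other group's
observed range). Percentiles use the inverse-ECDF convention (R quantile
type 1): the threshold is then an observed readout and the defining bound
— at most 5% of the old reference below the young-signature threshold —
holds at every sample size, which interpolation-based conventions violate
for small samples. Ties at a threshold are intermediate, and a cell
extreme for *both* references (possible when the groups separate so far
that the thresholds cross) is ambiguous and stays intermediate.
Proportions sum to 1 per animal and the labels are invariant under any
strictly monotone transform of the readouts.

`reprogrammingReport()` compares young, old, and treated groups: per-animal
medians, rank tests of every animal against the "youngest" old animal
(lowest old median), a Levene-type variance comparison (rank test on
absolute deviations from group medians) of treated vs old readouts, and
signature-proportion deltas against that reference animal.

## 6. Behavior association

`filterBehaviors()` removes readouts whose correlation p-value with the
age readout exceeds 0.3 (under the null this removes ~70%, as the
calibration test checks). `clusterBehaviors()` groups the survivors by
average-linkage clustering under `1 − |r|`; the cut is
silhouette-optimal, with near-ties (within 0.02, below the resolution of
silhouette differences at these sample sizes) resolved toward the finer
cut because the goal is mutually orthogonal clusters. Everything mutually
correlated collapses to one cluster; mutually orthogonal readouts become
singletons; the cluster count is an outcome, never a parameter.
Representatives are cluster medoids — several defensible selection rules
exist, and the medoid is the least arbitrary single readout.

`optimizeAlpha()` maximizes the correlation `R` of `Fα` with the age
readout under `Σα² = 1`. Because `R` is scale-invariant in `α`, the
maximizer on the unit sphere is the normalized OLS solution of the normal
equations on centered data, and `R` equals the multiple correlation
coefficient — verified against a dense random sphere search. A singular
design falls back to a small logged ridge. P-values come from permuting
animals (default 10⁴), since the constrained maximization invalidates the
parametric null; "minimize p" alongside "maximize R" is redundant at
fixed n, so maximizing `|R|` with a permutation p is the implemented
reading. `stabilizeAlpha()` adds leave-one-trial-out jackknife replicates
and (default 1000) random trial recombinations, sign-aligning replicate
solutions before averaging; per-coefficient SD over recombinations is the
stability spread, which inflates sharply when one trial is corrupt.

## 7. Synthetic generators: what they emulate, and what they do not

`makeImageFixture()` places non-overlapping disc/sphere nuclei and fills
each with Gaussian-smoothed white noise whose smoothing length grows with
a latent age in `[0,1]` (default `1 + 3·age` pixels) — the minimal texture
model whose TAS statistics are provably age-sensitive, mimicking chromatin
puncta coarsening. It does not model optics (no PSF, no photon noise
statistics beyond i.i.d. Gaussian grey-level noise, no radial falloff),
and is not photorealistic microscopy.

`makeFeatureFixture()` builds cohorts (defaults: 6 animals per group at
2, 15 and 27 months, 1000 cells per animal, 20 features, unit noise) in
which aging acts along a known unit drift vector by mean shift (default
2 z-units across the age range), by cell-type composition shift between
type means offset along the drift direction, or both — the composition
mechanism is the scenario bootstrap aggregation exists for.
`makeBehaviorFixture()` generates clustered readouts sharing per-cluster
latent factors coupled to the age readout, with within-cluster
correlation 0.8, per-trial replicate noise, and an age-independent factor
SD of 1 by default, so that even a fully coupled cluster owes at most
half its factor variance to age — both the realistic regime for
behavioral assays and the regime in which distinct clusters remain
statistically separable (with smaller factor noise, strongly coupled
clusters become mutually correlated through the shared age signal and no
method could recover the partition). All generators draw from named
substreams of a single root seed and are bit-reproducible.

Passing tests on these fixtures shows the pipeline recovers planted
structure under its own model assumptions — Gaussian cell clouds, linear
drift, i.i.d. noise. It does not show robustness to batch effects,
segmentation errors, spatially correlated staining artifacts, or
non-monotone aging dynamics; real-data performance must be established on
real data.

## 8. Problem sizes and numerical choices

The test suite and acceptance script run cohorts of 3–6 animals per group,
300–2000 cells per animal, 60–200 bootstraps of 100–200 cells, 10–20
split iterations, embeddings of 12–36 points, and 10–20 seed replicates
per stochastic claim — sizes at which every planted effect is decisively
detectable while the full suite runs in well under a minute. Key numeric
defaults: hyperboloid constraint maintained exactly by parameterization
(validity checks at 1e−6); Karcher-mean tolerance 1e−8; geodesic search
bracket 3 geodesic lengths beyond each endpoint; HMDS multi-start of 5;
Pythagoras identity and projection oracles asserted at 1e−9; zero-SD
features standardized to constant 0; all-zero TAS blocks emitted as zeros
with foreground counts retained for QC.

## 9. Known limitations

- The information distance estimates entropies from 10-bin histograms;
  with short feature vectors the independence limit `D → 1` is approached
  only slowly, and `D` between near-identical samples is noisy.
- HMDS is non-convex; multi-start with a classical-MDS initialization is
  a heuristic, and pathological distance matrices can converge to local
  minima (the diagnostics expose this — inspect stress and Shepherd R²).
- The behavior-coefficient optimization assumes more animals than
  representatives; with near-singular representative sets the ridge
  fallback changes the estimand slightly (the penalty is reported).
- Signature thresholds from small reference groups are order statistics
  and correspondingly variable; the purity-limit variant is the
  conservative alternative.
- 3D TAS assumes isotropic voxels; anisotropic z-steps should be
  resampled upstream or analyzed as 2D projections.
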