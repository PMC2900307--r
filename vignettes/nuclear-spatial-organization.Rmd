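---
title: "Testing the spatial organization of nuclear compartments in 3D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the spatial organization of nuclear compartments in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucspat)
```

## The problem

Interphase nuclei contain punctate compartments — centromeric spots
detected by CENP immunolabeling in mammalian cells, DAPI-bright
chromocenters in *Arabidopsis* — whose 3D arrangement carries information
about nuclear organization. Asking whether such a pattern is random,
clustered or regularly spaced is complicated by two facts. First, each
nucleus is a small, bounded, irregular domain, so the asymptotic theory of
homogeneous point processes in large windows does not apply, and the edge
corrections built into standard estimators are actively harmful: no point
can exist outside the nucleus, so discarding boundary-affected points only
loses information. Second, nuclei vary in size and shape within any
population, and no anatomical landmark permits registering them to a
common template.

`nucspat` addresses both problems by making each nucleus its own
reference. The observed pattern in a nucleus is compared against patterns
simulated in *that same* nucleus under the null model, so size and shape
variability cancels by construction, and results can be pooled across a
population without registration.

## Distance functions on a bounded nucleus

Two cumulative distance functions summarize a pattern of $k$ points inside
a nucleus mask:

* the **G-function** (nearest-neighbor distance function), the empirical
  CDF of the distance from each point to its nearest neighbor, built from
  exactly $k$ distances;
* the **F-function** (empty-space function), the CDF of the distance from
  an arbitrary position in the nucleus to its nearest pattern point;
  $F(y)$ is the fraction of nuclear volume within distance $y$ of the
  pattern.

$F$ is estimated stochastically: $N_E$ evaluation points are drawn
uniformly inside the mask (a uniformly chosen foreground voxel plus a
continuous offset within it, so both the evaluation points and the pattern
keep subvoxel precision), and $F(y)$ is the fraction of evaluation points
whose empty-space distance is at most $y$. $N_E = 10^4$ suffices to make
the sampling noise negligible relative to the Monte-Carlo reference
uncertainty. An independent estimator — the normalized cumulative
histogram of the Euclidean distance map from the voxel-rounded pattern —
is implemented as `f_function_edm_oracle()` and used as a cross-check: the
two routes agree to a sup-difference of about 0.01–0.02 at the voxel sizes
of real acquisitions (0.04–0.1 µm laterally). The distance-map route
rounds pattern coordinates to the grid, so its agreement with the
stochastic route degrades on coarsely sampled toy volumes; this is a
property of the rounding, not of either estimator, and is quantified in
the test suite at both resolutions. No edge correction is applied
anywhere, deliberately: the mask is the complete domain of the process.

All geometry is computed in physical micrometres; the axial spacing of
confocal stacks (here 0.122–0.3 µm against 0.04–0.1 µm laterally) enters
every distance, morphological operation and surface computation.

## The null model and the spatial distribution index

The null model is the **completely random binomial point process
(CRBPP)**: $k$ points placed uniformly and independently in the observed
mask, with $k$ fixed at the observed count. For chromocenters, which have
appreciable size, a **hardcore variant** additionally assigns each
simulated point one of the observed equivalent spherical radii (randomly
permuted per replicate) and rejects configurations where a point lies
closer than its radius to the nuclear envelope or closer than the sum of
radii to another point. The sum rule (non-overlapping spheres) is the
default; `hardcore_rule = "max"` gives the literal single-radius exclusion
for sensitivity analysis.

Per nucleus, the analysis proceeds in four steps:

1. estimate the CRBPP mean distance function $F_0$ (or $G_0$) from $P_1$
   simulated patterns, on a fixed grid of 512 radii spanning the mask
   bounding-box diagonal;
2. simulate a *second*, independent set of $P_2$ patterns and compute for
   each the signed maximum-amplitude deviation
   $D_i = (F_i - F_0)(y^*_i)$, where $y^*_i$ maximizes $|F_i - F_0|$
   (ties at the smallest radius). Reusing the first set here would
   underestimate the null fluctuations, since $F_0$ is fitted to it;
3. compute the observed deviation $D_{obs}$ the same way;
4. report the **spatial distribution index**
   $\mathrm{SDI} = \bigl(\#\{D_i \ge D_{obs}\} + 1\bigr)/(P_2 + 1)$.

The SDI is an exact Monte-Carlo p-value: under the null it is uniform on
$\{1/(P_2+1), \dots, 1\}$, it is never exactly zero, and the observed
pattern is exchangeable with the simulated ones. A flag
(`include_observed = FALSE`) provides the plain $\#\{D_i \ge
D_{obs}\}/P_2$ variant. For the F-function, *low* SDI indicates regularity
(the observed $F$ rises above the reference: empty space is filled faster
than chance) and *high* SDI indicates clustering; the G-function
concentrates the opposite way. All F evaluations within one nucleus share
one evaluation-point set, which preserves the exchangeability that the
p-value requires while removing a large, statistically unnecessary
sampling cost.

At the population level, $n$ per-nucleus SDIs are tested against
Uniform(0,1) with the two-sided one-sample Kolmogorov–Smirnov test.
Because Monte-Carlo SDIs live on a discrete support, ties occur by
construction, and the asymptotic p-value is used throughout; at
$n \approx 40$ this makes the test slightly conservative (empirically 3-4% rejections at nominal 5%, recomputed by `scripts/acceptance.R`).
A Kendall rank correlation between nuclear flatness and SDI (restricted,
in the intended use, to nuclei whose minor axis is Z-oriented) checks
whether apparent regularity merely reflects specimen flattening.

## Segmentation recipes

Three nucleus segmentation paths mirror three labeling regimes:

* **HP1β-stained embryo stacks** (`segment_nuclei_hp1()`): median and
  Gaussian denoising, a gradient-magnitude-weighted global threshold
  (`rats_threshold()`, the mean intensity weighted by the Gaussian
  gradient magnitude — it lands mid-edge independently of the
  object/background size ratio), watershed separation of touching nuclei
  on the inside distance map, and removal of border-truncated nuclei and
  of objects under 200 µm³;
* **rim-stained DAPI mammary stacks** (`segment_nucleus_dapi()`): caller
  threshold, morphological closing with a Euclidean ball (default 1 µm)
  to bridge the broken rim, binary hole filling, watershed separation;
* **single plant nuclei** (`segment_nucleus_arabidopsis()`): bounding-box
  crop, isodata (iterative intermeans) threshold, then re-thresholding at
  $m - 2s$ computed over the preliminary foreground — the isodata
  threshold is biased upward when the background dominates the field of
  view — followed by hole filling, opening and closing. The correction is
  applied once, not iterated. Note that $m \ge t_{pre}$ always (it is a
  mean over values above $t_{pre}$), so the corrected mask may be larger
  or smaller than the preliminary one depending on the foreground spread
  $s$; on the low-noise phantoms in the test suite it is slightly smaller,
  while on dim wide-spread nuclei it grows, which is the case the
  correction exists for.

Centromeric spots are detected by median/Gaussian denoising plus a
top-hat by size (subtraction of a grayscale *area opening*, which removes
every bright structure larger than a volume criterion — default 0.2 µm³ —
regardless of its shape), masking by the dilated nucleus (default 0.5 µm,
so spots elongated axially by the point spread function are not
truncated), removal of objects smaller than 0.02 µm³, and one of two
thresholding rules: the **count-constrained search** (smallest integer
threshold yielding at most 44 connected objects, the rabbit chromosome
number — the volume filter runs inside the search so the bound refers to
countable final objects) or the **regional-maxima rule** (median of the
11 brightest 3D regional maxima divided by 4; with fewer than 11 maxima
the median of all available ones is used, a case the original rule leaves
unspecified).

Chromocenters are segmented by partitioning the nucleus with a watershed
of the Gaussian gradient magnitude, valuing each region by the mean
intensity in a 0.15 µm ball around its barycenter, merging adjacent
regions (smallest absolute value difference first, label-id tie-break,
values recomputed as size-weighted means) until all adjacent differences
reach a threshold (default 10% of the in-mask intensity range), applying
one grayscale closing pass on the region adjacency graph (each value
replaced by the min-over-neighborhood of the max-over-neighborhood, self
included) so that dark basins such as the nucleolus stop inflating their
neighbors' contrast, and scoring each region by contrast (size-weighted
mean difference to neighbors) times compactness. Regions above an index
threshold — a CLI parameter standing in for the original interactive
choice, with the sorted index spectrum printed to aid it — become
chromocenters, each reduced to its center of gravity with its equivalent
spherical radius $(3V/4\pi)^{1/3}$. One caveat discovered during
validation and worth knowing: if aggressive merging leaves the
nucleoplasm as a *single* region whose every neighbor is a bright
chromocenter, the graph closing raises the nucleoplasm itself and
contrast collapses; a dark region (nucleolus) anywhere in its
neighborhood anchors it. Real nuclei contain such regions; featureless
phantoms must include one.

## Morphometry

Volume is voxel count times voxel volume. Surface area comes from a
triangulated model of the envelope: the mask is padded, Gaussian-smoothed
(default 1.5 lateral voxels, axially scaled by the spacing ratio) and the
0.5 level set triangulated by marching tetrahedra with welded edge
vertices, giving a watertight mesh whose area is within about 1% of the
analytic value for digitized spheres at the resolutions used here
(smoothing removes the voxelization staircase that otherwise inflates the
area by ~30%; tiny objects that would be smoothed below the iso level
fall back to the binary volume). Compactness is $36\pi V^2/S^3$ — the
unique standard sphericity form that equals 1 for a sphere and decreases
toward 0, matching the stated normalization. Principal axes come from the
eigen-decomposition of the foreground voxel covariance in micrometres;
the reported length along each eigenvector is the full axis
$2\sqrt{5\lambda_k}$ of the uniform ellipsoid with the same covariance
(volume moments are more noise-robust than surface-vertex moments; the
constant cancels from all ratios). Flatness is intermediate/shortest,
elongation longest/intermediate, and the flattening (elongation) axis is
the frame axis with the largest absolute cosine against the shortest
(longest) principal axis, ties resolved toward the earlier axis in
(X, Y, Z).

## The synthetic-data generator

`phantom_spec()` / `simulate_phantom()` generate ground-truthed nuclei
emulating the three imaged systems: spherical, ellipsoidal, invaginated
(1–3 spherical lobes carved from the boundary) and elongated
(aspect ≈ 2.6) masks at confocal anisotropy (defaults 0.1/0.1/0.24 µm;
plant-like phantoms use 0.05–0.06 µm laterally); CRBPP, hardcore or
parent–offspring cluster patterns; and rendered channels — a filled or
rim-weighted nuclear channel, and a spot channel of anisotropic Gaussians
(σ = 0.1 µm laterally, 0.3 µm axially) reproducing the axial PSF
elongation that pushes peripheral spots partly outside the mask, over a
constant background with additive Gaussian noise. Sizes and counts follow
the imaged populations: nuclear volumes of order 80–1200 µm³, 5–44 points
per nucleus, amplitude 200 over background 20 with noise σ = 4 (SNR well
above the ≥5 regime where detection error rates of a few percent are
expected). What the generator does not emulate: chromatin texture,
depth-dependent attenuation, Poisson photon statistics (an additive
Gaussian is used for simplicity) and optical aberrations beyond the
anisotropic Gaussian PSF. Passing tests therefore validate the
*algorithms* under controlled conditions, not performance on any
particular microscope's data.

## Numerical choices and problem sizes

* Radius grid: 512 equally spaced radii from 0 to the mask bounding-box
  diagonal, shared by observed and simulated functions.
* Watershed seeds for splitting touching nuclei: regional maxima of the
  distance map after h-maxima suppression with h equal to one voxel step
  on the coarsest axis; at fine lateral sampling a smaller h over-seeds on
  closure ripples.
* Ball morphology is computed exactly (center-to-center) through the
  anisotropic Euclidean distance transform; erosion uses the strict
  inequality so closing is extensive and opening anti-extensive.
* Empirical envelopes (2.5%/97.5% pointwise quantiles) are clamped to
  bracket the mean, which raw tail quantiles need not do when nearly all
  replicates sit at 1.
* Monte-Carlo budgets: the package defaults are $N_E = 10^4$,
  $P_1 = P_2 = 500$. The validation suite and `scripts/acceptance.R` use
  $N_E = 2000$, $P_1 = P_2 = 100$ with 200 populations of 40 nuclei for
  the null-calibration study, and 50 nuclei per condition for the
  direction/monotonicity study — sizes chosen so the whole study runs on
  one CPU in minutes while keeping the binomial uncertainty of the
  estimated rejection rate at about ±2 points.
* Reproducibility: all randomness flows through R's RNG (including the
  compiled samplers), so a single `set.seed()` or `analysis_config(seed=)`
  makes every result, including the compiled Monte-Carlo loops,
  bit-reproducible.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
spec <- phantom_spec(shape = "ellipsoid", semi_axes = c(5, 4, 3),
                     pattern_model = "hardcore", k = 20,
                     hardcore_radii = 0.8)
mask <- make_mask(spec)
pattern <- make_pattern(mask, spec)$pattern

morphometry(mask)

cfg <- analysis_config(n_eval = 2000, p1 = 100, p2 = 100, seed = 42)
sdi(point_pattern(pattern$points), mask, "F", cfg)
```

A hardcore-generated pattern analyzed against the plain CRBPP null gives
a small F-SDI (regularity); run over a population,
`population_sdi()` + `population_uniformity_test()` quantify the
departure exactly as the per-population analysis does.

## Known limitations

* Nucleoli (and other excluded volumes) are not carved out of the null
  domain; simulated points may fall where real compartments cannot. The
  resulting bias is toward *apparent clustering*, so it cannot manufacture
  spurious regularity; excluding the nucleolus is a natural extension of
  `sample_crbpp()`.
* The J-function and cross-type functions are out of scope.
* The hardcore sampler is sequential rejection; at packing densities near
  jamming it fails with an explicit error rather than silently biasing
  the configuration distribution.
* The graph-closing caveat for single-region nucleoplasm described above.
* The DAPI and chromocenter index thresholds replace interactive steps;
  they are parameters, not estimates.
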