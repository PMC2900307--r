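# nucspat

Spatial statistics and morphometry of nuclear compartments in 3D
microscopy images.

Interphase nuclei harbor punctate compartments — centromeric spots in
mammalian cells, DAPI-bright chromocenters in plants — and a recurring
question in nuclear-organization studies is whether these are placed at
random, attract each other (clustering), or repel each other (regular
spacing). Answering it inside single nuclei is awkward: each nucleus is a
small bounded domain of individual shape, classical point-process theory
assumes large homogeneous windows, and nuclei cannot be registered to a
common template. `nucspat` implements a complete pipeline for this
setting, aimed at microscopists and computational biologists working with
confocal stacks: segmentation of nuclei and of their compartments,
nuclear morphometry, and a per-nucleus Monte-Carlo test that uses each
nucleus as its own reference.

## The statistic at the core

For a pattern of `k` points inside a nucleus mask, two distance functions
are computed without any edge correction (the nucleus is the *complete*
domain — no point exists beyond it):

- `G(x)` — CDF of nearest-neighbor distances (k distances);
- `F(y)` — empty-space function, the fraction of nuclear volume within
  distance `y` of the pattern, estimated from `N_E` uniform random
  positions in the mask.

The observed function is compared with its mean `F0` under the
**completely random binomial point process** (CRBPP): `k` points uniform
and independent in the same mask (with a hardcore variant carrying
observed chromocenter radii). `F0` is estimated from `P1` simulated
patterns; a second, independent set of `P2` patterns yields the null
distribution of the signed maximum-amplitude deviation
`D = (F − F0)(y*)`, `y* = argmax |F − F0|`. The **spatial distribution
index**

```
SDI = (#{D_i >= D_obs} + 1) / (P2 + 1)
```

is an exact Monte-Carlo p-value, uniform on (0,1] under the null. For the
F-function, low SDI means regular spacing, high SDI means clustering.
Population-level departure from randomness is tested by a two-sided
Kolmogorov–Smirnov test of the SDIs against Uniform(0,1); a Kendall rank
correlation between SDI and nuclear flatness checks that regularity is
not an artifact of specimen flattening.

Everything operates in physical micrometres and honors anisotropic voxel
spacing (axial steps 2–3× the lateral ones are typical). Compiled kernels
(distance transforms, watershed, area opening, marching-tetrahedra
surfaces, Monte-Carlo distance loops) keep population-scale simulation
studies in the minutes range on one CPU.

## Worked example

```r
library(nucspat)
set.seed(1)
spec <- phantom_spec(shape = "ellipsoid", semi_axes = c(5, 4, 3),
                     pattern_model = "hardcore", k = 20,
                     hardcore_radii = 0.8)
mask    <- make_mask(spec)
pattern <- make_pattern(mask, spec)$pattern

morphometry(mask)
#>     volume  surface compactness axis_long axis_mid axis_short flatness
#> 1 250.9632 201.0269   0.8768184  10.01463 8.003247   5.980114  1.33831
#>   elongation flattening_axis elongation_axis
#> 1   1.251321               Z               X

cfg <- analysis_config(n_eval = 2000, p1 = 100, p2 = 100, seed = 42)
sdi(point_pattern(pattern$points), mask, "F", cfg)
#> <sdi_result> F-SDI = 0.0099 (D_obs = +0.1422, k = 20)
sdi(point_pattern(pattern$points), mask, "G", cfg)
#> <sdi_result> G-SDI = 1.0000 (D_obs = -0.6435, k = 20)
```

The morphometry row reads: a 251 µm³ ellipsoidal nucleus, compactness
0.88 (1 would be a perfect sphere), full axes ≈ 10 × 8 × 6 µm, hence
flatness 1.34 and elongation 1.25, flattened along Z and elongated along
X. The pattern was generated with a 0.8 µm hardcore repulsion and
analyzed against the plain random null: the F-SDI of 0.0099 (the smallest
value attainable with P2 = 100, meaning the observed deviation exceeded
every simulated one) flags significant regular spacing, and the G-SDI at
the opposite extreme agrees — nearest-neighbor distances are larger than
chance. For whole populations, `population_sdi()` and
`population_uniformity_test()` assemble the per-nucleus table and the KS
test.

Segmentation entry points: `segment_nuclei_hp1()` (gradient-weighted
threshold + watershed), `segment_nucleus_dapi()` (rim closing + hole
fill), `segment_nucleus_arabidopsis()` (isodata with mean − 2 SD
correction), `enhance_spots()` / `threshold_search_max_count()` /
`threshold_from_maxima()` for centromeric spots, and
`watershed_partition()` → `merge_regions()` → `region_closing()` →
`score_regions()` → `extract_chromocenters()` for chromocenters. A thin
command-line wrapper over these functions ships in `inst/cli/nucspat.R`.

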