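---
title: "Methods: local mixture statistics for smart region growing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local mixture statistics for smart region growing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrg)
```

## The pixel model and its assumptions

Confocal and two-photon detectors report counts: a pixel value is a photon
count plus an electronic offset. `smrg` models the intensities of a local
crop as a two-component mixture. With probability `alpha` a pixel is
background and `y - K0` follows a *discrete normal* distribution with
variance `vB` (the normalising constant is computed by explicit summation
of `exp(-k^2/2vB)` over the integer window `|k| <= 6*sqrt(vB)`, so the pmf
is a genuine probability mass function); otherwise it is signal and
`y - K0` follows a *negative binomial* with size `r` and probability `p`,
parameterized through the signal mean and variance (`p = muS/vS`,
`r = muS^2/(vS - muS)`). The negative binomial captures the overdispersion
(`vS >= muS`) and long upper tail of fluorescence counts. Two assumptions
matter:

* **a single signal class locally** — within one crop all signal pixels
  share one intensity distribution. This is why the model is fitted
  per crop rather than globally;
* **signal sits above the offset** — the signal component has support
  `y >= K0`; pixels below the offset are background by construction.

## EM fitting

The fit alternates an exact E-step (per-pixel background responsibilities
`alpha_y`) with a hybrid M-step: `alpha` is the mean responsibility; `K0`
is found by integer grid search over `[mode - 10, mode + 10]` of the crop
histogram (the offset is an integer, so there is no gradient to follow),
with `vB` at its responsibility-weighted variance for each candidate; and
`(p, r)` come from responsibility-weighted method of moments on `y - K0`.
Initialisation is deterministic — offset at the histogram mode, background
variance from the sub-mode pixels, `alpha` from the fraction below
`mode + 2*sqrt(vB)` — so identical crops always give identical fits.

Because the moment update for `(p, r)` is not an exact likelihood
maximiser, the usual EM monotonicity guarantee does not apply in theory.
The implementation therefore evaluates the observed-data log-likelihood
after every step and, if a step would decrease it, keeps the previous
parameters and stops (a generalized-EM acceptance guard). The reported
`loglik_trace` is consequently non-decreasing by construction, and the
guard fires rarely in practice (in the acceptance run it never prevents
convergence). Convergence is declared at a relative log-likelihood change
below `1e-6`, with at most 200 iterations. Two degeneracy guards: a
single-valued crop returns a non-converged all-background report, and a
transiently underdispersed weighted variance (`vS <= muS`) is clamped to
`p = 0.99` so the iteration can continue.

Whether the moment estimates for `(p, r)` should use raw or
responsibility-weighted moments is not prescribed by the method
description we follow; we use responsibility weighting, which is the
standard EM treatment and what makes the signal moments robust to the
background mass. Likewise we sum the log-likelihood over pixels
(equivalently, histogram-weighted intensity levels).

## Unimodality gating and Otsu fallback

A crop containing two well-separated intensity populations (e.g. half
soma, half background) violates the "sharp background peak plus tail"
shape the mixture expects, and is better served by a histogram split.
Hartigan's dip statistic — the sup-distance between the empirical CDF and
the closest unimodal CDF, computed with the iterative greatest-convex-
minorant / least-concave-majorant algorithm in `src/dip.cpp` — gates the
two branches at `p < 0.01`. The p-value is a bootstrap against the uniform
null (2000 resamples, fixed internal seed, memoised per sample size), the
classical calibration choice: the uniform is asymptotically the least
favourable unimodal distribution, so the test is exact at the nominal
level against it and conservative against peaked unimodal data. Both
behaviours are asserted in the tests (rejection rate within the binomial
interval around 0.01 on uniform samples; `p >= 0.01` for at least 95% of
normal samples).

Integer quantization needs care: a near-constant background spread over
two adjacent counts is an extreme two-atom sample whose dip is large, and
it would spuriously divert crops to the Otsu branch. Integer samples are
therefore dithered with deterministic uniform(-1/2, 1/2) jitter before the
test; genuinely separated modes survive the jitter unchanged while
quantization ties dissolve. Constant (or < 4-point) samples are unimodal
by convention. The Otsu fallback maximises between-class variance over the
observed integer histogram, with foreground strictly above the threshold
(the conservative choice against background inflation).

## The growing loop

Crops are `M/8 x N/8 x 3` windows (floor of the on-plane fraction, raised
to 32 x 32 x 3) centred on the current seed. At stack borders the window
is shifted toward the interior rather than clipped, so the mixture always
sees at least 3072 pixels; `extract_crop()` exposes plain clipping too.
Within a crop, admitted voxels (posterior above `tau = 0.999`, or above
the Otsu threshold on the multimodal branch) are kept only if 26-connected
to the seed — 26-connectivity because thin oblique neurites break under
6-connectivity. New seeds are the plateau-aware regional maxima of the 2D
Euclidean distance transform of each segmented plane (a plateau
contributes its centroid voxel, snapped onto the plateau); the distance
transform is per plane rather than 3D because crops are only three planes
deep. The global mask grows by logical OR — no voxel is ever removed — and
each voxel is used as a seed at most once, which both guarantees
termination and makes repeated seeds no-ops. The queue is FIFO
(breadth-first), keeping successive crops close to already-fitted
statistics. With a fixed stack, seed and configuration the whole loop is
deterministic: the only random ingredient, the bootstrap null table, uses
a fixed internal seed and restores the caller's RNG state.

Automatic seeding rasterizes a spherical Hough transform: boundary voxels
of the Otsu foreground vote along their smoothed intensity-gradient
direction at every radius in the requested range, and smoothed accumulator
peaks (with non-maximum suppression at the minimum radius) become seeds,
sorted by score.

## Skeletonization and SWC export

The mask is reduced to a medial curve by topology-preserving thinning:
voxels are deleted only if *simple* — their 26-neighbourhood contains
exactly one foreground 26-component, and the background within their
18-neighbourhood forms exactly one 6-component touching the voxel by a
face — and deletions proceed in order of increasing distance to the
boundary, which keeps the curve centred; voxels with at most one
foreground neighbour (curve endpoints) are preserved. Two practical
pre/post steps are essential on real segmentations. First, internal
cavities (background components not reachable from the stack border, e.g.
single sub-threshold voxels inside a neurite) are filled before thinning:
topology preservation would otherwise force medial *surfaces* around them.
Second, short endpoint chains attached to a junction ("spurs", produced by
bumps of the segmentation boundary) are pruned when shorter than the local
object radius at their junction (never shorter than 4 voxels), and the
result re-thinned; without pruning a straight tube's skeleton carries
roughly twice as many nodes as its axis, which destroys one-to-one
precision.

SWC conversion builds a breadth-first spanning tree over 26-adjacent
skeleton voxels rooted at the voxel nearest the user's seed (cycles left
by thinning are broken by the traversal); each additional component is
rooted at its own voxel nearest the seed. The node radius is the mask's
Euclidean distance transform at the skeleton voxel scaled by the mean
on-plane voxel size — an isotropic approximation, chosen because no
estimator of "neurite thickness" is canonical. Node coordinates are
`(index - 1) * voxel_size` micrometres; the root gets structure code 1,
all other nodes 3, and one node per skeleton voxel is kept without
resampling.

## Morphometry

* **Volume** is the voxel count times the voxel volume.
* **Surface area** comes in two estimators. `voxel_face` sums exposed face
  areas — exact for axis-aligned solids (the 10-voxel cube gives exactly
  600), but it overestimates curved surfaces (Manhattan effect).  `mesh`
  triangulates the 0.5 iso-surface of the Gaussian-smoothed (sigma = 1
  voxel) indicator with marching tetrahedra; smoothing removes the
  voxelization steps, and a rasterized radius-10 sphere comes out within
  ~2% of `4*pi*r^2`.
* **Sholl profiles** count, at each radius `k*step`, the 26-connected
  components of the segmented voxels inside the spherical shell of
  half-width `h` = half the voxel diagonal around that radius. The
  half-diagonal guarantees every crossing filament intersects the shell;
  counting components (not voxels) matches the definition of crossings.
  The AUC uses the trapezoidal rule. The default Sholl centre is the soma
  centre when one is detected, the mask centroid otherwise, and it is
  overridable.

## Reconstruction metrics

`SD` averages the two directional mean nearest-node distances
(`sum(d_AB)/(2|A|) + sum(d_BA)/(2|B|)`). `SSD` averages the two
directional means restricted to distances above the tolerance `S`; each
direction uses its own set size, an empty direction contributes zero
(encoding "no substantial discrepancy"), and `%SSD` is the percentage of
all nodes contributing. Precision/recall/F use greedy one-to-one matching
in ascending distance order with matches accepted within `S`; one-to-one
matching prevents a dense reconstruction from inflating precision, which
matters because the thinning produces roughly one node per skeleton voxel.
Metrics are computed in the units of their inputs — voxels for phantom
work (where `S = 2` is the conventional tolerance and sweeps run over
0.5–5), micrometres for physical SWC files.

## The phantom generator

Phantoms are trees of tapered capsules (linear radius interpolation along
each segment — the simplest model consistent with neurite thinning) plus
optional spherical somata, rasterized by a voxel-centre-in-solid test. The
ground-truth centerline traces each segment axis at one-voxel lattice
steps, which is the natural node density for voxel-space comparison and
matches the density of thinning output. Rendering draws background voxels
as `K0 + round(N(0, vB))` clipped at zero (detector counts are
non-negative) and mask voxels as `K0 + NB(r, p)` — i.i.d. given the mask,
bit-reproducible from the spec's seed. The standard suite fixes four
geometries (straight tube, Y-branch, a soma-bearing multi-branch tree, two
touching somata) at three contrast tiers, `muS/sqrt(vB)` of 10, 5 and 2.5
(`K0 = 100`, `vB = 25`, `vS = 3*muS`, i.e. `p = 1/3`), spanning easy to
marginal detectability.

The generator reproduces the *statistical* model of the segmentation
exactly, and deliberately not the optics: there is no point-spread blur,
no depth-dependent attenuation, no correlated noise, and no partial-volume
mixing at boundaries (a Gaussian-blur stress flag can be added upstream of
`grow()` by smoothing the rendered stack). Passing the phantom benchmarks
therefore demonstrates that the estimator, predicate, reseeding, thinning
and metrics are implemented correctly and are robust to seed placement —
not that the pipeline is robust to optical artefacts of any particular
microscope; on real stacks the local fit inherits whatever deviations the
optics introduce.

## Problem sizes and numerical choices

The shipped benchmarks use stacks up to 25 x 128 x 128 voxels, 3072-pixel
crops, 50-replicate parameter recovery, 1000-sample dip calibration and
10-seed reproducibility runs — sizes chosen so the full suite and the
acceptance script each complete in about a minute on a single CPU while
every rate is estimated with usable precision. Other defaults collected in
one place: posterior threshold 0.999; dip level 0.01 with B = 2000;
EM tolerance `1e-6` (relative), 200 iterations max; background variance
floored at 0.25 counts^2; spur-prune floor 4 voxels; Sholl step 10 um.

## Known limitations

* Touching neurons with strong mutual signal can merge into one mask; the
  mixture's preference for bright interiors suppresses dim boundaries but
  does not split merged objects (a watershed post-step is out of scope).
* The dip gate assumes the crop histogram is either unimodal or cleanly
  multimodal; heavy quantization is handled by dithering, but exotic
  discrete patterns may still gate unexpectedly.
* The radius estimate in SWC export is isotropic-approximate; with very
  anisotropic voxels node radii inherit the on-plane scale.
* `grow()` keeps the whole stack, mask and bookkeeping arrays in memory;
  multi-gigavoxel stacks need tiling upstream.
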