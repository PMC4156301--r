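---
title: "Discrete multiresolution tomography with tomodart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete multiresolution tomography with tomodart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomodart)
```

## The reconstruction problem

Computed tomography measures line integrals of an object's attenuation
map: a sinogram $p$ with one row per projection angle and one column per
detector bin. Discretising the object on a pixel grid turns acquisition
into a linear system $W x = p$, where $w_{ij}$ is the weight of pixel $j$
on ray $i$. When only a handful of projections are available, or a
contiguous angular range is missing entirely (the *missing wedge* typical
of electron tomography and some synchrotron set-ups), this system is
heavily underdetermined and generic reconstructions show streaks and
elongation artefacts.

*Discrete tomography* restores well-posedness through a strong prior: the
object consists of a few known materials, so the true image contains only
the grey values $\rho_1 < \dots < \rho_L$. tomodart implements the
standard algorithmic stack for this setting in plain R:

* a ray-driven **Joseph projector** for equiangular parallel- and
  fan-beam geometries (`tomoOperator`, `forwardProject`, `backProject`),
* **SIRT**, the simultaneous iterative reconstruction technique, with an
  optional fixed-pixel mask (`sirtRun`),
* **DART**, which alternates masked SIRT with segmentation
  (`dartReconstruct`),
* **MDART**, a coarse-to-fine multiresolution driver around DART
  (`mdartReconstruct`),

together with phantom generators, a Poisson photon-noise model,
segmentation-error metrics and a benchmark runner.

## Operator and SIRT

The Joseph projector steps along each ray's dominant axis one pixel
row/column at a time and interpolates linearly between the two adjacent
pixel centres on the minor axis; every sample carries the path-length
factor $s\sqrt{1+m^2}$ (pixel size $s$, minor-axis slope $m$), so
sinogram entries are physical line integrals. Back projection applies
the exact transpose, which the test suite verifies through inner-product
identities. The weights are assembled once per (grid, geometry) pair into
a sparse matrix held by the `TomoOperator`; at the problem sizes this
package targets (grids up to a few hundred pixels per side) this is far
faster in R than re-deriving weights on every application, while keeping
memory in the tens of megabytes. A dense representation is available only
for grids up to $16\times16$ (`denseSystemMatrix`), where it supports
direct linear-algebra cross-checks. Rays that miss the grid get zero
rows; their reciprocal row sums are defined as zero, which silently
removes them from the iteration.

SIRT iterates
$$x \leftarrow x + C\,W^T R\,(p - W x),$$
with $R$ and $C$ the reciprocal row- and column-sum scalings of $W$. When
DART supplies a mask of *non-fixed* pixels, the update is applied to those
pixels only, but the residual $p - Wx$ is always computed from the full
image, fixed pixels included — freezing a pixel removes it from the
update, not from the physics. No relaxation (factor 1) and no
non-negativity clipping are applied by default; both choices are exposed
in the configuration because neither is prescribed by the method's
standard formulation.

## The DART iteration

Each DART iteration, starting from a continuous iterate:

1. **segment** with global thresholds: values in
   $(\tau_{i-1}, \tau_i]$ map to $\rho_i$; thresholds default to
   grey-value midpoints. Ties at a threshold go to the lower class — a
   measure-zero convention on real data;
2. **partition**: boundary pixels (at least one 8-connected neighbour
   with a different grey level) plus an independent random sample of the
   remaining pixels (probability `fixProbability`, default 0.15) form the
   non-fixed set; everything else is fixed at its segmented grey value;
3. **masked SIRT**: `innerArmIters` (default 10) iterations on the
   non-fixed set;
4. **termination check** (below); if the run continues,
5. **smooth** the *entire* iterate: each pixel blends toward the mean of
   its 3×3 in-grid neighbourhood with weight `smoothingBlend`
   (default 0.1). Smoothing the whole image, not only the boundary band,
   follows the method's original description; the final returned image is
   the un-smoothed post-SIRT iterate.

The initial reconstruction is `initialArmIters` (default 200) unmasked
SIRT iterations from zero, unless an initial image is supplied. The
random freeing draws from R's RNG seeded by `rngSeed`, so every run is
exactly reproducible; the sample is redrawn at every DART iteration so
new boundaries can form anywhere. The default connectivity is 8
(diagonal neighbours count), giving a slightly larger, more conservative
non-fixed set; 4-connectivity is available.

Three termination rules are implemented (`terminationSpec`): a fixed
iteration count; the fraction of pixels whose segmentation changed
falling below a threshold; and the change in *projection distance*
$\lVert Wx - p\rVert_2$ between consecutive iterations falling below a
threshold. The thresholded rules fire only after holding for `patience`
consecutive iterations (default 3). The projection-distance rule is the
one used throughout the package's own experiments; because the distance
is an extensive quantity, the experiments set its threshold relative to
the data scale, at $5\times10^{-4}\,\lVert p\rVert$. DART also accepts an
explicit budget (wall seconds, or operator applications weighted by pixel
count); budgets are checked between DART iterations only, never
mid-SIRT, so iteration counts stay reproducible.

## Multiresolution DART

MDART with $n$ levels reconstructs on grids whose pixel size is
$2^{n-1}, \dots, 2, 1$ times the target pixel size, all spanning the same
physical field of view; the sinogram is never resampled. The coarsest
level starts from its own SIRT initial reconstruction; each finer level
is initialised by bilinear upsampling of the previous level's
*continuous* iterate (interpolating the segmentation would manufacture
invalid grey values). Upsampling treats pixel values as samples at pixel
centres and replicates edges outside the outermost centres, which keeps
the object centred across levels. With one level the algorithm runs
exactly plain DART — same seed, same trace, same output — which the test
suite asserts.

Two effects drive the method. First, a coarse grid divides the unknown
count by 4 per level while keeping every measured ray, so the few-view
problem is far better posed and the initial reconstruction correspondingly
cleaner. Second, one SIRT application at level $k$ costs about $4^{-k}$
of a target-level application, so the coarse levels are nearly free. The
package therefore measures work in *pixel-weighted operator applications*
(each forward or back projection costs the grid's pixel count), which
makes equal-budget algorithm comparisons hardware-independent; the trace
records both raw application counts and pixel work.

The flip side, also reproduced in the acceptance tests: features smaller
than one coarse pixel (for example holes whose radius is below the
coarsest pixel size) cannot be represented there, get segmented away, and
— under limited-angle, few-view data — are not always rediscovered on the
finer grids within the budget. Choosing the number of levels is a
trade-off between this loss and the speed-up, made with the feature sizes
of the object in mind.

## Phantoms, noise and metrics

The generators produce the classic discrete-tomography test objects: a
disk with randomly packed, non-overlapping circular holes
(`diskWithHoles`; rejection sampling with a hard cap of 10&nbsp;000
attempts and an explicit packing-failure error), a Siemens star
(`siemensStar`), multi-grey intersecting-ellipse composites
(`ellipsesPhantom`), and a parametric structured binary object
(`structuredBinary`) — a synthetic stand-in, built from rectangles,
disks, annuli and seeded hole batches, for machined parts whose exact
geometry is not publicly available. A pixel belongs to a shape iff its
centre does, so phantoms are exactly discrete and the grey-value prior
holds with no anti-aliasing artefacts. Following the usual simulation
protocol, generators render at an `oversample` factor (default 2) finer
than the nominal grid: projections are computed from the fine phantom
while reconstruction uses the coarser grid, so the projector applied to
the reconstruction never trivially inverts the projector applied to the
phantom, and pixelation effects on the data are reduced.

The noise model is transmission photon statistics: for a clean integral
$p_i$, a Poisson count $N_i$ with mean $I_0 e^{-p_i}$ is drawn and
converted back via $-\log(\max(N_i,1)/I_0)$; zero counts are clamped to
one photon to keep the log finite, and counts with mean above $10^7$ use
the Gaussian limit of the Poisson law (R's integer Poisson sampler
overflows near $2^{31}$), which is accurate to far below shot noise.
What the generators do **not** emulate: detector blur, scatter, beam
hardening, cone-beam geometry, and the correlated structures of real
detectors — so passing tests demonstrate algorithmic correctness on the
idealised acquisition model, not robustness to every physical effect in
real scans.

Reconstruction quality is the **relative number of misclassified pixels**
(`rnmp`): the segmented reconstruction is resampled onto the phantom grid
by nearest-neighbour interpolation, and the number of pixels whose grey
value differs from the phantom is divided by the number of phantom pixels
with nonzero grey value. `errorImage` returns the standard four-category
map (correct/misclassified × background/object).

## Study conditions used by the tests and the acceptance script

All experiments are sized for a desk run. Projector and adjoint checks
use $16\times16$ grids; the SIRT-versus-least-squares cross-check uses an
$8\times8$ grid with 16 parallel angles, where the dense normal equations
are solved directly as an independent oracle. DART recovery uses a
$64\times64$ disk with three holes of radius 5 from 15 fan-beam
projections over 360°. The multiresolution comparisons run on a
$128\times128$ target grid from 8 parallel projections over 180° with a
30° missing wedge — a few-view limited-angle regime in which the initial
full-resolution SIRT reconstruction is poor — under a shared budget equal
to DART's initial reconstruction plus 15 full-resolution DART iterations,
with phantoms oversampled twofold. These sizes keep the full suite within
a few minutes while preserving the unknowns-to-equations ratios that make
the multiresolution effect visible; on better-conditioned data (many
angles, full range, generous budgets) single-grid DART converges on its
own and the two algorithms tie, which the comparison protocol makes no
claim about.

## Known limitations

* 2-D only; no cone-beam or helical geometries, no detector tilts.
* Grey values and thresholds must be supplied; there is no automatic
  grey-value estimation from the data.
* SIRT is the only algebraic engine shipped; the masked-update interface
  is internal to `sirtRun`, so other solvers could be added but none are
  provided.
* Level ratios are dyadic (pixel size halves per switch).

## A complete run

```{r example, eval = FALSE}
model <- greyLevelModel(c(0, 1))
phantom <- diskWithHoles(64, diskRadius = 24, holeRadius = 5, nHoles = 3,
                         seed = 7, oversample = 2)
geom <- makeEquiangularGeometry("fan", nAngles = 15, angularRange = 360,
                                nDetectors = 96, detectorPixelSize = 1.5,
                                sourceObjectDistance = 192,
                                sourceDetectorDistance = 384)
sino <- forwardProject(phantom, geom)

cfg <- dartConfig(rngSeed = 1,
                  termination = terminationSpec("max_iterations", 50))
rec <- mdartReconstruct(sino, mdartConfig(imageGrid(64), 2, cfg), model)
rnmp(phantom, rec$segmented, model)
```
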