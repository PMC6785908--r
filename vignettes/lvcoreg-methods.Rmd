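---
title: "Models and methods behind lvcoreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lvcoreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lvcoreg)
```

`lvcoreg` compares cardiac MR of the same infarcted left ventricle acquired
in two conditions: in vivo (loaded, beating heart, typically ~1.2 mm LGE
voxels) and ex vivo (excised, arrested, unloaded heart, typically ~0.4 mm).
This vignette documents the models, the tunable parameters, the synthetic
phantom that stands in for animal data, and the numerical and design
decisions a user or reviewer would want to audit.

## 1. The synthetic paired phantom

No public paired in-vivo/ex-vivo data set with ground-truth deformation
exists, so validation rests on a phantom whose deformation is known in
closed form.

**Geometry.** The in-vivo endocardium is an axis-aligned ellipsoid (long
semiaxis 60 mm, short semiaxes 25 mm) truncated by a flat mitral-valve (MV)
disc plane, by default at the equator so the cavity long axis equals the
long semiaxis. The wall is the set of points within a uniform thickness
*t* = 9.95 mm of the endocardial surface (an exact offset shell of a convex
surface, so the endo-to-nearest-epi distance equals *t* everywhere). An
antero-septal scar occupies a 90° angular sector over 40% of the long axis,
centred mid-ventricle. Its transmural profile is two-region: a core
(transmurality 1, the first 65% of the sector's angular extent) and a rim
(transmurality 0.5). Scar occupies the sub-endocardial fraction
`tau * t` of the wall, extruded along surface normals, so a projection
measurement at an endocardial point reads back `tau` directly.

**Deformation.** The ex-vivo condition is produced by an analytic map with
two ingredients:

1. the endocardial surface (and the whole cavity) is scaled about the
   cavity centroid by (0.81, 0.81, 0.83) — the short- and long-axis cavity
   ratios of the default study conditions;
2. the local wall is re-extruded along the scaled surface's normals with
   thickness `t * m(e)`, where the multiplier *m* is 1.29 over healthy
   tissue, 1.05 over 0–50% transmural scar and 0.98 over 50–100% transmural
   scar.

Because the endocardium is convex and both ingredients act along normals of
a convex surface, the map is invertible in closed form (one
closest-point-on-ellipsoid solve per query). Ex-vivo labels are computed by
evaluating the inverse at each ex-vivo voxel centre and applying the
in-vivo membership rules — exact geometric membership, with no label
interpolation and hence no resampling bias in the ground truth. The forward
map transports landmarks; the dense displacement field is sampled on the
in-vivo grid and the analytic map is retained for exact evaluation at
arbitrary points. A numerical check over 10^5 random points confirms a
strictly positive Jacobian determinant (no folding) under the default
multipliers.

**Multiplier blending.** Real infarct border zones are narrow. The
multiplier field transitions between regions with a smoothstep over a 2 mm
band whose centre is shifted 1.5 mm *outside* each region border (into the
lower-transmurality side). Both numbers are free design choices, fixed
once: the scar sector is only ~35 x 24 mm, so a much wider band would leave
no tissue at the plateau multipliers and the per-bin thickness-change
analysis would have nothing to recover, while centring the transition
exactly on the border would give nodes whose projection just clips the
scar edge (small measured transmurality, hence binned as scar) a
near-healthy multiplier. Placing the transition slightly into the
lower-transmurality tissue keeps measured bins consistent with the
multipliers that generated them.

**Intensities.** Compartment means mimic LGE contrast in vivo (myocardium
30, blood pool 100, scar 150, arbitrary units) and the ex-vivo setting
(myocardium 40, bright saline bath and cavity 150, scar 160). Per-voxel
noise defaults to Gaussian with sigma = 5% of the wall–scar contrast
(Rician optional); the acquisition point-spread function is emulated by a
Gaussian blur of FWHM 0.8 mm applied to the intensity image only. The PSF
matters for realism of the ex-vivo thresholding rule: on a
noise-only image the `mean - 1 SD` rule retains 84% of a homogeneous
Gaussian scar class by construction, whereas with a PSF the scar-ROI SD is
inflated by boundary voxels and the threshold falls below the scar
interior, as it does on real data.

**Replicates.** A simulated "animal" is a seeded copy of the phantom with
semiaxes and scar extents jittered by ±10% (uniform); the imposed ratios
and multipliers are never jittered, since they are the quantities under
study. Landmarks are placed analytically (epicardial apex, two basal
vessel-related points above the MV plane, two papillary positions inside
the cavity) and are noise-free by default (`landmark_noise_sd` adds
picking error if wanted). Papillary-muscle bumps are off by default and
available behind a flag; the default phantom deliberately omits them.

**What the phantom does not emulate.** Trabeculation and papillary
anatomy (unless enabled), the right ventricle, motion/flow artefacts,
intensity inhomogeneity, partial-volume fuzz beyond the PSF, and any
biomechanics of unloading — the deformation is a geometric summary, not a
tissue model. Passing tests therefore demonstrate that the *operators*
recover known geometry and deformation, not that the registration would
achieve the same accuracy on arbitrary real anatomy.

## 2. Scar segmentation

*In vivo (FWHM).* The threshold is `fwhm_fraction` (default 0.5) times a
robust reference maximum: the 99th-percentile intensity among wall voxels
within a 2-voxel box neighbourhood of the seeds. Using a percentile near
the seeds rather than the global maximum makes the reference robust to
isolated hot voxels; the neighbourhood definition is ours, since the
classical rule leaves it to the operator. Voxels at or above threshold
survive only if connected (26-connectivity by default) to a seed.

*Ex vivo (mean − 1 SD).* The lower scar boundary is
`mean(scar ROI) − sd_multiplier * SD(scar ROI)` (default multiplier 1),
applied to wall voxels, followed by the same seeded component filter. The
remote-ROI statistics are recorded for QC. Manual voxel deletion is
replaced by an optional exclusion mask; nothing is ever added to the mask,
and both rules are monotone in their thresholds.

*Downsampling.* Ex-vivo labels are reduced to the in-vivo resolution by
world-space box binning: each fine voxel centre votes in the coarse voxel
containing it, the majority label wins, and ties break by the fixed
priority scar > cavity > myocardium > aorta > background (pro-scar, so thin
scar is not erased by downsampling). Non-integer voxel ratios work because
binning is in world space.

## 3. Registration

The chain is landmark-rigid → image rigid → affine → multi-level B-spline
FFD, with the downsampled ex-vivo label map as the *moving* image
registered onto the in-vivo (fixed) grid; transforms map fixed-space world
coordinates to moving-space coordinates, so resampling the moving image
requires no transform inversion.

**Metric.** Registration operates on segmentations, not intensities. Each
label map is expanded into three indicator channels (wall = myocardium +
scar, cavity, scar) smoothed with a Gaussian of sigma 1.5 mm — binary masks
carry no usable gradient, smoothed indicators do — and the metric is the
per-voxel-normalised SSD summed over channels, equally weighted. Joint
multi-channel matching was chosen over a single combined mask so that the
scar channel anchors the tangential position of the sector.

**Stages.** The landmark stage is an orthogonal Procrustes fit with
reflection correction over shared landmark names (at least 3,
non-collinear). Rigid (6 parameters, rotation about the fixed-image
centre) and affine (12) stages optimise the metric with L-BFGS-B and
numerical gradients over an image pyramid (default factors 4 then 2); both
stages return their initialisation if they fail to improve the metric, and
the affine stage rejects near-singular matrices through a determinant
barrier. The FFD stage optimises cubic B-spline control displacements on
lattices of 20, 10 and 5 mm spacing paired with pyramid factors 4/2/1,
with analytic gradients and a discrete bending-energy penalty
(second differences of the coefficients, per-node normalised; weight
`lambda = 1e-3`). Coarser solutions initialise finer lattices by evaluating
the displacement at the new control positions. Everything is deterministic
given the configuration; folding is discouraged by the bending term only,
matching common FFD practice on smooth anatomies.

**Known limitation (aperture).** Binary-mask registration constrains
displacement only near label boundaries and mostly along their normals;
tangential motion along a smooth boundary is recovered only through the
bending penalty and the curvature of the surfaces. Recovery tests using
random warps drawn from the FFD's own representable class (coefficients
~N(0, 4 mm) on a 20 mm lattice) recover mean wall displacement well under
one fixed-grid voxel, but large tangential sinusoidal warps are recovered
in overlap (wall DICE ≥ 0.95) more faithfully than in pointwise
displacement.

## 4. Morphometry

Surfaces are extracted by marching tetrahedra at iso-level 0.5 on the
compartment indicator (cavity for endo; cavity + wall for epi), after a
fixed light Gaussian pre-smoothing of the indicator (sigma 0.8 voxel) that
suppresses voxelisation stair-casing (a digital sphere's area is then
within 5% of closed form), followed by exactly 5 uniform Laplacian
iterations — fixed so results are deterministic. Meshes are truncated at
the MV plane by removing cap triangles; thickness and all projections use
the smoothed coordinates.

The "projection" is literal: each endocardial node is paired with its
Euclidean-nearest epicardial node (ties to the lowest index), thickness is
the segment length, and the segment is sampled at steps of half the
minimum voxel size, endpoints included, against half-open voxel boxes. A
node is scar if any sample lands in a scar voxel; transmurality is the
fraction of samples in scar. Nodal scar DICE pairs each node of one mesh
with its nearest node on the other and applies `2|both|/(|A| + |B mapped|)`;
two scar-free meshes define DICE 1 with a warning.

LV dimensions: the long axis is the distance from the cavity point
farthest below the MV plane to that plane; the basal short-axis plane is
fixed at 25% of the long axis below the MV disc (a choice the acquisition
protocols leave to the operator), and the two diameters are the extents of
the cavity cross-section along its principal axes, each extended by one
voxel to compensate voxel-centre truncation.

Thickness change between conditions pairs in-vivo endocardial nodes with
the comparison mesh by nearest neighbour — for the native comparison the
ex-vivo mesh is first brought into the in-vivo frame through the inverse
of the landmark rigid transform; for the post-registration comparison the
mesh is extracted from the registered label map. Per-node changes
`100 (t_cmp − t_in)/t_in` are aggregated over the in-vivo bins healthy
(scar flag false), (0, 0.5] and (0.5, 1] transmurality; 0.5 belongs to the
low bin.

## 5. Statistics

Ratio comparisons run as two-tailed paired t-tests on log-ratios (the
symmetric treatment of the two conditions), reporting the geometric mean
ratio with a 95% CI. Group comparisons use one-way ANOVA with Tukey HSD;
normality checks use Shapiro-Wilk; scar-volume association uses ordinary
least squares. All tests are two-tailed at alpha = 0.05. Degenerate inputs
take defined paths: identical paired samples return ratio 1 with an
undefined p and a warning; an all-constant ANOVA returns F = 0, p = 1; a
constant regression response returns slope 0 and R² = 0.

## 6. Problem sizes and numerical choices

The default phantom renders the in-vivo condition on a ~69³ grid at 1.2 mm
and the ex-vivo condition on a ~196³ grid at 0.4 mm; the full default
analysis of one pair (generation, both segmentations, downsampling, the
four-stage chain, native and registered morphometry) takes on the order of
two minutes on one CPU core. Unit tests exercise the same code paths on a
2.4 / 1.2 mm version of the phantom; the acceptance-style checks
(dimension-ratio recovery over 7 replicates, thickness-change recovery,
registration floors) run at the default resolution. Tie-breaks are fixed
and documented (label priority; lowest index for nearest-neighbour ties);
iso-surface level is 0.5; the FFD lattice always covers the fixed grid
plus a two-node spline-support margin; and all RNG flows through explicit
seeds, so identical configurations reproduce bit-identical reports.
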