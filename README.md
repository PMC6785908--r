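# lvcoreg

Co-registration and morphometry of in-vivo and ex-vivo cardiac MR
segmentations of infarcted left ventricles.

## The problem

Ex-vivo MR of an excised heart resolves myocardial scar at sub-millimetre
resolution, but the arrested, unloaded ventricle has a different shape from
the same ventricle imaged in vivo: the cavity shrinks anisotropically and
the wall thickens, more so in healthy muscle than in dense scar. Any
voxel-wise or surface-wise comparison between the two conditions therefore
needs a spatial mapping. `lvcoreg` implements the full comparison pipeline
for users who have segmented both acquisitions:

- **Scar segmentation** — the in-vivo LGE rule (full-width at half-maximum:
  scar = wall voxels above `0.5 x` a robust reference maximum, restricted to
  components connected to operator seeds) and the ex-vivo rule (voxels above
  `mean(scar ROI) - 1 x SD(scar ROI)`), plus majority-vote label
  downsampling with the tie priority scar > cavity > myocardium.
- **Registration** — rigid landmark initialisation (orthogonal Procrustes
  over named anatomical landmarks), then image-based rigid, affine and
  multi-level cubic B-spline free-form deformation (FFD) registration of the
  label maps, using a sum-of-squared-differences metric on Gaussian-smoothed
  per-label indicator channels with a bending-energy penalty.
- **Mesh morphometry** — endo/epicardial surface extraction, wall thickness
  as the distance from each endocardial node to its nearest epicardial node,
  scar transmurality as the fraction of that projection segment inside scar
  voxels, and nodal-wise scar DICE between registered surfaces,
  `2|A n B| / (|A| + |B|)`.
- **Metrics and statistics** — voxel-wise DICE, compartment volumes, paired
  ratio tests on log-ratios, one-way ANOVA with Tukey HSD, linear
  regression, Shapiro-Wilk.
- **A synthetic paired phantom** — a truncated thick-walled ellipsoidal LV
  with an antero-septal scar, deformed by an analytic map whose defaults
  encode measured in-vivo to ex-vivo shape changes (long-axis ratio 0.83,
  short-axis ratio 0.81; wall-thickness multipliers 1.29 / 1.05 / 0.98 for
  healthy, 0–50% and 50–100% transmural tissue). The map's inverse is
  analytic, so ex-vivo labels are exact geometric memberships and every
  downstream operator can be validated against known ground truth.

## Worked example

```r
library(lvcoreg)

spec <- phantom_spec(seed = 1)          # default paired-study conditions
invivo <- make_invivo_phantom(spec)
exvivo <- make_exvivo_pair(spec, invivo$labels)

# native dimensions: the imposed shape change read back
din <- measure_lv_dimensions(invivo$labels)
dex <- measure_lv_dimensions(exvivo$labels)
round(unname(dex / din), 3)
#> [1] 0.826 0.809 0.804

# full co-registration chain onto the in-vivo grid
ds <- downsample_labels(exvivo$labels, spec$invivo_voxel)
chain <- coregister_pair(invivo$labels, ds, invivo$landmarks, exvivo$landmarks)
voxel_dice(wall_mask(invivo$labels), wall_mask(chain$registered))
#> [1] 0.9843182

# projection morphometry on the in-vivo condition
mor <- lv_morphometry(invivo$labels)
mean(mor$endo$attributes$thickness_mm[!mor$endo$attributes$scar_flag])
#> [1] 9.870585
```

The first block shows the ex/in LV dimension ratios measured on the label
maps (long axis then the two basal short-axis diameters): the generator
imposed 0.83 and 0.81, and the dimension operator reads them back to within
half a voxel. The wall DICE of 0.984 after the landmark–rigid–affine–FFD
chain means the registered ex-vivo wall overlaps the in-vivo wall almost
voxel-for-voxel. The final number is the mean in-vivo wall thickness over
healthy endocardial nodes, matching the generator's 9.95 mm default to
within mesh discretisation.

A simulated multi-animal experiment (generation, segmentation,
registration, morphometry and group statistics over seeded replicates) runs
through `run_experiment(pipeline_config(...))`, and a thin command-line
front end with verbs `simulate`, `segment`, `register`, `morphometry`,
`stats` and `run` is installed at `inst/cli/lvcoreg.R`.

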