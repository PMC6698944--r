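---
title: "Tissue-segmentation-based synthetic CT from T1-weighted MR: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mr2sct methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mrsct` converts one contrast-enhanced T1-weighted MR head volume plus a
handful of manually drawn air contours into a synthetic CT (sCT) in
Hounsfield units, suitable for MR-only radiotherapy planning workflows.
This vignette documents the model and its assumptions, every tunable
parameter, the synthetic phantom used for validation, and the decisions
taken where the design was genuinely open.

## The segmentation model and its assumptions

The central difficulty is that T1 intensities are not standardized: they
change with scanner, coil, sequence and patient. The pipeline therefore
derives every threshold from the image itself:

1. **Air.** Air and cortical bone are both signal-free in T1, so air
   cannot be separated from bone by intensity. The user contours the
   sinus/airway regions on up to 12 axial slices; the package interpolates
   the contours across slices by linearly blending the signed distance
   transforms of the bracketing rasterized masks (shape-based
   interpolation), estimates air statistics, and removes enclosed soft
   tissue above `mu_Air + 3 sigma_Air`.
2. **Brain reference.** White matter is the most *uniform* bright tissue.
   The voxel maximizing uniformity `U = mu/sigma` (population sd) in a
   1 cm x 1 cm in-plane window on the middle coronal slice defines
   `wmIntensity`. Candidates are restricted to body voxels above the slice
   median, because air and background are also uniform; uniformity of a
   noisy constant region scales with its mean, so the restriction also
   favours parenchyma over dark structures.
3. **Edges.** Intensities outside `[0.53, 1.35] * wmIntensity` are zeroed
   and a 2D Canny detector runs on every axial and sagittal slice. Per
   axial slice the largest edge curve is traced in angular order around
   its centroid and gaps wider than one voxel are bridged with discrete
   straight segments. Edge voxels act as region-growing barriers — the
   guard against leakage through weak boundaries (e.g. post-surgical
   skulls).
4. **Brain, CSF, skull.** Initial brain: 3D region growing (6-connected,
   closed intervals) from the reference voxel in
   `[0.7, 1.2] * wmIntensity`. CSF reference: the most uniform 5 mm cubic
   window inside the initial brain whose centre is darker than
   `0.53 * wmIntensity`. Skull mask: grown from dark voxels within 1 cm of
   the body surface in `[0, mu_CSF + 2 sigma_CSF]`, barred from the brain,
   the CSF and the edges, then extended by everything that cannot be
   reached from the brain without crossing it. CSF: grown from the
   reference window in `mu_CSF +/- 2 sigma_CSF` constrained by the skull
   mask. Final brain: growth from the initial brain in the statistical
   range, again constrained by the skull mask.
5. **Eyes.** Connected regions darker than `0.7 * wmIntensity` in an
   anterior box (5 cm superior to 7 cm inferior of the widest brain
   slice), filtered by midline contact, volume and sphericity.
6. **Bone.** Cortical bone is grown from the skull seeds in the air-like
   window. The diploe enclosed by the cortical shell provides trabecular
   reference statistics; voxels within 5 mm of cortical bone inside
   `mu_trab +/- 2 sigma_trab` are recovered.
7. **Soft tissue.** The residual is classified per axial slice (pooling
   one adjacent slice on each side, which tracks the bias-field drift
   along the scan axis) into muscle, fat, and contrast artifact.
8. **Mapping.** Bulk values for air (-1000), CSF/eyes (45) and contrast
   (0); windowed linear (brain) and inverse-linear (bone, muscle, fat)
   transforms clipped at the window ends.

Assumptions: a single head on the grid, approximately RAS-like axes
(axial slices along the first array axis, rows posterior-to-anterior),
co-registered CT if evaluation is requested, non-negative MR intensities
(enforced on load), and contrast-enhanced T1 contrast (fat bright, CSF
dark, bone/air void).

## Tunable parameters

All knobs live in one nested configuration (`sct_config()`), echoed into
the run report. Units are mm or multiples of estimated statistics.

| key | default | meaning |
|---|---|---|
| `air$subtract_sigma` | 3.0 | soft-tissue subtraction cut `mu_Air + k sigma_Air` |
| `air$stats_fraction` | 0.5 | darkest ROI fraction for the air statistics |
| `body$closing_mm` | 3 | morphological closing of the body mask |
| `brain$stat_lo/hi` | 0.53 / 1.35 | statistical brain window (x `wmIntensity`) |
| `brain$grow_lo/hi` | 0.7 / 1.2 | initial growing window |
| `brain$window_mm` | 10 | uniformity window (in-plane) |
| `canny$sigma` | 1 voxel | Gaussian scale of the edge detector |
| `canny$low/high` | 0.4 / 0.8 | hysteresis thresholds, fractions of the max slice gradient (keeps every mask invariant to global intensity rescale) |
| `csf$window_mm` | 5 | CSF reference window |
| `csf$sigma` | 2.0 | CSF growing half-width (x sigma_CSF) |
| `skull$rim_cm` | 1.0 | seed search depth from the body surface |
| `eye$threshold_coeff` | 0.7 | eye threshold (x `wmIntensity`) |
| `eye$diameter_cm` | 4.0 | nominal eye diameter for the size rule |
| `eye$box_sup_cm`, `box_inf_cm` | 5, 7 | axial extent of the search box |
| `eye$sphericity_cm` | 1.0 | max spread of the three axis extents |
| `eye$size_rule` | "volume" | volume- vs diameter-based size reading |
| `bone$air_sigma` | 3.0 | cortical window top (x sigma_Air) |
| `bone$trab_window_mm` | 5 | trabecular recovery neighbourhood |
| `bone$trab_sigma` | 2.0 | trabecular window half-width |
| `soft$context_slices` | 1 | adjacent slices pooled per side |
| `soft$fat_sigma` | 2.0 | fat/contrast boundary (x sigma_soft) |
| `mapping$eye_hu` | 45 | bulk HU of the eyes |

The window coefficients (0.53/1.35/0.7/1.2), the 2-sigma tissue windows
and the HU intervals are the published clinical values and are treated as
fixed constants with config overrides; no derivation is attempted here.

## Decisions where the design was open

- **Air statistics.** The contours enclose mucosa and thin septa, so a
  plain ROI mean overestimates the air level. Statistics are computed on
  the darkest half of the ROI and *debiased* to full-population mean/sd
  under a Gaussian truncation model. A plain lower-half mean/sd
  understates sigma so badly that `mu + 3 sigma` would cut away ~30% of
  Rician air; the debiased estimator keeps the robustness of the
  truncation while preserving coverage.
- **CSF search region.** The ventricles are cavities *inside* the
  white-matter core, not part of the initial brain mask. The search
  region is the initial brain after morphological closing at the window
  scale (sealing the narrow ventricular outlets) and 3D hole filling.
  A looser bounding-box reading would admit the eyes, which are darker
  than `0.53 * wmIntensity` and more uniform than the ventricles by the
  `mu/sigma` criterion (uniformity scales with the mean under constant
  noise) — an instructive failure mode.
- **"External to the skull relative to the brain".** Implemented through
  connectivity: remove the grown skull, keep the connected component
  containing the initial brain; everything else joins the exclusion mask.
  A ray-to-brain-centroid test was rejected: skulls are non-convex (orbital
  roofs, anterior fossa), and rays from frontal gray matter clip the bone
  shelf, wrongly excluding brain tissue.
- **Skull growing vs the subarachnoid CSF.** The CSF film touches the
  inner table and lies inside the skull-growing window, so growing would
  consume it and the ventricles before the CSF stage can run. A
  provisional CSF mask (grown from the reference without the skull
  constraint) is part of the skull barrier; the definitive CSF mask is
  still produced afterwards under the skull constraint.
- **Trabecular reference robustness.** The enclosed-diploe set carries a
  minority of misassigned voxels (dark CSF remnants consumed by the skull
  growing, bright noise within the tables). The cortical mask is sealed
  with a 2 mm closing before the enclosure test (noise pinholes in a 2 mm
  table otherwise let the outside flood in), the reference is restricted
  to the skull zone, and mean/sd are taken after trimming at three
  median-absolute-deviations around the median.
- **Body mask.** Largest connected component is taken *before* the 3 mm
  closing: at a Rayleigh noise floor, ~4% of background voxels exceed the
  air threshold, and closing first would fuse that speckle into a solid
  pseudo-body.
- **Eye size rule.** The volume reading ("half a typical 4 cm eye") is
  the default with a diameter-based alternative via config. Note the
  volume reading rejects anatomically real 24 mm globes; the phantom uses
  32 mm eyes so that the default rule is exercised as specified.
- **Eye HU.** The published mapping table has no eye row; eyes are
  water-like and default to the CSF bulk value 45 HU (configurable).
- **Muscle/fat mapping windows.** Classification uses the per-slice
  statistics; the ED transform windows (muscle `[min_soft, mu + sigma]`,
  fat `[mu + sigma, mu + 2 sigma]`) are instantiated per slice as well,
  keeping the two consistent under the bias field.
- **Soft-tissue slice context.** "Adjacent slices" is read as one slice
  per side (3-slice context); `soft$context_slices` exposes the 5-slice
  alternative.
- **Label precedence.** Stages run in order body, air, brain/CSF, eyes,
  bone, soft tissue; on conflict AIR > CORTICAL_BONE > TRABECULAR_BONE >
  EYE > CSF > BRAIN > CONTRAST > FAT > MUSCLE — earlier, more specific
  stages win.

## Numerical choices

- All intensity windows are closed intervals; boundary intensities are
  included (`I = 0.7 wmIntensity` grows; `I = mu_soft` is muscle).
- Population (not sample) standard deviations throughout.
- Uniformity of a perfectly flat window is `+Inf`; ties are broken by the
  larger window mean, then the lowest voxel index — deterministic and
  meaningful for noise-free inputs where many windows are exactly flat.
- mm-to-voxel conversions use the odd count `2 floor(mm/spacing/2) + 1`.
- Region growing defaults to 6-connectivity (conservative against
  leakage); the Euclidean distance transform is exact and anisotropic.
- Degenerate mapping windows (`sigma = 0`) return the HU midpoint;
  intensities outside a window are clipped, never an error — partial
  volume places voxels outside mu +/- 2 sigma routinely.
- HU are clipped to `[-1024, 3071]` (with a warning) on write.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds a ~184 mm ellipsoidal head on a 192-voxel,
1 mm grid: 4 mm fat and 4 mm muscle scalp; a cranial vault of two 2 mm
cortical tables around a 3 mm patchy diploe with full-thickness cortical
bridges (suture-like, making the cortical shell connected and the diploe
pockets genuinely enclosed); a 3 mm subarachnoid CSF film, 6 mm gray
matter, a white-matter core with a ventricle and a narrow channel to the
film; two 32 mm eyes wrapped in extraocular muscle; a nasal cavity and
airway (the air truth from which the "manual" contours are traced on 12
slices); optional contrast lesion and surgical skull defect. MR set
points (arbitrary units): WM 1000, GM 650, CSF 200, eye 500, muscle 780,
fat 1150, trabecular 870, cortical/air 0. Degradation: a smooth
multiplicative bias field within +/- 5% and Rician noise
(sigma = 20, i.e. 2% of WM) — the Rayleigh floor in air is what the air
statistics must survive. Ground-truth CT values sit inside the mapping
intervals (cortical 1000, trabecular 600, brain 55, CSF/eye 45, muscle
50, fat -45, air -1000, contrast 0) so that the mapping error bound
(per-tissue MAE at most half the HU interval width when mapping the truth
labels) is meaningful; bulk-mapped tissues must match their bulk value
exactly for that bound to be attainable.

The contrast lesion is off by default: a perfectly uniform bright sphere
would win the uniformity search outright (uniformity is mean/sd), a
degenerate input real enhancing lesions — heterogeneous and smaller than
the search window — do not present. With the lesion on, its voxels exceed
`mu_soft + 2 sigma_soft` and are classified as contrast artifact.

What passing the phantom tests does **not** show: robustness to
partial-volume mixing (the phantom has crisp interfaces), to registration
error between MR and CT (the phantom pair is perfectly aligned), to
intensity non-uniformity beyond a smooth 5% field, to susceptibility or
motion artifacts, or to anatomical variability. The phantom validates the
logic and the numerics, not clinical performance.

## Problem sizes

The test suite runs the full pipeline on the 192-cubed phantom (about
7 million voxels) four times — default noise, noise-free, rescaled by
3.7, and a repeat for determinism — in roughly 40 s each, plus unit tests
on small grids (up to 20-cubed for the brute-force oracle comparisons, 200
random instances). Peak memory stays under 2 GB.

## Known limitations

- Orientation handling is by convention (axial-first, RAS-like); volumes
  in other layouts must be permuted on load.
- The DICOM layer reads/writes uncompressed little-endian files only.
- The skull-external rule (connectivity-based) does not add exterior soft
  tissue when a large skull defect connects it to the interior; in that
  case the CSF film and the edge barriers carry the leakage protection.
- Teeth are folded into cortical bone; gray/white matter are one brain
  class; no dosimetric evaluation is included.
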