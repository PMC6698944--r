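# mrsct

Synthetic CT (sCT) generation from a single contrast-enhanced T1-weighted
MR head volume, for MR-only radiotherapy treatment planning.

MRI is the modality of choice for delineating brain targets, but its voxel
intensities carry no electron-density (ED) information, so dose cannot be
calculated on MR directly. `mrsct` implements a tissue-segmentation-based
ED mapping: air, brain, cerebrospinal fluid (CSF), eyes, cortical and
trabecular bone, muscle, fat and contrast artifacts are segmented
automatically from the T1 image using patient-specific intensity
statistics (no atlas, no training data, no special bone sequence), and each
tissue's MR intensities are substituted by CT numbers in Hounsfield units
(HU). The only manual input is a set of closed air contours (sinuses and
airway) on at most a dozen axial slices; air and cortical bone are
otherwise indistinguishable in T1 images.

## Method in brief

All thresholds are *relative*, derived per patient:

- **Air.** The sparse manual contours are interpolated across slices
  (linear interpolation of signed distance transforms); robust statistics
  mu_Air, sigma_Air of the enclosed air are estimated and soft tissue
  inside the contours (intensity > mu_Air + 3 sigma_Air) is subtracted.
- **Brain.** The voxel with maximal intensity uniformity U = mu/sigma in a
  1 cm x 1 cm window on the middle coronal slice defines the reference
  white-matter intensity `wmIntensity`. The statistical brain range is
  `[0.53, 1.35] x wmIntensity`; Canny edges (axial and sagittal slices,
  gaps wider than one voxel closed) act as leakage barriers; the initial
  brain is grown 3D from the reference voxel in
  `[0.7, 1.2] x wmIntensity`.
- **CSF and skull.** A maximally uniform dark 5 mm window inside the
  initial brain yields mu_CSF, sigma_CSF; a skull exclusion mask is grown
  from dark voxels within 1 cm of the body contour in
  `[0, mu_CSF + 2 sigma_CSF]`; CSF is grown in mu_CSF +/- 2 sigma_CSF
  constrained by the skull mask; the final brain adds connected tissue in
  the statistical range outside the skull mask.
- **Eyes.** Anterior, darker-than-brain connected regions filtered by
  size and sphericity, labelled left/right.
- **Bone.** Cortical bone is grown in the air-like window
  `[0, mu_Air + 3 sigma_Air]`; trabecular bone statistics come from the
  diploe enclosed in the cortical mask and nearby voxels in
  mu +/- 2 sigma are recovered.
- **Soft tissue.** Remaining voxels are classified per axial slice (with
  one adjacent slice of context on each side) as muscle
  `[min_soft, mu_soft]`, fat `(mu_soft, mu_soft + 2 sigma_soft]` or
  contrast artifact above that.
- **ED mapping.** Air -> -1000 HU; CSF (and eyes) -> 45 HU; contrast -> 0;
  cortical bone mu +/- 2 sigma -> [700, 1100] HU inverse-linear;
  trabecular -> [500, 700] inverse-linear; brain -> [40, 75] linear;
  muscle -> [20, 80] and fat -> [-70, -20] inverse-linear.

The package ships a digital head phantom (`generate_phantom()`) producing
paired MR / ground-truth CT / label volumes with auto-derived air contours,
so the whole chain is testable end to end, plus the evaluation metrics used
for sCT validation: external bone contour distance on the widest slices,
Dice similarity and per-region mean / mean-absolute HU error.

## Worked example

```r
library(mrsct)

# paired MR / ground-truth CT head phantom (Rician noise, 5% bias field)
ph <- generate_phantom(seed = 0)

# synthetic CT from the MR volume and the manual air contours
res <- mr2sct(ph$mr, ph$contours)
print(res)
#> <sct> 192 x 192 x 192 voxels, HU range [-1000, 1100]
#>   wmIntensity 1017
#>      BACKGROUND             AIR   CORTICAL_BONE TRABECULAR_BONE           BRAIN
#>         4654431           17467          285293          155225          752848
#>             CSF             EYE          MUSCLE             FAT        CONTRAST
#>          144023           34155          721931          312369             146

# agreement with the ground-truth CT
ev <- evaluate_sct(res$sct, ph$ct, res$labels)
round(ev$contour_distance$per_view, 2)
#>    axial  coronal sagittal
#>     0.10     0.15     0.20
ev$dice
#>      bone
#> 0.9514426
subset(ev$errors, region %in% c("whole_body", "air", "soft_tissue", "bone"))
#>        region        ME       MAE n_voxels
#> 1  whole_body 13.471302  35.84147  2414813
#> 2         air  0.000000   0.00000  4671898
#> 3 soft_tissue -4.441746  17.39054  1963227
#> 4        bone 98.429760 117.94385   432861
```

`wmIntensity` is the detected white-matter reference (the phantom's set
point is 1000; the bias field shifts it slightly). The contour distances
are the mean directed distances (mm) between the external skull contours of
the sCT and the CT on the widest axial/coronal/sagittal slices; `ev$dice`
is the Dice coefficient of the 200 HU bone masks; ME/MAE are the mean and
mean-absolute HU differences (CT minus sCT) per evaluation region. The
bone errors are dominated by the continuous inverse-linear ED assignment
against the phantom's single-valued bone HU — the behaviour the
voxel-based mapping is designed to trade for realistic ED gradients.

A file-based interface (`run_pipeline()`) and a CLI
(`inst/cli/mr2sct run|evaluate|phantom`) wrap the same functions:

```sh
Rscript inst/cli/mr2sct phantom --seed 0 -o phantom/
Rscript inst/cli/mr2sct run --mr phantom/mr.nii.gz --air phantom/air.json -o out/
Rscript inst/cli/mr2sct evaluate --sct out/sct.nii.gz --ct phantom/ct.nii.gz -o metrics/
```

## Limitations

Real patient data differ from the phantom in ways the tests cannot cover:
partial-volume mixing at every boundary, anatomy-dependent intensity
overlap, imperfect MR/CT co-registration for validation, and
susceptibility or motion artifacts. See the methods vignette
(`vignettes/mr2sct-methods.Rmd`) for the model, the tunable parameters and
the design decisions.
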