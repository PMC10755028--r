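# RatioSeg

Segmentation of internal brainstem structures from co-registered T1- and
T2-weighted MR volumes, for neuroimaging researchers who need subject-level
maps of brainstem tissue classes (and their age-related volume changes)
without manual delineation.

Myelin raises T1-weighted and lowers T2-weighted signal, so the voxelwise
quotient T1/T2 (the RATIO image) amplifies the contrast that separates
myelin- and iron-rich tissue from gray matter. The pipeline:

1. recalibrates each subject's T1 and T2 by the unique affine map
   `out = in · fact − shift` sending the white-matter and CSF histogram
   modes onto fixed references (T1: wm → 100, csf → 20; T2: wm → 20,
   csf → 100; `fact = |ref1 − ref2| / |wm − csf|`), with neighborhood repair
   of negative voxels and of RATIO voxels above the in-mask 99th percentile;
2. clusters the z-scored (T1cal, T2cal, RATIO) intensities of the brainstem
   voxels with k-means (k = 5, squared Euclidean distance, 1000 iterations,
   100 restarts), matching cluster numbering across subjects by optimal
   centroid assignment;
3. builds probabilistic group priors by diffeomorphic groupwise template
   construction (stationary-velocity demons with scaling-and-squaring),
   projects them back through the inverse deformations, reassigns voxels
   whose cluster disagrees with the prior argmax (alternate prior ≥ 0.75,
   or margin ≥ 0.20), and emits probabilistic final segmentations
   (binary × prior × standardized centroid proximity);
4. quantifies morphometry by Jacobian determinants of the
   template-to-subject deformations: per-ROI means, linear and quadratic
   age regression, Benjamini–Hochberg FDR (q = 0.05), and ANOVA + Scheffé
   comparisons of clustering-input variants via misclassification index,
   misclassification distance and the subthreshold silhouette index.

A seeded synthetic brainstem phantom generator (five tissue classes, bias
fields, additive channel noise, diffeomorphic shape variation, age-linked
atrophy of designated ROIs) makes every stage testable without access to
restricted cohort data. See the methods vignette
(`vignettes/ratioseg-methods.Rmd`) for the models, assumptions and defaults.

## Worked example

Generate one synthetic subject, run the per-subject first pass, and compare
against the known tissue classes:

```r
library(RatioSeg)

cfg <- phantomConfig(seed = 1)                 # 48^3, 0.8 mm, SNR 20
subject <- generateSubject(cfg, age = 72, subjectSeed = 42)

fp <- runSubjectFirstpass(subject@t1, subject@t2, subject@tissueMaps,
                          subject@brainstemMask,
                          pipelineConfig(kmeans = list(replicates = 25)))
fp$rescale$T1
#> RescaleParams [T1]: modes wm=601.3 csf=111.5 -> fact=0.163332 shift=-1.78718
fp$rescale$T2
#> RescaleParams [T2]: modes wm=79.78 csf=400.5 -> fact=0.24944 shift=-0.0999473
fp$model
#> ClusterModel k=5 on 13486 voxels, channels {T1,T2,RATIO}, objective 907.8
```

The estimated histogram modes sit at the generator's white-matter/CSF means
(T1 600/120, T2 80/400, up to noise and bias), and the fitted parameters map
them onto the fixed references: 601.3 · 0.163332 + 1.787 ≈ 100. Against the
phantom's ground truth:

```r
truth <- maskedValues(subject@trueLabels, fp$mask)$values
agreement <- groundTruthAgreement(fp$model@labels, truth)
round(agreement$ari, 3)
#> [1] 0.998
round(agreement$dice, 3)
#> class1 class2 class3 class4 class5
#>  0.994  1.000  0.999  0.999  1.000
```

An adjusted Rand index of 0.998 means the five k-means clusters reproduce
the five generating tissue classes almost voxel-perfectly at this noise
level; the per-class Dice scores show no class is sacrificed. A full cohort
analysis — priors, reassignment, probabilistic finals, Jacobian morphometry
and age regression — runs through `runCohort()`; a thin command-line front
end with `phantom` / `run` / `stats` subcommands lives at
`inst/cli/ratioseg.R`.

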