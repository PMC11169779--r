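# aortaseg

Post-processing and evaluation toolkit for multi-class segmentations of
the aortic root in contrast CT angiography (CTA), built around the
analysis chain used in automated pre-TAVR planning: once a segmentation
stage (typically a trained network) has labelled the ascending aorta
(AA), left ventricle (LV), valve leaflets and calcification, the
questions that matter clinically are *how many cusps does this valve
have*, *is it a tricuspid or a bicuspid valve (Sievers type 0 or
type 1)*, *which leaflet is which*, and *how good is the segmentation*.
`aortaseg` answers these with deterministic, seeded, unit-tested
operations, and ships a synthetic aortic-root phantom generator so the
whole pipeline is testable without patient data.

## What it implements

**Preprocessing** (`resample_image`, `resample_labels`,
`clip_and_normalize`, `crop_to_body`, `extract_patch`, `augment`) —
trilinear resampling to isotropic spacing (nearest-neighbour for
labels), intensity clipping to the [0, 1200] HU window followed by
min–max normalization to [0, 1], body-region cropping, cubic patch
extraction, and seeded rotation/zoom/noise/artifact augmentation.

**Leaflet analysis** (`keep_largest_component`,
`determine_cuspid_number`, `refine_leaflet_boundary`, `name_leaflets`,
`classify_valve`, `confusion_and_accuracy`) — scattered-piece removal;
cuspid counting by K-means over the leaflet voxels' world coordinates
at k = 2 and k = 3, choosing the k whose cluster boundaries fall inside
the commissural gaps (with mean-silhouette fallback); K-nearest-
neighbour refinement of the inter-leaflet boundary; anatomical naming
(right-/left-/non-coronary, or anterior/posterior); bicuspid subtyping
by a geometric raphe-ridge detector; and cohort confusion matrices.

**Metrics** (`overlap_metrics`, `surface_extract`, `hd95`, `assd`,
`evaluate_case`, `dice_focal_loss`) — Dice similarity coefficient
`DSC = 2|P∩G| / (|P|+|G|)`, precision, recall, the 95th-percentile
symmetric Hausdorff distance and the average symmetric surface distance
in millimetres, plus the composite `λ·(1−softDice) + (1−λ)·focal`
training loss as a standalone scalar.

**Phantom generator** (`phantom_spec`, `generate_phantom`,
`generate_cohort`, `degrade_image`) — synthetic CTA-like volumes with a
bright aortic tube on an LV-outflow-tract + ellipsoid blood pool, 2 or
3 thin cup-shaped leaflet sheets separated at the commissures, an
optional raphe ridge (Sievers type 1), calcific nodules, Gaussian noise
and low-frequency artifacts. Pure functions of their seed.

**Pipeline** (`run_pipeline`, `reference_segmenter`, `read_volume`,
`write_volume`, `write_report`) — NIfTI I/O, a pluggable segmenter
contract with a deterministic threshold-based reference segmenter for
phantoms, per-case failure isolation, and CSV/JSON reporting.

## Worked example

```r
library(aortaseg)

spec <- phantom_spec("BAV1", seed = 42)
ph   <- generate_phantom(spec)
print(ph$labels)
#> <label_volume> 64x64x64 voxels, spacing 0.7x0.7x0.7 mm, origin (0, 0, 0), RAS
#>   labels: background=202992 AA=23968 LV=33021 leaflet=2001 calcification=162

leaf <- ph$labels$data == LABEL_VOCAB[["leaflet"]]
res  <- determine_cuspid_number(leaf, ph$labels$spacing_mm, seed = 1)
res$k
#> [1] 2
round(res$cut_fractions, 4)
#>    k2    k3
#> 0.000 0.083
```

The cut fractions say that the k = 2 partition separates cleanly along
the commissural gaps (no leaflet voxel touches the other cluster),
whereas a k = 3 partition would have to cut through a cusp sheet
(8.3% of voxels sit on that artificial cut) — so this is a two-cusp
valve. Subtyping and naming:

```r
res$assignment <- refine_leaflet_boundary(leaf, res$assignment, 15,
                                          ph$labels$spacing_mm)
classify_valve(res$k, leaf, ph$labels$spacing_mm, assignment = res$assignment)
#> $valve_class
#> [1] "BAV1"      # the raphe ridge on the conjoint cusp was found
#> $raphe_detected
#> [1] TRUE
name_leaflets(res$assignment, leaf, ph$labels)
#> [1] "anterior"  "posterior"
```

Segmentation quality against ground truth (here: against itself, so
all metrics are perfect):

```r
evaluate_case(ph$labels, ph$labels, case_id = "demo")
#> <case_report> demo
#>      structure dsc precision recall hd95_mm assd_mm absent degenerate
#>             AA   1         1      1       0       0  FALSE      FALSE
#>             LV   1         1      1       0       0  FALSE      FALSE
#>        leaflet   1         1      1       0       0  FALSE      FALSE
#>  calcification   1         1      1       0       0  FALSE      FALSE
```

A DSC of 1 means perfect voxel overlap; `hd95_mm` / `assd_mm` are the
95th-percentile and mean symmetric surface distances in millimetres
(0 = surfaces coincide).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/aortaseg.R", package="aortaseg"))')
Rscript $CLI phantom  --n-per-class 20 --noise 0 --out phantoms --seed 7
Rscript $CLI run      --in phantoms --out reports --seed 1
Rscript $CLI evaluate --pred preds --gt truth --out metrics.csv
Rscript $CLI cusps    --labels phantoms/case_0003_lab.nii.gz
```

## Scope

Training and running the segmentation network itself, DICOM ingestion,
and clinical expert grading are out of scope; the
segmenter is a plugin contract, and the bundled reference segmenter is
a deterministic stand-in tuned to the phantom palette. See
`vignettes/aortic-root-pipeline.Rmd` for the model, parameter and
design discussion.
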