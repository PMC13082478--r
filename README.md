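# neurotrackr

Longitudinal, lesion-level analysis of brain metastases (BMs) from 3D
segmentation masks.

Patients treated with stereotactic radiosurgery routinely carry multiple
small brain metastases that must each be measured and followed across many
MRI studies. Clinical reports typically reduce this to a handful of manual
2D caliper measurements, which are laborious and show substantial
inter-reader variability — especially for sub-centimeter lesions that
formal RANO-BM criteria decline to measure at all. `neurotrackr`
implements the computational core of an automated lesion-tracking
workflow: given one co-registered enhancing-tumor label volume per
timepoint (NIfTI-1), it identifies each anatomically distinct lesion,
measures it the way a radiologist would, follows it through time, and
classifies its treatment response.

## What it computes

* **Lesion extraction.** Foreground voxels are decomposed into connected
  components under 6/18/26-adjacency (default 26); each component is one
  lesion with volume `|voxels| × voxel volume` and physical centroid.
* **DMAX — maximum orthogonal diameters in the axial plane.** For every
  axial slice the lesion crosses, the longest center-to-center distance
  between cross-section voxels

  `d_long = max_{p,q} ||p − q||` (mm)

  and the caliper width of the cross-section orthogonal to that segment;
  the slice maximizing `d_long` is reported. Through-plane extent never
  enters the measurement.
* **Longitudinal matching.** Between consecutive studies, lesions are
  paired by a globally optimal one-to-one assignment maximizing total
  voxel overlap (Jonker–Volgenant solve), with a 10 mm centroid gate
  rescuing overlap-free small lesions; tracks that vanish stay eligible to
  re-match on regrowth. Per-diameter percent change vs the prior study is
  `100 (d_t − d_{t−1}) / d_{t−1}`.
* **Per-lesion modified RANO-BM response.** With baseline `d_0` and nadir
  `d_min` (smallest prior longest diameter): **PD** if growth over nadir
  exceeds +20% (or the lesion reappears after disappearing), **CR** if the
  lesion is absent or measures 0, **PR** if change from baseline is ≤
  −30%, else **SD**; tracks appearing after baseline are **NEW**. The
  endpoint response is the label at the last study within 12 months of the
  first. No absolute-mm minimum change is imposed, so sub-5 mm lesions are
  assessed.
* **Validation statistics.** Lesion-wise detection (optimal overlap
  matching; precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, F1), size
  stratification at 5 mm (inclusive), patient-wise Sørensen–Dice
  `2|A∩B|/(|A|+|B|)` pooled over studies, ICC(2,1), Spearman ρ and
  Bland–Altman limits `mean ± 1.96·SD` for two-reader agreement.
* **Synthetic phantoms.** Seeded longitudinal series of ellipsoidal
  lesions with known grow/shrink/vanish/appear trajectories, a simulated
  logistic-detection reader and a degraded segmenter, so the whole
  pipeline is testable without patient data.

## Worked example

```r
library(neurotrackr)

traj <- data.frame(type = c("grow", "shrink"), pct = c(30, 40), t_event = NA)
ph <- generate_phantom(phantom_config(shape = c(64, 64, 32), n_studies = 4,
                                      n_lesions = 2, diam_range_mm = c(8, 10),
                                      trajectories = traj, seed = 7))
res <- cmd_track(ph$volumes, "demo_run", study_dates = ph$dates,
                 patient_id = "DEMO")
writeLines(readLines("demo_run/lesion_card.csv"))
```

```
patient_id,track_id,study_index,study_date,series_label,longest_mm,perpendicular_mm,pct_change_long,pct_change_perp,response_label
DEMO,1,0,2020-01-01,,9.8,9.4,,,NA
DEMO,1,1,2020-03-31,,12.6,12.3,28.4,30.6,PD
DEMO,1,2,2020-06-29,,16.6,16.3,31.6,32.5,PD
DEMO,1,3,2020-09-27,,21.8,21.6,31.2,32.0,PD
DEMO,2,0,2020-01-01,,8.6,8.4,,,NA
DEMO,2,1,2020-03-31,,4.5,4.5,-48.0,-46.6,PR
DEMO,2,2,2020-06-29,,2.8,2.8,-36.8,-36.8,PR
DEMO,2,3,2020-09-27,,0.0,0.0,-100.0,-100.0,CR
```

Track 1 is the +30%/study lesion: every follow-up exceeds the +20%-over-
nadir threshold, so it is progressive disease at each timepoint. Track 2
shrinks 40% per study — partial response from the first follow-up — and by
study 3 it has collapsed to a single voxel (0.0 mm by the center-to-center
convention), which counts as complete response.

Detection metrics work directly from contingency counts too:

```r
m <- detection_metrics(502, 41, 105)
sprintf("precision %.3f sensitivity %.3f f1 %.3f", m$precision, m$sensitivity, m$f1)
#> "precision 0.924 sensitivity 0.827 f1 0.873"
```

A command-line front-end wraps the same pipeline
(`inst/cli/neurotrackr`): subcommands `track`, `evaluate`, `agreement`,
`phantom` with flags `--connectivity`, `--gate-mm`, `--pd-pct`,
`--pr-pct`, `--endpoint-months`, `--size-threshold-mm`, `--seed`,
`--counts-json`, `--allow-more-studies`.

## Scope

Masks are assumed co-registered (affine resampling of labels is provided;
image registration, segmentation-model inference and PACS/viewer
integration are out of scope). See `vignettes/lesion-tracking.Rmd` for the
measurement conventions, matching and response rules, phantom design and
known limitations.
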