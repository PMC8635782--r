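---
title: "Identifying MRI sequence types from DICOM metadata"
author: "mriseqid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying MRI sequence types from DICOM metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The classification problem

An MRI session produces several *series* (scans), each acquired with a
particular pulse sequence: a 3D T1-weighted anatomical, a 2D FLAIR, a
dual-echo PD/T2, a T2\*-weighted gradient echo, diffusion (DTI),
functional EPI (fMRI), plus utility acquisitions such as localizers and
coil calibrations. Downstream software needs this *sequence type*, but in
multi-site archives it is encoded only in free-text names that vary by
vendor, site and year, and the vendor-generated DICOM header
`(0018,0024) Sequence Name` is absent in roughly half of real scans.

`mriseqid` learns the sequence type from 18 scanner-generated metadata
features per series:

| # | feature | source |
|---|---------|--------|
| 1 | Scanning Sequence | (0018,0020) |
| 2 | Sequence Variant | (0018,0021) |
| 3 | Scan Options | (0018,0022) |
| 4 | MR Acquisition Type | (0018,0023) |
| 5 | Sequence Name | (0018,0024) |
| 6 | Image Type | (0008,0008), backslash-joined |
| 7–9 | Repetition / Echo / Inversion Time (ms) | (0018,0080/0081/0082) |
| 10 | Flip Angle (deg) | (0018,1314) |
| 11 | Pixel Bandwidth (Hz/px) | (0018,0095) |
| 12 | Image Orientation | (0020,0037), canonicalized |
| 13 | Diffusion b-value (s/mm²) | vendor-specific private tag |
| 14–15 | FOV X / Y (mm) | PixelSpacing × matrix size |
| 16–17 | MultiEcho TE1 / TE2 (ms) | two smallest distinct TEs |
| 18 | Manufacturer | (0008,0070) |

Free-text operator fields such as `(0008,103E) Series Description` are
deliberately excluded: they are exactly the unreliable input the
classifier is meant to replace. The diffusion b-value lives in a private
tag that depends on the vendor — `(0043,1039)` on GE (a multivalue whose
first element is the b-value), `(2001,1003)` on Philips, `(0019,100c)` on
Siemens — which is why the manufacturer string is itself a feature.

Extraction conventions (`extract_record()`): series-level tags are taken
from the first instance in filename-sorted order, with a warning if later
instances disagree; the b-value is summarized as the maximum over
instances; the multi-echo TEs are the two smallest distinct echo times
across instances and are missing when fewer than two exist; the six
orientation cosines are rounded to two decimals and joined into a single
categorical string, which absorbs float jitter while keeping orientation
a single feature. The package reads DICOM with a small built-in codec
restricted to explicit-VR little-endian headers; other transfer syntaxes
raise an error rather than risking silently wrong values.

## Feature engineering

Two kinds of absence carry different information and are kept distinct
end to end:

* **missing** — the tag is not in the header at all. Numeric missings
  become the sentinel `1,000,000` (far beyond any physical ms/Hz/mm
  value, effectively "infinity"); categorical missings become the
  category string `"1000000"`.
* **empty** — the tag is present with zero length. Empty strings become
  the category `"empty"`. (Blank numeric cells in tabular input are
  treated as missing; a zero-length numeric value has no separate
  meaning.)

After substitution, every categorical feature with *n* distinct training
values expands into *n* indicator columns (`fit_schema()` /
`encode_records()`). Vocabularies are byte-order sorted so the column
layout is identical across runs and machines. At prediction time a value
that was never seen in training leaves its whole block at zero — "none of
the known values" — which is both honest and useful: it denies the forest
any spurious match and tends to depress the confidence of genuinely novel
scans. Schemas are always fitted on training rows only; in every
experiment the split precedes the schema fit, so test-set vocabularies
cannot leak into the model.

## The classifier and its confidence

The model is a probability random forest of 100 trees with maximum depth
16 and Gini impurity, trained single-threaded with a fixed seed (the
forest itself is `ranger`; the package owns the schema, confidence and
flagging semantics around it). The class probability of a scan is the
per-tree leaf class probability averaged over trees; the prediction is
the arg-max class (ties broken by sorted class order) and the
**confidence** is the maximum probability. A scan is flagged as a
possible unknown sequence type when its confidence is strictly below the
threshold (default 0.8; 0.9 is a reasonable stricter choice).

The depth/tree-count operating point sits well past the accuracy plateau
visible in `run_hyperparameter_grid()`; more trees stabilize the
confidence estimates without overfitting. A third tuning axis in
discretizing forest implementations — the number of bins used to
discretize numeric features — has no counterpart in an exact-split
forest; for fidelity the configuration records `max_bins = 32` and
`train_model()` offers optional quantile pre-binning of numeric columns
(`bin_numeric = TRUE`), off by default since exact splits subsume binned
ones.

`feature_importance()` reports impurity importance summed over each
feature's one-hot block and normalized to total 1 across the 18 features,
so categorical features with many levels are compared to numeric ones on
a common scale.

## What the synthetic corpus emulates

The archive that motivated the method is access-restricted, so the
package generates a corpus with its published statistical structure and
runs every experiment on that. The defaults
(`default_generator_config()`) are fixed study conditions, not tuning
knobs:

* **Composition.** 32,341 scans: 3DT1 3,807; 2D FLAIR 1,458; PD/T2
  2,384; T2-star 1,773; DTI 9,385; fMRI 7,482; junk 4,589; plus ASL 87
  and Field Map 1,376 held out as unknowns.
* **Overlapping numeric ranges.** TR is drawn uniformly per class over
  3DT1 6.4–2,740 ms, PD/T2 2,017–16,000 ms, fMRI 1,500–2,800 ms, DTI
  3,800–14,000 ms (and comparable bands elsewhere), so no single timing
  parameter separates the classes — redundancy across features is what
  the forest exploits.
* **Name chaos.** The DTI profile carries 148 distinct sequence-name
  variants, fMRI three; 50% of sequence names are missing and 5% empty.
  Other features have 2–10% missingness (manufacturer always present, as
  in DICOM practice).
* **Vendor dialects.** Manufacturer is drawn 60/25/15
  Siemens/GE/Philips, and emitted DICOM fixtures route the b-value
  through the corresponding private tag.
* **A heterogeneous junk class**: a 45/30/25 mixture of localizer,
  AAHead-scout and calibration sub-profiles whose parameters collide
  with the anatomical classes in different places — by design the
  hardest class, as in real archives.
* **Unknowns as near-misses.** ASL is EPI-based like fMRI/DTI but with
  an intermediate echo time, no diffusion weighting, a TR band inside
  the DTI range, and (half the time) a 3D readout that no known EPI
  class has; Field Map is a dual-echo gradient echo like T2-star but
  with a second echo (65–85 ms) far outside the T2-star band and
  bandwidth/FOV in junk territory. Each unknown therefore matches
  *different* known classes on different features, which is exactly what
  makes forest trees disagree and confidence drop — mirroring the
  mechanism by which unknown sequences are caught in practice.

Distribution families are deliberately plain — uniform over printed
ranges, weighted categorical pools — because nothing finer than ranges
and variant counts is published. What the generator does **not**
emulate: per-site random effects beyond the vendor mixture, correlated
missingness (a truncated header usually loses several tags at once),
incorrectly *filled* headers, drifting protocols over time, or class
frequencies outside this archive. Passing tests on this corpus therefore
demonstrate the machinery and the qualitative behaviour of the method,
not a performance guarantee on any particular real archive.

## Experiment designs

* `run_learning_curve()`: training sizes 20–1,200 per class, 20 repeats
  each; repeat *r* uses seed `master + r` for both the split and the
  forest, making every number in the output reproducible bit for bit.
  Accuracy is the fraction of correct predictions on all remaining
  scans of the known classes.
* `run_confidence_distribution()`: pooled test confidences at selected
  training sizes, 20 equal-width bins on [0, 1] (right-open, the last
  bin closed), percent per bin, flagged fraction, medians.
* `run_unknown_class_experiment()`: a model trained on 1,200 scans per
  known class predicts the ASL and Field Map scans; reported are the
  confidence distribution and the known class each unknown scan was
  assigned to. The leave-one-out mode (`exclude_class = "fMRI"` or
  `"DTI"`) retrains without that class — schema refitted without it —
  and treats it as the unknown.
* `run_hyperparameter_grid()`: accuracy over a trees × depth (× bins)
  grid at 50 training scans per class, one shared split, CSV-exportable.

Problem sizes in the shipped test suite are the full default corpus for
the headline checks (800 or 1,200 training scans per class, ~25k test
scans, 20-repeat learning curve over sizes 20/100/400/800) and ~100-scan
corpora for the unit tests; the acceptance script averages the 800/class
accuracy over five derived seeds.

## Numerical and design choices

* Sentinels: `1e6` / `"1000000"` / `"empty"`, chosen to be unambiguous
  in both numeric and categorical space; substitution is idempotent.
* Table dialect: missing serializes as `"__MISSING__"` (CSV) or `null`
  (JSON-lines), empty as `""`; round trips are byte-identical, so the
  missing/empty distinction survives storage.
* Vocabulary order, class order and argmax tie-breaks are all byte-order
  sorts: no locale dependence, bit-identical cross-platform layouts.
* Flagging uses a strict `confidence < threshold` comparison.
* Degenerate inputs: single-class training yields a trivial model with
  confidence 1; a class with fewer records than the requested training
  count is a hard error naming the class; zero-row tables round-trip.
* Per-repeat seeds are `master + repeat index`; the generator restores
  the caller's RNG state, so package calls never perturb user code.

## Limitations

* The DICOM codec reads explicit-VR little-endian headers only —
  sufficient for the fixtures it writes and for most modern exports, but
  not a general DICOM implementation (no implicit VR, no compressed
  transfer syntaxes, sequences are skipped).
* A closed-world classifier can only *flag* unknowns, never name them;
  an unknown whose parameters are near-identical to a known class will
  be mislabelled at high confidence (observed here if the ASL profile is
  made fully fMRI-like, and in practice for, e.g., multi-band variants
  of a trained sequence).
* Real-data performance depends on labeling quality and on how well the
  18 features cover the local protocol mix; high-resolution fMRI, CT or
  PET would need the feature list revisited.
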