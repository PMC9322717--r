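# lnqdetect

Detection of compact hyperintense lesions ("tumors") in low-contrast 2D
grayscale slices, built as a fully seeded, testable R pipeline:
contrast-limited adaptive histogram equalization (CLAHE) for
preprocessing, Otsu's between-class-variance threshold for segmentation,
shape/intensity region features, and a learning-vector-quantization-style
classifier whose matching score is a max–min similarity, with optional
bit-width quantization of the classifier weights and
signal-to-quantization-noise (SQNR) accounting. Because no public imaging
dataset is bundled, the package ships a synthetic phantom generator with
exact ground truth, so every stage — and the pipeline end to end — is
validated on data whose answer is known.

It is aimed at readers who want a small, fully reproducible reference
implementation of this pipeline family: each stage is exposed as a plain
function with typed errors, and the classifier follows the classic R
modelling idiom (`lnq()` returns a fitted object with `print`, `summary`,
`coef`, `predict` and `plot` methods).

## The methods in brief

* **CLAHE.** Per tile, the gray-level histogram is clipped at
  `N_CL = max(1, ceil(clip_norm × tile_px))`, the excess redistributed
  deterministically, and the equalization LUT
  `f_i = round((n_out−1) · CDF(i))` built from the result; output pixels
  bilinearly blend the LUTs of the nearest tile centers. One tile and no
  clipping reduces bit-for-bit to global histogram equalization.
  Histogram entropy `E = −Σ p_i log2 p_i` is reported as a diagnostic and
  is maximal (`log2 n`) exactly for the uniform histogram.
* **Otsu.** The threshold maximizes
  `σ_b²(t) = ω0 ω1 (μ0 − μ1)²`, equivalently minimizes the within-class
  variance, with `σ² = σ_w²(t) + σ_b²(t)` holding exactly at every `t`.
  The lesion candidate is the largest 8-connected component above the
  threshold with at least `min_area` pixels.
* **Classifier.** Reference vectors per class in `[0,1]^d`; similarity
  `S(x,w) = Σ min(x_i,w_i) / Σ max(x_i,w_i)` (1 exactly at equality);
  LVQ1 training with linear rate decay; uniform mid-rise quantization of
  the codebook at `β` bits with `SQNR ≈ κ·β`, `κ ≈ 6` dB/bit, estimated
  by fit rather than assumed.
* **Evaluation.** Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`,
  specificity `TN/(TN+FP)`, and Dice overlap `2|A∩B|/(|A|+|B|)` against
  phantom ground truth.

The methods vignette (`vignettes/lnqdetect-methods.Rmd`) documents the
conventions, parameter defaults, design decisions and limitations.

## Worked example

```r
library(lnqdetect)

# a seeded 128x128 phantom with a known tumor ellipse
spec <- phantom_spec(tumor = list(center = c(60, 70), axes = c(10, 8),
                                  delta = 80), seed = 11)
ph <- make_phantom(spec)
print(ph)
#> phantom 128x128, label tumor, tumor area 245 px

seg <- segment_image(ph$image)
print(seg$candidate)
#> region candidate: area 245 px, bbox rows 50-70 cols 62-78
dice(seg$candidate$mask, ph$truth_mask)
#> [1] 1
```

The head threshold (Otsu on the CLAHE-enhanced image) lands at 104 and
the lesion threshold (second Otsu on native intensities within the head)
at 140 here: the candidate recovers the tumor ellipse exactly, so the
Dice overlap is 1. Region features for the candidate:

```r
round(region_features(ph$image, seg$candidate), 3)
#>           area      perimeter    circularity   eccentricity   centroid_row
#>        245.000         59.690          0.864          0.614          0.469
#>   centroid_col mean_intensity   sd_intensity
#>          0.547        201.073          5.070
```

Train a detector on one seeded cohort and evaluate on another:

```r
training <- make_cohort(60, 0.5, phantom_spec(), seed = 101)
model <- fit_detector(training, pipeline_config(seed = 1))
print(model)
#> Learning-quantization classifier: 2 classes x 3 clusters, d = 8 (unquantized)
#> classes: tumor, no_tumor
#> final training loss (1 - mean best-correct similarity): 0.1327

test_set <- make_cohort(50, 0.5, phantom_spec(), seed = 202)
res <- run_pipeline(test_set, model, pipeline_config(seed = 1))
print(res)
#> pipeline result: 50 image(s), 25 predicted tumor
#> evaluation report
#>   accuracy    1.0000
#>   precision   1.0000
#>   specificity 1.0000
#>   mean Dice over 25 tumor case(s): 1.0000
```

Perfect scores here say that the stages compose correctly under the
generator's controlled conditions (well-separated lesion intensities,
clean ellipses) — see the vignette for what the phantoms deliberately do
and do not model.

A thin command-line wrapper over the same functions lives at
`inst/cli/lnqdetect.R`:

```sh
Rscript inst/cli/lnqdetect.R simulate --out cohort --n 20 --seed 5
Rscript inst/cli/lnqdetect.R pipeline --in cohort --codebook codebook.json --out results
```

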