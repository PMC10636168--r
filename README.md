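# coralbof

Image-level localization of bleached corals in reef survey photographs
with a bag-of-hybrid-visual-features pipeline.

Coral bleaching — the loss of symbiotic zooxanthellae under thermal
stress, which whitens the colony — is monitored through underwater
survey imagery whose illumination, viewing angle, scale and orientation
vary wildly. `coralbof` classifies each survey image as *bleached* or
*unbleached* from local appearance statistics:

1. **Canonicalize** every image onto a 512×512 R,G,B canvas
   (pixel-center-aligned bilinear resize).
2. **Patch** it into M×M windows with 50% overlap (stride M/2; 361
   patches at M=50).
3. **Describe** each patch with a hybrid raw feature
   χ = [A(Iₛ); C(Iₛ)]: a deep patch embedding A (a seeded offline
   "stub" projection by default, pretrained AlexNet fc7 optionally)
   concatenated with a handcrafted color-texture descriptor C
   (per-channel quantization to Q levels + per-sub-block local
   histograms; 3·Q·g² values).
4. **Reduce** via a class-wise visual vocabulary: z-scored training
   features are clustered per class by Lloyd's k-means (k-means++
   seeding), V centroids per class, 2V words total. Each image becomes
   a 2V-bin histogram F: each patch is matched against all centroids
   with squared Euclidean distance, thresholded by its mean distance
   η_i = Σⱼ d²ᵢⱼ / m (`nearest_only` hard assignment by default;
   `all_below_threshold` implemented as the alternative reading).
5. **Classify** encoded images with a kernel SVM (linear, quadratic,
   cubic, or fine/medium/coarse Gaussian; positive class = bleached),
   evaluated under stratified 4-fold cross-validation repeated twice
   (75%/25% train/test per run).

A seeded synthetic coral-texture generator ships with the package, so
the full pipeline is testable and demonstrable without any download.
The methods vignette (`vignettes/bag-of-hybrid-features.Rmd`) documents
the model, every tunable parameter, and the design decisions.

## Worked example

```r
library(coralbof)

data_dir <- tempfile("coral_demo_")
cfg <- synthetic_config(n_per_class = 10, canvas = 256, separation = 0.8, seed = 42)
man <- generate_dataset(cfg, data_dir)
man
#> <coral_manifest> 20 images (10 bleached, 10 unbleached)

params <- pipeline_params(canvas = 256, patch_size = 50, vocab_size = 10)
report <- kfold_evaluate(man, params, eval_protocol(K = 4, repetitions = 2, seed = 42))
report
#> <coral_eval> 4-fold x 2 repetitions: accuracy 100.00% (SD 0.00), F1 1.0000
#>   confusion: TP=20 FP=0 TN=20 FN=0

head(report$predictions[, c("image_id", "truth", "predicted", "score")], 3)
#>       image_id    truth predicted     score
#> 1 bleached_003 bleached  bleached 0.9766305
#> 2 bleached_004 bleached  bleached 0.8986035
#> 3 bleached_009 bleached  bleached 0.9704490
```

The report's `mean_accuracy`/`sd_accuracy` are the mean and SD over the
8 per-run accuracies (4 folds × 2 repetitions), `f1` is computed over
the pooled held-out predictions with bleached as the positive class,
and `predictions` lists every held-out prediction with its fold and
repetition. At `separation = 0.8` the two synthetic classes differ
strongly in color and texture, so the study saturates at 100%;
`localization_report(report, "report.csv")` writes the per-image
account (plus an optional contact sheet of predicted-bleached images).

## Command line

```sh
inst/scripts/coralbof synth    --out-dir data --n-per-class 20 --seed 1
inst/scripts/coralbof evaluate --manifest data/manifest.csv --out-dir results \
                               --patch-size 50 --vocab-size 10 --kernel quadratic --seed 1
```

Every output directory receives the resolved `config.yaml` and a
deterministic `summary.json`; the same config and seed reproduce both
byte for byte. Unknown config keys are rejected.

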