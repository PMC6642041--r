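# histonet

Semantic tissue segmentation and treatment-response decision support for
hematoxylin-and-eosin (H&E) stained patient-derived xenograft (PDX)
histology.

Pre-clinical immuno-oncology screening with the single-mouse-trial (SMT)
design produces one whole-slide image per tumor model and treatment arm
(isotype control, anti-PD-L1, anti-CTLA4, combination) plus a CD45
immunostain. This package quantifies those slides for researchers in
translational immuno-oncology and digital pathology:

* an eight-class semantic segmentation network (tumor TUM, mouse stroma MST,
  necrosis NEC, blood cells/vessels BLC, vacuoles VAC, muscle MUS, artifacts
  TAR, background BGR) built from residual bottleneck blocks with SELU
  activations and Alpha-Dropout, trained with the three-term loss

  L = L_CCE + L_DDL + L_MSE

  (per-pixel cross-entropy + dice-distance loss + mean-square error of an
  auxiliary tissue-distribution head);
* Monte-Carlo-dropout uncertainty maps: five stochastic forward passes per
  tile give mean and variance probability maps, merged across a 25%-overlap
  grid with triangular blend windows;
* automated correction of the systematic BLC–NEC confusion: pixels whose
  variance rendering is light green — red/green ratio r = Vr/Vg in
  (0.35, 0.7) with Vb ≈ 0; an equal yellow/green mixture gives r = 0.5 and
  Vb = 0 exactly — are relabeled to necrosis after Gaussian smoothing
  (σ = 5 px) of the selection;
* Reinhard stain normalization in ℓαβ space, principal-component stain
  augmentation, and PCA-based two-stain decomposition of CD45
  immunohistochemistry;
* tumor-micro-environment meta-features: absolute areas f_i^(abs), tissue
  area A = Σ f_i over the six main classes, relative areas
  f_i^(rel) = f_i^(abs)/A, isotype differences Δf_i* = f_i* − f_i,isotype*,
  and the CD45-positive fraction;
* decision support: min-max scaling, stratified 10-fold cross-validation
  over a classifier panel (Gaussian naive Bayes, linear/RBF SVM, logistic
  regression, k-nearest-neighbors with Manhattan or Euclidean distance), and
  2D naive-Bayes decision surfaces;
* a classical texture baseline (RGB moments, GLCM, LBP, Tamura + SVM/random
  forest) for benchmarking, and a seeded synthetic-data module that makes
  the whole pipeline testable without any external data.

## Worked example

```r
library(histonet)

# train a small model on synthetic benchmark tiles
tiles <- synth_benchmark(24, c(48, 48), seed = 101)
fit <- histonet(tiles,
                net_config(levels = 2, base_width = 12, bottleneck_factor = 4,
                           blocks_per_level = 1, compression_widths = c(6, 8),
                           dropout_rate = 0.1, seed = 11),
                train_config(learning_rate = 2e-3, epochs = 60, seed = 5))
print(fit)
#> Tissue segmentation network (2 levels, base width 12, trained)
#>   8 classes, 4369 parameters, dropout 0.10
#>   final epoch 60: total loss 0.3969, training macro F1 0.925

# segment a held-out mosaic with uncertainty sampling and correction
mosaic <- synth_benchmark(1, c(96, 96), seed = 400)[[1]]
pred <- predict(fit, mosaic$image, patch_size = 48, overlap = 0.25,
                samples = 5, seed = 2)
print(pred)
#> tissue prediction 96 x 96 px
#>   TUM: 79.1%
#>   TAR: 12.4%
#>   MUS: 8.5%
mean(pred$labels == mosaic$annotation)
#> [1] 0.9853516

# meta-features of the corrected tissue map
mf <- meta_features(pred$labels)
mf$area            # tissue area A (px): 8070
mf$f_rel[["TUM"]]  # relative tumor area: 0.903

# decision support on a synthetic SMT cohort with a planted response effect
cohort <- synth_smt_cohort(n_models = 17, effect = 1, seed = 8)
ft <- build_feature_table(cohort)
cv <- cross_validate(ft$features, ft$labels,
                     classifier_spec("knn", k = 5, metric = "manhattan"),
                     k = 10, seed = 3)
print(cv)
#> 10-fold stratified CV, knn: accuracy 100.0%, AUC-ROC 100.0%
```

The fitted model reaches training macro F1 0.925 after 60 epochs and labels
98.5% of the held-out mosaic's pixels correctly; the prediction summary
lists the tissue composition of the corrected map. The cohort generator
plants a strong responder signature (smaller tumor, more relative necrosis,
larger CD45 shift against the isotype), which the 5-NN/Manhattan classifier
recovers perfectly at this effect size; with `effect = 0` the same pipeline
falls to chance.

A command-line wrapper for the three pipeline stages is installed at
`inst/scripts/histonet-cli.R` (subcommands `predict`, `correct`, `decide`).

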