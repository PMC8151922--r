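# renotex

Computer-aided staging of chronic kidney disease (CKD) from B-mode renal
ultrasound, for image-analysis researchers who want a fully reproducible,
testable reference pipeline. Clinical renal sonograms show a characteristic
progression: cortical echogenicity rises with fibrosis, the corticomedullary
boundary fades, and the kidney shrinks. `renotex` turns those cues into a
quantitative classifier:

1. **Texture.** Three 50×50 regions of interest (cortex, corticomedullary
   boundary, medulla) are preprocessed (histogram equalization, then a 3×3
   local range filter) and described by gray-level co-occurrence matrices
   (GLCM). For a quantized image with N gray levels, the GLCM at
   displacement *d* and orientation θ is
   p(i,j) = x(i,j) / Σᵢⱼ x(i,j), the normalized count of pixel pairs at
   gray levels (i, j). From each GLCM, 19 second-order descriptors are
   computed — contrast Σ(i−j)²p(i,j), energy Σp², entropy −Σp·log p,
   correlation, cluster prominence/shade, sum/difference statistics, the
   two information measures of correlation, and friends — and averaged over
   the four orientations 0°/45°/90°/135° at d = 1.
2. **Fusion.** 19 descriptors × 3 ROIs = 57 texture features, plus kidney
   size (cm) = a 58-dimensional sample vector.
3. **Classification.** A 58–10–3 feed-forward network (tanh hidden layer,
   softmax output, full-batch Adam, early stopping on a validation split,
   70/15/15 partitioning) assigns each kidney to *normal*,
   *mild-and-moderate CKD*, or *severe CKD*.
4. **Evaluation.** Confusion matrix, classification/misclassification
   rates, and one-vs-rest ROC curves with trapezoidal AUC.

Because the underlying clinical images are private, the package includes a
seeded synthetic cohort generator (correlated Gamma multiplicative speckle,
class-dependent echo levels, boundary sharpness, and kidney-size
distributions matching the published per-class means ± SD) so that every
stage — and the pipeline end to end — runs and is tested without any
patient data. The default cohort reproduces the published composition:
251 normal, 328 mild-and-moderate, 162 severe (741 kidneys).

## Worked example

```r
library(renotex)

cfg <- pipeline_config(
  cohort  = cohort_spec(counts = c(normal = 40, mild_moderate = 40, severe = 40),
                        seed = 42),
  network = network_config(seed = 42))
res <- run_all(cfg)
print(res$reports$test)
```

```
Evaluation on partition 'test' (n = 18)
  classification rate   100.0%
  misclassification     0.0%
  AUC (normal vs rest)  1.000
  AUC (mild_moderate vs rest)  1.000
  AUC (severe vs rest)  1.000
Confusion matrix (rows = truth):
               predicted
truth           normal mild_moderate severe
  normal             7             0      0
  mild_moderate      0             6      0
  severe             0             0      5
```

The held-out test partition (18 of 120 kidneys) is classified perfectly:
the three synthetic classes differ in cortical echo level, texture
coarseness, boundary crispness and kidney size, and the 58-feature vector
separates them cleanly. Individual features are interpretable, e.g. for the
first record:

```
   cortex.contrast cortex.correlation   boundary.entropy            size_cm
             2.584              0.532              2.928             12.331
```

— a normal kidney: fine cortical speckle (moderate contrast at d = 1) and a
size of 12.3 cm drawn from the normal-class distribution (11.7 ± 0.46 cm).

Lower-level entry points mirror the pipeline stages: `generate_cohort()`,
`preprocess_roi()`, `build_glcm()` / `glcm_features()`,
`extract_cohort_features()`, `train_network()`, `evaluate_network()`. A
thin command-line front end lives at `inst/cli/renotex.R`
(`simulate`, `extract`, `train-eval`, `run-all` subcommands over a YAML
config). See the methods vignette (`vignettes/renal-texture-pipeline.Rmd`)
for the model, its assumptions, and all numerical conventions.

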