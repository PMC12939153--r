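# fibroscore

Image-based fibrosity scoring of plant-based meat (texturized vegetable
protein, TVP) products.

The fibrous, meat-like layering visible in a product cross-section — its
*fibrosity* — is a key quality attribute of extruded plant proteins, and is
traditionally scored 1–10 by human experts inspecting photographs.
`fibroscore` implements an end-to-end pipeline that learns to reproduce such
expert scores with a residual convolutional regression network, and a
synthetic-stimulus harness that probes *which* image features drive the
estimates.

## What's in the package

* **Preprocessing** (`remove_background()`, `pad_and_center()`,
  `preprocess_image()`): pixelwise background thresholding, zero-padding to
  a square canvas, and centroid centering, so all images are aligned before
  they reach the network.
* **Augmentation** (`dihedral_orientations()`, `fine_orientations()`): the
  8 lossless square-image symmetries for photographs, and 32 fine rotations
  (22.5° steps, bilinear, black fill) for synthetic stimuli.
* **Multi-rater score data** (`scored_dataset()`, `split_dataset()`,
  `balance_by_score_bins()`): session scores s<sub>i,p</sub> ∈ [1,10], per-image
  means s̄<sub>i</sub> = P⁻¹ Σ<sub>p</sub> s<sub>i,p</sub>, per-orientation
  assigned scores drawn without replacement from the session multiset,
  image-level 85:15 splits, and score-bin balancing.
* **The network** (`network_config()`, `build_network()`, `fit()`,
  `predict()`): an 18-layer-family residual stack — 7×7/2 stem, 3×3/2
  max-pool, four blocks of four 3×3 convolutions with parameter-free
  subsampled skips, global average pool, and a two-layer fully connected
  head giving the scalar score ŝ.  Every layer operation also exists as a
  slow pure-R reference implementation (`conv2d_reference()` and friends)
  used as an oracle in the tests.  Training (`train_config()`) is Adam with
  decoupled weight decay on the sum-squared-error loss
  E = Σ (s<sub>i,l</sub> − ŝ<sub>i,l</sub>)², dropout after the hidden head
  layer, a reduce-on-plateau schedule, and early stopping; by default only
  the head is trained (transfer-learning style), with cached trunk features.
* **Evaluation** (`error_norms()`, `goodness_of_fit()`,
  `regression_fits()`, `full_report()`): E2 (MSE), E1 (MAE), R², Pearson C,
  the through-origin slope r, and the ordinary regression slope m and
  intercept b of estimated on true scores.  Ideal values: E2 = E1 = 0,
  R² = C = r = m = 1, b = 0.
* **Synthetic stimuli** (`catalog30()`, `random_synthetic_spec()`,
  `render_spec()`, `oracle_score()`): orange food-matrix shapes (large
  circle, box, ellipse, small circle) on black containing darker air cells
  of controlled count, size and elongation, plus a rule-based granularity
  oracle that scores a specification from its geometry.
* **Experiment harness** (`experiment_config()`, `run_experiment()`,
  `orientation_stats()`, `synthetic_table()`): orchestrates both experiment
  modes — real photographs with session-score CSVs, or oracle-labeled
  synthetic stimuli — at configurable scale, with seeded reproducibility.

A thin command-line front end lives at `inst/cli/fibro.R`
(`prep`, `augment`, `synth`, `eval` subcommands).

## Worked example

Train the network head on 200 oracle-labeled 128-px synthetic images
(85:15 image-level split, dihedral training augmentation, score-bin
balancing) and evaluate on the held-out images — about two minutes on one
CPU:

```r
library(fibroscore)
res <- run_experiment(experiment_config(mode = "synthetic", seed = 1))
res$report
#> Metric report (n = 30)
#>     E2     E1     R2      C      r      m      b
#> 0.2706 0.4042 0.8911 0.9511 0.9815 0.7973 0.8347
```

The held-out correlation C = 0.95 and slope m = 0.80 say the estimates
track the oracle's granularity scores closely, with mild slope shrinkage
typical of a regularized fit.  Scoring one catalog stimulus across its 8
dihedral orientations shows the orientation stability of the estimates:

```r
img <- render_spec(catalog30(canvas = 128)[[15]])
sc  <- predict(res$fit, dihedral_orientations(img))
round(orientation_stats(sc), 4)
#>    avg    med    min    max    std
#> 6.3144 6.3110 5.7708 6.8651 0.5157
```

The spread across orientations (std 8% of the mean) is small relative to
the 1–10 scale: the estimate responds to the image content, not to how the
image happens to be oriented.

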