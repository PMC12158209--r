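# reefdet

Detection of benthic organisms — holothurians (sea cucumbers), echinus
(sea urchins), scallops and starfish — in degraded underwater imagery is
hard for exactly three reasons: object scales vary by an order of
magnitude, animals overlap and occlude one another, and the water column
blurs and colour-casts everything.  `reefdet` implements, in R, the three
detector components aimed at those failure modes, wrapped in a minimal
one-stage detector scaffold so every component is trainable, measurable
and verifiable at desk scale without any external dataset:

* **MSDA — multi-scale dilated attention.**  Sliding-window dilated
  attention (SWDA) attends from each position to a `k x k` window of
  neighbours spaced `r` pixels apart; the attended square has side
  `(k-1)r + 1`, so rates `{1,2,3,4}` with `k = 3` mix 3/5/7/9-pixel
  receptive fields across attention heads in one layer.  Embedded in a
  residual split–transform–merge backbone block (`C2PSA_MSDA`).
* **ASFF head — adaptive spatial feature fusion.**  Each output level
  rescales the other two pyramid levels to its geometry and blends the
  three maps per position with softmax-normalised weights
  (`alpha + beta + gamma = 1`), computed by 1×1 control convolutions:
  `F_ij = alpha_ij x0_ij + beta_ij x1_ij + gamma_ij x2_ij`.
* **Slide Loss.**  Per-sample binary cross-entropy reweighted by a
  piecewise exponential function of the sample's IoU `x` around the
  adaptive batch-mean threshold `mu`: weight 1 for `x <= mu - 0.1`,
  `exp(1 - mu)` in the boundary band, `exp(1 - x)` for positives — hard
  samples near the decision boundary are up-weighted, easy ones are not.

Around the core: COCO-style evaluation (greedy matching, 101-point AP,
mAP@50 / mAP@50-95, max-F1 operating point), a seedable generator of
synthetic benthic scenes with YOLO-format labels (long-tailed classes,
occlusion, colour cast, blur), Poisson/Gaussian noise robustness sweeps,
a YAML-configured training driver, and a CLI
(`inst/scripts/reefdet`: `generate`, `train`, `eval`, `predict`,
`count-params`, `noise-sweep`).

There is no deep-learning framework underneath: the package ships its own
Rcpp/RcppArmadillo compute kernels and a reverse-mode autodiff tape,
validated against finite differences and brute-force oracles in the test
suite.

## Worked example

```r
library(reefdet)

# dilated-window geometry
effective_extent(3, 1:4)
#> [1] 3 5 7 9

# slide weight around mu = 0.5
slide_weight(c(0.3, 0.45, 0.5, 1.0), 0.5)
#> [1] 1.000000 1.648721 1.648721 1.000000

# parameter budgets of the assembled nano detectors (4 classes)
count_parameters(build_model(model_config("baseline")))$total_params / 1e6
#> [1] 2.590604
count_parameters(build_model(model_config("mas")))$total_params / 1e6
#> [1] 3.966717

# generate a small synthetic benthic dataset and train the desk profile
spec <- scene_spec(image_size = c(96L, 96L), seed = 5L)
generate_dataset(spec, 160, "ds")
cfg <- load_config(overrides = list(image_size = 96L, epochs = 24L,
                                    batch_size = 8L, seed = 1L,
                                    model = list(width_multiple = 0.125)))
run <- train_detector(cfg, "ds", checkpoint_path = "best.rds")
run$best_mAP50
```

The first two results are the printed geometry and weight-function values;
the parameter totals are the learnable-scalar counts of the assembled
baseline and MAS-variant detectors (2.59 M / 3.97 M).  Training prints one
JSON line per epoch (`loss`, validation `mAP50`, `P`, `R`, the adaptive
threshold `mu`) and returns the best validation mAP@50.

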