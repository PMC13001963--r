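# skelmotion

Occlusion-robust 2D→3D skeleton lifting and skeleton-based binary
classification, in pure R.

## Who this is for

Researchers in markerless movement analysis (clinical gait/sit-to-stand
assessment, digital motor biomarkers) who need a fully inspectable,
dependency-light reference implementation of an occlusion-robust pose
pipeline: confidence-weighted temporal imputation of missing keypoints,
trend-extrapolated boundary padding, a two-stage residual encoder with
cross-attention fusion and multi-scale adaptive-weighted temporal
modelling for 3D pose regression, an adaptive-graph skeleton classifier,
joint-level saliency, and the standard pose metrics (MPJPE, PCK, AUC) —
plus a synthetic-motion generator so every stage is testable without any
external dataset. All trainable parts run on a small reverse-mode autodiff
engine included in the package.

## The models

**Imputation (TLSI).** A missing joint \(j\) at frame \(f\) is replaced by
a normalized weighted mean of the same joint's observed positions in
neighbouring frames:

```
p[f,j] = Σ_{f'∈N(f)} w(f,f') p[f',j] / Σ w(f,f'),   w(f,f') = exp(-λt|f-f'|) · c[f',j]
```

**Padding (TTEP).** The mean consecutive-frame difference over the first
and last `k` frames, `Δ = (X_k − X_1)/(k−1)`, extrapolates `P` frames at
each boundary so padded frames continue the local motion trend.

**Lifting.** Two residual feed-forward stages `Z_i = X + FFN_i(LN(X))`;
per-stage temporal convolutions `E_i = Conv1d(Z_i)`; parameter-free
cross-attention fusion `F = softmax(E1 E2ᵀ/√d) E2`; temporal cropping;
per temporal scale a spatial transformer block, segmentation into
length-`s_d` segments with a shared local transformer inside each segment,
recomposition and a learned sigmoid gate `α_d ∈ (0,1)`; fusion
`Σ_d α_d F̂_d` and a frame-wise linear regression to `J × 3` coordinates.

**Classification (adaptive graph).** Per time step,
`A_d = softmax((X_t W_q)(X_t W_k)ᵀ/√d_k)` is fused with the static
skeleton adjacency, `A = λA0 + (1−λ)A_d`; a graph convolution
`σ(A X_t W_f)` and a residual per-node MLP produce frame features that are
stacked, pooled over time steps and joints (`g = mean_{t,j} H[t,j,·]`),
and classified by a two-layer sigmoid head. Saliency scores each joint by
the mean absolute input gradient of the logit, or by the mean absolute
logit change under joint-wise perturbation.

**Metrics.** MPJPE (mean per-joint Euclidean error), PCK (fraction of
joints with error strictly below a threshold, 150 by convention) and AUC
(mean PCK over 5-unit thresholds up to 150).

## Worked example

```r
library(skelmotion)
layout <- default_joint_layout()          # 17-joint tree, pelvis root

# 1. simulate a smooth 3D motion and its occluded 2D view
params   <- motion_params(n_frames = 18, noise_sd = 0, frequency_range = c(1, 4))
truth    <- gen_pose_sequence(layout, params, seed = 7)
occluded <- apply_occlusion(truth$pose2d, n_missing = 4, seed = 8)
occluded
#> <pose_sequence_2d> 18 frames x 17 joints; 72 unobserved entries

# 2. restore the missing joints
imputed <- tlsi_impute(occluded, window_halfwidth = 5, lambda_t = 0.5)
mean(sqrt(apply((imputed$coords - truth$pose2d$coords)^2, 1:2, sum)))
#> [1] 0.225     # mean 2D error of the 72 imputed/observed entries (coordinate units)

# 3. train a toy lifter on 20 occluded sequences and evaluate
cfg <- model_config(dm = 40, df = 32, attention_heads = 2, frames = 18,
                    pad = 2, segment_lengths = c(18, 6), epochs = 40,
                    lr = 0.003, lr_decay = 0.999, positional = FALSE)
train <- lapply(1:20, function(i) {
  g <- gen_pose_sequence(layout, params, seed = 100 + i)
  list(pose2d = apply_occlusion(g$pose2d, 4, seed = 200 + i), pose3d = g$pose3d)
})
lifter <- train_datp(train, cfg, layout, seed = 1)
eval_datp(lifter, list(list(pose2d = occluded, pose3d = truth$pose3d)))
#> <pose_error_summary> MPJPE 1.2499 | PCK@150 1.0000 | AUC 1.0000
```

The MPJPE is in the generator's abstract coordinate units (joint
trajectories span roughly ±2.5 units); PCK/AUC use the conventional
150-unit threshold and saturate on this scale. A mean-pose predictor
scores ≈ 1.5 on this world, so the toy lifter is using the occluded 2D
input; the acceptance battery quantifies this properly (monotone
degradation with occlusion, ablation gaps, overfit capacity).

```r
# 4. two-class motion (amplitude effect at hips/spine/thorax), classify, explain
eff <- class_effect(c(2, 5, 8, 9), effect_size = 3, n_per_class = 10)
ds  <- gen_classification_dataset(layout, eff,
                                  motion_params(n_frames = 24, noise_sd = 0.02),
                                  seed = 3)
ccfg <- model_config(clf_epochs = 40, clf_lr = 0.005, clf_milestones = c(28, 36),
                     gcn_dim = 16, dk = 4)
clf  <- train_agtm(ds, ccfg, layout, seed = 1)
classification_metrics(ds$labels, predict_agtm(clf, ds)$label)
#> <classification_report> acc 0.650 | prec 0.714 | rec 0.500 | F1 0.588 (TP 5 FP 2 FN 5 TN 8)

gradient_saliency(clf, ds$sequences[[which(ds$labels == 1)[1]]])
#> <saliency_map> method=gradient, 17 joints, top = 9, 12, 8, 10, 15
```

Even this few-seconds toy classifier (10 samples per class) already puts
the planted thorax (9) and spine (8) near the top of the saliency map; at
the acceptance-battery scale — 40 per class, longer training, scores
averaged over sequences — both saliency methods rank every planted joint
above the non-discriminative median in all three seeds
(`saliency_recovery_benchmark()`).

A command-line interface wraps the same pipeline
(`simulate`, `impute`, `pad`, `train-pose`, `eval-pose`, `train-clf`,
`eval-clf`, `explain`):

```sh
Rscript inst/cli/skelmotion.R simulate --frames 81 --n-missing 4 --seed 1 --out-dir out/
Rscript inst/cli/skelmotion.R impute --in out/pair_001_2d.json --out out/imputed.json
```

Every run writes a JSON manifest (command, config hash, seed, inputs,
outputs, wall time).

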