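# maskfuse

Adaptive union/intersection fusion of binary segmentation masks, with exact
Hausdorff-distance and IoU evaluation, for people who have several
segmentation models' output masks (e.g. U-Net-family brain tissue
segmentations of a head CT series) and want a single better mask plus
honest numbers about it.

## The method

Segmentation models err directionally. For each model *m*, count over a
labelled calibration set:

- `num_overseg(m)` = Σ false-positive pixels (background labelled foreground),
- `num_miss(m)` = Σ false-negative pixels (foreground labelled background).

The fusion strategy *F* over the model outputs is then

```
F = ∩ (pixel-wise AND)  if num_overseg > num_miss for ≥ 2 models  (fuse those models)
F = ∪ (pixel-wise OR)   if num_miss > num_overseg for ≥ 2 models  (fuse those models)
```

Intersection can only remove false positives; union can only recover missed
pixels — so the calibration counts pick the operation that attacks the
models' shared weakness. A two-model tie (one of each direction) is
undecidable by the rule; a third model resolves it by providing an agreeing
pair, and a fully unresolved tie falls back to intersection with the
decision trace recorded in the plan.

Results are optionally refined by a 9×9 Gaussian filter (σ = 1) followed by
binarization at 0.5, which deletes isolated specks and fills isolated
holes. Everything is scored by IoU (overlap/union pixels) and by the exact
symmetric Hausdorff distance `HD(A,B) = max(h(A,B), h(B,A))`,
`h(A,B) = max_{a∈A} min_{b∈B} ‖a−b‖`, over the masks' 4-connectivity
boundary pixel sets, in pixel units.

The package also ships a synthetic benchmark: head-series phantoms
(unimodal slice-area profile, perturbed-ellipse brain regions, distractor
structures on low slices) and simulated segmenters with controllable
over-/under-segmentation biases, so the whole pipeline is testable with no
clinical data.

## Worked example

```r
library(maskfuse)

cfg     <- phantom_config(seed = 20210101L)        # 31 slices, 128x128
phantom <- generate_phantom_series(cfg)
models  <- default_segmenter_profiles(cfg$seed)    # three biased segmenters
preds   <- lapply(models, function(m)
  simulate_model_output(phantom$gt, phantom$distractors, m))

profiles <- lapply(names(preds), function(id)
  accumulate_profile(preds[[id]], phantom$gt, id))
plan <- select_strategy(profiles)
print(plan)
#> <fusion_plan: intersection over {unet_like, unet2p_like, unet3p_like}>
#>   unet_like: num_overseg=17634, num_miss=20 -> OVER; unet2p_like: num_overseg=25778,
#>   num_miss=0 -> OVER; unet3p_like: num_overseg=18701, num_miss=34 -> OVER;
#>   3 model(s) over-segment; intersecting them removes false positives

fused <- fuse_series(preds, plan)
for (s in c(preds, list(fused = fused, fused_filtered = smooth_series(fused))))
  print(evaluate_series(s, phantom$gt))
#> <eval_result 'unet_like':   31 slices, mean IoU 0.8059, pooled IoU 0.8472, mean HD 59.731 (1 undefined)>
#> <eval_result 'unet2p_like': 31 slices, mean IoU 0.7510, pooled IoU 0.7915, mean HD 58.672 (1 undefined)>
#> <eval_result 'unet3p_like': 31 slices, mean IoU 0.7976, pooled IoU 0.8393, mean HD 60.084 (1 undefined)>
#> <eval_result 'fused':       31 slices, mean IoU 0.8844, pooled IoU 0.9210, mean HD 51.410 (1 undefined)>
#> <eval_result 'fused':       31 slices, mean IoU 0.8880, pooled IoU 0.9242, mean HD 46.764 (1 undefined)>
```

Every simulated model over-segments more than it misses, so the plan is
intersection over all three; the fused series' mean IoU (0.884, and 0.888
after Gaussian refinement) beats every single model (0.751–0.806). "1
undefined" flags the one slice whose ground truth is empty while the
prediction is not: its Hausdorff distance is undefined and is excluded from
the mean rather than replaced by an arbitrary constant. The mean HD stays
large here because the simulated models deliberately place false alarms on
the *same* distractor structures, so some survive intersection — see the
methods vignette (`vignettes/adaptive-mask-fusion.Rmd`) for what the
phantom does and does not emulate.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","maskfuse.R",package="maskfuse"))')" \
    simulate -c config.json -o bundle/
# ... profile --gt bundle/gt --pred unet=bundle/unet_like -o profile.csv
# ... fuse-eval --gt bundle/gt --pred a=... --pred b=... [--operation auto|union|intersection] -o out/
```

`fuse-eval` writes the fused series (raw and filtered), `fusion_plan.json`,
a per-slice IoU/HD CSV, and `summary.json`. Runs are deterministic: the
same config yields byte-identical outputs.

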