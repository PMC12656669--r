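# recovgait

Recovery of occluded 2D human-gait keypoints by unscented tracking with a
gated recurrent initialization, plus the downstream Parkinson's disease (PD)
vs. healthy gait classifier that motivates the recovery.

Markerless gait analysis extracts COCO-17 skeleton keypoints from walking
videos; occlusion (furniture, clothing, limb crossings) leaves joints
missing, conventionally encoded as the coordinate sentinel `(0, 0)`.
Zero-filled records cripple sequence classifiers — worst when the legs, the
most diagnostic region for parkinsonian gait, are the missing part. This
package is for researchers who need to (i) impute those missing
trajectories, (ii) quantify the recovery, and (iii) measure its effect on
classification, with a fully synthetic cohort so everything runs
self-contained.

## Method

Two estimators are combined, per coordinate series:

- **Gated initialization network.** A small GRU over sliding windows of 5
  consecutive frames with a rectified output state and a single linear
  output unit, trained with Adam (learning rate 0.001, MSE) on the pooled,
  window-anchored coordinate series of complete training sequences. It
  imputes missing values iteratively — each prediction window may contain
  earlier reconstructions.
- **Unscented Kalman Filter.** One 4-state filter per keypoint, state
  `[x, y, vx, vy]`, constant-velocity transition, position measurement,
  scaled unscented transform (α = 1e-3, β = 2, κ = 0):

  sigma points `X₀ = x`, `Xᵢ = x ± colᵢ √((n+λ)P)`; prior
  `x̂ = Σ Wᵐᵢ f(Xᵢ)`, `P = Σ Wᶜᵢ (f(Xᵢ)−x̂)(f(Xᵢ)−x̂)ᵀ + Q`; update via the
  innovation covariance `S = Σ Wᶜᵢ (zᵢ−ẑ)(zᵢ−ẑ)ᵀ + R`, cross covariance
  `P_xz`, gain `K = P_xz S⁻¹`, posterior `x̂ + K(z−ẑ)`,
  `P − K S Kᵀ`.

At the first missing frame the network seeds the filter's `x̂₀` and `P₀`.
Through the gap, the network's one-step prediction is fused as a
pseudo-measurement under inflated measurement noise (`R × 10`), and the
posterior is written back so the next prediction window consumes the refined
value. Recovery error is scored as MAE / MSE / MAPE over all 1700 record
values; classification as accuracy / precision / recall / F1 with PD
positive. Four ablation arms are built in: `none` (zero-fill), `ukf`
(predict-only extrapolation), `gated` (chain alone), `recovgait` (the
combination).

## Worked example

```r
library(recovgait)

# synthetic cohort: 12 base subjects -> 48 sequences after 4x augmentation
train <- make_dataset(n_pd = 6, n_healthy = 6, frames = 50, seed = 11)

# train the 50-unit gated initialization network on complete sequences
init <- train_gated_init(train, gated_init_config(hidden_units = 50, seed = 7))
init
#> <gated_init_model> 50 units, window 5, best epoch 25, held-out MSE 0.4198 (normalized)

# occlude the legs of a held-out subject for the last 40 of 50 frames
subject  <- generate_subject(gait_profile("HEALTHY"), frames = 50, seed = 501)
occluded <- simulate_missing(subject, "LEGS", missing_frames = 40)

# zero-fill error is analytic: 100 * 320/1700 of the record is missing
error_metrics(subject, occluded)$mape
#> [1] 18.82353

# recover and re-score
recovered <- recover_sequence(occluded, init, ukf_params(), method = "recovgait")
round(error_metrics(subject, recovered)$mape, 4)
#> [1] 1.5933
```

The MAPE of 18.82% for the zero-filled record is the exact missing-fraction
identity (320 of 1700 values); recovery brings it down to 1.59% for this
subject (median 1.91% over 20 such subjects), with the arms ordered
`recovgait < gated < ukf < none`. On the classification side, leg zero-fill
drops median test accuracy from 1.00 to 0.65 on the synthetic cohort, and
recovgait-recovered records restore 1.00 (5 seeds; the synthetic classes are
cleanly separable, so read these as pipeline mechanics, not clinical
performance).

A thin CLI covers the same flow from a shell:

```sh
exec/recovgait simulate --n-pd 26 --n-healthy 50 --seed 1 --out data.csv
exec/recovgait occlude  --in data.csv --group legs --missing-frames 40 --out occ.csv
exec/recovgait recover  --in occ.csv --train data.csv --method recovgait --units 50 --out rec.csv
exec/recovgait eval     --truth data.csv --pred rec.csv
```

## Package layout

- `R/keypoints.R` — `gait_sequence` container, body-part groups, CSV/JSON IO
- `R/synthetic.R` — gait profiles, skeleton generator, augmentation, datasets
- `R/occlusion.R` — score-weight merge, thresholding, occlusion simulation
- `R/gated_init.R`, `R/nn.R` — the GRU imputer and hand-rolled NN internals
- `R/ukf.R` — generic UKF engine and the per-keypoint recovery arms
- `R/classifier.R` — stacked-LSTM PD/healthy classifier
- `R/evaluation.R` — recovery and classification metrics, sweep tables
- `R/pipeline.R` — ablation / sensitivity / multi-part experiment harness
- `vignettes/recovgait-methods.Rmd` — models, assumptions, design choices
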