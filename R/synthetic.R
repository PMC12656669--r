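#' @title Synthetic walking skeletons
#' @description
#' A seeded generator of labeled walking-skeleton sequences used to exercise
#' every stage of the recovery and classification pipeline without any
#' external recordings. The kinematic model is deliberately simple: a pelvis
#' translating at constant speed, sinusoidal leg oscillation at the gait
#' cadence with left/right limbs in antiphase, counter-phase arm swing, and
#' a head riding the trunk, plus Gaussian pixel jitter. The Parkinsonian
#' profile differs from the healthy one by reduced stride amplitude, reduced
#' arm swing and slower walking speed — the shuffling, low-arm-swing gait
#' phenotype.
#' @name synthetic_gait
NULL

#' Class-specific gait profiles
#'
#' @param label `"PD"` or `"HEALTHY"`.
#' @param stride_amplitude peak leg (ankle) oscillation amplitude, pixels.
#' @param arm_swing_amplitude peak wrist oscillation amplitude, pixels.
#' @param cadence gait cycles per frame, in (0, 0.5).
#' @param trunk_height hip-to-shoulder distance, pixels.
#' @param jitter_sd per-coordinate Gaussian noise sd, pixels.
#' @param walk_speed horizontal pelvis speed, pixels per frame.
#' @return a `gait_profile` list.
#' @details The defaults encode the class contrast the classifier must learn:
#'   the PD profile has strictly smaller stride, arm swing and speed than the
#'   healthy one. At the healthy cadence of 0.08 cycles/frame a 50-frame clip
#'   holds four full gait cycles.
#' @export
gait_profile <- function(label = c("HEALTHY", "PD"),
                         stride_amplitude = NULL,
                         arm_swing_amplitude = NULL,
                         cadence = NULL,
                         trunk_height = NULL,
                         jitter_sd = 0.5,
                         walk_speed = NULL) {
  label <- match.arg(toupper(label[1]), c("HEALTHY", "PD"))
  defaults <- if (label == "PD") {
    list(stride_amplitude = 9, arm_swing_amplitude = 4, cadence = 0.06,
         trunk_height = 115, walk_speed = 1.8)
  } else {
    list(stride_amplitude = 22, arm_swing_amplitude = 14, cadence = 0.08,
         trunk_height = 120, walk_speed = 4)
  }
  p <- list(
    label = label,
    stride_amplitude = stride_amplitude %||% defaults$stride_amplitude,
    arm_swing_amplitude = arm_swing_amplitude %||% defaults$arm_swing_amplitude,
    cadence = cadence %||% defaults$cadence,
    trunk_height = trunk_height %||% defaults$trunk_height,
    jitter_sd = jitter_sd,
    walk_speed = walk_speed %||% defaults$walk_speed
  )
  stopifnot(p$stride_amplitude >= 0, p$arm_swing_amplitude >= 0,
            p$jitter_sd >= 0, p$cadence > 0, p$cadence < 0.5)
  class(p) <- "gait_profile"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noise-free skeleton trajectory for a profile
#'
#' The closed-form trajectory underlying [generate_subject]; exposed so the
#' sinusoidal kinematics can be checked independently of the noise path.
#'
#' @inheritParams generate_subject
#' @return numeric array `frames x 17 x 2`.
#' @export
skeleton_trajectory <- function(profile, frames) {
  t <- seq_len(frames) - 1
  phase <- 2 * pi * profile$cadence * t
  ground_y <- 420
  hip_y <- ground_y - 0.75 * profile$trunk_height
  shoulder_y <- hip_y - profile$trunk_height
  # canvas offset keeps every true coordinate strictly positive
  x0 <- 80
  px <- x0 + profile$walk_speed * t          # pelvis x
  co <- array(0, dim = c(frames, 17, 2))
  leg <- profile$stride_amplitude
  arm <- profile$arm_swing_amplitude
  set_kp <- function(k, x, y) {
    co[, k + 1L, 1] <<- x
    co[, k + 1L, 2] <<- y
  }
  bob <- 2 * sin(2 * phase)                  # double-frequency vertical bob
  # hips (11 left, 12 right): small antiphase sway
  set_kp(11, px - 9 + 0.15 * leg * sin(phase), hip_y + bob)
  set_kp(12, px + 9 - 0.15 * leg * sin(phase), hip_y + bob)
  # knees (13, 14) and ankles (15, 16): antiphase stride oscillation
  set_kp(13, px - 8 + 0.6 * leg * sin(phase), hip_y + 0.45 * profile$trunk_height)
  set_kp(14, px + 8 - 0.6 * leg * sin(phase), hip_y + 0.45 * profile$trunk_height)
  set_kp(15, px - 8 + leg * sin(phase), ground_y - 8 * abs(cos(phase)))
  set_kp(16, px + 8 - leg * sin(phase), ground_y - 8 * abs(cos(phase)))
  # shoulders (5, 6)
  set_kp(5, px - 12, shoulder_y + bob)
  set_kp(6, px + 12, shoulder_y + bob)
  # elbows (7, 8) and wrists (9, 10): counter-phase arm swing
  set_kp(7, px - 13 - 0.5 * arm * sin(phase), shoulder_y + 0.35 * profile$trunk_height + bob)
  set_kp(8, px + 13 + 0.5 * arm * sin(phase), shoulder_y + 0.35 * profile$trunk_height + bob)
  set_kp(9, px - 13 - arm * sin(phase), hip_y - 4 + bob)
  set_kp(10, px + 13 + arm * sin(phase), hip_y - 4 + bob)
  # head (0 nose, 1-2 eyes, 3-4 ears) rides the trunk
  head_y <- shoulder_y - 22 + bob
  set_kp(0, px + 4, head_y)
  set_kp(1, px + 2, head_y - 4)
  set_kp(2, px - 2, head_y - 4)
  set_kp(3, px - 5, head_y - 2)
  set_kp(4, px - 9, head_y - 2)
  co
}

#' Generate one synthetic walking subject
#'
#' Deterministic given `(profile, frames, seed)`. Gaussian jitter with sd
#' `profile$jitter_sd` is added to every coordinate of the closed-form
#' trajectory; the canvas offset guarantees no true coordinate is ever 0,
#' so the (0,0) occlusion sentinel stays unambiguous. All confidence scores
#' are 1.
#'
#' @param profile a [gait_profile].
#' @param frames frame count, at least 6 (one training window plus target).
#' @param seed integer RNG seed.
#' @param subject_id identifier for the sequence.
#' @return a [gait_sequence].
#' @export
generate_subject <- function(profile, frames = 50L, seed = 1L,
                             subject_id = NULL) {
  if (frames < 6L) {
    stop("frames must be >= 6 (window length + 1)", call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- sprintf("%s_s%d", tolower(profile$label), seed)
  }
  co <- skeleton_trajectory(profile, frames)
  if (profile$jitter_sd > 0) {
    co <- co + with_seed(seed, stats::rnorm(length(co), 0, profile$jitter_sd))
  }
  co <- pmax(co, 1e-6)  # jitter must not cross zero either
  gait_sequence(co, subject_id = subject_id, label = profile$label)
}

#' Augment a gait sequence (flip, scale, translate)
#'
#' Returns the four-sample augmentation family of a sequence: the original,
#' a horizontal flip about the sequence's mean mid-hip x, a scaling about
#' the same center, and a translation. Labels are preserved and occlusion
#' sentinels remain exactly (0, 0) under all transforms.
#'
#' @param seq a [gait_sequence].
#' @param scale_factor multiplicative factor for the scaled variant.
#' @param translation numeric `(dx, dy)` in pixels for the translated variant.
#' @return list of 4 [gait_sequence] objects, suffixed
#'   `_orig`, `_flip`, `_scale`, `_trans`.
#' @export
augment <- function(seq, scale_factor = 0.9, translation = c(15, 10)) {
  vis <- seq$visibility
  hips <- seq$coords[, 12:13, 1, drop = FALSE]            # keypoints 11, 12
  hip_vis <- vis[, 12:13, drop = FALSE]
  cx <- if (any(hip_vis)) mean(hips[hip_vis]) else mean(seq$coords[, , 1][vis])
  cy <- mean(seq$coords[, , 2][vis])
  transform <- function(fx, fy, tag) {
    co <- seq$coords
    live <- array(rep(vis, 2L), dim = dim(co))
    co[, , 1][live[, , 1]] <- fx(co[, , 1][live[, , 1]])
    co[, , 2][live[, , 2]] <- fy(co[, , 2][live[, , 2]])
    gait_sequence(co, subject_id = paste0(seq$subject_id, tag),
                  label = seq$label, scores = seq$scores, visibility = vis)
  }
  list(
    transform(identity, identity, "_orig"),
    transform(function(x) 2 * cx - x, identity, "_flip"),
    transform(function(x) cx + scale_factor * (x - cx),
              function(y) cy + scale_factor * (y - cy),
              "_scale"),
    transform(function(x) x + translation[1], function(y) y + translation[2],
              "_trans")
  )
}

#' Generate a labeled, augmented synthetic dataset
#'
#' Per-subject profiles are drawn around the class defaults with seeded
#' lognormal between-subject variation (sd 10% on amplitudes and speed);
#' every base subject is expanded by [augment], so the output holds
#' `4 * (n_pd + n_healthy)` sequences. Each sequence carries a `base_id`
#' attribute naming its base subject, which the train/test splitter uses to
#' keep augmentation families on one side of the split.
#'
#' @param n_pd,n_healthy base subject counts per class.
#' @param frames frames per sequence.
#' @param seed integer RNG seed.
#' @return list of `gait_sequence` objects.
#' @export
make_dataset <- function(n_pd = 26L, n_healthy = 50L, frames = 50L,
                         seed = 1L) {
  stopifnot(n_pd >= 1L || n_healthy >= 1L)
  out <- list()
  specs <- rbind(
    if (n_pd > 0) data.frame(label = "PD", i = seq_len(n_pd)),
    if (n_healthy > 0) data.frame(label = "HEALTHY", i = seq_len(n_healthy))
  )
  for (r in seq_len(nrow(specs))) {
    label <- specs$label[r]
    sub_seed <- (seed * 1000L + r) %% .Machine$integer.max
    mult <- with_seed(sub_seed, exp(stats::rnorm(3, 0, 0.1)))
    base <- gait_profile(label)
    prof <- gait_profile(
      label,
      stride_amplitude = base$stride_amplitude * mult[1],
      arm_swing_amplitude = base$arm_swing_amplitude * mult[2],
      walk_speed = base$walk_speed * mult[3],
      jitter_sd = base$jitter_sd
    )
    id <- sprintf("%s_%03d", tolower(label), specs$i[r])
    subj <- generate_subject(prof, frames, seed = sub_seed + 1L,
                             subject_id = id)
    fam <- augment(subj)
    fam <- lapply(fam, function(s) { attr(s, "base_id") <- id; s })
    out <- c(out, fam)
  }
  out
}

#' Evaluate code with a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
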