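#' @title Occlusion detection and simulation
#' @description
#' Two complementary facilities: (i) detection of occluded keypoints from the
#' redundant-detection confidence scores a top-down pose estimator emits —
#' the per-cluster scores are merged by a score-weight average and thresholded;
#' (ii) simulation of occlusion on clean data by zeroing the keypoints of a
#' body-part group over a trailing block (or explicit range) of frames, the
#' protocol used to build occluded test sets from complete recordings.
#' @name occlusion
NULL

#' Merge redundant-detection confidence scores
#'
#' For each keypoint `i`, computes the score-weight merge over the redundant
#' pose detections `j` of one cluster:
#' \deqn{merge_i = \sum_j cluster_{j,i} \; masked_{j,i} / \sum_k masked_{k,i}}
#' where `masked` equals `cluster` with detections too far from the reference
#' pose zeroed out (that masking is upstream pose-NMS behaviour and is taken
#' as given). If every masked score for a keypoint is 0 the merged score is
#' defined as 0 — the keypoint is treated as occluded, consistent with
#' confidence collapsing under occlusion.
#'
#' @param cluster_scores `detections x 17` matrix of confidence scores.
#' @param masked_scores same shape; zero for masked-out detections.
#' @return numeric vector of 17 merged scores.
#' @export
merge_score <- function(cluster_scores, masked_scores) {
  cluster_scores <- as.matrix(cluster_scores)
  masked_scores <- as.matrix(masked_scores)
  if (nrow(cluster_scores) < 1L) stop("empty cluster", call. = FALSE)
  if (!identical(dim(cluster_scores), dim(masked_scores))) {
    stop("cluster_scores and masked_scores must share shape", call. = FALSE)
  }
  num <- colSums(cluster_scores * masked_scores)
  den <- colSums(masked_scores)
  ifelse(den > 0, num / den, 0)
}

#' Classify keypoints as occluded from merged scores
#'
#' A keypoint is visible iff its merged score strictly exceeds the threshold
#' `tau`; a score equal to or below `tau` marks it occluded. The default
#' threshold is 0.5.
#'
#' @param merged numeric vector of 17 merged confidence scores.
#' @param tau threshold in \[0, 1\].
#' @return logical vector of 17, `TRUE` = occluded.
#' @export
detect_occluded <- function(merged, tau = 0.5) {
  stopifnot(tau >= 0, tau <= 1)
  !(merged > tau)
}

#' Describe an occlusion pattern
#'
#' @param groups character vector of body-part group names (see
#'   [body_part_groups]).
#' @param missing_frames suffix length `k`: the last `k` frames of the
#'   affected keypoints are removed. Ignored when `range` is given.
#' @param range optional explicit frame range `c(first, last)` (1-indexed)
#'   to remove instead of a suffix.
#' @return an `occlusion_spec` list.
#' @export
occlusion_spec <- function(groups, missing_frames = 40L, range = NULL) {
  indices <- sort(unique(unlist(lapply(groups, body_part_group))))
  if (is.null(range)) {
    stopifnot(missing_frames >= 0)
  } else {
    stopifnot(length(range) == 2L, range[1] >= 1L, range[2] >= range[1])
  }
  structure(list(groups = toupper(groups), indices = indices,
                 missing_frames = as.integer(missing_frames), range = range),
            class = "occlusion_spec")
}

#' Simulate occlusion on a gait sequence
#'
#' Returns a copy of `seq` in which every keypoint of the spec's groups has
#' its coordinates set to the (0, 0) sentinel and its visibility cleared over
#' the affected frames (the last `missing_frames` frames, or the explicit
#' range). All other values are untouched; the input is not mutated.
#'
#' @param seq a [gait_sequence].
#' @param spec an [occlusion_spec] (or arguments to build one, via `...`).
#' @param ... passed to [occlusion_spec] when `spec` is a character vector of
#'   group names.
#' @return a new [gait_sequence].
#' @export
simulate_missing <- function(seq, spec, ...) {
  if (is.character(spec)) spec <- occlusion_spec(spec, ...)
  frames <- n_frames(seq)
  if (is.null(spec$range)) {
    k <- spec$missing_frames
    if (k > frames) stop("missing_frames exceeds sequence length", call. = FALSE)
    if (k == 0L) return(seq)
    rows <- seq.int(frames - k + 1L, frames)
  } else {
    if (spec$range[2] > frames) stop("range exceeds sequence length", call. = FALSE)
    rows <- seq.int(spec$range[1], spec$range[2])
  }
  cols <- spec$indices + 1L
  co <- seq$coords
  sc <- seq$scores
  vis <- seq$visibility
  co[rows, cols, ] <- 0
  sc[rows, cols] <- 0
  vis[rows, cols] <- FALSE
  gait_sequence(co, subject_id = seq$subject_id, label = seq$label,
                scores = sc, visibility = vis)
}
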