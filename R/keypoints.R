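#' @title COCO-17 gait sequences
#' @description
#' The package's universal data container is the `gait_sequence`: one
#' subject's fixed-length trajectory of the 17 COCO skeleton keypoints
#' (nose, eyes, ears, shoulders, elbows, wrists, hips, knees, ankles) in
#' image pixel coordinates (origin top-left, x rightward, y downward),
#' together with per-keypoint detection confidence scores and a visibility
#' mask. A missing / occluded keypoint is encoded by the exact coordinate
#' sentinel (0, 0).
#' @name gait_sequence
NULL

N_KEYPOINTS <- 17L
VALUES_PER_FRAME <- 2L * N_KEYPOINTS

#' Body-part keypoint groups
#'
#' The four keypoint groups used for occlusion simulation and per-part
#' reporting. Indices are 0-based COCO keypoint ids: HEAD = nose, eyes and
#' ears (0-4); BODY = shoulders and elbows (5-8); HIPS = wrists and hips
#' (9-12, the wrists travel at hip height during walking); LEGS = knees and
#' ankles (13-16). The groups partition 0..16.
#'
#' @param name One of `"HEAD"`, `"BODY"`, `"HIPS"`, `"LEGS"` (case-insensitive).
#' @return `body_part_group()` returns an integer vector of 0-based keypoint
#'   indices; `body_part_groups()` returns the named list of all four.
#' @examples
#' body_part_group("HEAD")
#' names(body_part_groups())
#' @export
body_part_group <- function(name) {
  groups <- body_part_groups()
  key <- toupper(as.character(name))
  if (length(key) != 1L || is.na(key) || !key %in% names(groups)) {
    stop("unknown body part group '", name, "'; valid groups: ",
         paste(names(groups), collapse = ", "), call. = FALSE)
  }
  groups[[key]]
}

#' @rdname body_part_group
#' @export
body_part_groups <- function() {
  list(
    HEAD = 0:4,
    BODY = 5:8,
    HIPS = 9:12,
    LEGS = 13:16
  )
}

#' Construct a gait sequence
#'
#' @param coords numeric array `frames x 17 x 2` of pixel coordinates
#'   (last dimension is x, y).
#' @param subject_id character scalar identifier.
#' @param label `"PD"`, `"HEALTHY"` or `"UNKNOWN"`.
#' @param scores optional `frames x 17` matrix of confidence scores in
#'   \[0, 1\]. Defaults to 1 for visible keypoints and 0 for sentinel ones.
#' @param visibility optional `frames x 17` logical matrix; defaults to
#'   "coords are not the (0,0) sentinel". A keypoint flagged invisible by the
#'   caller (e.g. the occlusion detector) stays invisible even if its
#'   coordinates are nonzero.
#' @return An object of class `gait_sequence`: a list with elements
#'   `subject_id`, `label`, `coords`, `scores`, `visibility`.
#' @export
gait_sequence <- function(coords, subject_id = "subject", label = "UNKNOWN",
                          scores = NULL, visibility = NULL) {
  coords <- unname(coords)
  if (length(dim(coords)) != 3L || dim(coords)[2] != N_KEYPOINTS ||
      dim(coords)[3] != 2L) {
    stop("coords must be a frames x 17 x 2 array", call. = FALSE)
  }
  label <- match.arg(toupper(label), c("PD", "HEALTHY", "UNKNOWN"))
  frames <- dim(coords)[1]
  sentinel <- coords[, , 1] == 0 & coords[, , 2] == 0
  if (frames == 1L) sentinel <- matrix(sentinel, 1L, N_KEYPOINTS)
  if (is.null(visibility)) {
    visibility <- !sentinel
  } else {
    visibility <- matrix(as.logical(visibility), frames, N_KEYPOINTS)
    visibility <- visibility & !sentinel
  }
  if (is.null(scores)) {
    scores <- matrix(0, frames, N_KEYPOINTS)
    scores[visibility] <- 1
  } else {
    scores <- matrix(pmin(pmax(as.numeric(scores), 0), 1), frames, N_KEYPOINTS)
  }
  structure(
    list(subject_id = as.character(subject_id), label = label,
         coords = coords, scores = scores, visibility = visibility),
    class = "gait_sequence"
  )
}

#' @export
print.gait_sequence <- function(x, ...) {
  cat(sprintf("<gait_sequence> %s [%s]: %d frames x %d keypoints, %d occluded entries\n",
              x$subject_id, x$label, n_frames(x), N_KEYPOINTS,
              sum(!x$visibility)))
  invisible(x)
}

#' Number of frames in a gait sequence
#' @param seq a `gait_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) dim(seq$coords)[1]

#' Flatten a gait sequence into the per-record value vector
#'
#' Serializes the coordinate trajectory frame-major: for each frame in order,
#' keypoints 0..16 each contribute (x, y). A 50-frame sequence therefore
#' yields 50 x 34 = 1700 values.
#'
#' @param seq a `gait_sequence`.
#' @return numeric vector of length `frames * 34`.
#' @export
flatten_record <- function(seq) {
  # coords is frames x 17 x 2; interleave x,y per keypoint, frame-major
  as.vector(aperm(seq$coords, c(3, 2, 1)))
}

#' Rebuild a coordinate array from a flattened record
#' @param values numeric vector of length `frames * 34`.
#' @return numeric array `frames x 17 x 2`.
#' @keywords internal
unflatten_record <- function(values) {
  if (length(values) %% VALUES_PER_FRAME != 0L) {
    stop("record length ", length(values), " is not a multiple of ",
         VALUES_PER_FRAME, call. = FALSE)
  }
  frames <- length(values) %/% VALUES_PER_FRAME
  aperm(array(values, dim = c(2L, N_KEYPOINTS, frames)), c(3, 2, 1))
}

#' Read gait sequences from the per-record CSV layout
#'
#' One row per video: `subject_id`, `label`, then frame-major blocks of 34
#' values (keypoints 0..16, each as x then y) for every frame. Visibility is
#' inferred from the (0,0) sentinel; scores are set to 1 for visible and 0
#' for sentinel keypoints (the CSV layout carries no confidence scores).
#'
#' @param path CSV file with a header row.
#' @param frames expected frame count per record (default 50).
#' @return list of [gait_sequence] objects.
#' @export
read_records_csv <- function(path, frames = 50L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE)
  expected <- 2L + frames * VALUES_PER_FRAME
  lapply(seq_len(nrow(raw)), function(r) {
    row <- as.character(raw[r, ])
    if (length(row) != expected) {
      stop(sprintf("malformed record in row %d: %d cells, expected %d",
                   r, length(row), expected), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(row[-(1:2)]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      frame <- (bad - 1L) %/% VALUES_PER_FRAME + 1L
      stop(sprintf("non-numeric cell in row %d, frame %d, value %d ('%s')",
                   r, frame, (bad - 1L) %% VALUES_PER_FRAME + 1L,
                   row[bad + 2L]), call. = FALSE)
    }
    gait_sequence(unflatten_record(vals), subject_id = row[1],
                  label = row[2])
  })
}

#' Write gait sequences to the per-record CSV layout
#'
#' Inverse of [read_records_csv]: one row per sequence, columns
#' `subject_id`, `label`, then `f<frame>_k<keypoint>_{x,y}` frame-major.
#' Coordinates are serialized at full double precision.
#'
#' @param seqs list of [gait_sequence] objects sharing one frame count.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(seqs, path) {
  frames <- if (length(seqs)) n_frames(seqs[[1]]) else 50L
  counts <- vapply(seqs, n_frames, integer(1))
  if (length(counts) && any(counts != frames)) {
    stop("heterogeneous frame counts; offending ids: ",
         paste(vapply(seqs[counts != frames], `[[`, "", "subject_id"),
               collapse = ", "), call. = FALSE)
  }
  grid <- expand.grid(axis = c("x", "y"), k = 0:(N_KEYPOINTS - 1L),
                      f = seq_len(frames))
  header <- c("subject_id", "label",
              sprintf("f%d_k%d_%s", grid$f, grid$k, grid$axis))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  for (s in seqs) {
    writeLines(paste(c(s$subject_id, s$label,
                       format(flatten_record(s), digits = 17, trim = TRUE,
                              scientific = FALSE)),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Parse pose-estimator JSON output into gait sequences
#'
#' Accepts the common pose-estimator output shape: a JSON array of frame
#' entries `{frame_index, people: [{keypoints: [x, y, score] * 17}]}`. When
#' several people are detected, the person with the highest mean keypoint
#' score across frames is kept (the recordings are single-patient). Scores
#' are clamped to \[0, 1\]; frames with no detection are recorded with all
#' keypoints at the sentinel and score 0.
#'
#' @param path JSON file path.
#' @param frames frame budget per sequence; extra entries are truncated with
#'   a warning (default 50).
#' @param subject_id,label passed through to [gait_sequence].
#' @return a single [gait_sequence].
#' @export
parse_pose_json <- function(path, frames = 50L, subject_id = NULL,
                            label = "UNKNOWN") {
  entries <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.json$", "", basename(path))
  }
  if (length(entries) > frames) {
    warning(sprintf("%d frame entries, keeping the first %d",
                    length(entries), frames), call. = FALSE)
    entries <- entries[seq_len(frames)]
  }
  n <- length(entries)
  n_people <- max(c(1L, vapply(entries, function(e) length(e$people),
                               integer(1))))
  # per-person stacks; absent detections stay sentinel with score 0
  coords <- array(0, dim = c(n_people, n, N_KEYPOINTS, 2L))
  scores <- array(0, dim = c(n_people, n, N_KEYPOINTS))
  clamped <- FALSE
  for (f in seq_len(n)) {
    people <- entries[[f]]$people
    for (p in seq_along(people)) {
      kp <- matrix(unlist(people[[p]]$keypoints), ncol = 3L, byrow = TRUE)
      if (nrow(kp) != N_KEYPOINTS) {
        stop(sprintf("frame %d person %d: %d keypoints, expected 17",
                     f, p, nrow(kp)), call. = FALSE)
      }
      coords[p, f, , ] <- kp[, 1:2]
      if (any(kp[, 3] < 0 | kp[, 3] > 1)) clamped <- TRUE
      scores[p, f, ] <- pmin(pmax(kp[, 3], 0), 1)
    }
  }
  if (clamped) {
    warning("confidence scores outside [0, 1] were clamped", call. = FALSE)
  }
  best <- which.max(apply(scores, 1, mean))
  co <- array(coords[best, , , ], dim = c(n, N_KEYPOINTS, 2L))
  sc <- matrix(scores[best, , ], n, N_KEYPOINTS)
  gait_sequence(co, subject_id = subject_id, label = label, scores = sc)
}
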