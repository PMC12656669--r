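#' @title Experiment orchestration
#' @description
#' Harness for the train-on-complete / test-on-occluded experiment design:
#' generate (or load) a dataset, split by base subject, train the gated
#' initialization network and the classifier on complete training sequences,
#' occlude copies of the test sequences, recover them with each ablation arm
#' (`none` = zero-fill passthrough, `ukf` = unscented tracking only,
#' `gated` = gated imputation only, `recovgait` = the combination), and emit
#' long-format recovery and classification report tables.
#' @name pipeline
NULL

#' Run configuration
#'
#' @param n_pd,n_healthy,frames synthetic-dataset parameters (see
#'   [make_dataset]); ignored when `seqs` is supplied.
#' @param seqs optional pre-built list of [gait_sequence] objects.
#' @param groups body-part group names to occlude.
#' @param missing_frames suffix lengths `k` to sweep.
#' @param techniques subset of `c("none", "ukf", "gated", "recovgait")`.
#' @param hidden_units gated-init layer widths to sweep.
#' @param init_cfg,clf_cfg base configs; their `hidden_units` / `seed` fields
#'   are overridden per sweep cell.
#' @param ukf ukf parameter set, a [ukf_params].
#' @param seeds integer vector of run seeds.
#' @return a `run_config` list.
#' @export
run_config <- function(n_pd = 26L, n_healthy = 50L, frames = 50L,
                       seqs = NULL,
                       groups = c("HEAD", "BODY", "HIPS", "LEGS"),
                       missing_frames = 40L,
                       techniques = c("none", "ukf", "gated", "recovgait"),
                       hidden_units = 50L,
                       init_cfg = gated_init_config(),
                       clf_cfg = classifier_config(),
                       ukf = ukf_params(),
                       seeds = 1L) {
  if (length(techniques) == 0L || length(seeds) == 0L) {
    stop("need at least one technique and one seed", call. = FALSE)
  }
  techniques <- match.arg(techniques, several.ok = TRUE)
  structure(list(n_pd = n_pd, n_healthy = n_healthy, frames = frames,
                 seqs = seqs, groups = toupper(groups),
                 missing_frames = as.integer(missing_frames),
                 techniques = techniques,
                 hidden_units = as.integer(hidden_units),
                 init_cfg = init_cfg, clf_cfg = clf_cfg, ukf = ukf,
                 seeds = as.integer(seeds)),
            class = "run_config")
}

# one seed's shared context: dataset, split, trained models
seed_context_ <- function(cfg, seed, need_init = TRUE, need_clf = TRUE) {
  seqs <- cfg$seqs %||% make_dataset(cfg$n_pd, cfg$n_healthy, cfg$frames,
                                     seed = seed)
  split <- split_dataset(seqs, seed = seed)
  init_models <- list()
  if (need_init) {
    for (u in cfg$hidden_units) {
      icfg <- cfg$init_cfg
      icfg$hidden_units <- as.integer(u)
      icfg$seed <- as.integer(seed)
      init_models[[as.character(u)]] <- train_gated_init(split$train, icfg)
    }
  }
  clf <- NULL
  if (need_clf) {
    ccfg <- cfg$clf_cfg
    ccfg$seed <- as.integer(seed)
    clf <- train_classifier(split$train, ccfg)
  }
  list(seqs = seqs, split = split, init_models = init_models, clf = clf)
}

clf_report_ <- function(clf, seqs) {
  truth <- vapply(seqs, `[[`, "", "label")
  pred <- predict(clf, seqs)$label
  cc <- confusion_counts(truth, pred)
  classification_metrics(cc["tp"], cc["tn"], cc["fp"], cc["fn"])
}

recover_all_ <- function(test_occ, technique, init_model, ukf) {
  lapply(test_occ, recover_sequence, init_model = init_model, params = ukf,
         method = technique)
}

#' Run the recovery/classification ablation grid
#'
#' For every `(seed, hidden_units, group, missing_frames, technique)` cell:
#' the init network and classifier are trained once per `(seed, units)` on
#' the complete training split and shared across cells; test copies are
#' occluded, recovered with the technique, scored against ground truth
#' (recovery errors over all record values) and classified.
#'
#' @param cfg a [run_config].
#' @return list of data.frames `recovery` and `classification`.
#' @export
run_ablation <- function(cfg = run_config()) {
  rec_rows <- list(); clf_rows <- list()
  for (seed in cfg$seeds) {
    need_init <- any(cfg$techniques %in% c("gated", "recovgait"))
    ctx <- seed_context_(cfg, seed, need_init = need_init)
    for (u in cfg$hidden_units) {
      init_model <- if (need_init) ctx$init_models[[as.character(u)]]
      for (g in cfg$groups) {
        for (k in cfg$missing_frames) {
          occ <- lapply(ctx$split$test, simulate_missing,
                        spec = occlusion_spec(g, k))
          for (tech in cfg$techniques) {
            cell <- tryCatch({
              recv <- recover_all_(occ, tech, init_model, cfg$ukf)
              errs <- do.call(rbind, Map(error_metrics, ctx$split$test, recv))
              rec <- data.frame(technique = tech, group = g,
                                missing_frames = k, hidden_units = u,
                                seed = seed,
                                mae = mean(errs$mae), mse = mean(errs$mse),
                                mape = mean(errs$mape))
              clf <- cbind(data.frame(technique = tech, group = g,
                                      missing_frames = k, hidden_units = u,
                                      seed = seed),
                           clf_report_(ctx$clf, recv))
              list(rec = rec, clf = clf)
            }, error = function(e) {
              warning(sprintf("cell (%s, %s, k=%d, u=%d, seed=%d) failed: %s",
                              tech, g, k, u, seed, conditionMessage(e)),
                      call. = FALSE)
              NULL
            })
            if (!is.null(cell)) {
              rec_rows <- c(rec_rows, list(cell$rec))
              clf_rows <- c(clf_rows, list(cell$clf))
            }
          }
        }
      }
    }
  }
  keys <- c("technique", "group", "missing_frames", "hidden_units", "seed")
  list(recovery = sweep_report(rec_rows, keys),
       classification = sweep_report(clf_rows, keys))
}

#' Classification sensitivity to per-part occlusion (no recovery)
#'
#' Classifies zero-filled test data for each `(group, k)` cell plus a
#' complete-data baseline row (`group = "None"`, `k = 0`).
#'
#' @param cfg a [run_config]; its `missing_frames` must be non-empty.
#' @return data.frame of classification metrics per
#'   `(group, missing_frames, seed)`.
#' @export
run_part_sensitivity <- function(cfg = run_config(missing_frames = c(10L, 20L, 30L, 40L))) {
  if (length(cfg$missing_frames) == 0L) {
    stop("missing_frames must be non-empty", call. = FALSE)
  }
  rows <- list()
  for (seed in cfg$seeds) {
    ctx <- seed_context_(cfg, seed, need_init = FALSE)
    rows <- c(rows, list(cbind(
      data.frame(group = "None", missing_frames = 0L, seed = seed),
      clf_report_(ctx$clf, ctx$split$test))))
    for (g in cfg$groups) {
      for (k in cfg$missing_frames) {
        occ <- lapply(ctx$split$test, simulate_missing,
                      spec = occlusion_spec(g, k))
        rows <- c(rows, list(cbind(
          data.frame(group = g, missing_frames = k, seed = seed),
          clf_report_(ctx$clf, occ))))
      }
    }
  }
  sweep_report(rows, keys = c("group", "missing_frames", "seed"))
}

#' Recovery under multi-part occlusion
#'
#' Sweeps nested body-part sets (by default LEGS, LEGS+HIPS,
#' BODY+LEGS+HIPS, all four groups) at one suffix length and reports
#' recovery errors per nesting level and technique.
#'
#' @param cfg a [run_config] (only `techniques`, `hidden_units`,
#'   `missing_frames[1]`, seeds and data parameters are used).
#' @param levels list of character vectors of group names, expected nested.
#' @return data.frame of recovery errors per `(technique, level, seed)`.
#' @export
run_multipart <- function(cfg = run_config(techniques = "recovgait"),
                          levels = list(c("LEGS"),
                                        c("LEGS", "HIPS"),
                                        c("BODY", "LEGS", "HIPS"),
                                        c("HEAD", "BODY", "LEGS", "HIPS"))) {
  k <- cfg$missing_frames[1]
  rows <- list()
  for (seed in cfg$seeds) {
    need_init <- any(cfg$techniques %in% c("gated", "recovgait"))
    ctx <- seed_context_(cfg, seed, need_init = need_init, need_clf = FALSE)
    u <- cfg$hidden_units[1]
    init_model <- if (need_init) ctx$init_models[[as.character(u)]]
    for (li in seq_along(levels)) {
      occ <- lapply(ctx$split$test, simulate_missing,
                    spec = occlusion_spec(levels[[li]], k))
      for (tech in cfg$techniques) {
        recv <- recover_all_(occ, tech, init_model, cfg$ukf)
        errs <- do.call(rbind, Map(error_metrics, ctx$split$test, recv))
        rows <- c(rows, list(data.frame(
          technique = tech, level = li,
          groups = paste(levels[[li]], collapse = "+"),
          missing_frames = k, seed = seed,
          mae = mean(errs$mae), mse = mean(errs$mse), mape = mean(errs$mape))))
      }
    }
  }
  sweep_report(rows, keys = c("technique", "level", "seed"))
}
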