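#' @title Gated recurrent initialization network
#' @description
#' A lightweight univariate next-value predictor: one gated recurrent (GRU)
#' layer with a rectifier on its output and a single linear output unit. It
#' is trained on 5-frame sliding windows pooled over all coordinate series of
#' the complete training sequences, and serves two roles: iterative
#' imputation of missing coordinates (each missing value is predicted from
#' the previous window of observed-or-previously-reconstructed values and
#' written back), and construction of the Unscented Kalman Filter's initial
#' state and covariance at the first missing frame.
#' @name gated_init
NULL

#' Configuration for the gated initialization network
#'
#' @param window sliding-window length in frames (default 5).
#' @param hidden_units gated-layer width; 30, 50 and 70 are the studied sizes.
#' @param step_size Adam learning rate (default 0.001).
#' @param epochs maximum training epochs.
#' @param batch mini-batch size.
#' @param patience early-stopping patience on validation MSE, epochs.
#' @param val_fraction fraction of pooled windows held out for validation.
#' @param max_windows cap on pooled training windows; larger pools are
#'   subsampled (seeded) to keep training cost bounded.
#' @param seed integer RNG seed for initialization, shuffling and subsampling.
#' @return a `gated_init_config` list.
#' @export
gated_init_config <- function(window = 5L, hidden_units = 50L,
                              step_size = 0.001, epochs = 50L, batch = 32L,
                              patience = 5L, val_fraction = 0.1,
                              max_windows = 8000L, seed = 1L) {
  stopifnot(window >= 1L, hidden_units >= 1L, step_size > 0, epochs >= 1L,
            batch >= 1L, patience >= 1L)
  structure(list(window = as.integer(window),
                 hidden_units = as.integer(hidden_units),
                 step_size = step_size, epochs = as.integer(epochs),
                 batch = as.integer(batch), patience = as.integer(patience),
                 val_fraction = val_fraction,
                 max_windows = as.integer(max_windows),
                 seed = as.integer(seed)),
            class = "gated_init_config")
}

#' Sliding-window training pairs from a coordinate series
#'
#' Pair `t` has input `series[t .. t+window-1]` and target
#' `series[t+window]`. Any pair whose input or target touches a sentinel
#' value (exactly 0) is excluded.
#'
#' @param series numeric coordinate time series.
#' @param window window length.
#' @return list with `inputs` (`n x window` matrix) and `targets`
#'   (length-`n` vector); `n = 0` with a warning when the series is shorter
#'   than `window + 1`.
#' @export
make_windows <- function(series, window = 5L) {
  n <- length(series) - window
  if (n < 1L) {
    warning("series shorter than window + 1; no training pairs", call. = FALSE)
    return(list(inputs = matrix(numeric(0), 0, window), targets = numeric(0)))
  }
  idx <- outer(seq_len(n), 0:window, `+`)   # n x (window+1) frame indices
  vals <- matrix(series[idx], n, window + 1L)
  keep <- rowSums(vals == 0) == 0L
  list(inputs = vals[keep, seq_len(window), drop = FALSE],
       targets = vals[keep, window + 1L])
}

# per-coordinate-index (1..34) scale statistics over sequences: the sd of
# frame-to-frame differences, the natural scale of one-step motion. Windows
# are anchored at their last value, so the network sees translation-invariant
# inputs and predicts the next displacement.
coord_stats_ <- function(seqs) {
  deltas <- lapply(seqs, function(s) {
    m <- matrix(flatten_record(s), nrow = VALUES_PER_FRAME)  # 34 x frames
    m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  })
  vals <- matrix(unlist(deltas), nrow = VALUES_PER_FRAME)
  list(mu = rep(0, VALUES_PER_FRAME),
       sd = pmax(apply(vals, 1, stats::sd), 1e-6))
}

# coordinate index (1..34) for keypoint column k (1..17) and axis a (1..2)
coord_index_ <- function(k, a) (k - 1L) * 2L + a

#' Train the gated initialization network
#'
#' Pools normalized sliding windows from every coordinate series of the
#' (complete) training sequences, subsamples to `cfg$max_windows`, and fits
#' the GRU with Adam on MSE loss, early-stopping on a held-out validation
#' fraction and restoring the best-epoch parameters. Windows are normalized
#' by anchoring at their last value and scaling by the per-coordinate sd of
#' frame-to-frame differences (computed on the training set and stored in
#' the model), so the network learns translation-invariant local dynamics.
#'
#' @param train_seqs list of complete [gait_sequence] objects.
#' @param cfg a [gated_init_config].
#' @return a `gated_init_model`: parameters, config, normalization stats,
#'   held-out one-step MSE (normalized units) and the loss history.
#' @export
train_gated_init <- function(train_seqs, cfg = gated_init_config()) {
  if (length(train_seqs) == 0L) stop("empty training set", call. = FALSE)
  stats <- coord_stats_(train_seqs)
  w <- cfg$window
  Xs <- list(); ys <- list(); j <- 0L
  for (s in train_seqs) {
    for (k in seq_len(N_KEYPOINTS)) {
      for (a in 1:2) {
        c_idx <- coord_index_(k, a)
        series <- s$coords[, k, a]
        pw <- suppressWarnings(make_windows(series, w))
        if (length(pw$targets) == 0L) next
        j <- j + 1L
        anchor <- pw$inputs[, w]
        Xs[[j]] <- (pw$inputs - anchor) / stats$sd[c_idx]
        ys[[j]] <- (pw$targets - anchor) / stats$sd[c_idx]
      }
    }
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  with_seed(cfg$seed, {
    if (nrow(X) > cfg$max_windows) {
      pick <- sample.int(nrow(X), cfg$max_windows)
      X <- X[pick, , drop = FALSE]; y <- y[pick]
    }
    n_val <- max(1L, round(cfg$val_fraction * nrow(X)))
    vi <- sample.int(nrow(X), n_val)
    Xv <- X[vi, , drop = FALSE]; yv <- y[vi]
    Xt <- X[-vi, , drop = FALSE]; yt <- y[-vi]
    params <- gru_params_new_(cfg$hidden_units)
    opt <- adam_new_(params)
    best <- list(params = params, val = Inf, epoch = 0L)
    history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                          val_mse = numeric(0))
    wait <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(nrow(Xt))
      ep_loss <- 0
      for (b0 in seq(1L, nrow(Xt), by = cfg$batch)) {
        rows <- ord[b0:min(b0 + cfg$batch - 1L, nrow(Xt))]
        fwd <- gru_forward_(params, Xt[rows, , drop = FALSE])
        err <- fwd$y - yt[rows]
        ep_loss <- ep_loss + sum(err^2)
        grads <- clip_grads_(gru_backward_(params, fwd, 2 * err / length(err)))
        st <- adam_step_(opt, params, grads, cfg$step_size)
        opt <- st$opt; params <- st$params
      }
      val_mse <- mean((gru_forward_(params, Xv, keep_cache = FALSE)$y - yv)^2)
      history <- rbind(history, data.frame(epoch = ep,
                                           train_mse = ep_loss / nrow(Xt),
                                           val_mse = val_mse))
      if (val_mse < best$val) {
        best <- list(params = params, val = val_mse, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    structure(list(params = best$params, cfg = cfg, mu = stats$mu,
                   sd = stats$sd, heldout_mse = best$val,
                   best_epoch = best$epoch, history = history),
              class = "gated_init_model")
  })
}

#' @export
print.gated_init_model <- function(x, ...) {
  cat(sprintf("<gated_init_model> %d units, window %d, best epoch %d, held-out MSE %.4g (normalized)\n",
              x$cfg$hidden_units, x$cfg$window, x$best_epoch, x$heldout_mse))
  invisible(x)
}

#' One-step-ahead prediction from raw-unit windows
#'
#' @param model a `gated_init_model`.
#' @param windows `B x window` matrix of raw-pixel input windows.
#' @param coord_idx integer vector (length B) of coordinate indices 1..34
#'   selecting the normalization statistics per row.
#' @return length-B vector of predicted next values, in pixels.
#' @export
predict_next <- function(model, windows, coord_idx) {
  UseMethod("predict_next")
}

#' @rdname predict_next
#' @export
predict_next.gated_init_model <- function(model, windows, coord_idx) {
  windows <- matrix(windows, ncol = model$cfg$window)
  anchor <- windows[, model$cfg$window]
  Xn <- (windows - anchor) / model$sd[coord_idx]
  yn <- gru_forward_(model$params, Xn, keep_cache = FALSE)$y
  yn * model$sd[coord_idx] + anchor
}

#' Iteratively reconstruct missing coordinates
#'
#' Scans frames in time order; every coordinate of every invisible keypoint
#' is predicted from the previous `window` values (observed or previously
#' reconstructed) and written back, so later predictions consume earlier
#' reconstructions. Observed values are never altered. Reconstructed entries
#' are recorded in an `imputed` mask on the returned sequence; their
#' visibility stays `FALSE`.
#'
#' @param model a `gated_init_model`.
#' @param seq a [gait_sequence].
#' @return a new [gait_sequence] with an `imputed` logical matrix element.
#' @export
iterative_reconstruct <- function(model, seq) {
  w <- model$cfg$window
  vis <- seq$visibility
  if (all(vis)) {
    seq$imputed <- matrix(FALSE, n_frames(seq), N_KEYPOINTS)
    return(seq)
  }
  first_missing <- apply(vis, 2, function(v) if (all(v)) NA_integer_ else which(!v)[1])
  bad <- which(!is.na(first_missing) & first_missing <= w)
  if (length(bad)) {
    stop(sprintf("fewer than %d visible leading frames for keypoint %d (first missing frame %d)",
                 w, bad[1] - 1L, first_missing[bad[1]]), call. = FALSE)
  }
  co <- seq$coords
  frames <- n_frames(seq)
  for (t in seq_len(frames)) {
    miss_k <- which(!vis[t, ])
    if (!length(miss_k)) next
    ks <- rep(miss_k, each = 2L)
    as <- rep(1:2, times = length(miss_k))
    # window of working values per missing coordinate
    win <- t(vapply(seq_along(ks), function(i) co[(t - w):(t - 1L), ks[i], as[i]],
                    numeric(w)))
    pred <- predict_next(model, win, coord_index_(ks, as))
    co[cbind(t, ks, as)] <- pred
  }
  out <- gait_sequence(co, subject_id = seq$subject_id, label = seq$label,
                       scores = seq$scores, visibility = vis)
  out$imputed <- !vis
  out
}

#' Initial filter state and covariance from the gated model
#'
#' For each keypoint, the initial state is `[x, y, vx, vy]` where `(x, y)`
#' is the model's one-step prediction at the first missing frame `t0` and
#' `(vx, vy)` the finite difference between that prediction and the last
#' available position. The initial covariance is diagonal: position variance
#' equal to the model's held-out one-step MSE mapped back to pixel units via
#' the per-coordinate scale, velocity variance twice that.
#'
#' @param model a `gated_init_model`.
#' @param seq a [gait_sequence] whose frames `1 .. t0-1` are available for
#'   the keypoint.
#' @param t0 first missing frame index (1-based); must exceed
#'   `window + 1`.
#' @return list over the 17 keypoints of `list(x, P)` state/covariance pairs.
#' @export
initial_state <- function(model, seq, t0) {
  w <- model$cfg$window
  if (t0 < w + 2L) stop("t0 must be at least window + 2", call. = FALSE)
  lapply(seq_len(N_KEYPOINTS), function(k) {
    win <- t(vapply(1:2, function(a) seq$coords[(t0 - w):(t0 - 1L), k, a],
                    numeric(w)))
    pred <- predict_next(model, win, coord_index_(k, 1:2))
    last <- seq$coords[t0 - 1L, k, ]
    pos_var <- model$heldout_mse * model$sd[coord_index_(k, 1:2)]^2
    pos_var <- pmax(pos_var, 1e-6)
    list(x = c(pred, pred - last),
         P = diag(c(pos_var, 2 * pos_var)))
  })
}
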