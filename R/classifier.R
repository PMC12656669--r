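#' @title PD / Healthy sequence classifier
#' @description
#' A stacked-LSTM binary classifier over whole gait records: a 128-unit LSTM
#' layer, dropout 0.2, a 64-unit LSTM layer, a 32-unit rectified dense layer,
#' dropout 0.2, and a single sigmoid output unit. By default the flattened
#' 1700-value record is fed as one time step of 1700 features; an alternative
#' shaping of 50 steps x 34 features is available. Training uses Adam on
#' binary cross-entropy with early stopping on a validation split and
#' best-epoch checkpointing. The classifier is trained on complete sequences
#' and evaluated on occluded or recovered ones.
#' @name classifier
NULL

#' Classifier configuration
#'
#' @param step_size Adam learning rate, in \[0.00005, 0.001\]
#'   (default 0.0005, the midpoint of that range).
#' @param epochs maximum epochs (at most 50).
#' @param batch mini-batch size.
#' @param patience early-stopping patience on validation loss, epochs.
#' @param val_fraction fraction of the training set used for validation.
#' @param dropout dropout rate for both dropout layers.
#' @param input_shape `"flat"` (one step of frames*34 features, default) or
#'   `"frames"` (frames steps of 34 features).
#' @param activation cell/output activation of the LSTM layers (`"relu"`,
#'   per the architecture; `"tanh"` available).
#' @param units hidden sizes of the two LSTM layers and the dense layer.
#' @param threshold decision threshold; PD iff probability strictly exceeds it.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(step_size = 5e-4, epochs = 50L, batch = 32L,
                              patience = 5L, val_fraction = 0.15,
                              dropout = 0.2,
                              input_shape = c("flat", "frames"),
                              activation = c("relu", "tanh"),
                              units = c(128L, 64L, 32L),
                              threshold = 0.5, seed = 1L) {
  stopifnot(step_size >= 5e-5, step_size <= 1e-3, epochs >= 1L, epochs <= 50L,
            dropout >= 0, dropout < 1, patience >= 1L)
  structure(list(step_size = step_size, epochs = as.integer(epochs),
                 batch = as.integer(batch), patience = as.integer(patience),
                 val_fraction = val_fraction, dropout = dropout,
                 input_shape = match.arg(input_shape),
                 activation = match.arg(activation),
                 units = as.integer(units), threshold = threshold,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Stratified train/test split with an augmentation-leakage guard
#'
#' Splits by *base subject* (the `base_id` attribute attached by
#' [make_dataset], falling back to `subject_id`), stratified by class, so
#' that augmented variants of one subject never straddle the split.
#'
#' @param seqs list of [gait_sequence] objects.
#' @param fractions `c(train, test)` fractions summing to 1; the test
#'   fraction must be positive.
#' @param seed RNG seed.
#' @return `list(train = ..., test = ...)` of sequence lists.
#' @export
split_dataset <- function(seqs, fractions = c(0.7, 0.3), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  if (fractions[2] <= 0) stop("test fraction must be positive", call. = FALSE)
  base <- vapply(seqs, function(s) attr(s, "base_id") %||% s$subject_id, "")
  label <- vapply(seqs, `[[`, "", "label")
  classes <- unique(label)
  if (length(classes) < 2L) stop("both classes must be present", call. = FALSE)
  test_base <- character(0)
  with_seed(seed, {
    for (cl in classes) {
      bases <- unique(base[label == cl])
      if (length(bases) < 2L) {
        stop("class ", cl, " has fewer than 2 base subjects", call. = FALSE)
      }
      n_test <- max(1L, round(fractions[2] * length(bases)))
      test_base <- c(test_base, sample(bases, n_test))
    }
  })
  list(train = seqs[!base %in% test_base],
       test = seqs[base %in% test_base])
}

# sequences -> list over time steps of B x D matrices, plus labels
clf_inputs_ <- function(seqs, cfg, mu = NULL, sd = NULL) {
  X <- do.call(rbind, lapply(seqs, flatten_record))
  if (is.null(mu)) {
    mu <- colMeans(X)
    sd <- pmax(apply(X, 2, stats::sd), 1e-6)
  }
  Xn <- sweep(sweep(X, 2, mu), 2, sd, "/")
  Xs <- if (cfg$input_shape == "flat") {
    list(Xn)
  } else {
    frames <- ncol(Xn) %/% VALUES_PER_FRAME
    lapply(seq_len(frames), function(t) {
      Xn[, (t - 1L) * VALUES_PER_FRAME + seq_len(VALUES_PER_FRAME),
         drop = FALSE]
    })
  }
  list(Xs = Xs, mu = mu, sd = sd,
       y = as.numeric(vapply(seqs, `[[`, "", "label") == "PD"))
}

clf_forward_ <- function(params, Xs, cfg, masks = NULL, keep_cache = FALSE) {
  act <- cfg$activation
  l1 <- lstm_forward_(params$l1, Xs, act, keep_cache = keep_cache)
  h1 <- l1$hs
  if (!is.null(masks)) h1 <- Map(`*`, h1, masks$m1)
  l2 <- lstm_forward_(params$l2, h1, act, keep_cache = keep_cache)
  h2 <- l2$hs[[length(l2$hs)]]
  a1 <- addb_(h2 %*% params$d1$W, params$d1$b[1, ])
  d1 <- pmax(a1, 0)
  d1d <- if (!is.null(masks)) d1 * masks$m2 else d1
  p <- sigmoid_(addb_(d1d %*% params$d2$W, params$d2$b[1, ]))
  list(p = drop(p), l1 = l1, l2 = l2, h1drop = h1, h2 = h2, a1 = a1,
       d1drop = d1d)
}

clf_backward_ <- function(params, fwd, Xs, y, cfg, masks) {
  B <- length(y)
  dz <- matrix((fwd$p - y) / B, B, 1)        # sigmoid + BCE
  g <- list()
  g[["d2.W"]] <- t(fwd$d1drop) %*% dz
  g[["d2.b"]] <- matrix(colSums(dz), 1)
  dd1 <- (dz %*% t(params$d2$W)) * masks$m2 * (fwd$a1 > 0)
  g[["d1.W"]] <- t(fwd$h2) %*% dd1
  g[["d1.b"]] <- matrix(colSums(dd1), 1)
  dh2 <- dd1 %*% t(params$d1$W)
  Tn <- length(Xs)
  H2 <- ncol(params$l2$U) / 4L
  dhs2 <- lapply(seq_len(Tn), function(t) matrix(0, B, H2))
  dhs2[[Tn]] <- dh2
  b2 <- lstm_backward_(params$l2, fwd$l2, dhs2, cfg$activation)
  g[["l2.W"]] <- b2$grads$W; g[["l2.U"]] <- b2$grads$U; g[["l2.b"]] <- b2$grads$b
  dh1 <- Map(`*`, b2$dXs, masks$m1)
  b1 <- lstm_backward_(params$l1, fwd$l1, dh1, cfg$activation)
  g[["l1.W"]] <- b1$grads$W; g[["l1.U"]] <- b1$grads$U; g[["l1.b"]] <- b1$grads$b
  g
}

clf_params_flat_ <- function(params) {
  list(`l1.W` = params$l1$W, `l1.U` = params$l1$U, `l1.b` = params$l1$b,
       `l2.W` = params$l2$W, `l2.U` = params$l2$U, `l2.b` = params$l2$b,
       `d1.W` = params$d1$W, `d1.b` = params$d1$b,
       `d2.W` = params$d2$W, `d2.b` = params$d2$b)
}

clf_params_nest_ <- function(flat) {
  list(l1 = list(W = flat$`l1.W`, U = flat$`l1.U`, b = flat$`l1.b`),
       l2 = list(W = flat$`l2.W`, U = flat$`l2.U`, b = flat$`l2.b`),
       d1 = list(W = flat$`d1.W`, b = flat$`d1.b`),
       d2 = list(W = flat$`d2.W`, b = flat$`d2.b`))
}

bce_ <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the PD/Healthy classifier
#'
#' @param train_seqs list of complete [gait_sequence] objects with labels
#'   `"PD"` / `"HEALTHY"`.
#' @param cfg a [classifier_config].
#' @return a `gait_classifier`: best-epoch parameters, config, per-feature
#'   normalization statistics and the loss history.
#' @export
train_classifier <- function(train_seqs, cfg = classifier_config()) {
  if (length(train_seqs) < 2L) stop("need at least 2 training sequences", call. = FALSE)
  inp <- clf_inputs_(train_seqs, cfg)
  D <- ncol(inp$Xs[[1]])
  n <- length(inp$y)
  u <- cfg$units
  with_seed(cfg$seed, {
    vi <- sample.int(n, max(1L, round(cfg$val_fraction * n)))
    Xs_val <- lapply(inp$Xs, function(M) M[vi, , drop = FALSE])
    y_val <- inp$y[vi]
    Xs_tr <- lapply(inp$Xs, function(M) M[-vi, , drop = FALSE])
    y_tr <- inp$y[-vi]
    nt <- length(y_tr)
    params <- list(l1 = lstm_params_new_(D, u[1]),
                   l2 = lstm_params_new_(u[1], u[2]),
                   d1 = dense_params_new_(u[2], u[3]),
                   d2 = dense_params_new_(u[3], 1L))
    flat <- clf_params_flat_(params)
    opt <- adam_new_(flat)
    best <- list(flat = flat, val = Inf, epoch = 0L)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    wait <- 0L
    Tn <- length(Xs_tr)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(nt)
      ep_loss <- 0
      for (b0 in seq(1L, nt, by = cfg$batch)) {
        rows <- ord[b0:min(b0 + cfg$batch - 1L, nt)]
        B <- length(rows)
        Xb <- lapply(Xs_tr, function(M) M[rows, , drop = FALSE])
        masks <- list(
          m1 = lapply(seq_len(Tn), function(t) dropout_mask_(B, u[1], cfg$dropout)),
          m2 = dropout_mask_(B, u[3], cfg$dropout)
        )
        params <- clf_params_nest_(flat)
        fwd <- clf_forward_(params, Xb, cfg, masks, keep_cache = TRUE)
        if (any(!is.finite(fwd$p))) stop("non-finite training loss", call. = FALSE)
        ep_loss <- ep_loss + bce_(fwd$p, y_tr[rows]) * B
        grads <- clip_grads_(clf_backward_(params, fwd, Xb, y_tr[rows], cfg, masks))
        st <- adam_step_(opt, flat, grads, cfg$step_size)
        opt <- st$opt; flat <- st$params
      }
      pv <- clf_forward_(clf_params_nest_(flat), Xs_val, cfg)$p
      val_loss <- bce_(pv, y_val)
      history <- rbind(history, data.frame(epoch = ep,
                                           train_loss = ep_loss / nt,
                                           val_loss = val_loss))
      if (val_loss < best$val) {
        best <- list(flat = flat, val = val_loss, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    structure(list(params = clf_params_nest_(best$flat), cfg = cfg,
                   mu = inp$mu, sd = inp$sd, best_epoch = best$epoch,
                   val_loss = best$val, history = history,
                   n_features = length(inp$mu)),
              class = "gait_classifier")
  })
}

#' @export
print.gait_classifier <- function(x, ...) {
  cat(sprintf("<gait_classifier> LSTM %d-%d + dense %d, input '%s', best epoch %d (val loss %.4f)\n",
              x$cfg$units[1], x$cfg$units[2], x$cfg$units[3],
              x$cfg$input_shape, x$best_epoch, x$val_loss))
  invisible(x)
}

#' Classify gait sequences
#'
#' @param object a trained `gait_classifier`.
#' @param seqs list of [gait_sequence] objects with the training frame count.
#' @param ... unused.
#' @return data.frame with `subject_id`, `prob` (probability of PD) and
#'   `label` (`"PD"` iff `prob` strictly exceeds the threshold, else
#'   `"HEALTHY"`).
#' @export
predict.gait_classifier <- function(object, seqs, ...) {
  lens <- vapply(seqs, function(s) length(flatten_record(s)), integer(1))
  if (any(lens != object$n_features)) {
    stop("frame-count mismatch: record length ", lens[lens != object$n_features][1],
         ", model expects ", object$n_features, call. = FALSE)
  }
  inp <- clf_inputs_(seqs, object$cfg, object$mu, object$sd)
  p <- clf_forward_(object$params, inp$Xs, object$cfg)$p
  data.frame(subject_id = vapply(seqs, `[[`, "", "subject_id"),
             prob = p,
             label = ifelse(p > object$cfg$threshold, "PD", "HEALTHY"),
             stringsAsFactors = FALSE)
}
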