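# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small labeled training set of complete synthetic subjects
fixture_train_set <- function() {
  cached_fixture("train_set", make_dataset(6, 6, frames = 50, seed = 11))
}

# the 50-unit gated initialization network trained on the fixture set
fixture_init_model <- function() {
  cached_fixture("init_model",
                 train_gated_init(fixture_train_set(),
                                  gated_init_config(hidden_units = 50L,
                                                    seed = 7)))
}

# 20 held-out evaluation subjects, alternating classes
fixture_eval_subjects <- function() {
  cached_fixture("eval_subjects", lapply(1:20, function(i) {
    lab <- if (i %% 2) "PD" else "HEALTHY"
    generate_subject(gait_profile(lab), frames = 50, seed = 500 + i)
  }))
}

# a deterministic noiseless constant-velocity gait sequence: every keypoint
# moves linearly; useful for exact-recovery checks
cv_sequence <- function(frames = 50) {
  co <- array(0, dim = c(frames, 17, 2))
  for (k in 1:17) {
    co[, k, 1] <- 100 + 3 * k + (1 + 0.1 * k) * (seq_len(frames) - 1)
    co[, k, 2] <- 200 + 2 * k + (0.5 + 0.05 * k) * (seq_len(frames) - 1)
  }
  gait_sequence(co, subject_id = "cv", label = "UNKNOWN")
}

# an analytic "perfect" predictor for pure sinusoid-plus-drift series: fits
# the next value by linear extrapolation of an AR model known in closed form
# is unnecessary -- tests instead register this oracle that knows the true
# generating function of the series it is used on.
make_oracle_model <- function(fun, window = 5L) {
  structure(list(fun = fun,
                 cfg = list(window = window),
                 sd = rep(1, 34), mu = rep(0, 34),
                 heldout_mse = 1e-6),
            class = c("oracle_model", "gated_init_model"))
}

predict_next.oracle_model <- function(model, windows, coord_idx) {
  windows <- matrix(windows, ncol = model$cfg$window)
  model$fun(windows, coord_idx)
}
registerS3method("predict_next", "oracle_model", predict_next.oracle_model,
                 envir = asNamespace("recovgait"))
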