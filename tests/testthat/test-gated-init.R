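test_that("sliding windows enumerate pairs and skip sentinels", {
  pw <- make_windows(1:50, window = 5)
  expect_equal(nrow(pw$inputs), 45)
  expect_equal(pw$inputs[1, ], 1:5)
  expect_equal(pw$targets[1], 6)
  one <- make_windows(c(1, 2, 3, 4, 5, 6), window = 5)
  expect_equal(nrow(one$inputs), 1)
  expect_equal(one$targets, 6)
  expect_warning(short <- make_windows(1:4, window = 5), "no training pairs")
  expect_equal(nrow(short$inputs), 0)
  # sentinel at frame 20: brute-force the excluded pair count
  ser <- as.numeric(1:50); ser[20] <- 0
  pw2 <- make_windows(ser, window = 5)
  excluded <- sum(vapply(1:45, function(t) any(ser[t:(t + 5)] == 0), logical(1)))
  expect_equal(excluded, 6)
  expect_equal(nrow(pw2$inputs), 45 - excluded)
})

test_that("GRU gradients match finite differences", {
  ns <- asNamespace("recovgait")
  set.seed(31)
  p <- ns$gru_params_new_(6)
  X <- matrix(rnorm(20), 4, 5)
  y <- rnorm(4)
  fwd <- ns$gru_forward_(p, X)
  g <- ns$gru_backward_(p, fwd, 2 * (fwd$y - y) / 4)
  loss <- function(pp) mean((ns$gru_forward_(pp, X, keep_cache = FALSE)$y - y)^2)
  eps <- 1e-6
  for (nm in names(p)) {
    i <- sample(length(p[[nm]]), 1)
    pp <- p
    pp[[nm]][i] <- pp[[nm]][i] + eps; up <- loss(pp)
    pp[[nm]][i] <- pp[[nm]][i] - 2 * eps; dn <- loss(pp)
    expect_equal(g[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-5,
                 label = paste("grad", nm))
  }
})

test_that("training fits constant and sinusoidal series, reproducibly", {
  const_seq <- function(val) {
    gait_sequence(array(val, dim = c(30, 17, 2)), label = "HEALTHY")
  }
  cfg <- gated_init_config(hidden_units = 30L, epochs = 10L, seed = 2,
                           max_windows = 1000L)
  m <- train_gated_init(list(const_seq(120), const_seq(80)), cfg)
  pred <- predict_next(m, matrix(100, 1, 5), 1L)
  expect_equal(pred, 100, tolerance = 0.01)

  sin_seq <- function(phase, amp, freq) {
    t <- 0:29
    co <- array(200, dim = c(30, 17, 2))
    for (k in 1:17) co[, k, 1] <- 300 + amp * sin(2 * pi * freq * t + phase + k)
    gait_sequence(co, label = "HEALTHY")
  }
  train <- lapply(seq(0, 2, by = 0.25), sin_seq, amp = 20, freq = 0.08)
  m2 <- train_gated_init(train, gated_init_config(hidden_units = 30L,
                                                  epochs = 30L, seed = 3))
  held <- sin_seq(2.6, 20, 0.08)
  pw <- make_windows(held$coords[, 4, 1], 5)
  pred <- predict_next(m2, pw$inputs, rep(7L, length(pw$targets)))
  rel <- abs(pred - pw$targets) / abs(pw$targets)
  expect_lt(mean(rel), 0.05)
  # training loss decreases from the first epoch to the best epoch
  expect_lt(min(m2$history$train_mse), m2$history$train_mse[1])

  # seeded reproducibility of the whole fit
  m3 <- train_gated_init(train, gated_init_config(hidden_units = 30L,
                                                  epochs = 30L, seed = 3))
  expect_identical(m2$heldout_mse, m3$heldout_mse)
  expect_identical(m2$params, m3$params)
  expect_error(train_gated_init(list()), "empty")
})

test_that("iterative reconstruction fills gaps without touching observations", {
  m <- fixture_init_model()
  s <- fixture_eval_subjects()[[2]]
  expect_identical(iterative_reconstruct(m, s)$coords, s$coords)
  occ <- simulate_missing(s, "LEGS", missing_frames = 40)
  rec <- iterative_reconstruct(m, occ)
  expect_equal(sum(rec$coords == 0), 0)
  expect_identical(rec$coords[occ$visibility[, 14], 14, ],
                   occ$coords[occ$visibility[, 14], 14, ])
  expect_true(all(rec$imputed[11:50, 14:17]))
  expect_false(any(rec$imputed[, 1:13]))
  # a single missing frame at the end is one one-step prediction
  last <- simulate_missing(s, occlusion_spec("HEAD", range = c(50, 50)))
  rec1 <- iterative_reconstruct(m, last)
  manual <- predict_next(m, matrix(last$coords[45:49, 1, 1], 1), 1L)
  expect_equal(rec1$coords[50, 1, 1], manual)
  # too-early occlusion violates the leading-window precondition
  early <- simulate_missing(s, occlusion_spec("HEAD", range = c(3, 10)))
  expect_error(iterative_reconstruct(m, early), "visible leading frames")
})

test_that("a perfect oracle recovers a noiseless suffix almost exactly", {
  p <- gait_profile("HEALTHY", jitter_sd = 0)
  s <- generate_subject(p, frames = 50, seed = 6)
  occ <- simulate_missing(s, "LEGS", missing_frames = 40)
  # oracle: knows the closed-form next value of sinusoid+drift series via
  # an exact linear recurrence fitted on the true window (5 points determine
  # offset+drift+sin for known cadence)
  t <- 0:49
  oracle <- make_oracle_model(function(win, idx) {
    vapply(seq_len(nrow(win)), function(r) {
      w <- win[r, ]
      tt <- seq_along(w)
      fit <- stats::lm(w ~ tt + sin(2 * pi * p$cadence * tt) +
                         cos(2 * pi * p$cadence * tt))
      drop(stats::predict(fit, newdata = data.frame(tt = 6)))
    }, numeric(1))
  })
  rec <- iterative_reconstruct(oracle, occ)
  em <- error_metrics(s, rec, scope = "missing")
  expect_lt(em$mape, 1)
})

test_that("initial state and covariance are well-formed", {
  m <- fixture_init_model()
  s <- fixture_eval_subjects()[[1]]
  st <- initial_state(m, s, t0 = 11)
  expect_length(st, 17)
  for (k in c(1, 9, 16)) {
    expect_length(st[[k]]$x, 4)
    ev <- eigen(st[[k]]$P, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
  # constant series: velocity components vanish
  const <- gait_sequence(array(150, dim = c(20, 17, 2)))
  cm <- make_oracle_model(function(win, idx) win[, 5])
  stc <- initial_state(cm, const, t0 = 10)
  expect_equal(stc[[5]]$x, c(150, 150, 0, 0))
  # linear ramp with a perfect extrapolating model: velocity equals the slope
  ramp <- gait_sequence(array(rep(10 + 3 * (0:19), 34), dim = c(20, 17, 2)))
  rm_ <- make_oracle_model(function(win, idx) 2 * win[, 5] - win[, 4])
  str_ <- initial_state(rm_, ramp, t0 = 10)
  expect_equal(str_[[1]]$x[3:4], c(3, 3))
  expect_error(initial_state(m, s, t0 = 4), "window")
})
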