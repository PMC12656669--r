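# independent linear Kalman filter oracle used by the equivalence tests
kf_step <- function(x, P, z, F, H, Q, R) {
  x <- drop(F %*% x); P <- F %*% P %*% t(F) + Q
  S <- H %*% P %*% t(H) + R
  K <- P %*% t(H) %*% solve(S)
  x <- x + drop(K %*% (z - drop(H %*% x)))
  P <- P - K %*% S %*% t(K)
  list(x = x, P = P)
}

cv_mats <- function(dt = 1) {
  list(F = matrix(c(1, 0, 0, 0, 0, 1, 0, 0, dt, 0, 1, 0, 0, dt, 0, 1), 4, 4),
       H = matrix(c(1, 0, 0, 1, 0, 0, 0, 0), 2, 4))
}

test_that("unscented-transform weights follow the scaled construction", {
  w <- ut_weights(2, alpha = 1, beta = 0, kappa = 1)
  expect_equal(w$lambda, 1)
  expect_equal(w$Wm[1], 1 / 3)
  expect_equal(w$Wm[2], 1 / 6)
  expect_equal(sum(w$Wm), 1)
  expect_equal(w$Wc[1], w$Wm[1])   # alpha = 1, beta = 0 collapses Wc0 to Wm0
  w2 <- ut_weights(4, alpha = 1e-3, beta = 2, kappa = 0)
  expect_equal(sum(w2$Wm), 1)
  expect_equal(w2$Wc[1], w2$Wm[1] + 1 - 1e-6 + 2)
  expect_error(ut_weights(2, alpha = 1, kappa = -2), "positive")
  expect_error(ut_weights(2, alpha = 0))
})

test_that("sigma points match the closed form and reconstruct moments", {
  p1 <- ukf_params(n = 1, alpha = 1, kappa = 2, R = diag(1, 1))
  sp <- sigma_points(0, matrix(1), p1)
  expect_equal(drop(sp), c(0, sqrt(3), -sqrt(3)))
  set.seed(55)
  for (n in c(2, 4, 8)) {
    A <- matrix(rnorm(n * n), n)
    P <- A %*% t(A) + diag(0.5, n)
    x <- rnorm(n)
    for (alpha in c(1e-3, 1)) {
      pp <- ukf_params(n = n, alpha = alpha, kappa = 3 - n, R = diag(1, 2))
      X <- sigma_points(x, P, pp)
      xr <- drop(X %*% pp$Wm)
      D <- X - xr
      Pr <- D %*% (pp$Wc * t(D))
      expect_equal(xr, x, tolerance = 1e-9)
      expect_lt(max(abs(Pr - P)), 1e-10)
    }
  }
})

test_that("prediction reduces to the closed linear form", {
  params <- ukf_params()
  # identity transition with zero process noise is a fixed point
  p0 <- ukf_params(Q = matrix(0, 4, 4))
  st <- list(x = c(5, 6, 1, 2), P = diag(c(4, 3, 2, 1)))
  pr <- ukf_predict(st, identity, p0)
  expect_equal(pr$x, st$x)
  expect_equal(pr$P, st$P, tolerance = 1e-9)
  # constant-velocity propagation of the mean
  m <- cv_mats()
  f <- function(x) drop(m$F %*% x)
  pr2 <- ukf_predict(list(x = c(0, 0, 1, 2), P = diag(1, 4)), f, params)
  expect_equal(pr2$x[1:2], c(1, 2), tolerance = 1e-9)
  # linear f: covariance equals F P F^T + Q
  set.seed(66)
  A <- matrix(rnorm(16), 4); P <- A %*% t(A) + diag(0.1, 4)
  st3 <- list(x = rnorm(4), P = P)
  pr3 <- ukf_predict(st3, f, params)
  expect_lt(max(abs(pr3$P - (m$F %*% P %*% t(m$F) + params$Q))), 1e-9)
  expect_error(ukf_predict(st3, function(x) x * NA, params), "non-finite")
})

test_that("update honours the innovation and measurement-noise limits", {
  params <- ukf_params()
  m <- cv_mats()
  h <- function(x) drop(m$H %*% x)
  st <- list(x = c(10, 20, 1, -1), P = diag(2, 4))
  pr <- ukf_predict(st, function(x) drop(m$F %*% x), params)
  # zero innovation leaves the mean unchanged
  post <- ukf_update(pr, pr$x[1:2], h, params)
  expect_equal(post$x, pr$x, tolerance = 1e-9)
  # vanishing R drives the measured components onto the measurement
  tiny <- ukf_params(R = diag(1e-12, 2), Q = params$Q)
  post2 <- ukf_update(pr, c(42, 17), h, tiny)
  expect_equal(post2$x[1:2], c(42, 17), tolerance = 1e-5)
  # conditioning never inflates total uncertainty (linear case)
  expect_lte(sum(diag(post$P)), sum(diag(pr$P)) + 1e-12)
  expect_error(ukf_update(pr, c(NA, 1), h, params), "non-finite")
})

test_that("the UKF matches a textbook Kalman filter on a linear system", {
  params <- ukf_params()
  m <- cv_mats()
  f <- function(x) drop(m$F %*% x)
  h <- function(x) drop(m$H %*% x)
  set.seed(5)
  x_kf <- c(0, 0, 1, 2); P_kf <- diag(10, 4)
  st <- list(x = x_kf, P = P_kf)
  maxd <- 0
  for (t in 1:50) {
    z <- c(t, 2 * t) + rnorm(2, 0, 2)
    kf <- kf_step(x_kf, P_kf, z, m$F, m$H, params$Q, params$R)
    x_kf <- kf$x; P_kf <- kf$P
    st <- ukf_update(ukf_predict(st, f, params), z, h, params)
    maxd <- max(maxd, abs(st$x - x_kf), abs(st$P - P_kf))
  }
  expect_lt(maxd, 1e-8)
})

test_that("filtering a noisy constant-velocity track beats raw measurements", {
  params <- ukf_params(sigma_q = 0.05, sigma_r = 3)
  m <- cv_mats()
  f <- function(x) drop(m$F %*% x)
  h <- function(x) drop(m$H %*% x)
  sigma <- 3
  wins <- 0L
  for (run in 1:100) {
    set.seed(300 + run)
    truth <- cbind(10 + 1.5 * (0:29), 20 - 0.8 * (0:29))
    zs <- truth + matrix(rnorm(60, 0, sigma), ncol = 2)
    st <- list(x = c(truth[1, ], 1.5, -0.8), P = diag(c(9, 9, 1, 1)))
    est <- matrix(NA, 30, 2)
    est[1, ] <- st$x[1:2]
    for (t in 2:30) {
      st <- ukf_update(ukf_predict(st, f, params), zs[t, ], h, params)
      est[t, ] <- st$x[1:2]
    }
    if (sqrt(mean((est - truth)^2)) < sqrt(mean((zs - truth)^2))) wins <- wins + 1L
  }
  expect_gte(wins / 100, 0.95)
})

test_that("the engine handles a genuinely non-linear transition", {
  # sinusoidal acceleration: x'' = -omega^2 sin-coupled position term
  omega <- 0.4
  f <- function(x) c(x[1] + x[3], x[2] + x[4],
                     x[3] - omega^2 * sin(x[1] / 10), x[4])
  h <- function(x) x[1:2]
  params <- ukf_params(sigma_q = 0.1, sigma_r = 1)
  st <- list(x = c(1, 1, 0.5, 0.2), P = diag(1, 4))
  set.seed(77)
  for (t in 1:20) {
    st <- ukf_update(ukf_predict(st, f, params), c(t / 2, t / 3) + rnorm(2, 0, 1),
                     h, params)
  }
  expect_true(all(is.finite(st$x)))
  expect_true(all(eigen(st$P, symmetric = TRUE, only.values = TRUE)$values >= -1e-9))
})

test_that("sequence recovery is exact on noiseless linear motion", {
  s <- cv_sequence(50)
  occ <- simulate_missing(s, "HIPS", missing_frames = 10)
  rec <- recover_sequence(occ, params = ukf_params(), method = "ukf")
  expect_lt(max(abs(rec$coords - s$coords)), 1e-6)
  # untouched when nothing is missing
  expect_identical(recover_sequence(s, method = "ukf")$coords, s$coords)
  expect_identical(recover_sequence(occ, method = "none")$coords, occ$coords)
})

test_that("recovery never alters observed coordinates", {
  m <- fixture_init_model()
  s <- fixture_eval_subjects()[[3]]
  occ <- simulate_missing(s, "LEGS", missing_frames = 40)
  for (method in c("ukf", "gated", "recovgait")) {
    rec <- recover_sequence(occ, m, ukf_params(), method = method)
    expect_identical(rec$coords[1:10, , ], s$coords[1:10, , ])
    expect_identical(rec$coords[, 1:13, ], s$coords[, 1:13, ])
    expect_equal(sum(rec$coords == 0), 0)
  }
})

test_that("recovery arms are ordered on a leg-occluded synthetic cohort", {
  m <- fixture_init_model()
  subjects <- fixture_eval_subjects()[1:8]
  mape <- sapply(c("none", "ukf", "gated", "recovgait"), function(tech) {
    stats::median(sapply(subjects, function(s) {
      occ <- simulate_missing(s, "LEGS", missing_frames = 40)
      error_metrics(s, recover_sequence(occ, m, ukf_params(),
                                        method = tech))$mape
    }))
  })
  expect_lt(mape[["recovgait"]], mape[["none"]])
  expect_lt(mape[["gated"]], mape[["none"]])
  expect_lt(mape[["ukf"]], mape[["none"]])
})
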