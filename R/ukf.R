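#' @title Unscented Kalman Filter
#' @description
#' A from-scratch Unscented Kalman Filter with the scaled unscented
#' transform: 2n+1 sigma points are generated from the state mean and
#' covariance, propagated through the (possibly non-linear) state transition
#' and measurement functions, and recombined by weighted moments to give the
#' predicted state, innovation covariance, cross covariance, Kalman gain and
#' posterior. The gait application instantiates one 4-state filter per
#' keypoint (`[x, y, vx, vy]`, constant-velocity transition with a 1-frame
#' step), but the engine is generic over `f`, `h` and dimensions.
#' @name ukf
NULL

#' Scaled unscented-transform weights
#'
#' With scaling `lambda = alpha^2 (n + kappa) - n`:
#' `Wm[0] = lambda/(n+lambda)`, `Wc[0] = Wm[0] + 1 - alpha^2 + beta`, and
#' `Wm[i] = Wc[i] = 1/(2(n+lambda))` for the remaining 2n points.
#'
#' @param n state dimension.
#' @param alpha spread parameter in (0, 1].
#' @param beta prior-distribution parameter (2 is optimal for Gaussians).
#' @param kappa secondary scaling parameter.
#' @return list with `Wm`, `Wc` (length 2n+1) and `lambda`.
#' @export
ut_weights <- function(n, alpha = 1e-3, beta = 2, kappa = 0) {
  stopifnot(alpha > 0, alpha <= 1, n >= 1)
  lambda <- alpha^2 * (n + kappa) - n
  if (n + lambda <= 0) stop("n + lambda must be positive", call. = FALSE)
  Wm <- c(lambda / (n + lambda), rep(1 / (2 * (n + lambda)), 2 * n))
  Wc <- Wm
  Wc[1] <- Wm[1] + 1 - alpha^2 + beta
  list(Wm = Wm, Wc = Wc, lambda = lambda)
}

#' Unscented-filter parameter set
#'
#' @param n state dimension (4 for the per-keypoint gait filter).
#' @param alpha,beta,kappa unscented-transform parameters (see [ut_weights]).
#' @param Q process-noise covariance. Default: discrete white-noise
#'   acceleration blocks per axis with spectral strength `sigma_q^2`.
#' @param R measurement-noise covariance. Default `sigma_r^2 * I_2`.
#' @param sigma_q process-noise scale, pixels/frame^2 (default 0.5).
#' @param sigma_r measurement-noise scale, pixels (default 2).
#' @param r_pseudo_scale multiplier applied to `R` when fusing a
#'   model-generated pseudo-measurement instead of a real observation
#'   (default 10).
#' @param dt time step, frames.
#' @return a `ukf_params` list including the precomputed weights.
#' @export
ukf_params <- function(n = 4L, alpha = 1e-3, beta = 2, kappa = 0,
                       Q = NULL, R = NULL, sigma_q = 0.5, sigma_r = 2,
                       r_pseudo_scale = 10, dt = 1) {
  w <- ut_weights(n, alpha, beta, kappa)
  if (is.null(Q)) {
    # white-noise-acceleration block for one axis, states (pos, vel)
    blk <- sigma_q^2 * matrix(c(dt^4 / 4, dt^3 / 2, dt^3 / 2, dt^2), 2, 2)
    Q <- matrix(0, 4, 4)
    Q[c(1, 3), c(1, 3)] <- blk   # x, vx
    Q[c(2, 4), c(2, 4)] <- blk   # y, vy
    if (n != 4L) Q <- diag(sigma_q^2, n)
  }
  if (is.null(R)) R <- diag(sigma_r^2, 2)
  structure(list(n = as.integer(n), alpha = alpha, beta = beta, kappa = kappa,
                 lambda = w$lambda, Wm = w$Wm, Wc = w$Wc, Q = Q, R = R,
                 r_pseudo_scale = r_pseudo_scale, dt = dt),
            class = "ukf_params")
}

symmetrize_ <- function(P) (P + t(P)) / 2

# Cholesky factor of A with an escalating diagonal jitter ladder
chol_jitter_ <- function(A) {
  jitters <- c(0, 10^seq(-12, -6))
  scale <- mean(diag(A))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  for (j in jitters) {
    L <- tryCatch(t(chol(A + diag(j * scale, nrow(A)))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop(sprintf("covariance not positive definite (smallest eigenvalue %.3g)",
               min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)),
       call. = FALSE)
}

#' Generate sigma points
#'
#' Point 0 is the mean `x`; points `1..n` add the columns of the Cholesky
#' factor of `(n + lambda) P`; points `n+1..2n` subtract them.
#'
#' @param x state mean (length n).
#' @param P state covariance (n x n).
#' @param params a [ukf_params].
#' @return `n x (2n+1)` matrix of sigma points (columns).
#' @export
sigma_points <- function(x, P, params) {
  n <- length(x)
  L <- chol_jitter_((n + params$lambda) * symmetrize_(P))
  cbind(x, x + L, x - L, deparse.level = 0)
}

#' UKF prediction step
#'
#' Propagates the sigma points through the state transition `f`, then
#' recombines: prior mean is the weighted sigma mean, prior covariance the
#' weighted outer-product sum plus `Q`.
#'
#' @param state list with `x` (mean) and `P` (covariance).
#' @param f state transition function (vector to vector).
#' @param params a [ukf_params].
#' @return prior `list(x, P)` (plus the propagated sigma points as `sigmas`).
#' @export
ukf_predict <- function(state, f, params) {
  X <- sigma_points(state$x, state$P, params)
  Xp <- apply(X, 2, f)
  if (is.null(dim(Xp))) Xp <- matrix(Xp, nrow = 1L)
  if (any(!is.finite(Xp))) stop("non-finite state after transition", call. = FALSE)
  xbar <- drop(Xp %*% params$Wm)
  D <- Xp - xbar
  P <- symmetrize_(D %*% (params$Wc * t(D)) + params$Q)
  list(x = xbar, P = P, sigmas = Xp)
}

#' UKF update step
#'
#' Maps the predicted sigma points through the measurement function `h`,
#' forms the innovation covariance `S` (with `R` scaled by `r_scale`), the
#' state-measurement cross covariance, the Kalman gain, and conditions the
#' prior on the measurement `z`. The posterior covariance is re-symmetrized
#' and eigenvalue-floored at zero.
#'
#' @param prior a `list(x, P)`, typically the output of [ukf_predict].
#' @param z measurement vector.
#' @param h measurement function.
#' @param params a [ukf_params].
#' @param r_scale measurement-noise multiplier (1 for real observations,
#'   `params$r_pseudo_scale` for pseudo-measurements).
#' @return posterior `list(x, P)`.
#' @export
ukf_update <- function(prior, z, h, params, r_scale = 1) {
  if (any(!is.finite(z))) stop("non-finite measurement", call. = FALSE)
  stopifnot(r_scale >= 1)
  # sigma points are redrawn from the prior so the innovation covariance
  # reflects the full predicted covariance including process noise
  Xp <- sigma_points(prior$x, prior$P, params)
  Z <- apply(Xp, 2, h)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  zbar <- drop(Z %*% params$Wm)
  Dz <- Z - zbar
  Dx <- Xp - prior$x
  S <- symmetrize_(Dz %*% (params$Wc * t(Dz)) + r_scale * params$R)
  Pxz <- Dx %*% (params$Wc * t(Dz))
  K <- tryCatch(t(solve(S, t(Pxz))), error = function(e) {
    warning("singular innovation covariance; using pseudo-inverse", call. = FALSE)
    Pxz %*% pinv_(S)
  })
  x <- prior$x + drop(K %*% (z - zbar))
  P <- symmetrize_(prior$P - K %*% S %*% t(K))
  ev <- eigen(P, symmetric = TRUE)
  if (min(ev$values) < 0) {
    P <- symmetrize_(ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors)))
  }
  list(x = x, P = P)
}

pinv_ <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# constant-velocity transition and position measurement for one keypoint
cv_transition_ <- function(dt = 1) {
  function(x) c(x[1] + dt * x[3], x[2] + dt * x[4], x[3], x[4])
}
position_measurement_ <- function(x) x[1:2]

#' Recover a sequence's missing keypoints
#'
#' The full recovery combination: per keypoint, a 4-state constant-velocity
#' UKF is initialized from the gated model at the first missing frame
#' ([initial_state]) and run to the end of the sequence. At each frame it
#' predicts, then updates — with the real observation (`r_scale = 1`) when
#' the keypoint is visible; when it is missing, the gated network's one-step
#' prediction from the previous window of observed-or-refined values serves
#' as a pseudo-measurement under inflated measurement noise
#' (`r_scale = params$r_pseudo_scale`), and the posterior position is
#' written back so the next window consumes the refined value. This coupling
#' damps the error compounding of a raw prediction chain: the filter's
#' motion prior smooths each imputation before it feeds the next. Missing
#' coordinates are replaced by the posterior positions; observed coordinates
#' pass through unchanged. Should a keypoint's filter produce a non-finite
#' posterior, that keypoint falls back to the gated-only reconstruction with
#' a warning.
#'
#' @param seq occluded [gait_sequence].
#' @param init_model a trained `gated_init_model`.
#' @param params a [ukf_params] (4-state).
#' @param method one of `"recovgait"` (default; UKF over gated
#'   pseudo-measurements), `"gated"` (gated-only imputation), `"ukf"`
#'   (UKF without the gated model: initialized from the last two observed
#'   frames with a large diagonal covariance, predict-only through missing
#'   frames) or `"none"` (zero-fill passthrough).
#' @return recovered [gait_sequence].
#' @export
recover_sequence <- function(seq, init_model = NULL,
                             params = ukf_params(),
                             method = c("recovgait", "gated", "ukf", "none")) {
  method <- match.arg(method)
  vis <- seq$visibility
  if (method == "none" || all(vis)) return(seq)
  if (method %in% c("recovgait", "gated")) {
    if (is.null(init_model)) stop("init_model required for method ", method,
                                  call. = FALSE)
    if (method == "gated") return(iterative_reconstruct(init_model, seq))
  }
  f <- cv_transition_(params$dt)
  h <- position_measurement_
  co <- seq$coords
  frames <- n_frames(seq)
  w <- if (method == "recovgait") init_model$cfg$window
  init_all <- NULL
  recon <- NULL   # gated-only fallback, computed lazily
  for (k in seq_len(N_KEYPOINTS)) {
    if (all(vis[, k])) next
    t0 <- which(!vis[, k])[1]
    state <- if (method == "recovgait") {
      if (is.null(init_all)) init_all <- initial_state(init_model, seq, t0)
      init_all[[k]]
    } else {
      if (t0 < 3L) {
        stop("need two observed frames before the first missing one",
             call. = FALSE)
      }
      p1 <- seq$coords[t0 - 1L, k, ]
      v1 <- p1 - seq$coords[t0 - 2L, k, ]
      list(x = c(p1 + v1, v1), P = diag(c(25, 25, 25, 25)))
    }
    track <- tryCatch({
      out <- matrix(NA_real_, frames, 2L)
      work <- co[, k, , drop = FALSE]
      st <- state
      for (t in t0:frames) {
        pr <- if (t > t0) ukf_predict(st, f, params) else st
        if (vis[t, k]) {
          st <- ukf_update(pr, seq$coords[t, k, ], h, params, r_scale = 1)
        } else if (method == "recovgait") {
          win <- rbind(work[(t - w):(t - 1L), 1L, 1L],
                       work[(t - w):(t - 1L), 1L, 2L])
          z <- predict_next(init_model, win, coord_index_(k, 1:2))
          st <- ukf_update(pr, z, h, params,
                           r_scale = params$r_pseudo_scale)
          work[t, 1L, ] <- st$x[1:2]   # refined value feeds the next window
        } else {
          st <- list(x = pr$x, P = pr$P)   # predict-only through the gap
        }
        if (any(!is.finite(st$x))) stop("non-finite posterior")
        out[t, ] <- st$x[1:2]
      }
      out
    }, error = function(e) NULL)
    miss_t <- which(!vis[, k])
    if (is.null(track)) {
      warning(sprintf("filter failed for keypoint %d; %s", k - 1L,
                      if (method == "recovgait") "falling back to gated-only values"
                      else "leaving zero-fill"), call. = FALSE)
      if (method == "recovgait") {
        if (is.null(recon)) recon <- iterative_reconstruct(init_model, seq)
        co[miss_t, k, ] <- recon$coords[miss_t, k, ]
      }
    } else {
      co[miss_t, k, ] <- track[miss_t, ]
    }
  }
  out <- gait_sequence(co, subject_id = seq$subject_id, label = seq$label,
                       scores = seq$scores, visibility = vis)
  out$imputed <- !vis
  out
}
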