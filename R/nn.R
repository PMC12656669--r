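# Internal neural-network primitives: parameter initialization, Adam, and
# manual forward/backward passes for the gated recurrent (GRU) imputation
# network and the LSTM classifier. Gradients are exercised by
# finite-difference checks in the test suite.

sigmoid_ <- function(x) 1 / (1 + exp(-x))

# add a bias row-vector b to every row of matrix M (column-major trick)
addb_ <- function(M, b) M + rep(b, each = nrow(M))

glorot_ <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

# ---- Adam -------------------------------------------------------------------

adam_new_ <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step_ <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(opt = opt, params = params)
}

clip_grads_ <- function(grads, max_norm = 5) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(nrm) && nrm > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / nrm))
  }
  grads
}

# ---- univariate GRU (gated initialization network) --------------------------
# One gated recurrent layer of H units over a scalar input series, rectifier
# on the layer output, dense linear head of size 1.

gru_params_new_ <- function(H) {
  list(
    Wz = glorot_(1, H), Uz = glorot_(H, H), bz = matrix(0, 1, H),
    Wr = glorot_(1, H), Ur = glorot_(H, H), br = matrix(0, 1, H),
    Wc = glorot_(1, H), Uc = glorot_(H, H), bc = matrix(0, 1, H),
    w_out = glorot_(H, 1), b_out = matrix(0, 1, 1)
  )
}

# X: B x T matrix of (normalized) inputs; returns y (length B) and cache
gru_forward_ <- function(p, X, keep_cache = TRUE) {
  B <- nrow(X); Tn <- ncol(X); H <- ncol(p$Uz)
  h <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- X[, t]
    z <- sigmoid_(addb_(x %o% p$Wz[1, ] + h %*% p$Uz, p$bz[1, ]))
    r <- sigmoid_(addb_(x %o% p$Wr[1, ] + h %*% p$Ur, p$br[1, ]))
    cc <- tanh(addb_(x %o% p$Wc[1, ] + (r * h) %*% p$Uc, p$bc[1, ]))
    h_new <- (1 - z) * h + z * cc
    if (keep_cache) cache[[t]] <- list(x = x, hprev = h, z = z, r = r, cc = cc)
    h <- h_new
  }
  hrelu <- pmax(h, 0)
  y <- drop(hrelu %*% p$w_out) + p$b_out[1, 1]
  list(y = y, h = h, hrelu = hrelu, cache = cache)
}

# dy: dL/dy, length B
gru_backward_ <- function(p, fwd, dy) {
  H <- ncol(p$Uz)
  g <- lapply(p, function(x) x * 0)
  g$w_out <- t(fwd$hrelu) %*% dy
  g$b_out <- matrix(sum(dy), 1, 1)
  dh <- (dy %o% p$w_out[, 1]) * (fwd$h > 0)
  for (t in rev(seq_along(fwd$cache))) {
    s <- fwd$cache[[t]]
    dz <- dh * (s$cc - s$hprev)
    dcc <- dh * s$z
    dhprev <- dh * (1 - s$z)
    dc_pre <- dcc * (1 - s$cc^2)
    g$Wc <- g$Wc + colSums(dc_pre * s$x)
    g$Uc <- g$Uc + t(s$r * s$hprev) %*% dc_pre
    g$bc <- g$bc + colSums(dc_pre)
    dRH <- dc_pre %*% t(p$Uc)
    dr <- dRH * s$hprev
    dhprev <- dhprev + dRH * s$r
    dz_pre <- dz * s$z * (1 - s$z)
    dr_pre <- dr * s$r * (1 - s$r)
    g$Wz <- g$Wz + colSums(dz_pre * s$x)
    g$Uz <- g$Uz + t(s$hprev) %*% dz_pre
    g$bz <- g$bz + colSums(dz_pre)
    g$Wr <- g$Wr + colSums(dr_pre * s$x)
    g$Ur <- g$Ur + t(s$hprev) %*% dr_pre
    g$br <- g$br + colSums(dr_pre)
    dh <- dhprev + dz_pre %*% t(p$Uz) + dr_pre %*% t(p$Ur)
  }
  g
}

# ---- LSTM layer (classifier) ------------------------------------------------
# Gate order in the fused weight matrices: input, forget, candidate, output.
# `act` is the cell/output activation ("relu" or "tanh").

lstm_params_new_ <- function(D, H) {
  b <- matrix(0, 1, 4 * H)
  b[1, (H + 1):(2 * H)] <- 1   # forget-gate bias
  list(W = glorot_(D, 4 * H), U = glorot_(H, 4 * H), b = b)
}

act_ <- function(x, act) if (act == "relu") pmax(x, 0) else tanh(x)
dact_ <- function(pre, post, act) if (act == "relu") (pre > 0) + 0 else 1 - post^2

# Xs: list over time of B x D matrices. Returns hidden states per step.
lstm_forward_ <- function(p, Xs, act = "relu", keep_cache = TRUE) {
  H <- ncol(p$U) / 4L
  B <- nrow(Xs[[1]])
  h <- matrix(0, B, H); cstate <- matrix(0, B, H)
  hs <- vector("list", length(Xs))
  cache <- if (keep_cache) vector("list", length(Xs))
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H); i4 <- (3 * H + 1):(4 * H)
  for (t in seq_along(Xs)) {
    A <- addb_(Xs[[t]] %*% p$W + h %*% p$U, p$b[1, ])
    ig <- sigmoid_(A[, i1, drop = FALSE])
    fg <- sigmoid_(A[, i2, drop = FALSE])
    gpre <- A[, i3, drop = FALSE]
    gg <- act_(gpre, act)
    og <- sigmoid_(A[, i4, drop = FALSE])
    c_new <- fg * cstate + ig * gg
    phic <- act_(c_new, act)
    h_new <- og * phic
    if (keep_cache) {
      cache[[t]] <- list(x = Xs[[t]], hprev = h, cprev = cstate, ig = ig,
                         fg = fg, gpre = gpre, gg = gg, og = og,
                         c = c_new, phic = phic)
    }
    h <- h_new; cstate <- c_new
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

# dhs: list over time of dL/dh_t (zero matrices where no gradient flows in)
lstm_backward_ <- function(p, fwd, dhs, act = "relu") {
  H <- ncol(p$U) / 4L
  g <- list(W = p$W * 0, U = p$U * 0, b = p$b * 0)
  Tn <- length(fwd$cache)
  B <- nrow(dhs[[Tn]])
  dh_rec <- matrix(0, B, H); dc <- matrix(0, B, H)
  dXs <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    s <- fwd$cache[[t]]
    dh <- dhs[[t]] + dh_rec
    do_ <- dh * s$phic
    dc <- dc + dh * s$og * dact_(s$c, s$phic, act)
    di <- dc * s$gg
    dg <- dc * s$ig
    df <- dc * s$cprev
    dc <- dc * s$fg                      # carried to t-1
    dA <- cbind(di * s$ig * (1 - s$ig),
                df * s$fg * (1 - s$fg),
                dg * dact_(s$gpre, s$gg, act),
                do_ * s$og * (1 - s$og))
    g$W <- g$W + t(s$x) %*% dA
    g$U <- g$U + t(s$hprev) %*% dA
    g$b <- g$b + colSums(dA)
    dh_rec <- dA %*% t(p$U)
    dXs[[t]] <- dA %*% t(p$W)
  }
  list(grads = g, dXs = dXs)
}

# ---- dense ------------------------------------------------------------------

dense_params_new_ <- function(D, H) {
  list(W = glorot_(D, H), b = matrix(0, 1, H))
}

dropout_mask_ <- function(nr, nc, rate) {
  if (rate <= 0) return(matrix(1, nr, nc))
  matrix(stats::rbinom(nr * nc, 1, 1 - rate) / (1 - rate), nr, nc)
}
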