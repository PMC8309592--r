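# Minimal 2-D convolutional network: forward/backward passes and Adam
# updates. Activations use a channels-last (H, W, B, C) layout; the conv
# and pooling kernels are compiled (src/nn_ops.cpp). Pure-R reference
# kernels (*_ref) are kept for verification. All functions here are
# internal; the user-facing surface is in decoder.R.

conv_fwd <- function(X, W, b) cpp_conv_fwd(X, W, b)

conv_bwd <- function(dY, X, W, compute_dx = TRUE) {
  cpp_conv_bwd(X, W, dY, compute_dx)
}

pool_fwd <- function(X) cpp_pool_fwd(X)

pool_bwd <- function(dP, Xdim) cpp_pool_bwd(dP, as.integer(Xdim))

# ---- pure-R reference kernels (oracles for the compiled versions) ------

im2col_plane_ref <- function(P, kh, kw) {
  d <- dim(P)
  Hout <- d[1] - kh + 1L; Wout <- d[2] - kw + 1L
  M <- matrix(0, Hout * Wout * d[3], kh * kw)
  for (k in seq_len(kh * kw)) {
    di <- (k - 1L) %% kh
    dj <- (k - 1L) %/% kh
    M[, k] <- P[(1L + di):(Hout + di), (1L + dj):(Wout + dj), ]
  }
  M
}

conv_fwd_ref <- function(X, W, b) {
  d <- dim(X); kh <- dim(W)[1]; kw <- dim(W)[2]
  C <- dim(W)[3]; f <- dim(W)[4]
  Hout <- d[1] - kh + 1L; Wout <- d[2] - kw + 1L
  Y <- matrix(b, Hout * Wout * d[3], f, byrow = TRUE)
  for (c in seq_len(C)) {
    P <- X[, , , c, drop = FALSE]
    dim(P) <- d[1:3]
    Y <- Y + im2col_plane_ref(P, kh, kw) %*% matrix(W[, , c, ], kh * kw, f)
  }
  dim(Y) <- c(Hout, Wout, d[3], f)
  Y
}

conv_bwd_ref <- function(dY, X, W, compute_dx = TRUE) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; C <- dim(W)[3]; f <- dim(W)[4]
  d <- dim(dY)
  Hout <- d[1]; Wout <- d[2]; B <- d[3]
  dYmat <- dY
  dim(dYmat) <- c(Hout * Wout * B, f)
  dW <- array(0, dim(W))
  db <- colSums(dYmat)
  dX <- if (compute_dx) array(0, dim(X)) else NULL
  for (c in seq_len(C)) {
    P <- X[, , , c, drop = FALSE]
    dim(P) <- dim(X)[1:3]
    M <- im2col_plane_ref(P, kh, kw)
    dW[, , c, ] <- crossprod(M, dYmat)
    if (compute_dx) {
      dM <- tcrossprod(dYmat, matrix(W[, , c, ], kh * kw, f))
      plane <- array(0, dim(X)[1:3])
      for (k in seq_len(kh * kw)) {
        di <- (k - 1L) %% kh
        dj <- (k - 1L) %/% kh
        rows <- (1L + di):(Hout + di); cols <- (1L + dj):(Wout + dj)
        plane[rows, cols, ] <- plane[rows, cols, , drop = FALSE] +
          array(dM[, k], c(Hout, Wout, B))
      }
      dX[, , , c] <- plane
    }
  }
  list(dW = dW, db = db, dX = dX)
}

pool_fwd_ref <- function(X) {
  d <- dim(X)
  Hh <- d[1] %/% 2L; Wh <- d[2] %/% 2L
  o1 <- seq(1L, 2L * Hh, 2L)
  P1 <- (X[o1, , , , drop = FALSE] + X[o1 + 1L, , , , drop = FALSE]) / 2
  o2 <- seq(1L, 2L * Wh, 2L)
  (P1[, o2, , , drop = FALSE] + P1[, o2 + 1L, , , drop = FALSE]) / 2
}

# ---- network ------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# He-scaled initialization of all parameters for an input of size H x W.
nn_init <- function(cfg, H, W) {
  kh <- cfg$kernel; kw <- cfg$kernel
  C <- 1L
  params <- list()
  h <- H; w <- W
  for (i in seq_along(cfg$conv_filters)) {
    f <- cfg$conv_filters[i]
    fan_in <- kh * kw * C
    params[[paste0("W", i)]] <-
      array(stats::rnorm(kh * kw * C * f, sd = sqrt(2 / fan_in)),
            c(kh, kw, C, f))
    params[[paste0("b", i)]] <- numeric(f)
    h <- (h - kh + 1L) %/% 2L
    w <- (w - kw + 1L) %/% 2L
    C <- f
  }
  flat <- h * w * C
  if (flat < 1L) stopf("input %d x %d too small for %d conv blocks",
                       H, W, length(cfg$conv_filters))
  params$Wd <- matrix(stats::rnorm(cfg$dense * flat, sd = sqrt(2 / flat)),
                      cfg$dense, flat)
  params$bd <- numeric(cfg$dense)
  params$Wo <- matrix(stats::rnorm(cfg$dense, sd = sqrt(1 / cfg$dense)),
                      1L, cfg$dense)
  params$bo <- 0
  params
}

# Forward pass for a batch; X is (H, W, B). Returns probabilities and,
# optionally, the caches needed for backprop.
nn_forward <- function(params, cfg, X, cache = FALSE) {
  d <- dim(X)
  A <- X - 0.5       # fixed centering of [0, 1]-normalized inputs
  dim(A) <- c(d[1], d[2], d[3], 1L)
  caches <- list()
  for (i in seq_along(cfg$conv_filters)) {
    Z <- conv_fwd(A, params[[paste0("W", i)]], params[[paste0("b", i)]])
    R <- Z * (Z > 0)
    P <- pool_fwd(R)
    if (cache) caches[[i]] <- list(X = A, Z = Z, Rdim = dim(R))
    A <- P
  }
  pdim <- dim(A)                                   # (Hf, Wf, B, F)
  Fl <- aperm(A, c(1L, 2L, 4L, 3L))                # features x sample
  dim(Fl) <- c(pdim[1] * pdim[2] * pdim[4], pdim[3])
  Zd <- params$Wd %*% Fl + params$bd
  Ad <- Zd * (Zd > 0)
  Zo <- params$Wo %*% Ad + params$bo
  prob <- as.numeric(sigmoid(Zo))
  if (!cache) return(list(prob = prob))
  list(prob = prob, caches = caches, Fl = Fl, Zd = Zd, Ad = Ad, pdim = pdim)
}

nn_backward <- function(params, cfg, fw, y) {
  B <- length(y)
  grads <- list()
  dZo <- matrix(fw$prob - y, 1L, B) / B
  grads$Wo <- tcrossprod(dZo, fw$Ad)
  grads$bo <- sum(dZo)
  dAd <- crossprod(params$Wo, dZo)
  dZd <- dAd * (fw$Zd > 0)
  grads$Wd <- tcrossprod(dZd, fw$Fl)
  grads$bd <- rowSums(dZd)
  dFl <- crossprod(params$Wd, dZd)
  pd <- fw$pdim
  dP <- array(dFl, c(pd[1], pd[2], pd[4], pd[3]))
  dP <- aperm(dP, c(1L, 2L, 4L, 3L))
  for (i in rev(seq_along(cfg$conv_filters))) {
    cc <- fw$caches[[i]]
    dR <- pool_bwd(dP, cc$Rdim)
    dZ <- dR * (cc$Z > 0)
    cb <- conv_bwd(dZ, cc$X, params[[paste0("W", i)]],
                   compute_dx = i > 1L)
    grads[[paste0("W", i)]] <- cb$dW
    grads[[paste0("b", i)]] <- cb$db
    if (i > 1L) dP <- cb$dX
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Predict probabilities in batches to bound peak memory.
nn_predict <- function(params, cfg, X) {
  B <- dim(X)[3]
  out <- numeric(B)
  bs <- cfg$batch
  for (s in seq(1L, B, bs)) {
    e <- min(s + bs - 1L, B)
    out[s:e] <- nn_forward(params, cfg, X[, , s:e, drop = FALSE])$prob
  }
  out
}
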