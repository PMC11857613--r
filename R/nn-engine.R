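# Minimal multi-label neural-network engine: dense, 1-D convolutional and
# LSTM architectures with sigmoid outputs, trained under a differentiable
# Tanimoto or binary cross-entropy objective. All forward and backward
# passes are analytic and gradient-checked in the test suite.
#
# Every architecture carries a zero-initialized linear bypass from the input
# to the output logits (logits = deep(x) + x %*% Ws). Under the default
# optimizer (SGD with momentum and a proximal L1 penalty on weight matrices)
# the bypass recovers sparse bin-to-bit structure that small-corpus training
# would otherwise memorize away; see the methods vignette for the rationale.
# Everything here is internal; the user-facing surface is in models.R.

.glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  l <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -l, l), dim = dims)
}

.relu <- function(x) x * (x > 0)
.sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- parameter initialization (uses current RNG state) -------------------

.nn_init <- function(spec) {
  lp <- spec$layer_plan
  D <- spec$input_length; L <- spec$output_length
  base <- if (spec$architecture == "dense") {
    h <- lp$hidden
    list(W1 = .glorot(D, h[1]), b1 = numeric(h[1]),
         W2 = .glorot(h[1], h[2]), b2 = numeric(h[2]),
         W3 = .glorot(h[2], L), b3 = numeric(L))
  } else if (spec$architecture == "conv") {
    w <- lp$width; f1 <- lp$filters[1]; f2 <- lp$filters[2]
    dims <- .conv_dims(D, lp)
    list(Wc1 = .glorot(w * 1, f1, c(w * 1, f1)), bc1 = numeric(f1),
         Wc2 = .glorot(w * f1, f2, c(w * f1, f2)), bc2 = numeric(f2),
         Wd = .glorot(dims$flat, lp$dense), bd = numeric(lp$dense),
         Wo = .glorot(lp$dense, L), bo = numeric(L))
  } else if (spec$architecture == "recurrent") {
    H <- lp$hidden; cl <- .lstm_chunk(D, lp$steps)
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias init
    list(Wx = .glorot(cl, 4 * H, c(cl, 4 * H)),
         Wh = .glorot(H, 4 * H, c(H, 4 * H)),
         bg = b,
         Wd = .glorot(H, lp$dense), bd = numeric(lp$dense),
         Wo = .glorot(lp$dense, L), bo = numeric(L))
  } else stop("unknown architecture: ", spec$architecture)
  base$Ws <- matrix(0, D, L)  # linear bypass, zero so it starts silent
  base
}

.conv_dims <- function(D, lp) {
  w <- lp$width; p <- lp$pool
  t1 <- D - w + 1L
  t2 <- t1 %/% p
  t3 <- t2 - w + 1L
  t4 <- t3 %/% p
  if (t4 < 1) stop("input_length ", D, " too short for the convolutional plan")
  list(t1 = t1, t2 = t2, t3 = t3, t4 = t4, flat = t4 * lp$filters[2])
}

.lstm_chunk <- function(D, steps) as.integer(ceiling(D / steps))

## ---- dense ---------------------------------------------------------------

.fwd_dense <- function(p, X) {
  A1 <- .relu(sweep(X %*% p$W1, 2, p$b1, "+"))
  A2 <- .relu(sweep(A1 %*% p$W2, 2, p$b2, "+"))
  Z <- sweep(A2 %*% p$W3, 2, p$b3, "+") + X %*% p$Ws
  list(P = .sigmoid(Z), cache = list(X = X, A1 = A1, A2 = A2))
}

.bwd_dense <- function(p, cache, dZ) {
  A1 <- cache$A1; A2 <- cache$A2; X <- cache$X
  dW3 <- crossprod(A2, dZ); db3 <- colSums(dZ)
  dA2 <- (dZ %*% t(p$W3)) * (A2 > 0)
  dW2 <- crossprod(A1, dA2); db2 <- colSums(dA2)
  dA1 <- (dA2 %*% t(p$W2)) * (A1 > 0)
  dW1 <- crossprod(X, dA1); db1 <- colSums(dA1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3,
       Ws = crossprod(X, dZ))
}

## ---- 1-D convolution helpers ---------------------------------------------

# X3: array (n, T, C) -> column matrix (n*T_out, w*C)
.im2col <- function(X3, w) {
  n <- dim(X3)[1]; TT <- dim(X3)[2]; C <- dim(X3)[3]
  t_out <- TT - w + 1L
  col <- array(0, dim = c(n, t_out, w * C))
  for (wi in seq_len(w)) {
    col[, , ((wi - 1L) * C + 1L):(wi * C)] <- X3[, wi:(wi + t_out - 1L), , drop = FALSE]
  }
  dim(col) <- c(n * t_out, w * C)
  col
}

# scatter col-matrix gradient (n*T_out, w*C) back to (n, T, C)
.col2im <- function(dcol, n, TT, C, w) {
  t_out <- TT - w + 1L
  dim(dcol) <- c(n, t_out, w * C)
  dX <- array(0, dim = c(n, TT, C))
  for (wi in seq_len(w)) {
    sl <- wi:(wi + t_out - 1L)
    dX[, sl, ] <- dX[, sl, , drop = FALSE] +
      dcol[, , ((wi - 1L) * C + 1L):(wi * C), drop = FALSE]
  }
  dX
}

.pool2_fwd <- function(A) {
  n <- dim(A)[1]; TT <- dim(A)[2]; C <- dim(A)[3]
  t2 <- TT %/% 2L
  A1 <- A[, seq.int(1L, 2L * t2, 2L), , drop = FALSE]
  A2 <- A[, seq.int(2L, 2L * t2, 2L), , drop = FALSE]
  out <- pmax(A1, A2)
  list(out = out, mask = A1 >= A2, TT = TT)
}

.pool2_bwd <- function(dOut, pool, C) {
  n <- dim(dOut)[1]; t2 <- dim(dOut)[2]
  dA <- array(0, dim = c(n, pool$TT, C))
  dA[, seq.int(1L, 2L * t2, 2L), ] <- dOut * pool$mask
  dA[, seq.int(2L, 2L * t2, 2L), ] <- dOut * (1 - pool$mask)
  dA
}

.fwd_conv <- function(p, X, lp) {
  n <- nrow(X); D <- ncol(X)
  dims <- .conv_dims(D, lp)
  f1 <- lp$filters[1]; f2 <- lp$filters[2]; w <- lp$width
  X3 <- array(X, dim = c(n, D, 1L))
  col1 <- .im2col(X3, w)
  Z1 <- sweep(col1 %*% p$Wc1, 2, p$bc1, "+")
  A1 <- .relu(Z1); dim(A1) <- c(n, dims$t1, f1)
  pool1 <- .pool2_fwd(A1)
  col2 <- .im2col(pool1$out, w)
  Z2 <- sweep(col2 %*% p$Wc2, 2, p$bc2, "+")
  A2 <- .relu(Z2); dim(A2) <- c(n, dims$t3, f2)
  pool2 <- .pool2_fwd(A2)
  Fl <- pool2$out; dim(Fl) <- c(n, dims$flat)
  Ad <- .relu(sweep(Fl %*% p$Wd, 2, p$bd, "+"))
  Z <- sweep(Ad %*% p$Wo, 2, p$bo, "+") + X %*% p$Ws
  list(P = .sigmoid(Z),
       cache = list(n = n, D = D, dims = dims, X = X, col1 = col1, Z1 = Z1,
                    pool1 = pool1, col2 = col2, Z2 = Z2, pool2 = pool2,
                    Fl = Fl, Ad = Ad))
}

.bwd_conv <- function(p, cache, dZ, lp) {
  n <- cache$n; dims <- cache$dims
  f1 <- lp$filters[1]; f2 <- lp$filters[2]; w <- lp$width
  dWo <- crossprod(cache$Ad, dZ); dbo <- colSums(dZ)
  dAd <- (dZ %*% t(p$Wo)) * (cache$Ad > 0)
  dWd <- crossprod(cache$Fl, dAd); dbd <- colSums(dAd)
  dFl <- dAd %*% t(p$Wd)
  dim(dFl) <- c(n, dims$t4, f2)
  dA2 <- .pool2_bwd(dFl, cache$pool2, f2)
  dim(dA2) <- c(n * dims$t3, f2)
  dZ2 <- dA2 * (cache$Z2 > 0)
  dWc2 <- crossprod(cache$col2, dZ2); dbc2 <- colSums(dZ2)
  dcol2 <- dZ2 %*% t(p$Wc2)
  dPool1 <- .col2im(dcol2, n, dims$t2, f1, w)
  dA1 <- .pool2_bwd(dPool1, cache$pool1, f1)
  dim(dA1) <- c(n * dims$t1, f1)
  dZ1 <- dA1 * (cache$Z1 > 0)
  dWc1 <- crossprod(cache$col1, dZ1); dbc1 <- colSums(dZ1)
  list(Wc1 = dWc1, bc1 = dbc1, Wc2 = dWc2, bc2 = dbc2,
       Wd = dWd, bd = dbd, Wo = dWo, bo = dbo,
       Ws = crossprod(cache$X, dZ))
}

## ---- LSTM ----------------------------------------------------------------

# chunk (n, D) into sequence steps: list of T matrices (n, chunk), zero-padded
.lstm_chunks <- function(X, steps) {
  n <- nrow(X); D <- ncol(X)
  cl <- .lstm_chunk(D, steps)
  if (cl * steps > D) X <- cbind(X, matrix(0, n, cl * steps - D))
  lapply(seq_len(steps), function(t) X[, ((t - 1L) * cl + 1L):(t * cl), drop = FALSE])
}

.fwd_lstm <- function(p, X, lp) {
  H <- lp$hidden; steps <- lp$steps
  xs <- .lstm_chunks(X, steps)
  n <- nrow(X)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  steps_cache <- vector("list", steps)
  ii <- 1:H; ff <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H); oo <- (3 * H + 1):(4 * H)
  for (t in seq_len(steps)) {
    G <- sweep(xs[[t]] %*% p$Wx + h %*% p$Wh, 2, p$bg, "+")
    gi <- .sigmoid(G[, ii, drop = FALSE])
    gf <- .sigmoid(G[, ff, drop = FALSE])
    gg_ <- tanh(G[, gg, drop = FALSE])
    go <- .sigmoid(G[, oo, drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg_
    tc <- tanh(cc)
    h_prev <- h
    h <- go * tc
    steps_cache[[t]] <- list(x = xs[[t]], gi = gi, gf = gf, gg = gg_, go = go,
                             c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  Ad <- .relu(sweep(h %*% p$Wd, 2, p$bd, "+"))
  Z <- sweep(Ad %*% p$Wo, 2, p$bo, "+") + X %*% p$Ws
  list(P = .sigmoid(Z),
       cache = list(steps = steps_cache, h = h, Ad = Ad, H = H, X = X))
}

.bwd_lstm <- function(p, cache, dZ, lp) {
  H <- cache$H
  dWo <- crossprod(cache$Ad, dZ); dbo <- colSums(dZ)
  dAd <- (dZ %*% t(p$Wo)) * (cache$Ad > 0)
  dWd <- crossprod(cache$h, dAd); dbd <- colSums(dAd)
  dh <- dAd %*% t(p$Wd)
  dc <- matrix(0, nrow(dh), H)
  dWx <- array(0, dim = dim(p$Wx)); dWh <- array(0, dim = dim(p$Wh))
  dbg <- numeric(4 * H)
  for (t in rev(seq_along(cache$steps))) {
    st <- cache$steps[[t]]
    do_ <- dh * st$tc
    dc <- dc + dh * st$go * (1 - st$tc^2)
    di <- dc * st$gg
    dg <- dc * st$gi
    df <- dc * st$c_prev
    dc_prev <- dc * st$gf
    dGi <- di * st$gi * (1 - st$gi)
    dGf <- df * st$gf * (1 - st$gf)
    dGg <- dg * (1 - st$gg^2)
    dGo <- do_ * st$go * (1 - st$go)
    dG <- cbind(dGi, dGf, dGg, dGo)
    dWx <- dWx + crossprod(st$x, dG)
    dWh <- dWh + crossprod(st$h_prev, dG)
    dbg <- dbg + colSums(dG)
    dh <- dG %*% t(p$Wh)
    dc <- dc_prev
  }
  list(Wx = dWx, Wh = dWh, bg = dbg, Wd = dWd, bd = dbd, Wo = dWo, bo = dbo,
       Ws = crossprod(cache$X, dZ))
}

## ---- dispatch ------------------------------------------------------------

.nn_forward <- function(spec, params, X) {
  X <- X * spec$layer_plan$input_scale
  switch(spec$architecture,
         dense = .fwd_dense(params, X),
         conv = .fwd_conv(params, X, spec$layer_plan),
         recurrent = .fwd_lstm(params, X, spec$layer_plan))
}

.nn_backward <- function(spec, params, cache, dZ) {
  switch(spec$architecture,
         dense = .bwd_dense(params, cache, dZ),
         conv = .bwd_conv(params, cache, dZ, spec$layer_plan),
         recurrent = .bwd_lstm(params, cache, dZ, spec$layer_plan))
}

## ---- losses --------------------------------------------------------------

# returns loss (mean over samples) and gradient wrt pre-sigmoid logits
.loss_grad <- function(Y, P, loss) {
  n <- nrow(Y)
  if (loss == "tanimoto") {
    A <- rowSums(Y * P)
    B <- rowSums(Y) + rowSums(P) - A
    Bs <- pmax(B, 1e-9)
    li <- ifelse(B <= 0, 0, 1 - A / Bs)
    dP <- -(Y * Bs - A * (1 - Y)) / Bs^2 / n
    dP[B <= 0, ] <- 0
    list(loss = mean(li), dZ = dP * P * (1 - P))
  } else if (loss == "bce") {
    eps <- 1e-12
    l <- -mean(rowSums(Y * log(P + eps) + (1 - Y) * log(1 - P + eps)))
    list(loss = l, dZ = (P - Y) / n)
  } else stop("unknown loss: ", loss)
}

## ---- Adam optimizer ------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    upd <- lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    params[[k]] <- params[[k]] - upd
  }
  list(params = params, state = state)
}

## ---- training loop -------------------------------------------------------

# X, Y plain matrices; val_idx row indices held out for early stopping (may
# be empty). Returns params, per-epoch log, and the best validation loss.
.nn_train <- function(spec, params, X, Y, val_idx = integer(0), config) {
  train_idx <- setdiff(seq_len(nrow(X)), val_idx)
  Xtr <- X[train_idx, , drop = FALSE]; Ytr <- Y[train_idx, , drop = FALSE]
  Xv <- X[val_idx, , drop = FALSE]; Yv <- Y[val_idx, , drop = FALSE]
  use_adam <- identical(config$optimizer, "adam")
  state <- if (use_adam) .adam_init(params) else lapply(params, function(p) p * 0)
  lr <- config$learning_rate
  l1w <- lapply(params, function(p) 0)
  if (config$l1 > 0) {
    for (k in names(params)) if (grepl("^W", k)) l1w[[k]] <- config$l1
    l1w$Ws <- config$l1_bypass
  }
  n <- nrow(Xtr); bs <- min(config$batch_size, n)
  best_val <- Inf; best_params <- params; wait <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      fw <- .nn_forward(spec, params, Xtr[idx, , drop = FALSE])
      lg <- .loss_grad(Ytr[idx, , drop = FALSE], fw$P, config$loss)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite %s loss at epoch %d (batch starting %d); ",
                     config$loss, epoch, start),
             "consider lowering the learning rate")
      }
      grads <- .nn_backward(spec, params, fw$cache, lg$dZ)
      if (use_adam) {
        st <- .adam_step(params, grads, state, lr)
        params <- st$params; state <- st$state
      } else {
        for (k in names(params)) {
          state[[k]] <- config$momentum * state[[k]] + grads[[k]]
          params[[k]] <- params[[k]] - lr * state[[k]]
        }
      }
      # proximal (soft-threshold) L1 on weight matrices; biases exempt
      for (k in names(params)) {
        if (l1w[[k]] > 0) {
          params[[k]] <- sign(params[[k]]) * pmax(abs(params[[k]]) - lr * l1w[[k]], 0)
        }
      }
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    vl <- NA_real_
    if (length(val_idx) > 0) {
      fwv <- .nn_forward(spec, params, Xv)
      vl <- .loss_grad(Yv, fwv$P, config$loss)$loss
      if (vl < best_val - 1e-6) {
        best_val <- vl; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) {
          log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / nb, val_loss = vl))
          break
        }
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / nb, val_loss = vl))
  }
  if (length(val_idx) > 0) params <- best_params else best_val <- NA_real_
  list(params = params, log = log, best_val = best_val)
}
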