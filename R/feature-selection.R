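#' Supervised feature-selection configuration
#'
#' Defaults follow the standard chain: per-bin probe models scored by 5-fold
#' cross-validated micro-F1, the top 500 bins retained per ionization mode;
#' then a multi-output convolutional probe on the selected bins, retaining
#' fingerprint bits with mean fold F1 strictly above 0.8.
#'
#' Probe architectures: the bin probe is a one-hidden-layer perceptron (32
#' relu units, sigmoid outputs, binary cross-entropy); the fingerprint
#' probe is one convolution layer (32 filters of width 5) followed by a
#' dense layer of 64 and sigmoid outputs, plus the same linear bypass the
#' main models carry. Training budgets and optimizers are per-probe
#' configuration values.
#'
#' @param n_bins_keep Number of bins retained (default 500).
#' @param fp_f1_threshold Strict lower F1 bound for fingerprint retention.
#' @param n_folds Cross-validation folds (compound-level).
#' @param seed Integer seed (folds, probe initialization, batching).
#' @param method `"per_bin_probe"` (default: one probe per bin) or
#'   `"permutation"` (one joint perceptron; a bin's score is the
#'   cross-validated F1 after permuting that bin).
#' @param bin_probe Named list of bin-probe hyperparameters (`hidden`,
#'   `epochs`, `batch_size`, `learning_rate`, `optimizer`, `input_scale`).
#'   The bin probe is a one-scalar-input perceptron, so it trains with Adam
#'   for a short budget.
#' @param fp_probe Named list of fingerprint-probe hyperparameters
#'   (`filters`, `width`, `dense`, `epochs`, `batch_size`, `learning_rate`,
#'   `optimizer`, `momentum`, `l1`, `l1_bypass`, `input_scale`). The
#'   fingerprint probe sees the full selected-bin vector and is exposed to
#'   the same small-corpus memorization pressure as the main models, so it
#'   carries the same linear bypass and trains with sparse-regularized SGD
#'   by default.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_bins_keep = 500L, fp_f1_threshold = 0.8,
                             n_folds = 5L, seed = 1L,
                             method = c("per_bin_probe", "permutation"),
                             bin_probe = list(), fp_probe = list()) {
  method <- match.arg(method)
  stopifnot(n_folds >= 2, fp_f1_threshold > 0, fp_f1_threshold < 1)
  bp <- list(hidden = 32L, epochs = 30L, batch_size = 128L,
             learning_rate = 0.05, optimizer = "adam", momentum = 0.9,
             l1 = 0, l1_bypass = 0, input_scale = 0.01)
  for (k in names(bin_probe)) bp[[k]] <- bin_probe[[k]]
  fpp <- list(filters = 32L, width = 5L, dense = 64L, epochs = 150L,
              batch_size = 32L, learning_rate = 1, optimizer = "sgd",
              momentum = 0.9, l1 = 0.01, l1_bypass = 0.003,
              input_scale = 0.01)
  for (k in names(fp_probe)) fpp[[k]] <- fp_probe[[k]]
  structure(list(n_bins_keep = as.integer(n_bins_keep),
                 fp_f1_threshold = fp_f1_threshold,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 method = method, bin_probe = bp, fp_probe = fpp),
            class = "selection_config")
}

## ---- tiny probe networks (internal) --------------------------------------

.probe_mlp_init <- function(d_in, h, L) {
  list(W1 = .glorot(d_in, h), b1 = numeric(h),
       W2 = .glorot(h, L), b2 = numeric(L))
}

.probe_mlp_fwd <- function(p, X) {
  A1 <- .relu(sweep(X %*% p$W1, 2, p$b1, "+"))
  Z <- sweep(A1 %*% p$W2, 2, p$b2, "+")
  list(P = .sigmoid(Z), cache = list(X = X, A1 = A1))
}

.probe_mlp_bwd <- function(p, cache, dZ) {
  dW2 <- crossprod(cache$A1, dZ); db2 <- colSums(dZ)
  dA1 <- (dZ %*% t(p$W2)) * (cache$A1 > 0)
  list(W1 = crossprod(cache$X, dA1), b1 = colSums(dA1), W2 = dW2, b2 = db2)
}

.probe_conv_init <- function(d_in, pr, L) {
  t1 <- d_in - pr$width + 1L
  if (t1 < 1) stop("too few bins (", d_in, ") for a width-", pr$width, " convolution probe")
  list(Wc = .glorot(pr$width, pr$filters, c(pr$width, pr$filters)), bc = numeric(pr$filters),
       Wd = .glorot(t1 * pr$filters, pr$dense), bd = numeric(pr$dense),
       Wo = .glorot(pr$dense, L), bo = numeric(L),
       Ws = matrix(0, d_in, L))
}

.probe_conv_fwd <- function(p, X, pr) {
  n <- nrow(X); d <- ncol(X)
  t1 <- d - pr$width + 1L
  col <- .im2col(array(X, dim = c(n, d, 1L)), pr$width)
  Z1 <- sweep(col %*% p$Wc, 2, p$bc, "+")
  A1 <- .relu(Z1)
  Fl <- A1; dim(Fl) <- c(n, t1 * pr$filters)
  Ad <- .relu(sweep(Fl %*% p$Wd, 2, p$bd, "+"))
  Z <- sweep(Ad %*% p$Wo, 2, p$bo, "+") + X %*% p$Ws
  list(P = .sigmoid(Z),
       cache = list(X = X, col = col, Z1 = Z1, Fl = Fl, Ad = Ad, n = n, t1 = t1))
}

.probe_conv_bwd <- function(p, cache, dZ, pr) {
  dWo <- crossprod(cache$Ad, dZ); dbo <- colSums(dZ)
  dAd <- (dZ %*% t(p$Wo)) * (cache$Ad > 0)
  dWd <- crossprod(cache$Fl, dAd); dbd <- colSums(dAd)
  dFl <- dAd %*% t(p$Wd)
  dim(dFl) <- c(cache$n * cache$t1, pr$filters)
  dZ1 <- dFl * (cache$Z1 > 0)
  list(Wc = crossprod(cache$col, dZ1), bc = colSums(dZ1), Wd = dWd, bd = dbd,
       Wo = dWo, bo = dbo, Ws = crossprod(cache$X, dZ))
}

# generic mini-batch loop over a probe (BCE loss); optimizer per pr
.probe_train <- function(params, fwd, bwd, X, Y, pr) {
  use_adam <- identical(pr$optimizer, "adam")
  state <- if (use_adam) .adam_init(params) else lapply(params, function(p) p * 0)
  l1w <- lapply(params, function(p) 0)
  for (k in names(params)) if (grepl("^W", k)) l1w[[k]] <- pr$l1
  if (!is.null(params$Ws)) l1w$Ws <- pr$l1_bypass
  n <- nrow(X); bs <- min(pr$batch_size, n)
  for (epoch in seq_len(pr$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      fw <- fwd(params, X[idx, , drop = FALSE])
      lg <- .loss_grad(Y[idx, , drop = FALSE], fw$P, "bce")
      gr <- bwd(params, fw$cache, lg$dZ)
      if (use_adam) {
        st <- .adam_step(params, gr, state, pr$learning_rate)
        params <- st$params; state <- st$state
      } else {
        for (k in names(params)) {
          state[[k]] <- pr$momentum * state[[k]] + gr[[k]]
          params[[k]] <- params[[k]] - pr$learning_rate * state[[k]]
        }
      }
      for (k in names(params)) {
        if (l1w[[k]] > 0) {
          params[[k]] <- sign(params[[k]]) * pmax(abs(params[[k]]) - pr$learning_rate * l1w[[k]], 0)
        }
      }
    }
  }
  params
}

.micro_f1 <- function(pred, truth) {
  f1_score(confusion(as.vector(pred), as.vector(truth)))
}

## ---- bin scoring ---------------------------------------------------------

#' Score m/z bins by cross-validated probe F1
#'
#' For each bin, a small perceptron probe is trained on that bin's
#' intensities alone against all fingerprint bits; the score is the
#' micro-averaged F1 over bits on the held-out fold, averaged over
#' compound-level folds. A bin that is zero in every spectrum scores 0 by
#' convention. With `method = "permutation"`, one joint perceptron over all
#' bins is trained per fold and a bin's fold score is the drop in held-out
#' micro-F1 when that bin's values are permuted (permutation importance;
#' larger = more informative).
#'
#' @param X Numeric matrix, spectra x bins (scaled binned intensities).
#' @param Y Binary matrix, spectra x fingerprint bits, row-aligned with `X`.
#' @param compounds Per-row compound identifiers (fold blocking); defaults
#'   to one compound per row.
#' @param cfg A [selection_config].
#' @return data.frame with columns `feature_index`, `f1`, and a
#'   `fold_scores` matrix attribute (bins x folds); `f1` is the row mean.
#' @export
score_bins <- function(X, Y, compounds = NULL, cfg = selection_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (is.null(compounds)) compounds <- as.character(seq_len(nrow(X)))
  folds <- assign_folds(compounds, cfg$n_folds, cfg$seed)
  pr <- cfg$bin_probe
  nb <- ncol(X); L <- ncol(Y)
  fold_scores <- matrix(0, nb, cfg$n_folds)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed + 1L)
  nonzero <- which(colSums(X != 0) > 0)
  if (cfg$method == "per_bin_probe") {
    for (f in seq_len(cfg$n_folds)) {
      test <- folds == f
      Xtr <- X[!test, , drop = FALSE] * pr$input_scale
      Xte <- X[test, , drop = FALSE] * pr$input_scale
      Ytr <- Y[!test, , drop = FALSE]; Yte <- Y[test, , drop = FALSE]
      for (b in nonzero) {
        params <- .probe_mlp_init(1L, pr$hidden, L)
        params <- .probe_train(params, .probe_mlp_fwd, .probe_mlp_bwd,
                               Xtr[, b, drop = FALSE], Ytr, pr)
        pred <- binarize(.probe_mlp_fwd(params, Xte[, b, drop = FALSE])$P)
        fold_scores[b, f] <- .micro_f1(pred, Yte)
      }
    }
  } else {
    for (f in seq_len(cfg$n_folds)) {
      test <- folds == f
      Xtr <- X[!test, , drop = FALSE] * pr$input_scale
      Xte <- X[test, , drop = FALSE] * pr$input_scale
      Ytr <- Y[!test, , drop = FALSE]; Yte <- Y[test, , drop = FALSE]
      params <- .probe_mlp_init(nb, pr$hidden, L)
      params <- .probe_train(params, .probe_mlp_fwd, .probe_mlp_bwd, Xtr, Ytr, pr)
      baseline <- .micro_f1(binarize(.probe_mlp_fwd(params, Xte)$P), Yte)
      for (b in nonzero) {
        Xp <- Xte
        Xp[, b] <- Xp[sample.int(nrow(Xp)), b]
        pred <- binarize(.probe_mlp_fwd(params, Xp)$P)
        # importance = F1 drop when this bin is destroyed
        fold_scores[b, f] <- baseline - .micro_f1(pred, Yte)
      }
    }
  }
  out <- data.frame(feature_index = seq_len(nb), f1 = rowMeans(fold_scores))
  attr(out, "fold_scores") <- fold_scores
  out
}

#' Select the top-k bins by F1
#'
#' Ties at the cutoff are broken by ascending bin index; the result is
#' sorted ascending for a stable column order downstream.
#'
#' @param scores data.frame from [score_bins].
#' @param k Number of bins to retain (default 500).
#' @return Sorted integer vector of `min(k, nrow(scores))` bin indices.
#' @export
select_top_bins <- function(scores, k = 500L) {
  o <- order(-scores$f1, scores$feature_index)
  sort(scores$feature_index[o[seq_len(min(k, nrow(scores)))]])
}

#' Score fingerprint bits by cross-validated probe F1
#'
#' One multi-output convolutional probe is trained per compound-level fold
#' on the selected bins; each fingerprint bit receives its held-out F1 per
#' fold and the final score is the mean over informative folds. A held-out
#' fold containing no positive example for a bit carries no evidence about
#' that bit: by default (`empty_fold = "exclude"`) such folds are left out
#' of the bit's mean, so rare bits are not systematically pushed below the
#' selection threshold; `empty_fold = "zero"` scores them 0 instead. A bit
#' with no positives in any fold scores 0 either way.
#'
#' @param X_sel Numeric matrix restricted to the selected bins.
#' @param Y Binary fingerprint matrix, row-aligned.
#' @param empty_fold Handling of held-out folds without positive examples
#'   for a bit: `"exclude"` (default) or `"zero"`.
#' @inheritParams score_bins
#' @return data.frame with `feature_index`, `f1` and a `fold_scores`
#'   attribute (bits x folds; `NA` marks excluded positive-free folds).
#' @export
score_fingerprint_bits <- function(X_sel, Y, compounds = NULL,
                                   cfg = selection_config(),
                                   empty_fold = c("exclude", "zero")) {
  empty_fold <- match.arg(empty_fold)
  X_sel <- as.matrix(X_sel); Y <- as.matrix(Y)
  stopifnot(nrow(X_sel) == nrow(Y))
  if (is.null(compounds)) compounds <- as.character(seq_len(nrow(X_sel)))
  folds <- assign_folds(compounds, cfg$n_folds, cfg$seed)
  pr <- cfg$fp_probe
  L <- ncol(Y)
  fold_scores <- matrix(0, L, cfg$n_folds)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed + 2L)
  for (f in seq_len(cfg$n_folds)) {
    test <- folds == f
    Xtr <- X_sel[!test, , drop = FALSE] * pr$input_scale
    Xte <- X_sel[test, , drop = FALSE] * pr$input_scale
    Ytr <- Y[!test, , drop = FALSE]; Yte <- Y[test, , drop = FALSE]
    params <- .probe_conv_init(ncol(X_sel), pr, L)
    params <- .probe_train(params,
                           function(p, X) .probe_conv_fwd(p, X, pr),
                           function(p, cache, dZ) .probe_conv_bwd(p, cache, dZ, pr),
                           Xtr, Ytr, pr)
    pred <- binarize(.probe_conv_fwd(params, Xte, pr)$P)
    for (j in seq_len(L)) {
      # a held-out fold without a single positive example carries no
      # evidence about the bit's predictability
      if (sum(Yte[, j]) == 0) {
        fold_scores[j, f] <- if (empty_fold == "zero") 0 else NA_real_
      } else {
        fold_scores[j, f] <- f1_score(confusion(pred[, j], Yte[, j]))
      }
    }
  }
  f1 <- rowMeans(fold_scores, na.rm = TRUE)
  f1[!is.finite(f1)] <- 0  # no informative fold at all
  out <- data.frame(feature_index = seq_len(L), f1 = f1)
  attr(out, "fold_scores") <- fold_scores
  out
}

#' Select fingerprint bits above an F1 threshold
#'
#' Retention is strict: a bit at exactly the threshold is excluded.
#'
#' @param scores data.frame from [score_fingerprint_bits].
#' @param threshold Strict lower bound (default 0.8).
#' @return Integer vector of retained bit indices (possibly empty, with a
#'   warning).
#' @export
select_fingerprints <- function(scores, threshold = 0.8) {
  keep <- scores$feature_index[scores$f1 > threshold]
  if (length(keep) == 0) {
    warning("no fingerprint bit exceeds F1 ", threshold,
            "; consider proceeding with all bits")
  }
  keep
}
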