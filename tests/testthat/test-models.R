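test_that("the soft Tanimoto loss matches hand arithmetic and its conventions", {
  expect_equal(soft_tanimoto_loss(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(soft_tanimoto_loss(c(1, 1, 0), c(0, 0, 0)), 1)
  expect_equal(soft_tanimoto_loss(c(1, 0), c(0.5, 0.5)), 2 / 3)  # 1 - 0.5/1.5
  expect_equal(soft_tanimoto_loss(c(0, 0), c(0, 0)), 0)  # degenerate convention
  # batch: mean over rows
  y <- rbind(c(1, 0), c(0, 1)); p <- rbind(c(1, 0), c(0, 0))
  expect_equal(soft_tanimoto_loss(y, p), 0.5)
  # reduces to 1 - TP/(TP+FP+FN) on binary inputs
  yb <- c(1, 1, 0, 0); pb <- c(1, 0, 1, 0)
  expect_equal(1 - soft_tanimoto_loss(yb, pb),
               tanimoto_score(confusion(pb, yb)))
})

test_that("analytic gradients match numerical differentiation for every architecture and loss", {
  set.seed(42)
  for (arch in c("dense", "conv", "recurrent")) {
    lp <- switch(arch,
                 dense = list(hidden = c(7L, 5L)),
                 conv = list(filters = c(4L, 3L), width = 3L, pool = 2L, dense = 6L),
                 recurrent = list(steps = 4L, hidden = 5L, dense = 6L))
    lp$input_scale <- 1
    spec <- model_spec(arch, 12L, 4L, lp, seed = 3L)
    params <- asNamespace("ms2fp")$.nn_init(spec)
    # nudge all parameters off zero so no pre-activation sits on a relu kink
    params <- lapply(params, function(p) p + rnorm(length(p), 0, 0.05))
    X <- matrix(rnorm(5 * 12), 5, 12)
    Y <- matrix(rbinom(5 * 4, 1, 0.5), 5, 4)
    for (loss in c("tanimoto", "bce")) {
      ns <- asNamespace("ms2fp")
      fw <- ns$.nn_forward(spec, params, X)
      lg <- ns$.loss_grad(Y, fw$P, loss)
      gr <- ns$.nn_backward(spec, params, fw$cache, lg$dZ)
      for (k in names(params)) {
        for (idx in sample(length(params[[k]]), min(4, length(params[[k]])))) {
          ng <- numeric_grad(spec, params, X, Y, loss, k, idx)
          expect_equal(gr[[k]][idx], ng, tolerance = 1e-4,
                       label = sprintf("%s/%s grad[%s,%d]", arch, loss, k, idx))
        }
      }
    }
  }
})

test_that("model building is deterministic and spec-shaped", {
  spec <- model_spec("dense", 500L, 192L, seed = 21L)
  m1 <- build_model(spec); m2 <- build_model(spec)
  expect_identical(m1$params, m2$params)
  expect_equal(dim(m1$params$W1), c(500L, 512L))
  expect_equal(length(m1$params$b3), 192L)
  spec2 <- model_spec("conv", 500L, 272L, seed = 21L)
  m3 <- build_model(spec2)
  p <- predict(m3, matrix(runif(500), 1))
  expect_equal(ncol(p), 272L)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("prediction validates input length and stays in [0,1]", {
  spec <- model_spec("dense", 30L, 8L, list(hidden = c(8L, 6L)), seed = 2L)
  m <- build_model(spec)
  expect_error(predict(m, runif(29)), "expects 30")
  p <- predict(m, matrix(runif(3 * 30), 3))
  expect_equal(dim(p), c(3L, 8L))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("binarize thresholds at >= and handles bounds", {
  expect_equal(as.vector(binarize(c(0.49, 0.5, 0.51))), c(0L, 1L, 1L))
  expect_equal(as.vector(binarize(c(0, 0))), c(0L, 0L))
  expect_equal(as.vector(binarize(c(1, 1))), c(1L, 1L))
})

test_that("training rejects degenerate labels and mismatched shapes", {
  spec <- model_spec("dense", 10L, 4L, list(hidden = c(6L, 4L)), seed = 1L)
  X <- matrix(runif(20 * 10), 20)
  expect_error(train_model(spec, X, matrix(0, 20, 4)), "no positive labels")
  expect_error(train_model(spec, X, matrix(1, 19, 4)), "row counts")
  expect_error(train_model(spec, X, matrix(1, 20, 5)), "expects 4")
})

test_that("training is reproducible and learns a small planted mapping", {
  set.seed(33)
  n_bits <- 8L; n_comp <- 30L; reps <- 3L
  fp <- matrix(rbinom(n_comp * n_bits, 1, 0.4), n_comp, n_bits)
  fp[rowSums(fp) == 0, 1] <- 1L
  X1 <- fp[rep(seq_len(n_comp), each = reps), , drop = FALSE] * 100
  comp <- rep(sprintf("c%02d", seq_len(n_comp)), each = reps)
  spec <- model_spec("dense", n_bits, n_bits, list(hidden = c(16L, 12L)), seed = 5L)
  cfg <- train_config(epochs = 120L, patience = 120L)
  m1 <- train_model(spec, X1, fp[rep(seq_len(n_comp), each = reps), ], comp, cfg)
  m2 <- train_model(spec, X1, fp[rep(seq_len(n_comp), each = reps), ], comp, cfg)
  expect_identical(m1$params, m2$params)
  expect_equal(m1$validation_loss, m2$validation_loss)
  expect_lt(m1$validation_loss, 0.2)  # identity mapping is learnable
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(m1$training_log)))
})

test_that("serialization round-trips predictions bit-exactly", {
  spec <- model_spec("recurrent", 24L, 6L,
                     list(steps = 6L, hidden = 8L, dense = 8L), seed = 4L)
  m <- build_model(spec)
  m$trained <- TRUE
  x <- matrix(runif(24) * 100, 1)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m, x), predict(m2, x))
})
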