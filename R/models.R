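#' Specify a fingerprint-prediction model
#'
#' Three multi-label architectures map a binned-spectrum vector to
#' probabilities over condensed fingerprint bits:
#' \describe{
#'   \item{dense}{input -> 512 -> 256 -> sigmoid(L) (fully connected, relu).}
#'   \item{conv}{the input treated as a 1-channel sequence -> two
#'     convolution blocks (64 then 32 filters of width 5, each followed by
#'     max-pooling of 2) -> dense 128 -> sigmoid(L).}
#'   \item{recurrent}{the input segmented into 20 fixed-length chunks
#'     (zero-padded on the right when the length does not divide) forming a
#'     sequence -> LSTM(128) -> dense 128 -> sigmoid(L).}
#' }
#' Binned intensities (0-100 scale) are multiplied by `input_scale` on entry
#' so activations start in a well-conditioned range. All sizes live in
#' `layer_plan` and can be overridden.
#'
#' @param architecture One of `"dense"`, `"conv"`, `"recurrent"`.
#' @param input_length Number of selected m/z bins the model consumes.
#' @param output_length Number of fingerprint bits the model predicts.
#' @param layer_plan Named list of architecture sizes; missing entries take
#'   the defaults above.
#' @param seed Integer seed controlling parameter initialization.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(architecture = c("dense", "conv", "recurrent"),
                       input_length, output_length,
                       layer_plan = list(), seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(input_length > 0, output_length > 0)
  defaults <- switch(architecture,
    dense = list(hidden = c(512L, 256L)),
    conv = list(filters = c(64L, 32L), width = 5L, pool = 2L, dense = 128L),
    recurrent = list(steps = 20L, hidden = 128L, dense = 128L))
  defaults$input_scale <- 0.01
  for (k in names(layer_plan)) defaults[[k]] <- layer_plan[[k]]
  structure(list(architecture = architecture,
                 input_length = as.integer(input_length),
                 output_length = as.integer(output_length),
                 layer_plan = defaults, seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %d bins -> %d fingerprint bits (seed %d)\n",
              x$architecture, x$input_length, x$output_length, x$seed))
  invisible(x)
}

#' Build an untrained model
#'
#' Initializes parameters (Glorot-uniform; LSTM forget-gate biases at 1)
#' deterministically from `spec$seed`: two builds from the same spec are
#' identical.
#'
#' @param spec A [model_spec].
#' @return An object of class `ms2fp_model`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  params <- .nn_init(spec)
  structure(list(spec = spec, params = params, trained = FALSE,
                 training_log = NULL, mode = NULL,
                 selected_bins = NULL, selected_fps = NULL,
                 condensed_map = NULL),
            class = "ms2fp_model")
}

#' @export
print.ms2fp_model <- function(x, ...) {
  cat(sprintf("<ms2fp_model> %s, %d -> %d, %s\n", x$spec$architecture,
              x$spec$input_length, x$spec$output_length,
              if (x$trained) sprintf("trained (%d epochs)", max(x$training_log$epoch)) else "untrained"))
  invisible(x)
}

#' Training configuration
#'
#' The default optimizer is stochastic gradient descent with momentum plus a
#' proximal L1 penalty on weight matrices (`l1` for the deep layers,
#' `l1_bypass` for the linear bypass). The penalty biases training toward
#' sparse bin-to-bit solutions, which is what lets small spectral corpora
#' generalize across compounds instead of being memorized; Adam
#' (`optimizer = "adam"`) is available for larger corpora where memorization
#' pressure is low.
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Step size (default 1 for `"sgd"`; use ~1e-3 for
#'   `"adam"`).
#' @param optimizer `"sgd"` (momentum SGD, default) or `"adam"`.
#' @param momentum Momentum coefficient for SGD.
#' @param l1 Proximal L1 penalty applied per step to deep weight matrices.
#' @param l1_bypass Proximal L1 penalty on the linear bypass weights.
#' @param patience Early-stopping patience in epochs (validation loss).
#' @param validation_fraction Fraction of compounds held out for validation;
#'   the split is by compound so replicate spectra never straddle it.
#' @param loss `"tanimoto"` (differentiable Tanimoto, the default) or
#'   `"bce"` (binary cross-entropy).
#' @param seed Optional integer; defaults to the model spec's seed. Controls
#'   the validation split and batch shuffling, making training reproducible.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 400L, batch_size = 32L, learning_rate = NULL,
                         optimizer = c("sgd", "adam"), momentum = 0.9,
                         l1 = 0.01, l1_bypass = 0.003,
                         patience = 50L, validation_fraction = 0.2,
                         loss = c("tanimoto", "bce"), seed = NULL) {
  loss <- match.arg(loss)
  optimizer <- match.arg(optimizer)
  if (is.null(learning_rate)) {
    learning_rate <- if (optimizer == "sgd") 1 else 1e-3
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 momentum = momentum, l1 = l1, l1_bypass = l1_bypass,
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction, loss = loss,
                 seed = seed),
            class = "train_config")
}

#' Train a fingerprint-prediction model
#'
#' Mini-batch Adam under the configured loss, with early stopping on a
#' compound-disjoint validation split. Training is reproducible: the same
#' model seed and config give bit-identical parameters.
#'
#' @param model An `ms2fp_model` from [build_model] (an untrained one), or a
#'   [model_spec].
#' @param X Numeric matrix, samples x `input_length`.
#' @param Y Binary matrix, samples x `output_length`.
#' @param compounds Character vector of per-row compound identifiers (e.g.
#'   InChIKey skeleton blocks) used for the validation split; defaults to one
#'   compound per row.
#' @param config A [train_config].
#' @return The trained `ms2fp_model` with `training_log` and
#'   `validation_loss` fields.
#' @export
train_model <- function(model, X, Y, compounds = NULL, config = train_config()) {
  if (inherits(model, "model_spec")) model <- build_model(model)
  stopifnot(inherits(model, "ms2fp_model"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  spec <- model$spec
  if (ncol(X) != spec$input_length) {
    stop("X has ", ncol(X), " columns but the model expects ", spec$input_length)
  }
  if (ncol(Y) != spec$output_length) {
    stop("Y has ", ncol(Y), " columns but the model expects ", spec$output_length)
  }
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ")
  if (sum(Y) == 0) stop("Y contains no positive labels; nothing to train on")
  if (is.null(compounds)) compounds <- as.character(seq_len(nrow(X)))
  seed <- if (is.null(config$seed)) spec$seed else config$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  val_idx <- integer(0)
  if (config$validation_fraction > 0) {
    uc <- unique(compounds)
    n_val <- max(1L, round(length(uc) * config$validation_fraction))
    val_compounds <- sample(uc, n_val)
    val_idx <- which(compounds %in% val_compounds)
    if (length(val_idx) == nrow(X)) stop("validation split consumed all samples")
  }
  fit <- .nn_train(spec, model$params, X, Y, val_idx, config)
  model$params <- fit$params
  model$trained <- TRUE
  model$training_log <- fit$log
  model$validation_loss <- fit$best_val
  model
}

#' Predict fingerprint probabilities
#'
#' @param object A trained `ms2fp_model`.
#' @param newdata Numeric vector of length `input_length` or a matrix with
#'   that many columns.
#' @param ... Unused.
#' @return Probability matrix (samples x `output_length`), values in [0,1];
#'   a vector input yields a single-row matrix.
#' @export
predict.ms2fp_model <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$spec$input_length) {
    stop("input has length ", ncol(newdata), " but the model expects ",
         object$spec$input_length)
  }
  .nn_forward(object$spec, object$params, newdata)$P
}

#' Discretize predicted probabilities
#'
#' A bit is set iff its probability is greater than or equal to the
#' threshold.
#'
#' @param p Probability vector or matrix in [0,1].
#' @param threshold Decision threshold (default 0.5).
#' @return Integer 0/1 object of the same shape.
#' @export
binarize <- function(p, threshold = 0.5) {
  out <- (p >= threshold) * 1L
  out
}

#' Differentiable (soft) Tanimoto loss
#'
#' For a true binary vector y and prediction p in [0,1]^L:
#' `1 - sum(y*p) / (sum(y) + sum(p) - sum(y*p))`. On binary p this equals
#' one minus the Tanimoto similarity TP/(TP+FP+FN). The degenerate case of
#' y and p both all-zero is defined as loss 0. For matrices the mean over
#' rows (samples) is returned.
#'
#' @param y Binary vector or matrix.
#' @param p Probability vector or matrix of the same shape.
#' @return Scalar loss in [0,1].
#' @export
soft_tanimoto_loss <- function(y, p) {
  if (is.vector(y)) { y <- matrix(y, nrow = 1); p <- matrix(p, nrow = 1) }
  stopifnot(all(dim(y) == dim(p)))
  A <- rowSums(y * p)
  B <- rowSums(y) + rowSums(p) - A
  mean(ifelse(B <= 0, 0, 1 - A / pmax(B, .Machine$double.eps)))
}

#' Mean soft-Tanimoto similarity
#'
#' Convenience: `1 - soft_tanimoto_loss(y, p)`, the quantity tracked during
#' validation.
#'
#' @inheritParams soft_tanimoto_loss
#' @return Scalar in [0,1].
#' @export
soft_tanimoto_similarity <- function(y, p) 1 - soft_tanimoto_loss(y, p)

#' Save / load a trained model
#'
#' The serialized object bundles the parameters with the model's bin
#' selection, fingerprint selection and condensed map so predictions remain
#' tied to the feature space the model was trained in. Round-trips are
#' bit-exact.
#'
#' @param model An `ms2fp_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ms2fp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ms2fp_model"))
  model
}
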