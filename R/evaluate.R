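#' Confusion counts for binary vectors
#'
#' @param pred,truth Binary vectors of equal length.
#' @return Object of class `metric_counts` with fields `TP`, `FP`, `FN`,
#'   `TN` summing to the vector length.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("length mismatch: pred has ", length(pred), ", truth has ", length(truth))
  }
  pred <- as.integer(pred); truth <- as.integer(truth)
  structure(list(TP = sum(pred == 1L & truth == 1L),
                 FP = sum(pred == 1L & truth == 0L),
                 FN = sum(pred == 0L & truth == 1L),
                 TN = sum(pred == 0L & truth == 0L)),
            class = "metric_counts")
}

#' Tanimoto (Jaccard) similarity from confusion counts
#'
#' Standard form `TP / (TP + FP + FN)`; when `TP+FP+FN` is 0 (both vectors
#' empty) the similarity is defined as 1. `printed_form = TRUE` computes
#' `TP / (FP + FN - TP)` instead, a variant that appears in print but is not
#' bounded in [0,1]; it is provided for comparison only and is never used by
#' the pipeline.
#'
#' @param c A `metric_counts`.
#' @param printed_form Use the non-standard printed denominator.
#' @return Numeric similarity.
#' @export
tanimoto_score <- function(c, printed_form = FALSE) {
  if (printed_form) {
    d <- c$FP + c$FN - c$TP
    return(if (d == 0) NaN else c$TP / d)
  }
  d <- c$TP + c$FP + c$FN
  if (d == 0) 1 else c$TP / d
}

#' F1 score from confusion counts
#'
#' `2PR/(P+R)` with P = TP/(TP+FP), R = TP/(TP+FN). Degenerate conventions:
#' if nothing is predicted positive and nothing is positive, F1 = 1; if
#' TP = 0 with any FP or FN, F1 = 0.
#'
#' @param c A `metric_counts`.
#' @return Numeric in [0,1].
#' @export
f1_score <- function(c) {
  if (c$TP == 0) {
    if (c$FP == 0 && c$FN == 0) return(1)
    return(0)
  }
  p <- c$TP / (c$TP + c$FP)
  r <- c$TP / (c$TP + c$FN)
  2 * p * r / (p + r)
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; if any factor of
#' the denominator is zero the score is defined as 0.
#'
#' @param c A `metric_counts`.
#' @return Numeric in [-1, 1].
#' @export
mcc_score <- function(c) {
  d <- as.numeric(c$TP + c$FP) * (c$TP + c$FN) * (c$TN + c$FP) * (c$TN + c$FN)
  if (d == 0) return(0)
  (as.numeric(c$TP) * c$TN - as.numeric(c$FP) * c$FN) / sqrt(d)
}

#' Cross-validated fingerprint-prediction metrics
#'
#' Trains the given architecture on compound-disjoint folds and reports, on
#' the concatenated held-out predictions (binarized at 0.5): micro-averaged
#' F1 and Tanimoto over all bits and samples, and the mean over bits of the
#' per-bit MCC ("mean MCC"). Per-fold values are returned alongside the
#' pooled summary.
#'
#' @param spec A [model_spec].
#' @param X,Y Training matrices (samples x bins, samples x bits).
#' @param compounds Per-row compound identifiers defining the folds.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param config A [train_config] for the per-fold fits.
#' @return List with `summary` (named vector: f1, tanimoto, mean_mcc),
#'   `per_fold` data.frame, and `n_folds`.
#' @export
crossval_metrics <- function(spec, X, Y, compounds = NULL, n_folds = 5L,
                             seed = 1L, config = train_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(compounds)) compounds <- as.character(seq_len(nrow(X)))
  folds <- assign_folds(compounds, n_folds, seed)
  pred_all <- matrix(NA_integer_, nrow(Y), ncol(Y))
  per_fold <- data.frame(fold = integer(0), f1 = numeric(0), tanimoto = numeric(0))
  for (f in seq_len(n_folds)) {
    test <- which(folds == f)
    train <- setdiff(seq_len(nrow(X)), test)
    cfg <- config; cfg$validation_fraction <- 0
    fit <- train_model(model_spec(spec$architecture, spec$input_length,
                                  spec$output_length, spec$layer_plan,
                                  seed = spec$seed + f),
                       X[train, , drop = FALSE], Y[train, , drop = FALSE],
                       compounds = compounds[train], config = cfg)
    pb <- binarize(predict(fit, X[test, , drop = FALSE]))
    pred_all[test, ] <- pb
    cc <- confusion(as.vector(pb), as.vector(Y[test, , drop = FALSE]))
    per_fold <- rbind(per_fold, data.frame(fold = f, f1 = f1_score(cc),
                                           tanimoto = tanimoto_score(cc)))
  }
  cc <- confusion(as.vector(pred_all), as.vector(Y))
  per_bit_mcc <- vapply(seq_len(ncol(Y)), function(j) {
    mcc_score(confusion(pred_all[, j], Y[, j]))
  }, numeric(1))
  list(summary = c(f1 = f1_score(cc), tanimoto = tanimoto_score(cc),
                   mean_mcc = mean(per_bit_mcc)),
       per_fold = per_fold, n_folds = n_folds)
}

#' Compound-level fold assignment
#'
#' Unique compounds are shuffled deterministically by the seed and dealt
#' round-robin to folds, so all replicate spectra of a compound land in one
#' fold.
#'
#' @param compounds Character vector of per-row compound identifiers.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels (1..n_folds) per row.
#' @export
assign_folds <- function(compounds, n_folds = 5L, seed = 1L) {
  uc <- unique(compounds)
  if (length(uc) < n_folds) {
    stop("need at least ", n_folds, " distinct compounds for ", n_folds,
         "-fold cross-validation, got ", length(uc))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  shuffled <- sample(uc)
  fold_of <- stats::setNames(rep_len(seq_len(n_folds), length(uc)), shuffled)
  as.integer(fold_of[compounds])
}

#' Hit rule on InChIKeys
#'
#' A candidate is a hit iff it shares the first 14 characters (the skeleton
#' block) of the InChIKey with the truth; salt/protonation differences in
#' the later blocks do not matter.
#'
#' @param candidate_inchikey,truth_inchikey Well-formed InChIKeys.
#' @return Logical.
#' @export
is_hit <- function(candidate_inchikey, truth_inchikey) {
  if (!is_valid_inchikey(candidate_inchikey)) {
    stop("malformed candidate InChIKey: ", candidate_inchikey)
  }
  if (!is_valid_inchikey(truth_inchikey)) {
    stop("malformed truth InChIKey: ", truth_inchikey)
  }
  inchikey_block1(candidate_inchikey) == inchikey_block1(truth_inchikey)
}

#' Structure-disjoint training filter
#'
#' Removes every training spectrum whose compound shares an InChIKey
#' skeleton block with any test compound, guaranteeing a structure-disjoint
#' evaluation. Training records without an InChIKey cannot be verified and
#' are dropped (counted in attribute `n_missing_inchikey`).
#'
#' @param train_spectra List of [ms2_spectrum] objects with `inchikey`
#'   metadata.
#' @param test_inchikeys Character vector of test-set InChIKeys (or bare
#'   14-character skeleton blocks).
#' @return Filtered list of spectra, with attributes `n_removed_overlap` and
#'   `n_missing_inchikey`.
#' @export
structure_disjoint_filter <- function(train_spectra, test_inchikeys) {
  test_blocks <- unique(inchikey_block1(test_inchikeys))
  keep <- logical(length(train_spectra))
  n_missing <- 0L; n_overlap <- 0L
  for (i in seq_along(train_spectra)) {
    ik <- train_spectra[[i]]$metadata$inchikey
    if (is.null(ik) || is.na(ik)) {
      n_missing <- n_missing + 1L
    } else if (inchikey_block1(ik) %in% test_blocks) {
      n_overlap <- n_overlap + 1L
    } else {
      keep[i] <- TRUE
    }
  }
  if (!any(keep) && length(train_spectra) > 0) {
    warning("structure-disjoint filter removed every training spectrum")
  }
  out <- train_spectra[keep]
  attr(out, "n_removed_overlap") <- n_overlap
  attr(out, "n_missing_inchikey") <- n_missing
  out
}

#' Top-k hit-rate table
#'
#' Fraction of challenges whose true compound ranks at or below each k.
#' Misses are encoded as `NA` ranks. Fractions are non-decreasing in k.
#'
#' @param hit_ranks Integer vector of per-challenge ranks of the true
#'   compound (`NA` = miss).
#' @param ks Cutoffs (default `c(1, 3, 5, 10)`).
#' @param modes Optional per-challenge ionization modes; adds a per-mode
#'   breakdown.
#' @return Object of class `topk_table`: data.frame with columns `k`,
#'   `fraction` (and per-mode columns when `modes` given), attribute
#'   `n_challenges`.
#' @export
topk_table <- function(hit_ranks, ks = c(1L, 3L, 5L, 10L), modes = NULL) {
  n <- length(hit_ranks)
  if (n == 0) stop("no challenges supplied")
  frac <- vapply(ks, function(k) sum(!is.na(hit_ranks) & hit_ranks <= k) / n, numeric(1))
  out <- data.frame(k = ks, fraction = frac)
  if (!is.null(modes)) {
    stopifnot(length(modes) == n)
    for (m in unique(modes)) {
      idx <- modes == m
      out[[paste0("fraction_", m)]] <-
        vapply(ks, function(k) sum(!is.na(hit_ranks[idx]) & hit_ranks[idx] <= k) / sum(idx),
               numeric(1))
    }
  }
  attr(out, "n_challenges") <- n
  class(out) <- c("topk_table", "data.frame")
  out
}
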