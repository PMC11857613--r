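#' Run the full annotation pipeline on a synthetic study
#'
#' Exercises every stage against the generator's planted ground truth:
#' preprocessing (scaling, filters, top-N capping, binning, occupancy
#' filtering), supervised bin and fingerprint-bit selection, condensation of
#' the compound fingerprint matrix, model training under the soft-Tanimoto
#' objective, candidate retrieval with decoys, score fusion, ranking, and
#' top-k evaluation with the InChIKey skeleton hit rule.
#'
#' @param dataset A synthetic study from [generate_dataset] (generated from
#'   `cfg` if omitted).
#' @param cfg A [synth_config] used when `dataset` is missing.
#' @param architecture Model architecture (default `"conv"`).
#' @param layer_plan Optional layer-plan overrides for [model_spec].
#' @param train_cfg A [train_config].
#' @param selection_cfg A [selection_config]; bin/bit selection is skipped
#'   when `run_feature_selection = FALSE` (all occupancy-retained bins and
#'   all condensed bits are used).
#' @param run_feature_selection Run the supervised selection stage.
#' @param retrieval_cfg A [retrieval_config].
#' @param use_formula_scores Fuse the generated formula scores.
#' @param preprocess_cfg A [preprocess_config].
#' @param seed Seed for the model build/training (defaults to the dataset
#'   seed).
#' @return List: `model`, `topk` ([topk_table]), `hit_ranks`, `ranked`
#'   annotation table, `selected_bins`, `selected_fps`, `condensed_map`,
#'   `validation_similarity` (1 - best validation loss when the loss is
#'   soft-Tanimoto).
#' @export
run_synthetic_pipeline <- function(dataset = NULL, cfg = synth_config(),
                                   architecture = "conv", layer_plan = list(),
                                   train_cfg = train_config(),
                                   selection_cfg = selection_config(),
                                   run_feature_selection = TRUE,
                                   retrieval_cfg = retrieval_config(),
                                   use_formula_scores = FALSE,
                                   preprocess_cfg = preprocess_config(),
                                   seed = NULL) {
  if (is.null(dataset)) dataset <- generate_dataset(cfg)
  if (is.null(seed)) seed <- dataset$cfg$seed
  pp <- preprocess_spectra(dataset$spectra, preprocess_cfg)
  spectra <- dataset$spectra[pp$kept_spectra]
  compounds <- vapply(spectra, function(s) s$metadata$compound_id, character(1))
  X_all <- as.matrix(pp$binned[, pp$retained_bins, drop = FALSE])

  # condensed fingerprint space from the true training compounds
  cmap <- build_condensed_map(dataset$compounds$fingerprints)
  Yc <- project_fingerprint(dataset$compounds$fingerprints, cmap)
  Y_all <- Yc[match(compounds, rownames(dataset$compounds$fingerprints)), , drop = FALSE]

  if (run_feature_selection) {
    bs <- score_bins(X_all, Y_all, compounds, selection_cfg)
    sel_bins_local <- select_top_bins(bs, selection_cfg$n_bins_keep)
    fs <- score_fingerprint_bits(X_all[, sel_bins_local, drop = FALSE], Y_all,
                                 compounds, selection_cfg)
    sel_fps <- select_fingerprints(fs, selection_cfg$fp_f1_threshold)
    if (length(sel_fps) == 0) sel_fps <- seq_len(ncol(Y_all))
  } else {
    sel_bins_local <- seq_len(ncol(X_all))
    sel_fps <- seq_len(ncol(Y_all))
  }
  selected_bins <- pp$retained_bins[sel_bins_local]
  X <- X_all[, sel_bins_local, drop = FALSE]
  Y <- Y_all[, sel_fps, drop = FALSE]

  spec <- model_spec(architecture, ncol(X), ncol(Y), layer_plan, seed = seed)
  model <- train_model(build_model(spec), X, Y, compounds, train_cfg)
  model$selected_bins <- selected_bins
  model$selected_fps <- sel_fps
  model$condensed_map <- cmap
  model$mode <- dataset$cfg$ionization_mode

  db_fp_cond <- project_fingerprint(dataset$db$fingerprints, cmap)[, sel_fps, drop = FALSE]
  challenge_ids <- sprintf("%s#%d", compounds, seq_along(spectra))
  ranked <- annotate_spectra(model, spectra, dataset$db$table, db_fp_cond,
                             formula_scores = if (use_formula_scores) {
                               fs <- dataset$formula_scores
                               # formula scores are keyed by compound; expand to challenges
                               do.call(rbind, lapply(seq_along(challenge_ids), function(i) {
                                 rows <- fs[fs$challenge_id == compounds[i], , drop = FALSE]
                                 if (nrow(rows) == 0) return(NULL)
                                 rows$challenge_id <- challenge_ids[i]
                                 rows
                               }))
                             } else NULL,
                             challenge_ids = challenge_ids,
                             cfg = retrieval_cfg, preprocess_cfg = preprocess_cfg)
  truth <- data.frame(
    challenge_id = challenge_ids,
    inchikey = dataset$compounds$table$inchikey[
      match(compounds, dataset$compounds$table$compound_id)],
    stringsAsFactors = FALSE)
  hr <- hit_ranks(ranked, truth)
  vs <- if (train_cfg$loss == "tanimoto" && is.finite(model$validation_loss)) {
    1 - model$validation_loss
  } else NA_real_
  list(model = model, topk = topk_table(hr), hit_ranks = hr, ranked = ranked,
       selected_bins = selected_bins, selected_fps = sel_fps,
       condensed_map = cmap, validation_similarity = vs, dataset = dataset,
       X = X, Y = Y, train_compounds = compounds)
}
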