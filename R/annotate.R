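#' Adduct table
#'
#' Mass shifts from neutral monoisotopic mass M to the measured precursor
#' m/z, pinned to 6-decimal monoisotopic values (electron mass folded in):
#' positive mode \[M+H\]+ (+1.007276), \[M+NH4\]+ (+18.033823), \[M+Na\]+
#' (+22.989218); negative mode \[M-H\]- (-1.007276), \[M+Cl\]- (+34.969401),
#' \[M+FA-H\]- (+44.998201, formic acid adduct).
#'
#' @return data.frame with columns `label`, `mode`, `mass_shift`.
#' @export
adduct_table <- function() {
  data.frame(
    label = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M-H]-", "[M+Cl]-", "[M+FA-H]-"),
    mode = c("positive", "positive", "positive", "negative", "negative", "negative"),
    mass_shift = c(1.007276, 18.033823, 22.989218, -1.007276, 34.969401, 44.998201),
    stringsAsFactors = FALSE
  )
}

#' Neutral monoisotopic mass under an adduct hypothesis
#'
#' `M = precursor_mz - mass_shift(adduct)`. Singly-charged adducts only.
#'
#' @param precursor_mz Measured precursor m/z (Da).
#' @param adduct Adduct label present in [adduct_table()].
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(precursor_mz, adduct) {
  tab <- adduct_table()
  i <- match(adduct, tab$label)
  if (is.na(i)) stop("unknown adduct: ", adduct)
  precursor_mz - tab$mass_shift[i]
}

#' Candidate-retrieval configuration
#'
#' @param ppm_tolerance Mass-window half-width in parts per million
#'   (default 5).
#' @param fp_weight,formula_weight Fusion weights for the fingerprint and
#'   normalized formula scores (defaults 0.7 / 0.3; must sum to 1).
#' @param score_space `"binary"` (Tanimoto on the binarized prediction,
#'   default) or `"probability"` (soft Tanimoto on raw probabilities).
#' @return An object of class `retrieval_config`.
#' @export
retrieval_config <- function(ppm_tolerance = 5, fp_weight = 0.7,
                             formula_weight = 0.3,
                             score_space = c("binary", "probability")) {
  score_space <- match.arg(score_space)
  stopifnot(ppm_tolerance > 0,
            isTRUE(all.equal(fp_weight + formula_weight, 1)))
  structure(list(ppm_tolerance = ppm_tolerance, fp_weight = fp_weight,
                 formula_weight = formula_weight, score_space = score_space),
            class = "retrieval_config")
}

#' Retrieve candidate compounds by precursor m/z
#'
#' For each adduct of the spectrum's ionization mode, the precursor m/z is
#' converted to a neutral-mass hypothesis and all database compounds within
#' `ppm_tolerance` (relative to the hypothesis mass) are collected. A
#' compound matching under several adducts appears once, with all matching
#' adduct labels joined by `";"`.
#'
#' @param precursor_mz Query precursor m/z (Da).
#' @param mode `"positive"` or `"negative"`.
#' @param db data.frame with at least `compound_id`, `inchikey`, `formula`,
#'   `monoisotopic_mass`.
#' @param cfg A [retrieval_config].
#' @return Subset of `db` rows with an added `adduct` column (possibly
#'   zero rows).
#' @export
retrieve_candidates <- function(precursor_mz, mode, db, cfg = retrieval_config()) {
  if (nrow(db) == 0) stop("empty compound database")
  stopifnot(mode %in% c("positive", "negative"))
  adducts <- adduct_table()
  adducts <- adducts[adducts$mode == mode, ]
  o <- order(db$monoisotopic_mass)
  sorted_mass <- db$monoisotopic_mass[o]
  hits <- list()
  for (r in seq_len(nrow(adducts))) {
    M <- precursor_mz - adducts$mass_shift[r]
    if (M <= 0) next
    tol <- M * cfg$ppm_tolerance * 1e-6
    lo <- findInterval(M - tol, sorted_mass) + 1L
    hi <- findInterval(M + tol, sorted_mass)
    if (hi < lo) next
    idx <- o[lo:hi]
    # findInterval bounds are then confirmed against the ppm criterion
    idx <- idx[abs(db$monoisotopic_mass[idx] - M) / M <= cfg$ppm_tolerance * 1e-6]
    for (i in idx) {
      key <- as.character(i)
      hits[[key]] <- c(hits[[key]], adducts$label[r])
    }
  }
  if (length(hits) == 0) {
    out <- db[0, , drop = FALSE]
    out$adduct <- character(0)
    return(out)
  }
  rows <- as.integer(names(hits))
  out <- db[rows, , drop = FALSE]
  out$adduct <- vapply(hits, paste, character(1), collapse = ";")
  rownames(out) <- NULL
  out[order(out$compound_id), , drop = FALSE]
}

#' Fingerprint similarity between a prediction and a candidate
#'
#' In `"binary"` space the prediction is binarized at 0.5 and the Tanimoto
#' similarity TP/(TP+FP+FN) is computed; in `"probability"` space the soft
#' Tanimoto `sum(p*y) / (sum(y) + sum(p) - sum(p*y))` is used. Both vectors
#' must live in the model's condensed/selected fingerprint space.
#'
#' @param predicted Probability (or binary) vector from the model.
#' @param candidate_fp Candidate's 0/1 fingerprint in the same space.
#' @param space `"binary"` or `"probability"`.
#' @return Similarity in [0,1].
#' @export
fingerprint_score <- function(predicted, candidate_fp,
                              space = c("binary", "probability")) {
  space <- match.arg(space)
  if (length(predicted) != length(candidate_fp)) {
    stop("length mismatch: prediction ", length(predicted),
         ", candidate ", length(candidate_fp))
  }
  if (space == "binary") {
    return(tanimoto_score(confusion(binarize(predicted), candidate_fp)))
  }
  A <- sum(predicted * candidate_fp)
  B <- sum(candidate_fp) + sum(predicted) - A
  if (B <= 0) 1 else A / B
}

#' Min-max normalize a score vector
#'
#' `(s - min)/(max - min)`. When all scores are equal (including a single
#' candidate) every value maps to 1, which leaves the ranking untouched
#' while keeping the fused overall score's upper bound attainable.
#'
#' @param scores Numeric vector, length >= 1.
#' @return Numeric vector in [0,1].
#' @export
minmax_normalize <- function(scores) {
  if (length(scores) == 0) stop("cannot normalize an empty score vector")
  rng <- range(scores)
  if (rng[1] == rng[2]) return(rep(1, length(scores)))
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Fuse fingerprint and formula scores
#'
#' `fp_weight * fp + formula_weight * formula_norm` (7:3 by default). A
#' candidate without a formula score keeps its fingerprint score unchanged.
#'
#' @param fp Fingerprint similarity in [0,1] (vectorized).
#' @param formula_norm Normalized formula score in [0,1], or `NA` when
#'   absent.
#' @param cfg A [retrieval_config].
#' @return Overall score in [0,1].
#' @export
combine_scores <- function(fp, formula_norm = NA_real_, cfg = retrieval_config()) {
  ifelse(is.na(formula_norm), fp,
         cfg$fp_weight * fp + cfg$formula_weight * formula_norm)
}

#' Rank scored candidates
#'
#' Descending overall score with pessimistic tie handling: every member of a
#' tied block receives the block's worst rank, so top-k counts are never
#' inflated by ties. Row order is by rank, then compound_id for stability.
#'
#' @param candidates data.frame with columns `overall_score` and
#'   `compound_id`.
#' @return The data.frame with a `rank` column, reordered.
#' @export
rank_candidates <- function(candidates) {
  stopifnot("overall_score" %in% names(candidates))
  s <- candidates$overall_score
  candidates$rank <- vapply(s, function(x) sum(s >= x), integer(1))
  candidates[order(candidates$rank, candidates$compound_id), , drop = FALSE]
}

#' Random-ranking top-k baseline
#'
#' Shuffles each challenge's candidate list `n_shuffles` times and reports
#' the mean top-k indicator for the true compound, the floor any informative
#' ranking method must beat. Converges to `mean(min(k, N)/N)` over
#' challenges with N candidates each. A challenge whose candidate list lacks
#' the true compound counts as a miss.
#'
#' @param candidate_lists List; each element is a list/data.frame with
#'   `n_candidates` and `true_present` (logical), or an integer candidate
#'   count (truth assumed present).
#' @param n_shuffles Number of random orderings (default 100).
#' @param ks Top-k cutoffs.
#' @param seed Integer seed.
#' @return Named numeric vector of top-k fractions.
#' @export
random_baseline <- function(candidate_lists, n_shuffles = 100L,
                            ks = c(1L, 3L, 5L, 10L), seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hits <- matrix(0, length(candidate_lists), length(ks))
  for (i in seq_along(candidate_lists)) {
    cl <- candidate_lists[[i]]
    if (is.numeric(cl)) cl <- list(n_candidates = cl, true_present = TRUE)
    if (!isTRUE(cl$true_present)) next  # permanent miss
    n <- cl$n_candidates
    pos <- sample.int(n, n_shuffles, replace = TRUE)
    for (j in seq_along(ks)) hits[i, j] <- mean(pos <= ks[j])
  }
  stats::setNames(colMeans(hits), paste0("top", ks))
}

#' Annotate query spectra against a compound database
#'
#' End-to-end driver: each query spectrum is preprocessed with the model's
#' grid, restricted to the model's selected bins, passed through the model;
#' candidates are retrieved by precursor m/z under the mode's adducts,
#' scored by fingerprint similarity in the model's output space, optionally
#' fused 7:3 with min-max-normalized formula scores, and ranked.
#'
#' @param model A trained `ms2fp_model` carrying `selected_bins` (and, for
#'   real fingerprints, `condensed_map`/`selected_fps`).
#' @param spectra List of query [ms2_spectrum] objects (each with exactly
#'   one precursor and an `ionization_mode`).
#' @param db Compound table (`compound_id`, `inchikey`, `formula`,
#'   `monoisotopic_mass`).
#' @param db_fingerprints Binary matrix of candidate fingerprints in the
#'   model's output space, rows aligned with `db`.
#' @param formula_scores Optional data.frame (`challenge_id`, `formula`,
#'   `score`) of external formula-prediction scores.
#' @param challenge_ids Optional per-spectrum challenge identifiers
#'   (default: the spectrum's `compound_id`).
#' @param cfg A [retrieval_config].
#' @param preprocess_cfg A [preprocess_config] (the grid must match the one
#'   the model was trained on).
#' @return data.frame with one row per (challenge, candidate):
#'   `challenge_id`, `rank`, `compound_id`, `inchikey`, `adduct`,
#'   `fp_score`, `formula_score_norm`, `overall_score`.
#' @export
annotate_spectra <- function(model, spectra, db, db_fingerprints,
                             formula_scores = NULL, challenge_ids = NULL,
                             cfg = retrieval_config(),
                             preprocess_cfg = preprocess_config()) {
  stopifnot(inherits(model, "ms2fp_model"), model$trained)
  if (is.null(model$selected_bins)) stop("model carries no selected_bins manifest")
  stopifnot(nrow(db) == nrow(db_fingerprints))
  if (is.null(challenge_ids)) {
    challenge_ids <- vapply(spectra, function(s) {
      id <- s$metadata$compound_id
      if (is.null(id)) NA_character_ else id
    }, character(1))
  }
  out <- list()
  for (q in seq_along(spectra)) {
    s <- spectra[[q]]
    mode <- s$metadata$ionization_mode
    pmz <- s$metadata$precursor_mz
    if (is.null(mode) || is.null(pmz)) next
    pmz <- as.numeric(pmz)
    sp <- scale_intensities(s, preprocess_cfg$intensity_max)
    sp <- restrict_peaks(sp, preprocess_cfg)
    sp <- select_top_peaks(sp, preprocess_cfg$top_n_peaks)
    v <- bin_spectrum(sp, preprocess_cfg$grid)[model$selected_bins]
    pred <- predict(model, v)[1, ]
    cand <- retrieve_candidates(pmz, mode, db, cfg)
    if (nrow(cand) == 0) next
    fpidx <- match(cand$compound_id, db$compound_id)
    fps <- vapply(fpidx, function(i) {
      fingerprint_score(pred, db_fingerprints[i, ], cfg$score_space)
    }, numeric(1))
    fnorm <- rep(NA_real_, nrow(cand))
    if (!is.null(formula_scores)) {
      fs <- formula_scores[formula_scores$challenge_id == challenge_ids[q], , drop = FALSE]
      if (nrow(fs) > 0) {
        raw <- fs$score[match(cand$formula, fs$formula)]
        if (any(!is.na(raw))) {
          norm_present <- minmax_normalize(raw[!is.na(raw)])
          fnorm[!is.na(raw)] <- norm_present
        }
      }
    }
    cand$fp_score <- fps
    cand$formula_score_norm <- fnorm
    cand$overall_score <- combine_scores(fps, fnorm, cfg)
    cand <- rank_candidates(cand)
    cand$challenge_id <- challenge_ids[q]
    out[[length(out) + 1L]] <- cand[, c("challenge_id", "rank", "compound_id",
                                        "inchikey", "adduct", "fp_score",
                                        "formula_score_norm", "overall_score")]
  }
  if (length(out) == 0) {
    return(data.frame(challenge_id = character(0), rank = integer(0),
                      compound_id = character(0), inchikey = character(0),
                      adduct = character(0), fp_score = numeric(0),
                      formula_score_norm = numeric(0), overall_score = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank of the true compound per challenge
#'
#' Applies the InChIKey skeleton hit rule to a ranked annotation table and
#' returns, per challenge, the best rank of any hit (`NA` = miss).
#'
#' @param ranked data.frame from [annotate_spectra].
#' @param truth data.frame with `challenge_id` and `inchikey`.
#' @return Named integer vector of ranks (`NA` for misses), one per truth
#'   row.
#' @export
hit_ranks <- function(ranked, truth) {
  out <- stats::setNames(rep(NA_integer_, nrow(truth)), truth$challenge_id)
  for (i in seq_len(nrow(truth))) {
    rows <- ranked[ranked$challenge_id == truth$challenge_id[i], , drop = FALSE]
    if (nrow(rows) == 0) next
    hit <- inchikey_block1(rows$inchikey) == inchikey_block1(truth$inchikey[i])
    if (any(hit)) out[i] <- min(rows$rank[hit])
  }
  out
}
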