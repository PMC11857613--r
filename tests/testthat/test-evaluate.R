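test_that("confusion counts are standard and length-checked", {
  cc <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]), c(TP = 2, TN = 1, FP = 0, FN = 0))
  cc2 <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cc2[c("TP", "FP", "FN", "TN")]), c(TP = 1, FP = 1, FN = 1, TN = 1))
  cc3 <- confusion(rep(0, 4), rep(1, 4))
  expect_equal(cc3$FN, 4)
  expect_error(confusion(c(1, 0), c(1)), "mismatch")
})

test_that("tanimoto, F1 and MCC follow their formulas and degenerate conventions", {
  c1 <- confusion(c(1, 1, 0), c(1, 0, 1))  # TP=1, FP=1, FN=1
  expect_equal(tanimoto_score(c1), 1 / 3)
  expect_equal(f1_score(c1), 0.5)
  expect_equal(tanimoto_score(confusion(c(1, 0), c(1, 0))), 1)
  expect_equal(tanimoto_score(confusion(c(0, 1), c(1, 0))), 0)
  expect_equal(f1_score(confusion(c(0, 0), c(0, 0))), 1)   # nothing to find, nothing claimed
  expect_equal(f1_score(confusion(c(1, 0), c(0, 0))), 0)
  expect_equal(mcc_score(confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))), 0)
  expect_equal(mcc_score(confusion(c(1, 0, 1), c(1, 0, 1))), 1)
  expect_equal(mcc_score(confusion(c(0, 1, 0), c(1, 0, 1))), -1)
  expect_equal(mcc_score(confusion(c(0, 0), c(0, 0))), 0)  # zero denominator
  # the printed-denominator variant is exposed but not bounded
  expect_equal(tanimoto_score(c1, printed_form = TRUE), 1 / (1 + 1 - 1))
})

test_that("metrics agree with brute-force recomputation on random vectors", {
  set.seed(14)
  for (i in 1:250) {
    n <- sample(5:40, 1)
    pred <- rbinom(n, 1, runif(1))
    truth <- rbinom(n, 1, runif(1))
    cc <- confusion(pred, truth)
    oracle <- brute_metrics(pred, truth)
    expect_equal(tanimoto_score(cc), oracle$tanimoto, tolerance = 1e-12)
    expect_equal(f1_score(cc), oracle$f1, tolerance = 1e-12)
    expect_equal(mcc_score(cc), oracle$mcc, tolerance = 1e-12)
    # F1 = 2T/(1+T) identity on binary inputs
    expect_equal(f1_score(cc), 2 * oracle$tanimoto / (1 + oracle$tanimoto),
                 tolerance = 1e-12)
  }
})

test_that("fold assignment blocks compounds and is deterministic", {
  comp <- rep(sprintf("c%02d", 1:12), each = 3)
  f1 <- assign_folds(comp, 4, seed = 9)
  f2 <- assign_folds(comp, 4, seed = 9)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:4)
  # replicate spectra of one compound share a fold
  for (cid in unique(comp)) {
    expect_length(unique(f1[comp == cid]), 1)
  }
  expect_error(assign_folds(c("a", "b"), 5), "at least 5")
})

test_that("the hit rule compares only the InChIKey skeleton block", {
  a <- "AAAAAAAAAAAAAA-BBBBBBBBBB-N"
  expect_true(is_hit(a, a))
  expect_true(is_hit(a, "AAAAAAAAAAAAAA-CCCCCCCCCC-M"))  # same skeleton
  expect_false(is_hit(a, "AAAAAAAAAAAAAB-BBBBBBBBBB-N"))
  expect_error(is_hit("garbage", a), "malformed")
})

test_that("the structure-disjoint filter empties the train/test skeleton intersection", {
  mk <- function(ik) ms2_spectrum(c(110, 120, 130, 140, 150), rep(20, 5),
                                  metadata = list(inchikey = ik), precursor_count = 1L)
  iks <- paste0(c("AAAAAAAAAAAAAA", "BBBBBBBBBBBBBB", "CCCCCCCCCCCCCC"),
                "-XXXXXXXXXX-N")
  train <- list(mk(iks[1]), mk(iks[2]), mk(iks[3]))
  out <- structure_disjoint_filter(train, iks[2])
  expect_length(out, 2)
  blocks <- vapply(out, function(s) inchikey_block1(s$metadata$inchikey), character(1))
  expect_length(intersect(blocks, inchikey_block1(iks[2])), 0)
  # disjoint sets: identity
  expect_length(structure_disjoint_filter(train, "ZZZZZZZZZZZZZZ-XXXXXXXXXX-N"), 3)
  # full overlap: empty with a warning
  expect_warning(none <- structure_disjoint_filter(train, iks), "every training spectrum")
  expect_length(none, 0)
  # missing InChIKey records are dropped and counted
  noik <- ms2_spectrum(110, 5)
  out2 <- structure_disjoint_filter(list(noik, mk(iks[1])), iks[2])
  expect_length(out2, 1)
  expect_equal(attr(out2, "n_missing_inchikey"), 1L)
})

test_that("top-k tables count hits at rank <= k and are monotone in k", {
  tk <- topk_table(c(1, 2, 7), ks = c(1, 3, 5, 10))
  expect_equal(tk$fraction, c(1 / 3, 2 / 3, 2 / 3, 1))
  expect_equal(topk_table(c(NA, NA))$fraction, rep(0, 4))
  # property: monotone in k, invariant under relabeling, on random rank sets
  set.seed(8)
  for (i in 1:100) {
    ranks <- sample(c(1:20, NA), 12, replace = TRUE)
    fr <- topk_table(ranks)$fraction
    expect_true(all(diff(fr) >= 0))
    expect_equal(topk_table(sample(ranks))$fraction, fr)
  }
  expect_error(topk_table(integer(0)), "no challenges")
  # per-mode breakdown
  tk2 <- topk_table(c(1, 5, NA, 2), modes = c("positive", "positive", "negative", "negative"))
  expect_equal(tk2$fraction_positive, c(0.5, 0.5, 1, 1))
  expect_equal(tk2$fraction_negative, c(0, 0.5, 0.5, 0.5))
})

test_that("cross-validated metrics are deterministic and near zero MCC under label shuffling", {
  set.seed(55)
  n_comp <- 15L; reps <- 2L; n_bits <- 6L
  fp <- matrix(rbinom(n_comp * n_bits, 1, 0.5), n_comp, n_bits)
  fp[rowSums(fp) == 0, 1] <- 1L
  rows <- rep(seq_len(n_comp), each = reps)
  X <- fp[rows, , drop = FALSE] * 100
  comp <- sprintf("c%02d", rows)
  spec <- model_spec("dense", n_bits, n_bits, list(hidden = c(10L, 8L)), seed = 2L)
  cfg <- train_config(epochs = 60L, patience = 60L, validation_fraction = 0)
  r1 <- crossval_metrics(spec, X, fp[rows, ], comp, n_folds = 3, seed = 3, config = cfg)
  r2 <- crossval_metrics(spec, X, fp[rows, ], comp, n_folds = 3, seed = 3, config = cfg)
  expect_identical(r1$summary, r2$summary)
  expect_gt(r1$summary[["f1"]], 0.7)  # identity mapping is recoverable
  # shuffled labels destroy the signal: mean per-bit MCC near 0
  set.seed(4)
  Yshuf <- fp[sample(nrow(fp)), ][rows, , drop = FALSE]
  r3 <- crossval_metrics(spec, X, Yshuf, comp, n_folds = 3, seed = 3, config = cfg)
  expect_lt(abs(r3$summary[["mean_mcc"]]), 0.15)
})
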