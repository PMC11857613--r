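test_that("adduct arithmetic recovers neutral masses and round-trips", {
  # glucose [M+H]+ and [M-H]- agree on the neutral mass
  expect_equal(neutral_mass(181.070665, "[M+H]+"), 180.063389, tolerance = 1e-6)
  expect_equal(neutral_mass(179.056113, "[M-H]-"), 180.063389, tolerance = 1e-6)
  tab <- adduct_table()
  for (r in seq_len(nrow(tab))) {
    M <- 250.1
    mz <- M + tab$mass_shift[r]
    expect_equal(neutral_mass(mz, tab$label[r]), M, tolerance = 1e-9)
  }
  expect_error(neutral_mass(100, "[M+X]+"), "unknown adduct")
})

test_that("retrieval honors the 5 ppm window on the toy database", {
  db <- toy_db()
  hits <- retrieve_candidates(181.070664, "positive", db)
  expect_equal(hits$compound_id, "C1")  # the 180.065 entry is ~9 ppm away
  hits20 <- retrieve_candidates(181.070664, "positive", db,
                                retrieval_config(ppm_tolerance = 20))
  expect_setequal(hits20$compound_id, c("C1", "C2"))
  none <- retrieve_candidates(500.0, "positive", db)
  expect_equal(nrow(none), 0)
  expect_error(retrieve_candidates(181.07, "positive", db[0, ]), "empty")
})

test_that("retrieval equals the brute-force linear scan on random toy databases", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    db <- data.frame(
      compound_id = sprintf("X%03d", 1:n),
      inchikey = rep("AAAAAAAAAAAAAA-BBBBBBBBBB-N", n),
      formula = rep("C6H12O6", n),
      monoisotopic_mass = runif(n, 100, 900),
      stringsAsFactors = FALSE
    )
    mode <- sample(c("positive", "negative"), 1)
    # centre queries near db masses so windows are sometimes populated
    base <- sample(db$monoisotopic_mass, 1)
    shift <- adduct_table()
    shift <- shift$mass_shift[sample(which(shift$mode == mode), 1)]
    mz <- base + shift + runif(1, -0.01, 0.01)
    got <- retrieve_candidates(mz, mode, db)
    expect_equal(sort(got$compound_id), brute_force_retrieve(mz, mode, db, 5))
    # widening the tolerance is monotone (superset)
    wide <- retrieve_candidates(mz, mode, db, retrieval_config(ppm_tolerance = 25))
    expect_true(all(got$compound_id %in% wide$compound_id))
  }
})

test_that("a record matching under two adducts appears once with both tags", {
  # one compound whose mass matches a query under [M+H]+ and another under [M+Na]+
  M <- 300
  db <- data.frame(
    compound_id = c("A", "B"),
    inchikey = rep("AAAAAAAAAAAAAA-BBBBBBBBBB-N", 2),
    formula = rep("C10H10", 2),
    monoisotopic_mass = c(M, M - (22.989218 - 1.007276)),
    stringsAsFactors = FALSE
  )
  got <- retrieve_candidates(M + 1.007276, "positive", db)
  expect_equal(nrow(got), 2)
  expect_equal(got$adduct[got$compound_id == "A"], "[M+H]+")
  expect_equal(got$adduct[got$compound_id == "B"], "[M+Na]+")
  # same record under two adducts: make both hypotheses land on one mass
  db1 <- db[1, ]
  wide <- retrieval_config(ppm_tolerance = 80000)
  got2 <- retrieve_candidates(M + 1.007276, "positive", db1, wide)
  expect_equal(nrow(got2), 1)
  expect_true(grepl(";", got2$adduct))
})

test_that("fingerprint scoring matches Tanimoto in both score spaces", {
  expect_equal(fingerprint_score(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(fingerprint_score(c(1, 0), c(0, 1)), 0)
  expect_equal(fingerprint_score(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  # probability space uses the soft overlap
  expect_equal(fingerprint_score(c(0.5, 0.5), c(1, 0), space = "probability"),
               0.5 / (1 + 1 - 0.5))
  expect_error(fingerprint_score(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("min-max normalization maps to [0,1] with the all-equal convention", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(5), 1)
  expect_equal(minmax_normalize(c(3, 3, 3)), c(1, 1, 1))
  expect_equal(minmax_normalize(c(-3, 0, 3, 9)), c(0, 0.25, 0.5, 1))
  expect_error(minmax_normalize(numeric(0)), "empty")
})

test_that("score fusion is 7:3 with fingerprint-only fallback and is monotone", {
  cfg <- retrieval_config()
  expect_equal(combine_scores(0.8, 0.2, cfg), 0.62)
  expect_equal(combine_scores(0.5, NA, cfg), 0.5)
  expect_equal(combine_scores(1, 1, cfg), 1)
  # monotone in each argument with the other fixed
  f <- seq(0, 1, by = 0.1)
  expect_true(all(diff(combine_scores(f, 0.4, cfg)) > 0))
  expect_true(all(diff(combine_scores(0.4, f, cfg)) > 0))
})

test_that("ranking is descending with pessimistic shared ranks for ties", {
  cand <- data.frame(compound_id = c("a", "b", "c"),
                     overall_score = c(0.9, 0.2, 0.7))
  r <- rank_candidates(cand)
  expect_equal(r$rank[match(c("a", "b", "c"), r$compound_id)], c(1L, 3L, 2L))
  tie <- data.frame(compound_id = c("a", "b", "c"),
                    overall_score = c(0.9, 0.9, 0.1))
  rt <- rank_candidates(tie)
  expect_equal(rt$rank[match(c("a", "b"), rt$compound_id)], c(2L, 2L))
  expect_equal(rt$rank[rt$compound_id == "c"], 3L)
  single <- rank_candidates(data.frame(compound_id = "x", overall_score = 0.4))
  expect_equal(single$rank, 1L)
})

test_that("the random baseline converges to min(k, N)/N and is seed-stable", {
  lists <- replicate(40, 10L, simplify = FALSE)
  fr <- random_baseline(lists, n_shuffles = 100, ks = c(1, 3, 5, 10), seed = 2)
  # closed form: min(k, 10)/10; 3 s.e. of a mean of 4000 Bernoulli draws
  for (i in seq_along(c(1, 3, 5, 10))) {
    k <- c(1, 3, 5, 10)[i]
    p <- min(k, 10) / 10
    se <- sqrt(p * (1 - p) / (40 * 100))
    expect_lt(abs(fr[[i]] - p), max(3 * se, 1e-12))
  }
  expect_equal(fr[["top10"]], 1)  # k >= N
  expect_identical(fr, random_baseline(lists, n_shuffles = 100, ks = c(1, 3, 5, 10), seed = 2))
  # a challenge without the true compound counts as a miss
  fr2 <- random_baseline(list(list(n_candidates = 10, true_present = FALSE)),
                         n_shuffles = 50, ks = 10, seed = 1)
  expect_equal(fr2[["top10"]], 0)
})
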