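test_that("compound generation is deterministic with unique identifiers and planted activity", {
  cfg <- synth_config(n_compounds = 50, seed = 7)
  c1 <- generate_compounds(cfg)
  c2 <- generate_compounds(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$table), 50)
  expect_false(anyDuplicated(c1$table$compound_id) > 0)
  expect_false(anyDuplicated(c1$table$inchikey) > 0)
  expect_true(all(is_valid_inchikey(c1$table$inchikey)))
  expect_true(all(c1$table$monoisotopic_mass >= 150 &
                    c1$table$monoisotopic_mass <= 900))
  expect_true(all(rowSums(c1$fingerprints) >= 1))
})

test_that("mean fingerprint activity matches the configured rate (binomial check)", {
  cfg <- synth_config(n_compounds = 1000, n_bits = 64, bits_per_compound = 8, seed = 3)
  cc <- generate_compounds(cfg)
  p <- 8 / 64
  target <- 1000 * 64 * p
  se <- sqrt(1000 * 64 * p * (1 - p))
  expect_lt(abs(sum(cc$fingerprints) - target), 3 * se)
})

test_that("noiseless spectra are deterministic replicas matching the codebook count", {
  cfg <- synth_config(n_compounds = 5, n_spectra_per_compound = 2,
                      noise_peak_rate = 0, intensity_noise_sd = 0, seed = 11)
  cc <- generate_compounds(cfg)
  sp <- generate_spectra(cc, cfg)
  expect_length(sp, 10)
  # two spectra of one compound are identical under zero noise
  expect_equal(sp[[1]]$peaks, sp[[2]]$peaks)
  # k active bits emit exactly k * peaks_per_bit peaks
  k <- sum(cc$fingerprints[1, ])
  expect_equal(nrow(sp[[1]]$peaks), k * cfg$peaks_per_bit)
  # exactly one precursor, proton-shifted from the compound mass
  expect_equal(sp[[1]]$precursor_count, 1L)
  expect_equal(as.numeric(sp[[1]]$metadata$precursor_mz),
               cc$table$monoisotopic_mass[1] + 1.007276, tolerance = 1e-9)
  # generated spectra satisfy the spectrum-level filters by construction
  expect_true(all(vapply(sp, spectrum_passes_filters, logical(1),
                         cfg = preprocess_config())))
})

test_that("generated spectra survive an MSP round-trip", {
  cfg <- synth_config(n_compounds = 3, seed = 2)
  sp <- generate_spectra(generate_compounds(cfg), cfg)
  path <- tempfile(fileext = ".msp")
  write_msp(sp, path)
  back <- read_msp(path)
  expect_length(back, length(sp))
  expect_equal(back[[1]]$peaks$mz, sp[[1]]$peaks$mz, tolerance = 1e-5)
  expect_equal(back[[1]]$metadata$inchikey, sp[[1]]$metadata$inchikey)
})

test_that("decoys sit at the configured Hamming distance with novel skeletons", {
  cfg <- synth_config(n_compounds = 8, decoys_per_compound = 3,
                      decoy_bit_flips = 4, seed = 5)
  cc <- generate_compounds(cfg)
  db <- generate_database(cc, cfg)
  expect_equal(nrow(db$table), 8 * 4)
  dec <- db$table[db$table$is_decoy, ]
  true_blocks <- inchikey_block1(cc$table$inchikey)
  expect_length(intersect(inchikey_block1(dec$inchikey), true_blocks), 0)
  for (i in seq_len(nrow(dec))) {
    parent_fp <- cc$fingerprints[dec$parent[i], ]
    d_fp <- db$fingerprints[dec$compound_id[i], ]
    expect_equal(sum(parent_fp != d_fp), 4)
  }
})

test_that("decoy retrievability follows the configured ppm offsets", {
  # offsets below 5 ppm: every decoy is retrieved with its true compound
  cfg_in <- synth_config(n_compounds = 6, decoys_per_compound = 2,
                         decoy_ppm_offset_range = c(0.5, 4), seed = 9)
  cc <- generate_compounds(cfg_in)
  db_in <- generate_database(cc, cfg_in)
  for (i in seq_len(nrow(cc$table))) {
    mz <- cc$table$monoisotopic_mass[i] + 1.007276
    got <- retrieve_candidates(mz, "positive", db_in$table)
    members <- db_in$table$compound_id[db_in$table$parent == cc$table$compound_id[i]]
    expect_true(all(members %in% got$compound_id))
  }
  # offsets above 5 ppm: retrieval returns only true compounds
  cfg_out <- synth_config(n_compounds = 6, decoys_per_compound = 2,
                          decoy_ppm_offset_range = c(8, 20), seed = 9)
  db_out <- generate_database(cc, cfg_out)
  for (i in seq_len(nrow(cc$table))) {
    mz <- cc$table$monoisotopic_mass[i] + 1.007276
    got <- retrieve_candidates(mz, "positive", db_out$table)
    expect_false(any(db_out$table$is_decoy[match(got$compound_id,
                                                 db_out$table$compound_id)]))
  }
})

test_that("formula scores favor the true formula and honor the missing fraction", {
  cfg <- synth_config(n_compounds = 20, seed = 13)
  cc <- generate_compounds(cfg)
  db <- generate_database(cc, cfg)
  fs0 <- generate_formula_scores(db, cfg, missing_true_fraction = 0)
  expect_identical(fs0, generate_formula_scores(db, cfg, missing_true_fraction = 0))
  true_rows <- fs0$formula %in% cc$table$formula
  expect_equal(length(unique(fs0$challenge_id[true_rows])), 20)
  expect_gt(mean(fs0$score[true_rows]), mean(fs0$score[!true_rows]))
  fs1 <- generate_formula_scores(db, cfg, missing_true_fraction = 1)
  for (p in unique(fs1$challenge_id)) {
    tf <- cc$table$formula[cc$table$compound_id == p]
    expect_false(tf %in% fs1$formula[fs1$challenge_id == p])
  }
})

test_that("a written dataset is a set of readable plain-text files", {
  dir <- tempfile("synthdir")
  ds <- generate_dataset(synth_config(n_compounds = 4, seed = 21))
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("spectra.msp", "compounds.tsv",
                                               "truth.csv", "formula_scores.csv")))))
  tab <- read.delim(file.path(dir, "compounds.tsv"))
  expect_equal(nrow(tab), nrow(ds$db$table))
  expect_length(read_msp(file.path(dir, "spectra.msp")), length(ds$spectra))
})
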