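# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

msp_two_record_fixture <- function() {
  c("Name: alpha",
    "Formula: C6H12O6",
    "InChIKey: WQZGKKKJIJFFOK-GASJEMHNSA-N",
    "PrecursorMZ: 181.07066",
    "Precursor_type: [M+H]+",
    "Ion_mode: P",
    "Num Peaks: 5",
    "101.1 10", "120.5 40", "130.2 100", "150.0 25", "160.9 5",
    "",
    "NAME: beta",
    "FORMULA: C7H8N4O2",
    "INCHIKEY: YAPQBXQYLJRXSA-UHFFFAOYSA-N",
    "PRECURSORMZ: 195.08765",
    "ION_MODE: negative",
    "Num peaks: 7",
    "105.5\t12", "110.0\t30", "115.2\t55", "140.8\t100", "155.1\t70",
    "170.3\t22", "180.0\t9",
    "")
}

write_msp_fixture <- function(lines = msp_two_record_fixture()) {
  path <- tempfile(fileext = ".msp")
  writeLines(lines, path)
  path
}

mgf_single_block_fixture <- function() {
  c("BEGIN IONS",
    "TITLE=glucose",
    "PEPMASS=181.0707 12345.6",
    "CHARGE=1+",
    "SMILES=OCC1OC(O)C(O)C(O)C1O",
    "110.1 20",
    "133.2 100",
    "145.0 45",
    "END IONS")
}

# tiny compound table for retrieval tests
toy_db <- function() {
  data.frame(
    compound_id = c("C1", "C2", "C3"),
    inchikey = c("AAAAAAAAAAAAAA-BBBBBBBBBB-N",
                 "CCCCCCCCCCCCCC-DDDDDDDDDD-N",
                 "EEEEEEEEEEEEEE-FFFFFFFFFF-N"),
    formula = c("C6H12O6", "C6H12O7", "C12H22O11"),
    monoisotopic_mass = c(180.063388, 180.065000, 342.116212),
    stringsAsFactors = FALSE
  )
}

# brute-force retrieval oracle: linear scan over all db rows and mode adducts
brute_force_retrieve <- function(precursor_mz, mode, db, ppm) {
  tab <- adduct_table()
  tab <- tab[tab$mode == mode, ]
  hits <- character(0)
  for (r in seq_len(nrow(tab))) {
    M <- precursor_mz - tab$mass_shift[r]
    if (M <= 0) next
    ok <- abs(db$monoisotopic_mass - M) / M <= ppm * 1e-6
    hits <- c(hits, db$compound_id[ok])
  }
  sort(unique(hits))
}

# brute-force metric oracle from raw vectors
brute_metrics <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  tan <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  f1 <- if (tp == 0) { if (fp == 0 && fn == 0) 1 else 0 } else {
    p <- tp / (tp + fp); r <- tp / (tp + fn); 2 * p * r / (p + r)
  }
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
  list(tanimoto = tan, f1 = f1, mcc = mcc)
}

# numeric gradient of the training loss wrt one parameter entry
numeric_grad <- function(spec, params, X, Y, loss, k, idx, h = 1e-5) {
  ns <- asNamespace("ms2fp")
  f <- function(v) {
    p <- params; p[[k]][idx] <- v
    ns$.loss_grad(Y, ns$.nn_forward(spec, p, X)$P, loss)$loss
  }
  v0 <- params[[k]][idx]
  (f(v0 + h) - f(v0 - h)) / (2 * h)
}

# cache for the expensive default-scale synthetic study shared by the
# acceptance tests
.fixture_env <- new.env(parent = emptyenv())

default_synth_training_data <- function() {
  if (!is.null(.fixture_env$std)) return(.fixture_env$std)
  ds <- generate_dataset(synth_config(seed = 7))
  pp <- preprocess_spectra(ds$spectra)
  spectra <- ds$spectra[pp$kept_spectra]
  comp <- vapply(spectra, function(s) s$metadata$compound_id, character(1))
  X <- as.matrix(pp$binned[, pp$retained_bins, drop = FALSE])
  cmap <- build_condensed_map(ds$compounds$fingerprints)
  Y <- project_fingerprint(ds$compounds$fingerprints, cmap)
  Y <- Y[match(comp, rownames(ds$compounds$fingerprints)), , drop = FALSE]
  .fixture_env$std <- list(dataset = ds, pp = pp, spectra = spectra,
                           compounds = comp, X = X, Y = Y, cmap = cmap)
  .fixture_env$std
}
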