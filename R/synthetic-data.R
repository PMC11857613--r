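#' Synthetic-data configuration
#'
#' The generator plants a known fingerprint-to-fragment rule: a global
#' per-seed codebook assigns each fingerprint bit `peaks_per_bit` fixed
#' fragment m/z values (distinct bins in 100-1010 Da), and every spectrum of
#' a compound emits the peaks of its active bits with log-normal intensity
#' jitter plus Poisson-distributed spurious peaks. Decoy database entries
#' sit at controlled ppm offsets from their true compound and at a fixed
#' fingerprint Hamming distance, with a different InChIKey skeleton. This
#' makes the bin-to-bit mapping learnable by construction and gives every
#' pipeline stage a ground truth.
#'
#' @param n_compounds Number of true compounds.
#' @param n_bits Fingerprint length.
#' @param bits_per_compound Mean number of active bits (i.i.d. Bernoulli).
#' @param n_spectra_per_compound Replicate spectra per compound.
#' @param peaks_per_bit Characteristic peaks emitted per active bit.
#' @param noise_peak_rate Poisson mean of spurious peaks per spectrum.
#' @param intensity_noise_sd SD of the log-normal relative intensity jitter.
#' @param decoys_per_compound Decoy database entries per true compound.
#' @param decoy_bit_flips Exact Hamming distance of decoy fingerprints.
#' @param decoy_ppm_offset_range Range (ppm) of decoy mass offsets; the
#'   default (0.5, 4) keeps decoys inside a 5 ppm retrieval window so
#'   ranking is decided by fingerprint similarity.
#' @param ionization_mode Mode of the generated spectra.
#' @param seed Integer seed; every generator is fully deterministic given it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_compounds = 50L, n_bits = 64L, bits_per_compound = 8,
                         n_spectra_per_compound = 4L, peaks_per_bit = 2L,
                         noise_peak_rate = 0, intensity_noise_sd = 0,
                         decoys_per_compound = 5L, decoy_bit_flips = 4L,
                         decoy_ppm_offset_range = c(0.5, 4),
                         ionization_mode = c("positive", "negative"),
                         seed = 1L) {
  ionization_mode <- match.arg(ionization_mode)
  stopifnot(n_compounds > 0, n_bits > 0, bits_per_compound > 0,
            n_spectra_per_compound > 0, peaks_per_bit > 0,
            noise_peak_rate >= 0, intensity_noise_sd >= 0,
            decoys_per_compound > 0, decoy_bit_flips >= 1,
            decoy_bit_flips <= n_bits,
            length(decoy_ppm_offset_range) == 2,
            decoy_ppm_offset_range[1] <= decoy_ppm_offset_range[2])
  structure(list(n_compounds = as.integer(n_compounds), n_bits = as.integer(n_bits),
                 bits_per_compound = bits_per_compound,
                 n_spectra_per_compound = as.integer(n_spectra_per_compound),
                 peaks_per_bit = as.integer(peaks_per_bit),
                 noise_peak_rate = noise_peak_rate,
                 intensity_noise_sd = intensity_noise_sd,
                 decoys_per_compound = as.integer(decoys_per_compound),
                 decoy_bit_flips = as.integer(decoy_bit_flips),
                 decoy_ppm_offset_range = decoy_ppm_offset_range,
                 ionization_mode = ionization_mode, seed = as.integer(seed)),
            class = "synth_config")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.random_inchikey <- function(n) {
  block <- function(k) {
    replicate(n, paste(sample(LETTERS, k, replace = TRUE), collapse = ""))
  }
  paste0(block(14L), "-", block(10L), "-", block(1L))
}

.random_formula <- function(n) {
  sprintf("C%dH%dN%dO%d", sample(5:30, n, TRUE), sample(6:40, n, TRUE),
          sample(0:5, n, TRUE), sample(0:8, n, TRUE))
}

#' Generate synthetic compounds
#'
#' Compounds carry unique identifiers, InChIKey-like 14-10-1 keys, random
#' formulas, monoisotopic masses uniform in [150, 900] Da and i.i.d.
#' Bernoulli fingerprints with mean activity `bits_per_compound/n_bits`
#' (at least one active bit is guaranteed per compound).
#'
#' @param cfg A [synth_config].
#' @return List: `table` (data.frame `compound_id`, `inchikey`, `formula`,
#'   `monoisotopic_mass`) and `fingerprints` (n_compounds x n_bits binary
#'   matrix, rownames = compound ids).
#' @export
generate_compounds <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_compounds
    ids <- sprintf("SYN%04d", seq_len(n))
    ik <- .random_inchikey(n)
    while (anyDuplicated(ik) || anyDuplicated(inchikey_block1(ik))) {
      dup <- duplicated(inchikey_block1(ik)) | duplicated(ik)
      ik[dup] <- .random_inchikey(sum(dup))
    }
    fp <- matrix(stats::rbinom(n * cfg$n_bits, 1L,
                               min(1, cfg$bits_per_compound / cfg$n_bits)),
                 n, cfg$n_bits)
    empty <- rowSums(fp) == 0
    if (any(empty)) fp[cbind(which(empty), sample.int(cfg$n_bits, sum(empty), TRUE))] <- 1L
    rownames(fp) <- ids
    list(table = data.frame(compound_id = ids, inchikey = ik,
                            formula = .random_formula(n),
                            monoisotopic_mass = stats::runif(n, 150, 900),
                            stringsAsFactors = FALSE),
         fingerprints = fp)
  })
}

#' The planted bit-to-fragment codebook
#'
#' Drawn once per seed: each fingerprint bit receives `peaks_per_bit`
#' distinct fragment m/z values on the default grid's bin centers, all
#' within 100-1010 Da. Shared across all compounds so the mapping is
#' learnable.
#'
#' @param cfg A [synth_config].
#' @return Numeric matrix (n_bits x peaks_per_bit) of m/z values.
#' @export
fragment_codebook <- function(cfg) {
  .with_seed(cfg$seed + 1000L, {
    grid <- bin_grid()
    n_mz <- cfg$n_bits * cfg$peaks_per_bit
    bins <- sample.int(grid$n_bins - 1L, n_mz)  # distinct bins, last bin spared
    mz <- grid$mass_low + (bins - 1L) * grid$width + grid$width / 2
    matrix(mz, cfg$n_bits, cfg$peaks_per_bit)
  })
}

#' Generate synthetic MS/MS spectra
#'
#' Each spectrum of a compound emits, for every active fingerprint bit, the
#' codebook's characteristic peaks with intensity `100 * exp(N(0, sd))`,
#' plus `Poisson(noise_peak_rate)` spurious peaks at uniform m/z with
#' uniform (1, 50) intensities, and exactly one precursor at the compound
#' mass shifted by a proton (sign per ionization mode).
#'
#' @param compounds Output of [generate_compounds].
#' @param cfg A [synth_config].
#' @return List of [ms2_spectrum] objects
#'   (`n_compounds * n_spectra_per_compound`).
#' @export
generate_spectra <- function(compounds, cfg) {
  codebook <- fragment_codebook(cfg)
  proton <- 1.007276
  .with_seed(cfg$seed + 2000L, {
    spectra <- list()
    for (i in seq_len(nrow(compounds$table))) {
      active <- which(compounds$fingerprints[i, ] == 1L)
      base_mz <- as.vector(codebook[active, , drop = FALSE])
      mass <- compounds$table$monoisotopic_mass[i]
      pmz <- if (cfg$ionization_mode == "positive") mass + proton else mass - proton
      for (r in seq_len(cfg$n_spectra_per_compound)) {
        inten <- 100 * exp(stats::rnorm(length(base_mz), 0, cfg$intensity_noise_sd))
        mz <- base_mz
        n_noise <- stats::rpois(1, cfg$noise_peak_rate)
        if (n_noise > 0) {
          mz <- c(mz, stats::runif(n_noise, 100, 1010))
          inten <- c(inten, stats::runif(n_noise, 1, 50))
        }
        spectra[[length(spectra) + 1L]] <- ms2_spectrum(
          mz, inten,
          metadata = list(
            compound_id = compounds$table$compound_id[i],
            inchikey = compounds$table$inchikey[i],
            formula = compounds$table$formula[i],
            precursor_mz = pmz,
            adduct = if (cfg$ionization_mode == "positive") "[M+H]+" else "[M-H]-",
            ionization_mode = cfg$ionization_mode,
            collision_energy = "35", source = "synthetic"),
          precursor_count = 1L)
      }
    }
    spectra
  })
}

#' Generate a candidate database with decoys
#'
#' Every true compound contributes itself plus `decoys_per_compound` decoys
#' whose masses are offset by a uniform draw from
#' `decoy_ppm_offset_range` ppm (random sign) and whose fingerprints sit at
#' exactly `decoy_bit_flips` Hamming distance; decoy InChIKey skeletons
#' always differ from every true compound's.
#'
#' @param compounds Output of [generate_compounds].
#' @param cfg A [synth_config].
#' @return List: `table` (data.frame with `compound_id`, `inchikey`,
#'   `formula`, `monoisotopic_mass`, `is_decoy`, `parent`) and
#'   `fingerprints` (rows aligned with `table`).
#' @export
generate_database <- function(compounds, cfg) {
  .with_seed(cfg$seed + 3000L, {
    tab <- compounds$table
    n <- nrow(tab)
    true_blocks <- inchikey_block1(tab$inchikey)
    rows <- data.frame(compound_id = tab$compound_id, inchikey = tab$inchikey,
                       formula = tab$formula,
                       monoisotopic_mass = tab$monoisotopic_mass,
                       is_decoy = FALSE, parent = tab$compound_id,
                       stringsAsFactors = FALSE)
    fps <- compounds$fingerprints
    for (i in seq_len(n)) {
      for (d in seq_len(cfg$decoys_per_compound)) {
        ppm <- stats::runif(1, cfg$decoy_ppm_offset_range[1],
                            cfg$decoy_ppm_offset_range[2]) * sample(c(-1, 1), 1)
        ik <- .random_inchikey(1L)
        while (inchikey_block1(ik) %in% true_blocks) ik <- .random_inchikey(1L)
        fp <- compounds$fingerprints[i, ]
        flip <- sample.int(cfg$n_bits, cfg$decoy_bit_flips)
        fp[flip] <- 1L - fp[flip]
        rows <- rbind(rows, data.frame(
          compound_id = sprintf("%s-D%02d", tab$compound_id[i], d),
          inchikey = ik, formula = .random_formula(1L),
          monoisotopic_mass = tab$monoisotopic_mass[i] * (1 + ppm * 1e-6),
          is_decoy = TRUE, parent = tab$compound_id[i],
          stringsAsFactors = FALSE))
        fps <- rbind(fps, fp)
      }
    }
    rownames(fps) <- rows$compound_id
    list(table = rows, fingerprints = fps)
  })
}

#' Generate external formula-prediction scores
#'
#' Emulates a formula-prediction tool's per-challenge candidate scores: the
#' true compound's formula draws from a higher-mean distribution
#' (N(0.9, 0.05)) than decoy formulas (N(0.4, 0.15)), and a configurable
#' fraction of challenges lack the true formula entirely (downstream fusion
#' must then fall back to fingerprint-only scoring).
#'
#' @param db Output of [generate_database].
#' @param cfg A [synth_config].
#' @param missing_true_fraction Fraction of challenges whose true-formula
#'   row is withheld.
#' @return data.frame (`challenge_id`, `formula`, `score`); challenge ids
#'   are the true compound ids.
#' @export
generate_formula_scores <- function(db, cfg, missing_true_fraction = 0) {
  .with_seed(cfg$seed + 4000L, {
    parents <- unique(db$table$parent)
    drop_true <- stats::runif(length(parents)) < missing_true_fraction
    names(drop_true) <- parents
    out <- list()
    for (p in parents) {
      members <- db$table[db$table$parent == p, , drop = FALSE]
      sc <- ifelse(members$is_decoy,
                   stats::rnorm(nrow(members), 0.4, 0.15),
                   stats::rnorm(nrow(members), 0.9, 0.05))
      keep <- !(drop_true[p] & !members$is_decoy)
      out[[p]] <- data.frame(challenge_id = p, formula = members$formula[keep],
                             score = pmin(pmax(sc[keep], 0), 1),
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: compounds, spectra, decoy database, truth table and
#' formula scores from one config.
#'
#' @param cfg A [synth_config].
#' @param missing_true_fraction Passed to [generate_formula_scores].
#' @return List with `compounds`, `spectra`, `db`, `truth` (data.frame
#'   `challenge_id`, `inchikey`), `formula_scores`, and `cfg`.
#' @export
generate_dataset <- function(cfg = synth_config(), missing_true_fraction = 0) {
  compounds <- generate_compounds(cfg)
  spectra <- generate_spectra(compounds, cfg)
  db <- generate_database(compounds, cfg)
  truth <- data.frame(challenge_id = compounds$table$compound_id,
                      inchikey = compounds$table$inchikey,
                      stringsAsFactors = FALSE)
  list(compounds = compounds, spectra = spectra, db = db, truth = truth,
       formula_scores = generate_formula_scores(db, cfg), cfg = cfg)
}

#' Write a synthetic study to plain-text files
#'
#' Writes `spectra.msp`, `compounds.tsv` (with fingerprint columns),
#' `truth.csv` and `formula_scores.csv` under `dir`.
#'
#' @param dataset Output of [generate_dataset].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_msp(dataset$spectra, file.path(dir, "spectra.msp"))
  tab <- cbind(dataset$db$table,
               as.data.frame(dataset$db$fingerprints,
                             col.names = paste0("fp", seq_len(ncol(dataset$db$fingerprints)))))
  utils::write.table(tab, file.path(dir, "compounds.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(dataset$formula_scores, file.path(dir, "formula_scores.csv"),
                   row.names = FALSE)
  invisible(dir)
}
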