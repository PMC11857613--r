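#' Fixed m/z bin grid
#'
#' The binning scheme used throughout: bins of `width` Da covering
#' `[mass_low, mass_high]`, closed on both ends. With the defaults
#' (100-1010 Da, 0.01 Da) the grid has exactly 91,001 bins; a peak at
#' exactly `mass_high` is assigned to the last bin.
#'
#' @param mass_low,mass_high Grid bounds in Da.
#' @param width Bin width in Da.
#' @return An object of class `bin_grid` with fields `mass_low`, `mass_high`,
#'   `width`, `n_bins`.
#' @export
bin_grid <- function(mass_low = 100, mass_high = 1010, width = 0.01) {
  stopifnot(mass_high > mass_low, width > 0)
  # round before floor so representation error in (high-low)/width cannot
  # drop or add a bin
  n_bins <- as.integer(floor(round((mass_high - mass_low) / width, 6))) + 1L
  structure(list(mass_low = mass_low, mass_high = mass_high,
                 width = width, n_bins = n_bins),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> [%g, %g] Da, width %g Da, %d bins\n",
              x$mass_low, x$mass_high, x$width, x$n_bins))
  invisible(x)
}

#' Preprocessing configuration
#'
#' Defaults reproduce the standard processing chain: scale intensities to a
#' 0-100 range, keep spectra with exactly one precursor mass and at least 5
#' peaks, drop peaks outside the grid range or with scaled intensity below 1,
#' keep the 20 most intense peaks, bin, and drop bins occupied by fewer than
#' 0.1% of the training spectra.
#'
#' @param intensity_max Scaling ceiling for relative intensities.
#' @param min_peaks Minimum raw peak count for a spectrum to be retained.
#' @param top_n_peaks Number of most-intense peaks kept per spectrum.
#' @param min_scaled_intensity Minimum scaled intensity for a peak to be kept.
#' @param occupancy_fraction Minimum fraction of spectra in which a bin must
#'   be occupied for the bin to be retained (strictly-below removed).
#' @param grid A [bin_grid].
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(intensity_max = 100, min_peaks = 5L,
                              top_n_peaks = 20L, min_scaled_intensity = 1,
                              occupancy_fraction = 0.001, grid = bin_grid()) {
  stopifnot(intensity_max > 0, min_peaks > 0, top_n_peaks > 0,
            min_scaled_intensity > 0,
            occupancy_fraction > 0, occupancy_fraction < 1,
            inherits(grid, "bin_grid"))
  structure(list(intensity_max = intensity_max, min_peaks = as.integer(min_peaks),
                 top_n_peaks = as.integer(top_n_peaks),
                 min_scaled_intensity = min_scaled_intensity,
                 occupancy_fraction = occupancy_fraction, grid = grid),
            class = "preprocess_config")
}

#' Scale peak intensities to a common ceiling
#'
#' Multiplies all intensities by one positive factor so the maximum equals
#' `ceiling`. Idempotent on an already-scaled spectrum.
#'
#' @param s An [ms2_spectrum].
#' @param ceiling Target maximum intensity (default 100).
#' @return The scaled spectrum.
#' @export
scale_intensities <- function(s, ceiling = 100) {
  stopifnot(inherits(s, "ms2_spectrum"))
  m <- max(s$peaks$intensity, 0)
  if (nrow(s$peaks) == 0 || m <= 0) {
    stop("cannot scale a spectrum with no positive-intensity peaks")
  }
  s$peaks$intensity <- s$peaks$intensity * (ceiling / m)
  s
}

#' Spectrum-level quality filter
#'
#' A spectrum passes iff it has exactly one precursor mass and at least
#' `min_peaks` raw peaks (5 peaks passes the default threshold).
#'
#' @param s An [ms2_spectrum].
#' @param cfg A [preprocess_config].
#' @return Logical.
#' @export
spectrum_passes_filters <- function(s, cfg = preprocess_config()) {
  s$precursor_count == 1L && nrow(s$peaks) >= cfg$min_peaks
}

#' Restrict peaks to the grid mass range and intensity floor
#'
#' Retains peaks with `mass_low <= mz <= mass_high` (bounds inclusive) and
#' scaled intensity `>= min_scaled_intensity`. A spectrum left with no peaks
#' is returned flagged via attribute `empty = TRUE` so the caller can decide
#' to drop it.
#'
#' @inheritParams spectrum_passes_filters
#' @return The restricted spectrum (possibly with attribute `empty`).
#' @export
restrict_peaks <- function(s, cfg = preprocess_config()) {
  g <- cfg$grid
  keep <- s$peaks$mz >= g$mass_low & s$peaks$mz <= g$mass_high &
    s$peaks$intensity >= cfg$min_scaled_intensity
  s$peaks <- s$peaks[keep, , drop = FALSE]
  rownames(s$peaks) <- NULL
  if (nrow(s$peaks) == 0) attr(s, "empty") <- TRUE
  s
}

#' Keep the N most intense peaks
#'
#' Ties at the cutoff are broken by ascending m/z so the selection is
#' deterministic. Output peaks remain sorted by m/z.
#'
#' @param s An [ms2_spectrum].
#' @param n Number of peaks to keep (default 20).
#' @return The capped spectrum.
#' @export
select_top_peaks <- function(s, n = 20L) {
  if (nrow(s$peaks) <= n) return(s)
  o <- order(-s$peaks$intensity, s$peaks$mz)
  keep <- sort(o[seq_len(n)])
  s$peaks <- s$peaks[keep, , drop = FALSE]
  rownames(s$peaks) <- NULL
  s
}

#' Map an m/z value to its grid bin
#'
#' Returns the 1-based bin index `floor((mz - mass_low)/width) + 1`; an m/z
#' exactly at `mass_high` maps to the last bin (`n_bins`). The quotient is
#' rounded to 6 decimals before flooring so values sitting on a bin edge are
#' not pushed into the lower bin by floating-point representation error.
#'
#' @param mz Numeric vector of m/z values within the grid range.
#' @param grid A [bin_grid].
#' @return Integer vector of bin indices in `1..n_bins`.
#' @export
bin_index <- function(mz, grid = bin_grid()) {
  if (any(mz < grid$mass_low | mz > grid$mass_high)) {
    stop("m/z out of grid range [", grid$mass_low, ", ", grid$mass_high, "]")
  }
  idx <- as.integer(floor(round((mz - grid$mass_low) / grid$width, 6))) + 1L
  pmin(idx, grid$n_bins)
}

#' Bin a preprocessed spectrum
#'
#' Sums the intensities of the peaks mapped to each grid bin. The sum of the
#' binned vector equals the summed intensity of the retained peaks.
#'
#' @param s An [ms2_spectrum] (fully preprocessed).
#' @param grid A [bin_grid].
#' @return A numeric vector of length `grid$n_bins` with attribute `grid`.
#' @export
bin_spectrum <- function(s, grid = bin_grid()) {
  v <- numeric(grid$n_bins)
  if (nrow(s$peaks) > 0) {
    idx <- bin_index(s$peaks$mz, grid)
    agg <- rowsum(s$peaks$intensity, idx)
    v[as.integer(rownames(agg))] <- agg[, 1]
  }
  attr(v, "grid") <- grid
  v
}

#' Bin a collection of spectra into a sparse matrix
#'
#' @param spectra List of preprocessed [ms2_spectrum] objects.
#' @param grid A [bin_grid].
#' @return A `dgCMatrix` (spectra x bins).
#' @export
bin_spectra <- function(spectra, grid = bin_grid()) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(spectra)) {
    p <- spectra[[k]]$peaks
    if (nrow(p) == 0) next
    idx <- bin_index(p$mz, grid)
    agg <- rowsum(p$intensity, idx)
    jj <- c(jj, as.integer(rownames(agg)))
    ii <- c(ii, rep.int(k, nrow(agg)))
    xx <- c(xx, agg[, 1])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(spectra), grid$n_bins))
}

#' Fraction of spectra occupying each bin
#'
#' @param binned A spectra x bins matrix (dense or sparse) of binned
#'   intensities.
#' @return Numeric vector: per-bin fraction of spectra with a nonzero value.
#' @export
compute_bin_occupancy <- function(binned) {
  if (nrow(binned) == 0) stop("occupancy of an empty spectrum collection is undefined")
  as.numeric(Matrix::colSums(binned > 0)) / nrow(binned)
}

#' Retain bins by occupancy
#'
#' Bins occupied by strictly fewer than `fraction` of the spectra are
#' removed; a bin exactly at the threshold survives. Positive- and
#' negative-mode corpora are expected to be filtered separately by the
#' caller.
#'
#' @param occupancy Per-bin occupancy fractions.
#' @param fraction Occupancy threshold (default 0.001).
#' @return Sorted integer vector of retained (1-based) bin indices.
#' @export
filter_bins <- function(occupancy, fraction = 0.001) {
  keep <- which(occupancy >= fraction)
  if (length(keep) == 0) warning("no bins pass the occupancy filter")
  keep
}

#' Run the full preprocessing chain on a spectrum collection
#'
#' Applies, in order: intensity scaling, the spectrum-level filter (exactly
#' one precursor, minimum peak count), peak restriction to the grid range and
#' intensity floor, top-N peak capping, and binning. Bin occupancy filtering
#' is a corpus-level decision and is exposed separately
#' ([compute_bin_occupancy], [filter_bins]); `preprocess_spectra` returns the
#' occupancy-filtered retained-bin set alongside the binned matrix.
#'
#' @param spectra List of [ms2_spectrum] objects.
#' @param cfg A [preprocess_config].
#' @param apply_occupancy_filter If `TRUE` (default) compute occupancy and
#'   the retained-bin set from this collection.
#' @return List with `binned` (sparse spectra x n_bins matrix over kept
#'   spectra), `kept_spectra` (indices into `spectra`), `retained_bins`
#'   (integer indices, or `NULL` if not computed), `occupancy`, and `cfg`.
#' @export
preprocess_spectra <- function(spectra, cfg = preprocess_config(),
                               apply_occupancy_filter = TRUE) {
  kept <- integer(0); processed <- list()
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    if (nrow(s$peaks) == 0 || max(s$peaks$intensity) <= 0) next
    s <- scale_intensities(s, cfg$intensity_max)
    if (!spectrum_passes_filters(s, cfg)) next
    s <- restrict_peaks(s, cfg)
    if (isTRUE(attr(s, "empty"))) next
    s <- select_top_peaks(s, cfg$top_n_peaks)
    kept <- c(kept, k)
    processed[[length(processed) + 1L]] <- s
  }
  binned <- bin_spectra(processed, cfg$grid)
  occ <- NULL; retained <- NULL
  if (apply_occupancy_filter && length(processed) > 0) {
    occ <- compute_bin_occupancy(binned)
    retained <- filter_bins(occ, cfg$occupancy_fraction)
  }
  list(binned = binned, kept_spectra = kept, retained_bins = retained,
       occupancy = occ, cfg = cfg)
}
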