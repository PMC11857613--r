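test_that("the default grid has exactly 91001 bins and bin_index follows the floor rule", {
  g <- bin_grid()
  expect_equal(g$n_bins, 91001L)
  # floor arithmetic (1-based indices)
  expect_equal(bin_index(100.004, g), 1L)
  expect_equal(bin_index(250.123, g), 15013L)
  expect_equal(bin_index(1010.0, g), 91001L)  # closed upper bound
  expect_equal(bin_index(100.0, g), 1L)
  # bin edges are not pushed down by representation error
  expect_equal(bin_index(250.12, g), 15013L)
  expect_error(bin_index(99.99, g), "range")
  expect_error(bin_index(1010.01, g), "range")
})

test_that("intensity scaling hits the ceiling, is linear and idempotent", {
  s <- ms2_spectrum(c(150, 200), c(2, 4))
  sc <- scale_intensities(s, 100)
  expect_equal(sc$peaks$intensity, c(50, 100))
  one <- scale_intensities(ms2_spectrum(300, 7), 100)
  expect_equal(one$peaks$intensity, 100)
  expect_equal(scale_intensities(sc, 100)$peaks$intensity, sc$peaks$intensity)
  expect_error(scale_intensities(ms2_spectrum(100, 0)), "positive-intensity")
})

test_that("spectrum filter requires exactly one precursor and at least five peaks", {
  cfg <- preprocess_config()
  mk <- function(n, pc) ms2_spectrum(seq(110, 110 + n - 1), rep(50, n),
                                     precursor_count = pc)
  expect_true(spectrum_passes_filters(mk(5, 1L), cfg))   # boundary: 5 passes
  expect_false(spectrum_passes_filters(mk(4, 1L), cfg))
  expect_false(spectrum_passes_filters(mk(20, 2L), cfg))
  expect_false(spectrum_passes_filters(mk(20, 0L), cfg))
})

test_that("peak restriction uses inclusive mass bounds and the >= intensity floor", {
  s <- ms2_spectrum(c(99.99, 100.00, 1010.00, 1010.01), rep(50, 4))
  r <- restrict_peaks(s)
  expect_equal(r$peaks$mz, c(100.00, 1010.00))
  s2 <- ms2_spectrum(c(150, 160), c(0.99, 1.0))
  r2 <- restrict_peaks(s2)
  expect_equal(r2$peaks$mz, 160)
  all_out <- restrict_peaks(ms2_spectrum(c(50, 60), c(99, 98)))
  expect_true(isTRUE(attr(all_out, "empty")))
})

test_that("top-N selection keeps the N most intense with deterministic low-m/z tie-break", {
  set.seed(1)
  mz <- seq(110, 110 + 29)
  inten <- sample(seq(10, 300, by = 10), 30)
  s <- ms2_spectrum(mz, inten)
  top <- select_top_peaks(s, 20)
  expect_equal(nrow(top$peaks), 20)
  expect_equal(sort(top$peaks$intensity, decreasing = TRUE),
               sort(inten, decreasing = TRUE)[1:20])
  expect_false(is.unsorted(top$peaks$mz))
  # fewer than the cap: untouched
  s12 <- ms2_spectrum(mz[1:12], inten[1:12])
  expect_equal(nrow(select_top_peaks(s12, 20)$peaks), 12)
  # tie at the cutoff: the lower-m/z peak wins
  tie <- ms2_spectrum(c(110, 120, 130), c(100, 50, 50))
  expect_equal(select_top_peaks(tie, 2)$peaks$mz, c(110, 120))
})

test_that("binning sums intensities within bins and conserves total intensity", {
  g <- bin_grid()
  s <- ms2_spectrum(c(250.123, 250.129), c(40, 30))
  v <- bin_spectrum(s, g)
  expect_equal(v[15013], 70)
  expect_equal(sum(v), sum(s$peaks$intensity))
  s2 <- ms2_spectrum(c(250.123, 250.131), c(40, 30))
  v2 <- bin_spectrum(s2, g)
  expect_equal(v2[15013], 40)
  expect_equal(v2[15014], 30)
  empty <- ms2_spectrum(numeric(0), numeric(0))
  expect_equal(sum(bin_spectrum(empty, g)), 0)
})

test_that("occupancy and the bin filter implement the strictly-below removal rule", {
  m <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 1, 2), x = c(5, 1, 2),
                            dims = c(10, 4))
  occ <- compute_bin_occupancy(m)
  expect_equal(occ, c(0.2, 0.1, 0, 0))
  expect_equal(filter_bins(occ, 0.1), c(1L, 2L))  # exactly at threshold survives
  expect_equal(filter_bins(occ, 0.11), 1L)
  expect_warning(keep <- filter_bins(c(0, 0), 0.5), "no bins")
  expect_length(keep, 0)
  expect_error(compute_bin_occupancy(m[0, , drop = FALSE]), "empty")
})

test_that("occupancy filtering is monotone: raising the threshold never adds bins", {
  set.seed(42)
  occ <- runif(200)
  fr <- sort(runif(10))
  kept <- lapply(fr, function(f) filter_bins(occ, f))
  for (i in 2:length(kept)) {
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  }
})

test_that("the full preprocessing chain orders stages correctly and conserves intensity", {
  # spectrum A: passes everything; B: too few peaks; C: two precursors
  a <- ms2_spectrum(seq(110, 170, by = 10), c(2, 4, 8, 1, 6, 3, 10),
                    precursor_count = 1L)
  b <- ms2_spectrum(c(110, 120), c(5, 5), precursor_count = 1L)
  cc <- ms2_spectrum(seq(110, 170, by = 10), rep(5, 7), precursor_count = 2L)
  pp <- preprocess_spectra(list(a, b, cc))
  expect_equal(pp$kept_spectra, 1L)
  total <- sum(pp$binned[1, ])
  # peak of intensity 1 scales to 10 (< min 1? no: 1*(100/10)=10) so all retained
  expect_equal(total, sum(c(2, 4, 8, 1, 6, 3, 10)) * 10)
  expect_equal(length(pp$occupancy), bin_grid()$n_bins)
})

test_that("binned matrices agree with per-spectrum binning", {
  set.seed(3)
  sp <- lapply(1:4, function(i) {
    ms2_spectrum(runif(6, 150, 900), runif(6, 10, 100))
  })
  g <- bin_grid()
  M <- bin_spectra(sp, g)
  for (i in seq_along(sp)) {
    expect_equal(as.numeric(M[i, ]), as.numeric(bin_spectrum(sp[[i]], g)),
                 tolerance = 1e-12)
  }
})
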