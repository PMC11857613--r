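#' Construct an MS/MS spectrum
#'
#' A spectrum is a peak list (m/z, intensity) together with the reference
#' compound and acquisition metadata carried by spectral libraries. Peaks are
#' stored sorted ascending by m/z.
#'
#' @param mz Numeric vector of mass-to-charge ratios (Da), all > 0.
#' @param intensity Numeric vector of abundances, all >= 0, same length as
#'   `mz`.
#' @param metadata Named list of metadata fields. Recognized fields:
#'   `compound_id`, `formula`, `inchikey`, `smiles`, `precursor_mz`,
#'   `adduct`, `ionization_mode` ("positive"/"negative"),
#'   `collision_energy`, `source`.
#' @param precursor_count Integer count of precursor-mass entries found in the
#'   raw record. Raw library records can carry zero or several precursor
#'   fields; downstream filters reject anything but exactly one, so the count
#'   is preserved verbatim rather than defaulted to 1.
#' @return An object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(mz, intensity, metadata = list(),
                         precursor_count = if (is.null(metadata$precursor_mz)) 0L else 1L) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 0) {
    if (any(!is.finite(mz)) || any(mz <= 0)) stop("all m/z values must be finite and > 0")
    if (any(!is.finite(intensity)) || any(intensity < 0)) stop("all intensities must be finite and >= 0")
  }
  if (!is.null(metadata$ionization_mode) &&
      !metadata$ionization_mode %in% c("positive", "negative")) {
    stop("ionization_mode must be 'positive' or 'negative', got: ", metadata$ionization_mode)
  }
  if (!is.null(metadata$inchikey) && !is_valid_inchikey(metadata$inchikey)) {
    stop("malformed InChIKey: ", metadata$inchikey)
  }
  o <- order(mz)
  structure(list(
    peaks = data.frame(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o])),
    metadata = metadata,
    precursor_count = as.integer(precursor_count)
  ), class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  id <- x$metadata$compound_id
  cat(sprintf("<ms2_spectrum> %s: %d peaks, precursor_count=%d, mode=%s\n",
              if (is.null(id)) "(unnamed)" else id,
              nrow(x$peaks), x$precursor_count,
              if (is.null(x$metadata$ionization_mode)) "?" else x$metadata$ionization_mode))
  invisible(x)
}

#' @export
length.ms2_spectrum <- function(x) nrow(x$peaks)

#' Validate an InChIKey string
#'
#' Checks the standard 27-character layout: a 14-character skeleton block, a
#' 10-character block and a single protonation character, separated by
#' hyphens, all uppercase letters.
#'
#' @param x Character vector.
#' @return Logical vector.
#' @export
is_valid_inchikey <- function(x) {
  !is.na(x) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

#' InChIKey skeleton block
#'
#' First 14 characters of an InChIKey, hashing the connectivity skeleton.
#' Used for structure identity in hit calling and structure-disjoint splits.
#'
#' @param x Character vector of InChIKeys.
#' @return Character vector of 14-character blocks.
#' @export
inchikey_block1 <- function(x) substr(x, 1L, 14L)

## metadata key normalization shared by the MSP and MGF readers -------------

# maps lowercased raw keys to canonical metadata field names
.msp_key_map <- c(
  "name" = "compound_id", "title" = "compound_id", "compound_id" = "compound_id",
  "formula" = "formula", "molecular_formula" = "formula",
  "inchikey" = "inchikey", "inchi_key" = "inchikey",
  "smiles" = "smiles",
  "precursormz" = "precursor_mz", "precursor_mz" = "precursor_mz",
  "pepmass" = "precursor_mz",
  "precursortype" = "adduct", "precursor_type" = "adduct", "adduct" = "adduct",
  "ion" = "adduct",
  "ionmode" = "ionization_mode", "ion_mode" = "ionization_mode",
  "ionization_mode" = "ionization_mode",
  "collisionenergy" = "collision_energy", "collision_energy" = "collision_energy",
  "ce" = "collision_energy",
  "source" = "source", "db" = "source", "database" = "source"
)

.normalize_mode <- function(x) {
  v <- tolower(trimws(x))
  if (v %in% c("positive", "p", "+", "pos")) return("positive")
  if (v %in% c("negative", "n", "-", "neg")) return("negative")
  NA_character_
}

# Builds one ms2_spectrum from accumulated key/value pairs and peak rows.
# `precursor_values` are all numbers seen in precursor-mass fields.
.assemble_spectrum <- function(keys, values, mz, intensity, precursor_values) {
  md <- list()
  for (i in seq_along(keys)) {
    canon <- .msp_key_map[[tolower(keys[i])]]
    if (is.null(canon) || is.na(canon)) next
    val <- trimws(values[i])
    if (canon == "ionization_mode") {
      m <- .normalize_mode(val)
      if (!is.na(m)) md$ionization_mode <- m
    } else if (canon == "precursor_mz") {
      # handled through precursor_values
    } else if (!nzchar(val)) {
      next
    } else {
      md[[canon]] <- val
    }
  }
  pc <- length(precursor_values)
  if (pc >= 1) md$precursor_mz <- precursor_values[[1]]
  ms2_spectrum(mz, intensity, metadata = md, precursor_count = pc)
}

.parse_peak_lines <- function(lines, where, on_error) {
  txt <- trimws(lines)
  txt <- txt[nzchar(txt)]
  parts <- strsplit(txt, "[ \t;]+")
  mz <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1])), numeric(1))
  it <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2])), numeric(1))
  if (any(is.na(mz)) || any(is.na(it))) {
    msg <- sprintf("unparsable peak line in %s", where)
    if (identical(on_error, "fail")) stop(msg)
    warning(msg)
    keep <- !(is.na(mz) | is.na(it))
    mz <- mz[keep]; it <- it[keep]
  }
  list(mz = mz, intensity = it)
}

#' Read an MSP spectral library
#'
#' Parses NIST-style and MoNA-style MSP text. Keys are matched
#' case-insensitively; peak lines may be space-, tab- or semicolon-separated.
#' Records are delimited by blank lines after the `Num Peaks` peak block.
#' The number of precursor-mass fields in each record is preserved in
#' `precursor_count` (it is not defaulted to 1), since library records may
#' legitimately carry zero or several.
#'
#' @param path Path to an MSP file.
#' @param on_error `"fail"` (default) stops on a malformed record naming its
#'   index; `"skip"` drops the record with a warning.
#' @return List of [ms2_spectrum] objects.
#' @export
read_msp <- function(path, on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L; n <- length(lines); rec <- 0L
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    rec <- rec + 1L
    parse_record <- function() {
      keys <- character(); values <- character(); prec <- numeric()
      while (i <= n && nzchar(trimws(lines[i]))) {
        ln <- lines[i]
        colon <- regexpr(":", ln, fixed = TRUE)
        if (colon < 0) stop(sprintf("record %d: expected 'Key: value' line, got '%s'", rec, ln))
        key <- trimws(substr(ln, 1, colon - 1))
        val <- trimws(substr(ln, colon + 1, nchar(ln)))
        i <<- i + 1L
        if (tolower(key) %in% c("num peaks", "numpeaks", "num_peaks")) {
          npeaks <- as.integer(val)
          if (is.na(npeaks)) stop(sprintf("record %d: unparsable peak count '%s'", rec, val))
          peak_lines <- character()
          while (i <= n && nzchar(trimws(lines[i]))) {
            peak_lines <- c(peak_lines, lines[i]); i <<- i + 1L
          }
          pk <- .parse_peak_lines(peak_lines, sprintf("record %d", rec), "fail")
          if (length(pk$mz) != npeaks) {
            stop(sprintf("record %d: Num Peaks is %d but %d peak lines parsed",
                         rec, npeaks, length(pk$mz)))
          }
          return(.assemble_spectrum(keys, values, pk$mz, pk$intensity, prec))
        } else {
          canon <- .msp_key_map[[tolower(key)]]
          if (!is.null(canon) && !is.na(canon) && canon == "precursor_mz") {
            vals <- suppressWarnings(as.numeric(strsplit(val, "[,; \t]+")[[1]]))
            vals <- vals[!is.na(vals)]
            prec <- c(prec, vals)
          }
          keys <- c(keys, key); values <- c(values, val)
        }
      }
      # header without a peak block: treat as record with zero peaks
      .assemble_spectrum(keys, values, numeric(0), numeric(0), prec)
    }
    res <- tryCatch(parse_record(), error = function(e) {
      if (on_error == "fail") stop(e)
      warning(conditionMessage(e)); NULL
    })
    if (!is.null(res)) spectra[[length(spectra) + 1L]] <- res
    # advance past any malformed remainder of the record
    while (i <= n && nzchar(trimws(lines[i]))) i <- i + 1L
  }
  spectra
}

#' Read an MGF spectral library
#'
#' Parses Mascot generic format: `BEGIN IONS`/`END IONS` blocks with
#' `KEY=value` headers and peak lines. `PEPMASS` supplies the precursor m/z
#' (any trailing intensity on the PEPMASS line is ignored); the ionization
#' mode is taken from an `IONMODE` field or the sign of `CHARGE`, never from
#' adduct text. The count of PEPMASS lines per block is preserved in
#' `precursor_count`.
#'
#' @inheritParams read_msp
#' @return List of [ms2_spectrum] objects.
#' @export
read_mgf <- function(path, on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L; n <- length(lines); blk <- 0L
  while (i <= n) {
    if (toupper(trimws(lines[i])) != "BEGIN IONS") { i <- i + 1L; next }
    blk <- blk + 1L
    i <- i + 1L
    keys <- character(); values <- character(); prec <- numeric()
    peak_lines <- character(); charge_sign <- NA_character_
    closed <- FALSE
    while (i <= n) {
      ln <- trimws(lines[i])
      if (toupper(ln) == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (toupper(ln) == "BEGIN IONS") break
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0 && !grepl("^[0-9.]", ln)) {
        key <- trimws(substr(ln, 1, eq - 1))
        val <- trimws(substr(ln, eq + 1, nchar(ln)))
        if (toupper(key) == "PEPMASS") {
          v <- suppressWarnings(as.numeric(strsplit(val, "[ \t]+")[[1]][1]))
          if (!is.na(v)) prec <- c(prec, v)
        } else if (toupper(key) == "CHARGE") {
          if (grepl("-", val, fixed = TRUE)) charge_sign <- "negative"
          else if (grepl("\\d", val)) charge_sign <- "positive"
        } else {
          keys <- c(keys, key); values <- c(values, val)
        }
      } else if (nzchar(ln)) {
        peak_lines <- c(peak_lines, ln)
      }
      i <- i + 1L
    }
    res <- tryCatch({
      if (!closed) stop(sprintf("MGF block %d: missing END IONS", blk))
      pk <- .parse_peak_lines(peak_lines, sprintf("MGF block %d", blk), "fail")
      s <- .assemble_spectrum(keys, values, pk$mz, pk$intensity, prec)
      if (is.null(s$metadata$ionization_mode) && !is.na(charge_sign)) {
        s$metadata$ionization_mode <- charge_sign
      }
      s
    }, error = function(e) {
      if (on_error == "fail") stop(e)
      warning(conditionMessage(e)); NULL
    })
    if (!is.null(res)) spectra[[length(spectra) + 1L]] <- res
  }
  spectra
}

# canonical output keys, in writing order
.msp_out_keys <- c(compound_id = "Name", formula = "Formula", inchikey = "InChIKey",
                   smiles = "SMILES", precursor_mz = "PrecursorMZ",
                   adduct = "Precursor_type", ionization_mode = "Ion_mode",
                   collision_energy = "Collision_energy", source = "Source")

.fmt_intensity <- function(x) formatC(signif(x, 4), format = "fg", flag = "#")

#' Write spectra to an MSP file
#'
#' m/z values are written with 5 decimals and intensities with 4 significant
#' figures; optional metadata fields that are absent are omitted from the
#' record. `read_msp(write_msp(x))` reproduces peaks to the printed precision
#' and all populated metadata.
#'
#' @param spectra List of [ms2_spectrum] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    md <- s$metadata
    for (field in names(.msp_out_keys)) {
      v <- md[[field]]
      if (is.null(v)) next
      if (field == "precursor_mz") v <- sprintf("%.5f", as.numeric(v))
      writeLines(paste0(.msp_out_keys[[field]], ": ", v), con)
    }
    writeLines(sprintf("Num Peaks: %d", nrow(s$peaks)), con)
    if (nrow(s$peaks) > 0) {
      writeLines(sprintf("%.5f %s", s$peaks$mz, .fmt_intensity(s$peaks$intensity)), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write spectra to an MGF file
#'
#' @inheritParams write_msp
#' @return Invisibly, `path`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    md <- s$metadata
    writeLines("BEGIN IONS", con)
    if (!is.null(md$compound_id)) writeLines(paste0("TITLE=", md$compound_id), con)
    if (!is.null(md$precursor_mz)) writeLines(sprintf("PEPMASS=%.5f", as.numeric(md$precursor_mz)), con)
    if (!is.null(md$ionization_mode)) {
      writeLines(paste0("IONMODE=", md$ionization_mode), con)
      writeLines(paste0("CHARGE=1", if (md$ionization_mode == "negative") "-" else "+"), con)
    }
    for (f in c("formula", "inchikey", "smiles", "adduct", "collision_energy", "source")) {
      if (!is.null(md[[f]])) writeLines(paste0(toupper(f), "=", md[[f]]), con)
    }
    if (nrow(s$peaks) > 0) {
      writeLines(sprintf("%.5f %s", s$peaks$mz, .fmt_intensity(s$peaks$intensity)), con)
    }
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}
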