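#' The five-family concatenated fingerprint scheme
#'
#' Fixed concatenation order and published family lengths:
#' FP3 (55), FP4 (307), PubChem (881), MACCS (166, keys 1-166),
#' Klekota-Roth (4860), for a total of 6269 bits.
#'
#' FP3, FP4 and MACCS are computed with the Open Babel pattern
#' implementations (via ChemmineOB). The PubChem- and Klekota-Roth-length
#' blocks are filled with deterministic hashed linear-fragment keys: all
#' simple atom/bond paths up to 6 bonds are enumerated from the molecular
#' graph, canonicalized, and hashed into the block with a family-specific
#' salt. These hashed blocks preserve the fingerprint algebra (fixed length,
#' determinism, representation invariance, substructure-driven Tanimoto
#' similarity) used by the rest of the pipeline.
#'
#' @return An object of class `fingerprint_scheme` with `families`
#'   (data.frame of name, n_bits, offset) and `total_bits`.
#' @export
fingerprint_scheme <- function() {
  fam <- data.frame(
    name = c("FP3", "FP4", "PubChem", "MACCS", "KlekotaRoth"),
    n_bits = c(55L, 307L, 881L, 166L, 4860L),
    stringsAsFactors = FALSE
  )
  fam$offset <- cumsum(c(0L, fam$n_bits[-nrow(fam)]))
  structure(list(families = fam, total_bits = sum(fam$n_bits)),
            class = "fingerprint_scheme")
}

#' @export
print.fingerprint_scheme <- function(x, ...) {
  cat(sprintf("<fingerprint_scheme> %d bits: %s\n", x$total_bits,
              paste(sprintf("%s(%d)", x$families$name, x$families$n_bits),
                    collapse = " + ")))
  invisible(x)
}

#' Canonicalize a SMILES string
#'
#' @param smiles A SMILES string.
#' @return Canonical SMILES (Open Babel canonical form).
#' @export
canonical_smiles <- function(smiles) {
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", smiles),
                  error = function(e) "")
  out <- trimws(strsplit(out, "[\t\n ]")[[1]][1])
  if (is.na(out) || !nzchar(out)) stop("unparsable SMILES: ", smiles)
  out
}

# Open Babel fingerprints come back padded to word multiples; truncate to the
# published pattern counts. MACCS bit 1 is the unused key-0 slot.
.ob_fingerprint <- function(smiles, name, n_bits, skip_first = 0L) {
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  fp <- ChemmineOB::fingerprint_OB(mol, name)
  as.integer(fp[seq.int(skip_first + 1L, skip_first + n_bits)])
}

# molecular graph (atoms + bonds) from canonical SMILES, via an SDF block
.mol_graph <- function(can_smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(can_smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  adj <- vector("list", n)
  bond_order <- list()
  if (!is.null(bb) && nrow(bb) > 0) {
    for (r in seq_len(nrow(bb))) {
      a <- bb[r, 1]; b <- bb[r, 2]; o <- bb[r, 3]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
      bond_order[[paste(min(a, b), max(a, b))]] <- o
    }
  }
  list(elements = elements, adj = adj, bond_order = bond_order, n = n)
}

# all simple paths up to max_bonds bonds, as canonical label strings
.enumerate_paths <- function(g, max_bonds = 6L) {
  paths <- new.env(hash = TRUE, parent = emptyenv())
  bkey <- function(a, b) paste(min(a, b), max(a, b))
  walk <- function(path, labels) {
    # canonical form: lexicographic min of forward and reverse spellings
    fwd <- paste(labels, collapse = "")
    rev_ <- paste(rev(labels), collapse = "")
    assign(min(fwd, rev_), TRUE, envir = paths)
    if ((length(path) - 1L) >= max_bonds) return()
    last <- path[length(path)]
    for (nb in g$adj[[last]]) {
      if (nb %in% path) next
      o <- g$bond_order[[bkey(last, nb)]]
      walk(c(path, nb), c(labels, paste0("~", o, "~"), g$elements[nb]))
    }
  }
  for (a in seq_len(g$n)) walk(a, g$elements[a])
  ls(paths)
}

# deterministic string hash (31-polynomial mod 2^31-1), exact in doubles
.hash_string <- function(s, salt) {
  h <- salt
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

.hashed_path_block <- function(path_strings, n_bits, salt) {
  v <- integer(n_bits)
  for (s in path_strings) {
    v[.hash_string(s, salt) %% n_bits + 1L] <- 1L
  }
  v
}

#' Compute the 6269-bit concatenated molecular fingerprint
#'
#' Computes the five family blocks in the fixed order of
#' [fingerprint_scheme()] from a SMILES string. The input is canonicalized
#' first, so different SMILES spellings of one molecule yield identical
#' vectors.
#'
#' @param smiles A SMILES string.
#' @param scheme A [fingerprint_scheme] (the default is the only supported
#'   layout).
#' @return Integer 0/1 vector of length `scheme$total_bits`.
#' @export
compute_fingerprint <- function(smiles, scheme = fingerprint_scheme()) {
  can <- canonical_smiles(smiles)
  g <- .mol_graph(can)
  paths <- .enumerate_paths(g)
  blocks <- list(
    FP3 = .ob_fingerprint(can, "FP3", 55L),
    FP4 = .ob_fingerprint(can, "FP4", 307L),
    PubChem = .hashed_path_block(paths, 881L, salt = 17L),
    MACCS = .ob_fingerprint(can, "MACCS", 166L, skip_first = 1L),
    KlekotaRoth = .hashed_path_block(paths, 4860L, salt = 101L)
  )
  fp <- unlist(blocks[scheme$families$name], use.names = FALSE)
  stopifnot(length(fp) == scheme$total_bits)
  fp
}

#' Fingerprint matrix for a table of SMILES
#'
#' @param smiles Character vector of SMILES strings.
#' @param scheme A [fingerprint_scheme].
#' @return Integer matrix (compounds x total_bits), rownames from `names(smiles)`.
#' @export
fingerprint_matrix <- function(smiles, scheme = fingerprint_scheme()) {
  m <- t(vapply(smiles, compute_fingerprint, integer(scheme$total_bits),
                scheme = scheme))
  rownames(m) <- names(smiles)
  m
}

#' Identify constant fingerprint columns
#'
#' Columns that are all-0 or all-1 across the training compounds carry no
#' discriminative information and are dropped before condensation.
#'
#' @param mat Binary matrix (compounds x bits), at least 2 rows.
#' @return List with integer index vectors `kept` and `dropped`.
#' @export
remove_constant_bits <- function(mat) {
  stopifnot(nrow(mat) >= 2)
  cs <- colSums(mat)
  dropped <- which(cs == 0 | cs == nrow(mat))
  kept <- setdiff(seq_len(ncol(mat)), dropped)
  if (length(kept) == 0) warning("every fingerprint column is constant")
  list(kept = kept, dropped = as.integer(dropped))
}

#' Condense duplicate fingerprint columns
#'
#' Columns with identical 0/1 patterns across all training compounds are
#' merged into one condensed column; the group representative is the lowest
#' original bit index. Together with [remove_constant_bits] this partitions
#' the original bit set: every bit index is either dropped as constant or a
#' member of exactly one kept group.
#'
#' @param mat Binary matrix restricted to non-constant columns.
#' @param kept Original bit indices of `mat`'s columns (default
#'   `seq_len(ncol(mat))`).
#' @param dropped Original bit indices removed as constant (bookkeeping only).
#' @param total_bits Total original bit count (bookkeeping only).
#' @return An object of class `condensed_map`: `groups` (list of original
#'   index vectors, ordered by representative), `representatives`,
#'   `dropped_constant`, `condensed_length`, `total_bits`.
#' @export
condense_duplicates <- function(mat, kept = seq_len(ncol(mat)),
                                dropped = integer(0),
                                total_bits = length(kept) + length(dropped)) {
  stopifnot(ncol(mat) == length(kept))
  key <- unname(apply(mat, 2, paste, collapse = ""))
  reps_key <- key[!duplicated(key)]
  groups <- lapply(reps_key, function(k) as.integer(unname(kept[key == k])))
  reps <- vapply(groups, min, integer(1))
  o <- order(reps)
  structure(list(groups = unname(groups[o]), representatives = reps[o],
                 dropped_constant = as.integer(dropped),
                 condensed_length = length(groups),
                 total_bits = as.integer(total_bits)),
            class = "condensed_map")
}

#' @export
print.condensed_map <- function(x, ...) {
  cat(sprintf("<condensed_map> %d bits -> %d condensed (%d constant dropped, %d duplicate groups)\n",
              x$total_bits, x$condensed_length, length(x$dropped_constant),
              sum(lengths(x$groups) > 1)))
  invisible(x)
}

#' Build a condensed map from a full fingerprint matrix
#'
#' Convenience chain: [remove_constant_bits] then [condense_duplicates].
#'
#' @param mat Full binary fingerprint matrix (compounds x total bits).
#' @return A `condensed_map`.
#' @export
build_condensed_map <- function(mat) {
  cb <- remove_constant_bits(mat)
  condense_duplicates(mat[, cb$kept, drop = FALSE], kept = cb$kept,
                      dropped = cb$dropped, total_bits = ncol(mat))
}

#' Project a full fingerprint into the condensed space
#'
#' Each condensed column takes the value of its group's representative bit.
#' For unseen molecules a duplicate group's member bits can disagree; the
#' representative's value is used and the number of disagreeing groups is
#' returned in attribute `disagreements`.
#'
#' @param fp Full-length 0/1 vector (or compounds x bits matrix).
#' @param map A `condensed_map`.
#' @return Condensed 0/1 vector (or matrix) of length
#'   `map$condensed_length`, with attribute `disagreements`.
#' @export
project_fingerprint <- function(fp, map) {
  stopifnot(inherits(map, "condensed_map"))
  if (is.matrix(fp)) {
    stopifnot(ncol(fp) == map$total_bits)
    out <- fp[, map$representatives, drop = FALSE]
    dis <- 0L
    for (grp in map$groups[lengths(map$groups) > 1]) {
      sub <- fp[, grp, drop = FALSE]
      dis <- dis + sum(matrixStats_rowAnyDiff(sub))
    }
    attr(out, "disagreements") <- dis
    return(out)
  }
  stopifnot(length(fp) == map$total_bits)
  out <- fp[map$representatives]
  dis <- sum(vapply(map$groups[lengths(map$groups) > 1],
                    function(grp) length(unique(fp[grp])) > 1, logical(1)))
  attr(out, "disagreements") <- as.integer(dis)
  out
}

# rows where not all entries are equal (no matrixStats dependency)
matrixStats_rowAnyDiff <- function(m) {
  if (ncol(m) < 2) return(rep(FALSE, nrow(m)))
  apply(m, 1, function(r) length(unique(r)) > 1)
}

#' Expand a condensed fingerprint back to kept bits
#'
#' Inverse check for the projection: every member bit of a group receives the
#' group's condensed value. Projection of a training compound followed by
#' expansion reconstructs its kept bits exactly.
#'
#' @param condensed 0/1 vector of length `map$condensed_length`.
#' @param map A `condensed_map`.
#' @return Named-by-position vector over the original bit space with dropped
#'   constant bits set to `NA`.
#' @export
expand_fingerprint <- function(condensed, map) {
  stopifnot(length(condensed) == map$condensed_length)
  out <- rep(NA_integer_, map$total_bits)
  for (j in seq_along(map$groups)) out[map$groups[[j]]] <- condensed[j]
  out
}
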