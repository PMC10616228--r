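# chunked bitmask utilities: a set over a domain of n items is stored as
# ceiling(n/31) non-negative integers, 31 bits per chunk (the sign bit is
# never used). A family of sets is an integer matrix, one row per set.

BITS_PER_CHUNK <- 31L

mask_nchunks <- function(n) max(1L, as.integer(ceiling(n / BITS_PER_CHUNK)))

# indices (1-based) -> one mask row
mask_from_indices <- function(idx, n) {
  m <- integer(mask_nchunks(n))
  for (i in idx) {
    ch <- (i - 1L) %/% BITS_PER_CHUNK + 1L
    m[ch] <- bitwOr(m[ch], bitwShiftL(1L, (i - 1L) %% BITS_PER_CHUNK))
  }
  m
}

# family matrix + single mask -> family with the mask OR'ed into every row
mask_or_rows <- function(fam, m) {
  for (ch in seq_along(m)) fam[, ch] <- bitwOr(fam[, ch], m[ch])
  fam
}

mask_dedupe <- function(fam) {
  if (ncol(fam) == 1L) {
    fam[!duplicated(fam[, 1L]), , drop = FALSE]
  } else {
    fam[!duplicated(do.call(paste, as.data.frame(fam))), , drop = FALSE]
  }
}

# logical membership matrix (rows = sets, cols = domain items) from masks
mask_membership <- function(fam, n) {
  out <- matrix(FALSE, nrow(fam), n)
  for (i in seq_len(n)) {
    ch <- (i - 1L) %/% BITS_PER_CHUNK + 1L
    bit <- bitwShiftL(1L, (i - 1L) %% BITS_PER_CHUNK)
    out[, i] <- bitwAnd(fam[, ch], bit) != 0L
  }
  out
}

mask_from_membership <- function(memb) {
  n <- ncol(memb)
  nch <- mask_nchunks(n)
  fam <- matrix(0L, nrow(memb), nch)
  for (i in seq_len(n)) {
    ch <- (i - 1L) %/% BITS_PER_CHUNK + 1L
    bit <- bitwShiftL(1L, (i - 1L) %% BITS_PER_CHUNK)
    fam[memb[, i], ch] <- bitwOr(fam[memb[, i], ch], bit)
  }
  fam
}

# union closure of a family of atoms (rows), always including the empty set.
# Incremental basis closure: after processing atom a, the family holds every
# union of a subset of the atoms seen so far; each step is vectorized and
# deduplicated, so the cost is bounded by the size of the final family.
close_under_union <- function(atoms) {
  fam <- matrix(0L, 1L, ncol(atoms))
  for (k in seq_len(nrow(atoms))) {
    fam <- mask_dedupe(rbind(fam, mask_or_rows(fam, atoms[k, ])))
  }
  fam
}
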