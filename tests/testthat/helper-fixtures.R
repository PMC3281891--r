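# Shared fixtures and independent oracles, all built in code.

# tiny alignment from gapped row strings
mk_msa <- function(..., ids = NULL) {
  rows <- c(...)
  if (is.null(ids)) ids <- paste0("s", seq_along(rows))
  aa_alignment(ids, rows)
}

mk_records <- function(seqs, prefix = "t") {
  data.frame(id = paste0(prefix, seq_along(seqs)), desc = "",
             seq = seqs, stringsAsFactors = FALSE)
}

# Exhaustive enumeration of local alignments under the same affine-gap
# model as the DP kernel (between consecutive matched pairs a gap may run
# in only one of the two sequences); independent oracle for small inputs.
brute_force_local <- function(S, open, extend) {
  n <- nrow(S); m <- ncol(S)
  best <- 0
  gap_cost <- function(d) if (d == 0L) 0 else open + (d - 1L) * extend
  recurse <- function(i, j, score) {
    if (score > best) best <<- score
    if (i < n && j < m) {
      for (i2 in (i + 1L):n) for (j2 in (j + 1L):m) {
        di <- i2 - i - 1L; dj <- j2 - j - 1L
        if (di > 0L && dj > 0L) next
        recurse(i2, j2, score - gap_cost(di) - gap_cost(dj) + S[i2, j2])
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m)) recurse(i, j, S[i, j])
  best
}

# single-sequence profile with no pseudocounts: unit emission vectors
unit_profile <- function(seq, tm = NULL) {
  build_profile(mk_msa(seq), pseudocount = 0, tm_annotation = tm)
}

# default family realisation used across tests
default_family <- function(seed = 1, ...) {
  sp <- family_spec(seed = seed, ...)
  simulate(sp, 1, seed = seed)[[1]]
}

# profile of a family built from its truth alignment with truth TM spans
family_profile <- function(fam) {
  build_profile(fam$truth$alignment,
                tm_annotation = attr(fam$truth$alignment, "col_tm"))
}

# seed alignment (first k members) of a proteome's first family, with TM
# annotation remapped through the all-gap-column drop
seed_alignment <- function(prot, k = 3L) {
  aln <- prot$truth$families[[1]]$alignment
  sub <- aa_alignment(aln$id[seq_len(k)], aln$seq[seq_len(k)])
  m <- do.call(rbind, strsplit(sub$seq, ""))
  keep <- which(colSums(m != "-") > 0L)
  sub2 <- aa_alignment(sub$id, apply(m[, keep, drop = FALSE], 1L,
                                     paste, collapse = ""))
  tm0 <- attr(aln, "col_tm")
  attr(sub2, "col_tm") <- cbind(start = match(tm0[, 1], keep),
                                end = match(tm0[, 2], keep))
  sub2
}

AA_ALPHABET <- pqfam:::AA_ALPHABET
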