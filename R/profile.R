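# Position-specific profiles: construction from alignments, local scoring
# of sequences, and profile-to-profile local alignment.  Scores are in bits
# throughout.  The profile is deliberately simple (match-column emissions
# with affine gap constants, no insert-state emissions): the discovery
# protocol needs reliable ranking and aligned spans, not full HMM parity.

# Henikoff position-based sequence weights, normalised to sum to 1.  Gap
# characters do not contribute to a column's residue counts.
position_weights <- function(mat) {
  n <- nrow(mat)
  w <- numeric(n)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    keep <- col != "-" & col != "X"
    if (!any(keep)) next
    tab <- table(col[keep])
    r <- length(tab)
    w[keep] <- w[keep] + 1 / (r * as.numeric(tab[col[keep]]))
  }
  if (sum(w) == 0) w <- rep(1, n)
  w / sum(w)
}

#' Build a position-specific profile from an alignment
#'
#' Match columns are those with at most 50% gaps (ties count as match).
#' Emissions are Henikoff-weighted residue frequencies mixed with
#' `pseudocount` parts background and renormalised; `X` contributes its
#' weight to the background part.  TM segment annotation given in alignment
#' columns is mapped through the match-column indexing.
#'
#' @param msa an [aa_alignment()].
#' @param pseudocount background pseudocount weight per column (default 1).
#' @param tm_annotation optional two-column matrix of TM segment spans in
#'   alignment-column coordinates (e.g. `attr(truth$alignment, "col_tm")`).
#' @param gap_open,gap_extend affine gap penalties in bits.
#' @return Object of class `seq_profile`: `mat` (20 x columns emission
#'   probabilities), `bg`, `tm_segments` (spans in match-column
#'   coordinates), `match_cols` (original alignment columns), `n_effective`,
#'   gap penalties.
#' @export
build_profile <- function(msa, pseudocount = 1, tm_annotation = NULL,
                          gap_open = 11, gap_extend = 1) {
  mat <- aln_matrix(msa)
  gapfrac <- colMeans(mat == "-")
  match_cols <- which(gapfrac <= 0.5)
  if (length(match_cols) == 0L) stop("no match columns")
  w <- position_weights(mat)
  bg <- aa_background()
  nm <- length(match_cols)
  P <- matrix(0, nrow = 20L, ncol = nm, dimnames = list(AA_ALPHABET, NULL))
  for (k in seq_len(nm)) {
    col <- mat[, match_cols[k]]
    counts <- setNames(numeric(20L), AA_ALPHABET)
    xw <- 0
    for (i in seq_along(col)) {
      a <- col[i]
      if (a == "-") next
      if (a == "X") xw <- xw + w[i]
      else counts[a] <- counts[a] + w[i]
    }
    num <- counts + (pseudocount + xw) * bg
    P[, k] <- num / sum(num)
  }
  tm_segments <- NULL
  if (!is.null(tm_annotation)) {
    tm_annotation <- as.matrix(tm_annotation)
    tm_segments <- t(apply(tm_annotation, 1L, function(sp) {
      inside <- which(match_cols >= sp[1] & match_cols <= sp[2])
      if (length(inside) == 0L) return(c(NA_integer_, NA_integer_))
      range(inside)
    }))
    colnames(tm_segments) <- c("start", "end")
    tm_segments <- tm_segments[!is.na(tm_segments[, 1]), , drop = FALSE]
  }
  structure(list(mat = P, bg = bg, tm_segments = tm_segments,
                 match_cols = match_cols,
                 n_effective = 1 / sum(w^2),
                 gap_open = gap_open, gap_extend = gap_extend,
                 source_ids = msa$id),
            class = "seq_profile")
}

#' @export
print.seq_profile <- function(x, ...) {
  cat("Sequence profile: ", ncol(x$mat), " match columns, ",
      if (is.null(x$tm_segments)) 0L else nrow(x$tm_segments),
      " TM segments, n_eff ", round(x$n_effective, 1), "\n", sep = "")
  cat("  built from ", length(x$source_ids), " sequences; gap open/extend ",
      x$gap_open, "/", x$gap_extend, " bits\n", sep = "")
  invisible(x)
}

# log-odds score matrix of a profile against an encoded sequence
# (columns x residues); X scores 0 everywhere.
profile_logodds <- function(profile) {
  lo <- log2(profile$mat / profile$bg)
  cbind(t(lo), X = 0)  # columns x 21
}

#' Score a sequence against a profile
#'
#' Smith-Waterman local dynamic programming over per-column log-odds
#' emission scores with affine gaps.  A sequence of only `X` (which scores
#' as background everywhere) returns score 0 with an empty span.
#'
#' @param profile a [build_profile()] object.
#' @param seq a sequence string or one-row record data.frame.
#' @return List with `score` (bits), `qstart`/`qend` (profile columns),
#'   `tstart`/`tend` (sequence positions), and `pairs` (matched
#'   column/position index pairs).
#' @export
score_sequence <- function(profile, seq) {
  if (is.data.frame(seq)) seq <- seq$seq[1]
  if (!nzchar(seq)) stop("empty sequence")
  codes <- encode_residues(gsub("-", "", seq))
  S <- profile_logodds(profile)[, codes, drop = FALSE]
  .sw_affine(S, profile$gap_open, profile$gap_extend)
}

#' Score sequences against a profile
#'
#' `predict()` on a profile scores a set of sequences and returns a hit
#' table (one row per sequence, scores in bits; E-values if a calibration
#' is supplied).
#'
#' @param object a `seq_profile`.
#' @param newdata data.frame of sequence records (`id`, `seq`).
#' @param calibration optional [calibrate_profile()] result.
#' @param ... unused.
#' @return data.frame with columns `id`, `score_bits`, `qstart`, `qend`,
#'   `tstart`, `tend` (and `evalue` when calibrated).
#' @export
predict.seq_profile <- function(object, newdata, calibration = NULL, ...) {
  lo <- profile_logodds(object)
  res <- lapply(seq_len(nrow(newdata)), function(i) {
    codes <- encode_residues(gsub("-", "", newdata$seq[i]))
    .sw_affine(lo[, codes, drop = FALSE], object$gap_open, object$gap_extend)
  })
  out <- data.frame(
    id = newdata$id,
    score_bits = vapply(res, `[[`, numeric(1), "score"),
    qstart = vapply(res, function(r) as.integer(r$qstart), integer(1)),
    qend = vapply(res, function(r) as.integer(r$qend), integer(1)),
    tstart = vapply(res, function(r) as.integer(r$tstart), integer(1)),
    tend = vapply(res, function(r) as.integer(r$tend), integer(1)),
    stringsAsFactors = FALSE)
  if (!is.null(calibration)) out$evalue <- evalue(calibration, out$score_bits)
  out
}

#' Local profile-to-profile alignment
#'
#' Column-column score is the log2 co-emission ratio
#' `sum_a p_a q_a / f_a`; the optimal local pairing under affine gaps is
#' found by the same dynamic programming kernel used for sequences.  Gap
#' penalties are taken from the query profile.
#'
#' @param query,target `seq_profile` objects.
#' @return List with `score` (bits), `pairs` (query/target column pairing),
#'   spans `qstart`/`qend`/`tstart`/`tend`, and `covered_query_segments`
#'   (indices of query TM segments overlapped by the query span).
#' @export
align_profiles <- function(query, target) {
  S <- log2(crossprod(query$mat, target$mat / query$bg))
  res <- .sw_affine(S, query$gap_open, query$gap_extend)
  res$covered_query_segments <- if (!is.null(query$tm_segments) &&
                                    !is.na(res$qstart))
    segments_covered(query$tm_segments, res$qstart, res$qend,
                     min_overlap = 1L)
  else integer(0)
  res
}

# indices of TM segments whose overlap with [qstart, qend] is at least
# min_overlap columns
segments_covered <- function(tm_segments, qstart, qend, min_overlap = 5L) {
  if (is.null(tm_segments) || nrow(tm_segments) == 0L) return(integer(0))
  ov <- pmin(tm_segments[, "end"], qend) -
    pmax(tm_segments[, "start"], qstart) + 1L
  which(ov >= min_overlap)
}
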