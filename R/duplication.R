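# Internal duplication: the N- and C-terminal halves of a 7-TM profile
# (3 helices each, delineated at the midpoints of the loops flanking the
# central helix) are aligned against each other; significance against a
# column-shuffled null supports origin of the family by duplication of a
# 3-TM half.  Short half-proteins are classified by which half of the full
# profile their significant-but-partial hits cover.

# subset a profile to a span of match columns, remapping TM segments
subset_profile <- function(profile, from, to) {
  out <- profile
  out$mat <- profile$mat[, from:to, drop = FALSE]
  tm <- profile$tm_segments
  if (!is.null(tm)) {
    keep <- tm[, "start"] >= from & tm[, "end"] <= to
    out$tm_segments <- tm[keep, , drop = FALSE] - from + 1L
  }
  out$match_cols <- profile$match_cols[from:to]
  out
}

#' Split a profile into its N- and C-terminal halves
#'
#' For `2k` or `2k+1` TM segments the N-half runs from the first column to
#' the midpoint of the loop following segment `k`, and the C-half from the
#' midpoint of the loop preceding segment `n-k+1` to the last column; with
#' an odd count the central segment belongs to neither half's core.  For
#' the 7-helix architecture this yields segments 1-3 and 5-7.
#'
#' @param profile a [build_profile()] object with at least 2 TM segments.
#' @return `list(n = ProfileN, c = ProfileC)`.
#' @export
split_profile <- function(profile) {
  tm <- profile$tm_segments
  if (is.null(tm) || nrow(tm) < 2L)
    stop("profile needs at least 2 TM segments to split")
  nseg <- nrow(tm)
  k <- nseg %/% 2L
  m <- ncol(profile$mat)
  # loop between segment k and k+1
  n_cut <- tm[k, "end"] + (tm[k + 1L, "start"] - tm[k, "end"]) %/% 2L
  # loop between segment nseg-k and nseg-k+1
  c_from_seg <- nseg - k + 1L
  c_cut <- tm[c_from_seg - 1L, "end"] +
    (tm[c_from_seg, "start"] - tm[c_from_seg - 1L, "end"] + 1L) %/% 2L
  list(n = subset_profile(profile, 1L, n_cut),
       c = subset_profile(profile, c_cut, m))
}

#' Test a profile for internal N-half/C-half duplication
#'
#' Aligns the N-half profile against the C-half profile and calibrates the
#' score against `n_null` column-shuffled copies of the C-half.  The
#' verdict is "duplicated" when the E-value falls below `e_threshold`.
#'
#' @param profile a [build_profile()] object with TM segments.
#' @param n_null null sample size (default 500).
#' @param seed RNG seed.
#' @param e_threshold verdict threshold (default 1e-3; deliberately
#'   separate from the search acceptance threshold).
#' @return Object of class `duplication_test`: `score_bits`, `evalue`,
#'   `verdict` (logical), `covered_n_segments` (N-half TM segments covered
#'   by the duplication alignment), `alignment` (the profile pairing) and
#'   the calibration.
#' @export
detect_duplication <- function(profile, n_null = 500L, seed = 1L,
                               e_threshold = 1e-3) {
  halves <- split_profile(profile)
  res <- align_profiles(halves$n, halves$c)
  cal <- calibrate_profile(halves$n, n_null = n_null, database_size = 1L,
                           seed = seed, mode = "profile", target = halves$c)
  e <- evalue(cal, res$score)
  covered <- if (!is.na(res$qstart))
    segments_covered(halves$n$tm_segments, res$qstart, res$qend, 5L)
  else integer(0)
  structure(list(score_bits = res$score, evalue = e,
                 verdict = e < e_threshold,
                 covered_n_segments = covered,
                 alignment = res, calibration = cal,
                 e_threshold = e_threshold),
            class = "duplication_test")
}

#' @export
print.duplication_test <- function(x, ...) {
  cat("Internal duplication test (N-half vs C-half profile alignment)\n")
  cat("  score: ", round(x$score_bits, 2), " bits; E = ",
      signif(x$evalue, 3), " (threshold ", x$e_threshold, ")\n", sep = "")
  cat("  verdict: ", if (x$verdict) "duplicated" else "no duplication detected",
      "; N-half TM segments covered: ",
      paste(x$covered_n_segments, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Classify a sequence as an N-half or C-half protein
#'
#' Scores the sequence against the full profile.  If the hit is significant
#' (`E < e_accept`) but fails the all-segments coverage rule with its
#' covered segments confined to one half of the bundle, the sequence is
#' labelled with that half; a short sequence whose span straddles the
#' centre without covering everything is labelled with the better-covered
#' half and flagged `both_halves` (the behaviour of short proteins
#' homologous to both halves of a duplicated family).
#'
#' @param profile full family profile with TM segments.
#' @param seq sequence string or one-row record.
#' @param config a [search_config()].
#' @param calibration a [calibrate_profile()] result for this profile.
#' @return `list(half = "N"|"C"|"none", covered_segments, both_halves,
#'   evalue, score_bits)`.
#' @export
classify_half_protein <- function(profile, seq, config = search_config(),
                                  calibration) {
  res <- score_sequence(profile, seq)
  e <- evalue(calibration, res$score)
  nseg <- nrow(profile$tm_segments)
  covered <- if (!is.na(res$qstart))
    segments_covered(profile$tm_segments, res$qstart, res$qend,
                     config$min_segment_overlap)
  else integer(0)
  out <- list(half = "none", covered_segments = covered,
              both_halves = FALSE, evalue = e, score_bits = res$score)
  if (e >= config$e_accept || length(covered) == nseg || nseg < 2L)
    return(out)
  k <- nseg %/% 2L
  mid <- k + if (nseg %% 2L == 1L) 1L else 0L
  n_half <- seq_len(mid)                 # {1..4} for 7 segments
  c_half <- (nseg - mid + 1L):nseg       # {4..7} for 7 segments
  in_n <- length(intersect(covered, n_half))
  in_c <- length(intersect(covered, c_half))
  if (length(covered) == 0L) return(out)
  if (all(covered %in% n_half) && !all(covered %in% c_half)) {
    out$half <- "N"
  } else if (all(covered %in% c_half) && !all(covered %in% n_half)) {
    out$half <- "C"
  } else if (all(covered %in% n_half) && all(covered %in% c_half)) {
    # everything in the shared central segment; call the better-scoring side
    out$half <- if (in_n >= in_c) "N" else "C"
  } else {
    out$half <- if (in_n >= in_c) "N" else "C"
    out$both_halves <- TRUE
  }
  out
}
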