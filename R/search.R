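# The iterative family-discovery loop with the dual acceptance criterion:
# a hit is accepted only if (i) its E-value is below `e_accept` and (ii)
# its alignment covers every TM segment of the query profile (by at least
# `min_segment_overlap` columns).  Accepted sequences are realigned to the
# profile, the profile rebuilt and recalibrated, and the search repeated
# until the accepted identifier set stops changing.

#' Search configuration
#'
#' @param e_accept acceptance E-value threshold (default 1e-5).
#' @param e_seed_iterate inclusion threshold for seed-stage iteration, kept
#'   for parity with PSI-BLAST-style protocols (default 1e-3).
#' @param min_segment_overlap columns of a TM segment a hit's query span
#'   must overlap for the segment to count as covered (default 5).
#' @param require_all_segments if `TRUE` (default) a hit must cover every
#'   TM segment of the query; if `FALSE` one covered segment suffices.
#' @param max_iterations iteration cap of the discovery loop.
#' @param identity_split fractional identity above which sequences may be
#'   aligned directly rather than via profiles (default 0.40).
#' @param n_null calibration sample size per iteration.
#' @return Object of class `search_config`.
#' @export
search_config <- function(e_accept = 1e-5, e_seed_iterate = 1e-3,
                          min_segment_overlap = 5L,
                          require_all_segments = TRUE,
                          max_iterations = 10L,
                          identity_split = 0.40,
                          n_null = 200L) {
  if (e_accept <= 0) stop("e_accept must be positive")
  if (min_segment_overlap < 0L) stop("min_segment_overlap must be >= 0")
  structure(list(e_accept = e_accept, e_seed_iterate = e_seed_iterate,
                 min_segment_overlap = as.integer(min_segment_overlap),
                 require_all_segments = isTRUE(require_all_segments),
                 max_iterations = as.integer(max_iterations),
                 identity_split = identity_split,
                 n_null = as.integer(n_null)),
            class = "search_config")
}

#' Coverage rule of the dual acceptance criterion
#'
#' With `require_all_segments` the hit's query span must overlap every TM
#' segment of the profile by at least `min_segment_overlap` columns;
#' otherwise one covered segment suffices.  With `min_segment_overlap = 0`
#' any overlap (even an adjacent span) counts; that degenerate setting is
#' supported but not recommended.
#'
#' @param hit one row of a [search_proteome()] hit table (or any list with
#'   `qstart`/`qend`).
#' @param profile the query profile.
#' @param config a [search_config()].
#' @return `TRUE` if the hit satisfies the coverage rule.
#' @export
coverage_filter <- function(hit, profile, config = search_config()) {
  nseg <- if (is.null(profile$tm_segments)) 0L else nrow(profile$tm_segments)
  if (nseg == 0L) return(TRUE)
  if (is.na(hit$qstart)) return(FALSE)
  cov <- segments_covered(profile$tm_segments, hit$qstart, hit$qend,
                          max(config$min_segment_overlap, 0L))
  if (config$require_all_segments) length(cov) == nseg else length(cov) >= 1L
}

#' Search a proteome with a calibrated profile
#'
#' Scores every target, attaches E-values, computes the TM segments covered
#' by each hit's query span, and applies the dual acceptance criterion.
#' Hits are sorted by E-value with ties broken by target identifier.
#'
#' @param profile query [build_profile()] (with TM segments).
#' @param proteome data.frame of sequence records.
#' @param config a [search_config()].
#' @param calibration a [calibrate_profile()] result for this profile and
#'   `database_size = nrow(proteome)`.
#' @return data.frame with columns `id`, `score_bits`, `evalue`, `qstart`,
#'   `qend`, `tstart`, `tend`, `covered_segments` (comma string),
#'   `n_covered`, `accepted`.
#' @export
search_proteome <- function(profile, proteome, config = search_config(),
                            calibration) {
  if (nrow(proteome) == 0L)
    return(data.frame(id = character(0), score_bits = numeric(0),
                      evalue = numeric(0), qstart = integer(0),
                      qend = integer(0), tstart = integer(0),
                      tend = integer(0), covered_segments = character(0),
                      n_covered = integer(0), accepted = logical(0),
                      stringsAsFactors = FALSE))
  hits <- predict(profile, proteome, calibration = calibration)
  nseg <- if (is.null(profile$tm_segments)) 0L else nrow(profile$tm_segments)
  cov <- lapply(seq_len(nrow(hits)), function(i) {
    if (is.na(hits$qstart[i])) return(integer(0))
    segments_covered(profile$tm_segments, hits$qstart[i], hits$qend[i],
                     max(config$min_segment_overlap, 0L))
  })
  hits$covered_segments <- vapply(cov, paste, character(1), collapse = ",")
  hits$n_covered <- lengths(cov)
  covered_ok <- if (config$require_all_segments & nseg > 0L)
    hits$n_covered == nseg
  else if (nseg > 0L) hits$n_covered >= 1L else TRUE
  hits$accepted <- hits$evalue < config$e_accept & covered_ok
  hits[order(hits$evalue, hits$id), , drop = FALSE]
}

#' Align sequences to a profile
#'
#' Each sequence is aligned to the profile's match columns by local
#' dynamic-programming traceback; residues falling between consecutive
#' matched columns are placed in insert blocks (one shared block per
#' profile column, padded with gaps).  Unaligned termini are clipped, as in
#' curated family alignments that omit non-homologous extensions.
#'
#' @param profile a [build_profile()] object.
#' @param sequences data.frame of sequence records.
#' @return An [aa_alignment()] with attribute `profile_cols` giving, for
#'   each profile column, its column index in the new alignment (so TM
#'   annotation can be carried through), and attribute `tm_cols` with the
#'   profile's TM spans mapped to new columns.
#' @export
align_to_profile <- function(profile, sequences) {
  m <- ncol(profile$mat)
  n <- nrow(sequences)
  placed <- vector("list", n)
  inserts <- vector("list", n)
  for (i in seq_len(n)) {
    ungapped <- gsub("-", "", sequences$seq[i])
    res <- score_sequence(profile, ungapped)
    chars <- rep("-", m)
    ins <- vector("list", m + 1L)
    if (nrow(res$pairs) > 0L) {
      pr <- res$pairs
      sres <- strsplit(ungapped, "")[[1]]
      chars[pr[, 1]] <- sres[pr[, 2]]
      # residues between consecutive matched columns go to insert blocks
      for (r in seq_len(nrow(pr) - 1L)) {
        gap_res <- if (pr[r + 1L, 2] - pr[r, 2] > 1L)
          sres[(pr[r, 2] + 1L):(pr[r + 1L, 2] - 1L)] else character(0)
        if (length(gap_res))
          ins[[pr[r, 1] + 1L]] <- paste(gap_res, collapse = "")
      }
    }
    placed[[i]] <- chars
    inserts[[i]] <- ins
  }
  ins_max <- integer(m + 1L)
  for (i in seq_len(n)) {
    lens <- vapply(inserts[[i]], function(s) if (is.null(s)) 0L else nchar(s),
                   integer(1))
    ins_max <- pmax(ins_max, lens)
  }
  col_of <- seq_len(m) + cumsum(ins_max[seq_len(m)])
  ncolumns <- m + sum(ins_max)
  rows <- character(n)
  for (i in seq_len(n)) {
    chars <- rep("-", ncolumns)
    chars[col_of] <- placed[[i]]
    for (slot in which(!vapply(inserts[[i]], is.null, logical(1)))) {
      s <- inserts[[i]][[slot]]
      start <- if (slot == 1L) 1L else col_of[slot - 1L] + 1L
      chars[start:(start + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
    }
    rows[i] <- paste(chars, collapse = "")
  }
  nonempty <- gsub("-", "", rows) != ""
  out <- aa_alignment(sequences$id[nonempty], rows[nonempty])
  attr(out, "profile_cols") <- col_of
  if (!is.null(profile$tm_segments))
    attr(out, "tm_cols") <- cbind(start = col_of[profile$tm_segments[, "start"]],
                                  end = col_of[profile$tm_segments[, "end"]])
  out
}

#' Iterative family discovery
#'
#' The discovery loop: build a profile from the seed alignment, calibrate
#' its null score distribution, search the proteome, accept hits by the
#' dual criterion (E-value and full TM coverage), realign the accepted
#' sequences to the profile, rebuild, and repeat until the accepted
#' identifier set is unchanged (or `max_iterations` is hit, which flags
#' possible oscillation).  Repeating the search seeded with a converged
#' accepted set returns the same set.
#'
#' @param seed_msa seed [aa_alignment()].  TM annotation is taken from
#'   `tm_annotation`, else from `attr(seed_msa, "col_tm")` (generator
#'   truth) or `attr(seed_msa, "tm_cols")`; if absent it is predicted with
#'   [predict_tm()] + [consensus_topology()].
#' @param proteome data.frame of target sequence records.
#' @param config a [search_config()].
#' @param seed RNG seed for the per-iteration calibrations.
#' @param tm_annotation optional TM spans in seed alignment columns.
#' @return Object of class `family_search`: `accepted` (sorted ids),
#'   `alignment`, `profile`, `hits` (final hit table), `calibration`,
#'   `log` (per-iteration data.frame), `converged`, `iterations`.
#' @export
discover_family <- function(seed_msa, proteome, config = search_config(),
                            seed = 1L, tm_annotation = NULL) {
  if (is.null(tm_annotation))
    tm_annotation <- attr(seed_msa, "col_tm")
  if (is.null(tm_annotation))
    tm_annotation <- attr(seed_msa, "tm_cols")
  if (is.null(tm_annotation)) {
    preds <- lapply(seq_along(seed_msa$id), function(i)
      predict_tm(gsub("-", "", seed_msa$seq[i])))
    cons <- consensus_topology(seed_msa, preds)
    tm_annotation <- cons$segments
  }
  msa <- seed_msa
  accepted_prev <- character(0)
  log <- data.frame(iteration = integer(0), n_accepted = integer(0),
                    added = character(0), dropped = character(0),
                    stringsAsFactors = FALSE)
  converged <- FALSE
  profile <- NULL; hits <- NULL; cal <- NULL
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    profile <- build_profile(msa, tm_annotation = tm_annotation)
    cal <- calibrate_profile(profile, n_null = config$n_null,
                             database_size = nrow(proteome),
                             seed = seed + iter,
                             lengths = nchar(proteome$seq))
    hits <- search_proteome(profile, proteome, config, cal)
    accepted <- sort(hits$id[hits$accepted])
    log <- rbind(log, data.frame(
      iteration = iter, n_accepted = length(accepted),
      added = paste(setdiff(accepted, accepted_prev), collapse = ","),
      dropped = paste(setdiff(accepted_prev, accepted), collapse = ","),
      stringsAsFactors = FALSE))
    if (identical(accepted, accepted_prev)) { converged <- TRUE; break }
    if (length(accepted) == 0L) {
      warning("no sequences accepted; returning seed-stage result")
      break
    }
    accepted_prev <- accepted
    acc_records <- proteome[match(accepted, proteome$id), , drop = FALSE]
    msa <- align_to_profile(profile, acc_records)
    tm_annotation <- attr(msa, "tm_cols")
  }
  if (!converged && iter >= config$max_iterations)
    warning("accepted set did not stabilise within max_iterations ",
            "(possible oscillation)")
  structure(list(accepted = accepted_prev, alignment = msa,
                 profile = profile, hits = hits, calibration = cal,
                 log = log, converged = converged, iterations = iter,
                 config = config, seed = seed),
            class = "family_search")
}

#' @export
print.family_search <- function(x, ...) {
  cat("Iterative profile search: ", length(x$accepted),
      " sequences accepted after ", x$iterations, " iteration(s)",
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.family_search <- function(object, ...) {
  cat("Iterative family discovery\n")
  cat("  accepted sequences: ", length(object$accepted), "\n", sep = "")
  cat("  iterations: ", object$iterations,
      if (object$converged) " (converged)" else " (not converged)",
      "\n", sep = "")
  cat("  profile: ", ncol(object$profile$mat), " columns, ",
      nrow(object$profile$tm_segments), " TM segments\n", sep = "")
  cat("  acceptance: E < ", object$config$e_accept,
      if (object$config$require_all_segments)
        " and all TM segments covered" else " and >= 1 TM segment covered",
      "\n", sep = "")
  print(object$log)
  invisible(object)
}
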