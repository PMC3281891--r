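# Transmembrane topology: windowed Kyte-Doolittle hydropathy prediction per
# sequence, alignment-level consensus, and the alternating sidedness model
# (N-terminus lumenal by default, as established experimentally for the
# KDEL receptors).

#' Topology model constructor
#'
#' @param segments two-column matrix of ordered, non-overlapping residue
#'   (or column) spans.
#' @param n_side side of the N-terminus, `"lumen"` or `"cytoplasm"`.
#' @param coordinates `"residue"` or `"column"`.
#' @return Object of class `tm_topology` with `segments`, `n_helices`,
#'   `n_side` and per-loop sidedness (`loop_sides`, including the
#'   C-terminal tail as the last entry).
#' @export
tm_topology <- function(segments, n_side = "lumen",
                        coordinates = c("residue", "column")) {
  coordinates <- match.arg(coordinates)
  segments <- matrix(as.integer(segments), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  if (nrow(segments) > 1L) {
    if (any(diff(segments[, "start"]) <= 0) ||
        any(segments[-1L, "start"] <= segments[-nrow(segments), "end"]))
      stop("TM segments must be ordered and non-overlapping")
  }
  obj <- structure(list(segments = segments,
                        n_helices = nrow(segments),
                        n_side = n_side, loop_sides = NULL,
                        coordinates = coordinates),
                   class = "tm_topology")
  orient_topology(obj, n_side)
}

#' Assign alternating sidedness to a topology
#'
#' Loops alternate between the two membrane faces starting from the side of
#' the N-terminus; each helix crossing flips the side, so with 7 helices
#' and a lumenal N-terminus the C-terminal tail is cytoplasmic.  With zero
#' helices both termini share `n_side`.
#'
#' @param topology a `tm_topology`.
#' @param n_side `"lumen"` or `"cytoplasm"`.
#' @return The topology with `n_side` and `loop_sides` updated;
#'   `loop_sides[i]` is the side of the loop after helix `i` (the last
#'   entry is the C-terminal tail).
#' @export
orient_topology <- function(topology, n_side = c("lumen", "cytoplasm")) {
  n_side <- match.arg(n_side)
  other <- if (n_side == "lumen") "cytoplasm" else "lumen"
  k <- topology$n_helices
  sides <- if (k == 0L) n_side else
    ifelse(seq_len(k) %% 2L == 1L, other, n_side)
  topology$n_side <- n_side
  topology$loop_sides <- sides
  topology
}

#' @export
print.tm_topology <- function(x, ...) {
  cat("TM topology: ", x$n_helices, " helices (", x$coordinates,
      " coordinates), N-terminus ", x$n_side, "\n", sep = "")
  if (x$n_helices > 0L)
    for (i in seq_len(x$n_helices))
      cat(sprintf("  helix %d: %d-%d (%s side after)\n", i,
                  x$segments[i, 1], x$segments[i, 2], x$loop_sides[i]))
  invisible(x)
}

# centered moving average of hydropathy; windows are truncated at the
# sequence ends (mean over the residues actually present), so helices
# immediately following a short terminal tail are not penalised
window_hydropathy <- function(seq, window = 19L) {
  kd <- c(kyte_doolittle(), X = 0)
  vals <- kd[strsplit(seq, "")[[1]]]
  n <- length(vals)
  if (n < window) return(rep(NA_real_, n))
  half <- window %/% 2L
  cs <- cumsum(c(0, vals))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# split runs longer than max_len recursively at the interior hydropathy
# minimum, keeping both parts at least min_run long
split_long_runs <- function(start, end, hyd, max_len, min_run) {
  len <- end - start + 1L
  if (len <= max_len) return(matrix(c(start, end), 1L, 2L))
  lo <- start + min_run
  hi <- end - min_run
  if (lo > hi) return(matrix(c(start, end), 1L, 2L))
  inner <- hyd[lo:hi]
  inner[is.na(inner)] <- Inf
  cut <- lo + which.min(inner) - 1L
  rbind(split_long_runs(start, cut - 1L, hyd, max_len, min_run),
        split_long_runs(cut + 1L, end, hyd, max_len, min_run))
}

#' Predict TM helices from windowed hydropathy
#'
#' Residues whose centred Kyte-Doolittle window mean exceeds `threshold`
#' are candidates; runs of at least `min_run` candidates become segments,
#' and runs longer than `max_run` are split recursively at their interior
#' hydropathy minimum (two merged 21-residue helices exceed 35 and are
#' separated at the loop between them).
#'
#' @param seq sequence string (or one-row record data.frame).
#' @param window window length (default 19).
#' @param threshold window-mean hydropathy cutoff (default 1.6).
#' @param min_run minimum marked run length forming a segment (default 15).
#' @param max_run runs longer than this are split (default 35).
#' @param n_side N-terminal side annotation.
#' @return A [tm_topology()] in residue coordinates.  Sequences shorter
#'   than the window yield zero segments with a warning.
#' @export
predict_tm <- function(seq, window = 19L, threshold = 1.6,
                       min_run = 15L, max_run = 35L, n_side = "lumen") {
  if (is.data.frame(seq)) seq <- seq$seq[1]
  seq <- gsub("-", "", seq)
  if (nchar(seq) < window) {
    warning("sequence shorter than the hydropathy window; no segments")
    return(tm_topology(matrix(integer(0), 0L, 2L), n_side))
  }
  hyd <- window_hydropathy(seq, window)
  marked <- !is.na(hyd) & hyd > threshold
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- matrix(integer(0), 0L, 2L)
  for (k in which(r$values)) {
    if (r$lengths[k] < min_run) next
    segs <- rbind(segs, split_long_runs(starts[k], ends[k], hyd,
                                        max_run, min_run))
  }
  segs <- segs[segs[, 2] - segs[, 1] + 1L >= min_run, , drop = FALSE]
  tm_topology(segs, n_side)
}

#' Consensus topology from an alignment
#'
#' An alignment column is consensus-TM if more than half of the sequences
#' having a residue in that column place it inside one of their predicted
#' segments.  Runs of at least `min_run` such columns become consensus
#' segments; runs longer than `max_run` are split at the column of minimum
#' mean hydropathy, exactly as in the per-sequence predictor.
#'
#' @param msa an [aa_alignment()].
#' @param per_seq list of [predict_tm()] results, one per row of `msa`
#'   (computed from the ungapped rows if omitted).
#' @param min_run minimum consensus run length in columns (default 12).
#' @param max_run consensus runs longer than this are split (default 35).
#' @param n_side N-terminal side annotation.
#' @param ... forwarded to [predict_tm()] when `per_seq` is omitted.
#' @return A [tm_topology()] in alignment-column coordinates.
#' @export
consensus_topology <- function(msa, per_seq = NULL, min_run = 12L,
                               max_run = 35L, n_side = "lumen", ...) {
  mat <- aln_matrix(msa)
  n <- nrow(mat); m <- ncol(mat)
  if (is.null(per_seq))
    per_seq <- lapply(seq_len(n), function(i)
      suppressWarnings(predict_tm(gsub("-", "", msa$seq[i]), ...)))
  inside <- matrix(FALSE, n, m)
  has_res <- mat != "-"
  for (i in seq_len(n)) {
    pos_of_col <- cumsum(has_res[i, ])
    segs <- per_seq[[i]]$segments
    if (nrow(segs) == 0L) next
    in_seg <- rep(FALSE, max(pos_of_col))
    for (s in seq_len(nrow(segs)))
      in_seg[segs[s, 1]:segs[s, 2]] <- TRUE
    inside[i, ] <- has_res[i, ] & in_seg[pmax(pos_of_col, 1L)]
  }
  votes <- colSums(inside)
  voters <- colSums(has_res)
  tm_col <- voters > 0L & votes > voters / 2
  # mean hydropathy per column for the split rule
  kd <- c(kyte_doolittle(), X = 0, "-" = NA)
  kd_mat <- matrix(kd[mat], n, m)
  col_hyd <- colMeans(kd_mat, na.rm = TRUE)
  col_hyd[is.nan(col_hyd)] <- 0
  r <- rle(as.vector(tm_col))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- matrix(integer(0), 0L, 2L)
  for (k in which(r$values)) {
    if (r$lengths[k] < min_run) next
    segs <- rbind(segs, split_long_runs(starts[k], ends[k], col_hyd,
                                        max_run, min_run))
  }
  segs <- segs[segs[, 2] - segs[, 1] + 1L >= min_run, , drop = FALSE]
  tm_topology(segs, n_side, coordinates = "column")
}
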