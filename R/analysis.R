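# Family characterisation: per-column conservation (relative entropy vs
# background), motif and conserved-residue-class detection, p-distances and
# the neighbor-joining phylogeny.

#' Per-column conservation track
#'
#' For every alignment column the relative entropy (in bits) of the
#' sequence-weighted, pseudocounted residue frequencies against the
#' background composition, together with the majority residue and gap
#' fraction.  Columns with more than 50% gaps are masked (`NA` score).
#'
#' @param msa an [aa_alignment()].
#' @param pseudocount background pseudocount weight (default 0.05; light,
#'   so near-invariant columns keep scores well above diverse ones).
#' @return data.frame of class `conservation_track` with columns `column`,
#'   `score`, `majority`, `majority_fraction` (weighted frequency of the
#'   majority residue among residues present) and `gap_fraction`.
#' @export
column_conservation <- function(msa, pseudocount = 0.05) {
  mat <- aln_matrix(msa)
  w <- position_weights(mat)
  bg <- aa_background()
  m <- ncol(mat)
  score <- numeric(m); majority <- character(m); gapf <- numeric(m)
  majf <- numeric(m)
  for (j in seq_len(m)) {
    col <- mat[, j]
    gapf[j] <- mean(col == "-")
    keep <- col != "-" & col != "X"
    if (gapf[j] > 0.5 || !any(keep)) {
      score[j] <- NA_real_; majority[j] <- "-"; majf[j] <- NA_real_
      next
    }
    counts <- setNames(numeric(20L), AA_ALPHABET)
    for (i in which(keep)) counts[col[i]] <- counts[col[i]] + w[i]
    p <- counts + pseudocount * bg
    p <- p / sum(p)
    score[j] <- sum(p * log2(p / bg))
    majority[j] <- AA_ALPHABET[which.max(counts)]
    majf[j] <- max(counts) / sum(counts)
  }
  structure(data.frame(column = seq_len(m), score = score,
                       majority = majority, majority_fraction = majf,
                       gap_fraction = gapf,
                       stringsAsFactors = FALSE),
            class = c("conservation_track", "data.frame"))
}

#' Find a loop motif in an alignment
#'
#' Scans each member's ungapped sequence, restricted to the given loop
#' column regions, for exact occurrences of `motif` (e.g. the PQ doublet),
#' maps each occurrence to the alignment column of its first residue, and
#' reports the column spans carried by at least `threshold` of the
#' members.
#'
#' @param msa an [aa_alignment()].
#' @param motif motif string (default `"PQ"`).
#' @param loop_regions two-column matrix of loop spans in alignment-column
#'   coordinates (e.g. the complement of a consensus topology's TM
#'   segments).  `NULL` scans everywhere.
#' @param threshold minimum carrier fraction (default 0.5).
#' @return data.frame with columns `col_start`, `col_end`, `fraction`,
#'   sorted by column; zero rows when the motif is absent.
#' @export
find_motif <- function(msa, motif = "PQ", loop_regions = NULL,
                       threshold = 0.5) {
  mat <- aln_matrix(msa)
  n <- nrow(mat)
  ml <- nchar(motif)
  counts <- integer(ncol(mat))
  for (i in seq_len(n)) {
    has_res <- mat[i, ] != "-"
    cols <- which(has_res)
    seq_i <- paste(mat[i, cols], collapse = "")
    hits <- gregexpr(motif, seq_i, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (pos in as.integer(hits)) {
      col <- cols[pos]
      if (!is.null(loop_regions)) {
        inside <- any(col >= loop_regions[, 1] & col <= loop_regions[, 2])
        if (!inside) next
      }
      counts[col] <- counts[col] + 1L
    }
  }
  frac <- counts / n
  sel <- which(frac >= threshold)
  data.frame(col_start = sel, col_end = pmin(sel + ml - 1L, ncol(mat)),
             fraction = frac[sel])
}

#' Columns conserved within a residue class
#'
#' Reports, per residue class, the alignment columns whose conservation
#' score is at least `min_score` and whose majority residue belongs to the
#' class.  The defaults look for the strongly conserved basic (K/R/H) and
#' serine columns characteristic of PQ-loop-like families.
#'
#' @param track a [column_conservation()] result.
#' @param classes named list of residue-letter vectors.
#' @param min_score conservation cutoff in bits (default 2.8).
#' @param max_gap_fraction occupancy requirement: a conserved column must
#'   be present in nearly all members (default at most 10% gaps), so that
#'   sparsely occupied loop columns cannot outrank fully-present ones.
#' @param min_majority_fraction near-invariance requirement on the
#'   weighted majority-residue frequency (default 0.85): relative entropy
#'   alone conflates rarity with conservation, so a rare residue kept by
#'   chance in most members can outscore a genuinely invariant common one.
#' @param tm_regions optional two-column matrix of TM segment spans in
#'   alignment-column coordinates (e.g. a consensus topology's segments).
#'   When given, only columns inside a span are considered -- the
#'   conserved basic/serine columns of PQ-loop-like families sit in the
#'   helical body, and the restriction keeps sporadically conserved loop
#'   columns from diluting the call.
#' @return Named list (one element per class) of column indices.
#' @export
find_conserved_class_columns <- function(track,
                                         classes = list(
                                           basic = c("K", "R", "H"),
                                           serine = "S"),
                                         min_score = 2.8,
                                         max_gap_fraction = 0.1,
                                         min_majority_fraction = 0.85,
                                         tm_regions = NULL) {
  in_tm <- if (is.null(tm_regions)) rep(TRUE, nrow(track)) else
    vapply(track$column, function(col)
      any(col >= tm_regions[, 1] & col <= tm_regions[, 2]), logical(1))
  lapply(classes, function(cls) {
    sel <- !is.na(track$score) & track$score >= min_score &
      track$gap_fraction <= max_gap_fraction &
      track$majority_fraction >= min_majority_fraction &
      track$majority %in% cls & in_tm
    track$column[sel]
  })
}

#' Pairwise p-distances from an alignment
#'
#' Distance between two rows is 1 minus fractional identity over their
#' mutually ungapped columns; rows sharing no ungapped column get distance
#' 1 with a warning.  A `-ln(1-p)` Poisson correction is available.
#'
#' @param msa an [aa_alignment()].
#' @param correction `"none"` (p-distance, default) or `"poisson"`.
#' @return Symmetric distance matrix with zero diagonal, row/column names
#'   from the alignment ids.
#' @export
pairwise_distances <- function(msa, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  mat <- aln_matrix(msa)
  n <- nrow(mat)
  has <- mat != "-"
  D <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- has[i, ] & has[j, ]
      if (!any(both)) {
        warning("rows ", msa$id[i], " and ", msa$id[j],
                " share no ungapped column; distance set to 1")
        D[i, j] <- D[j, i] <- 1
        next
      }
      p <- 1 - mean(mat[i, both] == mat[j, both])
      if (correction == "poisson") p <- -log(pmax(1 - p, 1e-10))
      D[i, j] <- D[j, i] <- p
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Classical neighbor-joining on a distance matrix (via `ape::nj` for four
#' or more taxa; the three-taxon case uses the closed-form three-point
#' branch lengths, and two taxa join by a single edge split evenly).
#' Negative branch lengths are clamped to zero with a message.
#'
#' @param distances symmetric distance matrix with row/column names.
#' @return An `ape` `phylo` tree.
#' @export
nj_tree <- function(distances) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (n < 2L) stop("need at least 2 taxa")
  ids <- rownames(distances)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  if (n == 2L) {
    d <- distances[1L, 2L]
    tree <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                          ids[1], d / 2, ids[2], d / 2))
  } else if (n == 3L) {
    d12 <- distances[1, 2]; d13 <- distances[1, 3]; d23 <- distances[2, 3]
    b <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2,
           (d13 + d23 - d12) / 2)
    tree <- ape::read.tree(text = sprintf("(%s:%g,%s:%g,%s:%g);",
                                          ids[1], b[1], ids[2], b[2],
                                          ids[3], b[3]))
  } else {
    tree <- ape::nj(stats::as.dist(distances))
  }
  if (any(tree$edge.length < 0)) {
    message("clamping ", sum(tree$edge.length < 0),
            " negative branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}
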