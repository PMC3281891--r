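# Sequence and alignment I/O.  Unaligned sequences travel as a plain
# data.frame with columns id / desc / seq ("sequence set"); alignments are
# the S3 class "aa_alignment" defined below.

#' Construct an alignment object
#'
#' An alignment is an ordered set of equal-length gapped rows over the
#' amino-acid alphabet plus `-`.  Per-column annotations (e.g. Stockholm
#' `#=GC` lines) are kept in `gc` as named strings of the same length.
#'
#' @param id character vector of unique row identifiers (no whitespace).
#' @param seq character vector of gapped row strings, all the same length.
#' @param desc optional character vector of free-text descriptions.
#' @param gc optional named list/character of per-column annotation strings.
#' @return An object of class `aa_alignment` with fields `id`, `desc`,
#'   `seq` and `gc`.
#' @export
aa_alignment <- function(id, seq, desc = NULL, gc = NULL) {
  id <- as.character(id)
  seq <- as.character(seq)
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (length(seq) < 1L) stop("alignment needs at least one row")
  if (any(grepl("[[:space:]]", id))) stop("row ids must not contain whitespace")
  if (anyDuplicated(id)) stop("duplicate row id(s): ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  w <- unique(nchar(seq))
  if (length(w) != 1L) {
    off <- id[nchar(seq) != nchar(seq)[1]][1]
    stop("ragged alignment rows (offending row: ", off, ")")
  }
  if (w == 0L) stop("alignment rows are empty")
  if (any(gsub("-", "", seq) == "")) stop("alignment row with no residues")
  if (is.null(desc)) desc <- rep("", length(id))
  gc <- as.list(gc)
  if (length(gc) && any(nchar(unlist(gc)) != w))
    stop("per-column annotation length differs from column count")
  structure(list(id = id, desc = desc, seq = seq, gc = gc),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Amino-acid alignment: ", length(x$id), " rows x ", aln_ncol(x),
      " columns\n", sep = "")
  show <- utils::head(seq_along(x$id), 8L)
  for (i in show) {
    row <- x$seq[i]
    if (nchar(row) > 60) row <- paste0(substr(row, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", x$id[i], row))
  }
  if (length(x$id) > 8L) cat("  ...\n")
  invisible(x)
}

#' Number of columns of an alignment
#'
#' @param msa an [aa_alignment()].
#' @return Integer column count.
#' @export
aln_ncol <- function(msa) nchar(msa$seq[1])

# alignment rows as a character matrix (rows x columns)
aln_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$seq, ""))
}

#' Read unaligned FASTA sequences
#'
#' Wraps `Biostrings::readAAStringSet()` and returns a plain data.frame.
#' Non-standard residue letters (B, Z, U, O, ...) are mapped to `X` with a
#' warning; gap characters are stripped unless `aligned = TRUE`.
#'
#' @param path path to a FASTA file.
#' @param aligned keep gap characters (aligned-FASTA mode).
#' @return data.frame with columns `id` (first header token), `desc`
#'   (remainder of the header) and `seq`.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    stop("FASTA format error at line 1: empty file")
  if (!startsWith(first, ">"))
    stop("FASTA format error at line 1: expected '>' header")
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  headers <- names(set)
  id <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  if (anyDuplicated(id))
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  seqs <- normalize_residues(as.character(set))
  if (!aligned) seqs <- gsub("-", "", seqs)
  if (any(seqs == "")) stop("empty sequence for id ", id[seqs == ""][1])
  data.frame(id = id, desc = desc, seq = seqs, stringsAsFactors = FALSE)
}

#' Write unaligned (or aligned) FASTA
#'
#' @param records data.frame with columns `id`, `desc`, `seq`.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$desc[i]))
      paste(records$id[i], records$desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and Stockholm 1.0.  Stockholm per-column `#=GC`
#' annotations are preserved in the `gc` field of the returned alignment.
#'
#' @param path path to the alignment file.
#' @param dialect `"stockholm"` or `"aligned_fasta"`.
#' @return An [aa_alignment()] object.
#' @export
read_msa <- function(path, dialect = c("aligned_fasta", "stockholm")) {
  dialect <- match.arg(dialect)
  if (dialect == "aligned_fasta") {
    rec <- read_fasta(path, aligned = TRUE)
    if (length(unique(nchar(rec$seq))) != 1L) {
      off <- rec$id[nchar(rec$seq) != nchar(rec$seq)[1]][1]
      stop("ragged alignment rows (offending row: ", off, ")")
    }
    return(aa_alignment(rec$id, rec$seq, rec$desc))
  }
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[1]))
    stop("Stockholm format error at line 1: missing '# STOCKHOLM' header")
  seqs <- list(); gc <- list()
  for (ln in lines[-1]) {
    if (grepl("^\\s*$", ln) || identical(ln, "//")) next
    if (startsWith(ln, "#=GC ")) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      gc[[f[2]]] <- paste0(gc[[f[2]]], f[3])
    } else if (startsWith(ln, "#")) {
      next
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) != 2L) stop("Stockholm format error near: ", ln)
      seqs[[f[1]]] <- paste0(seqs[[f[1]]], f[2])
    }
  }
  if (length(seqs) == 0L) stop("Stockholm format error: no sequence rows")
  seqv <- normalize_residues(gsub("\\.", "-", unlist(seqs)))
  lens <- nchar(seqv)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment rows (offending row: ",
         names(seqs)[lens != lens[1]][1], ")")
  aa_alignment(names(seqs), unname(seqv), gc = gc)
}

#' Write an alignment
#'
#' @param msa an [aa_alignment()] object.
#' @param path output path.
#' @param dialect `"stockholm"` or `"aligned_fasta"`.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, dialect = c("stockholm", "aligned_fasta")) {
  dialect <- match.arg(dialect)
  if (dialect == "aligned_fasta") {
    return(write_fasta(data.frame(id = msa$id, desc = msa$desc, seq = msa$seq,
                                  stringsAsFactors = FALSE),
                       path, width = 1000000L))
  }
  wid <- max(nchar(msa$id), if (length(msa$gc)) nchar(names(msa$gc)) + 5L else 0L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(sprintf("%-*s %s", wid, msa$id, msa$seq), con)
  for (nm in names(msa$gc))
    writeLines(sprintf("#=GC %-*s %s", wid - 5L, nm, msa$gc[[nm]]), con)
  writeLines("//", con)
  invisible(path)
}

# drop columns that are all-gap; returns alignment plus map new->old column
drop_allgap_columns <- function(msa) {
  m <- aln_matrix(msa)
  keep <- which(colSums(m != "-") > 0L)
  seqs <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  gc <- lapply(msa$gc, function(s)
    paste(strsplit(s, "")[[1]][keep], collapse = ""))
  out <- aa_alignment(msa$id, seqs, msa$desc, gc)
  attr(out, "col_map") <- keep
  out
}

#' Load the packaged PQ-loop family tables
#'
#' Packaged TSV transcriptions of the curated human and yeast PQ-loop
#' protein tables.  The three short human proteins homologous to both the
#' N- and the C-terminal half of the full-length members (BRP44, BRP44L,
#' C3orf55) carry `short_half_flag = TRUE`.
#'
#' @param which `"human"` or `"yeast"`.
#' @return data.frame with columns `uniprot_id`, `swissprot_id`,
#'   `protein_name`, `gene_name`, `length`, `short_half_flag`.
#' @export
load_family_table <- function(which = c("human", "yeast")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0(which, "_pq_loop.tsv"), package = "pqfam")
  if (!nzchar(path)) stop("packaged fixture not found for table ", which)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  tab$short_half_flag <- as.logical(tab$short_half_flag)
  stopifnot(all(tab$length > 0L))
  tab
}
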