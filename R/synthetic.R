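# Synthetic membrane-protein families with complete ground truth.
#
# The generator emulates the architecture of PQ-loop-like proteins: a bundle
# of hydrophobic TM helices joined by short loops, a one-residue N-terminal
# tail and a ~15-residue C-terminal tail; optionally the C-terminal three
# helices (and their interleaving loops) are a diverged copy of the
# N-terminal three (internal duplication); short motifs (e.g. the PQ
# doublet) and strongly conserved basic/serine columns are planted at known
# sites and evolve at a reduced rate.  Everything is seeded and emits truth
# (TM spans, motif spans, conserved positions, per-member coordinate maps,
# and the by-construction multiple alignment).

#' Specification of a synthetic membrane-protein family
#'
#' @param n_helices number of TM helices (default 7).
#' @param helix_len helix length in residues (default 21).
#' @param loop_len_range inclusive range of inter-helix loop lengths;
#'   loops are short, under 20 residues, by default.
#' @param n_term_len,c_term_len terminal tail lengths (defaults 1 and 15,
#'   the KDEL-receptor-like architecture).
#' @param duplication if `TRUE`, the C-terminal half of the helix bundle is
#'   generated as a diverged copy of the N-terminal half.
#' @param motif_spec list of `list(loop=, motif=, rate_mult=)` entries: a
#'   motif string planted centrally in the given loop, evolving at
#'   `rate_mult` times the family rate.  Default plants "PQ" in the loops
#'   after helices 1 and 5 (one per half).
#' @param conserved_cols list of `list(helix=, offset=, class=)` entries
#'   with class `"basic"` (K/R) or `"serine"`; planted columns evolve at
#'   `conserved_rate_mult` times the family rate.
#' @param n_members number of family members emitted by [evolve_family()].
#' @param divergence expected substitutions per site separating each member
#'   from the ancestor (and the two halves at the duplication event).
#' @param indel_rate per-site indel initiation probability, loops and
#'   termini only.
#' @param conserved_rate_mult rate multiplier at planted conserved columns.
#' @param min_helix_hydropathy membrane-insertion viability floor: minimum
#'   helix-mean Kyte-Doolittle hydropathy of an emitted ancestral helix
#'   (draws below it are rejected and redrawn).
#' @param seed default RNG seed for operations on this spec.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_helices = 7L, helix_len = 21L,
                        loop_len_range = c(3L, 19L),
                        n_term_len = 1L, c_term_len = 15L,
                        duplication = TRUE,
                        motif_spec = list(
                          list(loop = 1L, motif = "PQ", rate_mult = 0.05),
                          list(loop = 5L, motif = "PQ", rate_mult = 0.05)),
                        conserved_cols = list(
                          list(helix = 2L, offset = 1L, class = "basic"),
                          list(helix = 6L, offset = 1L, class = "basic"),
                          list(helix = 3L, offset = 3L, class = "serine")),
                        n_members = 20L, divergence = 0.5,
                        indel_rate = 0.02, conserved_rate_mult = 0.05,
                        min_helix_hydropathy = 3.2, seed = 1L) {
  if (n_helices < 1L) stop("n_helices must be >= 1")
  if (divergence < 0) stop("divergence must be >= 0")
  if (n_members < 1L) stop("n_members must be >= 1")
  if (length(loop_len_range) != 2L || loop_len_range[1] > loop_len_range[2])
    stop("loop_len_range must be an increasing pair")
  for (m in motif_spec) {
    if (m$loop >= n_helices)
      stop("motif loop index ", m$loop, " outside 1..", n_helices - 1L)
    if (nchar(m$motif) > loop_len_range[2])
      stop("motif '", m$motif, "' longer than the maximum loop length")
  }
  for (cc in conserved_cols) {
    if (cc$helix > n_helices || cc$offset > helix_len)
      stop("conserved column outside the helix bundle")
    if (!cc$class %in% c("basic", "serine"))
      stop("conserved column class must be 'basic' or 'serine'")
  }
  structure(list(n_helices = as.integer(n_helices),
                 helix_len = as.integer(helix_len),
                 loop_len_range = as.integer(loop_len_range),
                 n_term_len = as.integer(n_term_len),
                 c_term_len = as.integer(c_term_len),
                 duplication = isTRUE(duplication),
                 motif_spec = motif_spec,
                 conserved_cols = conserved_cols,
                 n_members = as.integer(n_members),
                 divergence = divergence,
                 indel_rate = indel_rate,
                 conserved_rate_mult = conserved_rate_mult,
                 min_helix_hydropathy = min_helix_hydropathy,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' @export
print.family_spec <- function(x, ...) {
  cat("Synthetic family spec: ", x$n_helices, " TM helices x ", x$helix_len,
      " aa, loops ", x$loop_len_range[1], "-", x$loop_len_range[2],
      " aa\n", sep = "")
  cat("  duplication: ", x$duplication, "; members: ", x$n_members,
      "; divergence: ", x$divergence, " subs/site; seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# sample `n` residues from a distribution over the 20-letter alphabet
sample_residues <- function(n, prob) {
  if (n <= 0L) return(character(0))
  sample(AA_ALPHABET, n, replace = TRUE, prob = prob)
}

#' Generate the ancestral sequence of a family
#'
#' Helices draw from the hydrophobic-biased [helix_distribution()] subject
#' to a membrane-insertion viability floor (`spec$min_helix_hydropathy` on
#' the helix-mean Kyte-Doolittle value: draws below it are rejected and
#' redrawn, as a helix that would not partition into the bilayer would not
#' survive in a polytopic membrane protein); loops and termini draw from
#' [aa_background()].  Conserved basic/serine columns are planted before
#' the viability check so the check applies to the helix as emitted.  With
#' `spec$duplication` the last `floor(n_helices/2)` helices and their
#' interleaving loops are a copy of the first ones with `spec$divergence`
#' substitutions per site applied (the mutated copy is itself redrawn
#' until it passes the viability floor).  Motifs are overwritten centrally
#' in their loops afterwards.
#'
#' @param spec a [family_spec()].
#' @param seed RNG seed (default `spec$seed`).
#' @return `list(record=, truth=)`: a one-row sequence data.frame and the
#'   ancestral truth (TM/loop spans, motif and conserved-column positions,
#'   per-site class table, duplication flag).
#' @export
make_ancestor <- function(spec, seed = spec$seed) {
  set.seed(seed)
  nh <- spec$n_helices
  hl <- spec$helix_len
  hdist <- helix_distribution()
  bg <- aa_background()
  kd <- kyte_doolittle()

  loop_len <- integer(max(nh - 1L, 0L))
  if (nh > 1L)
    loop_len <- sample(seq(spec$loop_len_range[1], spec$loop_len_range[2]),
                       nh - 1L, replace = TRUE)
  # motif-bearing loops must be able to hold their motif
  for (m in spec$motif_spec)
    loop_len[m$loop] <- max(loop_len[m$loop], nchar(m$motif))

  k <- nh %/% 2L
  if (spec$duplication && k >= 1L && nh > 1L) {
    # loops interleaving the last k helices mirror those of the first k
    if (k >= 2L)
      loop_len[(nh - k + 1L):(nh - 1L)] <- loop_len[1L:(k - 1L)]
  }

  # lay out regions
  regions <- list(list(type = "nterm", idx = 0L, len = spec$n_term_len))
  for (i in seq_len(nh)) {
    regions[[length(regions) + 1L]] <- list(type = "helix", idx = i, len = hl)
    if (i < nh)
      regions[[length(regions) + 1L]] <-
        list(type = "loop", idx = i, len = loop_len[i])
  }
  regions[[length(regions) + 1L]] <-
    list(type = "cterm", idx = 0L, len = spec$c_term_len)

  type <- unlist(lapply(regions, function(r) rep(r$type, r$len)))
  elem <- unlist(lapply(regions, function(r) rep(r$idx, r$len)))
  L <- length(type)
  res <- character(L)
  res[type != "helix"] <- sample_residues(sum(type != "helix"), bg)

  helix_span <- function(i) range(which(type == "helix" & elem == i))
  loop_span <- function(i) range(which(type == "loop" & elem == i))
  tm <- t(vapply(seq_len(nh), helix_span, numeric(2)))
  colnames(tm) <- c("start", "end")

  # planted conserved residues, fixed before the viability check
  cons_helix <- vapply(spec$conserved_cols, function(cc) cc$helix, integer(1))
  cons_offset <- vapply(spec$conserved_cols, function(cc) cc$offset, integer(1))
  cons_residue <- vapply(spec$conserved_cols, function(cc)
    if (cc$class == "basic") sample(c("K", "R"), 1L) else "S", character(1))

  viable <- function(h) mean(kd[h]) >= spec$min_helix_hydropathy
  draw_helix <- function(i) {
    fixed <- which(cons_helix == i)
    for (attempt in 1:1000) {
      h <- sample_residues(hl, hdist)
      h[cons_offset[fixed]] <- cons_residue[fixed]
      if (viable(h)) return(h)
    }
    h
  }
  mutate_helix <- function(src, i) {
    # diverged copy of helix `src`, redrawn until it passes the floor
    fixed <- which(cons_helix == i)
    for (attempt in 1:1000) {
      h <- src
      hit <- stats::rpois(hl, spec$divergence) > 0L
      h[hit] <- sample_residues(sum(hit), hdist)
      h[cons_offset[fixed]] <- cons_residue[fixed]
      if (viable(h)) return(h)
    }
    h
  }

  dup <- spec$duplication && k >= 1L && nh > 1L
  n_fresh <- if (dup) nh - k else nh  # C-half helices are copies
  for (i in seq_len(n_fresh))
    res[tm[i, "start"]:tm[i, "end"]] <- draw_helix(i)
  if (dup) {
    for (j in seq_len(k)) {
      dst <- nh - k + j
      res[tm[dst, "start"]:tm[dst, "end"]] <-
        mutate_helix(res[tm[j, "start"]:tm[j, "end"]], dst)
    }
    # interleaving loops of the C-half copy the N-half loops, diverged
    if (k >= 2L) {
      for (j in seq_len(k - 1L)) {
        sp_src <- loop_span(j)
        sp_dst <- loop_span(nh - k + j)
        lsrc <- res[sp_src[1]:sp_src[2]]
        hit <- stats::rpois(length(lsrc), spec$divergence) > 0L
        lsrc[hit] <- sample_residues(sum(hit), bg)
        res[sp_dst[1]:sp_dst[2]] <- lsrc
      }
    }
  }

  # record the planted conserved columns
  conserved <- data.frame(
    pos = if (length(cons_helix))
      tm[cbind(cons_helix, 1L)] + cons_offset - 1L else integer(0),
    class = vapply(spec$conserved_cols, `[[`, character(1), "class"),
    residue = cons_residue, stringsAsFactors = FALSE)
  rate_mult <- rep(1, L)
  planted <- rep(FALSE, L)
  if (nrow(conserved)) {
    rate_mult[conserved$pos] <- spec$conserved_rate_mult
    planted[conserved$pos] <- TRUE
  }

  # plant motifs centrally in their loops
  motifs <- list()
  for (m in spec$motif_spec) {
    sp <- loop_span(m$loop)
    llen <- sp[2] - sp[1] + 1L
    ml <- nchar(m$motif)
    if (ml > llen) stop("motif '", m$motif, "' longer than loop ", m$loop)
    start <- sp[1] + (llen - ml) %/% 2L
    pos <- start:(start + ml - 1L)
    res[pos] <- strsplit(m$motif, "")[[1]]
    rate_mult[pos] <- m$rate_mult
    planted[pos] <- TRUE
    motifs[[length(motifs) + 1L]] <-
      list(loop = m$loop, motif = m$motif, start = start,
           end = start + ml - 1L, rate_mult = m$rate_mult)
  }

  loops <- if (nh > 1L)
    t(vapply(seq_len(nh - 1L), loop_span, numeric(2))) else
    matrix(numeric(0), 0L, 2L)
  colnames(loops) <- c("start", "end")

  truth <- list(tm = tm, loops = loops, motifs = motifs,
                conserved = conserved,
                site_type = type, site_elem = elem,
                rate_mult = rate_mult, planted = planted,
                duplication = spec$duplication, n_side = "lumen",
                length = L)
  record <- data.frame(id = "ancestor", desc = "synthetic family ancestor",
                       seq = paste(res, collapse = ""),
                       stringsAsFactors = FALSE)
  list(record = record, truth = truth)
}

# one evolved member: substitutions everywhere, indels in unplanted
# loop/terminus sites only.  Returns residue vector (NA = deleted) and a
# list of insertion strings keyed by the preceding ancestral site (0 = before
# the first site).
evolve_member <- function(res, truth, spec) {
  L <- truth$length
  hdist <- helix_distribution()
  bg <- aa_background()
  lambda <- spec$divergence * truth$rate_mult
  nsub <- stats::rpois(L, lambda)
  hit <- nsub > 0L
  in_helix <- truth$site_type == "helix" & !truth$planted
  hx <- hit & in_helix
  ot <- hit & !in_helix
  res[hx] <- sample_residues(sum(hx), hdist)
  res[ot] <- sample_residues(sum(ot), bg)

  eligible <- truth$site_type %in% c("loop", "nterm", "cterm") & !truth$planted
  del <- rep(FALSE, L)
  ins <- vector("list", L + 1L)
  u <- stats::runif(L)
  for (i in which(eligible)) {
    if (u[i] < spec$indel_rate / 2) {
      g <- stats::rgeom(1L, 0.5) + 1L
      ins[[i + 1L]] <- paste(sample_residues(g, bg), collapse = "")
    } else if (u[i] < spec$indel_rate) {
      g <- stats::rgeom(1L, 0.5) + 1L
      j <- i
      while (g > 0L && j <= L && eligible[j]) {
        del[j] <- TRUE
        j <- j + 1L
        g <- g - 1L
      }
    }
  }
  list(res = res, del = del, ins = ins)
}

#' Evolve a family of sequences from an ancestor
#'
#' Each member receives Poisson(divergence x site rate) substitutions:
#' helix sites are resampled from the hydrophobicity-preserving helix
#' distribution, other sites from background, planted motif/conserved sites
#' at `rate_mult`/`conserved_rate_mult` times the rate.  Indels (geometric
#' length, mean 2) occur only in unplanted loop and terminus sites.  The
#' truth gains per-member TM/motif/conserved coordinates, ancestor-to-member
#' coordinate maps, and the by-construction multiple alignment.
#'
#' @param ancestor,truth output of [make_ancestor()].
#' @param spec the [family_spec()].
#' @param seed RNG seed (default `spec$seed + 1`).
#' @param id_prefix prefix for member identifiers.
#' @return `list(records=, truth=)` where `records` is a data.frame of
#'   `spec$n_members` sequences and `truth` extends the ancestral truth with
#'   `members` (per-member spans and maps) and `alignment` (an
#'   [aa_alignment()] whose attributes `col_tm`, `col_motifs`,
#'   `col_conserved` give truth features in column coordinates).
#' @export
evolve_family <- function(ancestor, truth, spec, seed = spec$seed + 1L,
                          id_prefix = "M") {
  set.seed(seed)
  res0 <- strsplit(ancestor$seq[1], "")[[1]]
  L <- truth$length
  n <- spec$n_members
  evolved <- vector("list", n)
  for (m in seq_len(n)) evolved[[m]] <- evolve_member(res0, truth, spec)

  ins_max <- integer(L + 1L)
  for (m in seq_len(n)) {
    lens <- vapply(evolved[[m]]$ins, function(s) if (is.null(s)) 0L else nchar(s),
                   integer(1))
    ins_max <- pmax(ins_max, lens)
  }
  # column index of ancestral site i: site columns interleave with the
  # insertion blocks preceding them (ins_max[s] = width of the block before
  # site s; slot L+1 holds insertions after the last site)
  col_of <- seq_len(L) + cumsum(ins_max[seq_len(L)])
  ncolumns <- L + sum(ins_max)

  ids <- sprintf("%s%02d", id_prefix, seq_len(n))
  rows <- character(n)
  members <- vector("list", n)
  names(members) <- ids
  for (m in seq_len(n)) {
    ev <- evolved[[m]]
    chars <- rep("-", ncolumns)
    keep <- !ev$del
    chars[col_of[keep]] <- ev$res[keep]
    for (slot in which(!vapply(ev$ins, is.null, logical(1)))) {
      s <- ev$ins[[slot]]
      start <- if (slot == 1L) 1L else col_of[slot - 1L] + 1L
      chars[start:(start + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
    }
    rows[m] <- paste(chars, collapse = "")

    # ancestor-site -> member-residue map
    present <- chars != "-"
    colpos <- cumsum(present)
    map <- rep(NA_integer_, L)
    map[keep] <- colpos[col_of[keep]]
    span_map <- function(sp)
      c(start = min(map[sp[1]:sp[2]], na.rm = TRUE),
        end = max(map[sp[1]:sp[2]], na.rm = TRUE))
    tm_m <- t(apply(truth$tm, 1L, span_map))
    motifs_m <- lapply(truth$motifs, function(mo) {
      c(start = map[mo$start], end = map[mo$end])
    })
    conserved_m <- map[truth$conserved$pos]
    members[[m]] <- list(seq = paste(chars[present], collapse = ""),
                         tm = tm_m, motifs = motifs_m,
                         conserved = conserved_m, map = map)
  }

  records <- data.frame(id = ids, desc = "synthetic family member",
                        seq = vapply(members, `[[`, character(1), "seq"),
                        stringsAsFactors = FALSE, row.names = NULL)
  aln <- aa_alignment(ids, rows)
  attr(aln, "col_tm") <- cbind(start = col_of[truth$tm[, "start"]],
                               end = col_of[truth$tm[, "end"]])
  attr(aln, "col_motifs") <- lapply(truth$motifs, function(mo)
    c(start = col_of[mo$start], end = col_of[mo$end]))
  attr(aln, "col_conserved") <- col_of[truth$conserved$pos]

  truth$members <- members
  truth$alignment <- aln
  truth$col_of <- col_of
  list(records = records, truth = truth)
}

#' Generate decoy sequences
#'
#' @param n number of decoys.
#' @param length_range inclusive length range (globular/random kinds).
#' @param kind `"globular"` (background composition), `"random"` (uniform
#'   letters) or `"k_tm"` (same construction as a family ancestor with `k`
#'   helices, independently drawn, hence no homology to any family).
#' @param k number of helices for `kind = "k_tm"`.
#' @param seed RNG seed.
#' @param id_prefix identifier prefix.
#' @return data.frame of sequence records (possibly 0 rows).
#' @export
make_decoys <- function(n, length_range = c(150L, 400L),
                        kind = c("globular", "random", "k_tm"), k = 7L,
                        seed = 1L, id_prefix = "DEC") {
  kind <- match.arg(kind)
  if (n == 0L)
    return(data.frame(id = character(0), desc = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  set.seed(seed)
  ids <- sprintf("%s%03d", id_prefix, seq_len(n))
  seqs <- character(n)
  if (kind == "k_tm") {
    for (i in seq_len(n)) {
      sp <- family_spec(n_helices = k, duplication = FALSE,
                        motif_spec = list(), conserved_cols = list(),
                        n_members = 1L, seed = seed)
      seqs[i] <- make_ancestor(sp, seed = sample.int(2^30, 1L))$record$seq
    }
  } else {
    prob <- if (kind == "globular") aa_background() else rep(1 / 20, 20L)
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- vapply(lens, function(l)
      paste(sample_residues(l, prob), collapse = ""), character(1))
  }
  data.frame(id = ids, desc = paste0(kind, " decoy"), seq = seqs,
             stringsAsFactors = FALSE)
}

#' Generate half-proteins homologous to one half of a family
#'
#' Cuts the family ancestor at the midpoint of the loop following (N) or
#' preceding (C) the central helix region, keeping the `floor(n_helices/2)`
#' helices of that half, then evolves `n` members from the cut ancestor
#' exactly as [evolve_family()] does.  Truth lists 3 TM spans per member
#' for the default 7-helix architecture.
#'
#' @param spec a [family_spec()].
#' @param n number of half-proteins.
#' @param seed RNG seed.
#' @param ancestor optional `list(record=, truth=)` from [make_ancestor()];
#'   pass the family's own ancestor so the halves are genuinely homologous
#'   to that family.  If `NULL` a fresh ancestor is drawn from `spec`.
#' @param half `"N"` or `"C"`.
#' @param id_prefix identifier prefix.
#' @return `list(records=, truth=)` as for [evolve_family()].
#' @export
make_half_proteins <- function(spec, n, seed = spec$seed + 2L,
                               ancestor = NULL, half = c("N", "C"),
                               id_prefix = "H") {
  half <- match.arg(half)
  if (is.null(ancestor)) ancestor <- make_ancestor(spec, seed = seed)
  truth <- ancestor$truth
  nh <- spec$n_helices
  k <- nh %/% 2L
  if (k < 1L) stop("half-proteins need at least 2 helices")
  if (half == "N") {
    lp <- truth$loops[k, ]  # loop after helix k
    cut <- lp["start"] + (lp["end"] - lp["start"]) %/% 2
    keep <- 1L:cut
  } else {
    lp <- truth$loops[nh - k, ]  # loop before helix nh-k+1
    cut <- lp["start"] + (lp["end"] - lp["start"] + 1L) %/% 2
    keep <- cut:truth$length
  }
  off <- keep[1] - 1L
  res <- strsplit(ancestor$record$seq[1], "")[[1]][keep]
  sel_h <- which(truth$tm[, "start"] %in% keep & truth$tm[, "end"] %in% keep)
  sel_l <- which(truth$loops[, "start"] %in% keep &
                 truth$loops[, "end"] %in% keep)
  keep_motifs <- Filter(function(mo) mo$start %in% keep && mo$end %in% keep,
                        truth$motifs)
  keep_cons <- truth$conserved[truth$conserved$pos %in% keep, , drop = FALSE]
  half_truth <- list(
    tm = truth$tm[sel_h, , drop = FALSE] - off,
    loops = truth$loops[sel_l, , drop = FALSE] - off,
    motifs = lapply(keep_motifs, function(mo) {
      mo$start <- mo$start - off; mo$end <- mo$end - off; mo }),
    conserved = transform(keep_cons, pos = pos - off),
    site_type = truth$site_type[keep],
    site_elem = truth$site_elem[keep],
    rate_mult = truth$rate_mult[keep],
    planted = truth$planted[keep],
    duplication = FALSE, n_side = truth$n_side,
    length = length(keep), half = half)
  half_spec <- spec
  half_spec$n_members <- n
  rec <- data.frame(id = "half_ancestor", desc = "half-protein ancestor",
                    seq = paste(res, collapse = ""), stringsAsFactors = FALSE)
  evolve_family(rec, half_truth, half_spec, seed = seed + 1L,
                id_prefix = id_prefix)
}

#' Assemble a synthetic proteome with a truth manifest
#'
#' Concatenates (and shuffles) the members of one or more synthetic
#' families, optional half-proteins derived from each family's own
#' ancestor, and decoys.  The manifest partitions every identifier into its
#' role and carries the full per-family truth.
#'
#' @param families list of [family_spec()] objects (or a single spec).
#' @param n_decoys,decoy_kind,decoy_length_range decoy parameters passed to
#'   [make_decoys()].
#' @param n_half number of half-proteins per family (0 for none).
#' @param seed RNG seed governing every draw.
#' @return `list(records=, truth=)`; `truth$roles` is a named character
#'   vector over all ids (`"family<f>"`, `"half<f>"`, `"decoy"`),
#'   `truth$families` / `truth$halves` hold the per-family truths.
#' @export
make_proteome <- function(families, n_decoys = 200L,
                          decoy_kind = "globular",
                          decoy_length_range = c(150L, 400L),
                          n_half = 0L, seed = 1L) {
  if (inherits(families, "family_spec")) families <- list(families)
  records <- list()
  roles <- character(0)
  fam_truths <- list()
  half_truths <- list()
  for (f in seq_along(families)) {
    sp <- families[[f]]
    anc <- make_ancestor(sp, seed = seed + 97L * f)
    fam <- evolve_family(anc$record, anc$truth, sp, seed = seed + 97L * f + 1L,
                         id_prefix = sprintf("F%d_M", f))
    records[[length(records) + 1L]] <- fam$records
    roles[fam$records$id] <- paste0("family", f)
    fam_truths[[f]] <- fam$truth
    if (n_half > 0L) {
      hp <- make_half_proteins(sp, n_half, seed = seed + 97L * f + 2L,
                               ancestor = anc, id_prefix = sprintf("F%d_H", f))
      records[[length(records) + 1L]] <- hp$records
      roles[hp$records$id] <- paste0("half", f)
      half_truths[[f]] <- hp$truth
    }
  }
  if (n_decoys > 0L) {
    dec <- make_decoys(n_decoys, decoy_length_range, decoy_kind,
                       seed = seed + 7919L)
    records[[length(records) + 1L]] <- dec
    roles[dec$id] <- "decoy"
  }
  all <- do.call(rbind, records)
  set.seed(seed)
  all <- all[sample.int(nrow(all)), , drop = FALSE]
  rownames(all) <- NULL
  list(records = all,
       truth = list(roles = roles, families = fam_truths,
                    halves = half_truths, seed = seed))
}

#' Simulate families from a specification
#'
#' `simulate()` on a [family_spec()] draws `nsim` independent families
#' (ancestor plus evolved members plus truth).
#'
#' @param object a [family_spec()].
#' @param nsim number of families.
#' @param seed base RNG seed; family `i` uses `seed + i - 1`.
#' @param ... unused.
#' @return List of `nsim` elements, each `list(ancestor=, records=, truth=)`.
#' @export
simulate.family_spec <- function(object, nsim = 1L, seed = object$seed, ...) {
  lapply(seq_len(nsim), function(i) {
    anc <- make_ancestor(object, seed = seed + i - 1L)
    fam <- evolve_family(anc$record, anc$truth, object,
                         seed = (seed + i - 1L) * 2L + 1L)
    list(ancestor = anc, records = fam$records, truth = fam$truth)
  })
}
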