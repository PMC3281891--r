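# Synthetic family generator: determinism, truth consistency, divergence
# behaviour, decoys, half-proteins, proteome assembly

test_that("ancestor realises the specified architecture with valid truth", {
  fam <- make_ancestor(family_spec(seed = 1))
  tr <- fam$truth
  expect_equal(nrow(tr$tm), 7L)
  expect_true(all(diff(as.vector(t(tr$tm))) > 0))  # ordered, non-overlapping
  expect_true(all(tr$tm[, "end"] - tr$tm[, "start"] + 1L == 21L))
  expect_equal(nchar(fam$record$seq), tr$length)
  # planted motifs and conserved columns are where truth says they are
  res <- strsplit(fam$record$seq, "")[[1]]
  for (mo in tr$motifs)
    expect_equal(paste(res[mo$start:mo$end], collapse = ""), mo$motif)
  expect_equal(res[tr$conserved$pos], tr$conserved$residue)
})

test_that("zero-divergence duplication copies the N-half verbatim outside plants", {
  sp <- family_spec(divergence = 0, seed = 3)
  fam <- make_ancestor(sp)
  tr <- fam$truth
  res <- strsplit(fam$record$seq, "")[[1]]
  # helices 5-7 equal helices 1-3 except at planted positions
  for (j in 1:3) {
    src <- res[tr$tm[j, 1]:tr$tm[j, 2]]
    dst <- res[tr$tm[4L + j, 1]:tr$tm[4L + j, 2]]
    planted_src <- tr$planted[tr$tm[j, 1]:tr$tm[j, 2]]
    planted_dst <- tr$planted[tr$tm[4L + j, 1]:tr$tm[4L + j, 2]]
    free <- !(planted_src | planted_dst)
    expect_equal(src[free], dst[free])
  }
})

test_that("helices are hydrophobic relative to loops (truth-span check)", {
  kd <- kyte_doolittle()
  diffs <- vapply(1:30, function(s) {
    fam <- make_ancestor(family_spec(seed = s), seed = s)
    res <- strsplit(fam$record$seq, "")[[1]]
    tm_idx <- unlist(apply(fam$truth$tm, 1L, function(r) r[1]:r[2]))
    mean(kd[res[tm_idx]]) - mean(kd[res[-tm_idx]])
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("evolution is seeded-deterministic and divergence-monotone", {
  sp <- family_spec(n_members = 8, seed = 5)
  a <- simulate(sp, 1, seed = 5)[[1]]
  b <- simulate(sp, 1, seed = 5)[[1]]
  expect_identical(a$records, b$records)
  expect_identical(a$truth$alignment$seq, b$truth$alignment$seq)

  mean_ident <- function(div, seed) {
    spd <- family_spec(n_members = 8, divergence = div, seed = seed)
    f <- simulate(spd, 1, seed = seed)[[1]]
    m <- do.call(rbind, strsplit(f$truth$alignment$seq, ""))
    pairs <- utils::combn(nrow(m), 2)
    mean(apply(pairs, 2, function(p) {
      keep <- m[p[1], ] != "-" & m[p[2], ] != "-"
      mean(m[p[1], keep] == m[p[2], keep])
    }))
  }
  idents <- sapply(c(0, 0.3, 0.6, 1.0), function(d)
    mean(sapply(1:20, function(s) mean_ident(d, s))))
  expect_gt(idents[1], 0.999)  # only indel-inserted residues can differ
  expect_true(all(diff(idents) < 0))
})

test_that("members at zero divergence equal the ancestor", {
  sp <- family_spec(divergence = 0, indel_rate = 0, n_members = 5, seed = 2)
  anc <- make_ancestor(sp)
  fam <- evolve_family(anc$record, anc$truth, sp)
  expect_true(all(fam$records$seq == anc$record$seq))
})

test_that("truth spans index into member sequences and alternate sidedness", {
  fam <- default_family(seed = 4)
  for (mem in fam$truth$members) {
    L <- nchar(mem$seq)
    expect_true(all(mem$tm >= 1 & mem$tm <= L))
    expect_true(all(diff(as.vector(t(mem$tm))) > 0))
    res <- strsplit(mem$seq, "")[[1]]
  }
  topo <- tm_topology(fam$truth$tm, "lumen")
  expect_equal(length(unique(topo$loop_sides[c(1, 3, 5, 7)])), 1L)
  expect_equal(length(unique(topo$loop_sides[c(2, 4, 6)])), 1L)
  expect_false(topo$loop_sides[1] == topo$loop_sides[2])
})

test_that("planted PQ survives in most members at default divergence", {
  carried <- sapply(1:50, function(s) {
    fam <- default_family(seed = 100 + s)
    mean(vapply(fam$truth$members, function(mem) {
      all(vapply(mem$motifs, function(sp) {
        substr(mem$seq, sp["start"], sp["end"]) == "PQ"
      }, logical(1)))
    }, logical(1)))
  })
  expect_gt(mean(carried), 0.9)
})

test_that("decoys respect kind, count and length range", {
  expect_equal(nrow(make_decoys(0)), 0L)
  d <- make_decoys(50, c(100, 200), "random", seed = 9)
  expect_equal(nrow(d), 50L)
  expect_true(all(nchar(d$seq) >= 100 & nchar(d$seq) <= 200))
  expect_false(anyDuplicated(d$id) > 0)
  d2 <- make_decoys(3, kind = "k_tm", k = 7, seed = 9)
  expect_equal(nrow(d2), 3L)
  # independent draws: no two decoys identical
  expect_false(anyDuplicated(d2$seq) > 0)
})

test_that("half-proteins carry 3 TM spans and are shorter than the ancestor", {
  sp <- family_spec(seed = 6)
  anc <- make_ancestor(sp)
  hp <- make_half_proteins(sp, 6, seed = 60, ancestor = anc)
  expect_equal(nrow(hp$records), 6L)
  for (mem in hp$truth$members) {
    expect_equal(nrow(mem$tm), 3L)
    expect_lt(nchar(mem$seq), nchar(anc$record$seq))
  }
  hc <- make_half_proteins(sp, 2, seed = 61, ancestor = anc, half = "C")
  expect_equal(nrow(hc$truth$tm), 3L)
})

test_that("proteome assembly partitions ids and is byte-deterministic", {
  sp <- family_spec(n_members = 10, seed = 7)
  p1 <- make_proteome(sp, n_decoys = 30, n_half = 5, seed = 7)
  expect_equal(nrow(p1$records), 45L)
  expect_equal(sum(startsWith(names(p1$truth$roles), "F1_M")), 10L)
  expect_setequal(names(p1$truth$roles), p1$records$id)
  expect_false(anyDuplicated(p1$records$id) > 0)

  p2 <- make_proteome(sp, n_decoys = 30, n_half = 5, seed = 7)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(p1$records, f1); write_fasta(p2$records, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("spec validation rejects impossible settings", {
  expect_error(family_spec(n_helices = 0), "n_helices")
  expect_error(family_spec(divergence = -1), "divergence")
  expect_error(family_spec(motif_spec = list(
    list(loop = 9, motif = "PQ", rate_mult = 0.1))), "loop index")
  expect_error(family_spec(
    loop_len_range = c(3, 4),
    motif_spec = list(list(loop = 1, motif = "PQPQP", rate_mult = 0.1))),
    "longer than")
  expect_error(family_spec(conserved_cols = list(
    list(helix = 2, offset = 30, class = "basic"))), "outside")
})
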