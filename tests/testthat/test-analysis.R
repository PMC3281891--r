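# Conservation track, motif and conserved-class detection, distances and
# the neighbor-joining tree

test_that("conservation scores match a hand-computed oracle on a toy MSA", {
  msa <- mk_msa("RAC", "RAD", "RGC", "RGD")
  trk <- column_conservation(msa, pseudocount = 0.5)
  bg <- aa_background()
  # equal Henikoff weights by symmetry: col 1 invariant R, col 2 A/G half
  oracle <- function(counts) {
    p <- counts + 0.5 * bg
    p <- p / sum(p)
    sum(p * log2(p / bg))
  }
  c1 <- setNames(numeric(20), AA_ALPHABET); c1["R"] <- 1
  c2 <- setNames(numeric(20), AA_ALPHABET); c2[c("A", "G")] <- 0.5
  expect_equal(trk$score[1], oracle(c1), tolerance = 1e-12)
  expect_equal(trk$score[2], oracle(c2), tolerance = 1e-12)
  expect_equal(trk$majority[1], "R")
  expect_equal(trk$majority_fraction[1], 1)
})

test_that("background-frequency columns score near zero and gaps mask", {
  set.seed(1)
  bg <- aa_background()
  rows <- replicate(200, paste(sample(AA_ALPHABET, 20, replace = TRUE,
                                      prob = bg), collapse = ""))
  msa <- aa_alignment(paste0("s", 1:200), rows)
  trk <- column_conservation(msa, pseudocount = 0.05)
  # finite-sample bias only: scores sit near zero, far below conserved ones
  expect_lt(mean(trk$score), 0.15)

  gappy <- mk_msa("A-", "A-", "AC", "A-")
  trk2 <- column_conservation(gappy)
  expect_true(is.na(trk2$score[2]))
  expect_equal(trk2$gap_fraction[2], 0.75)
})

test_that("conservation is invariant under row permutation", {
  fam <- default_family(seed = 3, n_members = 8)
  msa <- fam$truth$alignment
  perm <- sample(seq_along(msa$id))
  msa2 <- aa_alignment(msa$id[perm], msa$seq[perm])
  expect_equal(column_conservation(msa)$score,
               column_conservation(msa2)$score)
})

test_that("planted PQ doublets are reported in both halves", {
  fam <- default_family(seed = 4)
  truth_cols <- attr(fam$truth$alignment, "col_motifs")
  hits <- find_motif(fam$truth$alignment, "PQ")
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$col_start,
                  vapply(truth_cols, `[[`, numeric(1), "start"))
  expect_true(all(hits$fraction >= 0.5))
  # absent motif
  expect_equal(nrow(find_motif(fam$truth$alignment, "WWWW")), 0L)
})

test_that("differential motif decay shows up in carrier fractions", {
  # C-half PQ mutates slower than the N-half PQ
  sp <- family_spec(seed = 5, motif_spec = list(
    list(loop = 1L, motif = "PQ", rate_mult = 0.9),
    list(loop = 5L, motif = "PQ", rate_mult = 0.02)))
  fr <- sapply(1:25, function(s) {
    f <- simulate(sp, 1, seed = 40 + s)[[1]]
    hits <- find_motif(f$truth$alignment, "PQ", threshold = 0)
    cols <- attr(f$truth$alignment, "col_motifs")
    n_col <- cols[[1]]["start"]; c_col <- cols[[2]]["start"]
    c(n = sum(hits$fraction[hits$col_start == n_col]),
      c = sum(hits$fraction[hits$col_start == c_col]))
  })
  expect_gt(mean(fr["c", ]), mean(fr["n", ]))
})

test_that("conserved-class columns recover the planted (2 basic, 1 serine)", {
  got <- sapply(1:25, function(s) {
    f <- default_family(seed = s)
    trk <- column_conservation(f$truth$alignment)
    cls <- find_conserved_class_columns(trk,
      tm_regions = attr(f$truth$alignment, "col_tm"))
    cc <- attr(f$truth$alignment, "col_conserved")
    c(basic = length(cls$basic), serine = length(cls$serine),
      located = all(c(cls$basic, cls$serine) %in% cc))
  })
  expect_gte(mean(got["basic", ] == 2 & got["serine", ] == 1), 0.85)
  expect_true(all(got["located", ] == 1))
  # a threshold above the maximum attainable score returns nothing
  f <- default_family(seed = 1)
  trk <- column_conservation(f$truth$alignment)
  empty <- find_conserved_class_columns(trk, min_score = log2(1 / 0.01))
  expect_equal(lengths(empty), c(basic = 0L, serine = 0L))
})

test_that("p-distances match hand counts and flag disjoint rows", {
  msa <- mk_msa("ACDEF", "ACDFF", "AC---")
  D <- pairwise_distances(msa)
  expect_equal(D["s1", "s2"], 1 / 5)
  expect_equal(D["s1", "s3"], 0)       # identical over shared columns
  expect_equal(diag(D), setNames(rep(0, 3), msa$id))
  expect_equal(D, t(D))
  disjoint <- mk_msa("AC--", "--DE")
  expect_warning(D2 <- pairwise_distances(disjoint), "no ungapped")
  expect_equal(D2[1, 2], 1)
  # Poisson correction grows with p
  msa3 <- mk_msa("AAAA", "AAAC", "ACCC")
  Dp <- pairwise_distances(msa3, correction = "poisson")
  expect_equal(Dp[1, 2], -log(1 - 0.25))
})

test_that("3-taxon NJ solves the closed-form three-point formulas", {
  D <- matrix(c(0, .3, .5, .3, 0, .6, .5, .6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(D)
  bl <- setNames(tree$edge.length[order(tree$edge[, 2])][1:3],
                 tree$tip.label)
  expect_equal(bl[["a"]], (.3 + .5 - .6) / 2)
  expect_equal(bl[["b"]], (.3 + .6 - .5) / 2)
  expect_equal(bl[["c"]], (.5 + .6 - .3) / 2)
  # 2 taxa: one edge split evenly; fewer: error
  t2 <- nj_tree(matrix(c(0, .4, .4, 0), 2, 2,
                       dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(sum(t2$edge.length), .4)
  expect_error(nj_tree(matrix(0, 1, 1)), "at least 2")
})

test_that("NJ recovers quartet splits on random additive matrices", {
  set.seed(13)
  good <- vapply(1:100, function(i) {
    # random quartet ab|cd with positive branch lengths
    e <- runif(5, 0.05, 1)  # a, b, c, d, internal
    D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    D["a", "b"] <- D["b", "a"] <- e[1] + e[2]
    D["c", "d"] <- D["d", "c"] <- e[3] + e[4]
    for (p in list(c("a", "c"), c("a", "d"), c("b", "c"), c("b", "d"))) {
      idx <- match(p, letters[1:4])
      D[p[1], p[2]] <- D[p[2], p[1]] <- e[idx[1]] + e[idx[2]] + e[5]
    }
    tree <- ape::unroot(nj_tree(D))
    ref <- ape::unroot(ape::read.tree(text = "((a,b),(c,d));"))
    ape::dist.topo(tree, ref) == 0
  }, logical(1))
  expect_equal(mean(good), 1)
})

test_that("NJ reproduces an ultrametric generating tree exactly", {
  # heights: ((a:1,b:1):1,(c:1.5,d:1.5):0.5)
  tree0 <- ape::read.tree(text = "((a:1,b:1):1,(c:1.5,d:1.5):0.5);")
  D <- cophenetic(tree0)
  tree <- nj_tree(D)
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(tree0)), 0,
               ignore_attr = TRUE)
  expect_equal(cophenetic(tree)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
})
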