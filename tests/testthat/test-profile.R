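# Profile construction, sequence scoring and profile-profile alignment,
# with hand-count and brute-force enumeration oracles

test_that("single-sequence profile without pseudocounts has unit columns", {
  prof <- unit_profile("ACD")
  expect_equal(ncol(prof$mat), 3L)
  expect_equal(prof$mat[, 1], setNames(as.numeric(AA_ALPHABET == "A"),
                                       AA_ALPHABET))
  expect_equal(unname(prof$mat["C", 2]), 1)
  expect_equal(unname(prof$mat["D", 3]), 1)
})

test_that("duplicated rows do not change the profile", {
  p1 <- build_profile(mk_msa("ACDEF"))
  p2 <- build_profile(mk_msa("ACDEF", "ACDEF"))
  expect_equal(p1$mat, p2$mat, tolerance = 1e-12)
})

test_that("3-row toy emissions match the hand-count oracle", {
  # rows AAC / A-C / AGC, pseudocount 1.  Henikoff weights: col 1 {A,A,A}
  # gives each row 1/3; col 2 {A,G} gives rows 1 and 3 each 1/(2*1); col 3
  # {C,C,C} gives 1/3 each.  Raw weights (7/6, 2/3, 7/6), normalised.
  msa <- mk_msa("AAC", "A-C", "AGC")
  prof <- build_profile(msa, pseudocount = 1)
  w <- c(7 / 6, 2 / 3, 7 / 6) / 3
  bg <- aa_background()
  counts1 <- setNames(numeric(20), AA_ALPHABET)
  counts1["A"] <- sum(w)
  exp1 <- (counts1 + bg) / sum(counts1 + bg)
  expect_equal(prof$mat[, 1], exp1, tolerance = 1e-12)
  counts2 <- setNames(numeric(20), AA_ALPHABET)
  counts2["A"] <- w[1]; counts2["G"] <- w[3]
  exp2 <- (counts2 + bg) / sum(counts2 + bg)
  expect_equal(prof$mat[, 2], exp2, tolerance = 1e-12)
})

test_that("emissions normalise and gappy columns are excluded", {
  fam <- default_family(seed = 2)
  prof <- family_profile(fam)
  expect_true(all(abs(colSums(prof$mat) - 1) < 1e-9))
  msa <- mk_msa("A--", "AC-", "ACD", "AC-")
  prof2 <- build_profile(msa)
  expect_equal(prof2$match_cols, c(1L, 2L))  # col 3 has 75% gaps
  expect_error(build_profile(mk_msa("A---", "-C--", "--D-", "---E")),
               "no match columns")
})

test_that("TM annotation maps through match-column indexing", {
  fam <- default_family(seed = 3)
  prof <- family_profile(fam)
  expect_equal(nrow(prof$tm_segments), 7L)
  expect_true(all(prof$tm_segments[, "end"] <= ncol(prof$mat)))
  expect_true(all(diff(as.vector(t(prof$tm_segments))) > 0))
})

test_that("self-score equals the closed-form log-odds sum", {
  seqs <- c("MKTAYIAKQRLWWFEH", "ACDEFGHIKLMNPQRSTVWY")
  for (s in seqs) {
    prof <- unit_profile(s)
    res <- score_sequence(prof, s)
    oracle <- sum(log2(1 / aa_background()[strsplit(s, "")[[1]]]))
    expect_equal(res$score, oracle, tolerance = 1e-9)
    expect_equal(res$qstart, 1L)
    expect_equal(res$qend, nchar(s))
  }
})

test_that("local scores are non-negative and X-only sequences score zero", {
  prof <- unit_profile("MKWC")
  res <- score_sequence(prof, "XXXX")
  expect_equal(res$score, 0)
  expect_equal(nrow(res$pairs), 0L)
  expect_true(score_sequence(prof, "DDDD")$score >= 0)
})

test_that("shuffling a sequence destroys its profile score", {
  fam <- default_family(seed = 5)
  prof <- family_profile(fam)
  intact <- score_sequence(prof, fam$records$seq[1])$score
  set.seed(42)
  worse <- sapply(1:100, function(i) {
    shuf <- paste(sample(strsplit(fam$records$seq[1], "")[[1]]), collapse = "")
    score_sequence(prof, shuf)$score < intact
  })
  expect_gte(mean(worse), 0.99)
})

test_that("profile self-alignment pairs columns on the diagonal", {
  fam <- default_family(seed = 6)
  prof <- family_profile(fam)
  res <- align_profiles(prof, prof)
  m <- ncol(prof$mat)
  expect_equal(res$pairs, cbind(seq_len(m), seq_len(m)),
               ignore_attr = TRUE)
  expect_equal(length(res$covered_query_segments), 7L)
})

test_that("disjoint unit profiles yield an empty local alignment", {
  q <- unit_profile("AAAA")
  t <- unit_profile("WWWW")
  res <- align_profiles(q, t)
  expect_equal(res$score, 0)
  expect_equal(nrow(res$pairs), 0L)
})

test_that("profile alignment score is symmetric", {
  f1 <- default_family(seed = 7)
  f2 <- default_family(seed = 8)
  p1 <- family_profile(f1); p2 <- family_profile(f2)
  expect_equal(align_profiles(p1, p2)$score, align_profiles(p2, p1)$score,
               tolerance = 1e-6)
})

test_that("DP equals brute-force enumeration on small random inputs", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    S <- matrix(rnorm(n * m, mean = 0.3, sd = 2), n, m)
    open <- runif(1, 0.5, 4); extend <- runif(1, 0.1, open)
    dp <- pqfam:::.sw_affine(S, open, extend)
    expect_equal(dp$score, brute_force_local(S, open, extend),
                 tolerance = 1e-9)
  }
})
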