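# Proteome search, coverage rule, realignment and the iterative discovery
# loop on reduced problem sizes (the acceptance suite runs the full demo)

small_demo <- function(seed = 7, n_members = 10, n_decoys = 40, n_half = 4) {
  sp <- family_spec(n_members = n_members, seed = seed)
  make_proteome(sp, n_decoys = n_decoys, n_half = n_half, seed = seed)
}

test_that("coverage filter implements the all-segments rule", {
  tm <- cbind(start = c(1, 30, 60), end = c(20, 50, 80))
  prof <- list(tm_segments = tm)
  cfg <- search_config()
  expect_true(coverage_filter(list(qstart = 1, qend = 80), prof, cfg))
  expect_false(coverage_filter(list(qstart = 1, qend = 50), prof, cfg))
  expect_false(coverage_filter(list(qstart = NA, qend = NA), prof, cfg))
  # with the requirement off, one covered segment suffices
  cfg1 <- search_config(require_all_segments = FALSE)
  expect_true(coverage_filter(list(qstart = 1, qend = 10), prof, cfg1))
  expect_false(coverage_filter(list(qstart = 22, qend = 26), prof, cfg1))
  # degenerate min overlap: any intersecting span counts
  cfg0 <- search_config(min_segment_overlap = 0)
  expect_true(coverage_filter(list(qstart = 20, qend = 60), prof, cfg0))
})

test_that("search separates members, decoys and half-proteins", {
  prot <- small_demo(seed = 7)
  fam <- prot$truth$families[[1]]
  prof <- build_profile(fam$alignment,
                        tm_annotation = attr(fam$alignment, "col_tm"))
  cal <- calibrate_profile(prof, n_null = 150,
                           database_size = nrow(prot$records), seed = 1,
                           lengths = nchar(prot$records$seq))
  hits <- search_proteome(prof, prot$records, search_config(), cal)
  roles <- prot$truth$roles[hits$id]
  expect_setequal(hits$id[hits$accepted],
                  names(prot$truth$roles)[prot$truth$roles == "family1"])
  halves <- hits[roles == "half1", ]
  expect_true(all(halves$evalue < 1e-5))       # significant ...
  expect_true(all(halves$n_covered <= 4))      # ... but not full coverage
  expect_false(any(halves$accepted))
  expect_false(any(hits$accepted[roles == "decoy"]))
  expect_true(!is.unsorted(hits$evalue))
  expect_equal(nrow(search_proteome(prof, prot$records[0, ],
                                    search_config(), cal)), 0L)
})

test_that("acceptance is monotone in the E-value threshold", {
  prot <- small_demo(seed = 9)
  fam <- prot$truth$families[[1]]
  prof <- build_profile(fam$alignment,
                        tm_annotation = attr(fam$alignment, "col_tm"))
  cal <- calibrate_profile(prof, n_null = 150,
                           database_size = nrow(prot$records), seed = 2,
                           lengths = nchar(prot$records$seq))
  sets <- lapply(c(1e-10, 1e-5, 1e-2, 1), function(e)
    with(search_proteome(prof, prot$records, search_config(e_accept = e),
                         cal), sort(id[accepted])))
  for (k in seq_len(length(sets) - 1))
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
})

test_that("align_to_profile reproduces source structure and records inserts", {
  fam <- default_family(seed = 4, n_members = 8)
  prof <- family_profile(fam)
  realn <- align_to_profile(prof, fam$records)
  expect_s3_class(realn, "aa_alignment")
  expect_gte(aln_ncol(realn), ncol(prof$mat))
  expect_equal(length(attr(realn, "profile_cols")), ncol(prof$mat))
  tm_cols <- attr(realn, "tm_cols")
  expect_equal(nrow(tm_cols), 7L)
  # residues at profile columns agree with the source alignment for most
  # match columns (termini may be clipped by the local model)
  src <- pqfam:::aln_matrix(fam$truth$alignment)[, prof$match_cols]
  out <- pqfam:::aln_matrix(realn)[, attr(realn, "profile_cols")]
  agree <- mean(src == out)
  expect_gt(agree, 0.9)
})

test_that("discovery converges on a family-only proteome (self-recovery)", {
  fam <- default_family(seed = 12, n_members = 8)
  fit <- discover_family(seed_alignment(list(truth = list(families =
    list(fam$truth)))), fam$records, search_config(n_null = 120), seed = 3)
  expect_true(fit$converged)
  expect_setequal(fit$accepted, fam$records$id)
})

test_that("iterative discovery is exact on the reduced demo; the dual
          criterion is what excludes the half-proteins", {
  prot <- small_demo(seed = 11)
  seedmsa <- seed_alignment(prot)
  fit <- discover_family(seedmsa, prot$records,
                         search_config(n_null = 150), seed = 5)
  roles <- prot$truth$roles
  pos <- names(roles)[roles == "family1"]
  expect_true(fit$converged)
  expect_setequal(fit$accepted, pos)
  expect_true(all(diff(fit$log$n_accepted) >= 0))

  fit2 <- discover_family(seedmsa, prot$records,
                          search_config(require_all_segments = FALSE,
                                        n_null = 150), seed = 5)
  extra <- setdiff(fit2$accepted, fit$accepted)
  expect_setequal(extra, names(roles)[roles == "half1"])
})

test_that("re-searching with the converged set returns the same set", {
  prot <- small_demo(seed = 13)
  fit <- discover_family(seed_alignment(prot), prot$records,
                         search_config(n_null = 150), seed = 6)
  expect_true(fit$converged)
  reseed <- fit$alignment
  fit2 <- discover_family(reseed, prot$records,
                          search_config(n_null = 150), seed = 60,
                          tm_annotation = attr(reseed, "tm_cols"))
  expect_setequal(fit2$accepted, fit$accepted)
})

test_that("configuration validation", {
  expect_error(search_config(e_accept = 0), "positive")
  expect_error(search_config(min_segment_overlap = -1), ">= 0")
})
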