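test_that("default design yields the 23-nt motif around a central bulge", {
  set.seed(61)
  for (i in 1:5) {
    m <- random_rna(21)
    site <- design_mimic_site(as_member(m))
    expect_equal(nchar(site$site), 23L)
    expect_equal(site$bulge_interval, c(10L, 13L))
    rc <- reverse_complement(m, "DNA")
    # flanks are the exact covering complement, position 11's partner removed
    expect_equal(substr(site$site, 1, 10), substr(rc, 1, 10))
    expect_equal(substr(site$site, 14, 23), substr(rc, 12, 21))
    aln <- align_duplex(m, site$site)
    expect_equal(aln$unpaired_mirna, 11L)
    expect_equal(score_duplex(aln)$bulge_between, c(10L, 12L))
  }
})

test_that("bulge choice is deterministic and lexicographically earliest", {
  set.seed(62)
  m <- as_member(random_rna(21))
  s1 <- design_mimic_site(m)
  s2 <- design_mimic_site(m)
  expect_identical(s1$site, s2$site)
  # every candidate before the chosen one is logged with a reason
  dp <- design_params()
  chosen_at <- match(s1$bulge, dp$bulge_candidate_order)
  expect_equal(s1$rejections$candidate,
               dp$bulge_candidate_order[seq_len(chosen_at - 1)])
  # and each logged rejection is reproducible from the stated clauses
  left <- substr(s1$site, 1, 10)
  right <- substr(s1$site, 14, 23)
  for (k in seq_len(chosen_at - 1)) {
    cand <- dp$bulge_candidate_order[k]
    site <- paste0(left, cand, right)
    aln <- align_duplex(m, site)
    sc <- score_duplex(aln)
    ok_geom <- !is.null(aln$bulge_interval) &&
      identical(aln$bulge_interval, c(10L, 13L)) &&
      identical(aln$unpaired_mirna, 11L)
    admissible <- ok_geom && !is_cleavable(aln, sc) && is_capturing(aln, sc)
    expect_false(admissible, info = paste("candidate", cand))
  }
})

test_that("bulge candidates restoring central pairing are rejected", {
  set.seed(63)
  m <- as_member(random_rna(21))
  rc <- reverse_complement(m$sequence, "DNA")
  left <- substr(rc, 1, 10)
  right <- substr(rc, 12, 21)
  pairing <- substr(rc, 11, 11)              # the removed partner of position 11
  bad <- paste0(pairing, "AA")
  dp_bad <- design_params(bulge_candidate_order = bad)
  expect_error(choose_bulge_sequence(m, left, right, dparams = dp_bad),
               "no admissible bulge")
  good <- design_mimic_site(m)$bulge
  dp_mixed <- design_params(bulge_candidate_order = c(bad, good))
  res <- choose_bulge_sequence(m, left, right, dparams = dp_mixed)
  expect_equal(res$bulge, good)
  expect_equal(res$rejections$candidate, bad)
})

test_that("homopolymer runs across the bulge junction are rejected", {
  # positions 10, 12, 13 are U, so the site flanks meet the bulge with A...A
  m <- as_member(paste0("ACGACGACG", "U", "G", "UU", "ACGACGAC"))
  rc <- reverse_complement(m$sequence, "DNA")
  left <- substr(rc, 1, 10)
  right <- substr(rc, 12, 21)
  res <- choose_bulge_sequence(m, left, right,
                               dparams = design_params(
                                 bulge_candidate_order = c("AAA", "AGA")))
  expect_equal(res$bulge, "AGA")
  expect_equal(res$rejections$reason, "homopolymer")
})

test_that("validation distinguishes functional, cleavable and inert sites", {
  set.seed(64)
  m <- as_member(random_rna(21))
  expect_equal(validate_mimic(design_mimic_site(m)$site, m)$status,
               "MIMIC_FUNCTIONAL")
  rc <- reverse_complement(m$sequence, "DNA")
  expect_equal(validate_mimic(rc, m)$status, "CLEAVABLE")
  sn <- single_mismatch_site(m$sequence, 11L)
  v <- validate_mimic(sn, m)
  expect_false(v$status == "MIMIC_FUNCTIONAL")
  expect_equal(v$status, "CLEAVABLE")
  expect_equal(v$score$total, 2.0)
  # heavily mismatched ungapped site: neither captures nor cleaves
  far <- reverse_complement(transversion_at(m$sequence, c(2, 4, 6, 8, 14, 16, 18, 20)),
                            "DNA")
  expect_equal(validate_mimic(far, m)$status, "INERT")
})

test_that("mimic naming follows the family/subfamily convention", {
  expect_equal(name_mimic("172"), "MIM172")
  expect_equal(name_mimic("169", c("d", "e", "f", "g"), whole_family = FALSE),
               "MIM169defg")
  expect_equal(name_mimic("161", ".1", whole_family = FALSE), "MIM161.1")
  expect_equal(name_mimic("169", c("g", "d"), whole_family = FALSE), "MIM169dg")
})

test_that("capture matrix resolves close and distant families", {
  set.seed(65)
  base <- random_rna(21)
  a <- as_member(base, "xxx-miR600a")
  b <- as_member(transversion_at(base, c(15, 18)), "xxx-miR601a")
  c3 <- as_member(transversion_at(base, c(2, 4, 6, 8, 14, 16, 18, 20)),
                  "xxx-miR602a")
  cat1 <- rbind(a, b, c3)
  mimics <- lapply(seq_len(3), function(i) {
    design_mimic_site(cat1[i, , drop = FALSE])
  })
  cm <- capture_matrix(mimics, cat1)
  expect_true(all(diag(cm$captures)))
  # two non-central, non-core differences: mutual off-target capture
  expect_true(cm$captures["MIM600a", "xxx-miR601a"])
  expect_true(cm$captures["MIM601a", "xxx-miR600a"])
  # eight differences: no cross-capture
  expect_false(cm$captures["MIM600a", "xxx-miR602a"])
  expect_false(cm$captures["MIM602a", "xxx-miR600a"])
  off <- off_target_captures(cm)
  expect_setequal(off$mimic, c("MIM600a", "MIM601a"))
})

test_that("length-incompatible pairs are marked not alignable", {
  set.seed(66)
  long <- as_member(random_rna(26), "xxx-miR700a")
  short <- as_member(random_rna(18), "xxx-miR701a")
  cat1 <- rbind(long, short)
  mim <- design_mimic_site(long)        # 28-nt site, 10 nt beyond the 18-mer
  cm <- capture_matrix(list(mim), cat1)
  expect_false(cm$alignable["MIM700a", "xxx-miR701a"])
  expect_false(cm$captures["MIM700a", "xxx-miR701a"])
  expect_true(is.na(cm$noncentral["MIM700a", "xxx-miR701a"]))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_capture_tsv(cm, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 2L)
  expect_false(any(tab$off_target))
})
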