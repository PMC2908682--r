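test_that("base-pair classification follows Watson-Crick plus G:U wobble", {
  expect_equal(classify_pair(c("A", "U", "G", "C"), c("T", "A", "C", "G")),
               rep("wc", 4))
  expect_equal(classify_pair(c("G", "U"), c("T", "G")), rep("wobble", 2))
  expect_equal(classify_pair(c("A", "A", "C", "U"), c("C", "G", "T", "T")),
               rep("mismatch", 4))
  expect_error(classify_pair("N", "A"), "invalid miRNA residue")
  expect_error(classify_pair("A", "N"), "invalid site residue")
})

test_that("a perfect reverse complement aligns ungapped at zero score", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_rna(21)
    aln <- align_duplex(m, reverse_complement(m, "DNA"))
    expect_true(all(aln$columns$state == "wc"))
    expect_equal(score_duplex(aln)$total, 0)
    # antiparallel: column i pairs miRNA i with site L - i + 1
    expect_equal(aln$columns$site_pos, 21L - aln$columns$mirna_pos + 1L)
  }
})

test_that("scoring weights wobbles and mismatches by the core region", {
  m <- paste(rep("U", 21), collapse = "")
  site <- paste(rep("A", 21), collapse = "")
  # wobble at miRNA position 5 (inside core 2-13): 0.5 x 2
  s5 <- site; substr(s5, 17, 17) <- "G"   # partner index 21 - 5 + 1
  expect_equal(score_duplex(align_duplex(m, s5))$total, 1.0)
  # mismatch at miRNA position 20 (outside core): 1.0 x 1
  s20 <- site; substr(s20, 2, 2) <- "C"
  expect_equal(score_duplex(align_duplex(m, s20))$total, 1.0)
  # mismatch at position 5: 1.0 x 2
  s5m <- site; substr(s5m, 17, 17) <- "C"
  expect_equal(score_duplex(align_duplex(m, s5m))$total, 2.0)
})

test_that("equal-score bulge placements resolve to the leftmost gap index", {
  m <- paste(rep("A", 21), collapse = "")
  site <- paste(rep("T", 23), collapse = "")   # every placement pairs A:T
  aln <- align_duplex(m, site)
  expect_equal(aln$layout$g, 0L)
  expect_equal(aln$layout$e, 0L)
  expect_equal(score_duplex(aln)$bulge_length, 2L)
})

test_that("site length errors are reported", {
  m <- random_rna(21)
  expect_error(align_duplex(m, reverse_complement(substr(m, 3, 21), "DNA")),
               "shorter than miRNA")
  expect_error(align_duplex(m, paste0(reverse_complement(m, "DNA"), "ACGTAC")),
               "max_site_bulge")
})

test_that("cleavable and capturing are mutually exclusive", {
  set.seed(31)
  for (i in 1:40) {
    m <- random_rna(21)
    site <- if (i %% 2 == 0) {
      design_mimic_site(as_member(m))$site
    } else {
      random_dna(21 + sample(0:4, 1))
    }
    aln <- align_duplex(m, site)
    sc <- score_duplex(aln)
    expect_false(is_cleavable(aln, sc) && is_capturing(aln, sc))
  }
})

test_that("introducing a mismatch never decreases the total score", {
  set.seed(41)
  for (i in 1:20) {
    m <- random_rna(21)
    site <- design_mimic_site(as_member(m))$site
    t0 <- score_duplex(align_duplex(m, site))$total
    # corrupt one paired (non-bulge) site base into a guaranteed mismatch
    aln <- align_duplex(m, site)
    paired <- which(aln$columns$state %in% c("wc", "wobble"))
    pick <- sample(paired, 1)
    sp <- aln$columns$site_pos[pick]
    mb <- aln$columns$mirna_base[pick]
    site2 <- site
    substr(site2, sp, sp) <- mismatch_partner(mb)
    t1 <- score_duplex(align_duplex(m, site2))$total
    expect_gte(t1, t0)
  }
})

test_that("aligner matches independent exhaustive enumeration (spot check)", {
  set.seed(51)
  p <- scoring_params()
  for (i in 1:100) {
    Lm <- sample(8:12, 1)
    d <- sample(0:3, 1)
    m <- random_rna(Lm)
    site <- random_dna(Lm + d)
    got <- score_duplex(align_duplex(m, site, p), p)$total
    expect_equal(got, oracle_min_score(m, site, p))
  }
})

test_that("the duplex diagram renders three equal-width strand lines", {
  m <- random_rna(21)
  aln <- align_duplex(m, design_mimic_site(as_member(m))$site)
  fd <- format_duplex(aln)
  expect_length(fd, 3L)
  body <- substr(fd, 4, 4 + nrow(aln$columns) - 1)
  expect_equal(nchar(body), rep(nrow(aln$columns), 3))
  expect_match(fd[2], "\\|")
  # looped-out miRNA base faces a gap on the site line
  gap_col <- which(aln$columns$state == "mirna_loop")
  expect_equal(substr(body[1], gap_col, gap_col), "-")
})
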