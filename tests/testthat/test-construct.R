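make_design <- function(seed = 71, motif_len = 24L) {
  spec <- fixture_spec(seed = seed, n_families = 1, members_per_family = 1)
  m <- generate_mirna_set(spec)[1, ]
  list(bb = generate_backbone(spec, motif_len), mimic = design_mimic_site(m))
}

test_that("motif replacement preserves flanks and length arithmetic", {
  d <- make_design()
  cons <- assemble_construct(d$bb, d$mimic)
  expect_equal(nchar(cons$sequence), 300L - 24L + 23L)
  s <- d$bb$motif_interval[1]; e <- d$bb$motif_interval[2]
  expect_equal(substr(cons$sequence, 1, s), substr(d$bb$sequence, 1, s))
  expect_equal(substr(cons$sequence, cons$motif_interval[2] + 1, nchar(cons$sequence)),
               substr(d$bb$sequence, e + 1, nchar(d$bb$sequence)))
  # round trip: the new motif interval holds exactly the mimic site
  expect_equal(substr(cons$sequence, cons$motif_interval[1] + 1,
                      cons$motif_interval[2]),
               d$mimic$site)
  expect_error(assemble_construct(list(sequence = "ACGT"), d$mimic),
               "motif_interval")
})

test_that("Wallace-rule melting temperature is exact and monotone", {
  expect_equal(melting_temperature("ACGT"), 12)
  expect_equal(melting_temperature(paste0(strrep("G", 10), strrep("A", 10))), 60)
  expect_equal(melting_temperature("acgt"), 12)
  expect_error(melting_temperature(""), "empty")
  set.seed(72)
  s <- random_dna(20)
  i <- regexpr("A", s)[1]
  if (i > 0) {
    s2 <- s; substr(s2, i, i) <- "G"
    expect_equal(melting_temperature(s2), melting_temperature(s) + 2)
  }
})

test_that("mutagenic and outer primers obey their anchors and Tm targets", {
  d <- make_design()
  pr <- design_mutagenesis_primers(d$bb, d$mimic)
  cons <- pr$construct$sequence
  expect_match(pr$mutagenic$forward, d$mimic$site, fixed = TRUE)
  # anchors map back to the construct with zero mismatches
  for (p in pr[c("mutagenic", "outer")]) {
    fa <- p$forward_anchor; ra <- p$reverse_anchor
    expect_equal(p$forward, substr(cons, fa[1] + 1, fa[2]))
    expect_equal(p$reverse,
                 reverse_complement(substr(cons, ra[1] + 1, ra[2]), "DNA"))
  }
  # flanks of the mutagenic primer cover at least min_flank on each side
  expect_gte(pr$construct$motif_interval[1] - pr$mutagenic$forward_anchor[1], 20L)
  expect_gte(pr$mutagenic$forward_anchor[2] - pr$construct$motif_interval[2], 20L)
  # independent Wallace recomputation from the emitted primer sequences
  wallace <- function(s) {
    cc <- strsplit(s, "")[[1]]
    2 * sum(cc %in% c("A", "T")) + 4 * sum(cc %in% c("G", "C"))
  }
  expect_gte(wallace(pr$outer$forward), 55)
  expect_gte(wallace(pr$outer$reverse), 55)
  expect_lte(wallace(pr$outer$forward), 63)
  expect_lte(wallace(pr$outer$reverse), 63)
  expect_equal(pr$mutagenic$tm_forward, wallace(pr$mutagenic$forward))
})

test_that("too-short backbone flanks are refused", {
  d <- make_design()
  set.seed(73)
  short_bb <- backbone("tiny", random_dna(60), c(5, 29))
  expect_error(design_mutagenesis_primers(short_bb, d$mimic), "min_flank")
})

test_that("overlap-extension stitching reconstructs the construct", {
  d <- make_design()
  pr <- design_mutagenesis_primers(d$bb, d$mimic)
  cons <- pr$construct$sequence
  p1 <- substr(cons, pr$outer$forward_anchor[1] + 1,
               pr$mutagenic$reverse_anchor[2])
  p2 <- substr(cons, pr$mutagenic$forward_anchor[1] + 1,
               pr$outer$reverse_anchor[2])
  expect_equal(stitch_overlap(p1, p2), cons)
  expect_error(stitch_overlap("ACGTACGTACGTACGTA", "TTTTTTTTTTTTTTTTT"),
               "no exact overlap")
})

test_that("GenBank flat file carries features and the full sequence", {
  d <- make_design()
  pr <- design_mutagenesis_primers(d$bb, d$mimic)
  f <- withr::local_tempfile(fileext = ".gb")
  write_construct_genbank(pr$construct, pr[c("mutagenic", "outer")], f)
  lines <- readLines(f)
  expect_match(lines[1], "^LOCUS")
  expect_true(any(grepl("^FEATURES", lines)))
  expect_true(any(grepl("misc_feature", lines)))
  expect_true(any(grepl("primer_bind", lines)))
  expect_equal(tail(lines, 1), "//")
  ori <- which(lines == "ORIGIN")
  seq_lines <- lines[(ori + 1):(length(lines) - 1)]
  seqn <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  expect_equal(seqn, pr$construct$sequence)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_primer_tsv(pr[c("mutagenic", "outer")], pr$construct$name, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$anchor_start[tab$role == "OUTER" & tab$direction == "forward"], 1L)
})
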