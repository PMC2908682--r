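# Small sequence utilities shared across test files.

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

as_member <- function(seq, id = "xxx-miR500a") {
  lab <- family_label(id)
  data.frame(id = id, family = lab$family, variant = lab$variant,
             sequence = toupper(seq), description = "",
             stringsAsFactors = FALSE)
}

# first DNA base that mismatches the given miRNA base (deterministic)
mismatch_partner <- function(base) {
  for (cand in c("T", "G", "C", "A")) {
    if (classify_pair(base, cand) == "mismatch") return(cand)
  }
  stop("unreachable")
}

# exact-complement site with the partner of one miRNA position replaced by a
# mismatching base (the classic inert single-central-mismatch geometry)
single_mismatch_site <- function(mirna, pos = 11L) {
  site <- reverse_complement(mirna, "DNA")
  idx <- nchar(mirna) - pos + 1L
  b <- substr(mirna, pos, pos)
  paste0(substr(site, 1L, idx - 1L), mismatch_partner(b),
         substr(site, idx + 1L, nchar(site)))
}

# apply transversions (uncoverable by any single site base) at given positions
transversion_at <- function(seq, positions) {
  map <- c(A = "C", C = "A", G = "U", U = "G")
  cc <- strsplit(seq, "")[[1]]
  cc[positions] <- unname(map[cc[positions]])
  paste(cc, collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

write_tmp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
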