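# Construct assembly and overlap-extension mutagenesis primer design.
#
# The mimic site replaces the miRNA-complementary motif of a carrier backbone
# (the natural template being the IPS1 non-coding transcript).  Mutagenic
# primers carry the full replacement site flanked by backbone anchors; outer
# primers sit at the construct ends; the two PCR products are stitched by
# their overlap.

#' Insert a mimic site into a backbone
#'
#' @param bb A [backbone()] object.
#' @param mimic A `"mimic_site"` object.
#' @return An object of class `"mim_construct"`: `name`, `sequence`,
#'   `motif_interval` (0-based half-open, the new site), and an `annotations`
#'   data.frame (feature, start, end, label; 0-based half-open).
#' @export
assemble_construct <- function(bb, mimic) {
  if (!inherits(bb, "backbone")) stop("backbone without motif_interval")
  s <- bb$motif_interval[1]; e <- bb$motif_interval[2]
  up <- substr(bb$sequence, 1L, s)
  down <- substr(bb$sequence, e + 1L, nchar(bb$sequence))
  seqn <- paste0(up, mimic$site, down)
  motif <- c(s, s + nchar(mimic$site))
  ann <- data.frame(
    feature = c("misc_feature", "regulatory"),
    start = c(motif[1], 0L),
    end = c(motif[2], 0L),
    label = c(paste0(mimic$name, " mimic site"),
              "p35S promoter (informational placeholder)"),
    stringsAsFactors = FALSE)
  structure(list(name = mimic$name, sequence = seqn,
                 motif_interval = motif, annotations = ann,
                 backbone = bb$name),
            class = "mim_construct")
}

#' @export
print.mim_construct <- function(x, ...) {
  cat(sprintf("<mim_construct> %s: %d bp (backbone %s), mimic site [%d,%d)\n",
              x$name, nchar(x$sequence), x$backbone,
              x$motif_interval[1], x$motif_interval[2]))
  invisible(x)
}

#' Oligonucleotide melting temperature (Wallace rule)
#'
#' Tm = 2(A+T) + 4(G+C) degrees C; the standard quick estimate for short
#' primers.
#'
#' @param seq DNA sequence.
#' @return Numeric Tm in degrees C.
#' @export
melting_temperature <- function(seq) {
  seq <- normalize_sequence(seq, "DNA", what = "primer")
  cc <- strsplit(seq, "")[[1]]
  2 * sum(cc %in% c("A", "T")) + 4 * sum(cc %in% c("G", "C"))
}

# extend an anchor one base at a time (3' direction of the primer) until the
# Wallace Tm reaches tm_target; returns the final length or errors
.extend_to_tm <- function(get_seq, start_len, max_len, tm_target, what) {
  len <- start_len
  while (len <= max_len) {
    if (melting_temperature(get_seq(len)) >= tm_target) return(len)
    len <- len + 1L
  }
  stop(what, ": target Tm unreachable before running off the sequence")
}

#' Design overlap-extension mutagenesis primers
#'
#' The mutagenic forward primer is `[upstream flank][full mimic site]
#' [downstream flank]` anchored on the assembled construct, with each flank at
#' least `min_flank` nt and extended base by base until its own Wallace Tm
#' reaches `tm_target`; the mutagenic reverse primer is the reverse complement
#' of the same region.  Outer primers anchor at the construct ends and are
#' extended until their Tm lies in `[tm_target, tm_target + 8]`.
#'
#' @param bb A [backbone()] object.
#' @param mimic A `"mimic_site"` object.
#' @param min_flank Minimum backbone anchor on each side of the site (nt).
#' @param tm_target Flank/primer melting temperature target (degrees C).
#' @return List with the assembled `construct` and two `"primer_pair"`
#'   objects, `mutagenic` and `outer`.  Each pair holds `forward`, `reverse`,
#'   their 0-based half-open anchor intervals on the construct, Wallace Tm
#'   values and the `role`.
#' @export
design_mutagenesis_primers <- function(bb, mimic, min_flank = 20L,
                                       tm_target = 55) {
  cons <- assemble_construct(bb, mimic)
  seqn <- cons$sequence
  L <- nchar(seqn)
  s <- cons$motif_interval[1]; e <- cons$motif_interval[2]
  if (s < min_flank || (L - e) < min_flank) {
    stop("backbone flank shorter than min_flank (", min_flank, " nt)")
  }
  up_len <- .extend_to_tm(
    function(k) substr(seqn, s - k + 1L, s), min_flank, s, tm_target,
    "upstream mutagenic flank")
  down_len <- .extend_to_tm(
    function(k) substr(seqn, e + 1L, e + k), min_flank, L - e, tm_target,
    "downstream mutagenic flank")
  m_start <- s - up_len          # 0-based
  m_end <- e + down_len
  fwd <- substr(seqn, m_start + 1L, m_end)
  mutagenic <- structure(list(
    forward = fwd,
    reverse = reverse_complement(fwd, "DNA"),
    forward_anchor = c(m_start, m_end),
    reverse_anchor = c(m_start, m_end),
    tm_forward = melting_temperature(fwd),
    tm_reverse = melting_temperature(reverse_complement(fwd, "DNA")),
    role = "MUTAGENIC"), class = "primer_pair")
  of_len <- .extend_to_tm(function(k) substr(seqn, 1L, k), 1L, L, tm_target,
                          "outer forward")
  or_len <- .extend_to_tm(function(k) substr(seqn, L - k + 1L, L), 1L, L,
                          tm_target, "outer reverse")
  of <- substr(seqn, 1L, of_len)
  orseq <- reverse_complement(substr(seqn, L - or_len + 1L, L), "DNA")
  for (tm in c(melting_temperature(of), melting_temperature(orseq))) {
    if (tm > tm_target + 8) {
      stop("outer primer Tm overshoots [", tm_target, ",", tm_target + 8, "]")
    }
  }
  outer <- structure(list(
    forward = of, reverse = orseq,
    forward_anchor = c(0L, of_len),
    reverse_anchor = c(L - or_len, L),
    tm_forward = melting_temperature(of),
    tm_reverse = melting_temperature(orseq),
    role = "OUTER"), class = "primer_pair")
  list(construct = cons, mutagenic = mutagenic, outer = outer)
}

#' Stitch two overlapping PCR products
#'
#' Finds the longest suffix of `seq1` that is an exact prefix of `seq2`
#' (at least `min_overlap` nt) and returns the merged sequence, as in
#' overlap-extension PCR.
#'
#' @param seq1,seq2 DNA product sequences (sense strand).
#' @param min_overlap Minimum exact overlap (nt).
#' @return Merged DNA sequence.
#' @export
stitch_overlap <- function(seq1, seq2, min_overlap = 15L) {
  n1 <- nchar(seq1); n2 <- nchar(seq2)
  if (min(n1, n2) < min_overlap) stop("products shorter than min_overlap")
  for (k in rev(seq.int(min_overlap, min(n1, n2)))) {
    if (substr(seq1, n1 - k + 1L, n1) == substr(seq2, 1L, k)) {
      return(paste0(seq1, substr(seq2, k + 1L, n2)))
    }
  }
  stop("no exact overlap of at least ", min_overlap, " nt")
}

#' Write primer pairs as TSV
#'
#' Coordinates are reported 1-based inclusive.
#'
#' @param pairs Named list of `"primer_pair"` objects (typically
#'   `list(mutagenic = ..., outer = ...)`).
#' @param construct_name Construct the anchors refer to.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_primer_tsv <- function(pairs, construct_name, file) {
  rows <- list()
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      construct = construct_name,
      name = paste0(construct_name, "_", nm, c("_F", "_R")),
      role = p$role, direction = c("forward", "reverse"),
      sequence = c(p$forward, p$reverse),
      anchor_start = c(p$forward_anchor[1], p$reverse_anchor[1]) + 1L,
      anchor_end = c(p$forward_anchor[2], p$reverse_anchor[2]),
      tm = c(p$tm_forward, p$tm_reverse),
      stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a construct as a GenBank-style flat file
#'
#' Minimal flat file with `misc_feature` for the mimic motif and
#' `primer_bind` features for any primers; coordinates 1-based inclusive.
#'
#' @param cons A `"mim_construct"`.
#' @param primers Optional list of `"primer_pair"` objects.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_construct_genbank <- function(cons, primers = NULL, file) {
  L <- nchar(cons$sequence)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN", cons$name, L),
    sprintf("DEFINITION  %s artificial miRNA target mimic construct.", cons$name),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L))
  for (i in seq_len(nrow(cons$annotations))) {
    a <- cons$annotations[i, ]
    loc <- if (a$end > a$start) sprintf("%d..%d", a$start + 1L, a$end) else "1"
    lines <- c(lines,
               sprintf("     %-15s %s", a$feature, loc),
               sprintf("                     /label=\"%s\"", a$label))
  }
  for (p in primers) {
    for (side in c("forward", "reverse")) {
      anch <- if (side == "forward") p$forward_anchor else p$reverse_anchor
      lines <- c(lines,
                 sprintf("     %-15s %d..%d", "primer_bind", anch[1] + 1L, anch[2]),
                 sprintf("                     /label=\"%s %s\"", p$role, side),
                 sprintf("                     /note=\"Tm %.0f C (Wallace)\"",
                         if (side == "forward") p$tm_forward else p$tm_reverse))
    }
  }
  lines <- c(lines, "ORIGIN")
  seqlow <- tolower(cons$sequence)
  for (off in seq(1L, L, by = 60L)) {
    chunk <- substr(seqlow, off, min(off + 59L, L))
    tens <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, file)
  invisible(file)
}
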