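# Sequence input/output and normalization.
#
# Conventions used throughout the package:
#  * sequences are plain uppercase character scalars, read 5'->3';
#  * miRNAs are RNA ({A,C,G,U}), decoy sites and backbones are DNA ({A,C,G,T});
#  * intervals are 0-based half-open internally; human-readable reports use
#    1-based inclusive coordinates.

.RNA_BASES <- c("A", "C", "G", "U")
.DNA_BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide sequence
#'
#' Uppercases and converts a sequence into the requested alphabet (U<->T is
#' lossless and involutive). Any residue outside the plain 4-letter alphabet
#' (including ambiguity codes such as N) is rejected.
#'
#' @param x Character scalar, the sequence.
#' @param alphabet `"RNA"` or `"DNA"`.
#' @param what Label used in error messages (e.g. a record id).
#' @return Normalized character scalar.
#' @export
normalize_sequence <- function(x, alphabet = c("RNA", "DNA"), what = "sequence") {
  alphabet <- match.arg(alphabet)
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("sequence must be a single character string (", what, ")")
  }
  x <- toupper(x)
  x <- if (alphabet == "RNA") chartr("T", "U", x) else chartr("U", "T", x)
  if (!nzchar(x)) stop("empty sequence (", what, ")")
  ok <- if (alphabet == "RNA") .RNA_BASES else .DNA_BASES
  bad <- regexpr(sprintf("[^%s]", paste(ok, collapse = "")), x)
  if (bad != -1L) {
    stop(sprintf("invalid residue '%s' at position %d in %s",
                 substr(x, bad, bad), as.integer(bad), what))
  }
  x
}

#' Convert a sequence to the RNA or DNA alphabet
#'
#' @param x Character scalar (or vector), any mix of case and U/T.
#' @return Character of the same length in the requested alphabet.
#' @export
to_rna <- function(x) chartr("T", "U", toupper(x))

#' @rdname to_rna
#' @export
to_dna <- function(x) chartr("U", "T", toupper(x))

#' Reverse complement
#'
#' Antiparallel complement of a nucleotide sequence, returned in the requested
#' alphabet. The input alphabet is inferred from the presence of U or T (a
#' sequence containing neither is treated as RNA) unless given explicitly.
#'
#' @param x Character scalar sequence.
#' @param out_alphabet `"RNA"` or `"DNA"`; default keeps the input alphabet.
#' @param alphabet Input alphabet; inferred when `NULL`.
#' @return Character scalar, the reverse complement 5'->3'.
#' @export
reverse_complement <- function(x, out_alphabet = NULL, alphabet = NULL) {
  if (is.null(alphabet)) {
    up <- toupper(x)
    alphabet <- if (grepl("T", up, fixed = TRUE)) "DNA" else "RNA"
  }
  x <- normalize_sequence(x, alphabet)
  if (is.null(out_alphabet)) out_alphabet <- alphabet
  out_alphabet <- match.arg(out_alphabet, c("RNA", "DNA"))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(to_dna(x))))
  if (out_alphabet == "RNA") to_rna(rc) else rc
}

#' Parse family and variant labels from mature miRNA ids
#'
#' Ids follow the miRBase mature grammar `<species>-miR<number><variant>` where
#' the variant is an optional letter suffix (e.g. `a`, `b`) or a `.n` token
#' (e.g. `.1` for families producing several distinct mature species).
#'
#' @param id Character vector of mature miRNA ids.
#' @return A data.frame with columns `id`, `family` (the numeric token, as
#'   text) and `variant` (possibly empty).
#' @export
#' @examples
#' family_label(c("ath-miR172a", "ath-miR161.1"))
family_label <- function(id) {
  rx <- "^[A-Za-z]+-miR([0-9]+)([a-z]+|\\.[0-9]+)?$"
  ok <- grepl(rx, id)
  if (any(!ok)) {
    stop("unparseable miRNA id(s): ", paste(id[!ok], collapse = ", "))
  }
  family <- sub(rx, "\\1", id)
  variant <- sub(rx, "\\2", id)
  data.frame(id = id, family = family, variant = variant,
             stringsAsFactors = FALSE)
}

#' Read a mature miRNA catalogue from FASTA
#'
#' Reads a miRBase-style `mature.fa` dialect: the first whitespace-delimited
#' header token is the id, the remainder is kept as a free-text description.
#' Sequences are uppercased and converted to the RNA alphabet; residues outside
#' A/C/G/U/T and duplicated ids are rejected.
#'
#' @param file Path to a FASTA file (ignored when `text` is given).
#' @param species_prefix Optional species code (e.g. `"ath"`); only records
#'   whose id starts with `<prefix>-` are kept.
#' @param text Optional character vector of FASTA lines, used instead of `file`.
#' @param min_length,max_length Accepted mature length bounds.
#' @return A data.frame with columns `id`, `family`, `variant`, `sequence`
#'   (RNA) and `description`, one row per retained record, in file order.
#' @export
parse_mirna_fasta <- function(file = NULL, species_prefix = NULL, text = NULL,
                              min_length = 18L, max_length = 26L) {
  if (!is.null(text)) {
    file <- tempfile(fileext = ".fa")
    on.exit(unlink(file), add = TRUE)
    writeLines(text, file)
  }
  if (is.null(file) || !file.exists(file)) {
    stop("catalogue FASTA not found: ", if (is.null(file)) "<missing>" else file)
  }
  ss <- Biostrings::readBStringSet(file)
  if (length(ss) == 0L) stop("no FASTA records in ", file)
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(ss)
  if (!is.null(species_prefix)) {
    keep <- startsWith(id, paste0(species_prefix, "-"))
    id <- id[keep]; description <- description[keep]; seqs <- seqs[keep]
  }
  if (length(id) == 0L) {
    return(data.frame(id = character(), family = character(),
                      variant = character(), sequence = character(),
                      description = character(), stringsAsFactors = FALSE))
  }
  if (anyDuplicated(id)) {
    stop("duplicate miRNA id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seqs <- vapply(seq_along(seqs), function(i) {
    normalize_sequence(seqs[i], "RNA", what = sprintf("record '%s'", id[i]))
  }, character(1))
  len <- nchar(seqs)
  off <- len < min_length | len > max_length
  if (any(off)) {
    stop("mature length outside [", min_length, ",", max_length, "] for: ",
         paste(sprintf("%s (%d nt)", id[off], len[off]), collapse = ", "))
  }
  lab <- family_label(id)
  data.frame(id = id, family = lab$family, variant = lab$variant,
             sequence = unname(seqs), description = description,
             stringsAsFactors = FALSE)
}

#' Write a mature miRNA catalogue to FASTA
#'
#' Inverse of [parse_mirna_fasta()]: ids (plus descriptions, when present) in
#' the headers, sequences wrapped at 60 columns.
#'
#' @param catalogue Catalogue data.frame.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_mirna_fasta <- function(catalogue, file) {
  headers <- ifelse(nzchar(catalogue$description),
                    paste(catalogue$id, catalogue$description),
                    catalogue$id)
  ss <- Biostrings::RNAStringSet(stats::setNames(catalogue$sequence, headers))
  Biostrings::writeXStringSet(ss, file, width = 60L)
  invisible(file)
}

#' Construct a decoy backbone object
#'
#' A backbone is the DNA carrier transcript (IPS1-like) whose
#' miRNA-complementary motif will be replaced by a designed mimic site.
#'
#' @param name Backbone name.
#' @param sequence DNA sequence.
#' @param motif_interval Integer pair, 0-based half-open coordinates of the
#'   motif to replace; width must lie in \[20, 30\].
#' @return An object of class `"backbone"`.
#' @export
backbone <- function(name, sequence, motif_interval) {
  sequence <- normalize_sequence(sequence, "DNA", what = paste0("backbone '", name, "'"))
  motif_interval <- as.integer(motif_interval)
  if (length(motif_interval) != 2L || anyNA(motif_interval)) {
    stop("motif_interval must be two integers (0-based half-open)")
  }
  s <- motif_interval[1]; e <- motif_interval[2]
  if (!(s >= 0L && s < e && e <= nchar(sequence))) {
    stop("motif_interval out of bounds for backbone '", name, "'")
  }
  w <- e - s
  if (w < 20L || w > 30L) {
    stop("motif width must be in [20,30] nt, got ", w)
  }
  structure(list(name = name, sequence = sequence,
                 motif_interval = motif_interval),
            class = "backbone")
}

#' Read a backbone and its motif coordinates
#'
#' @param fasta Path to a single- or multi-record DNA FASTA.
#' @param motif_tsv Path to a headerless 3-column TSV `name start end`
#'   (0-based half-open) giving the motif interval per backbone.
#' @param name Which record to load; default the first in the FASTA.
#' @return A `"backbone"` object.
#' @export
read_backbone <- function(fasta, motif_tsv, name = NULL) {
  ss <- Biostrings::readBStringSet(fasta)
  if (length(ss) == 0L) stop("no FASTA records in ", fasta)
  ids <- sub("\\s.*$", "", names(ss))
  if (is.null(name)) name <- ids[1]
  i <- match(name, ids)
  if (is.na(i)) stop("backbone '", name, "' not found in ", fasta)
  tab <- utils::read.delim(motif_tsv, header = FALSE,
                           col.names = c("name", "start", "end"),
                           stringsAsFactors = FALSE)
  j <- match(name, tab$name)
  if (is.na(j)) stop("no motif coordinates for backbone '", name, "' in ", motif_tsv)
  backbone(name, as.character(ss[[i]]), c(tab$start[j], tab$end[j]))
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %s: %d bp, motif [%d,%d) (%d nt)\n",
              x$name, nchar(x$sequence),
              x$motif_interval[1], x$motif_interval[2],
              diff(x$motif_interval)))
  invisible(x)
}

#' Write named DNA sequences to FASTA (60-column wrap)
#'
#' @param seqs Named character vector of DNA sequences.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_dna_fasta <- function(seqs, file) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, file, width = 60L)
  invisible(file)
}
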