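# Mimic site design, validation, naming, and the cross-capture matrix.
#
# A mimic site is the reverse complement (DNA) of the target miRNA (or the
# per-position consensus covering bases of a subgroup) in which the partner of
# one central miRNA position -- by default position 11, immediately 3' of the
# scissile bond -- is removed and a 3-nt bulge is inserted in its place.  For
# a 21-nt miRNA this yields the classic 23-nt motif (L - 1 + 3).  The bulge
# 3-mer is not arbitrary: it must not restore a cleavage-competent central
# duplex, must leave the central bulge as the preferred alignment, and must
# not create long homopolymer runs with its flanks.

#' Design parameters for mimic construction
#'
#' @param bulge_length Bulge length in nt (>= 3; 3 is the IPS1 geometry).
#' @param bulge_replaces_position 1-based miRNA position whose site partner is
#'   removed; must lie inside the scoring central window.
#' @param bulge_candidate_order Character vector fixing the enumeration order
#'   of candidate bulge sequences; default all `bulge_length`-mers in
#'   lexicographic order A < C < G < T.
#' @param homopolymer_max Longest homopolymer run (nt) the inserted bulge may
#'   form together with its flanks.
#' @return An object of class `"design_params"`.
#' @export
design_params <- function(bulge_length = 3L,
                          bulge_replaces_position = 11L,
                          bulge_candidate_order = NULL,
                          homopolymer_max = 3L) {
  bulge_length <- as.integer(bulge_length)
  if (bulge_length < 3L) stop("bulge_length must be >= 3 nt")
  if (is.null(bulge_candidate_order)) {
    grid <- expand.grid(rep(list(c("A", "C", "G", "T")), bulge_length),
                        stringsAsFactors = FALSE)
    kmers <- apply(grid[, rev(seq_len(bulge_length)), drop = FALSE], 1, paste0,
                   collapse = "")
    bulge_candidate_order <- sort(kmers)
  }
  structure(list(bulge_length = bulge_length,
                 bulge_replaces_position = as.integer(bulge_replaces_position),
                 bulge_candidate_order = bulge_candidate_order,
                 homopolymer_max = as.integer(homopolymer_max)),
            class = "design_params")
}

.as_members <- function(target) {
  if (is.character(target)) {
    lab <- tryCatch(family_label(target), error = function(e) NULL)
    target <- data.frame(id = if (is.null(lab)) paste0("query", seq_along(target)) else lab$id,
                         family = if (is.null(lab)) "" else lab$family,
                         variant = if (is.null(lab)) "" else lab$variant,
                         sequence = NA_character_, stringsAsFactors = FALSE)
    stop("design targets must be catalogue rows with id and sequence")
  }
  stopifnot(is.data.frame(target), nrow(target) >= 1L,
            all(c("id", "sequence") %in% names(target)))
  target
}

# longest homopolymer run that overlaps [from, to] (1-based, inclusive)
.max_run_overlapping <- function(seq, from, to) {
  cc <- strsplit(seq, "")[[1]]
  rl <- rle(cc)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  hit <- starts <= to & ends >= from
  if (!any(hit)) return(0L)
  max(rl$lengths[hit])
}

#' Choose the bulge sequence for a mimic site
#'
#' Scans the fixed candidate order and returns the first bulge k-mer whose
#' assembled site, for every source miRNA, (i) is not cleavable, (ii) is
#' capturing with the bulge placed at the intended interval by the
#' minimum-score alignment, and (iii) creates no homopolymer run longer than
#' `homopolymer_max` together with its flanks.
#'
#' @param members Data.frame of source miRNAs (catalogue rows).
#' @param left,right Site sequence 5' and 3' of the bulge (DNA).
#' @param sparams,dparams Parameter objects.
#' @return List with `bulge` (the chosen k-mer) and `rejections` (data.frame
#'   of candidate, reason for each rejected earlier candidate).
#' @export
choose_bulge_sequence <- function(members, left, right,
                                  sparams = scoring_params(),
                                  dparams = design_params()) {
  members <- .as_members(members)
  intended <- c(nchar(left), nchar(left) + dparams$bulge_length)
  brp <- dparams$bulge_replaces_position
  rejections <- list()
  for (cand in dparams$bulge_candidate_order) {
    site <- paste0(left, cand, right)
    run <- .max_run_overlapping(site, nchar(left) + 1L,
                                nchar(left) + dparams$bulge_length)
    if (run > dparams$homopolymer_max) {
      rejections[[length(rejections) + 1L]] <-
        data.frame(candidate = cand, reason = "homopolymer", stringsAsFactors = FALSE)
      next
    }
    reason <- NULL
    for (i in seq_len(nrow(members))) {
      aln <- align_duplex(members[i, , drop = FALSE], site, sparams)
      geom_ok <- !is.null(aln$bulge_interval) &&
        identical(as.integer(aln$bulge_interval), as.integer(intended)) &&
        identical(aln$unpaired_mirna, brp)
      if (!geom_ok) { reason <- "bulge_not_preferred_placement"; break }
      sc <- score_duplex(aln, sparams)
      if (is_cleavable(aln, sc, sparams)) { reason <- "cleavage_site_reconstituted"; break }
      if (!is_capturing(aln, sc, sparams)) { reason <- "not_capturing"; break }
    }
    if (is.null(reason)) {
      rej <- if (length(rejections)) do.call(rbind, rejections) else
        data.frame(candidate = character(), reason = character(),
                   stringsAsFactors = FALSE)
      return(list(bulge = cand, rejections = rej))
    }
    rejections[[length(rejections) + 1L]] <-
      data.frame(candidate = cand, reason = reason, stringsAsFactors = FALSE)
  }
  rej <- do.call(rbind, rejections)
  stop("no admissible bulge sequence; rejection reasons: ",
       paste(sprintf("%s(%s)", rej$candidate, rej$reason), collapse = ", "))
}

#' Design a mimic site for a miRNA or subgroup
#'
#' Builds the covering reverse-complement site, removes the partner of
#' `bulge_replaces_position`, inserts the bulge chosen by
#' [choose_bulge_sequence()], and validates that every source is captured and
#' none can cleave.
#'
#' @param target One catalogue row, or a subgroup data.frame (one family,
#'   aligned 5'-anchored; the site is designed against the longest member).
#' @param sparams,dparams Parameter objects.
#' @param name Optional mimic name; default from [name_mimic()] treating the
#'   target as a proper subgroup.
#' @return An object of class `"mimic_site"`: `name`, `site` (DNA),
#'   `bulge_interval` (0-based half-open site coordinates), `bulge`,
#'   `sources`, `family`, `status` (always `"MIMIC_FUNCTIONAL"` for a fresh
#'   design) and the bulge `rejections` log.
#' @export
design_mimic_site <- function(target, sparams = scoring_params(),
                              dparams = design_params(), name = NULL) {
  members <- .as_members(target)
  brp <- dparams$bulge_replaces_position
  w <- sparams$central_window
  if (brp < w[1] || brp > w[2]) {
    stop("bulge_replaces_position must lie inside the central window")
  }
  L <- max(nchar(members$sequence))
  if (brp >= L) stop("bulge position beyond miRNA length")
  profile <- .position_profile(members)
  cover <- rep(NA_character_, L)
  for (p in seq_len(L)) {
    if (p == brp) next
    cover[p] <- choose_site_base(profile[[p]])
    if (is.na(cover[p])) {
      stop(sprintf(
        "no single site base covers position %d (member bases: %s)",
        p, paste(sort(profile[[p]]), collapse = ",")))
    }
  }
  left <- paste(cover[L:(brp + 1L)], collapse = "")
  right <- paste(cover[(brp - 1L):1L], collapse = "")
  choice <- choose_bulge_sequence(members, left, right, sparams, dparams)
  site <- paste0(left, choice$bulge, right)
  for (i in seq_len(nrow(members))) {
    v <- validate_mimic(site, members[i, , drop = FALSE], sparams, dparams)
    if (v$status != "MIMIC_FUNCTIONAL") {
      stop("designed site fails validation for ", members$id[i],
           " (status ", v$status, ")")
    }
  }
  fam <- if ("family" %in% names(members)) members$family[1] else ""
  if (is.null(name)) {
    variants <- if ("variant" %in% names(members)) members$variant else ""
    name <- name_mimic(fam, variants, whole_family = all(!nzchar(variants)))
  }
  structure(list(name = name, site = site,
                 bulge_interval = c(nchar(left), nchar(left) + dparams$bulge_length),
                 bulge = choice$bulge,
                 sources = members$id, family = fam,
                 status = "MIMIC_FUNCTIONAL",
                 rejections = choice$rejections),
            class = "mimic_site")
}

#' @export
print.mimic_site <- function(x, ...) {
  cat(sprintf("<mimic_site> %s: %d nt, bulge %s at [%d,%d), sources: %s\n",
              x$name, nchar(x$site), x$bulge,
              x$bulge_interval[1], x$bulge_interval[2],
              paste(x$sources, collapse = ", ")))
  invisible(x)
}

#' Classify an arbitrary site against a miRNA
#'
#' Three-way validation mirroring the functional trichotomy of central-site
#' variants: a site that captures is `MIMIC_FUNCTIONAL`; a non-capturing site
#' that still presents a cleavage-competent duplex is `CLEAVABLE`; anything
#' else is `INERT`.
#'
#' @param site DNA site sequence.
#' @param mirna Catalogue row or RNA sequence.
#' @param sparams,dparams Parameter objects.
#' @return List with `status`, `alignable`, and (when alignable) `alignment`,
#'   `score`, `noncentral`.
#' @export
validate_mimic <- function(site, mirna, sparams = scoring_params(),
                           dparams = design_params()) {
  aln <- tryCatch(align_duplex(mirna, site, sparams), error = function(e) NULL)
  if (is.null(aln)) {
    return(list(status = "INERT", alignable = FALSE,
                alignment = NULL, score = NULL, noncentral = NA_real_))
  }
  sc <- score_duplex(aln, sparams)
  status <- if (is_capturing(aln, sc, sparams)) "MIMIC_FUNCTIONAL"
  else if (is_cleavable(aln, sc, sparams)) "CLEAVABLE"
  else "INERT"
  list(status = status, alignable = TRUE, alignment = aln, score = sc,
       noncentral = noncentral_score(aln, sparams))
}

#' Name a mimic after its family or subfamily
#'
#' Whole-family mimics are `MIM<family>`; subfamily mimics append the sorted
#' variant tokens (e.g. `MIM169defg`, `MIM161.1`).
#'
#' @param family Family label (numeric token as text).
#' @param variants Character vector of member variant tokens.
#' @param whole_family Does the mimic serve the whole family?
#' @return Character scalar name.
#' @export
name_mimic <- function(family, variants = character(0), whole_family = TRUE) {
  if (whole_family) return(paste0("MIM", family))
  paste0("MIM", family,
         paste(sort(unique(variants[nzchar(variants)])), collapse = ""))
}

#' Cross-capture specificity matrix
#'
#' Aligns every designed mimic against every catalogue miRNA and records
#' whether the mimic is predicted to capture it, together with the score
#' outside the bulge.  Off-target captures (capture of a miRNA that is not
#' among the mimic's sources) are how near-identical families that a mimic
#' cannot discriminate show up.
#'
#' @param mimics List of `"mimic_site"` objects.
#' @param catalogue Catalogue data.frame.
#' @param sparams [scoring_params()].
#' @return An object of class `"capture_matrix"`: logical matrix `captures`
#'   (mimics x miRNAs), numeric matrix `noncentral`, logical matrix
#'   `alignable`, and the `sources` list.
#' @export
capture_matrix <- function(mimics, catalogue, sparams = scoring_params()) {
  mnames <- vapply(mimics, function(m) m$name, character(1))
  ids <- catalogue$id
  captures <- matrix(FALSE, length(mimics), nrow(catalogue),
                     dimnames = list(mnames, ids))
  noncentral <- matrix(NA_real_, length(mimics), nrow(catalogue),
                       dimnames = list(mnames, ids))
  alignable <- captures
  for (i in seq_along(mimics)) {
    for (j in seq_len(nrow(catalogue))) {
      aln <- tryCatch(align_duplex(catalogue[j, , drop = FALSE],
                                   mimics[[i]]$site, sparams),
                      error = function(e) NULL)
      if (is.null(aln)) next
      alignable[i, j] <- TRUE
      sc <- score_duplex(aln, sparams)
      captures[i, j] <- is_capturing(aln, sc, sparams)
      noncentral[i, j] <- noncentral_score(aln, sparams)
    }
  }
  structure(list(captures = captures, noncentral = noncentral,
                 alignable = alignable,
                 sources = stats::setNames(lapply(mimics, function(m) m$sources),
                                           mnames)),
            class = "capture_matrix")
}

#' Off-target captures in a capture matrix
#'
#' @param cm A `"capture_matrix"`.
#' @return Data.frame (mimic, mirna_id, noncentral_score) of captures of
#'   miRNAs outside the mimic's own sources.
#' @export
off_target_captures <- function(cm) {
  out <- list()
  for (m in rownames(cm$captures)) {
    hit <- colnames(cm$captures)[cm$captures[m, ]]
    off <- setdiff(hit, cm$sources[[m]])
    if (length(off)) {
      out[[length(out) + 1L]] <- data.frame(
        mimic = m, mirna_id = off,
        noncentral_score = cm$noncentral[m, off],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(mimic = character(), mirna_id = character(),
               noncentral_score = numeric(), stringsAsFactors = FALSE)
}

#' Write a capture matrix as TSV
#'
#' Long format: mimic, miRNA id, alignable, captures, noncentral score,
#' off-target flag.
#'
#' @param cm A `"capture_matrix"`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_capture_tsv <- function(cm, file) {
  rows <- expand.grid(mimic = rownames(cm$captures),
                      mirna_id = colnames(cm$captures),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$alignable <- cm$alignable[cbind(rows$mimic, rows$mirna_id)]
  rows$captures <- cm$captures[cbind(rows$mimic, rows$mirna_id)]
  rows$noncentral_score <- cm$noncentral[cbind(rows$mimic, rows$mirna_id)]
  rows$off_target <- rows$captures &
    !mapply(function(m, id) id %in% cm$sources[[m]], rows$mimic, rows$mirna_id)
  rows <- rows[order(rows$mimic, rows$mirna_id), ]
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @export
print.capture_matrix <- function(x, ...) {
  cat(sprintf("<capture_matrix> %d mimics x %d miRNAs; %d capture calls (%d off-target)\n",
              nrow(x$captures), ncol(x$captures), sum(x$captures),
              nrow(off_target_captures(x))))
  invisible(x)
}
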