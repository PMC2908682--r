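# Family grouping and subfamily partitioning.
#
# One mimic can serve a whole miRNA family only if a single site base can pair
# (Watson-Crick or G:U wobble) with every member base at every non-bulge
# position.  Families whose members diverge beyond wobble coverage are split
# into subfamilies, each getting its own mimic, via a deterministic greedy set
# cover over capture-validated candidate subgroups.

#' Group a catalogue by miRNA family
#'
#' @param catalogue Catalogue data.frame from [parse_mirna_fasta()] (or
#'   [generate_mirna_set()]).
#' @return Named list (family label -> member data.frame), family keys sorted,
#'   members sorted by id.
#' @export
group_by_family <- function(catalogue) {
  if (nrow(catalogue) == 0L) return(stats::setNames(list(), character(0)))
  catalogue <- catalogue[order(catalogue$id), , drop = FALSE]
  fams <- split(catalogue, catalogue$family)
  fams[order(names(fams))]
}

#' Choose a single site base covering a set of miRNA bases
#'
#' Enumerates the four DNA bases and returns one that pairs (Watson-Crick or
#' wobble) with every member base at this position, or `NA` if none does.
#' Candidates pairing more members by Watson-Crick are preferred; remaining
#' ties are resolved in the fixed order T > G > C > A.
#'
#' @param column_bases Character vector of RNA residues observed at one
#'   aligned position across subgroup members.
#' @return A single DNA base, or `NA_character_` when no base covers all.
#' @export
#' @examples
#' choose_site_base(c("A", "G"))  # "T": A:T Watson-Crick, G:T wobble
#' choose_site_base(c("A", "C"))  # NA: no single base pairs both
choose_site_base <- function(column_bases) {
  bases <- unique(to_rna(column_bases))
  if (length(bases) == 0L) stop("empty base set")
  if (any(!bases %in% .RNA_BASES)) {
    stop("invalid residue(s): ", paste(setdiff(bases, .RNA_BASES), collapse = ","))
  }
  best <- NA_character_
  best_wc <- -1L
  for (cand in c("T", "G", "C", "A")) {
    st <- classify_pair(bases, rep(cand, length(bases)))
    if (any(st == "mismatch")) next
    n_wc <- sum(st == "wc")
    if (n_wc > best_wc) {
      best <- cand
      best_wc <- n_wc
    }
  }
  best
}

# Per-position base sets for a subgroup, 5'-anchored; shorter members simply
# do not contribute beyond their length (their 3' overhang is uncovered).
.position_profile <- function(members) {
  L <- max(nchar(members$sequence))
  chars <- lapply(members$sequence, function(s) strsplit(s, "")[[1]])
  lapply(seq_len(L), function(p) {
    unique(unlist(lapply(chars, function(cc) if (p <= length(cc)) cc[p])))
  })
}

# memoised feasibility: can this member set be served by one designed mimic?
.feasible_design <- function(members, sparams, dparams, cache = NULL) {
  key <- paste(sort(members$id), collapse = "|")
  if (!is.null(cache) && exists(key, envir = cache, inherits = FALSE)) {
    return(get(key, envir = cache, inherits = FALSE)[[1]])
  }
  res <- tryCatch(design_mimic_site(members, sparams, dparams),
                  error = function(e) NULL)
  if (!is.null(cache)) assign(key, list(res), envir = cache)  # keep NULLs too
  res
}

#' Partition a miRNA family into mimic-compatible subgroups
#'
#' Candidate subgroups are maximal compatible sets grown from each member (in
#' id order): a set is compatible when a covering site base exists at every
#' non-bulge position and the resulting designed mimic captures every member.
#' A greedy set cover then repeatedly selects the candidate covering the most
#' uncovered members (ties to the lexicographically smallest seed id); already
#' covered members are dropped from later picks, so the result is a partition.
#'
#' @param members Data.frame of catalogue rows, all from one family.
#' @param sparams [scoring_params()].
#' @param dparams [design_params()].
#' @return List of data.frames (the subgroups), each sorted by id; attribute
#'   `"family"` carries the family label.
#' @export
partition_for_mimics <- function(members, sparams = scoring_params(),
                                 dparams = design_params()) {
  stopifnot(nrow(members) >= 1L)
  if (length(unique(members$family)) != 1L) {
    stop("members must all belong to one family")
  }
  members <- members[order(members$id), , drop = FALSE]
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(members))) {
    if (is.null(.feasible_design(members[i, , drop = FALSE], sparams, dparams, cache))) {
      stop("member ", members$id[i],
           " cannot be captured even by its own dedicated mimic")
    }
  }
  n <- nrow(members)
  candidates <- vector("list", n)
  for (s in seq_len(n)) {
    set <- s
    for (j in setdiff(seq_len(n), s)) {
      trial <- sort(c(set, j))
      if (!is.null(.feasible_design(members[trial, , drop = FALSE],
                                    sparams, dparams, cache))) {
        set <- trial
      }
    }
    candidates[[s]] <- members$id[set]
  }
  uncovered <- members$id
  groups <- list()
  while (length(uncovered) > 0L) {
    gain <- vapply(candidates, function(ids) length(intersect(ids, uncovered)),
                   integer(1))
    pick <- which.max(gain)  # candidates are in seed-id order: first max wins
    ids <- sort(intersect(candidates[[pick]], uncovered))
    groups[[length(groups) + 1L]] <-
      members[match(ids, members$id), , drop = FALSE]
    uncovered <- setdiff(uncovered, ids)
  }
  structure(groups, family = members$family[1])
}

#' Partition report table
#'
#' One row per (subgroup, member) with the consensus coverage flag per member:
#' whether every non-bulge position of the member is covered Watson-Crick
#' (`wc`) or needs wobble pairs (`wobble`).
#'
#' @param groups Result of [partition_for_mimics()].
#' @param sparams,dparams Parameter objects used for the designs.
#' @return A data.frame (family, subgroup, member_id, mimic_name, coverage).
#' @export
partition_report <- function(groups, sparams = scoring_params(),
                             dparams = design_params()) {
  fam <- attr(groups, "family")
  out <- list()
  for (k in seq_along(groups)) {
    sub <- groups[[k]]
    mimic <- design_mimic_site(sub, sparams, dparams)
    for (i in seq_len(nrow(sub))) {
      aln <- align_duplex(sub[i, , drop = FALSE], mimic$site, sparams)
      st <- aln$columns$state
      coverage <- if (any(st == "wobble")) "wobble" else "wc"
      out[[length(out) + 1L]] <- data.frame(
        family = fam, subgroup = k, member_id = sub$id[i],
        mimic_name = mimic$name, coverage = coverage,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
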