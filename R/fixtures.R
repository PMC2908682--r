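# Deterministic synthetic data: miRNA catalogues with controlled family and
# subfamily structure, and decoy backbones.
#
# Family structure is planted so the design rules have something real to
# recover: members of one block differ from their block ancestor by a small
# number of transitions (A<->G, C<->U), which a single consensus site can
# always absorb through G:U wobble pairing; blocks within a family are
# separated by transversions (A<->C, G<->U) outside the central window, which
# no single site base can cover, so each block needs its own mimic.

.TRANSITION <- c(A = "G", G = "A", C = "U", U = "C")
.TRANSVERSION <- c(A = "C", C = "A", G = "U", U = "G")

#' Specification for synthetic fixtures
#'
#' @param seed Integer seed; fixtures are a pure function of the spec.
#' @param n_families Number of miRNA families.
#' @param members_per_family Members per family.
#' @param mirna_length Mature length (nt).
#' @param within_family_subs Maximum substitutions (transitions) of a member
#'   from its block ancestor.
#' @param subfamily_blocks Blocks per family (scalar or per-family vector);
#'   `NULL` or 1 means no subfamily structure.
#' @param between_block_subs Transversions separating block ancestors, placed
#'   outside the scoring central window.
#' @param backbone_length Backbone length (nt).
#' @param central_window Window avoided by between-block substitutions.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_families = 5L, members_per_family = 3L,
                         mirna_length = 21L, within_family_subs = 1L,
                         subfamily_blocks = NULL, between_block_subs = 5L,
                         backbone_length = 300L,
                         central_window = c(9L, 12L)) {
  spec <- list(seed = as.integer(seed), n_families = as.integer(n_families),
               members_per_family = as.integer(members_per_family),
               mirna_length = as.integer(mirna_length),
               within_family_subs = as.integer(within_family_subs),
               subfamily_blocks = subfamily_blocks,
               between_block_subs = as.integer(between_block_subs),
               backbone_length = as.integer(backbone_length),
               central_window = as.integer(central_window))
  stopifnot(spec$n_families >= 1L, spec$members_per_family >= 1L,
            spec$mirna_length >= 18L, spec$mirna_length <= 26L,
            spec$within_family_subs >= 0L,
            spec$within_family_subs < spec$between_block_subs,
            spec$backbone_length >= 60L)
  structure(spec, class = "fixture_spec")
}

.mutate_positions <- function(chars, positions, map) {
  chars[positions] <- unname(map[chars[positions]])
  chars
}

#' Generate a synthetic mature miRNA catalogue
#'
#' Per family, a uniform-random RNA ancestor; block ancestors (if any) are
#' separated by `between_block_subs` transversions outside the central window;
#' members carry up to `within_family_subs` random transitions.  Ids follow
#' the `xxx-miR<N><letter>` grammar (families numbered from 101).  Fully
#' determined by the spec seed.
#'
#' @param spec A [fixture_spec()].
#' @return Catalogue data.frame (`id`, `family`, `variant`, `sequence`,
#'   `description`, plus the planted `block` index); attribute `"ancestors"`
#'   holds the family/block ancestor sequences.
#' @export
generate_mirna_set <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  L <- spec$mirna_length
  w <- spec$central_window
  nb <- spec$subfamily_blocks
  if (is.null(nb)) nb <- 1L
  nb <- rep_len(as.integer(nb), spec$n_families)
  stopifnot(all(spec$members_per_family >= nb))
  withr::with_seed(spec$seed, {
    rows <- list(); anc <- list()
    for (f in seq_len(spec$n_families)) {
      fam <- as.character(100L + f)
      ancestor <- sample(.RNA_BASES, L, replace = TRUE)
      block_anc <- list(ancestor)
      if (nb[f] > 1L) {
        outside <- setdiff(seq_len(L), w[1]:w[2])
        for (b in 2:nb[f]) {
          pos <- sample(outside, spec$between_block_subs)
          block_anc[[b]] <- .mutate_positions(ancestor, pos, .TRANSVERSION)
        }
      }
      block_of <- sort(rep_len(seq_len(nb[f]), spec$members_per_family))
      for (i in seq_len(spec$members_per_family)) {
        base <- block_anc[[block_of[i]]]
        k <- sample(0:spec$within_family_subs, 1L)
        member <- if (k > 0L) {
          .mutate_positions(base, sample(L, k), .TRANSITION)
        } else base
        rows[[length(rows) + 1L]] <- data.frame(
          id = paste0("xxx-miR", fam, letters[i]),
          family = fam, variant = letters[i],
          sequence = paste(member, collapse = ""),
          description = sprintf("synthetic family %s block %d", fam, block_of[i]),
          block = block_of[i], stringsAsFactors = FALSE)
      }
      for (b in seq_len(nb[f])) {
        anc[[length(anc) + 1L]] <- data.frame(
          family = fam, block = b,
          sequence = paste(block_anc[[b]], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    cat_df <- do.call(rbind, rows)
    attr(cat_df, "ancestors") <- do.call(rbind, anc)
    cat_df
  })
}

#' Generate a synthetic decoy backbone
#'
#' Uniform-random DNA with the motif interval centered at the midpoint.
#' Deterministic in the spec seed (an independent stream, offset from the
#' catalogue stream).
#'
#' @param spec A [fixture_spec()].
#' @param motif_len Motif width (nt), must lie in \[20, 30\].
#' @return A [backbone()] object.
#' @export
generate_backbone <- function(spec, motif_len = 24L) {
  stopifnot(inherits(spec, "fixture_spec"))
  motif_len <- as.integer(motif_len)
  if (motif_len < 20L || motif_len > 30L) {
    stop("motif_len must be in [20,30] nt")
  }
  n <- spec$backbone_length
  withr::with_seed(spec$seed + 424243L, {
    seqn <- paste(sample(.DNA_BASES, n, replace = TRUE), collapse = "")
    start <- (n - motif_len) %/% 2L
    backbone(paste0("synthbb_", spec$seed), seqn, c(start, start + motif_len))
  })
}

#' Write fixture files (catalogue FASTA + backbone FASTA/motif TSV)
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param motif_len Backbone motif width.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_files <- function(spec, dir, motif_len = 24L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cat_df <- generate_mirna_set(spec)
  bb <- generate_backbone(spec, motif_len)
  paths <- c(catalogue = file.path(dir, "catalogue.fa"),
             backbone = file.path(dir, "backbone.fa"),
             motif = file.path(dir, "backbone_motif.tsv"))
  write_mirna_fasta(cat_df, paths[["catalogue"]])
  write_dna_fasta(stats::setNames(bb$sequence, bb$name), paths[["backbone"]])
  utils::write.table(
    data.frame(bb$name, bb$motif_interval[1], bb$motif_interval[2]),
    paths[["motif"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
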