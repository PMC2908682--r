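# End-to-end orchestration: catalogue -> family grouping -> subfamily
# partition -> mimic design -> capture matrix -> (optional) construct and
# primer design, with machine-readable reports.  The design pipeline is
# seed-free and deterministic; randomness exists only in the fixtures module.

#' Run the full mimic design pipeline
#'
#' @param catalogue Catalogue data.frame, or path to a mature-miRNA FASTA.
#' @param bb Optional [backbone()] object (or `NULL` to skip construct and
#'   primer design).
#' @param out_dir Optional output directory; when given, writes
#'   `mimics.fasta`, `capture_matrix.tsv`, `partition.tsv`,
#'   `design_report.json`, `summary.tsv` and, with a backbone,
#'   `constructs.fasta`, `<name>.gb` files and `primers.tsv`.
#' @param species_prefix Optional species filter applied when `catalogue` is
#'   a path.
#' @param sparams,dparams Parameter objects (echoed into the JSON report).
#' @param min_flank,tm_target Primer-design parameters.
#' @param on_error `"stop"` (default) fails if any family cannot be designed;
#'   `"keep"` records failures in the summary and continues.
#' @return Invisibly, a list of class `"mim_design_run"`: `catalogue`,
#'   `partitions`, `mimics`, `capture`, `off_target`, `constructs`,
#'   `primers`, `summary`, `failures`.
#' @export
run_design_pipeline <- function(catalogue, bb = NULL, out_dir = NULL,
                                species_prefix = NULL,
                                sparams = scoring_params(),
                                dparams = design_params(),
                                min_flank = 20L, tm_target = 55,
                                on_error = c("stop", "keep")) {
  on_error <- match.arg(on_error)
  if (is.character(catalogue)) {
    catalogue <- parse_mirna_fasta(catalogue, species_prefix = species_prefix)
  }
  if (nrow(catalogue) == 0L) stop("empty catalogue")
  fams <- group_by_family(catalogue)
  partitions <- list()
  mimics <- list()
  part_rows <- list()
  failures <- list()
  for (fam in names(fams)) {
    groups <- tryCatch(partition_for_mimics(fams[[fam]], sparams, dparams),
                       error = function(e) conditionMessage(e))
    if (is.character(groups)) {
      failures[[fam]] <- groups
      next
    }
    partitions[[fam]] <- groups
    whole <- length(groups) == 1L
    for (k in seq_along(groups)) {
      sub <- groups[[k]]
      nm <- name_mimic(fam, sub$variant, whole_family = whole)
      mimic <- design_mimic_site(sub, sparams, dparams, name = nm)
      mimics[[nm]] <- mimic
      part_rows[[length(part_rows) + 1L]] <- data.frame(
        family = fam, subgroup = k, mimic_name = nm,
        member_id = sub$id, stringsAsFactors = FALSE)
    }
  }
  if (length(mimics) == 0L) {
    stop("no mimics designed; failures: ",
         paste(names(failures), unlist(failures), collapse = "; "))
  }
  cm <- capture_matrix(unname(mimics), catalogue, sparams)
  off <- off_target_captures(cm)
  constructs <- list(); primers <- list()
  if (!is.null(bb)) {
    for (nm in names(mimics)) {
      pr <- design_mutagenesis_primers(bb, mimics[[nm]], min_flank, tm_target)
      constructs[[nm]] <- pr$construct
      primers[[nm]] <- pr[c("mutagenic", "outer")]
    }
  }
  summary <- list(
    n_mirnas = nrow(catalogue),
    n_families = length(fams),
    n_subgroups = sum(vapply(partitions, length, integer(1))),
    n_mimics = length(mimics),
    n_off_target_captures = nrow(off),
    n_failed_families = length(failures))
  run <- structure(list(catalogue = catalogue, partitions = partitions,
                        mimics = mimics, capture = cm, off_target = off,
                        constructs = constructs, primers = primers,
                        summary = summary, failures = failures,
                        sparams = sparams, dparams = dparams),
                   class = "mim_design_run")
  if (!is.null(out_dir)) .write_run_outputs(run, out_dir)
  if (length(failures) && on_error == "stop") {
    stop("design failed for famil(ies) ",
         paste(names(failures), collapse = ", "), ": ",
         paste(unlist(failures), collapse = "; "))
  }
  invisible(run)
}

.write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sites <- vapply(run$mimics, function(m) m$site, character(1))
  write_dna_fasta(sites, file.path(out_dir, "mimics.fasta"))
  write_capture_tsv(run$capture, file.path(out_dir, "capture_matrix.tsv"))
  part <- do.call(rbind, lapply(names(run$partitions), function(fam) {
    groups <- run$partitions[[fam]]
    do.call(rbind, lapply(seq_along(groups), function(k) {
      data.frame(family = fam, subgroup = k, member_id = groups[[k]]$id,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(part, file.path(out_dir, "partition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- list(
    parameters = list(scoring = unclass(run$sparams),
                      design = unclass(run$dparams)[c("bulge_length",
                                                      "bulge_replaces_position",
                                                      "homopolymer_max")]),
    mimics = lapply(run$mimics, function(m) {
      list(name = m$name, site = m$site, bulge = m$bulge,
           bulge_interval = m$bulge_interval, sources = m$sources,
           status = m$status,
           n_rejected_bulge_candidates = nrow(m$rejections),
           rejected_bulge_candidates = m$rejections)
    }),
    summary = run$summary,
    failures = run$failures)
  jsonlite::write_json(report, file.path(out_dir, "design_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  sm <- run$summary
  utils::write.table(
    data.frame(key = names(sm), value = unlist(sm)),
    file.path(out_dir, "summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (length(run$constructs)) {
    cs <- vapply(run$constructs, function(x) x$sequence, character(1))
    write_dna_fasta(cs, file.path(out_dir, "constructs.fasta"))
    prows <- list()
    for (nm in names(run$constructs)) {
      write_construct_genbank(run$constructs[[nm]], run$primers[[nm]],
                              file.path(out_dir, paste0(nm, ".gb")))
      prows[[nm]] <- utils::read.delim(
        write_primer_tsv(run$primers[[nm]], nm,
                         tmp <- tempfile(fileext = ".tsv")))
      unlink(tmp)
    }
    utils::write.table(do.call(rbind, c(prows, make.row.names = FALSE)),
                       file.path(out_dir, "primers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.mim_design_run <- function(x, ...) {
  s <- x$summary
  cat("<mim_design_run>\n")
  cat(sprintf("  miRNAs: %d in %d families -> %d subgroups, %d mimics\n",
              s$n_mirnas, s$n_families, s$n_subgroups, s$n_mimics))
  cat(sprintf("  off-target captures: %d; failed families: %d\n",
              s$n_off_target_captures, s$n_failed_families))
  if (length(x$constructs)) {
    cat(sprintf("  constructs + primer pairs: %d\n", length(x$constructs)))
  }
  invisible(x)
}
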