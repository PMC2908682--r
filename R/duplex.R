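# miRNA:site duplex model.
#
# The duplex is the antiparallel pairing of a mature miRNA (RNA, 5'->3') with
# a decoy site (DNA, 5'->3').  The alignment family is global and end-to-end
# with at most one contiguous internal loop in which r site bases and
# m in {0,1} miRNA bases are unpaired (r > m), plus an optional unpaired run
# at the site 5' terminus (which faces the miRNA 3' end; used by consensus
# sites covering 3'-shorter family members).  Site-side unpaired bases are
# "site_bulge" columns; a looped-out miRNA base is a "mirna_loop" column.
# This is exactly the geometry of an IPS1-style mimic: the site partner of one
# central miRNA position is replaced by a 3-nt bulge, so cleavage opposite
# miRNA positions 10-11 is impossible while seed-side pairing is intact.

.PAIR_LOOKUP <- c(AT = "wc", UA = "wc", GC = "wc", CG = "wc",
                  GT = "wobble", UG = "wobble")

#' Scoring parameters for duplex evaluation
#'
#' Penalties follow the common plant target-prediction convention: mismatches
#' cost 1, G:U wobbles 0.5, unpaired site bases 1 per nt, and any column whose
#' (nearest) miRNA position falls in the core region 2-13 is doubled.
#'
#' @param mismatch_penalty,wobble_penalty,bulge_penalty_per_nt Per-column
#'   penalties (score units, all >= 0).
#' @param core_region 1-based miRNA position interval weighted by
#'   `core_weight`.
#' @param core_weight Multiplier applied inside `core_region`.
#' @param central_window miRNA position interval that must hold the bulge of a
#'   functional mimic (and must be bulge-free for a cleavable site).
#' @param cleavage_site_positions Adjacent miRNA positions flanking the
#'   scissile bond of RISC-guided cleavage.
#' @param max_site_bulge Maximum tolerated site minus miRNA length difference.
#' @param cleavable_max_score Total-score ceiling for a cleavable site.
#' @param capture_max_noncentral_score Ceiling on the score outside bulge
#'   columns for a capturing site.
#' @param capture_min_bulge Minimum central bulge run (nt) required for
#'   capture.
#' @param capture_5prime_region miRNA positions that must be fully paired
#'   (Watson-Crick or wobble) for capture.
#' @return An object of class `"scoring_params"`.
#' @export
scoring_params <- function(mismatch_penalty = 1.0,
                           wobble_penalty = 0.5,
                           bulge_penalty_per_nt = 1.0,
                           core_region = c(2L, 13L),
                           core_weight = 2.0,
                           central_window = c(9L, 12L),
                           cleavage_site_positions = c(10L, 11L),
                           max_site_bulge = 5L,
                           cleavable_max_score = 4.0,
                           capture_max_noncentral_score = 3.0,
                           capture_min_bulge = 3L,
                           capture_5prime_region = c(2L, 9L)) {
  p <- list(mismatch_penalty = mismatch_penalty,
            wobble_penalty = wobble_penalty,
            bulge_penalty_per_nt = bulge_penalty_per_nt,
            core_region = as.integer(core_region),
            core_weight = core_weight,
            central_window = as.integer(central_window),
            cleavage_site_positions = as.integer(cleavage_site_positions),
            max_site_bulge = as.integer(max_site_bulge),
            cleavable_max_score = cleavable_max_score,
            capture_max_noncentral_score = capture_max_noncentral_score,
            capture_min_bulge = as.integer(capture_min_bulge),
            capture_5prime_region = as.integer(capture_5prime_region))
  stopifnot(p$mismatch_penalty >= 0, p$wobble_penalty >= 0,
            p$bulge_penalty_per_nt >= 0, p$core_weight >= 1,
            length(p$core_region) == 2L, p$core_region[1] <= p$core_region[2],
            length(p$central_window) == 2L,
            p$central_window[1] <= p$central_window[2],
            length(p$cleavage_site_positions) == 2L,
            p$cleavage_site_positions[2] == p$cleavage_site_positions[1] + 1L,
            p$max_site_bulge >= 1L, p$capture_min_bulge >= 1L)
  structure(p, class = "scoring_params")
}

#' Classify a single miRNA:site base pair
#'
#' Watson-Crick pairs (miRNA:site) are A:T, U:A, G:C and C:G; G:T and U:G are
#' G:U wobbles (T stands in for U on the DNA site); everything else is a
#' mismatch.
#'
#' @param mirna_base RNA residue(s), 5'->3' strand of the miRNA.
#' @param site_base DNA residue(s) of the site.
#' @return Character vector in `c("wc", "wobble", "mismatch")`.
#' @export
classify_pair <- function(mirna_base, site_base) {
  m <- to_rna(mirna_base)
  s <- to_dna(site_base)
  if (any(!m %in% .RNA_BASES)) {
    stop("invalid miRNA residue: ", paste(unique(m[!m %in% .RNA_BASES]), collapse = ","))
  }
  if (any(!s %in% .DNA_BASES)) {
    stop("invalid site residue: ", paste(unique(s[!s %in% .DNA_BASES]), collapse = ","))
  }
  st <- unname(.PAIR_LOOKUP[paste0(m, s)])
  st[is.na(st)] <- "mismatch"
  st
}

# fast per-layout score used during alignment search (no data.frame built)
.layout_score <- function(mm, ss, g, r, m, e, p) {
  Lm <- length(mm); Ls <- length(ss)
  if (r == 0L) {
    mi <- seq_len(Lm); si <- Ls - mi + 1L
  } else {
    mi <- c(seq_len(g), if (g + m < Lm) (g + m + 1L):Lm)
    si <- c(if (g > 0L) Ls - seq_len(g) + 1L,
            if (g + m < Lm) Ls - r + m + 1L - ((g + m + 1L):Lm))
  }
  st <- unname(.PAIR_LOOKUP[paste0(mm[mi], ss[si])])
  st[is.na(st)] <- "mismatch"
  pen <- numeric(length(st))
  pen[st == "wobble"] <- p$wobble_penalty
  pen[st == "mismatch"] <- p$mismatch_penalty
  w <- ifelse(mi >= p$core_region[1] & mi <= p$core_region[2], p$core_weight, 1)
  total <- sum(pen * w)
  if (r > 0L) {
    fl <- c(if (g >= 1L) g, if (g + 1L <= Lm) g + 1L)
    wr <- if (any(fl >= p$core_region[1] & fl <= p$core_region[2])) p$core_weight else 1
    total <- total + r * p$bulge_penalty_per_nt * wr
  }
  if (e > 0L) {
    we <- if (Lm >= p$core_region[1] && Lm <= p$core_region[2]) p$core_weight else 1
    total <- total + e * p$bulge_penalty_per_nt * we
  }
  list(total = total, n_mismatch = sum(st == "mismatch"))
}

.build_columns <- function(mm, ss, g, r, m, e) {
  Lm <- length(mm); Ls <- length(ss)
  add <- function(mp, sp, state) {
    data.frame(mirna_pos = mp, site_pos = sp,
               mirna_base = ifelse(is.na(mp), NA_character_, mm[ifelse(is.na(mp), 1L, mp)]),
               site_base = ifelse(is.na(sp), NA_character_, ss[ifelse(is.na(sp), 1L, sp)]),
               state = state, stringsAsFactors = FALSE)
  }
  pieces <- list()
  if (r == 0L) {
    mi <- seq_len(Lm); si <- Ls - mi + 1L
    pieces[[1]] <- add(mi, si, classify_pair(mm[mi], ss[si]))
  } else {
    if (g > 0L) {
      mi <- seq_len(g); si <- Ls - mi + 1L
      pieces[[length(pieces) + 1L]] <- add(mi, si, classify_pair(mm[mi], ss[si]))
    }
    run <- (Ls - g):(Ls - g - r + 1L)
    pieces[[length(pieces) + 1L]] <- add(rep(NA_integer_, r), run,
                                         rep("site_bulge", r))
    if (m > 0L) {
      lp <- (g + 1L):(g + m)
      pieces[[length(pieces) + 1L]] <- add(lp, rep(NA_integer_, m),
                                           rep("mirna_loop", m))
    }
    if (g + m < Lm) {
      mi <- (g + m + 1L):Lm
      si <- Ls - r + m + 1L - mi
      pieces[[length(pieces) + 1L]] <- add(mi, si, classify_pair(mm[mi], ss[si]))
    }
  }
  if (e > 0L) {
    pieces[[length(pieces) + 1L]] <- add(rep(NA_integer_, e), e:1L,
                                         rep("site_bulge", e))
  }
  do.call(rbind, pieces)
}

.seq_of <- function(x) {
  if (is.data.frame(x)) x$sequence[1] else if (is.list(x)) x$sequence else x
}
.id_of <- function(x) {
  if (is.data.frame(x) && "id" %in% names(x)) x$id[1]
  else if (is.list(x) && !is.null(x$id)) x$id
  else NA_character_
}

#' Align a miRNA against a candidate decoy site
#'
#' Finds the minimum-score global alignment in the single-loop family (see the
#' package vignette for the exact family and tie rules).  Ties are broken by
#' fewest mismatch columns, then smallest site-terminal unpaired run, then the
#' smallest miRNA gap index (leftmost bulge), then the smaller number of
#' looped-out miRNA bases.
#'
#' @param mirna Mature miRNA: a catalogue row, a list with `$sequence`, or a
#'   character RNA sequence.
#' @param site Candidate site, DNA, 5'->3'.
#' @param params A [scoring_params()] object.
#' @return An object of class `"duplex_alignment"` with a `columns`
#'   data.frame (`mirna_pos`, `site_pos`, `mirna_base`, `site_base`, `state`),
#'   the chosen `layout`, the internal `bulge_interval` (0-based half-open
#'   site coordinates, or `NULL`), and `unpaired_mirna` positions.
#' @export
align_duplex <- function(mirna, site, params = scoring_params()) {
  id <- .id_of(mirna)
  mirna <- normalize_sequence(.seq_of(mirna), "RNA", what = "miRNA")
  site <- normalize_sequence(site, "DNA", what = "site")
  Lm <- nchar(mirna); Ls <- nchar(site)
  d <- Ls - Lm
  if (d < 0L) stop("site shorter than miRNA is not supported")
  if (d > params$max_site_bulge) {
    stop("site exceeds miRNA length by ", d, " nt (max_site_bulge = ",
         params$max_site_bulge, ")")
  }
  mm <- strsplit(mirna, "")[[1]]
  ss <- strsplit(site, "")[[1]]
  if (d == 0L) {
    layouts <- list(list(g = NA_integer_, r = 0L, m = 0L, e = 0L))
  } else {
    layouts <- list()
    for (m in 0:1) {
      for (e in 0:(d - 1L)) {
        r <- d - e + m
        for (g in 0:(Lm - m)) {
          if (g + m == Lm && e > 0L) next
          layouts[[length(layouts) + 1L]] <- list(g = g, r = r, m = m, e = e)
        }
      }
    }
  }
  sc <- vapply(layouts, function(l) {
    s <- .layout_score(mm, ss, l$g, l$r, l$m, l$e, params)
    c(s$total, s$n_mismatch)
  }, numeric(2))
  g_key <- vapply(layouts, function(l) if (is.na(l$g)) -1L else l$g, integer(1))
  e_key <- vapply(layouts, function(l) l$e, integer(1))
  m_key <- vapply(layouts, function(l) l$m, integer(1))
  best <- order(sc[1, ], sc[2, ], e_key, g_key, m_key)[1]
  l <- layouts[[best]]
  cols <- .build_columns(mm, ss, if (is.na(l$g)) 0L else l$g, l$r, l$m, l$e)
  structure(list(
    columns = cols,
    mirna = mirna, site = site, mirna_id = id,
    mirna_len = Lm, site_len = Ls,
    layout = l,
    bulge_interval = if (l$r > 0L) c(Ls - l$g - l$r, Ls - l$g) else NULL,
    unpaired_mirna = if (l$m > 0L) (l$g + 1L):(l$g + l$m) else integer(0)
  ), class = "duplex_alignment")
}

# maximal runs of site-side unpaired columns, with nearest flanking miRNA
# positions (NA at an open end)
.bulge_runs <- function(cols) {
  is_b <- cols$state == "site_bulge"
  if (!any(is_b)) return(list())
  rl <- rle(is_b)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- list()
  mp <- cols$mirna_pos
  for (k in which(rl$values)) {
    s <- starts[k]; e <- ends[k]
    before <- mp[seq_len(s - 1L)]
    after <- if (e < nrow(cols)) mp[(e + 1L):nrow(cols)] else integer(0)
    prev <- if (any(!is.na(before))) max(before, na.rm = TRUE) else NA_integer_
    nxt <- if (any(!is.na(after))) min(after, na.rm = TRUE) else NA_integer_
    runs[[length(runs) + 1L]] <- list(start = s, end = e, len = e - s + 1L,
                                      prev = prev, nxt = nxt)
  }
  runs
}

#' Score a duplex alignment
#'
#' Per column: Watson-Crick 0, wobble `wobble_penalty`, mismatch
#' `mismatch_penalty`, site-side unpaired base `bulge_penalty_per_nt`;
#' columns whose miRNA position (or, for site-side bulges, whose nearest
#' flanking miRNA position) lies in the core region are multiplied by the core
#' weight.  Looped-out miRNA bases carry no separate charge: their cost is the
#' widened site-side run.
#'
#' @param aln A `"duplex_alignment"`.
#' @param params A [scoring_params()] object.
#' @return An object of class `"duplex_score"`: `total`, `per_column`,
#'   `bulge_length` (number of site-side unpaired columns) and `bulge_between`
#'   (paired miRNA positions flanking the internal loop, or `NULL`).
#' @export
score_duplex <- function(aln, params = scoring_params()) {
  cols <- aln$columns
  n <- nrow(cols)
  pen <- numeric(n)
  pen[cols$state == "wobble"] <- params$wobble_penalty
  pen[cols$state == "mismatch"] <- params$mismatch_penalty
  pen[cols$state == "site_bulge"] <- params$bulge_penalty_per_nt
  w <- rep(1, n)
  in_core <- function(p) !is.na(p) & p >= params$core_region[1] & p <= params$core_region[2]
  paired <- !is.na(cols$mirna_pos)
  w[paired & in_core(cols$mirna_pos)] <- params$core_weight
  for (run in .bulge_runs(cols)) {
    if (in_core(run$prev) || in_core(run$nxt)) {
      w[run$start:run$end] <- params$core_weight
    }
  }
  per_column <- pen * w
  l <- aln$layout
  bulge_between <- NULL
  if (l$r > 0L) {
    bulge_between <- c(if (l$g >= 1L) l$g else NA_integer_,
                       if (l$g + l$m + 1L <= aln$mirna_len) l$g + l$m + 1L else NA_integer_)
  }
  structure(list(total = sum(per_column), per_column = per_column,
                 bulge_length = sum(cols$state == "site_bulge"),
                 bulge_between = bulge_between),
            class = "duplex_score")
}

#' Score outside the bulge columns
#'
#' Sum of per-column penalties over paired columns only (site-side bulge runs
#' and looped-out miRNA bases excluded).  This is the quantity bounded by
#' `capture_max_noncentral_score` in the capture predicate.
#'
#' @inheritParams score_duplex
#' @return Numeric scalar.
#' @export
noncentral_score <- function(aln, params = scoring_params()) {
  sc <- score_duplex(aln, params)
  keep <- !aln$columns$state %in% c("site_bulge", "mirna_loop")
  sum(sc$per_column[keep])
}

#' Is the site predicted to be cleaved by the miRNA-loaded RISC?
#'
#' A site is called cleavable when (a) no site-side bulge interrupts the
#' central window, (b) at most one non-Watson-Crick column sits at miRNA
#' positions 9-11 (the scissile bond region), and (c) the total score does not
#' exceed `cleavable_max_score`.
#'
#' @param aln A `"duplex_alignment"`.
#' @param score Optional precomputed [score_duplex()] result.
#' @param params A [scoring_params()] object.
#' @return Logical scalar.
#' @export
is_cleavable <- function(aln, score = NULL, params = scoring_params()) {
  if (is.null(score)) score <- score_duplex(aln, params)
  w <- params$central_window
  for (run in .bulge_runs(aln$columns)) {
    a <- if (is.na(run$prev)) 0L else run$prev
    b <- if (is.na(run$nxt)) aln$mirna_len + 1L else run$nxt
    if (a < w[2] && b > w[1]) return(FALSE)
  }
  cp <- params$cleavage_site_positions
  region <- (cp[1] - 1L):cp[2]
  cols <- aln$columns
  nonwc <- sum(!is.na(cols$mirna_pos) & cols$mirna_pos %in% region &
                 cols$state != "wc")
  # a looped-out position inside the region counts as non-WC via state above
  if (nonwc > 1L) return(FALSE)
  score$total <= params$cleavable_max_score
}

#' Is the site predicted to capture (sequester) the miRNA-loaded RISC?
#'
#' A site captures when (a) a site-side bulge run of at least
#' `capture_min_bulge` nt sits inside the central window (both flanking paired
#' miRNA positions within the window), (b) miRNA positions 2-9 are all paired
#' by Watson-Crick or wobble pairs, and (c) the score outside the bulge
#' columns does not exceed `capture_max_noncentral_score`.
#'
#' @inheritParams is_cleavable
#' @return Logical scalar.
#' @export
is_capturing <- function(aln, score = NULL, params = scoring_params()) {
  if (is.null(score)) score <- score_duplex(aln, params)
  w <- params$central_window
  central <- FALSE
  for (run in .bulge_runs(aln$columns)) {
    if (run$len >= params$capture_min_bulge &&
        !is.na(run$prev) && !is.na(run$nxt) &&
        run$prev >= w[1] && run$nxt <= w[2]) {
      central <- TRUE
      break
    }
  }
  if (!central) return(FALSE)
  r5 <- params$capture_5prime_region
  cols <- aln$columns
  seed <- !is.na(cols$mirna_pos) & cols$mirna_pos >= r5[1] & cols$mirna_pos <= r5[2]
  if (any(!cols$state[seed] %in% c("wc", "wobble"))) return(FALSE)
  keep <- !cols$state %in% c("site_bulge", "mirna_loop")
  sum(score$per_column[keep]) <= params$capture_max_noncentral_score
}

#' Text diagram of a duplex
#'
#' Three lines: site 3'->5', pairing symbols (`|` Watson-Crick, `:` wobble,
#' `.` mismatch, space unpaired), miRNA 5'->3'.
#'
#' @param aln A `"duplex_alignment"`.
#' @return Character vector of three lines.
#' @export
format_duplex <- function(aln) {
  cols <- aln$columns
  sym <- c(wc = "|", wobble = ":", mismatch = ".",
           site_bulge = " ", mirna_loop = " ")[cols$state]
  top <- ifelse(is.na(cols$site_base), "-", cols$site_base)
  bot <- ifelse(is.na(cols$mirna_base), "-", cols$mirna_base)
  c(paste0("3' ", paste(top, collapse = ""), " 5'  site"),
    paste0("   ", paste(sym, collapse = ""), ""),
    paste0("5' ", paste(bot, collapse = ""), " 3'  miRNA"))
}

#' @export
print.duplex_alignment <- function(x, ...) {
  id <- if (is.na(x$mirna_id)) "" else paste0(" (", x$mirna_id, ")")
  cat(sprintf("<duplex_alignment>%s %d-nt miRNA vs %d-nt site\n",
              id, x$mirna_len, x$site_len))
  cat(format_duplex(x), sep = "\n")
  invisible(x)
}

#' Alignment columns as a data.frame
#'
#' @param aln A `"duplex_alignment"`.
#' @return The `columns` data.frame (one row per alignment column).
#' @export
alignment_columns <- function(aln) aln$columns
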