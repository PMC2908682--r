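# Independent brute-force reference for the duplex aligner: enumerates every
# legal layout of the single-loop alignment family by explicit pairing-map
# construction and scores it from first principles.  Kept deliberately
# separate from the package's vectorized search path.

oracle_pair_pen <- function(m, s, p) {
  key <- paste0(m, s)
  if (key %in% c("AT", "UA", "GC", "CG")) return(c(0, 0))
  if (key %in% c("GT", "UG")) return(c(p$wobble_penalty, 0))
  c(p$mismatch_penalty, 1)
}

oracle_layout_score <- function(mm, ss, g, m, e, p) {
  Lm <- length(mm); Ls <- length(ss)
  d <- Ls - Lm
  r <- d - e + m
  in_core <- function(q) q >= p$core_region[1] && q <= p$core_region[2]
  tot <- 0; nmis <- 0L
  for (i in seq_len(Lm)) {
    if (r > 0 && i > g && i <= g + m) next   # looped-out miRNA base
    sp <- if (r == 0 || i <= g) Ls - i + 1 else Ls - r + m + 1 - i
    pp <- oracle_pair_pen(mm[i], ss[sp], p)
    tot <- tot + pp[1] * (if (in_core(i)) p$core_weight else 1)
    nmis <- nmis + pp[2]
  }
  if (r > 0) {
    fl <- c(if (g >= 1) g, if (g + 1 <= Lm) g + 1)
    wr <- if (any(vapply(fl, in_core, logical(1)))) p$core_weight else 1
    tot <- tot + r * p$bulge_penalty_per_nt * wr
  }
  if (e > 0) {
    tot <- tot + e * p$bulge_penalty_per_nt *
      (if (in_core(Lm)) p$core_weight else 1)
  }
  c(tot, nmis)
}

oracle_min_score <- function(mirna, site, p = scoring_params()) {
  mm <- strsplit(toupper(mirna), "")[[1]]
  ss <- strsplit(toupper(site), "")[[1]]
  Lm <- length(mm); Ls <- length(ss)
  d <- Ls - Lm
  stopifnot(d >= 0, d <= p$max_site_bulge)
  if (d == 0) return(oracle_layout_score(mm, ss, 0L, 0L, 0L, p)[1])
  best <- Inf
  for (m in 0:1) {
    for (e in 0:(d - 1)) {
      for (g in 0:(Lm - m)) {
        if (g + m == Lm && e > 0) next
        best <- min(best, oracle_layout_score(mm, ss, g, m, e, p)[1])
      }
    }
  }
  best
}

# all partitions of 1..n into unlabeled nonempty blocks (Bell(n) of them)
set_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}
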