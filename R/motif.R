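# Conserved motif discovery in minichromosome non-coding regions (NCRs).
# Louse minichromosomes share an AT-rich motif upstream and a GC-rich motif
# downstream of the coding region; within a species these motifs are nearly
# identical across minichromosomes. The discovery algorithm is deliberately
# desk-scale and deterministic: k-mer seeding (k = 8) with approximate
# recruitment, then symmetric extension while each new column stays
# conserved. Motif boundaries are therefore defined by the conservation
# threshold, so published motif lengths are matched within tolerance, not
# exactly.

#' AT and GC composition of a nucleotide sequence
#'
#' Ambiguity codes are apportioned fractionally (e.g. `W` contributes fully
#' to AT, `N` contributes half to each), so `AT + GC = 100` always.
#'
#' @param seq Nucleotide sequence (IUPAC).
#' @return Named numeric vector `c(AT = , GC = )` in percent.
#' @export
#' @examples
#' composition("ACGT")   # AT 50, GC 50
composition <- function(seq) {
  seq <- check_dna(seq)
  chars <- strsplit(seq, "")[[1]]
  if (!length(chars)) stop("empty sequence")
  at_w <- vapply(chars, function(c) {
    e <- IUPAC_EXPAND[[c]]
    sum(e %in% c("A", "T")) / length(e)
  }, numeric(1))
  at <- 100 * sum(at_w) / length(chars)
  c(AT = at, GC = 100 - at)
}

# all k-mers of a sequence with 1-based start positions
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  stats::setNames(substring(seq, starts, starts + k - 1L), starts)
}

#' Discover a conserved motif shared across non-coding regions
#'
#' Seeds on the 8-mer shared (exactly) by the largest number of input NCRs,
#' recruits the remaining NCRs by best approximate occurrence, and extends
#' the window outward column by column while the fraction of copies agreeing
#' with the column consensus stays at or above `min_identity`. The window is
#' reported when per-copy identity to the consensus reaches `min_identity`
#' in at least `min_coverage` of the input minichromosomes; otherwise
#' `NULL` (no conserved motif, as for the sea lion louse upstream NCRs).
#'
#' @param ncrs Named character vector of NCR sequences; names are
#'   minichromosome labels.
#' @param position_class `"upstream"` or `"downstream"` of the coding
#'   region (metadata recorded in the report; the two classes are searched
#'   independently).
#' @param min_coverage Minimum fraction of minichromosomes carrying the
#'   motif (default 0.8).
#' @param min_identity Minimum per-copy percent identity to the consensus,
#'   also used as the per-column conservation threshold during extension
#'   (default 70).
#' @param min_length Minimum reportable window length in bp (default 20,
#'   just below the shortest published louse NCR motif of 25 bp): shorter
#'   windows arise by chance among AT-biased random sequences and are not
#'   motifs.
#' @param k Seed k-mer length.
#' @return A list of class `mk_motif_report` (`consensus`, `length`,
#'   `composition_pct`, `rich_class`, `position_class`, `coverage`,
#'   `occurrences` data.frame), or `NULL` when no window qualifies.
#' @export
find_conserved_motif <- function(ncrs, position_class = c("upstream", "downstream"),
                                 min_coverage = 0.8, min_identity = 70,
                                 min_length = 20L, k = 8L) {
  position_class <- match.arg(position_class)
  if (length(ncrs) < 2L) stop("need at least 2 NCR sequences")
  ncrs <- vapply(ncrs, check_dna, character(1))
  ncrs <- ncrs[order(names(ncrs), method = "radix")]  # input-order invariance
  n <- length(ncrs)

  # seed: the exact k-mer present in the most sequences (ties: smallest)
  km_list <- lapply(ncrs, kmers_of, k = k)
  seen <- lapply(km_list, unique)
  pooled <- unlist(seen, use.names = FALSE)
  if (!length(pooled)) return(NULL)
  cov <- table(pooled)
  cov <- cov[order(names(cov), method = "radix")]
  seed <- names(cov)[which.max(cov)]

  # recruit every sequence at its best occurrence of the seed (exact first,
  # else minimum-Hamming window within the mismatch budget)
  budget <- ceiling(k * (1 - min_identity / 100))
  seed_raw <- charToRaw(seed)
  offs <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hit <- which(km_list[[i]] == seed)
    if (length(hit)) { offs[i] <- as.integer(names(km_list[[i]])[hit[1]]); next }
    d <- vapply(km_list[[i]], function(x)
      sum(charToRaw(x) != seed_raw), integer(1))
    if (length(d) && min(d) <= budget) {
      offs[i] <- as.integer(names(km_list[[i]])[which.min(d)])
    }
  }
  rec <- which(!is.na(offs))
  if (length(rec) < 2L) return(NULL)

  lens <- nchar(ncrs)
  raws <- lapply(ncrs, charToRaw)

  # column characters at window-relative position `rel` (0-based from the
  # anchor offset), restricted to copies whose window stays in bounds
  col_chars <- function(offs, rec, rel) {
    pos <- offs[rec] + rel
    ok <- pos >= 1L & pos <= lens[rec]
    list(chars = substring(ncrs[rec][ok], pos[ok], pos[ok]), n_ok = sum(ok))
  }
  col_conserved <- function(offs, rec, rel) {
    cc <- col_chars(offs, rec, rel)
    if (cc$n_ok < max(2L, ceiling(length(rec) / 2))) return(FALSE)
    tab <- table(factor(cc$chars, levels = c("A", "C", "G", "T")))
    max(tab) / cc$n_ok >= min_identity / 100
  }
  # symmetric extension while each new column stays conserved; copies whose
  # window would leave the sequence drop out of that column's vote (a
  # majority of recruited copies must remain in bounds)
  extend_window <- function(offs, rec, width) {
    left <- 0L; right <- 0L
    repeat {
      grew <- FALSE
      if (col_conserved(offs, rec, -(left + 1L))) { left <- left + 1L; grew <- TRUE }
      if (col_conserved(offs, rec, width + right)) { right <- right + 1L; grew <- TRUE }
      if (!grew) break
    }
    c(left, right)
  }
  consensus_window <- function(offs, rec, left, width, right) {
    rels <- seq(-left, width - 1L + right)
    vapply(rels, function(rel) {
      cc <- col_chars(offs, rec, rel)
      tab <- table(factor(cc$chars, levels = c("A", "C", "G", "T")))
      names(tab)[which.max(tab)]
    }, character(1))
  }

  ext <- extend_window(offs, rec, k)
  cons <- paste(consensus_window(offs, rec, ext[1], k, ext[2]), collapse = "")

  # relocation pass: slide the provisional consensus over every NCR and
  # re-anchor each copy at its best (minimum-mismatch) offset. This corrects
  # copies recruited at a chance occurrence of an AT-rich seed in the
  # AT-rich background, whose misplacement would otherwise truncate the
  # window and misreport positions.
  cons_raw <- charToRaw(cons)
  L <- length(cons_raw)
  offs2 <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (lens[i] < L) next
    mism <- vapply(seq_len(lens[i] - L + 1L), function(o)
      sum(raws[[i]][o:(o + L - 1L)] != cons_raw), integer(1))
    offs2[i] <- which.min(mism)
  }
  rec <- which(!is.na(offs2))
  if (length(rec) < 2L) return(NULL)
  ext <- extend_window(offs2, rec, L)
  cons_chars <- consensus_window(offs2, rec, ext[1], L, ext[2])
  cons <- paste(cons_chars, collapse = "")
  if (nchar(cons) < min_length) return(NULL)

  # per-copy identity to the consensus over the full window; positions
  # outside a copy's sequence count as mismatches
  rels <- seq(-ext[1], L - 1L + ext[2])
  ident <- vapply(seq_along(rec), function(ri) {
    pos <- offs2[rec[ri]] + rels
    inb <- pos >= 1L & pos <= lens[rec[ri]]
    chars <- substring(ncrs[rec[ri]], pos[inb], pos[inb])
    100 * sum(chars == cons_chars[inb]) / length(rels)
  }, numeric(1))
  starts <- pmax(offs2[rec] - ext[1], 1L)
  ends <- pmin(offs2[rec] + L - 1L + ext[2], lens[rec])
  pass <- ident >= min_identity
  coverage <- sum(pass) / n
  if (coverage < min_coverage) return(NULL)

  comp <- composition(cons)
  rich <- if (comp["AT"] > 50) "AT" else "GC"
  occ <- data.frame(minichromosome = names(ncrs)[rec], start = starts,
                    end = ends, identity_pct = unname(ident),
                    passes = pass, stringsAsFactors = FALSE)
  rownames(occ) <- NULL
  out <- list(consensus = cons, length = nchar(cons),
              composition_pct = unname(comp[paste0(rich)]),
              rich_class = rich, position_class = position_class,
              coverage = coverage, occurrences = occ,
              params = list(min_coverage = min_coverage,
                            min_identity = min_identity, k = k))
  class(out) <- "mk_motif_report"
  out
}

#' @export
print.mk_motif_report <- function(x, ...) {
  cat(sprintf("<motif> %s-rich (%.1f%%) %d bp, %s, coverage %.2f\n",
              x$rich_class, x$composition_pct, x$length, x$position_class,
              x$coverage))
  cat("  consensus:", x$consensus, "\n")
  invisible(x)
}
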