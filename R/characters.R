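# Minichromosomal characters: the testable units of karyotype structure used
# by the parsimony rule. Two kinds are extracted:
#   * co-membership blocks  - a set of genes resident on one minichromosome,
#     order- and orientation-insensitive (singletons included; pairs are the
#     atomic multi-gene form);
#   * oriented adjacencies  - an ordered, orientation-sensitive pair of
#     consecutive genes.
# Support is ternary per taxon: a character is "missing" (unscorable), never
# "absent", in a taxon whose declared missing genes include any constituent
# base name. Gene matching is paralog-tag sensitive throughout.

gene_key <- function(base, tag) paste0(base, tag)

# Internal: characters observed in one karyotype, as a named list keyed by a
# canonical id. Blocks: "blk:key1+key2" (sorted); adjacencies:
# "adj:tok1>tok2" with "!" orientation markers.
observed_characters <- function(k) {
  out <- list()
  for (mc in k$minichromosomes) {
    g <- mc$genes
    keys <- gene_key(g$base, g$tag)
    # singleton blocks
    for (i in seq_len(nrow(g))) {
      id <- paste0("blk:", keys[i])
      out[[id]] <- list(kind = "block", bases = g$base[i], tags = g$tag[i])
    }
    # pair blocks
    if (nrow(g) >= 2L) {
      for (i in seq_len(nrow(g) - 1L)) {
        for (j in seq(i + 1L, nrow(g))) {
          ord <- order(c(keys[i], keys[j]), method = "radix")
          id <- paste0("blk:", paste(c(keys[i], keys[j])[ord], collapse = "+"))
          out[[id]] <- list(kind = "block",
                            bases = c(g$base[i], g$base[j])[ord],
                            tags = c(g$tag[i], g$tag[j])[ord])
        }
      }
      # oriented adjacencies
      for (i in seq_len(nrow(g) - 1L)) {
        t1 <- format_gene_token(g$base[i], g$tag[i], g$rev[i])
        t2 <- format_gene_token(g$base[i + 1L], g$tag[i + 1L], g$rev[i + 1L])
        id <- paste0("adj:", t1, ">", t2)
        out[[id]] <- list(kind = "adjacency",
                          bases = g$base[c(i, i + 1L)],
                          tags = g$tag[c(i, i + 1L)],
                          revs = g$rev[c(i, i + 1L)])
      }
    }
  }
  out
}

# Internal: ternary score of one character in one karyotype.
score_character <- function(k, ch) {
  if (any(ch$bases %in% k$missing_genes)) return("missing")
  keys <- gene_key(ch$bases, ch$tags)
  if (ch$kind == "block") {
    for (mc in k$minichromosomes) {
      mk <- gene_key(mc$genes$base, mc$genes$tag)
      if (all(keys %in% mk)) return("present")
    }
    return("absent")
  }
  # adjacency: consecutive, in order, with matching orientation flags
  for (mc in k$minichromosomes) {
    g <- mc$genes
    if (nrow(g) < 2L) next
    mk <- gene_key(g$base, g$tag)
    for (i in seq_len(nrow(g) - 1L)) {
      if (mk[i] == keys[1] && mk[i + 1L] == keys[2] &&
          g$rev[i] == ch$revs[1] && g$rev[i + 1L] == ch$revs[2]) {
        return("present")
      }
    }
  }
  "absent"
}

#' Extract minichromosomal characters from a set of karyotypes
#'
#' Enumerates every co-membership block (singletons and pairs) and every
#' oriented adjacency observed in at least one input karyotype, and scores a
#' ternary support value per taxon: `"present"`, `"absent"`, or `"missing"`
#' when a constituent gene is in that taxon's declared missing set (missing
#' data is unscorable, never counted as absence).
#'
#' @param karyotypes List of `mt_karyotype` objects (at least 2).
#' @return An object of class `mk_characters`: a list with one element per
#'   character, each carrying `id`, `kind`, `bases`, `tags`, and `support`
#'   (named character vector over taxa).
#' @export
#' @examples
#' ks <- seal_louse_karyotypes()
#' ch <- extract_characters(ks)
#' ch[["blk:E+cob"]]$support
extract_characters <- function(karyotypes) {
  stopifnot(length(karyotypes) >= 2L)
  taxa <- vapply(karyotypes, function(k) k$taxon, character(1))
  if (anyDuplicated(taxa)) stop("duplicate taxon names among karyotypes")
  all_ch <- list()
  for (k in karyotypes) {
    obs <- observed_characters(k)
    for (id in names(obs)) if (is.null(all_ch[[id]])) all_ch[[id]] <- obs[[id]]
  }
  ids <- sort_c(names(all_ch))
  out <- lapply(ids, function(id) {
    ch <- all_ch[[id]]
    ch$id <- id
    ch$support <- vapply(karyotypes, score_character, character(1), ch = ch)
    names(ch$support) <- taxa
    ch
  })
  names(out) <- ids
  class(out) <- "mk_characters"
  out
}

#' @export
print.mk_characters <- function(x, ...) {
  n_adj <- sum(vapply(x, function(c) c$kind == "adjacency", logical(1)))
  cat(sprintf("<minichromosomal characters> %d total (%d blocks, %d adjacencies) over %d taxa\n",
              length(x), length(x) - n_adj, n_adj,
              length(x[[1]]$support)))
  invisible(x)
}

# Internal: presence counts for one character.
support_counts <- function(ch) {
  s <- ch$support
  c(present = sum(s == "present"), absent = sum(s == "absent"),
    missing = sum(s == "missing"))
}
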