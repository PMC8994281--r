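# Ancestral karyotype inference by the two-clause parsimony rule:
# a minichromosomal character is ancestral to a clade if
#   1) it is present in >=1 ingroup taxon AND in the previously inferred
#      karyotype of the enclosing clade's MRCA (the outgroup karyotype), or
#   2) it is present in every ingroup taxon in which it is scorable, where
#      taxa missing a constituent gene are excluded from the denominator,
#      provided it is scorable in a majority of the ingroup.
# The majority floor on clause 2 prevents a character whose genes are
# identified in a single taxon from being vacuously "present in all":
# without it trnC (identified in one seal louse only) would be inferred
# ancestral, contradicting the unscorable status such genes should keep.
#
# Placement semantics: protein-coding and rRNA (anchor) genes are placed on
# singleton-block support - an anchor observed in the ingroup and the MRCA
# defines a minichromosome even when nothing else can be attached (cox2).
# tRNAs are placed only through multi-gene characters, because a singleton
# says nothing about position or arrangement. Ancestral characters are then
# assembled into maximal consistent minichromosomes (connected components of
# the gene graph), ordered and oriented by the outgroup arrangement where
# available, otherwise by the most frequent ingroup arrangement.

#' Infer the ancestral mitochondrial karyotype of a clade
#'
#' @param ingroup List of `mt_karyotype` objects (the clade's sampled taxa).
#' @param outgroup_mrca The karyotype inferred previously for the MRCA of the
#'   enclosing clade (e.g. the packaged sucking-louse MRCA), or `NULL` when
#'   no outgroup information exists (clause 1 then never fires).
#' @param clade Name for the inferred ancestor (tree node label).
#' @return An object of classes `mt_ancestral_karyotype` and `mt_karyotype`
#'   with extra fields: `unplaced_genes` (base names observed in the ingroup
#'   or outgroup whose position could not be inferred) and `rule_trace`
#'   (data.frame recording, per character, which clause fired and the
#'   support counts).
#' @export
#' @examples
#' anc <- infer_ancestral(seal_louse_karyotypes(),
#'                        louse_karyotype("MRCA_sucking_lice"),
#'                        clade = "Echinophthiriidae_MRCA")
#' length(anc$minichromosomes)   # >= 13
#' anc$unplaced_genes
infer_ancestral <- function(ingroup, outgroup_mrca = NULL,
                            clade = "ancestor") {
  stopifnot(length(ingroup) >= 1L)
  n <- length(ingroup)
  pool <- ingroup
  if (!is.null(outgroup_mrca)) pool <- c(pool, list(outgroup_mrca))
  chars <- if (length(pool) >= 2L) extract_characters(pool) else {
    stop("need at least two karyotypes (ingroup plus outgroup) to extract characters")
  }
  taxa <- vapply(ingroup, function(k) k$taxon, character(1))
  og_taxon <- if (is.null(outgroup_mrca)) NULL else outgroup_mrca$taxon

  trace <- lapply(chars, function(ch) {
    s <- ch$support[taxa]
    n_present <- sum(s == "present")
    n_scorable <- sum(s != "missing")
    og_present <- !is.null(og_taxon) &&
      identical(unname(ch$support[og_taxon]), "present")
    clause1 <- n_present >= 1L && og_present
    clause2 <- n_scorable > n / 2 && n_present >= 1L &&
      n_present == n_scorable
    singleton <- length(ch$bases) == 1L
    placement_informative <- !singleton || is_anchor_gene(ch$bases[1])
    data.frame(id = ch$id, kind = ch$kind,
               genes = paste(gene_key(ch$bases, ch$tags), collapse = "+"),
               n_present = n_present, n_scorable = n_scorable,
               outgroup_present = og_present,
               clause = if (clause1) 1L else if (clause2) 2L else NA_integer_,
               ancestral = (clause1 || clause2) && placement_informative,
               stringsAsFactors = FALSE)
  })
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL

  anc_ids <- trace$id[trace$ancestral]
  anc_chars <- chars[anc_ids]

  # gene graph: nodes are (base, tag) keys of ancestral characters
  nodes <- unique(do.call(rbind, lapply(anc_chars, function(ch)
    data.frame(base = ch$bases, tag = ch$tags, key = gene_key(ch$bases, ch$tags),
               stringsAsFactors = FALSE))))
  edges <- do.call(rbind, lapply(anc_chars, function(ch) {
    if (length(ch$bases) < 2L) return(NULL)
    k <- gene_key(ch$bases, ch$tags)
    data.frame(a = k[1], b = k[2], stringsAsFactors = FALSE)
  }))
  comp <- components_of(nodes$key, edges)

  mcs <- lapply(comp, function(keys) {
    arr <- arrange_component(keys, outgroup_mrca, ingroup)
    minichromosome(do.call(rbind, lapply(seq_along(arr$keys), function(i) {
      row <- nodes[match(arr$keys[i], nodes$key), ]
      mt_gene(row$base, row$tag, arr$rev[i])
    })))
  })
  # deterministic order
  mcs <- mcs[order(vapply(mcs, mc_label, character(1)), method = "radix")]

  placed_bases <- unique(nodes$base)
  observed_bases <- unique(unlist(lapply(pool, function(k)
    c(karyotype_genes(k)$base, k$missing_genes))))
  unplaced <- sort_c(setdiff(observed_bases, placed_bases))
  missing <- sort_c(setdiff(mt_gene_table()$base, placed_bases))

  k <- karyotype(clade, mcs, missing_genes = missing,
                 source = "inferred by two-clause parsimony")
  k$unplaced_genes <- unplaced
  k$rule_trace <- trace
  class(k) <- c("mt_ancestral_karyotype", class(k))
  k
}

# Connected components over character keys.
components_of <- function(keys, edges) {
  parent <- stats::setNames(keys, keys)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (!is.null(edges)) for (i in seq_len(nrow(edges))) {
    ra <- find(edges$a[i]); rb <- find(edges$b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(keys, find, character(1))
  unname(split(keys, roots))
}

# Order and orient a component's genes. Sources are tried in priority order:
# the outgroup MRCA first, then each ingroup karyotype; the first source
# holding every component gene on one minichromosome supplies the induced
# order and orientation. If several sources qualify, the most frequent
# induced arrangement wins (outgroup breaks ties). Fallback for components
# never seen complete on one minichromosome: the source covering the largest
# subset supplies the backbone and the remaining genes are appended in key
# order (surfaced via attribute "partial_order").
arrange_component <- function(keys, outgroup_mrca, ingroup) {
  sources <- c(if (!is.null(outgroup_mrca)) list(outgroup_mrca), ingroup)
  induced <- list()
  for (k in sources) {
    for (mc in k$minichromosomes) {
      g <- mc$genes
      mk <- gene_key(g$base, g$tag)
      if (all(keys %in% mk)) {
        sel <- mk %in% keys
        induced[[length(induced) + 1L]] <-
          list(keys = mk[sel], rev = g$rev[sel])
      }
    }
  }
  if (length(induced)) {
    sig <- vapply(induced, function(x)
      paste(paste0(x$keys, ifelse(x$rev, "!", "")), collapse = "-"),
      character(1))
    # most frequent induced arrangement; ties resolved by source priority
    counts <- table(factor(sig, levels = unique(sig)))
    best <- names(counts)[which.max(counts)]
    return(induced[[match(best, sig)]])
  }
  # partial coverage fallback
  best_cover <- NULL; best_n <- -1L
  for (k in sources) {
    for (mc in k$minichromosomes) {
      mk <- gene_key(mc$genes$base, mc$genes$tag)
      nn <- sum(keys %in% mk)
      if (nn > best_n) {
        sel <- mk %in% keys
        best_cover <- list(keys = mk[sel], rev = mc$genes$rev[sel])
        best_n <- nn
      }
    }
  }
  rest <- sort_c(setdiff(keys, best_cover$keys))
  out <- list(keys = c(best_cover$keys, rest),
              rev = c(best_cover$rev, rep(FALSE, length(rest))))
  attr(out, "partial_order") <- TRUE
  out
}

#' @export
print.mt_ancestral_karyotype <- function(x, ...) {
  NextMethod()
  if (length(x$unplaced_genes))
    cat("  unplaced:", paste(x$unplaced_genes, collapse = " "), "\n")
  cat(sprintf("  rule trace: %d characters evaluated, %d ancestral\n",
              nrow(x$rule_trace), sum(x$rule_trace$ancestral)))
  invisible(x)
}
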