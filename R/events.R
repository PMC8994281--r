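# Classification of karyotype differences along a branch as minichromosome
# split, merger, tRNA translocation, or gene loss, and tallying of events
# over a phylogeny.
#
# Events are anchored on protein-coding and rRNA genes: tRNAs move too often
# to define chromosome identity, so their relocations are reported as
# translocations. Genes are matched across karyotypes by base name (paralog
# tags collapse; paralog emergence is reported as a duplication note, not an
# event). Two deliberate asymmetries implement the published counting logic:
#   * an anchor gene unidentified in the descendant never vetoes a split -
#     an ancestral minichromosome with one identified anchor and one anchor
#     in the descendant's missing set is counted as split (this is what makes
#     the count a lower bound, "at least" so many splits);
#   * a descendant minichromosome carrying only tRNAs, all of which derive
#     from a single ancestral minichromosome whose anchor persists elsewhere,
#     is a fission product and counts toward that minichromosome's split
#     (the cox3-A -> cox3 + A case); a tRNA-only minichromosome of mixed
#     ancestral origin is a set of translocations instead.

#' Detect rearrangement events between an ancestor and a descendant
#'
#' @param ancestor,descendant `mt_karyotype` objects (the ancestor may be an
#'   `mt_ancestral_karyotype`; its unplaced genes count as missing).
#' @param branch Branch identifier recorded on each event.
#' @return A data.frame of class `mk_events` with columns `branch`, `kind`
#'   (`"split"`, `"merger"`, `"translocation"`, `"loss"`),
#'   `ancestral_mcs`, `descendant_mcs` (minichromosome labels, `;`-joined)
#'   and `anchor_genes`. A k-way split counts as ONE split of the ancestral
#'   minichromosome. Attributes `duplications` and `novel_genes` carry
#'   warning-level notes.
#' @export
#' @examples
#' ev <- detect_events(louse_karyotype("P_pubis"),
#'                     louse_karyotype("P_gorillae"), branch = "to_gorillae")
#' subset(ev, kind == "split")
detect_events <- function(ancestor, descendant, branch = "branch") {
  a_tab <- karyotype_genes(ancestor)
  d_tab <- karyotype_genes(descendant)
  if (!length(intersect(a_tab$base[is_anchor_gene(a_tab$base)],
                        d_tab$base[is_anchor_gene(d_tab$base)]))) {
    stop("ancestor and descendant share no anchor (protein/rRNA) gene")
  }
  a_mc_of <- function(b) a_tab$mc[match(b, a_tab$base)]
  d_mc_of <- function(b) d_tab$mc[match(b, d_tab$base)]
  a_lab <- vapply(ancestor$minichromosomes, mc_label, character(1))
  d_lab <- vapply(descendant$minichromosomes, mc_label, character(1))

  ev <- list()
  add <- function(kind, amc, dmc, anchors) {
    ev[[length(ev) + 1L]] <<- data.frame(
      branch = branch, kind = kind,
      ancestral_mcs = paste(a_lab[sort(unique(amc))], collapse = ";"),
      descendant_mcs = paste(d_lab[sort(unique(dmc))], collapse = ";"),
      anchor_genes = paste(sort_c(unique(anchors)), collapse = ";"),
      stringsAsFactors = FALSE)
  }

  # --- fission products: tRNA-only descendant minichromosomes wholly derived
  # from one ancestral minichromosome
  fission_src <- integer(0)   # ancestral mc index -> has fission product
  fission_dmc <- list()
  for (j in seq_along(descendant$minichromosomes)) {
    g <- descendant$minichromosomes[[j]]$genes
    if (any(is_anchor_gene(g$base))) next
    src <- unique(a_mc_of(g$base))
    if (length(src) == 1L && !anyNA(src)) {
      fission_src <- c(fission_src, src)
      fission_dmc[[as.character(src)]] <-
        c(fission_dmc[[as.character(src)]], j)
    }
  }

  # --- splits, one per ancestral minichromosome
  split_amcs <- integer(0)
  for (i in seq_along(ancestor$minichromosomes)) {
    g <- ancestor$minichromosomes[[i]]$genes
    anchors <- unique(g$base[is_anchor_gene(g$base)])
    id_anch <- anchors[anchors %in% d_tab$base]
    unid_anch <- anchors[anchors %in% descendant$missing_genes]
    dmcs <- unique(d_mc_of(id_anch))
    fission_here <- (i %in% fission_src) && length(id_anch) >= 1L
    split_by_anchor <- length(dmcs) >= 2L ||
      (length(dmcs) >= 1L && length(unid_anch) >= 1L)
    if (split_by_anchor || fission_here) {
      extra <- fission_dmc[[as.character(i)]]
      add("split", i, c(dmcs, extra), c(id_anch, unid_anch))
      split_amcs <- c(split_amcs, i)
    }
  }

  # --- mergers, one per descendant minichromosome
  merger_dmcs <- integer(0)
  for (j in seq_along(descendant$minichromosomes)) {
    g <- descendant$minichromosomes[[j]]$genes
    anchors <- unique(g$base[is_anchor_gene(g$base)])
    id_anch <- anchors[anchors %in% a_tab$base]
    amcs <- unique(a_mc_of(id_anch))
    if (length(amcs) >= 2L) {
      add("merger", amcs, j, id_anch)
      merger_dmcs <- c(merger_dmcs, j)
    }
  }

  # --- losses: ancestral genes absent from the descendant and NOT declared
  # missing there
  lost <- setdiff(a_tab$base, c(d_tab$base, descendant$missing_genes))
  for (b in lost) add("loss", a_mc_of(b), integer(0), b)

  # --- tRNA translocations: anchor context changed, not already explained by
  # a split/merger/fission involving the tRNA's minichromosome
  shared_trnas <- intersect(a_tab$base[a_tab$category == "tRNA"],
                            d_tab$base[d_tab$category == "tRNA"])
  ctx <- function(tab, mc_i) {
    b <- tab$base[tab$mc == mc_i]
    paste(sort_c(unique(b[is_anchor_gene(b)])), collapse = "+")
  }
  fission_js <- unlist(fission_dmc, use.names = FALSE)
  for (t in shared_trnas) {
    ai <- a_mc_of(t); dj <- d_mc_of(t)
    if (ai %in% split_amcs || dj %in% merger_dmcs ||
        dj %in% fission_js) next
    if (!identical(ctx(a_tab, ai), ctx(d_tab, dj))) {
      add("translocation", ai, dj, t)
    }
  }

  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(branch = character(), kind = character(),
               ancestral_mcs = character(), descendant_mcs = character(),
               anchor_genes = character(), stringsAsFactors = FALSE)
  out <- out[order(out$kind, out$anchor_genes, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL

  # duplication / novel-gene notes (warning level, never events)
  dup <- intersect(d_tab$base[duplicated(d_tab$base)], a_tab$base)
  novel <- setdiff(d_tab$base, c(a_tab$base, ancestor$missing_genes))
  attr(out, "duplications") <- sort_c(unique(dup))
  attr(out, "novel_genes") <- sort_c(unique(novel))
  class(out) <- c("mk_events", class(out))
  out
}

#' Tally rearrangement events over a phylogeny
#'
#' Runs [detect_events()] on every branch connecting two karyotyped nodes:
#' each node with a karyotype is compared against its nearest karyotyped
#' ancestor (intervening unkaryotyped internal nodes are passed through, so
#' events on an unsampled stem accrue to the compound branch). Events on a
#' stem shared by several descendants are thereby counted once.
#'
#' @param tree A rooted `phylo` object with labelled internal nodes.
#' @param node_karyotypes Named list of `mt_karyotype` objects; names must be
#'   tip or node labels of `tree`.
#' @param families Optional named character vector mapping node labels to
#'   family names (events are assigned to the descendant node's family).
#' @return An `mk_event_tally` list: `events` (row-bound [detect_events()]
#'   output, ordered by branch), `by_kind`, `by_branch`, `by_family`
#'   (tables), and `total`.
#' @export
tally_events <- function(tree, node_karyotypes, families = NULL) {
  stopifnot(inherits(tree, "phylo"))
  labels <- c(tree$tip.label, tree$node.label)
  unknown <- setdiff(names(node_karyotypes), labels)
  if (length(unknown)) {
    stop("configuration error: node(s) not in tree: ",
         paste(unknown, collapse = ", "))
  }
  n_tip <- length(tree$tip.label)
  parent_of <- function(node) {
    i <- match(node, tree$edge[, 2])
    if (is.na(i)) NA_integer_ else tree$edge[i, 1]
  }
  label_of <- function(node) {
    if (node <= n_tip) tree$tip.label[node] else tree$node.label[node - n_tip]
  }
  karyotyped <- names(node_karyotypes)

  all_ev <- list()
  for (nm in sort_c(karyotyped)) {
    node <- match(nm, labels)
    anc <- parent_of(node)
    while (!is.na(anc) && !(label_of(anc) %in% karyotyped)) {
      anc <- parent_of(anc)
    }
    if (is.na(anc)) next  # no karyotyped ancestor (e.g. the root)
    anc_nm <- label_of(anc)
    br <- paste0(anc_nm, "->", nm)
    all_ev[[br]] <- detect_events(node_karyotypes[[anc_nm]],
                                  node_karyotypes[[nm]], branch = br)
  }
  events <- do.call(rbind, c(lapply(unname(all_ev), as.data.frame),
                             list(stringsAsFactors = FALSE)))
  if (is.null(events)) {
    events <- data.frame(branch = character(), kind = character(),
                         ancestral_mcs = character(),
                         descendant_mcs = character(),
                         anchor_genes = character(),
                         stringsAsFactors = FALSE)
  }
  events <- events[order(events$branch, events$kind, events$anchor_genes, method = "radix"), ,
                   drop = FALSE]
  rownames(events) <- NULL

  kinds <- c("split", "merger", "translocation", "loss")
  by_kind <- table(factor(events$kind, levels = kinds))
  by_branch <- if (nrow(events))
    table(events$branch, factor(events$kind, levels = kinds)) else
      table(character(), factor(character(), levels = kinds))
  by_family <- NULL
  if (!is.null(families) && nrow(events)) {
    desc <- sub("^.*->", "", events$branch)
    fam <- unname(families[desc])
    fam[is.na(fam)] <- "unassigned"
    by_family <- table(fam, factor(events$kind, levels = kinds))
  }
  out <- list(events = events, by_kind = by_kind, by_branch = by_branch,
              by_family = by_family, total = nrow(events))
  class(out) <- "mk_event_tally"
  out
}

#' @export
print.mk_event_tally <- function(x, ...) {
  cat("<event tally>", x$total, "events\n")
  print(x$by_kind)
  if (!is.null(x$by_family)) { cat("by family:\n"); print(x$by_family) }
  invisible(x)
}

#' Write an event table as TSV
#'
#' @param events An `mk_events` or the `events` element of a tally.
#' @param path Output file.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
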