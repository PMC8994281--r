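# Synthetic data with the statistical structure the analysis assumes, plus
# ground-truth logs, so every stage is testable without downloads.
#
# Karyotypes evolve along a rooted tree by split / merger / tRNA
# translocation / loss events drawn Poisson per branch (rates are expected
# events per branch; branch lengths drive only sequence divergence).
# Sequences evolve by a single-parameter substitution model: the number of
# substitution events per site is Poisson(rate * branch length) and each
# event redraws the base uniformly from the four nucleotides, so two
# sequences separated by total path length d match with probability
# exp(-2d) + (1 - exp(-2d)) / 4 -- the closed form the identity tests check.
# NCRs are random AT-biased backgrounds with a motif planted at a known
# offset and per-copy noise. All draws come from R's RNG; pass `seed` for
# byte-identical outputs.

#' Simulation configuration
#'
#' @param tree A rooted `phylo` tree with branch lengths and unique labels.
#' @param root_karyotype `mt_karyotype` at the root.
#' @param split_rate,merge_rate,translocation_rate,loss_rate Expected events
#'   per branch (Poisson means). Defaults reflect the published regime:
#'   splits several times more frequent than mergers.
#' @param substitution_rate Substitutions per site per unit branch length.
#' @param motif_spec Optional list (`length`, `at`, `noise`) describing the
#'   planted NCR motif; see [simulate_ncrs()] for defaults.
#' @param seed Integer RNG seed recorded in the ground truth.
#' @return A `mk_sim_config` list.
#' @export
simulation_config <- function(tree, root_karyotype, split_rate = 0.3,
                              merge_rate = 0.08, translocation_rate = 0.2,
                              loss_rate = 0, substitution_rate = 0.05,
                              motif_spec = NULL, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), inherits(root_karyotype, "mt_karyotype"),
            split_rate >= 0, merge_rate >= 0, translocation_rate >= 0,
            loss_rate >= 0, substitution_rate >= 0)
  if (merge_rate > 0 && length(root_karyotype$minichromosomes) < 2L) {
    stop("config error: merge_rate > 0 requires a root karyotype with >= 2 minichromosomes")
  }
  if (is.null(tree$node.label)) {
    tree$node.label <- paste0("n", seq_len(tree$Nnode))
  }
  structure(list(tree = tree, root_karyotype = root_karyotype,
                 split_rate = split_rate, merge_rate = merge_rate,
                 translocation_rate = translocation_rate,
                 loss_rate = loss_rate,
                 substitution_rate = substitution_rate,
                 motif_spec = motif_spec, seed = as.integer(seed)),
            class = "mk_sim_config")
}

# apply one event in place; returns list(karyotype, before, after) or NULL
# when no eligible target exists. `detectable` restricts splits/merges to
# anchor-preserving configurations so that detect_events can recover the
# log exactly on clean histories.
apply_random_event <- function(k, kind, detectable = TRUE) {
  mcs <- k$minichromosomes
  lab <- vapply(mcs, mc_label, character(1))
  if (kind == "split") {
    n_anch <- vapply(mcs, function(m) sum(is_anchor_gene(m$genes$base)),
                     integer(1))
    len <- vapply(mcs, function(m) nrow(m$genes), integer(1))
    eligible <- if (detectable) which(n_anch >= 2L) else which(len >= 2L)
    if (!length(eligible)) return(NULL)
    i <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    g <- mcs[[i]]$genes
    anchor_pos <- which(is_anchor_gene(g$base))
    cuts <- seq_len(nrow(g) - 1L)
    if (detectable || length(anchor_pos) >= 2L) {
      # keep >= 1 anchor on each side when possible
      ok <- cuts[cuts >= min(anchor_pos) & cuts < max(anchor_pos)]
      if (length(ok)) cuts <- ok
    }
    cut <- if (length(cuts) == 1L) cuts else sample(cuts, 1L)
    parts <- list(minichromosome(g[seq_len(cut), , drop = FALSE]),
                  minichromosome(g[-seq_len(cut), , drop = FALSE]))
    k$minichromosomes <- c(mcs[-i], parts)
    return(list(karyotype = k, before = lab[i],
                after = vapply(parts, mc_label, character(1)),
                anchors = sort_c(unique(g$base[is_anchor_gene(g$base)]))))
  }
  if (kind == "merge") {
    n_anch <- vapply(mcs, function(m) sum(is_anchor_gene(m$genes$base)),
                     integer(1))
    eligible <- if (detectable) which(n_anch >= 1L) else seq_along(mcs)
    if (length(eligible) < 2L) return(NULL)
    ij <- sample(eligible, 2L)
    merged <- minichromosome(rbind(mcs[[ij[1]]]$genes, mcs[[ij[2]]]$genes))
    k$minichromosomes <- c(mcs[-ij], list(merged))
    mg <- merged$genes
    return(list(karyotype = k, before = lab[ij], after = mc_label(merged),
                anchors = sort_c(unique(mg$base[is_anchor_gene(mg$base)]))))
  }
  if (kind == "translocation") {
    if (length(mcs) < 2L) return(NULL)
    tr <- which(vapply(mcs, function(m) any(m$genes$category == "tRNA"),
                       logical(1)))
    # only move tRNAs that leave a non-empty source minichromosome behind
    tr <- tr[vapply(mcs[tr], function(m) nrow(m$genes) >= 2L, logical(1))]
    if (!length(tr)) return(NULL)
    i <- if (length(tr) == 1L) tr else sample(tr, 1L)
    g <- mcs[[i]]$genes
    pos <- which(g$category == "tRNA")
    p <- if (length(pos) == 1L) pos else sample(pos, 1L)
    gene <- g[p, , drop = FALSE]
    src <- minichromosome(g[-p, , drop = FALSE])
    j <- if (length(mcs) == 2L) setdiff(seq_along(mcs), i) else
      sample(setdiff(seq_along(mcs), i), 1L)
    dg <- mcs[[j]]$genes
    at <- sample.int(nrow(dg) + 1L, 1L)
    dst <- minichromosome(rbind(
      if (at > 1L) dg[seq_len(at - 1L), , drop = FALSE],
      gene,
      if (at <= nrow(dg)) dg[seq(at, nrow(dg)), , drop = FALSE]))
    k$minichromosomes[[i]] <- src
    k$minichromosomes[[j]] <- dst
    return(list(karyotype = k, before = lab[c(i, j)],
                after = c(mc_label(src), mc_label(dst)),
                anchors = gene$base))
  }
  if (kind == "loss") {
    tab <- karyotype_genes(k)
    r <- sample.int(nrow(tab), 1L)
    i <- tab$mc[r]
    g <- mcs[[i]]$genes
    p <- tab$pos[r] + 1L
    if (nrow(g) == 1L) {
      if (length(mcs) == 1L) return(NULL)
      k$minichromosomes <- mcs[-i]
      return(list(karyotype = k, before = lab[i], after = character(0),
                  anchors = tab$base[r]))
    }
    newmc <- minichromosome(g[-p, , drop = FALSE])
    k$minichromosomes[[i]] <- newmc
    return(list(karyotype = k, before = lab[i], after = mc_label(newmc),
                anchors = tab$base[r]))
  }
  stop("unknown event kind: ", kind)
}

#' Simulate karyotype evolution with a ground-truth event log
#'
#' @param cfg A [simulation_config()].
#' @param detectable Restrict splits and mergers to anchor-preserving
#'   configurations (each split part keeps an anchor; only anchor-bearing
#'   minichromosomes merge) so clean histories are exactly recoverable by
#'   [detect_events()].
#' @return A list of class `mk_sim_result`: `tips` (named karyotype list),
#'   `node_karyotypes` (every node incl. internals), `events` (data.frame
#'   `branch`, `kind`, `before`, `after`, `anchors`), `config`.
#'   The replay invariant holds: applying `events` to the root reproduces
#'   every tip exactly (see [replay_events()]).
#' @export
simulate_karyotypes <- function(cfg, detectable = TRUE) {
  stopifnot(inherits(cfg, "mk_sim_config"))
  set.seed(cfg$seed)
  tree <- cfg$tree
  n_tip <- length(tree$tip.label)
  labels <- c(tree$tip.label, tree$node.label)
  root <- n_tip + 1L
  karyo <- list()
  karyo[[labels[root]]] <- cfg$root_karyotype
  rates <- c(split = cfg$split_rate, merge = cfg$merge_rate,
             translocation = cfg$translocation_rate, loss = cfg$loss_rate)
  log <- list()

  # preorder over edges
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(ord))) {
    parent <- labels[ord[e, 1]]; child <- labels[ord[e, 2]]
    k <- karyo[[parent]]
    k$taxon <- child
    branch <- paste0(parent, "->", child)
    n_ev <- stats::rpois(length(rates), rates)
    kinds <- rep(names(rates), n_ev)
    if (length(kinds) > 1L) kinds <- sample(kinds)
    for (kind in kinds) {
      res <- apply_random_event(k, kind, detectable = detectable)
      if (is.null(res)) next
      k <- res$karyotype
      log[[length(log) + 1L]] <- data.frame(
        branch = branch, kind = kind,
        before = paste(res$before, collapse = ";"),
        after = paste(res$after, collapse = ";"),
        anchors = paste(res$anchors, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    validate_karyotype(k)
    karyo[[child]] <- k
  }
  events <- if (length(log)) do.call(rbind, log) else
    data.frame(branch = character(), kind = character(),
               before = character(), after = character(),
               anchors = character(), stringsAsFactors = FALSE)
  out <- list(tips = karyo[tree$tip.label],
              node_karyotypes = karyo,
              events = events, config = cfg)
  class(out) <- "mk_sim_result"
  out
}

#' Replay a ground-truth event log
#'
#' Applies the structured event log of [simulate_karyotypes()] to the root
#' karyotype, branch by branch down the tree, and returns the reconstructed
#' karyotype at each node. Used to verify the replay invariant:
#' reconstruction equals simulation output exactly.
#'
#' @param cfg The `mk_sim_config` used for simulation.
#' @param events The `events` data.frame from the simulation result.
#' @return Named list of karyotypes (all nodes).
#' @export
replay_events <- function(cfg, events) {
  tree <- cfg$tree
  labels <- c(tree$tip.label, tree$node.label)
  karyo <- list()
  karyo[[labels[length(tree$tip.label) + 1L]]] <- cfg$root_karyotype
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(ord))) {
    parent <- labels[ord[e, 1]]; child <- labels[ord[e, 2]]
    k <- karyo[[parent]]
    k$taxon <- child
    branch <- paste0(parent, "->", child)
    ev <- events[events$branch == branch, , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      before <- strsplit(ev$before[r], ";", fixed = TRUE)[[1]]
      after <- strsplit(ev$after[r], ";", fixed = TRUE)[[1]]
      after <- after[nzchar(after)]
      lab <- vapply(k$minichromosomes, mc_label, character(1))
      idx <- match(before, lab)
      if (anyNA(idx)) stop("replay failed: minichromosome not found: ",
                           paste(before[is.na(idx)], collapse = ", "))
      k$minichromosomes <- c(k$minichromosomes[-idx],
                             lapply(after, function(s)
                               minichromosome(strsplit(s, "-", fixed = TRUE)[[1]])))
    }
    karyo[[child]] <- k
  }
  karyo
}

random_dna <- function(n, p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate gene sequences along the tree
#'
#' @param cfg A [simulation_config()]; `substitution_rate` and the tree's
#'   branch lengths set the divergence.
#' @param genes Named character vector of root sequences, or a named integer
#'   vector of lengths to generate AT-biased root sequences
#'   (A/T 0.35 each, C/G 0.15 each, the typical louse mt composition).
#' @return A list: `root` (named vector), `tips` (list of named vectors per
#'   tip taxon).
#' @export
simulate_sequences <- function(cfg, genes) {
  stopifnot(inherits(cfg, "mk_sim_config"))
  set.seed(cfg$seed + 1L)
  if (is.numeric(genes)) {
    genes <- vapply(genes, function(n)
      random_dna(n, c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)), character(1))
  }
  tree <- cfg$tree
  labels <- c(tree$tip.label, tree$node.label)
  seqs <- list()
  seqs[[labels[length(tree$tip.label) + 1L]]] <- genes
  ord <- ape::reorder.phylo(tree, "cladewise")
  bl <- ord$edge.length
  for (e in seq_len(nrow(ord$edge))) {
    parent <- labels[ord$edge[e, 1]]; child <- labels[ord$edge[e, 2]]
    d <- cfg$substitution_rate * bl[e]
    seqs[[child]] <- vapply(seqs[[parent]], function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- stats::rpois(length(ch), d) > 0L
      if (any(hit)) ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit),
                                      replace = TRUE)
      paste(ch, collapse = "")
    }, character(1))
  }
  list(root = genes, tips = seqs[tree$tip.label])
}

#' Simulate non-coding regions with a planted motif
#'
#' Generates `n` AT-biased random NCRs and plants a shared motif at a random
#' offset in each, with independent per-site noise per copy, returning the
#' ground truth needed by the planted-motif recovery tests.
#'
#' @param n Number of NCRs (minichromosomes).
#' @param ncr_length NCR length in bp (published NCR windows are
#'   200-320 bp; default 300).
#' @param motif_length Planted motif length (default 56 bp, a published
#'   AT-rich motif length).
#' @param motif_at AT fraction of the motif (default 0.85).
#' @param noise Per-site mutation probability per copy (default 0.05).
#' @param background_at AT fraction of the background (default 0.70).
#' @return A list: `ncrs` (named character vector `mc01`...), `motif` (true
#'   planted consensus), `starts` (1-based plant offsets).
#' @export
simulate_ncrs <- function(n = 11, ncr_length = 300, motif_length = 56,
                          motif_at = 0.85, noise = 0.05,
                          background_at = 0.70) {
  stopifnot(n >= 2, motif_length < ncr_length)
  pm <- c(A = motif_at / 2, C = (1 - motif_at) / 2,
          G = (1 - motif_at) / 2, T = motif_at / 2)
  pb <- c(A = background_at / 2, C = (1 - background_at) / 2,
          G = (1 - background_at) / 2, T = background_at / 2)
  motif <- random_dna(motif_length, pm)
  starts <- sample.int(ncr_length - motif_length + 1L, n, replace = TRUE)
  ncrs <- vapply(seq_len(n), function(i) {
    bg <- strsplit(random_dna(ncr_length, pb), "")[[1]]
    copy <- strsplit(motif, "")[[1]]
    hit <- stats::runif(motif_length) < noise
    if (any(hit)) copy[hit] <- sample(c("A", "C", "G", "T"), sum(hit),
                                      replace = TRUE)
    bg[seq(starts[i], starts[i] + motif_length - 1L)] <- copy
    paste(bg, collapse = "")
  }, character(1))
  names(ncrs) <- sprintf("mc%02d", seq_len(n))
  list(ncrs = ncrs, motif = motif, starts = starts)
}

#' Random valid karyotype (property-test generator)
#'
#' Draws a random subset of the 37-gene vocabulary, partitions it into
#' minichromosomes, assigns random orientations, and declares the unused
#' genes missing. Used for parse/write round-trip properties.
#'
#' @param n_genes Number of genes to place (default random 10-37).
#' @param taxon Taxon name.
#' @return An `mt_karyotype`.
#' @export
random_karyotype <- function(n_genes = sample(10:37, 1), taxon = "random") {
  tab <- mt_gene_table()
  pick <- sample(tab$base, n_genes)
  n_mc <- sample.int(max(1L, n_genes %/% 2L), 1L)
  assign <- sort(c(seq_len(n_mc),
                   sample.int(n_mc, max(0L, n_genes - n_mc), replace = TRUE)))
  mcs <- lapply(split(pick, assign), function(bases) {
    rows <- lapply(bases, function(b)
      mt_gene(b, tag = "", rev = stats::runif(1) < 0.15))
    minichromosome(do.call(rbind, rows))
  })
  karyotype(taxon, unname(mcs), missing_genes = setdiff(tab$base, pick),
            source = "simulated")
}
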