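# Pairwise alignment identity with ClustalW-style DNA scoring: IUB matrix
# (+1.9 for an identical unambiguous match, 0 for a mismatch, ambiguity
# codes scored as the mean over their expansions), affine gap penalties with
# open 15 and extend 6.66, a gap of length L costing open + L * extend.
# Identity is identical columns / alignment length * 100; by default the
# denominator covers the full alignment including internal gaps but
# excluding terminal overhangs (dialect switchable, since published percent
# identities rarely state whether gap columns were counted).

IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' IUB-style DNA substitution matrix
#'
#' @param match Score of an identical unambiguous match.
#' @param mismatch Score of a mismatch.
#' @return A 15x15 numeric matrix over the IUPAC alphabet; the score of two
#'   ambiguity codes is the expected score over their expansions.
#' @export
iub_matrix <- function(match = 1.9, mismatch = 0) {
  codes <- names(IUPAC_EXPAND)
  m <- matrix(0, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    ea <- IUPAC_EXPAND[[a]]; eb <- IUPAC_EXPAND[[b]]
    p_match <- length(intersect(ea, eb)) / (length(ea) * length(eb))
    m[a, b] <- match * p_match + mismatch * (1 - p_match)
  }
  m
}

check_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), names(IUPAC_EXPAND))
  if (length(bad)) {
    stop("non-IUPAC character(s) in ", what, ": ",
         paste(bad, collapse = ", "))
  }
  x
}

# Shared identity computation from two gapped strings.
identity_from_alignment <- function(a_aln, b_aln, count_terminal_gaps) {
  ca <- strsplit(a_aln, "")[[1]]; cb <- strsplit(b_aln, "")[[1]]
  len <- length(ca)
  keep <- rep(TRUE, len)
  if (!count_terminal_gaps && len) {
    gap <- ca == "-" | cb == "-"
    lead <- cumsum(!gap) == 0
    trail <- rev(cumsum(rev(!gap)) == 0)
    keep <- !(gap & (lead | trail))
  }
  n_id <- sum(ca == cb & ca != "-" & keep)
  denom <- sum(keep)
  list(identity_pct = if (denom) 100 * n_id / denom else 0,
       n_identical = n_id, columns = denom)
}

#' Global alignment identity of two nucleotide sequences
#'
#' Needleman-Wunsch alignment with affine gaps under the IUB scoring scheme
#' (see [iub_matrix()]); defaults reproduce the ClustalW DNA parameters
#' gap open 15, gap extend 6.66.
#'
#' @param a,b Nucleotide sequences (IUPAC alphabet; case-insensitive).
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @param submat Substitution matrix, by default [iub_matrix()].
#' @param count_terminal_gaps Include terminal overhang columns in the
#'   identity denominator (default `FALSE`; internal gap columns always
#'   count).
#' @return A list of class `mk_alignment`: `score`, `a_aln`, `b_aln`,
#'   `identity_pct`, `n_identical`, `columns`.
#' @export
#' @examples
#' global_identity("ACGT", "ACGA")$identity_pct   # 75
global_identity <- function(a, b, gap_open = 15, gap_extend = 6.66,
                            submat = iub_matrix(),
                            count_terminal_gaps = FALSE) {
  a <- check_dna(a, "a"); b <- check_dna(b, "b")
  al <- .gotoh_align(a, b, submat, gap_open, gap_extend, "global")
  out <- c(al[c("score", "a_aln", "b_aln")],
           identity_from_alignment(al$a_aln, al$b_aln, count_terminal_gaps))
  class(out) <- "mk_alignment"
  out
}

#' @export
print.mk_alignment <- function(x, ...) {
  cat(sprintf("<alignment> score %.2f, identity %.1f%% (%d identical / %d columns)\n",
              x$score, x$identity_pct, x$n_identical, x$columns))
  invisible(x)
}

#' Per-gene identity table between two taxa
#'
#' Computes [global_identity()] for every gene name shared between two
#' sequence sets and summarises the distribution; the mean is the unweighted
#' average of per-gene identities.
#'
#' @param genes_a,genes_b Named character vectors (or named lists) of
#'   nucleotide sequences; names are gene identifiers.
#' @param ... Passed to [global_identity()].
#' @return A list: `table` (data.frame `gene`, `identity_pct`) and `summary`
#'   (`min`, `max`, `mean`).
#' @export
identity_table <- function(genes_a, genes_b, ...) {
  genes_a <- unlist(genes_a); genes_b <- unlist(genes_b)
  shared <- sort_c(intersect(names(genes_a), names(genes_b)))
  if (!length(shared)) stop("no shared gene names between the two sets")
  id <- vapply(shared, function(g)
    global_identity(genes_a[[g]], genes_b[[g]], ...)$identity_pct,
    numeric(1))
  list(table = data.frame(gene = shared, identity_pct = unname(id),
                          stringsAsFactors = FALSE),
       summary = c(min = min(id), max = max(id), mean = mean(id)))
}

#' Rank paralog candidates by cross-taxon identity
#'
#' Given several candidate copies of a gene from one taxon (e.g. two trnW
#' paralogs) and the orthologous sequence from each of several other taxa,
#' ranks the candidates by their mean identity to the orthologs; the
#' top-ranked candidate is labelled the likely original copy.
#'
#' @param candidates Named character vector of candidate sequences.
#' @param orthologs Named character vector of ortholog sequences (one per
#'   taxon).
#' @param ... Passed to [global_identity()].
#' @return A data.frame ordered by decreasing `mean_identity` with columns
#'   `candidate`, `mean_identity`, `min_identity`, `max_identity`,
#'   `likely_original`.
#' @export
classify_paralog <- function(candidates, orthologs, ...) {
  candidates <- unlist(candidates); orthologs <- unlist(orthologs)
  stopifnot(length(candidates) >= 1L, length(orthologs) >= 1L)
  rows <- lapply(names(candidates), function(nm) {
    id <- vapply(orthologs, function(o)
      global_identity(candidates[[nm]], o, ...)$identity_pct, numeric(1))
    data.frame(candidate = nm, mean_identity = mean(id),
               min_identity = min(id), max_identity = max(id),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_identity, out$candidate, method = "radix"), ,
             drop = FALSE]
  out$likely_original <- seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  out
}

#' Scan a non-coding sequence for degenerate gene remnants
#'
#' Aligns a non-coding sequence locally against each full-length reference
#' gene and reports segments passing identity and length thresholds, with
#' 1-based inclusive coordinates on the reference. Degenerate genes are
#' pseudogenized remnants: non-coding stretches retaining partial identity
#' to a functional gene.
#'
#' @param ncs Non-coding nucleotide sequence.
#' @param reference_genes Named character vector of full-length gene
#'   sequences.
#' @param min_identity Minimum percent identity of the local alignment,
#'   in (0, 100].
#' @param min_length Minimum aligned reference-segment length in bp.
#' @param gap_open,gap_extend As in [global_identity()].
#' @param submat Substitution matrix for the local scan. The global IUB
#'   scheme scores mismatches 0, which makes a maximal-segment (local)
#'   alignment unbounded; the local variant therefore defaults to a
#'   symmetric +1.9 / -1.9 scheme, under which segment extension is
#'   profitable only above 50 percent identity.
#' @return A data.frame with columns `gene`, `ref_start`, `ref_end`,
#'   `length`, `identity_pct`, `n_identical`, ordered by decreasing
#'   identity; zero rows when nothing passes.
#' @export
degenerate_scan <- function(ncs, reference_genes, min_identity = 50,
                            min_length = 50, gap_open = 15,
                            gap_extend = 6.66,
                            submat = iub_matrix(mismatch = -1.9)) {
  stopifnot(min_identity > 0, min_identity <= 100, min_length >= 1)
  ncs <- check_dna(ncs, "ncs")
  rows <- lapply(sort_c(names(reference_genes)), function(g) {
    ref <- check_dna(reference_genes[[g]], g)
    al <- .gotoh_align(ncs, ref, submat, gap_open, gap_extend, "local")
    if (!nzchar(al$a_aln)) return(NULL)
    stats <- identity_from_alignment(al$a_aln, al$b_aln, TRUE)
    seg_len <- al$b_end - al$b_start + 1L
    if (stats$identity_pct >= min_identity && seg_len >= min_length) {
      data.frame(gene = g, ref_start = al$b_start, ref_end = al$b_end,
                 length = seg_len, identity_pct = stats$identity_pct,
                 n_identical = stats$n_identical, stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), ref_start = integer(),
                      ref_end = integer(), length = integer(),
                      identity_pct = numeric(), n_identical = integer(),
                      stringsAsFactors = FALSE)
  } else {
    out <- out[order(-out$identity_pct, out$gene, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' character sequences keyed by the first word of each record id.
#'
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
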