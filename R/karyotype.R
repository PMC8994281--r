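# Data model for fragmented mitochondrial genomes: minichromosomes (ordered,
# oriented gene lists with optional flanking non-coding sequence) and
# karyotypes (the set of minichromosomes of one taxon plus its declared
# missing genes), with a plain-text interchange format.
#
# Text format, one file per taxon:
#   #taxon <name>
#   #missing <space-separated base names>
#   #source <free text>            (optional, repeatable)
#   <gene>-<gene>-...              (one minichromosome per line)
# Gene tokens are vocabulary names with an optional paralog tag ([0-9*]) and
# an optional "!" suffix marking reverse transcription orientation, e.g.
#   Q!-nad1!-T*!-W1

#' Construct a minichromosome
#'
#' @param genes A gene table as built by [mt_gene()] rows (`rbind` them), or a
#'   character vector of gene tokens such as `c("Q!", "nad1!", "T*!", "W1")`.
#'   Order is coding order, upstream (AT-motif) end first.
#' @param ncr_upstream,ncr_downstream Optional nucleotide strings flanking the
#'   coding region.
#' @return An object of class `mt_minichromosome` with a deterministic
#'   `label` (hyphen-joined gene tokens).
#' @export
#' @examples
#' minichromosome(c("K", "nad4"))
minichromosome <- function(genes, ncr_upstream = NULL, ncr_downstream = NULL) {
  if (is.character(genes)) {
    rows <- lapply(genes, function(tok) {
      g <- parse_gene_token(tok)
      mt_gene(g$base, g$tag, g$rev)
    })
    genes <- do.call(rbind, rows)
  }
  stopifnot(is.data.frame(genes))
  if (nrow(genes) == 0L) stop("a minichromosome must contain at least one gene")
  mc <- list(genes = genes, ncr_upstream = ncr_upstream,
             ncr_downstream = ncr_downstream)
  class(mc) <- "mt_minichromosome"
  mc
}

#' Canonical label of a minichromosome
#'
#' Hyphen-joined gene tokens in coding order; regenerates deterministically
#' from the gene table, so labels are stable identifiers.
#'
#' @param mc An `mt_minichromosome`.
#' @return A character scalar such as `"Q!-nad1!-T*!-W1"`.
#' @export
mc_label <- function(mc) {
  g <- mc$genes
  paste(format_gene_token(g$base, g$tag, g$rev), collapse = "-")
}

#' @export
print.mt_minichromosome <- function(x, ...) {
  cat("<minichromosome>", mc_label(x), "\n")
  invisible(x)
}

#' Construct a karyotype
#'
#' A karyotype is the full mitochondrial complement of one taxon: which genes
#' sit on which minichromosome, in what order and orientation, together with
#' an explicit set of genes that were *not identified* in that taxon.
#' Missingness is first-class data, not inferred from absence: the parsimony
#' rule and event calling treat a missing gene as unscorable, never as absent.
#'
#' @param taxon Species identifier.
#' @param minichromosomes List of [minichromosome()] objects.
#' @param missing_genes Character vector of base names not identified.
#' @param source Free-text provenance.
#' @return An object of class `mt_karyotype`.
#' @export
karyotype <- function(taxon, minichromosomes, missing_genes = character(),
                      source = "") {
  stopifnot(is.list(minichromosomes))
  k <- list(taxon = taxon, minichromosomes = minichromosomes,
            missing_genes = sort_c(unique(missing_genes)), source = source)
  class(k) <- "mt_karyotype"
  validate_karyotype(k)
  k
}

# Integrity checks: vocabulary membership of missing genes, no duplicated
# (base, tag) across minichromosomes, and missing/present disjointness.
validate_karyotype <- function(k) {
  if (length(k$missing_genes)) mt_gene_category(k$missing_genes)
  g <- karyotype_genes(k)
  key <- paste0(g$base, ":", g$tag)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate gene(s) in karyotype '", k$taxon, "': ",
         paste(sub(":$", "", dup), collapse = ", "), call. = FALSE)
  }
  clash <- intersect(k$missing_genes, g$base)
  if (length(clash)) {
    stop("gene(s) declared missing but present in karyotype '", k$taxon,
         "': ", paste(clash, collapse = ", "), call. = FALSE)
  }
  invisible(k)
}

#' All genes of a karyotype as one table
#'
#' @param k An `mt_karyotype`.
#' @return A data.frame with columns `base`, `tag`, `rev`, `category`,
#'   `mc` (index) and `pos` (0-based position within the minichromosome,
#'   counted from the upstream end).
#' @export
karyotype_genes <- function(k) {
  out <- lapply(seq_along(k$minichromosomes), function(i) {
    g <- k$minichromosomes[[i]]$genes
    g$mc <- i
    g$pos <- seq_len(nrow(g)) - 1L
    g
  })
  do.call(rbind, out)
}

#' Minichromosome labels of a karyotype
#'
#' @param k An `mt_karyotype`.
#' @param sorted Sort labels lexicographically (the canonical order used by
#'   [write_karyotype()]).
#' @return Character vector of labels.
#' @export
karyotype_labels <- function(k, sorted = TRUE) {
  lab <- vapply(k$minichromosomes, mc_label, character(1))
  if (sorted) sort_c(lab) else lab
}

#' @export
print.mt_karyotype <- function(x, ...) {
  cat("<mt karyotype>", x$taxon, "\n")
  cat(sprintf("  %d minichromosomes, %d genes placed, %d declared missing\n",
              length(x$minichromosomes), nrow(karyotype_genes(x)),
              length(x$missing_genes)))
  for (lab in karyotype_labels(x)) cat("  ", lab, "\n", sep = "")
  if (length(x$missing_genes))
    cat("  missing:", paste(x$missing_genes, collapse = " "), "\n")
  invisible(x)
}

#' Parse the karyotype text format
#'
#' @param text A character scalar (possibly multi-line) or character vector of
#'   lines in the karyotype format described in the package vignette.
#' @return An `mt_karyotype`.
#' @seealso [read_karyotype()] to read from a file, [write_karyotype()] for
#'   the inverse operation.
#' @export
#' @examples
#' k <- parse_karyotype("#taxon demo\n#missing nad6\nK-nad4\nE-cob")
#' karyotype_labels(k)
parse_karyotype <- function(text) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  taxon <- ""; missing <- character(); src <- character()
  mcs <- list()
  for (i in seq_along(text)) {
    line <- trimws(text[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, "#taxon")) {
      taxon <- trimws(sub("^#taxon", "", line)); next
    }
    if (startsWith(line, "#missing")) {
      m <- trimws(sub("^#missing", "", line))
      if (nzchar(m)) missing <- c(missing, strsplit(m, "[ \t]+")[[1]])
      next
    }
    if (startsWith(line, "#source")) {
      src <- c(src, trimws(sub("^#source", "", line))); next
    }
    if (startsWith(line, "#")) next  # comment
    toks <- strsplit(line, "-", fixed = TRUE)[[1]]
    if (length(toks) == 0L || any(!nzchar(trimws(toks)))) {
      stop(sprintf("line %d: empty gene token in minichromosome line '%s'",
                   i, line), call. = FALSE)
    }
    genes <- lapply(trimws(toks), function(tok) {
      g <- tryCatch(parse_gene_token(tok),
                    error = function(e) {
                      stop(sprintf("line %d: %s", i, conditionMessage(e)),
                           call. = FALSE)
                    })
      mt_gene(g$base, g$tag, g$rev)
    })
    mcs[[length(mcs) + 1L]] <- minichromosome(do.call(rbind, genes))
  }
  karyotype(taxon, mcs, missing, paste(src, collapse = "; "))
}

#' Read a karyotype file
#'
#' @param path Path to a karyotype-format text file.
#' @return An `mt_karyotype`.
#' @export
read_karyotype <- function(path) {
  parse_karyotype(readLines(path, warn = FALSE))
}

#' Write a karyotype in canonical text form
#'
#' Output is deterministic: header lines followed by one minichromosome per
#' line, sorted lexicographically by label, so that
#' `parse_karyotype(write_karyotype(k))` reproduces `k` up to minichromosome
#' order (the canonical form).
#'
#' @param k An `mt_karyotype`.
#' @param path Optional file path; if `NULL` the text is returned.
#' @return The karyotype text, invisibly when written to a file.
#' @export
write_karyotype <- function(k, path = NULL) {
  lines <- c(paste("#taxon", k$taxon))
  if (length(k$missing_genes)) {
    lines <- c(lines, paste("#missing", paste(k$missing_genes, collapse = " ")))
  }
  if (nzchar(k$source)) lines <- c(lines, paste("#source", k$source))
  lines <- c(lines, karyotype_labels(k, sorted = TRUE))
  text <- paste(lines, collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(text)
}

#' Compare two karyotypes
#'
#' Two karyotypes are equal when the multisets of canonical minichromosome
#' labels are identical. Declared missing genes are compared separately and
#' reported in the difference object, but do not affect equality.
#'
#' @param a,b `mt_karyotype` objects.
#' @return A `karyotype_diff` list: `equal` (logical), `only_a` / `only_b`
#'   (labels private to each karyotype), `missing_only_a` / `missing_only_b`.
#' @export
#' @examples
#' a <- parse_karyotype("#taxon x\nK-nad4")
#' karyotype_equal(a, a)$equal
karyotype_equal <- function(a, b) {
  la <- karyotype_labels(a); lb <- karyotype_labels(b)
  # multiset difference
  only_a <- la[!vapply(seq_along(la), function(i)
    sum(lb == la[i]) >= sum(la[seq_len(i)] == la[i]), logical(1))]
  only_b <- lb[!vapply(seq_along(lb), function(i)
    sum(la == lb[i]) >= sum(lb[seq_len(i)] == lb[i]), logical(1))]
  out <- list(
    equal = length(only_a) == 0L && length(only_b) == 0L,
    only_a = only_a, only_b = only_b,
    missing_only_a = setdiff(a$missing_genes, b$missing_genes),
    missing_only_b = setdiff(b$missing_genes, a$missing_genes),
    taxa = c(a$taxon, b$taxon)
  )
  class(out) <- "karyotype_diff"
  out
}

#' @export
print.karyotype_diff <- function(x, ...) {
  cat(sprintf("<karyotype diff> %s vs %s: %s\n", x$taxa[1], x$taxa[2],
              if (x$equal) "identical" else "different"))
  if (length(x$only_a)) cat("  only in", x$taxa[1], ":",
                            paste(x$only_a, collapse = ", "), "\n")
  if (length(x$only_b)) cat("  only in", x$taxa[2], ":",
                            paste(x$only_b, collapse = ", "), "\n")
  if (length(x$missing_only_a) || length(x$missing_only_b))
    cat("  missing-gene sets differ\n")
  invisible(x)
}
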