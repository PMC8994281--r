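# The 37-gene mitochondrial vocabulary of bilaterian animals, as used for
# sucking-louse minichromosomes: 13 protein-coding genes, 2 rRNA genes and
# 22 tRNA genes (single-letter amino-acid codes, with L1/L2 and S1/S2
# disambiguated).

MT_PROTEINS <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
                 "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
MT_RRNAS    <- c("rrnS", "rrnL")
MT_TRNAS    <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
                 "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y")

#' The 37-gene mitochondrial vocabulary
#'
#' Returns the fixed vocabulary of mitochondrial gene names used throughout
#' the package, with the category of each gene. `base_name`s outside this
#' vocabulary are rejected by all constructors and parsers.
#'
#' @return A data.frame with columns `base` and `category`
#'   (`"protein"`, `"rRNA"` or `"tRNA"`).
#' @export
#' @examples
#' tab <- mt_gene_table()
#' nrow(tab)                 # 37
#' tab$category[tab$base == "cox1"]
mt_gene_table <- function() {
  data.frame(
    base = c(MT_PROTEINS, MT_RRNAS, MT_TRNAS),
    category = c(rep("protein", length(MT_PROTEINS)),
                 rep("rRNA", length(MT_RRNAS)),
                 rep("tRNA", length(MT_TRNAS))),
    stringsAsFactors = FALSE
  )
}

#' Category of a mitochondrial gene
#'
#' @param base Character vector of base names from the 37-gene vocabulary.
#' @return Character vector: `"protein"`, `"rRNA"` or `"tRNA"`.
#' @export
mt_gene_category <- function(base) {
  tab <- mt_gene_table()
  i <- match(base, tab$base)
  if (anyNA(i)) {
    stop("unknown mitochondrial gene name(s): ",
         paste(unique(base[is.na(i)]), collapse = ", "))
  }
  tab$category[i]
}

#' Is a gene an anchor (protein-coding or rRNA) gene?
#'
#' Anchor genes define minichromosome identity across karyotypes for
#' rearrangement-event calling; tRNAs are too mobile and are tracked as
#' translocations instead.
#'
#' @param base Character vector of base names.
#' @return Logical vector.
#' @export
is_anchor_gene <- function(base) {
  mt_gene_category(base) %in% c("protein", "rRNA")
}

# Locale-independent (C-ordering) sort, used everywhere ordering feeds a
# canonical identifier or deterministic output.
sort_c <- function(x) sort(x, method = "radix")

# Parse one gene token of the karyotype text format into base / paralog tag /
# orientation. Grammar: <vocab-name><tag?>"!"? where tag is [0-9*]+ and "!"
# marks reverse orientation relative to the minichromosome's non-coding
# region. Longest vocabulary match wins so that "L1" is trnL1, never trnL
# with tag "1", and "nad4L" is never nad4 with a tag.
parse_gene_token <- function(token) {
  raw <- token
  rev <- grepl("!$", token)
  token <- sub("!$", "", token)
  if (!nzchar(token)) stop("empty gene token", call. = FALSE)
  vocab <- c(MT_PROTEINS, MT_RRNAS, MT_TRNAS)
  vocab <- vocab[order(-nchar(vocab))]
  base <- NA_character_; tag <- ""
  for (v in vocab) {
    if (token == v) { base <- v; break }
    if (startsWith(token, v)) {
      rest <- substring(token, nchar(v) + 1L)
      if (grepl("^[0-9*]+$", rest)) { base <- v; tag <- rest; break }
    }
  }
  if (is.na(base)) {
    stop(sprintf("unknown gene token '%s'", raw), call. = FALSE)
  }
  list(base = base, tag = tag, rev = rev)
}

# Render a gene row back to its token.
format_gene_token <- function(base, tag = "", rev = FALSE) {
  paste0(base, tag, ifelse(rev, "!", ""))
}

#' Construct a mitochondrial gene
#'
#' @param base Base name from the 37-gene vocabulary.
#' @param tag Optional paralog/variant tag (digits or `"*"`), kept verbatim;
#'   e.g. the two trnW copies of *Lepidophthirus macrorhini* are `"W"` with
#'   tags `"1"` and `"2"`, and the variant trnT is `"T"` with tag `"*"`.
#' @param rev Logical; `TRUE` if the gene is transcribed in the opposite
#'   orientation to the minichromosome's non-coding region.
#' @return A one-row data.frame with columns `base`, `tag`, `rev`,
#'   `category`.
#' @export
#' @examples
#' mt_gene("nad1", rev = TRUE)
#' mt_gene("W", tag = "2")
mt_gene <- function(base, tag = "", rev = FALSE) {
  stopifnot(is.character(base), length(base) == 1L)
  if (!grepl("^([0-9*]*)$", tag)) {
    stop("paralog tag must consist of digits or '*': ", tag)
  }
  data.frame(base = base, tag = tag, rev = isTRUE(rev),
             category = mt_gene_category(base), stringsAsFactors = FALSE)
}
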