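# Minimal GenBank flat-file reader for annotated minichromosome records:
# enough to recover the coding-region gene order/orientation from the
# feature table and the flanking non-coding sequence from ORIGIN. No
# de-novo annotation is performed; only the deposited feature table is
# trusted.

# map common mt gene annotations to the 37-gene vocabulary
GENBANK_NAME_MAP <- c(
  ATP6 = "atp6", ATP8 = "atp8", COB = "cob", CYTB = "cob",
  COX1 = "cox1", COI = "cox1", COX2 = "cox2", COII = "cox2",
  COX3 = "cox3", COIII = "cox3",
  ND1 = "nad1", ND2 = "nad2", ND3 = "nad3", ND4 = "nad4",
  ND4L = "nad4L", ND5 = "nad5", ND6 = "nad6",
  NAD1 = "nad1", NAD2 = "nad2", NAD3 = "nad3", NAD4 = "nad4",
  NAD4L = "nad4L", NAD5 = "nad5", NAD6 = "nad6",
  RRNS = "rrnS", RRNL = "rrnL", `12S` = "rrnS", `16S` = "rrnL",
  `S-RRNA` = "rrnS", `L-RRNA` = "rrnL"
)
AA3_TO_1 <- c(Ala = "A", Cys = "C", Asp = "D", Glu = "E", Phe = "F",
              Gly = "G", His = "H", Ile = "I", Lys = "K", Met = "M",
              Asn = "N", Pro = "P", Gln = "Q", Arg = "R", Thr = "T",
              Val = "V", Trp = "W", Tyr = "Y")

normalise_gb_gene <- function(name) {
  up <- toupper(name)
  if (up %in% names(GENBANK_NAME_MAP)) return(GENBANK_NAME_MAP[[up]])
  if (name %in% mt_gene_table()$base) return(name)
  # tRNA styles: trnW, trnW1, trnL1, tRNA-Trp, trnL(uag)
  m <- regmatches(name, regexec("^trn([A-Z])([0-9*]?)", name))[[1]]
  if (length(m)) {
    base <- m[2]; tag <- m[3]
    if (base %in% c("L", "S") && tag %in% c("1", "2")) {
      return(paste0(base, tag))
    }
    return(paste0(base, tag))
  }
  m <- regmatches(up, regexec("^TRNA-([A-Z]{3})", up))[[1]]
  if (length(m) && m[2] %in% toupper(names(AA3_TO_1))) {
    return(AA3_TO_1[[which(toupper(names(AA3_TO_1)) == m[2])]])
  }
  NA_character_
}

#' Read GenBank flat-file records
#'
#' Parses LOCUS/ACCESSION, gene-bearing features (`gene`, `CDS`, `tRNA`,
#' `rRNA` with `/gene=` or `/product=` qualifiers) and the ORIGIN sequence.
#' Handles simple and `complement(a..b)` locations only, which covers
#' single-minichromosome deposits.
#'
#' @param path GenBank flat file (possibly multi-record).
#' @return List of records: `accession`, `sequence`, `features`
#'   (data.frame `type`, `gene`, `start`, `end`, `complement`).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(grepl("^LOCUS", lines)))
  recs <- recs[names(recs) != "0"]
  lapply(unname(recs), parse_genbank_record)
}

parse_genbank_record <- function(lines) {
  acc <- sub("^ACCESSION\\s+", "", grep("^ACCESSION", lines, value = TRUE)[1])
  ori <- grep("^ORIGIN", lines)
  seq <- ""
  if (length(ori)) {
    body <- lines[seq(ori[1] + 1L, length(lines))]
    body <- body[!grepl("^//", body)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  fstart <- grep("^FEATURES", lines)
  feats <- NULL
  if (length(fstart)) {
    fend <- if (length(ori)) ori[1] - 1L else length(lines)
    flines <- lines[seq(fstart[1] + 1L, fend)]
    new_feat <- grepl("^ {5}\\S", flines)
    groups <- split(flines, cumsum(new_feat))
    groups <- groups[names(groups) != "0"]
    feats <- do.call(rbind, lapply(unname(groups), function(g) {
      hdr <- g[1]
      type <- sub("^ +", "", substr(hdr, 1, 21))
      type <- trimws(type)
      loc <- trimws(substr(hdr, 22, nchar(hdr)))
      comp <- grepl("complement", loc)
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      if (length(nums) < 2L) return(NULL)
      quals <- paste(g[-1], collapse = " ")
      gene <- regmatches(quals, regexec('/gene="([^"]+)"', quals))[[1]]
      if (length(gene) < 2L) {
        gene <- regmatches(quals, regexec('/product="([^"]+)"', quals))[[1]]
      }
      if (length(gene) < 2L) return(NULL)
      data.frame(type = type, gene = gene[2], start = min(nums),
                 end = max(nums), complement = comp,
                 stringsAsFactors = FALSE)
    }))
  }
  list(accession = acc, sequence = seq, features = feats)
}

#' Build a minichromosome from a GenBank record
#'
#' Orders the record's gene features by start coordinate, maps annotation
#' names onto the 37-gene vocabulary, takes `complement` strand as reverse
#' orientation, and stores the sequence before the first and after the last
#' feature as the upstream/downstream non-coding regions.
#'
#' @param record One element of [read_genbank()] output.
#' @return An `mt_minichromosome`.
#' @export
genbank_to_minichromosome <- function(record) {
  f <- record$features
  f <- f[f$type %in% c("gene", "CDS", "tRNA", "rRNA"), , drop = FALSE]
  if (is.null(f) || !nrow(f)) stop("record ", record$accession,
                                   " has no gene features")
  # prefer 'gene' features; fall back to CDS/tRNA/rRNA for genes lacking one
  f <- f[order(f$start, match(f$type, c("gene", "CDS", "tRNA", "rRNA"))), ,
         drop = FALSE]
  f <- f[!duplicated(paste(f$start, f$end)), , drop = FALSE]
  rows <- lapply(seq_len(nrow(f)), function(i) {
    nm <- normalise_gb_gene(f$gene[i])
    if (is.na(nm)) stop("unrecognised gene annotation '", f$gene[i],
                        "' in ", record$accession)
    g <- parse_gene_token(nm)
    mt_gene(g$base, g$tag, rev = f$complement[i])
  })
  minichromosome(do.call(rbind, rows),
                 ncr_upstream = if (min(f$start) > 1)
                   substr(record$sequence, 1, min(f$start) - 1L) else NULL,
                 ncr_downstream = if (max(f$end) < nchar(record$sequence))
                   substr(record$sequence, max(f$end) + 1L,
                          nchar(record$sequence)) else NULL)
}
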