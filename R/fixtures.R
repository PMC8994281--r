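# Packaged karyotype fixtures, the phylogeny, and the taxon->family map.

FIXTURE_FILES <- c(
  L_macrorhini      = "lepidophthirus_macrorhini.txt",
  P_fluctus         = "proechinophthirus_fluctus.txt",
  A_carlinii        = "antarctophthirus_carlinii.txt",
  A_lobodontis      = "antarctophthirus_lobodontis.txt",
  A_microchir       = "antarctophthirus_microchir.txt",
  P_gorillae        = "pthirus_gorillae.txt",
  P_pubis           = "pthirus_pubis.txt",
  MRCA_sucking_lice = "mrca_sucking_lice.txt",
  MRCA_primate_lice = "mrca_primate_lice_synthetic.txt",
  H_apri            = "haematopinus_apri_synthetic.txt",
  P_obtusus         = "pedicinus_obtusus_synthetic.txt"
)

#' Available karyotype fixtures
#'
#' @return Character vector of fixture keys accepted by [louse_karyotype()].
#' @export
louse_karyotypes <- function() names(FIXTURE_FILES)

#' Load a packaged louse karyotype
#'
#' Fixtures transcribe the published mitochondrial karyotypes of five seal
#' louse species and the gorilla louse, plus supporting karyotypes (human
#' pubic louse, sucking-louse MRCA, and synthetic reconstructions used for
#' the merger tally). Each file's `#source` header states which placements
#' are transcribed and which are synthetic.
#'
#' @param taxon A key from [louse_karyotypes()].
#' @return An `mt_karyotype`.
#' @export
#' @examples
#' k <- louse_karyotype("L_macrorhini")
#' length(k$minichromosomes)  # 11
louse_karyotype <- function(taxon) {
  taxon <- match.arg(taxon, names(FIXTURE_FILES))
  path <- system.file("extdata", "karyotypes", FIXTURE_FILES[[taxon]],
                      package = "minikaryo", mustWork = TRUE)
  read_karyotype(path)
}

#' The five seal-louse karyotypes
#'
#' Convenience accessor for the Echinophthiriidae ingroup used by the
#' ancestral-karyotype inference.
#'
#' @return Named list of five `mt_karyotype` objects.
#' @export
seal_louse_karyotypes <- function() {
  keys <- c("A_carlinii", "A_lobodontis", "A_microchir", "L_macrorhini",
            "P_fluctus")
  stats::setNames(lapply(keys, louse_karyotype), keys)
}

#' Packaged sucking-louse phylogeny
#'
#' A rooted tree with labelled internal nodes (topology from published
#' mitochondrial phylogenetics; tree estimation is out of scope and the
#' topology is consumed as data).
#'
#' @return An [ape::read.tree()] `phylo` object.
#' @export
louse_tree <- function() {
  ape::read.tree(system.file("extdata", "anoplura_tree.nwk",
                             package = "minikaryo", mustWork = TRUE))
}

#' Taxon-to-family map
#'
#' @return Named character vector mapping tree labels to louse families.
#' @export
louse_families <- function() {
  unlist(jsonlite::read_json(system.file("extdata", "config",
                                         "families.json",
                                         package = "minikaryo",
                                         mustWork = TRUE)))
}
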