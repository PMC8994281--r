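# karyotype model: vocabulary, parsing, writing, equality, fixture audit

test_that("gene tokens parse with tags, orientation and vocabulary checks", {
  g <- parse_karyotype("#taxon t\nK-nad4")$minichromosomes[[1]]$genes
  expect_equal(g$base, c("K", "nad4"))
  expect_false(any(g$rev))
  expect_equal(g$category, c("tRNA", "protein"))

  # reverse markers and paralog tags, incl. L1/S1 vs W1-style tags
  k <- parse_karyotype("#taxon t\nQ!-nad1!-T*!-W1\nL1-rrnS")
  g1 <- k$minichromosomes[[1]]$genes
  expect_equal(nrow(g1), 4L)
  expect_equal(g1$rev, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(g1$base, c("Q", "nad1", "T", "W"))
  expect_equal(g1$tag, c("", "", "*", "1"))
  g2 <- k$minichromosomes[[2]]$genes
  expect_equal(g2$base, c("L1", "rrnS"))  # L1 is a base name, not L + tag
  expect_equal(g2$tag, c("", ""))

  expect_error(parse_karyotype("#taxon t\nfoo-nad4"), "unknown gene token")
  expect_error(parse_karyotype("#taxon t\nK--nad4"), "empty gene token")
  expect_error(parse_karyotype("#taxon t\nK-nad4\nnad4"), "duplicate gene")
  expect_error(parse_karyotype("#taxon t\n#missing nad4\nK-nad4"),
               "declared missing but present")
})

test_that("write/parse round-trips on canonical form (property)", {
  set.seed(101)
  for (r in 1:50) {
    k <- random_karyotype(taxon = paste0("rt", r))
    txt <- write_karyotype(k)
    k2 <- parse_karyotype(txt)
    expect_identical(write_karyotype(k2), txt)
    expect_identical(karyotype_labels(k2), karyotype_labels(k))
    expect_identical(k2$missing_genes, k$missing_genes)
  }
})

test_that("packaged fixtures reproduce the printed counts", {
  audit <- list(  # minichromosomes, identified genes (distinct base names)
    L_macrorhini = c(11L, 27L), P_fluctus = c(10L, 22L),
    A_carlinii = c(9L, 30L), A_lobodontis = c(9L, 30L),
    A_microchir = c(12L, 20L), P_gorillae = c(17L, 36L))
  for (nm in names(audit)) {
    k <- louse_karyotype(nm)
    expect_identical(length(k$minichromosomes), audit[[nm]][1],
                     label = paste(nm, "minichromosome count"))
    expect_identical(length(unique(karyotype_genes(k)$base)), audit[[nm]][2],
                     label = paste(nm, "identified gene count"))
    # identified + missing covers the 37-gene vocabulary
    expect_identical(
      length(unique(karyotype_genes(k)$base)) + length(k$missing_genes), 37L)
  }
  # the sucking-louse MRCA fixture carries all 37 genes on 11 minichromosomes
  mrca <- louse_karyotype("MRCA_sucking_lice")
  expect_identical(length(mrca$minichromosomes), 11L)
  expect_identical(length(unique(karyotype_genes(mrca)$base)), 37L)
})

test_that("karyotype_equal reports identity and differences", {
  a <- louse_karyotype("A_carlinii"); b <- louse_karyotype("A_lobodontis")
  expect_true(karyotype_equal(a, b)$equal)
  expect_true(karyotype_equal(a, a)$equal)  # reflexive

  d <- karyotype_equal(louse_karyotype("P_pubis"),
                       louse_karyotype("P_gorillae"))
  expect_false(d$equal)
  expect_true("cox3-A" %in% d$only_a)          # split in the gorilla louse
  expect_true(all(c("A", "cox3") %in% d$only_b))

  # reflexivity over random karyotypes
  set.seed(7)
  for (r in 1:10) {
    k <- random_karyotype()
    expect_true(karyotype_equal(k, k)$equal)
  }
})

test_that("minichromosome labels are deterministic and writing is stable", {
  mc <- minichromosome(c("Q!", "nad1!", "T*!", "W1"))
  expect_identical(mc_label(mc), "Q!-nad1!-T*!-W1")
  k1 <- parse_karyotype("#taxon t\nE-cob\ncox1")
  k2 <- parse_karyotype("#taxon t\ncox1\nE-cob")  # input order differs
  expect_identical(write_karyotype(k1), write_karyotype(k2))
  expect_identical(write_karyotype(parse_karyotype("#taxon t\ncox1")),
                   "#taxon t\ncox1")
})
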