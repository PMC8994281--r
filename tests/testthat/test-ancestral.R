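# two-clause parsimony inference of ancestral karyotypes

seal_ancestor <- function() {
  infer_ancestral(seal_fixtures(), louse_karyotype("MRCA_sucking_lice"),
                  clade = "Echinophthiriidae_MRCA")
}

test_that("the seal-louse ancestor has >= 13 minichromosomes with the expected structure", {
  anc <- seal_ancestor()
  expect_gte(length(anc$minichromosomes), 13L)
  labs <- karyotype_labels(anc)
  # splits of the three ancestral minichromosomes leave these products
  expect_true(all(c("cox2", "R-nad4L", "P-cox3-A", "Q!-nad1!-T*!", "nad3",
                    "K-nad4", "E-cob", "atp8-atp6-N", "M-I-cox1-L2",
                    "H-nad5", "L1-rrnS", "V-rrnL", "nad2") %in% labs))
  # every placed gene appears exactly once
  g <- karyotype_genes(anc)
  expect_false(anyDuplicated(paste0(g$base, g$tag)) > 0)
})

test_that("nad6 and the eight variable tRNAs are unplaced", {
  anc <- seal_ancestor()
  expect_identical(anc$unplaced_genes,
                   sort(c("nad6", "C", "D", "F", "G", "S1", "S2", "W", "Y"),
                        method = "radix"))
  expect_true("nad6" %in% anc$missing_genes)
  expect_identical(length(setdiff(anc$unplaced_genes, "nad6")), 8L)
})

test_that("characters present only in the outgroup are not ancestral (rule trace)", {
  anc <- seal_ancestor()
  tr <- anc$rule_trace
  # S1/S2 sit with E-cob in the MRCA but in none of the five seal lice
  for (id in c("blk:E+S1", "blk:E+S2", "blk:S1+cob", "blk:S2+cob")) {
    row <- tr[tr$id == id, ]
    expect_identical(nrow(row), 1L, label = id)
    expect_false(row$ancestral, label = id)
    expect_identical(row$n_present, 0L, label = id)
  }
  # every inferred minichromosome cites a clause: each ancestral character
  # fired clause 1 or clause 2
  expect_true(all(!is.na(tr$clause[tr$ancestral])))
  # clause 1 requires outgroup presence
  expect_true(all(tr$outgroup_present[which(tr$clause == 1L)]))
})

test_that("identical ingroup with trivial outgroup is a fixed point (clause 2)", {
  k <- louse_karyotype("A_carlinii")
  ing <- list(k, k, k)
  ing[[2]]$taxon <- "copy2"; ing[[3]]$taxon <- "copy3"
  # outgroup sharing no arrangement: a single unrelated minichromosome
  og <- parse_karyotype("#taxon og\ncox1")
  anc <- infer_ancestral(ing, og, clade = "fp")
  expect_setequal(karyotype_labels(anc), karyotype_labels(k))
  tr <- anc$rule_trace
  expect_true(all(tr$clause[tr$ancestral & tr$kind == "block" &
                              grepl("\\+", tr$genes)] == 2L))
})

test_that("clause-1 monotonicity: adding a taxon bearing a character never demotes it", {
  set.seed(31)
  base_ing <- seal_fixtures()
  og <- louse_karyotype("MRCA_sucking_lice")
  anc0 <- infer_ancestral(base_ing, og, "c0")
  anc0_ids <- anc0$rule_trace$id[anc0$rule_trace$ancestral &
                                   anc0$rule_trace$clause %in% 1L]
  # add a sixth taxon that carries the full MRCA arrangement (possesses
  # every clause-1 character)
  extra <- og; extra$taxon <- "extra_taxon"
  anc1 <- infer_ancestral(c(base_ing, list(extra)), og, "c1")
  tr1 <- anc1$rule_trace
  for (id in anc0_ids) {
    expect_true(tr1$ancestral[tr1$id == id], label = id)
  }
})

test_that("simulated split-only clades recover the true root karyotype", {
  root <- louse_karyotype("MRCA_sucking_lice")
  root$taxon <- "root"
  # independent recoverability oracle: a root co-membership pair is
  # recoverable by clause 1 iff it survives intact in at least one tip
  pair_sets <- function(k) {
    unlist(lapply(k$minichromosomes, function(mc) {
      b <- paste0(mc$genes$base, mc$genes$tag)
      if (length(b) < 2L) return(character(0))
      cmb <- utils::combn(sort(b, method = "radix"), 2L)
      paste(cmb[1, ], cmb[2, ], sep = "+")
    }))
  }
  root_pairs <- pair_sets(root)
  for (seed in c(11L, 22L, 33L)) {
    cfg <- simulation_config(quartet_tree(), root, split_rate = 0.6,
                             merge_rate = 0, translocation_rate = 0,
                             loss_rate = 0, seed = seed)
    sim <- simulate_karyotypes(cfg)
    surviving <- unique(unlist(lapply(sim$tips, pair_sets)))
    anc <- infer_ancestral(unname(sim$tips), root, "sim_root")
    if (all(root_pairs %in% surviving)) {
      # full signal: exact recovery of the root karyotype
      expect_true(karyotype_equal(anc, root)$equal,
                  label = paste("seed", seed))
    } else {
      # signal loss: inferred blocks must still nest within root blocks
      expect_setequal(setdiff(pair_sets(anc), root_pairs), character(0))
    }
    # split-only histories never lose genes: everything stays placed
    expect_identical(nrow(karyotype_genes(anc)), 37L)
  }
})
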