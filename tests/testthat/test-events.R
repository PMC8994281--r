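# rearrangement-event detection and phylogenetic tallying

test_that("the three stem splits to the seal lice are detected with their anchors", {
  mrca <- louse_karyotype("MRCA_sucking_lice")
  anc <- infer_ancestral(seal_fixtures(), mrca, "Echinophthiriidae_MRCA")
  ev <- detect_events(mrca, anc, branch = "stem")
  sp <- ev[ev$kind == "split", ]
  expect_identical(nrow(sp), 3L)
  expect_setequal(sp$ancestral_mcs,
                  c("D-Y-cox2-nad6", "R-nad4L-P-cox3-A",
                    "Q!-nad1!-T*!-G-nad3-W"))
  # nad6 is unidentified in the descendant yet does not veto the split
  expect_identical(sp$anchor_genes[sp$ancestral_mcs == "D-Y-cox2-nad6"],
                   "cox2;nad6")
  expect_identical(sum(ev$kind == "merger"), 0L)
  expect_identical(sum(ev$kind == "loss"), 0L)
})

test_that("the northern fur seal louse shows one merger of the nad4L and rrnS minichromosomes", {
  anc <- infer_ancestral(seal_fixtures(), louse_karyotype("MRCA_sucking_lice"),
                         "Echinophthiriidae_MRCA")
  ev <- detect_events(anc, louse_karyotype("P_fluctus"), "to_Pfluctus")
  mg <- ev[ev$kind == "merger", ]
  expect_identical(nrow(mg), 1L)
  expect_identical(mg$anchor_genes, "nad4L;rrnS")
  # the merger involves exactly two ancestral minichromosomes
  expect_identical(length(strsplit(mg$ancestral_mcs, ";")[[1]]), 2L)
  expect_identical(sum(ev$kind == "split"), 0L)
})

test_that("one split in the gorilla louse: cox3-A into cox3 and A", {
  ev <- detect_events(louse_karyotype("P_pubis"), louse_karyotype("P_gorillae"),
                      "to_gorillae")
  sp <- ev[ev$kind == "split", ]
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$ancestral_mcs, "cox3-A")
  expect_setequal(strsplit(sp$descendant_mcs, ";")[[1]], c("cox3", "A"))
  expect_identical(sum(ev$kind == "merger"), 0L)
})

test_that("identical karyotypes yield zero events", {
  ev <- detect_events(louse_karyotype("A_carlinii"),
                      louse_karyotype("A_lobodontis"), "twin")
  expect_identical(nrow(as.data.frame(ev)), 0L)
})

test_that("the family tally reproduces the published merger census", {
  cfg <- default_pipeline_config()
  res <- run_pipeline(cfg, out_dir = tempfile("tally"), verbose = FALSE)
  tally <- res$tally
  expect_identical(unname(as.integer(tally$by_kind["merger"])), 4L)
  mg <- tally$events[tally$events$kind == "merger", ]
  # two mergers in Haematopinidae, one in Pedicinidae, one in the seal lice
  fams <- louse_families()[sub("^.*->", "", mg$branch)]
  expect_identical(sum(fams == "Haematopinidae"), 2L)
  expect_identical(sum(fams == "Pedicinidae"), 1L)
  expect_identical(sum(fams == "Echinophthiriidae"), 1L)
  # nad2 participates in two distinct merger events
  expect_identical(sum(grepl("(^|;)nad2(;|$)", mg$anchor_genes)), 2L)
})

test_that("a single branch with identical tip and root tallies zero", {
  tr <- ape::read.tree(text = "(tipA:1.0)rootN;")
  k <- louse_karyotype("MRCA_sucking_lice")
  k2 <- k; k2$taxon <- "tipA"
  tally <- tally_events(tr, list(rootN = k, tipA = k2))
  expect_identical(tally$total, 0L)
  expect_error(tally_events(tr, list(nosuch = k)), "not in tree")
})

test_that("splits and mergers are mirror images under branch reversal", {
  set.seed(91)
  root <- louse_karyotype("MRCA_sucking_lice"); root$taxon <- "root"
  for (r in 1:10) {
    k <- root
    for (e in 1:3) {
      kind <- sample(c("split", "merge"), 1)
      res <- minikaryo:::apply_random_event(k, kind, detectable = TRUE)
      if (!is.null(res)) k <- res$karyotype
    }
    fwd <- detect_events(root, k, "fwd")
    rev <- detect_events(k, root, "rev")
    expect_identical(sum(fwd$kind == "split"), sum(rev$kind == "merger"))
    expect_identical(sum(fwd$kind == "merger"), sum(rev$kind == "split"))
    # the same anchor sets drive the mirrored events
    expect_setequal(fwd$anchor_genes[fwd$kind == "split"],
                    rev$anchor_genes[rev$kind == "merger"])
  }
})

test_that("ground-truth recovery: exact on clean histories, never over-counted", {
  root <- louse_karyotype("MRCA_sucking_lice"); root$taxon <- "root"
  for (seed in 1:8) {
    cfg <- simulation_config(quartet_tree(), root, split_rate = 0.35,
                             merge_rate = 0.15, translocation_rate = 0,
                             loss_rate = 0, seed = seed)
    sim <- simulate_karyotypes(cfg)
    truth <- sim$events
    for (br in unique(truth$branch)) {
      nodes <- strsplit(br, "->", fixed = TRUE)[[1]]
      det <- detect_events(sim$node_karyotypes[[nodes[1]]],
                           sim$node_karyotypes[[nodes[2]]], br)
      tb <- truth[truth$branch == br, ]
      n_true <- c(split = sum(tb$kind == "split"),
                  merge = sum(tb$kind == "merge"))
      n_det <- c(split = sum(det$kind == "split"),
                 merge = sum(det$kind == "merger"))
      if (nrow(tb) <= 1L) {
        # non-overlapping events: exact recovery incl. anchor genes
        expect_identical(unname(n_det), unname(n_true), label = br)
        if (nrow(tb) == 1L && tb$kind %in% c("split", "merge")) {
          expect_identical(det$anchor_genes[det$kind %in% c("split", "merger")],
                           tb$anchors, label = br)
        }
      } else {
        # overlapping events can mask each other but never inflate
        expect_lte(sum(n_det), sum(n_true))
      }
    }
  }
})
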