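# affine-gap alignment identity, paralog ranking, degenerate scanning

test_that("identity basics: self, simple mismatch, symmetry", {
  expect_equal(global_identity("ACGTACGT", "ACGTACGT")$identity_pct, 100)
  expect_equal(global_identity("ACGT", "ACGA")$identity_pct, 75)
  set.seed(5)
  for (r in 1:10) {
    a <- rand_dna(sample(10:40, 1)); b <- rand_dna(sample(10:40, 1))
    expect_equal(global_identity(a, b)$identity_pct,
                 global_identity(b, a)$identity_pct)
  }
  expect_error(global_identity("ACGZ", "ACGT"), "non-IUPAC")
})

test_that("DP score equals exhaustive enumeration for short pairs (oracle)", {
  set.seed(42)
  sub <- iub_matrix()
  for (r in 1:120) {
    a <- rand_dna(sample(1:6, 1)); b <- rand_dna(sample(1:6, 1))
    dp <- global_identity(a, b)$score
    expect_equal(dp, oracle_align_score(a, b, sub, 15, 6.66),
                 tolerance = 1e-9, label = paste(a, "vs", b))
  }
  # also under a different (local-style) matrix and gap costs
  sub2 <- iub_matrix(mismatch = -1.9)
  for (r in 1:30) {
    a <- rand_dna(sample(1:5, 1)); b <- rand_dna(sample(1:5, 1))
    dp <- global_identity(a, b, gap_open = 4, gap_extend = 1.5,
                          submat = sub2)$score
    expect_equal(dp, oracle_align_score(a, b, sub2, 4, 1.5),
                 tolerance = 1e-9)
  }
})

test_that("identity decreases monotonically under accumulating point mutations", {
  set.seed(9)
  for (r in 1:5) {
    a <- rand_dna(120)
    ch <- strsplit(a, "")[[1]]
    prev <- 100
    for (step in 1:6) {
      pos <- sample(seq_along(ch), 8)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      id <- global_identity(a, paste(ch, collapse = ""))$identity_pct
      expect_lte(id, prev + 1e-9)
      prev <- id
    }
  }
})

test_that("ambiguity codes score as the mean over expansions", {
  m <- iub_matrix()
  expect_equal(m["A", "A"], 1.9)
  expect_equal(m["A", "C"], 0)
  expect_equal(m["A", "N"], 1.9 / 4)
  expect_equal(m["R", "A"], 1.9 / 2)
  expect_equal(m["R", "Y"], 0)      # disjoint expansions
  expect_equal(m["N", "N"], 1.9 / 4)
})

test_that("identity_table summarises shared genes; closed form under simulation", {
  expect_equal(identity_table(c(g1 = "ACGT"), c(g1 = "ACGT"))$summary[["mean"]],
               100)
  expect_error(identity_table(c(g1 = "ACGT"), c(g2 = "ACGT")), "no shared")

  # simulated orthologs: mean identity ~ (1 - p) * 100 for small per-site
  # mutation probability p (gapless regime)
  set.seed(77)
  p <- 0.05
  ga <- setNames(lapply(1:6, function(i) rand_dna(600)),
                 paste0("gene", 1:6))
  gb <- lapply(ga, mutate_seq, p = p)
  res <- identity_table(ga, gb)
  # binomial 3 sigma on the pooled 3600 sites
  sigma <- 100 * sqrt(p * (1 - p) / 600) / sqrt(6)
  expect_lt(abs(res$summary[["mean"]] - (1 - p) * 100), 3 * sigma)
  expect_identical(nrow(res$table), 6L)
})

test_that("classify_paralog recovers the original copy of a duplicated tRNA", {
  # single candidate is trivially first
  one <- classify_paralog(c(w1 = "ACGTACGTAC"), c(t1 = "ACGTACGTAC"))
  expect_true(one$likely_original[1])

  # duplicate evolving 3x faster than the original: the slow copy keeps
  # higher identity to the orthologs of other taxa
  set.seed(123)
  n_rep <- 200; hit <- 0
  for (r in seq_len(n_rep)) {
    anc <- rand_dna(65)                        # ancestral tRNA
    w1 <- mutate_seq(anc, 0.10)                # original
    w2 <- mutate_seq(anc, 0.30)                # duplicate, 3x rate
    orth <- setNames(lapply(1:4, function(i) mutate_seq(anc, 0.15)),
                     paste0("taxon", 1:4))
    rk <- classify_paralog(c(W1 = w1, W2 = w2), orth)
    if (rk$candidate[rk$likely_original] == "W1") hit <- hit + 1
  }
  expect_gte(hit / n_rep, 0.95)
})

test_that("degenerate_scan finds planted segments with exact reference coordinates", {
  set.seed(7)
  gene <- rand_dna(400)
  # 215 bp of the gene (ref 101..315) embedded in a 285-bp non-coding seq
  ncs <- paste0(rand_dna(40), substr(gene, 101, 315), rand_dna(30))
  hit <- degenerate_scan(ncs, c(gx = gene), min_identity = 90,
                         min_length = 100)
  expect_identical(nrow(hit), 1L)
  # the maximal-scoring segment must cover the planted region; it may gain
  # a few chance-match columns at the flanks (local-alignment semantics)
  expect_lte(hit$ref_start, 101L)
  expect_gte(101L - hit$ref_start, 0L)
  expect_lt(101L - hit$ref_start, 10L)
  expect_gte(hit$ref_end, 315L)
  expect_lt(hit$ref_end - 315L, 10L)
  expect_gte(hit$n_identical, 215L)
  expect_gte(hit$identity_pct, 99)

  # a 5' remnant abutting the reference start maps to nucleotide 1 exactly
  ncs2 <- paste0(substr(gene, 1, 215), rand_dna(3))
  hit2 <- degenerate_scan(ncs2, c(gx = gene), min_identity = 90,
                          min_length = 100)
  expect_identical(hit2$ref_start[1], 1L)
  expect_gte(hit2$ref_end[1], 215L)
  expect_lte(hit2$ref_end[1], 218L)
  expect_gte(hit2$n_identical[1], 215L)
})

test_that("random sequences produce no degenerate hits at strict thresholds", {
  set.seed(11)
  gene <- rand_dna(400)
  hits <- 0L
  for (r in 1:100) {
    h <- degenerate_scan(rand_dna(300), c(gx = gene), min_identity = 90,
                         min_length = 100)
    hits <- hits + nrow(h)
  }
  expect_identical(hits, 0L)
})
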