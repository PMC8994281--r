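# synthetic-data generator: determinism, replay invariant, rate calibration

sim_root <- function() {
  k <- louse_karyotype("MRCA_sucking_lice")
  k$taxon <- "root"
  k
}

test_that("zero rates give tips identical to the root; fixed seeds reproduce", {
  cfg <- simulation_config(quartet_tree(), sim_root(), split_rate = 0,
                           merge_rate = 0, translocation_rate = 0,
                           loss_rate = 0, seed = 4L)
  sim <- simulate_karyotypes(cfg)
  for (k in sim$tips) expect_true(karyotype_equal(k, sim_root())$equal)
  expect_identical(nrow(sim$events), 0L)

  cfg2 <- simulation_config(quartet_tree(), sim_root(), seed = 8L)
  a <- simulate_karyotypes(cfg2); b <- simulate_karyotypes(cfg2)
  expect_identical(lapply(a$tips, write_karyotype),
                   lapply(b$tips, write_karyotype))
  expect_identical(a$events, b$events)
})

test_that("replay invariant: the event log reconstructs every node exactly", {
  for (seed in c(3L, 14L, 159L)) {
    cfg <- simulation_config(quartet_tree(), sim_root(), split_rate = 0.5,
                             merge_rate = 0.2, translocation_rate = 0.3,
                             loss_rate = 0.1, seed = seed)
    sim <- simulate_karyotypes(cfg)
    rp <- replay_events(cfg, sim$events)
    for (nm in names(sim$node_karyotypes)) {
      expect_true(karyotype_equal(sim$node_karyotypes[[nm]], rp[[nm]])$equal,
                  label = paste("seed", seed, "node", nm))
    }
  }
})

test_that("split counts are Poisson with the configured per-branch mean", {
  n_rep <- 150
  counts <- integer(0)
  for (seed in seq_len(n_rep)) {
    cfg <- simulation_config(quartet_tree(), sim_root(), split_rate = 0.5,
                             merge_rate = 0, translocation_rate = 0,
                             loss_rate = 0, seed = seed)
    sim <- simulate_karyotypes(cfg)
    counts <- c(counts, sum(sim$events$kind == "split"))
  }
  # 6 branches at rate 0.5: mean 3 per replicate, 3 sigma binomial-ish bound
  mu <- 6 * 0.5
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / n_rep))
})

test_that("sequence evolution: zero rate copies the root; divergence follows the closed form", {
  cfg0 <- simulation_config(quartet_tree(), sim_root(),
                            substitution_rate = 0, seed = 5L)
  s0 <- simulate_sequences(cfg0, c(g1 = 200L, g2 = 120L))
  for (tp in s0$tips) expect_identical(unname(tp), unname(s0$root))

  # two tips whose MRCA is at per-lineage divergence d = rate * 0.1:
  # P(match) = exp(-2d) + (1 - exp(-2d)) / 4 under uniform redraw
  cfg <- simulation_config(quartet_tree(), sim_root(),
                           substitution_rate = 2, seed = 91L)
  ss <- simulate_sequences(cfg, c(g1 = 4000L))
  d <- 2 * 0.1
  p <- exp(-2 * d) + (1 - exp(-2 * d)) / 4
  obs <- global_identity(ss$tips$t1[["g1"]], ss$tips$t2[["g1"]])$identity_pct
  expect_lt(abs(obs / 100 - p), 3 * sqrt(p * (1 - p) / 4000))
})

test_that("config validation rejects impossible settings", {
  one_mc <- parse_karyotype("#taxon r\nK-nad4")
  expect_error(simulation_config(quartet_tree(), one_mc, merge_rate = 0.5),
               "config error")
  expect_error(simulation_config(quartet_tree(), sim_root(),
                                 split_rate = -1))
})

test_that("random_karyotype generates valid, varied karyotypes", {
  set.seed(12)
  for (r in 1:20) {
    k <- random_karyotype()
    g <- karyotype_genes(k)
    expect_identical(length(unique(g$base)) + length(k$missing_genes), 37L)
    expect_true(all(vapply(k$minichromosomes,
                           function(m) nrow(m$genes) >= 1L, logical(1))))
  }
})
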