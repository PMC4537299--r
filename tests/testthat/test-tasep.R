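test_that("enabled events follow the exclusion rules of the extended lattice", {
  rates <- uniformRates(2)
  g <- geneModel("g", c(rep("AAA", 11), "TAA"), rates, k0 = 1)

  # empty lattice: only initiation
  ev <- enabledEvents(integer(), g, 10)
  expect_equal(ev$type, "initiate")

  # A-site at 1 covers 1..10: initiation blocked, codon 11 free -> elongate@1
  ev <- enabledEvents(1, g, 10)
  expect_equal(ev$type, "elongate")
  expect_equal(ev$position, 1L)

  # A-sites {1, 11}: elongation@1 blocked (codon 11 covered), 11+10 > 12 so
  # the lead can elongate; initiation blocked
  ev <- enabledEvents(c(1, 11), g, 10)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$position, 11L)

  # ribosome on the stop codon terminates
  ev <- enabledEvents(12, g, 10)
  expect_true("terminate" %in% ev$type)

  expect_error(enabledEvents(c(1, 5), g, 10), "closer than L")
})

test_that("single-site lattice matches the two-state closed form", {
  # S = 1, L = 1: n1 = a/(a+b), J = ab/(a+b)
  a <- 1.5; b <- 0.75
  rates <- uniformRates(b)
  g <- geneModel("g", "TAA", rates, k0 = a)
  sim <- simulateGene(g, quickCfg(L = 1, burn = 100, steps = 2e5), seed = 5)
  expect_lt(abs(occupancy(sim) - a / (a + b)), 0.01)
  expect_lt(abs(productionRate(sim) - a * b / (a + b)), 0.02)
  ex <- exactOccupancy(b, a, 1)
  expect_equal(ex$n, a / (a + b))
  expect_equal(ex$J, a * b / (a + b))
})

test_that("simulation streams are deterministic and order-independent", {
  genes <- lapply(1:4, function(i) polyGene(paste0("g", i), 60, k0 = 0.05))
  cfg <- quickCfg(burn = 50, steps = 2e4)
  b1 <- batchSimulate(genes, cfg, master_seed = 99)
  b2 <- batchSimulate(rev(genes), cfg, master_seed = 99)
  for (g in names(b1)) {
    expect_identical(occupancy(b1[[g]]), occupancy(b2[[g]]))
    expect_identical(b1[[g]]@J, b2[[g]]@J)
  }
  # different master seed gives a different trajectory
  b3 <- batchSimulate(genes[1], cfg, master_seed = 100)
  expect_false(identical(occupancy(b1$g1), occupancy(b3$g1)))
  # a failing gene is recorded, the batch continues
  bad <- polyGene("tiny", 5, k0 = 0.05)
  b4 <- batchSimulate(list(bad, genes[[1]]), cfg, master_seed = 99)
  expect_s3_class(b4$tiny, "simulation-error")
  expect_identical(occupancy(b4$g1), occupancy(b1$g1))
})

test_that("exclusion, time accounting and current bounds hold", {
  # heavy queueing with the exclusion assertion armed
  sr <- stats::setNames(rep(1, 64), allCodons()); sr["CCC"] <- 0.1
  g <- geneModel("q", c(rep("AAA", 30), rep("CCC", 29), "TAA"),
                 codonRateSet(sr), k0 = 2)
  cfg <- quickCfg(burn = 100, steps = 5e4)
  sim <- simulateGene(g, cfg, seed = 17, check_exclusion = TRUE)
  # occupancy cannot exceed the packing bound
  expect_lte(sum(occupancy(sim)), ceiling(60 / 10) + 1)
  expect_true(all(occupancy(sim) >= 0 & occupancy(sim) <= 1))

  # L = 1: J bounded by the slowest rate and k0
  g1 <- geneModel("b", c(rep("AAA", 20), rep("CCC", 19), "TAA"),
                  codonRateSet(sr), k0 = 5)
  s1 <- simulateGene(g1, quickCfg(L = 1, burn = 200, steps = 1e5), seed = 3)
  expect_lte(productionRate(s1), min(5, min(siteRates(g1))) * 1.05)

  # flux conservation: termination rate equals initiation rate long-run;
  # with o_0 = 1 the entry flux is k0 * P(first L codons free)
  g2 <- polyGene("f", 40, k0 = 0.2)
  s2 <- simulateGene(g2, quickCfg(burn = 500, steps = 4e5), seed = 8)
  expect_lt(abs(productionRate(s2) / (s2@F / s2@T) - 1), 1e-12)
  expect_gt(s2@F, 0)
})

test_that("rate rescaling leaves occupancies invariant (time-scale equivariance)", {
  # a power-of-two rescaling keeps every event probability bit-identical, so
  # the two runs follow the same trajectory with time compressed exactly 4x
  g <- geneModel("g", c(rep("AAA", 79), "TAA"), uniformRates(1), k0 = 0.0625)
  cfg <- quickCfg(burn = 100, steps = 3e4)
  s1 <- simulateGene(g, cfg, seed = 12)
  g4 <- geneModel("g", g@codons, uniformRates(4), k0 = 0.25)
  s4 <- simulateGene(g4, cfg, seed = 12)
  expect_equal(occupancy(s1), occupancy(s4), tolerance = 1e-12)
  expect_equal(productionRate(s4) / productionRate(s1), 4, tolerance = 1e-9)
})

test_that("initiation perturbation screen distinguishes limitation regimes", {
  cfg <- quickCfg(burn = 200, steps = 1e5)
  ini <- polyGene("ini", 100, k0 = 0.005)         # deeply initiation-limited
  sr <- stats::setNames(rep(1, 64), allCodons()); sr["CCC"] <- 0.02
  elo <- geneModel("elo", c(rep("AAA", 50), rep("CCC", 49), "TAA"),
                   codonRateSet(sr), k0 = 10)     # elongation-limited
  res <- perturbInitiationScreen(list(ini, elo), cfg, repeats = 3,
                                 master_seed = 21)
  expect_gt(res$rel_change[res$gene_id == "ini"], 0.05)
  expect_lt(abs(res$rel_change[res$gene_id == "elo"]), 0.02)
  expect_equal(res$group[res$gene_id == "elo"], "none")

  # identity perturbation with paired seeds is exactly zero
  res0 <- perturbInitiationScreen(list(ini), cfg, factor = 1, repeats = 2,
                                  master_seed = 5)
  expect_equal(res0$rel_change, 0)
})
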