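test_that("generation is byte-identical under a fixed seed", {
  sp <- synthSpec(n_genes = 3, length_range = c(60, 100),
                  sim_cfg = quickCfg(burn = 50, steps = 1e4), seed = 77)
  d1 <- generateSynthData(sp)
  d2 <- generateSynthData(sp)
  expect_identical(lapply(d1$counts, riboCounts), lapply(d2$counts, riboCounts))
  expect_identical(d1$truth$k0, d2$truth$k0)
  expect_identical(d1$truth$occupancy, d2$truth$occupancy)
  # changing the seed changes the data
  sp2 <- synthSpec(n_genes = 3, length_range = c(60, 100),
                   sim_cfg = quickCfg(burn = 50, steps = 1e4), seed = 78)
  d3 <- generateSynthData(sp2)
  expect_false(identical(lapply(d1$counts, riboCounts),
                         lapply(d3$counts, riboCounts)))
})

test_that("expected footprint counts are proportional to true occupancy", {
  # noise off, deep sequencing, spread rates (so occupancy varies along the
  # CDS): per-codon counts regress on true n_i with unit slope in log space
  set.seed(2)
  spread <- codonRateSet(stats::setNames(exp(stats::rnorm(64, 0, 0.6)),
                                         allCodons()))
  sp <- synthSpec(n_genes = 2, length_range = c(200, 200),
                  ribo_depth = 5e4, rna_depth = 2e3, true_rates = spread,
                  replicate_noise_sigma = 0, mrna_sdlog = 0,
                  sim_cfg = quickCfg(burn = 500, steps = 5e5), seed = 5)
  ds <- generateSynthData(sp)
  g <- names(ds$counts)[1]
  y <- rowSums(riboCounts(ds$counts[[g]]))
  x <- ds$truth$occupancy[[g]]
  keep <- y > 0 & x > 0
  slope <- unname(stats::coef(stats::lm(log(y[keep]) ~ log(x[keep])))[2])
  expect_lt(abs(slope - 1), 0.05)

  # in the deep-sequencing limit the root-segment ratio recovers the mean
  # occupancy up to the dataset-wide scale
  trees <- buildSegmentTrees(ds$counts, ds$sizes)
  tg <- makeInitTargets(trees, ds$truth$lnC_true)
  nbar <- vapply(ds$truth$occupancy[tg$gene_id], mean, 0)
  expect_equal(tg$target, unname(nbar), tolerance = 0.03)
})

test_that("the generator's replicate noise closes the loop with the error model", {
  # each assay carries an independent log-normal factor of sd 0.3 per
  # replicate, so a single ratio measurement has shape sqrt(2) * 0.3
  sp <- synthSpec(n_genes = 40, length_range = c(120, 250),
                  replicate_noise_sigma = 0.3,
                  sim_cfg = quickCfg(burn = 100, steps = 2e4), seed = 31)
  ds <- generateSynthData(sp)
  trees <- buildSegmentTrees(ds$counts, ds$sizes)
  expect_gt(length(trees), 30)
  # root segments only: one independent noise draw per gene and assay
  roots <- lapply(trees, function(tr) {
    tr@nodes <- tr@nodes[1, , drop = FALSE]
    tr@R <- tr@R[1, , drop = FALSE]; tr@M <- tr@M[1, , drop = FALSE]
    tr@d_ribo <- tr@d_ribo[1, , drop = FALSE]
    tr@d_rna <- tr@d_rna[1, , drop = FALSE]
    tr@omega <- tr@omega[1, , drop = FALSE]
    tr@mu <- tr@mu[1]; tr@sigma <- tr@sigma[1]; tr@group <- tr@group[1]
    tr
  })
  em <- estimateSigma(roots, cfg = runConfig(n_length_groups = 1))
  expect_lt(abs(groupSigma(em) - sqrt(2) * 0.3) / (sqrt(2) * 0.3), 0.35)
})

test_that("truth reports quantify parameter recovery", {
  rates <- stats::setNames(exp(stats::rnorm(64, 0, 0.5)), allCodons())
  truth <- list(rates = codonRateSet(rates),
                k0 = c(a = 0.01, b = 0.02),
                sequences = list(a = c("AAA", "GCT", "TAA"),
                                 b = c("CCG", "GCT", "TAA")))
  fitted <- list(rates = truth$rates,
                 k0 = data.frame(gene_id = c("a", "b"), k0 = c(0.01, 0.03)))
  rep <- truthReport(truth, fitted)
  expect_equal(rep$spearman, 1)
  expect_equal(rep$pearson, 1)
  expect_equal(rep$slope, 1)
  expect_equal(rep$intercept, 0, tolerance = 1e-9)
  expect_equal(unname(rep$k0_rel_err), c(0, 0.5))
  expect_setequal(rep$codons, c("AAA", "GCT", "CCG"))

  bad <- list(rates = truth$rates,
              k0 = data.frame(gene_id = "zz", k0 = 1))
  expect_error(truthReport(truth, bad), "no genes in common")
})
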