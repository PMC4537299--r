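# tiny synthetic study shared by the fitting tests: few genes, short CDSes,
# reduced budgets -- enough structure for the objective machinery without
# the cost of a full recovery experiment (that lives in the acceptance suite)
tinyStudy <- function(seed = 17, n_genes = 8) {
  simcfg <- quickCfg(burn = 200, steps = 6e4)
  alphabet <- c("GCT", "CCG", "AAA", "CTG")
  rates <- stats::setNames(rep(1, 64), allCodons())
  rates[alphabet] <- c(0.5, 2.0, 0.8, 1.4)
  sp <- synthSpec(n_genes = n_genes, length_range = c(120, 200),
                  codon_alphabet = alphabet,
                  true_rates = codonRateSet(rates),
                  k0_range = c(0.01, 0.05), replicate_noise_sigma = 0.15,
                  sim_cfg = simcfg, seed = seed)
  ds <- generateSynthData(sp)
  trees <- buildSegmentTrees(ds$counts, ds$sizes)
  em <- estimateSigma(trees, cfg = runConfig(n_length_groups = 2))
  trees <- assignSigma(trees, em)
  list(ds = ds, trees = trees, cfg = simcfg)
}

test_that("candidate objective is reproducible and prefers truthful rates", {
  st <- tinyStudy()
  seqs <- st$ds$truth$sequences[names(st$trees)]
  lnC <- st$ds$truth$lnC_true
  a <- candidateObjective(NULL, seqs, st$trees, st$ds$truth$rates, lnC,
                         st$cfg, seed = 9)
  b <- candidateObjective(NULL, seqs, st$trees, st$ds$truth$rates, lnC,
                         st$cfg, seed = 9)
  expect_identical(a$psi, b$psi)
  expect_identical(a$k0, b$k0)

  # swapping the slow and fast codon classes hurts the objective
  wrong <- codonRates(st$ds$truth$rates)
  wrong[c("GCT", "CCG")] <- wrong[c("CCG", "GCT")]
  wrong[c("AAA", "CTG")] <- wrong[c("CTG", "AAA")]
  w <- candidateObjective(NULL, seqs, st$trees,
                          codonRateSet(wrong), lnC, st$cfg, seed = 9)
  expect_gt(a$psi, w$psi)
})

test_that("updateRates guards the fixed codon and zero generations is a no-op", {
  start <- uniformRates()
  expect_error(
    candidateObjective(stats::setNames(0.1, "GAA"), list(), list(), start, 0),
    "fixed codon")
  st <- tinyStudy(seed = 23, n_genes = 3)
  seqs <- st$ds$truth$sequences[names(st$trees)]
  fit <- fitRates(seqs, st$trees, st$ds$truth$rates, st$ds$truth$lnC_true,
                  st$cfg, mode = "elong", generations = 0,
                  master_seed = 2, final_n_refine = 2)
  expect_equal(codonRates(fit$rates), codonRates(st$ds$truth$rates))
  expect_equal(fit$generations_run, 0L)
  init <- fitRates(seqs, st$trees, st$ds$truth$rates, st$ds$truth$lnC_true,
                   st$cfg, mode = "init_only", master_seed = 2,
                   final_n_refine = 2)
  expect_equal(init$mode, "init_only")
  expect_true(all(init$k0$k0 > 0))
})

test_that("cross-validation folds balance segments then genes", {
  om <- cbind(1, 1)
  mk <- function(id, nseg) {
    tr <- forestTree(id, rep(25L, nseg), matrix(1, nseg, 2))
    tr
  }
  # equal segment counts, 10 genes, 5 folds -> 2 genes per fold
  trees <- lapply(1:10, function(i) mk(paste0("g", i), 3))
  names(trees) <- paste0("g", 1:10)
  f <- makeCvFolds(trees, 5, seed = 1)
  expect_equal(as.integer(table(f)), rep(2L, 5))

  # segment counts {9,1,1,1,1,1,1,1}, k = 2: greedy puts the 9 alone-ish,
  # totals (9, 7)
  trees2 <- c(list(big = mk("big", 9)),
              lapply(1:7, function(i) mk(paste0("s", i), 1)))
  names(trees2) <- c("big", paste0("s", 1:7))
  f2 <- makeCvFolds(trees2, 2, seed = 1)
  tot <- vapply(1:2, function(k)
    sum(vapply(trees2[names(f2)[f2 == k]], function(t) nrow(t@nodes), 0L)), 0)
  expect_setequal(tot, c(9, 7))

  # k = n gives one gene per fold; k > n errors
  f3 <- makeCvFolds(trees[1:4], 4, seed = 1)
  expect_equal(as.integer(table(f3)), rep(1L, 4))
  expect_error(makeCvFolds(trees[1:3], 4), "more folds")
})

test_that("cross-validation fits on one fold and evaluates on the rest", {
  st <- tinyStudy(seed = 29, n_genes = 6)
  seqs <- st$ds$truth$sequences[names(st$trees)]
  cv <- crossval(seqs, st$trees, st$ds$truth$rates, st$ds$truth$lnC_true,
                 st$cfg, k = 2, master_seed = 7, mode = "init_only",
                 final_n_refine = 2)
  expect_equal(nrow(cv$test), 2)
  expect_true(all(is.finite(cv$test$psi)))
  # each test set is the complement of its training fold
  expect_equal(sort(unname(cv$folds)), c(1, 1, 1, 2, 2, 2))
  expect_true(is.finite(cv$summary["psi_sd"]))
})

test_that("geometric-mean consensus rates combine fold fits", {
  r1 <- uniformRates(2)
  r2 <- uniformRates(8)
  gm <- geomMeanRates(list(r1, r2))
  expect_true(all(codonRates(gm) == 4))
  expect_equal(fixedCodon(gm), "GAA")
})
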