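test_that("segment averages aggregate occupancy over tree segments", {
  om <- cbind(c(1, 1, 1), c(1, 1, 1))
  tr <- forestTree("g", c(10L, 4L, 2L), om)
  tr@nodes$l <- c(1L, 1L, 3L); tr@nodes$r <- c(10L, 4L, 4L)
  tr@sigma <- rep(1, 3)
  occ <- seq(0.1, 1, by = 0.1)
  pr <- segmentAverages(occ, tr)
  expect_equal(pr$N, c(mean(occ), mean(occ[1:4]), mean(occ[3:4])))

  # constant profile: every segment mean equals the constant
  pr2 <- segmentAverages(rep(0.37, 10), tr)
  expect_true(all(pr2$N == 0.37))

  # nested segments: parent mean is the length-weighted mean of children
  trc <- forestTree("h", c(10L, 5L, 5L), om)
  trc@nodes$parent <- c(0L, 1L, 1L)
  trc@nodes$l <- c(1L, 1L, 6L); trc@nodes$r <- c(10L, 5L, 10L)
  pc <- segmentAverages(occ, trc)
  expect_equal(pc$N[1], (5 * pc$N[2] + 5 * pc$N[3]) / 10)

  # zero means are floored, profiles shorter than the tree are an error
  expect_equal(segmentAverages(rep(0, 10), tr)$N, rep(1e-8, 3))
  expect_error(segmentAverages(rep(0.1, 4), tr), "shorter")
})

test_that("closed-form lnC matches its defining weighted mean and shifts", {
  p1 <- data.frame(N = 1, mu = log(2), sigma = 1)
  expect_equal(optimalLnC(p1), log(2))
  p2 <- data.frame(N = c(1, 1), mu = c(0, 1), sigma = c(1, 2))
  expect_equal(optimalLnC(p2), (0 * 1 + 1 * 0.25) / 1.25)
  # scaling all N by a shifts lnC by exactly -log(a)
  set.seed(2)
  p <- data.frame(N = exp(stats::rnorm(30)), mu = stats::rnorm(30),
                  sigma = stats::runif(30, 0.1, 2))
  a <- 7.3
  ps <- p; ps$N <- ps$N * a
  expect_equal(optimalLnC(ps), optimalLnC(p) - log(a))
  expect_error(optimalLnC(p[0, ]), "no segments")
})

test_that("psi evaluates the log-normal objective and peaks at the closed form", {
  one <- data.frame(gene_id = "g", N = 1, mu = 0, sigma = 1)
  expect_equal(psiObjective(one, lnC = 0)$psi, 0)
  expect_equal(psiObjective(one, lnC = 1)$psi, -0.5)

  set.seed(31)
  for (i in 1:20) {
    p <- data.frame(gene_id = sample(letters[1:3], 40, TRUE),
                    N = exp(stats::rnorm(40)), mu = stats::rnorm(40),
                    sigma = stats::runif(40, 0.1, 2))
    ln_star <- optimalLnC(p)
    # independent numeric maximization: root of the derivative in lnC
    dpsi <- function(x) sum((p$mu - log(p$N) - x) / p$sigma^2)
    ln_num <- stats::uniroot(dpsi, ln_star + c(-10, 10), tol = 1e-13)$root
    expect_lt(abs(ln_star - ln_num), 1e-8)
    for (delta in c(1e-3, 1e-1)) {
      expect_gte(psiObjective(p, ln_star)$psi, psiObjective(p, ln_star + delta)$psi)
      expect_gte(psiObjective(p, ln_star)$psi, psiObjective(p, ln_star - delta)$psi)
    }
    # additive decomposition over genes
    parts <- psiObjective(p, ln_star)
    expect_equal(sum(parts$per_gene), parts$psi)
    # scale invariance of the maximized objective: rescaling N is absorbed
    # by lnC exactly, shifting psi* only through the -log N Jacobian term
    a <- 3.7
    ps <- p; ps$N <- ps$N * a
    expect_equal(psiObjective(ps, optimalLnC(ps))$psi -
                   psiObjective(p, ln_star)$psi,
                 -nrow(p) * log(a))
  }
  expect_error(psiObjective(data.frame(N = NA, mu = 0, sigma = 1), 0),
               "non-finite")
})

test_that("evaluateModel scores profiles jointly and reports missing genes", {
  set.seed(8)
  om <- cbind(exp(stats::rnorm(6, 0, .1)), exp(stats::rnorm(6, 0, .1)))
  t1 <- forestTree("g1", rep(20L, 6), om); t1@sigma <- rep(0.3, 6)
  t2 <- forestTree("g2", rep(20L, 6), om); t2@sigma <- rep(0.3, 6)
  trees <- list(g1 = t1, g2 = t2)
  occ <- list(g1 = rep(0.05, 20), g2 = rep(0.02, 20))
  ev <- evaluateModel(occ, trees)
  expect_equal(ev$n_segments, 12)
  expect_length(ev$per_gene, 2)
  expect_equal(sum(ev$per_gene), ev$psi)

  expect_warning(ev2 <- evaluateModel(occ["g1"], trees), "g2")
  expect_equal(ev2$missing_genes, "g2")
  expect_equal(ev2$n_segments, 6)
  expect_error(evaluateModel(occ, list()), "no segment trees")

  # a profile consistent with the measurements outscores a permuted one
  set.seed(9)
  prof <- stats::runif(40, 0.01, 0.2)
  lens <- rep(20L, 8)
  starts <- seq(1L, 40L, by = 5L)[1:8]
  omc <- exp(cbind(log(vapply(1:8, function(i) mean(prof[(5 * i - 4):(5 * i)]), 0)) +
                     stats::rnorm(8, 0, 0.05),
                   log(vapply(1:8, function(i) mean(prof[(5 * i - 4):(5 * i)]), 0)) +
                     stats::rnorm(8, 0, 0.05)))
  t3 <- forestTree("g", lens, omc)
  t3@nodes$l <- starts; t3@nodes$r <- starts + 4L
  t3@sigma <- rep(0.1, 8)
  good <- evaluateModel(list(g = prof), list(g = t3))$psi
  perm <- evaluateModel(list(g = rev(prof)), list(g = t3))$psi
  expect_gt(good, perm)
})
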