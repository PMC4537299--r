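test_that("segment density and density ratio follow the defining formulas", {
  expect_equal(segmentDensity(100, 50, 1000), 0.002)
  expect_equal(segmentDensity(0, 7, 123), 0)
  expect_equal(segmentDensity(42, 1, 1), 42)
  expect_error(segmentDensity(1, 1, 0), "library size")

  expect_equal(densityRatio(0.002, 0.001), 2)
  expect_equal(densityRatio(0.37, 0.37), 1)
  expect_equal(densityRatio(0, 0.001), 0)
  expect_error(densityRatio(1, 0), "positive")
})

test_that("cut points split combined counts most evenly, ties to smaller p", {
  expect_equal(chooseCutPoint(c(4, 4, 4, 4), 1, 4), 2L)
  # |10 - 2| = 8 beats |11 - 1| = 10
  expect_equal(chooseCutPoint(c(10, 1, 1), 1, 3), 1L)
  # tie between p = 1 and p = 2 (both diff 1) -> smaller p
  expect_equal(chooseCutPoint(c(1, 1, 1), 1, 3), 1L)
  # all-zero fallback: midpoint
  expect_equal(chooseCutPoint(rep(0, 5), 11, 15), 13L)

  # exhaustive-search agreement on random instances
  set.seed(7)
  for (i in 1:50) {
    l <- sample(1:30, 1)
    len <- sample(2:40, 1)
    r <- l + len - 1L
    cc <- stats::rpois(len, sample(c(0.5, 3, 20), 1))
    if (sum(cc) == 0) next
    brute <- {
      tot <- sum(cc)
      imb <- vapply(seq_len(len - 1), function(p)
        abs(sum(cc[1:p]) - (tot - sum(cc[1:p]))), 0)
      l - 1L + which.min(imb)   # which.min takes the first = smallest p
    }
    expect_identical(chooseCutPoint(cc, l, r), as.integer(brute))
  }
})

test_that("tree construction enforces thresholds and conserves counts", {
  cfg <- runConfig()
  sizes <- librarySizes(c(a = 1e5, b = 1e5), c(a = 1e5, b = 1e5))

  # uniform 300-codon gene, 2 reads/codon/replicate in both assays:
  # hand-simulated recursion: every split halves counts and length; a child
  # fails once its summed reads < 128, i.e. once its length < 128/4 = 32
  u <- positionCounts("u", matrix(2L, 300, 2), matrix(2L, 300, 2))
  tr <- buildSegmentTree(u, sizes, cfg)
  nd <- nodeTable(tr)
  expect_equal(nd[nd$parent == 0, c("l", "r")],
               data.frame(l = 1L, r = 300L), ignore_attr = TRUE)
  leaves <- nd[!(nd$id %in% nd$parent), ]
  expect_true(all(leaves$length >= 32))
  expect_true(all(leaves$length < 64))
  # every retained node passes both thresholds
  expect_true(all(rowSums(tr@R) >= 128 & rowSums(tr@M) >= 128))
  expect_true(all(nd$length >= 20))

  # 19 codons with abundant reads: rejected on length
  short <- positionCounts("s", matrix(100L, 19, 2), matrix(100L, 19, 2))
  expect_null(buildSegmentTree(short, sizes, cfg))

  # 127 summed ribo reads vs abundant RNA: rejected on the per-assay floor
  ribo <- matrix(0L, 100, 2); ribo[1:127] <- 1L
  poor <- positionCounts("p", ribo, matrix(50L, 100, 2))
  expect_equal(sum(riboCounts(poor)), 127)
  expect_null(buildSegmentTree(poor, sizes, cfg))
  ribo[128] <- 1L
  expect_s4_class(buildSegmentTree(positionCounts("p", ribo,
                                                  matrix(50L, 100, 2)),
                                   sizes, cfg), "SegmentTree")

  # random genes: count conservation and determinism (validity re-checks the
  # parent = left + right identity on every construction)
  set.seed(11)
  for (i in 1:20) {
    pc <- randomCounts(paste0("g", i), sample(60:250, 1))
    t1 <- buildSegmentTree(pc, sizes, cfg)
    if (is.null(t1)) next
    expect_true(validObject(t1))
    t2 <- buildSegmentTree(pc, sizes, cfg)
    expect_equal(t1@nodes, t2@nodes)
    expect_equal(t1@mu, t2@mu)
    # children are shorter than their parent
    nd <- t1@nodes
    for (j in which(nd$parent != 0)) {
      p <- match(nd$parent[j], nd$id)
      expect_lt(nd$r[j] - nd$l[j], nd$r[p] - nd$l[p])
    }
  }
})

test_that("node statistics derive from the node's own counts per replicate", {
  sizes <- librarySizes(c(a = 1000, b = 2000), c(a = 4000, b = 4000))
  pc <- positionCounts("g", matrix(5L, 40, 2), matrix(10L, 40, 2),
                       c("a", "b"))
  tr <- buildSegmentTree(pc, sizes, runConfig(min_reads = 50))
  root <- 1
  expect_equal(unname(tr@d_ribo[root, "a"]), 200 / (40 * 1000))
  expect_equal(unname(tr@d_ribo[root, "b"]), 200 / (40 * 2000))
  expect_equal(unname(tr@d_rna[root, "a"]), 400 / (40 * 4000))
  expect_equal(tr@omega[root, "a"],
               tr@d_ribo[root, "a"] / tr@d_rna[root, "a"])
  expect_equal(tr@mu[root], mean(log(tr@omega[root, ])))
})

test_that("bias correction hooks: identity is a no-op, detrending flattens", {
  set.seed(23)
  n <- 400
  base <- stats::runif(n, -9, -3)   # a segment's density, shared by replicates
  ld <- cbind(base + stats::rnorm(n, 0, 0.1), base + stats::rnorm(n, 0, 0.1))
  # replicate 1 carries a linear density-dependent bias, replicate 2 the
  # opposite, so the inter-replicate log-ratio trends with density
  mu0 <- stats::rnorm(n, 0, 0.5)
  slope <- 0.15
  lw <- cbind(mu0 + slope * ld[, 1] + stats::rnorm(n, 0, 0.05),
              mu0 - slope * ld[, 2] + stats::rnorm(n, 0, 0.05))
  tr <- forestTree("g", rep(30L, n), exp(lw))
  tr@d_ribo <- exp(ld) * exp(lw); tr@d_rna <- exp(ld)
  trees <- list(g = tr)

  same <- correctDensityBias(trees, "identity")
  expect_equal(same$g@omega, trees$g@omega)
  expect_equal(same$g@mu, trees$g@mu)

  fixed <- correctDensityBias(trees, "detrend")
  slopeOf <- function(t) {
    e <- log(t@omega[, 1]) - log(t@omega[, 2])
    x <- rowMeans(log(sqrt(t@d_ribo * t@d_rna)))
    unname(stats::coef(stats::lm(e ~ x))[2])
  }
  expect_gt(abs(slopeOf(trees$g)), 0.2)   # injected trend is present
  expect_lt(abs(slopeOf(fixed$g)), 0.05)  # and removed by the reference hook

  one <- trees
  one$g@omega <- one$g@omega[, 1, drop = FALSE]
  expect_error(correctDensityBias(one), ">= 2 replicates")
})
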