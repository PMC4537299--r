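# shared fixtures: small rate sets, reduced simulation budgets, and a
# constructor for bare segment "forests" used by the error-model tests

uniformRates <- function(value = 1) {
  codonRateSet(stats::setNames(rep(value, 64), allCodons()))
}

# reduced-budget configuration for quick simulations in tests
quickCfg <- function(L = 10, burn = 300L, steps = 2e5, eps = 1e-9, ...) {
  runConfig(footprint_L = L, burn_in_terminations = burn, max_steps = steps,
            first_check_step = 1e12, check_interval = 1e12, epsilon = eps,
            ...)
}

# a polyA gene of n codons ending in a stop
polyGene <- function(id, n, rates = uniformRates(), k0 = NA_real_,
                     codon = "AAA") {
  geneModel(id, c(rep(codon, n - 1L), "TAA"), rates, k0 = k0)
}

# single-level "forest" tree: n unrelated root nodes with given lengths and
# per-replicate omegas; counts are placeholders consistent per node
forestTree <- function(gene_id, lengths, omega) {
  n <- length(lengths)
  stopifnot(nrow(omega) == n)
  nodes <- data.frame(id = seq_len(n), parent = 0L, depth = 0L,
                      l = 1L, r = as.integer(lengths))
  R <- matrix(200, n, ncol(omega))
  M <- matrix(200, n, ncol(omega))
  d_rna <- matrix(1e-6, n, ncol(omega))
  new("SegmentTree", gene_id = gene_id, nodes = nodes,
      R = R, M = M, d_ribo = omega * 1e-6, d_rna = d_rna, omega = omega,
      mu = rowMeans(log(omega)), sigma = rep(NA_real_, n),
      group = rep(NA_integer_, n),
      replicate_ids = paste0("rep", seq_len(ncol(omega))))
}

# random PositionCounts with Poisson counts around given per-codon means
randomCounts <- function(id, n_codons, ribo_mean = 3, rna_mean = 3,
                         n_rep = 2L) {
  ribo <- matrix(stats::rpois(n_codons * n_rep, ribo_mean), n_codons, n_rep)
  rna <- matrix(stats::rpois(n_codons * n_rep, rna_mean), n_codons, n_rep)
  positionCounts(id, ribo, rna, paste0("rep", seq_len(n_rep)))
}

librarySizes <- function(n_ribo, n_rna) {
  new("LibrarySizes", n_ribo = n_ribo, n_rna = n_rna)
}
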