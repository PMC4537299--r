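#' Specification of a synthetic ribosome profiling dataset
#'
#' Defines the generative conditions for a fully synthetic dataset with known
#' ground-truth kinetics: gene lengths and codon usage, true codon rates,
#' the initiation-rate distribution, sequencing depths, and the
#' replicate-level multiplicative log-normal noise that the error model is
#' built to capture.
#'
#' The defaults emulate duplicate yeast-like measurements: CDS lengths of
#' 60-600 codons, uniform sense-codon usage, initiation rates log-uniform
#' over a 20-fold initiation-limited range, sequencing depths that put a
#' typical gene well above the 128-read reliability threshold, and a
#' replicate noise of sigma = 0.3 on the natural-log scale.
#'
#' @param n_genes number of genes (default 20).
#' @param length_range CDS length range in codons, stop included (default
#'   60-600).
#' @param codon_alphabet sense codons to draw from (default all 61).
#' @param codon_probs usage probabilities over `codon_alphabet` (default
#'   uniform).
#' @param usage_block_codons when set, codon usage varies along each CDS in
#'   blocks of this many codons: each block draws its own usage from a
#'   Dirichlet centred on `codon_probs` (mimicking the regional codon-usage
#'   structure of real transcripts). NULL (default) keeps usage homogeneous.
#' @param usage_alpha Dirichlet concentration for block usage (total;
#'   smaller = blockier, default 4).
#' @param stop_codon stop codon appended to every gene (default "TAA").
#' @param true_rates a [CodonRateSet-class] of ground-truth rates (default
#'   all 1).
#' @param k0_range log-uniform range of true initiation rates (default
#'   0.005-0.1, initiation-limited for unit elongation rates).
#' @param ribo_depth expected footprint reads per codon per unit
#'   `m_g * n_i` (default 500).
#' @param rna_depth expected mRNA reads per codon per unit `m_g`
#'   (default 20).
#' @param mrna_sdlog log-normal spread of per-gene mRNA abundance `m_g`
#'   (default 0.5; meanlog 0).
#' @param replicate_noise_sigma sd of the per-gene, per-replicate,
#'   per-assay log-normal factor (default 0.3).
#' @param rna_positional_noise gamma overdispersion of per-position RNA
#'   coverage (variance of the unit-mean positional factor; 0 = uniform
#'   coverage, the default).
#' @param shared_bias_sd sd of a log-normal per-position bias shared by both
#'   assays (cancels in the density ratio; 0 by default, a stress knob).
#' @param n_replicates replicates per assay (default 2).
#' @param sim_cfg [runConfig()] used to compute true occupancies (default
#'   full budget).
#' @param seed RNG seed.
#' @return a `SynthSpec` list.
#' @export
synthSpec <- function(n_genes = 20L, length_range = c(60L, 600L),
                      codon_alphabet = NULL, codon_probs = NULL,
                      usage_block_codons = NULL, usage_alpha = 4,
                      stop_codon = "TAA", true_rates = NULL,
                      k0_range = c(0.005, 0.1), ribo_depth = 500,
                      rna_depth = 20, mrna_sdlog = 0.5,
                      replicate_noise_sigma = 0.3,
                      rna_positional_noise = 0, shared_bias_sd = 0,
                      n_replicates = 2L, sim_cfg = runConfig(), seed = 1L) {
  code <- geneticCode()
  if (is.null(codon_alphabet))
    codon_alphabet <- names(code)[code != "*"]
  if (is.null(codon_probs))
    codon_probs <- rep(1 / length(codon_alphabet), length(codon_alphabet))
  if (is.null(true_rates))
    true_rates <- codonRateSet(stats::setNames(rep(1, 64), allCodons()))
  spec <- list(n_genes = as.integer(n_genes),
               length_range = as.integer(length_range),
               codon_alphabet = codon_alphabet, codon_probs = codon_probs,
               usage_block_codons = if (is.null(usage_block_codons)) NULL
                                    else as.integer(usage_block_codons),
               usage_alpha = usage_alpha,
               stop_codon = stop_codon, true_rates = true_rates,
               k0_range = as.numeric(k0_range), ribo_depth = ribo_depth,
               rna_depth = rna_depth, mrna_sdlog = mrna_sdlog,
               replicate_noise_sigma = replicate_noise_sigma,
               rna_positional_noise = rna_positional_noise,
               shared_bias_sd = shared_bias_sd,
               n_replicates = as.integer(n_replicates),
               sim_cfg = sim_cfg, seed = as.integer(seed))
  stopifnot(spec$n_genes > 0, all(spec$length_range >= sim_cfg$footprint_L),
            spec$ribo_depth > 0, spec$rna_depth > 0,
            spec$replicate_noise_sigma >= 0, spec$n_replicates >= 1)
  class(spec) <- "SynthSpec"
  spec
}

#' Generate a synthetic dataset with known ground truth
#'
#' Per gene: draws a codon sequence and a true initiation rate, simulates
#' the TASEP at the `sim_cfg` budget to obtain true occupancies `n_i` and
#' production rate `J`, then samples sequencing counts. Ribo-seq counts at
#' codon i are Poisson with mean
#' `ribo_depth * m_g * n_i * exp(eps_rep)`; RNA-seq counts are Poisson with
#' mean `rna_depth * m_g * exp(eps'_rep) * pos_i` where `m_g` is the
#' per-gene mRNA abundance, `eps` are iid Normal(0, replicate_noise_sigma^2)
#' per gene/replicate/assay (the log-normal inter-replicate noise), and
#' `pos_i` are iid unit-mean gamma positional factors (RNA coverage is
#' uniform in expectation). Library sizes are the realized totals.
#'
#' Footprint counts scale with `m_g`, so the density ratio estimates the
#' per-transcript occupancy up to one dataset-wide scaling factor; its true
#' log value is returned as `lnC_true`.
#'
#' @param spec a [synthSpec()] list.
#' @return list with `counts` (named list of [PositionCounts-class]),
#'   `sizes` ([LibrarySizes-class]), and `truth` (list: `rates`, `k0`,
#'   `occupancy`, `J`, `mrna`, `sequences`, `lnC_true`, `spec`).
#' @export
generateSynthData <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  set.seed(spec$seed)
  reps <- paste0("rep", seq_len(spec$n_replicates))
  ids <- sprintf("synth%03d", seq_len(spec$n_genes))

  lens <- spec$length_range[1] - 1L +
    sample.int(spec$length_range[2] - spec$length_range[1] + 1L,
               spec$n_genes, replace = TRUE)
  drawCodons <- function(n) {
    if (is.null(spec$usage_block_codons))
      return(sample(spec$codon_alphabet, n, replace = TRUE,
                    prob = spec$codon_probs))
    out <- character(0)
    while (length(out) < n) {
      # block-level Dirichlet usage centred on codon_probs
      a <- stats::rgamma(length(spec$codon_alphabet),
                         shape = spec$usage_alpha * spec$codon_probs)
      a <- a / sum(a)
      out <- c(out, sample(spec$codon_alphabet, spec$usage_block_codons,
                           replace = TRUE, prob = a))
    }
    out[seq_len(n)]
  }
  sequences <- lapply(seq_len(spec$n_genes), function(i)
    c(drawCodons(lens[i] - 1L), spec$stop_codon))
  names(sequences) <- ids
  k0 <- exp(stats::runif(spec$n_genes, log(spec$k0_range[1]),
                         log(spec$k0_range[2])))
  names(k0) <- ids
  m_g <- stats::rlnorm(spec$n_genes, 0, spec$mrna_sdlog)
  names(m_g) <- ids

  occ <- list(); J <- stats::setNames(numeric(spec$n_genes), ids)
  counts <- list()
  for (i in seq_len(spec$n_genes)) {
    g <- geneModel(ids[i], sequences[[i]], spec$true_rates, k0 = k0[i])
    sim <- simulateGene(g, spec$sim_cfg,
                        seed = deriveSeed(spec$seed, ids[i]))
    occ[[ids[i]]] <- occupancy(sim)
    J[i] <- productionRate(sim)
    S <- lens[i]
    shared <- if (spec$shared_bias_sd > 0)
      stats::rlnorm(S, -spec$shared_bias_sd^2 / 2, spec$shared_bias_sd)
    else rep(1, S)
    ribo <- matrix(0L, S, spec$n_replicates, dimnames = list(NULL, reps))
    rna <- ribo
    for (r in seq_len(spec$n_replicates)) {
      fac_ribo <- exp(stats::rnorm(1, 0, spec$replicate_noise_sigma))
      fac_rna <- exp(stats::rnorm(1, 0, spec$replicate_noise_sigma))
      pos <- if (spec$rna_positional_noise > 0) {
        sh <- 1 / spec$rna_positional_noise
        stats::rgamma(S, shape = sh, rate = sh)
      } else rep(1, S)
      ribo[, r] <- stats::rpois(S, spec$ribo_depth * m_g[i] * occ[[ids[i]]] *
                                  fac_ribo * shared)
      rna[, r] <- stats::rpois(S, spec$rna_depth * m_g[i] * fac_rna * pos *
                                 shared)
    }
    if (sum(ribo) < spec$n_replicates || sum(rna) < spec$n_replicates)
      warning("gene ", ids[i], " has expected counts below 1 per replicate")
    counts[[ids[i]]] <- positionCounts(ids[i], ribo, rna, reps)
  }
  n_ribo <- vapply(reps, function(r)
    sum(vapply(counts, function(p) sum(p@ribo[, r]), 0)), 0)
  n_rna <- vapply(reps, function(r)
    sum(vapply(counts, function(p) sum(p@rna[, r]), 0)), 0)
  sizes <- new("LibrarySizes", n_ribo = n_ribo, n_rna = n_rna)
  # omega ~= n_bar * (ribo_depth * N_rna) / (rna_depth * N_ribo) = n_bar * C:
  # the dataset-wide scale from occupancy units to ratio units
  lnC_true <- log(spec$ribo_depth / spec$rna_depth) +
    log(mean(n_rna) / mean(n_ribo))
  list(counts = counts, sizes = sizes,
       truth = list(rates = spec$true_rates, k0 = k0, occupancy = occ,
                    J = J, mrna = m_g, sequences = sequences,
                    lnC_true = lnC_true, spec = spec))
}

#' Recovery metrics of a fit against synthetic ground truth
#'
#' @param truth the `truth` element of [generateSynthData()] output.
#' @param fitted a fit from [fitRates()] (uses `rates` and `k0`).
#' @param codons which codons to compare (default the free codons actually
#'   present in the truth's sequences, excluding the fixed codon and stop).
#' @return list with `spearman`, `pearson` (fitted vs true log elongation
#'   rates), `slope`, `intercept` (fitted-vs-true regression in log space),
#'   `k0_rel_err` (named per-gene relative errors), `codons`.
#' @export
truthReport <- function(truth, fitted, codons = NULL) {
  if (is.null(codons)) {
    present <- unique(unlist(truth$sequences, use.names = FALSE))
    codons <- setdiff(present,
                      c(fixedCodon(truth$rates), stopCodons()))
  }
  lt <- log(codonRates(truth$rates)[codons])
  lf <- log(codonRates(fitted$rates)[codons])
  fit_k0 <- stats::setNames(fitted$k0$k0, fitted$k0$gene_id)
  common <- intersect(names(fit_k0), names(truth$k0))
  if (length(common) == 0) stop("no genes in common between fit and truth")
  k0_rel <- (fit_k0[common] - truth$k0[common]) / truth$k0[common]
  reg <- stats::lm(lf ~ lt)
  list(spearman = stats::cor(lt, lf, method = "spearman"),
       pearson = stats::cor(lt, lf),
       slope = unname(stats::coef(reg)[2]),
       intercept = unname(stats::coef(reg)[1]),
       k0_rel_err = k0_rel, codons = codons)
}
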