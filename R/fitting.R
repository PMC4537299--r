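#' Objective of one candidate rate vector
#'
#' The inner loop of model fitting: assemble a full [CodonRateSet-class] from
#' the candidate log-rates (the fixed codon keeps its reference rate),
#' re-approximate every gene's initiation rate under the proposed scale,
#' simulate all genes, aggregate per-segment averages, determine the optimal
#' scaling factor, and return psi. Deterministic for a fixed `seed`.
#'
#' @param log_rates named numeric of candidate log elongation rates for the
#'   free codons (NULL or empty keeps `start_rates` unchanged).
#' @param sequences named list of codon vectors (the genes to simulate).
#' @param trees named list of [SegmentTree-class] with sigma assigned.
#' @param start_rates a [CodonRateSet-class]; source of all non-candidate
#'   rates and of the fixed codon.
#' @param lnC_tilde proposed scaling factor for initiation-rate targets.
#' @param cfg a [runConfig()] list (use reduced budgets in the inner loop).
#' @param seed seed for this evaluation (common random numbers: use the same
#'   seed for all candidates of a generation).
#' @param n_refine verification simulations inside [approxK0()] (default 0:
#'   pure mean-field inversion, the cheap inner-loop mode).
#' @return list with `psi`, `lnC`, `rates` ([CodonRateSet-class]), `k0`
#'   (data.frame from [batchApprox()]), `failed_genes`.
#' @export
candidateObjective <- function(log_rates, sequences, trees, start_rates,
                               lnC_tilde, cfg = runConfig(), seed = cfg$rng_seed,
                               n_refine = 0L) {
  rates <- updateRates(start_rates, log_rates)
  genes <- lapply(names(sequences), function(g)
    geneModel(g, sequences[[g]], rates))
  names(genes) <- names(sequences)
  k0 <- batchApprox(genes, trees, lnC_tilde, cfg, master_seed = seed,
                    n_refine = n_refine)
  for (i in seq_len(nrow(k0)))
    genes[[k0$gene_id[i]]]@k0 <- k0$k0[i]
  genes <- genes[k0$gene_id]
  segs <- lapply(trees[k0$gene_id], function(tr)
    as.matrix(tr@nodes[tr@nodes$parent != 0L | nrow(tr@nodes) == 1L,
                       c("l", "r")]))
  sims <- batchSimulate(genes, cfg, master_seed = seed, segments = segs)
  failed <- names(sims)[vapply(sims, inherits, TRUE, "simulation-error")]
  ok <- setdiff(names(sims), failed)
  if (length(ok) == 0) stop("all gene simulations failed")
  ev <- evaluateModel(sims[ok], trees[ok])
  list(psi = ev$psi, lnC = ev$lnC, rates = rates, k0 = k0,
       failed_genes = failed)
}

# overwrite the free codons of a rate set with exp(log_rates)
updateRates <- function(start_rates, log_rates) {
  if (is.null(log_rates) || length(log_rates) == 0) return(start_rates)
  stopifnot(!is.null(names(log_rates)))
  if (fixedCodon(start_rates) %in% names(log_rates))
    stop("the fixed codon must not appear among the candidate rates")
  r <- codonRates(start_rates)
  r[names(log_rates)] <- exp(log_rates)
  codonRateSet(r, fixedCodon(start_rates))
}

#' Fit translation rates by maximizing psi
#'
#' Two modes. `"init_only"`: elongation rates stay at `start_rates`
#' (e.g. tRNA-adaptation-based values); only the per-gene initiation rates
#' are approximated, followed by one evaluation. `"elong"`: the log
#' elongation rates of all free codons are optimized with CMA-ES (the fixed
#' codon anchors the scale, removing the rate-scaling degeneracy), with
#' initiation rates re-approximated for every candidate. Candidates within a
#' generation share a seed (common random numbers); seeds are fresh across
#' generations so the search does not overfit one noise realization. The
#' final incumbent is re-evaluated at the full simulation budget.
#'
#' @param sequences named list of codon vectors.
#' @param trees named list of [SegmentTree-class] with sigma assigned.
#' @param start_rates a [CodonRateSet-class] starting point.
#' @param lnC_tilde proposed scaling factor.
#' @param cfg full-budget [runConfig()] used for the final evaluation.
#' @param mode `"elong"` or `"init_only"`.
#' @param free_codons codons whose rates are optimized; default all codons
#'   present in `sequences` except the fixed codon (rates of codons absent
#'   from the data are unidentifiable and keep their starting values).
#' @param inner_cfg reduced-budget [runConfig()] for candidate evaluations
#'   (defaults to `cfg`).
#' @param population CMA-ES population size.
#' @param sigma0 initial CMA-ES step on the log-rate axis (default 0.3).
#' @param generations CMA-ES generation budget (0 returns `start_rates`).
#' @param master_seed seed for the whole fit.
#' @param final_n_refine verification simulations for the final
#'   initiation-rate approximation (default 12).
#' @return list with `rates`, `k0`, `psi`, `lnC`, `psi_trace` (best psi per
#'   generation, nondecreasing), `generations_run`, `mode`, `seed`.
#' @export
fitRates <- function(sequences, trees, start_rates, lnC_tilde,
                     cfg = runConfig(), mode = c("elong", "init_only"),
                     free_codons = NULL, inner_cfg = cfg,
                     population = 12L, sigma0 = 0.3, generations = 30L,
                     master_seed = cfg$rng_seed, final_n_refine = 12L) {
  mode <- match.arg(mode)
  finalEval <- function(rates) {
    res <- candidateObjective(NULL, sequences, trees, rates, lnC_tilde,
                              cfg, seed = master_seed,
                              n_refine = final_n_refine)
    res$rates <- rates
    res
  }
  if (mode == "init_only" || generations <= 0) {
    res <- finalEval(start_rates)
    return(list(rates = res$rates, k0 = res$k0, psi = res$psi,
                lnC = res$lnC, psi_trace = res$psi,
                generations_run = 0L, mode = mode, seed = master_seed))
  }
  if (is.null(free_codons)) {
    present <- unique(unlist(sequences, use.names = FALSE))
    free_codons <- setdiff(present, fixedCodon(start_rates))
  }
  stopifnot(length(free_codons) > 0)
  x0 <- log(codonRates(start_rates)[free_codons])
  obj <- function(x, gen) {
    lr <- stats::setNames(x, free_codons)
    gen_seed <- as.integer((master_seed + 104729 * gen) %% 2147483647)
    -candidateObjective(lr, sequences, trees, start_rates, lnC_tilde,
                        inner_cfg, seed = gen_seed)$psi
  }
  opt <- cmaES(x0, obj, sigma0 = sigma0, lambda = population,
               max_generations = generations, seed = master_seed)
  fitted <- updateRates(start_rates, stats::setNames(opt$par, free_codons))
  res <- finalEval(fitted)
  list(rates = fitted, k0 = res$k0, psi = res$psi, lnC = res$lnC,
       psi_trace = -opt$trace, generations_run = opt$generations,
       mode = mode, seed = master_seed)
}

#' Balanced cross-validation folds over genes
#'
#' Greedy stratified partition: genes are sorted by segment count
#' (descending, ties shuffled deterministically under `seed`) and each gene
#' joins the fold that currently has the smallest segment total, breaking
#' ties by the smaller gene count and then by fold index. This balances both
#' the number of segments and the number of genes across folds.
#'
#' @param trees named list of [SegmentTree-class] (segment counts come from
#'   here).
#' @param k number of folds (default 5).
#' @param seed seed for tie shuffling.
#' @return named integer vector: fold index (1..k) per gene id.
#' @export
makeCvFolds <- function(trees, k = 5L, seed = 1L) {
  stopifnot(k >= 2)
  if (k > length(trees)) stop("more folds than genes")
  nseg <- vapply(trees, function(tr) nrow(tr@nodes), 0L)
  set.seed(as.integer(seed))
  ord <- order(-nseg, sample.int(length(nseg)))
  fold_seg <- integer(k); fold_genes <- integer(k)
  assign <- integer(length(trees))
  for (i in ord) {
    f <- order(fold_seg, fold_genes, seq_len(k))[1]
    assign[i] <- f
    fold_seg[f] <- fold_seg[f] + nseg[i]
    fold_genes[f] <- fold_genes[f] + 1L
  }
  stats::setNames(assign, names(trees))
}

#' Cross-validated fitting and evaluation
#'
#' For every fold, fits on that single fold and evaluates on the union of
#' the remaining folds (training on the small side keeps fitting cheap;
#' set `invert = TRUE` for the conventional k-1/1 split). Test-time
#' initiation rates are re-approximated from the test genes' own trees.
#'
#' @param sequences named list of codon vectors.
#' @param trees named list of [SegmentTree-class] with sigma assigned.
#' @param start_rates a [CodonRateSet-class].
#' @param lnC_tilde proposed scaling factor.
#' @param cfg full-budget [runConfig()].
#' @param k number of folds.
#' @param invert train on k-1 folds instead of 1 (default FALSE).
#' @param master_seed seed.
#' @param ... passed to [fitRates()] (mode, budgets, ...).
#' @return list with `folds`, per-fold `fits`, `test` (data.frame of fold,
#'   psi, lnC, n_segments) and `summary` (mean and SD of test psi and lnC).
#' @export
crossval <- function(sequences, trees, start_rates, lnC_tilde,
                     cfg = runConfig(), k = 5L, invert = FALSE,
                     master_seed = cfg$rng_seed, ...) {
  folds <- makeCvFolds(trees, k, seed = master_seed)
  fits <- list(); rows <- list()
  for (f in seq_len(k)) {
    train_ids <- names(folds)[if (invert) folds != f else folds == f]
    test_ids <- setdiff(names(folds), train_ids)
    fit <- fitRates(sequences[train_ids], trees[train_ids], start_rates,
                    lnC_tilde, cfg, master_seed = master_seed + f, ...)
    test <- candidateObjective(NULL, sequences[test_ids], trees[test_ids],
                               fit$rates, lnC_tilde, cfg,
                               seed = master_seed + f,
                               n_refine = 12L)
    fits[[f]] <- fit
    rows[[f]] <- data.frame(fold = f, psi = test$psi, lnC = test$lnC,
                            n_segments = sum(vapply(trees[test_ids],
                                                    function(tr) nrow(tr@nodes),
                                                    0L)))
  }
  test <- do.call(rbind, rows)
  list(folds = folds, fits = fits, test = test,
       summary = c(psi_mean = mean(test$psi), psi_sd = stats::sd(test$psi),
                   lnC_mean = mean(test$lnC), lnC_sd = stats::sd(test$lnC)))
}

#' Per-codon geometric mean of rate sets
#'
#' Combines the rate sets fitted on different cross-validation folds into a
#' single consensus set (used for fitting only initiation rates on all data).
#'
#' @param rate_sets list of [CodonRateSet-class].
#' @return a [CodonRateSet-class] with the fixed codon of the first set.
#' @export
geomMeanRates <- function(rate_sets) {
  stopifnot(length(rate_sets) > 0)
  logs <- vapply(rate_sets, function(rs) log(codonRates(rs)),
                 numeric(64))
  m <- if (is.matrix(logs)) rowMeans(logs) else logs
  codonRateSet(exp(m), fixedCodon(rate_sets[[1]]))
}
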