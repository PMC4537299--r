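#' Occupancy targets for initiation-rate approximation
#'
#' Converts each gene's root-segment density ratio into a dimensionless mean
#' A-site occupancy target under a proposed scaling factor:
#' `target = exp(mu_root - lnC_tilde)`. The proposed scale plays the role of
#' the fitted scale `C` but is supplied up front (e.g. computed from
#' ribosomes and mRNA molecules per cell) so that initiation rates come out
#' in physiologically meaningful units.
#'
#' @param trees named list of [SegmentTree-class].
#' @param lnC_tilde proposed scaling factor on the natural-log axis.
#' @return data.frame with `gene_id`, `mu_root`, `target`.
#' @export
makeInitTargets <- function(trees, lnC_tilde) {
  stopifnot(is.finite(lnC_tilde))
  rows <- lapply(trees, function(tr) {
    root <- which(tr@nodes$parent == 0L)
    if (length(root) != 1L) {
      warning("tree of ", tr@gene_id, " has no unique root; skipped")
      return(NULL)
    }
    data.frame(gene_id = tr@gene_id, mu_root = tr@mu[root],
               target = exp(tr@mu[root] - lnC_tilde))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Proposed scaling factor from cell physiology
#'
#' Computes `lnC_tilde` from two physiology numbers: the total count of
#' actively translating ribosomes per cell and the total codon content of the
#' mRNA pool per cell. Their ratio is the cell-wide mean A-site occupancy per
#' codon; the proposed scale maps the (arbitrary-unit) density ratios onto
#' that occupancy scale via the across-gene mean root-segment ratio.
#'
#' @param trees named list of [SegmentTree-class].
#' @param ribosomes_per_cell actively translating ribosomes per cell.
#' @param mrna_codons_per_cell summed codon content of the mRNA pool.
#' @return `lnC_tilde` (natural log).
#' @export
proposedLnC <- function(trees, ribosomes_per_cell, mrna_codons_per_cell) {
  stopifnot(ribosomes_per_cell > 0, mrna_codons_per_cell > 0)
  mu_root <- vapply(trees, function(tr)
    tr@mu[which(tr@nodes$parent == 0L)], 0)
  mean(mu_root) - log(ribosomes_per_cell / mrna_codons_per_cell)
}

# Mean-field density of a lattice without ribosome interference: each
# ribosome spends 1/k_i at codon i and initiations never block, so the
# A-site occupancy is n_i = k0 / k_i and the mean density is
# k0 * mean(1 / k_i). Valid in the initiation-limited regime; used to seed
# and bracket the bisection on simulated density.
meanFieldDensity <- function(k0, site_rates) k0 * mean(1 / site_rates)

meanFieldK0 <- function(target, site_rates) target / mean(1 / site_rates)

#' Approximate the initiation rate matching a density target
#'
#' Finds `k0` such that the simulated mean A-site occupancy of the gene
#' matches `target` within `rel_tol`. The mean-field inverse (exact when
#' ribosomes never interfere) provides the starting point; when
#' `n_refine > 0` the candidate is verified by short simulations and refined
#' by monotone bisection on `log(k0)` — simulated mean density is
#' nondecreasing in `k0`, which guarantees the bisection's validity. All
#' verification simulations of one gene share a seed, so the empirical
#' density curve is a deterministic nondecreasing function of `k0` during
#' the search. Targets above the achievable density at `k0_max` return the
#' bracket top with a saturation flag.
#'
#' @param gene a [GeneModel-class] (its `k0` slot is ignored).
#' @param target desired dimensionless mean A-site occupancy, > 0.
#' @param cfg a [runConfig()] list used for the verification simulations
#'   (pass reduced budgets for inner-loop use).
#' @param rel_tol relative density tolerance (default 0.05).
#' @param n_refine maximum verification simulations (default 12; 0 returns
#'   the pure mean-field inverse, the cheap inner-loop mode).
#' @param k0_min,k0_max bracket; defaults `1e-6 * min(k_i)` and
#'   `1e2 * min(k_i)`.
#' @param seed seed shared by this gene's verification simulations.
#' @return list with `k0`, `achieved` (simulated density, NA when
#'   `n_refine = 0`), `rel_err`, `saturated`, `n_sims`.
#' @export
approxK0 <- function(gene, target, cfg = runConfig(), rel_tol = 0.05,
                     n_refine = 12L, k0_min = NULL, k0_max = NULL,
                     seed = cfg$rng_seed) {
  if (!is.finite(target) || target <= 0) stop("target density must be > 0")
  kmin <- min(gene@site_rates)
  if (is.null(k0_min)) k0_min <- 1e-6 * kmin
  if (is.null(k0_max)) k0_max <- 1e2 * kmin
  clamp <- function(x) min(max(x, k0_min), k0_max)
  guess <- clamp(meanFieldK0(target, gene@site_rates))
  if (n_refine <= 0)
    return(list(k0 = guess, achieved = NA_real_, rel_err = NA_real_,
                saturated = guess >= k0_max, n_sims = 0L))

  n_sims <- 0L
  density_at <- function(k0) {
    g <- gene; g@k0 <- k0
    n_sims <<- n_sims + 1L
    mean(occupancy(simulateGene(g, cfg, seed = seed)))
  }
  best <- list(k0 = guess, achieved = NA_real_, rel_err = Inf,
               saturated = FALSE)
  note <- function(k0, d) {
    re <- abs(d - target) / target
    if (re < best$rel_err)
      best <<- list(k0 = k0, achieved = d, rel_err = re, saturated = FALSE)
    re
  }
  d <- density_at(guess)
  if (note(guess, d) <= rel_tol)
    return(c(best, n_sims = n_sims))

  # bracket the target by geometric expansion
  lo <- hi <- guess; dlo <- dhi <- d
  while (dhi < target && hi < k0_max && n_sims < n_refine) {
    lo <- hi; dlo <- dhi
    hi <- clamp(hi * 4)
    dhi <- density_at(hi)
    if (note(hi, dhi) <= rel_tol) return(c(best, n_sims = n_sims))
  }
  while (dlo > target && lo > k0_min && n_sims < n_refine) {
    hi <- lo; dhi <- dlo
    lo <- clamp(lo / 4)
    dlo <- density_at(lo)
    if (note(lo, dlo) <= rel_tol) return(c(best, n_sims = n_sims))
  }
  if (dhi < target && hi >= k0_max) {
    # even saturating initiation cannot reach the target
    return(list(k0 = k0_max, achieved = dhi, rel_err = abs(dhi - target) / target,
                saturated = TRUE, n_sims = n_sims))
  }
  while (n_sims < n_refine) {
    mid <- sqrt(lo * hi)
    dm <- density_at(mid)
    if (note(mid, dm) <= rel_tol) break
    if (dm < target) { lo <- mid; dlo <- dm } else { hi <- mid; dhi <- dm }
  }
  c(best, n_sims = n_sims)
}

#' Approximate initiation rates for a gene collection
#'
#' Builds density targets from the trees' root segments under the proposed
#' scale and runs [approxK0()] per gene. Deterministic given the master
#' seed; genes without a tree are absent from the output.
#'
#' @param genes named list of [GeneModel-class] (k0 slots ignored).
#' @param trees named list of [SegmentTree-class].
#' @param lnC_tilde proposed scaling factor (natural log).
#' @param cfg a [runConfig()] list for verification simulations.
#' @param master_seed per-gene verification seeds derive from this.
#' @param ... further arguments to [approxK0()] (`rel_tol`, `n_refine`, ...).
#' @return data.frame with `gene_id`, `k0`, `achieved_density`, `rel_err`,
#'   `saturated`, `n_sims`.
#' @export
batchApprox <- function(genes, trees, lnC_tilde, cfg = runConfig(),
                        master_seed = cfg$rng_seed, ...) {
  targets <- makeInitTargets(trees, lnC_tilde)
  targets <- targets[targets$gene_id %in% names(genes), , drop = FALSE]
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    gid <- targets$gene_id[i]
    r <- approxK0(genes[[gid]], targets$target[i], cfg,
                  seed = deriveSeed(master_seed, gid), ...)
    data.frame(gene_id = gid, k0 = r$k0, achieved_density = r$achieved,
               rel_err = r$rel_err, saturated = r$saturated,
               n_sims = r$n_sims)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
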