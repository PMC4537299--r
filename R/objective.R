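#' Average predicted occupancy per tree segment
#'
#' Aggregates a per-position occupancy profile over every segment of a gene's
#' tree: the arithmetic mean of `n_i` over the segment's codons. Segment
#' means of zero (possible at finite sampling) are floored at `n_floor`
#' before any logarithm is taken downstream.
#'
#' @param occupancy numeric per-position occupancy covering the full CDS
#'   (a [SimResult-class] is also accepted).
#' @param tree the gene's [SegmentTree-class]; `sigma` must be assigned when
#'   the predictions feed the objective.
#' @param n_floor floor for zero segment means (default 1e-8).
#' @return data.frame with `gene_id`, `l`, `r`, `N`, `mu`, `sigma`.
#' @export
segmentAverages <- function(occupancy, tree, n_floor = 1e-8) {
  if (is(occupancy, "SimResult")) occupancy <- occupancy@n
  nd <- tree@nodes
  if (max(nd$r) > length(occupancy))
    stop("occupancy profile shorter than the tree of ", tree@gene_id)
  N <- vapply(seq_len(nrow(nd)), function(i)
    mean(occupancy[nd$l[i]:nd$r[i]]), 0)
  data.frame(gene_id = tree@gene_id, l = nd$l, r = nd$r,
             N = pmax(N, n_floor), mu = tree@mu, sigma = tree@sigma,
             row.names = NULL)
}

#' Closed-form optimal scaling factor
#'
#' The log scaling factor maximizing the objective for fixed predictions:
#' the precision-weighted mean of `mu - log(N)` with weights `1 / sigma^2`.
#'
#' @param predictions data.frame from [segmentAverages()] (possibly
#'   row-bound over genes) with columns `N`, `mu`, `sigma`.
#' @return `lnC` on the natural-log axis.
#' @export
optimalLnC <- function(predictions) {
  if (nrow(predictions) == 0) stop("no segments to scale")
  w <- 1 / predictions$sigma^2
  sum(w * (predictions$mu - log(predictions$N))) / sum(w)
}

#' Objective value psi at a given scale
#'
#' Sum over segments of
#' `-(log(N) - mu + lnC)^2 / (2 sigma^2) - log(N)`:
#' the log-likelihood of the predicted average segment occupancies under the
#' segment-wise log-normal error model, constants dropped. The `-log(N)`
#' term is the log-normal Jacobian; psi values are therefore comparable only
#' within a fixed tree and error model.
#'
#' @param predictions data.frame with columns `N`, `mu`, `sigma` (and
#'   `gene_id` for the per-gene breakdown).
#' @param lnC log scaling factor (defaults to the closed-form optimum).
#' @return list with `psi`, `lnC`, `n_segments`, and `per_gene` (named psi
#'   contributions).
#' @export
psiObjective <- function(predictions, lnC = optimalLnC(predictions)) {
  if (!all(is.finite(predictions$N)) || !all(is.finite(predictions$mu)) ||
      !all(is.finite(predictions$sigma)) || !is.finite(lnC))
    stop("non-finite inputs to the objective")
  lnN <- log(predictions$N)
  contrib <- -(lnN - predictions$mu + lnC)^2 / (2 * predictions$sigma^2) - lnN
  per_gene <- if ("gene_id" %in% names(predictions))
    vapply(split(contrib, predictions$gene_id), sum, 0) else NULL
  list(psi = sum(contrib), lnC = lnC, n_segments = nrow(predictions),
       per_gene = per_gene)
}

#' Score occupancy profiles from any source against segment trees
#'
#' Attaches group sigmas, aggregates predictions per segment, determines the
#' scaling factor jointly over all genes' segments via the closed form, and
#' evaluates psi. Occupancy profiles may come from this package's simulator
#' or from any external model (a plain list of per-gene numeric profiles).
#'
#' @param occupancies named list (by gene id) of per-position occupancy
#'   profiles or [SimResult-class] objects.
#' @param trees named list of [SegmentTree-class] with `sigma` assigned
#'   (see [assignSigma()]).
#' @param n_floor floor for zero segment means (default 1e-8).
#' @return list with `psi`, `lnC`, `n_segments`, `per_gene`, and
#'   `missing_genes` (tree genes lacking a profile; they are excluded with a
#'   warning).
#' @export
evaluateModel <- function(occupancies, trees, n_floor = 1e-8) {
  if (length(trees) == 0) stop("no segment trees to evaluate against")
  missing <- setdiff(names(trees), names(occupancies))
  if (length(missing))
    warning("no occupancy profile for: ", paste(missing, collapse = ", "))
  use <- setdiff(names(trees), missing)
  if (length(use) == 0) stop("no gene has both a tree and a profile")
  preds <- do.call(rbind, lapply(use, function(g)
    segmentAverages(occupancies[[g]], trees[[g]], n_floor)))
  if (anyNA(preds$sigma))
    stop("trees carry unassigned sigma; run assignSigma() first")
  out <- psiObjective(preds)
  out$missing_genes <- missing
  out
}
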