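#' Location parameter of a segment's ratio distribution
#'
#' The log of the geometric mean of the replicate density ratios.
#'
#' @param omegas positive per-replicate density ratios.
#' @return `mu` on the natural-log scale.
#' @export
segmentMu <- function(omegas) {
  if (any(!is.finite(omegas)) || any(omegas <= 0))
    stop("all omegas must be positive")
  mean(log(omegas))
}

#' Equal-content length groups for the error model
#'
#' Group edges are placed at empirical quantiles of the segment-length
#' distribution and then shifted to the nearest boundary between distinct
#' observed lengths so that every segment maps to exactly one group (left
#' edge inclusive, right edge exclusive).
#'
#' @param lengths integer segment lengths (codons) pooled over all genes.
#' @param n_groups requested number of groups (default 10).
#' @return numeric vector of `n_groups + 1` strictly increasing edges; fewer
#'   groups (with a warning) when there are not enough distinct lengths.
#' @export
makeLengthGroups <- function(lengths, n_groups = 10L) {
  stopifnot(n_groups >= 1, length(lengths) > 0)
  u <- sort(unique(lengths))
  if (length(u) < n_groups) {
    warning(sprintf("only %d distinct lengths; reducing groups from %d to %d",
                    length(u), n_groups, length(u)))
    n_groups <- length(u)
  }
  # candidate boundaries lie between consecutive distinct lengths
  bounds <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else numeric()
  q <- stats::quantile(lengths, probs = seq_len(n_groups - 1L) / n_groups,
                       names = FALSE, type = 7)
  inner <- vapply(q, function(qq) bounds[which.min(abs(bounds - qq))],
                  0)[seq_len(max(0L, n_groups - 1L))]
  inner <- sort(unique(inner))
  edges <- c(min(u), inner, max(u) + 1)
  if (length(edges) < n_groups + 1L)
    warning(sprintf("duplicate quantile boundaries; %d groups instead of %d",
                    length(edges) - 1L, n_groups))
  edges
}

# Group index per length under left-inclusive, right-exclusive edges.
# Lengths outside the fitted range are clamped into the first/last group so
# the assignment is a total function.
lengthGroupIndex <- function(lengths, edges) {
  idx <- findInterval(lengths, edges, all.inside = TRUE)
  as.integer(idx)
}

#' Estimate the length-grouped error model from segment trees
#'
#' For every group, inter-replicate errors `e = log(omega_rep_a / omega_rep_b)`
#' are collected over all unordered replicate pairs of all member segments and
#' a centred normal is fitted, giving the i.r.e. shape `sigma_ire`
#' (`sqrt(mean(e^2))`, or `1.4826 * mad` for the robust variant). The shape of
#' a single measurement's error is then `sigma_group = sigma_ire / sqrt(2)`,
#' since the log-ratio of two iid log-normal measurements has twice the
#' log-variance of one. Groups with fewer than `min_group_segments` segments
#' borrow the sigma of the nearest adequately filled group. Estimated sigmas
#' are floored at `cfg$sigma_floor` so objective weights `1 / sigma^2` stay
#' finite.
#'
#' @param trees named list of [SegmentTree-class] (>= 2 replicates).
#' @param edges group edges from [makeLengthGroups()]; computed from the
#'   trees when NULL.
#' @param cfg a [runConfig()] list (uses `n_length_groups`, `sigma_floor`).
#' @param robust use `1.4826 * mad(e, center = 0)` instead of the
#'   root-mean-square (default FALSE).
#' @param min_group_segments minimum segments per group (default 10).
#' @return a [LengthGroupModel-class].
#' @export
estimateSigma <- function(trees, edges = NULL, cfg = runConfig(),
                          robust = FALSE, min_group_segments = 10L) {
  stopifnot(length(trees) > 0)
  lens <- unlist(lapply(trees, function(tr)
    tr@nodes$r - tr@nodes$l + 1L), use.names = FALSE)
  if (is.null(edges)) edges <- makeLengthGroups(lens, cfg$n_length_groups)
  nrep <- ncol(trees[[1]]@omega)
  if (nrep < 2) stop("sigma estimation requires >= 2 replicates")
  lw <- do.call(rbind, lapply(trees, function(tr) log(tr@omega)))
  pairs <- utils::combn(nrep, 2)
  e <- c(apply(pairs, 2, function(p) lw[, p[1]] - lw[, p[2]]))
  grp <- lengthGroupIndex(lens, edges)
  grp_e <- rep(grp, ncol(pairs))
  k <- length(edges) - 1L
  n_seg <- vapply(seq_len(k), function(g) sum(grp == g), 0L)
  sigma_ire <- rep(NA_real_, k)
  for (g in seq_len(k)) {
    eg <- e[grp_e == g]
    if (n_seg[g] >= min_group_segments) {
      sigma_ire[g] <- if (robust) 1.4826 * stats::mad(eg, center = 0)
                      else sqrt(mean(eg^2))
    }
  }
  if (anyNA(sigma_ire)) {
    ok <- which(!is.na(sigma_ire))
    if (length(ok) == 0) stop("no group has enough segments")
    for (g in which(is.na(sigma_ire))) {
      nb <- ok[which.min(abs(ok - g))]
      warning(sprintf(
        "group %d has %d < %d segments; borrowing sigma from group %d",
        g, n_seg[g], min_group_segments, nb))
      sigma_ire[g] <- sigma_ire[nb]
    }
  }
  sigma <- sigma_ire / sqrt(2)
  floored <- sigma < cfg$sigma_floor
  if (any(floored)) {
    warning(sprintf("sigma floored at %g for group(s) %s", cfg$sigma_floor,
                    paste(which(floored), collapse = ", ")))
    sigma[floored] <- cfg$sigma_floor
  }
  new("LengthGroupModel", edges = as.numeric(edges), sigma = sigma,
      n_segments = n_seg)
}

#' Assign per-segment sigma from the length-group model
#'
#' Total over segments: every node of every tree receives the sigma (and
#' group index) of its length group.
#'
#' @param trees named list of [SegmentTree-class].
#' @param model a [LengthGroupModel-class].
#' @return the trees with `sigma` and `group` filled in.
#' @export
assignSigma <- function(trees, model) {
  for (g in names(trees)) {
    len <- trees[[g]]@nodes$r - trees[[g]]@nodes$l + 1L
    idx <- lengthGroupIndex(len, model@edges)
    trees[[g]]@group <- idx
    trees[[g]]@sigma <- model@sigma[idx]
  }
  trees
}
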