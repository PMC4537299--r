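#' Read density of a segment
#'
#' Density in arbitrary units: reads per codon per total mapped read,
#' `counts / (L_seg * library_size)`.
#'
#' @param counts reads assigned to the segment.
#' @param L_seg segment length in codons.
#' @param library_size total mapped reads of the assay/replicate.
#' @return density (vectorized over `counts`).
#' @export
segmentDensity <- function(counts, L_seg, library_size) {
  stopifnot(L_seg >= 1)
  if (any(library_size <= 0)) stop("library size must be positive")
  counts / (L_seg * library_size)
}

#' Density ratio omega
#'
#' Per-transcript ribosome density estimate: ribo-seq density divided by
#' RNA-seq density of the same segment. Computing the mRNA density per segment
#' (rather than one value per gene) cancels local sequencing bias shared
#' between the two assays.
#'
#' @param d_ribo,d_rna densities from [segmentDensity()].
#' @return omega (dimensionless).
#' @export
densityRatio <- function(d_ribo, d_rna) {
  if (any(d_rna <= 0)) stop("mRNA density must be positive")
  d_ribo / d_rna
}

#' Choose the balanced cut point of a segment
#'
#' Returns the position `p` in `[l, r - 1]` that divides the combined
#' (ribo + RNA, summed over replicates) read counts most equally between
#' `[l, p]` and `[p + 1, r]`; ties are broken towards the smaller `p`. If the
#' segment carries no reads at all the midpoint `floor((l + r) / 2)` is used.
#'
#' @param combined numeric vector of combined counts for positions `l..r`.
#' @param l,r 1-based inclusive segment bounds.
#' @return cut point `p`.
#' @export
chooseCutPoint <- function(combined, l, r) {
  stopifnot(r > l, length(combined) == r - l + 1)
  if (sum(combined) == 0) return(as.integer((l + r) %/% 2))
  cs <- cumsum(combined)
  tot <- cs[length(cs)]
  imb <- abs(cs[-length(cs)] - (tot - cs[-length(cs)]))
  as.integer(l - 1L + which.min(imb))
}

#' Build the segment tree of one gene
#'
#' Recursive balanced bisection of the CDS. The root spans the whole CDS and
#' is created only if the gene passes the reliability thresholds: summed
#' (over replicates) ribo-seq reads >= `min_reads`, summed RNA-seq reads >=
#' `min_reads` (each assay separately), and length >= `min_segment_codons`.
#' A node is split only if both prospective children individually pass all
#' thresholds, so every stored node is reliable. Node statistics (densities,
#' density ratios, `mu`) are computed per replicate from the node's own
#' counts; the same cut points are used for all replicates so replicate
#' measurements remain mergeable.
#'
#' @param counts a [PositionCounts-class].
#' @param sizes a [LibrarySizes-class].
#' @param cfg a [runConfig()] list.
#' @return a [SegmentTree-class], or NULL if the gene fails the root
#'   thresholds.
#' @export
buildSegmentTree <- function(counts, sizes, cfg = runConfig()) {
  ribo <- counts@ribo
  rna <- counts@rna
  S <- nrow(ribo)
  combined <- rowSums(ribo) + rowSums(rna)
  passes <- function(l, r) {
    (r - l + 1) >= cfg$min_segment_codons &&
      sum(ribo[l:r, ]) >= cfg$min_reads &&
      sum(rna[l:r, ]) >= cfg$min_reads
  }
  if (!passes(1L, S)) return(NULL)

  ids <- integer(); parents <- integer(); depths <- integer()
  ls <- integer(); rs <- integer()
  recurse <- function(l, r, depth, parent) {
    id <- length(ids) + 1L
    ids[[id]] <<- id; parents[[id]] <<- parent
    depths[[id]] <<- depth; ls[[id]] <<- l; rs[[id]] <<- r
    if (r > l) {
      p <- chooseCutPoint(combined[l:r], l, r)
      if (passes(l, p) && passes(p + 1L, r)) {
        recurse(l, p, depth + 1L, id)
        recurse(p + 1L, r, depth + 1L, id)
      }
    }
    invisible(NULL)
  }
  recurse(1L, S, 0L, 0L)

  n <- length(ids)
  nrep <- ncol(ribo)
  R <- matrix(0, n, nrep, dimnames = list(NULL, counts@replicate_ids))
  M <- R
  for (i in seq_len(n)) {
    R[i, ] <- colSums(ribo[ls[i]:rs[i], , drop = FALSE])
    M[i, ] <- colSums(rna[ls[i]:rs[i], , drop = FALSE])
  }
  len <- rs - ls + 1
  d_ribo <- R / (len * rep(sizes@n_ribo, each = n))
  d_rna <- M / (len * rep(sizes@n_rna, each = n))
  omega <- d_ribo / d_rna
  mu <- rowMeans(log(omega))
  new("SegmentTree", gene_id = counts@gene_id,
      nodes = data.frame(id = ids, parent = parents, depth = depths,
                         l = ls, r = rs),
      R = R, M = M, d_ribo = d_ribo, d_rna = d_rna, omega = omega,
      mu = mu, sigma = rep(NA_real_, n), group = rep(NA_integer_, n),
      replicate_ids = counts@replicate_ids)
}

#' Build segment trees for a collection of genes
#'
#' @param counts named list of [PositionCounts-class].
#' @param sizes a [LibrarySizes-class].
#' @param cfg a [runConfig()] list.
#' @param exclude gene ids to skip (e.g. dubious or mitochondrial genes,
#'   flagged upstream).
#' @return named list of [SegmentTree-class]; genes failing the root
#'   thresholds are absent.
#' @export
buildSegmentTrees <- function(counts, sizes, cfg = runConfig(),
                              exclude = character()) {
  counts <- counts[setdiff(names(counts), exclude)]
  trees <- lapply(counts, buildSegmentTree, sizes = sizes, cfg = cfg)
  trees[!vapply(trees, is.null, TRUE)]
}

#' Correct the density-dependent bias of the ratio measurements
#'
#' Applies a correction hook to the replicate log-omegas of all segments
#' jointly. The default hook is the identity. The provided reference method
#' (`method = "detrend"`) removes, per replicate, a monotone trend of the
#' deviation of the replicate log-omega from the across-replicate mean
#' against the log mean density: isotonic fits of both signs are computed and
#' the better-fitting one is subtracted, so the correction is symmetric across
#' replicates and leaves `mu`'s across-segment mean structure intact.
#'
#' @param trees named list of [SegmentTree-class] (>= 2 replicates).
#' @param method `"identity"`, `"detrend"`, or a function
#'   `f(log_omega, log_density)` mapping the segments x replicates matrix of
#'   log-omegas (given the segments x replicates matrix of log mean
#'   densities) to an adjusted log-omega matrix.
#' @return the trees with adjusted `omega` and `mu`.
#' @export
correctDensityBias <- function(trees, method = c("identity", "detrend")) {
  if (length(trees) == 0) return(trees)
  nrep <- ncol(trees[[1]]@omega)
  if (nrep < 2) stop("bias correction requires >= 2 replicates")
  lw <- do.call(rbind, lapply(trees, function(tr) log(tr@omega)))
  ld <- do.call(rbind, lapply(trees, function(tr)
    log(sqrt(tr@d_ribo * tr@d_rna))))
  if (is.function(method)) {
    adj <- method(lw, ld)
  } else {
    method <- match.arg(method)
    adj <- if (identical(method, "identity")) lw else detrendLogOmega(lw, ld)
  }
  if (!all(is.finite(adj)))
    stop("bias-correction hook returned non-finite log-omegas")
  idx <- 0L
  for (g in names(trees)) {
    n <- nrow(trees[[g]]@omega)
    block <- adj[idx + seq_len(n), , drop = FALSE]
    trees[[g]]@omega <- exp(block)
    trees[[g]]@mu <- rowMeans(block)
    idx <- idx + n
  }
  trees
}

# Reference bias correction: per replicate, isotonically detrend the
# deviation from the across-replicate mean log-omega against log density.
detrendLogOmega <- function(lw, ld) {
  center <- rowMeans(lw)
  adj <- lw
  for (j in seq_len(ncol(lw))) {
    e <- lw[, j] - center
    x <- ld[, j]
    o <- order(x)
    up <- stats::isoreg(x[o], e[o])
    dn <- stats::isoreg(x[o], -e[o])
    fit <- numeric(length(e))
    if (sum((up$yf - e[o])^2) <= sum((-dn$yf - e[o])^2))
      fit[o] <- up$yf
    else
      fit[o] <- -dn$yf
    adj[, j] <- lw[, j] - fit
  }
  adj
}
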