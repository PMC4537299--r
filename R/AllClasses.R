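#' @useDynLib riboTASEP, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Per-gene, per-codon read counts from a ribosome profiling experiment
#'
#' Holds A-site-assigned ribosome footprint (ribo-seq) counts and
#' centre-assigned mRNA fragment (RNA-seq) counts at codon resolution, for one
#' gene across replicates. Rows are codon positions (1-based, 5' to 3'),
#' columns are replicates.
#'
#' @slot gene_id gene identifier.
#' @slot ribo integer matrix, `n_codons x n_replicates`, footprint reads per codon.
#' @slot rna integer matrix, same shape, mRNA fragment reads per codon.
#' @slot replicate_ids ordered replicate labels.
#'
#' @exportClass PositionCounts
setClass("PositionCounts",
  representation(gene_id = "character", ribo = "matrix", rna = "matrix",
                 replicate_ids = "character"))

setValidity("PositionCounts", function(object) {
  msg <- character()
  if (length(object@gene_id) != 1L) msg <- c(msg, "gene_id must be a single string")
  if (!identical(dim(object@ribo), dim(object@rna)))
    msg <- c(msg, "ribo and rna must have identical dimensions")
  if (ncol(object@ribo) != length(object@replicate_ids))
    msg <- c(msg, "one column per replicate required")
  for (m in list(object@ribo, object@rna)) {
    if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (length(msg)) msg else TRUE
})

#' Total mapped reads per replicate
#'
#' Library sizes used to normalize segment read counts into densities:
#' total ribo-seq (`n_ribo`) and RNA-seq (`n_rna`) reads aligned to all CDSes,
#' one entry per replicate.
#'
#' @slot n_ribo named numeric, total ribo-seq reads per replicate.
#' @slot n_rna named numeric, total RNA-seq reads per replicate.
#' @exportClass LibrarySizes
setClass("LibrarySizes",
  representation(n_ribo = "numeric", n_rna = "numeric"))

setValidity("LibrarySizes", function(object) {
  if (length(object@n_ribo) != length(object@n_rna))
    return("n_ribo and n_rna must have one entry per replicate")
  if (any(object@n_ribo <= 0) || any(object@n_rna <= 0))
    return("library sizes must be positive")
  TRUE
})

#' Multi-scale segment tree of density measurements for one gene
#'
#' Nested `[l, r]` codon segments obtained by recursive balanced bisection of
#' the CDS. Every retained node passes the read-count and segment-length
#' reliability thresholds and carries per-replicate read counts, densities,
#' density ratios `omega`, their log geometric mean `mu`, and (after error
#' model estimation) a length-group shape parameter `sigma`.
#'
#' Nodes are stored flattened in pre-order; `parent` is 0 for the root and the
#' two children of an internal node partition it as `[l, p]`, `[p + 1, r]`.
#'
#' @slot gene_id gene identifier.
#' @slot nodes data.frame with columns `id`, `parent`, `depth`, `l`, `r`.
#' @slot R,M numeric matrices (`n_nodes x n_replicates`) of ribo-/RNA-seq counts.
#' @slot d_ribo,d_rna per-replicate densities (reads per codon per mapped read).
#' @slot omega per-replicate density ratios `d_ribo / d_rna`.
#' @slot mu numeric, per-node mean over replicates of `log(omega)`.
#' @slot sigma numeric, per-node shape parameter (NA until assigned).
#' @slot group integer, per-node length-group index (NA until assigned).
#' @slot replicate_ids ordered replicate labels.
#' @exportClass SegmentTree
setClass("SegmentTree",
  representation(gene_id = "character", nodes = "data.frame",
                 R = "matrix", M = "matrix",
                 d_ribo = "matrix", d_rna = "matrix", omega = "matrix",
                 mu = "numeric", sigma = "numeric", group = "integer",
                 replicate_ids = "character"))

setValidity("SegmentTree", function(object) {
  nd <- object@nodes
  msg <- character()
  need <- c("id", "parent", "depth", "l", "r")
  if (!all(need %in% names(nd))) return("nodes must have id/parent/depth/l/r")
  n <- nrow(nd)
  for (nm in c("R", "M", "d_ribo", "d_rna", "omega"))
    if (nrow(slot(object, nm)) != n)
      msg <- c(msg, sprintf("slot %s must have one row per node", nm))
  if (length(object@mu) != n || length(object@sigma) != n ||
      length(object@group) != n)
    msg <- c(msg, "mu, sigma, group must have one entry per node")
  if (n > 0) {
    if (any(nd$l > nd$r) || any(nd$l < 1))
      msg <- c(msg, "invalid segment bounds")
    kids <- split(seq_len(n), nd$parent)
    for (p in names(kids)) {
      pid <- as.integer(p)
      if (pid == 0L) next
      ch <- kids[[p]]
      if (length(ch) != 2L) {
        msg <- c(msg, "internal nodes must have exactly 2 children")
        next
      }
      ch <- ch[order(nd$l[ch])]
      i <- match(pid, nd$id)
      if (nd$l[ch[1]] != nd$l[i] || nd$r[ch[2]] != nd$r[i] ||
          nd$l[ch[2]] != nd$r[ch[1]] + 1L)
        msg <- c(msg, "children must partition the parent segment")
      if (any(abs(object@R[i, ] - object@R[ch[1], ] - object@R[ch[2], ]) > 1e-8) ||
          any(abs(object@M[i, ] - object@M[ch[1], ] - object@M[ch[2], ]) > 1e-8))
        msg <- c(msg, "parent counts must equal the sum over children")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Codon-specific elongation and termination rates
#'
#' All 64 codon rates (events per unit time); the three stop codons' entries
#' act as termination rates. One codon is marked as fixed: its rate anchors
#' the overall rate scale during fitting (TASEP output is invariant to a
#' common rescaling of all rates, so one rate must be pinned).
#'
#' @slot rates named numeric of length 64 (names are DNA codons, e.g. "GAA").
#' @slot fixed_codon codon whose rate is never optimized (default "GAA").
#' @exportClass CodonRateSet
setClass("CodonRateSet",
  representation(rates = "numeric", fixed_codon = "character"))

setValidity("CodonRateSet", function(object) {
  all_codons <- allCodons()
  missing <- setdiff(all_codons, names(object@rates))
  if (length(missing))
    return(paste("missing codons:", paste(missing, collapse = ", ")))
  if (length(object@rates) != 64L) return("exactly 64 rates required")
  if (any(!is.finite(object@rates)) || any(object@rates <= 0))
    return("all rates must be finite and > 0")
  if (!(object@fixed_codon %in% names(object@rates)))
    return("fixed_codon must be one of the 64 codons")
  TRUE
})

#' A gene as a TASEP lattice
#'
#' A CDS at codon resolution together with its translation kinetics: the codon
#' sequence (the last codon is the stop), the per-site elongation rates derived
#' from a [CodonRateSet] (the stop codon's rate acting as termination rate),
#' and the gene-specific initiation rate `k0`.
#'
#' @slot gene_id gene identifier.
#' @slot codons character vector of S codons.
#' @slot k0 initiation rate (events per unit time; may be NA before assignment).
#' @slot site_rates numeric length S, `k_i` for i = 1..S.
#' @exportClass GeneModel
setClass("GeneModel",
  representation(gene_id = "character", codons = "character",
                 k0 = "numeric", site_rates = "numeric"))

setValidity("GeneModel", function(object) {
  S <- length(object@codons)
  if (length(object@site_rates) != S)
    return("site_rates must have one entry per codon")
  if (any(!is.finite(object@site_rates)) || any(object@site_rates <= 0))
    return("site rates must be positive")
  if (!is.na(object@k0) && object@k0 < 0) return("k0 must be >= 0")
  TRUE
})

#' Result of a TASEP simulation
#'
#' Steady-state estimates from a continuous-time Monte Carlo run: per-position
#' A-site occupancy fractions `n_i = T_i / T`, the protein production rate
#' `J = F / T`, the simulated time `T` (post burn-in), the termination count
#' `F`, the number of state-changing events executed, the number of attempted
#' events, and a convergence flag.
#'
#' @slot n numeric length S, occupancy fractions in [0, 1].
#' @slot J protein production rate (per unit time).
#' @slot T total simulated time after burn-in.
#' @slot F number of terminations after burn-in.
#' @slot steps state-changing events executed.
#' @slot attempts attempted events (incl. blocked ones) represented.
#' @slot converged TRUE if the early-stopping criterion fired.
#' @slot seed RNG seed used.
#' @exportClass SimResult
setClass("SimResult",
  representation(n = "numeric", J = "numeric", T = "numeric", F = "numeric",
                 steps = "numeric", attempts = "numeric",
                 converged = "logical", seed = "integer"))

setValidity("SimResult", function(object) {
  if (any(object@n < -1e-12) || any(object@n > 1 + 1e-12))
    return("occupancies must lie in [0, 1]")
  if (object@T < 0) return("T must be >= 0")
  TRUE
})

#' Length-grouped log-normal error model
#'
#' Segments from all genes are pooled into length groups ("equal-content":
#' group edges at quantiles of the segment-length distribution, adjusted so
#' every distinct length maps to exactly one group). Each group carries a
#' shape parameter `sigma` (natural-log scale) of the density-ratio
#' measurement error, estimated from inter-replicate errors.
#'
#' @slot edges numeric length `n_groups + 1`; group k covers lengths in
#'   `[edges[k], edges[k+1])`.
#' @slot sigma per-group shape parameter, > 0.
#' @slot n_segments per-group segment counts used in estimation.
#' @exportClass LengthGroupModel
setClass("LengthGroupModel",
  representation(edges = "numeric", sigma = "numeric",
                 n_segments = "integer"))

setValidity("LengthGroupModel", function(object) {
  k <- length(object@sigma)
  if (length(object@edges) != k + 1L)
    return("edges must have length n_groups + 1")
  if (is.unsorted(object@edges, strictly = TRUE))
    return("edges must be strictly increasing")
  if (any(object@sigma <= 0)) return("sigma must be positive")
  TRUE
})
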