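#' @rdname riboTASEP-accessors
#' @export
setMethod("geneId", "PositionCounts", function(object) object@gene_id)
#' @rdname riboTASEP-accessors
#' @export
setMethod("geneId", "SegmentTree", function(object) object@gene_id)
#' @rdname riboTASEP-accessors
#' @export
setMethod("geneId", "GeneModel", function(object) object@gene_id)

#' @rdname riboTASEP-accessors
#' @export
setMethod("nCodons", "PositionCounts", function(object) nrow(object@ribo))
#' @rdname riboTASEP-accessors
#' @export
setMethod("nCodons", "GeneModel", function(object) length(object@codons))

#' @rdname riboTASEP-accessors
#' @export
setMethod("riboCounts", "PositionCounts", function(object) object@ribo)
#' @rdname riboTASEP-accessors
#' @export
setMethod("rnaCounts", "PositionCounts", function(object) object@rna)
#' @rdname riboTASEP-accessors
#' @export
setMethod("replicateIds", "PositionCounts", function(object) object@replicate_ids)
#' @rdname riboTASEP-accessors
#' @export
setMethod("replicateIds", "SegmentTree", function(object) object@replicate_ids)

#' @rdname riboTASEP-accessors
#' @export
setMethod("riboCounts", "LibrarySizes", function(object) object@n_ribo)
#' @rdname riboTASEP-accessors
#' @export
setMethod("rnaCounts", "LibrarySizes", function(object) object@n_rna)

#' @rdname riboTASEP-accessors
#' @export
setMethod("nodeTable", "SegmentTree", function(object) {
  nd <- object@nodes
  nd$length <- nd$r - nd$l + 1L
  nd$mu <- object@mu
  nd$sigma <- object@sigma
  nd$group <- object@group
  nd
})
#' @rdname riboTASEP-accessors
#' @export
setMethod("nodeOmega", "SegmentTree", function(object) object@omega)
#' @rdname riboTASEP-accessors
#' @export
setMethod("nodeMu", "SegmentTree", function(object) object@mu)
#' @rdname riboTASEP-accessors
#' @export
setMethod("nodeSigma", "SegmentTree", function(object) object@sigma)

#' @rdname riboTASEP-accessors
#' @export
setMethod("codonRates", "CodonRateSet", function(object) object@rates)
#' @rdname riboTASEP-accessors
#' @export
setMethod("fixedCodon", "CodonRateSet", function(object) object@fixed_codon)

#' @rdname riboTASEP-accessors
#' @export
setMethod("initiationRate", "GeneModel", function(object) object@k0)
#' @rdname riboTASEP-accessors
#' @export
setMethod("siteRates", "GeneModel", function(object) object@site_rates)

#' @rdname riboTASEP-accessors
#' @export
setMethod("occupancy", "SimResult", function(object) object@n)
#' @rdname riboTASEP-accessors
#' @export
setMethod("productionRate", "SimResult", function(object) object@J)

#' @rdname riboTASEP-accessors
#' @export
setMethod("groupEdges", "LengthGroupModel", function(object) object@edges)
#' @rdname riboTASEP-accessors
#' @export
setMethod("groupSigma", "LengthGroupModel", function(object) object@sigma)

setMethod("show", "PositionCounts", function(object) {
  cat(sprintf("PositionCounts: %s, %d codons, %d replicates (%s)\n",
              object@gene_id, nrow(object@ribo), ncol(object@ribo),
              paste(object@replicate_ids, collapse = ", ")))
  cat(sprintf("  ribo reads: %s | rna reads: %s\n",
              paste(colSums(object@ribo), collapse = "/"),
              paste(colSums(object@rna), collapse = "/")))
})

setMethod("show", "SegmentTree", function(object) {
  nd <- object@nodes
  cat(sprintf("SegmentTree: %s, %d nodes, depth %d, CDS [%d, %d]\n",
              object@gene_id, nrow(nd), max(nd$depth), min(nd$l), max(nd$r)))
})

setMethod("show", "CodonRateSet", function(object) {
  cat(sprintf("CodonRateSet: 64 rates in [%.4g, %.4g], fixed codon %s (%.4g)\n",
              min(object@rates), max(object@rates), object@fixed_codon,
              object@rates[[object@fixed_codon]]))
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel: %s, S = %d codons, k0 = %.4g\n",
              object@gene_id, length(object@codons), object@k0))
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf(
    "SimResult: mean occupancy %.4g, J = %.4g, T = %.4g, F = %g, %s\n",
    mean(object@n), object@J, object@T, object@F,
    if (object@converged) "converged" else "budget-limited"))
})

setMethod("show", "LengthGroupModel", function(object) {
  cat(sprintf("LengthGroupModel: %d groups\n", length(object@sigma)))
  cat(sprintf("  edges: %s\n", paste(object@edges, collapse = ", ")))
  cat(sprintf("  sigma: %s\n",
              paste(signif(object@sigma, 4), collapse = ", ")))
})
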