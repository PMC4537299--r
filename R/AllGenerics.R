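#' @name riboTASEP-accessors
#' @title Accessors for riboTASEP classes
#' @description Slot access for the package's S4 classes goes through these
#'   generics; slots themselves are internal.
#' @param object an object of the documented class.
NULL

#' @rdname riboTASEP-accessors
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("nCodons", function(object) standardGeneric("nCodons"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("riboCounts", function(object) standardGeneric("riboCounts"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("rnaCounts", function(object) standardGeneric("rnaCounts"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("replicateIds", function(object) standardGeneric("replicateIds"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("nodeTable", function(object) standardGeneric("nodeTable"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("nodeOmega", function(object) standardGeneric("nodeOmega"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("nodeMu", function(object) standardGeneric("nodeMu"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("nodeSigma", function(object) standardGeneric("nodeSigma"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("codonRates", function(object) standardGeneric("codonRates"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("fixedCodon", function(object) standardGeneric("fixedCodon"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("initiationRate", function(object) standardGeneric("initiationRate"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("siteRates", function(object) standardGeneric("siteRates"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("productionRate", function(object) standardGeneric("productionRate"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("groupEdges", function(object) standardGeneric("groupEdges"))

#' @rdname riboTASEP-accessors
#' @export
setGeneric("groupSigma", function(object) standardGeneric("groupSigma"))
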