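#' @name tknet-accessors
#' @title Accessors for tknet classes
#' @description Slot access for \linkS4class{MultiOmicsDataset},
#'   \linkS4class{TranskingdomNetwork} and \linkS4class{TopologyReport}
#'   goes through these generics; slots are internal.
#' @param x a tknet object.
#' @param layer character layer name.
#' @return See the individual methods.
NULL

#' @rdname tknet-accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname tknet-accessors
#' @export
setGeneric("assayLayer", function(x, layer) standardGeneric("assayLayer"))

#' @rdname tknet-accessors
#' @export
setGeneric("layerInfo", function(x) standardGeneric("layerInfo"))

#' @rdname tknet-accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname tknet-accessors
#' @export
setGeneric("dietLabels", function(x) standardGeneric("dietLabels"))

#' @rdname tknet-accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname tknet-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname tknet-accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname tknet-accessors
#' @export
setGeneric("constructionReport", function(x) standardGeneric("constructionReport"))

#' @rdname tknet-accessors
#' @export
setGeneric("coupledPairs", function(x) standardGeneric("coupledPairs"))

#' @rdname tknet-accessors
#' @export
setGeneric("dietEffectSign", function(x) standardGeneric("dietEffectSign"))

#' @rdname tknet-accessors
#' @export
setGeneric("factorLoadings", function(x) standardGeneric("factorLoadings"))

#' @rdname tknet-accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' Nodes of a network belonging to given layers
#'
#' @param x a \linkS4class{TranskingdomNetwork}.
#' @param layers character vector of layer names.
#' @return character vector of node ids.
#' @export
setGeneric("layerNodes", function(x, layers) standardGeneric("layerNodes"))
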