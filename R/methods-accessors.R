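#' @rdname tknet-accessors
#' @aliases layerNames,MultiOmicsDataset-method
setMethod("layerNames", "MultiOmicsDataset", function(x) names(x@layers))

#' @rdname tknet-accessors
#' @aliases assayLayer,MultiOmicsDataset-method
setMethod("assayLayer", "MultiOmicsDataset", function(x, layer) {
  if (!layer %in% names(x@layers))
    stop("unknown layer '", layer, "'; available: ",
         paste(names(x@layers), collapse = ", "))
  x@layers[[layer]]
})

#' @rdname tknet-accessors
#' @aliases layerInfo,MultiOmicsDataset-method
setMethod("layerInfo", "MultiOmicsDataset", function(x) x@layerInfo)

#' @rdname tknet-accessors
#' @aliases sampleData,MultiOmicsDataset-method
setMethod("sampleData", "MultiOmicsDataset", function(x) x@sampleData)

#' @rdname tknet-accessors
#' @aliases dietLabels,MultiOmicsDataset-method
setMethod("dietLabels", "MultiOmicsDataset", function(x) {
  factor(x@sampleData$diet, levels = c("NC", "HFD"))
})

#' @rdname tknet-accessors
#' @aliases nodeTable,TranskingdomNetwork-method
setMethod("nodeTable", "TranskingdomNetwork", function(x) x@nodes)

#' @rdname tknet-accessors
#' @aliases edgeTable,TranskingdomNetwork-method
setMethod("edgeTable", "TranskingdomNetwork", function(x) x@edges)

#' @rdname tknet-accessors
#' @aliases asIgraph,TranskingdomNetwork-method
setMethod("asIgraph", "TranskingdomNetwork", function(x) x@graph)

#' @rdname tknet-accessors
#' @aliases constructionReport,TranskingdomNetwork-method
setMethod("constructionReport", "TranskingdomNetwork", function(x) x@report)

#' @rdname tknet-accessors
#' @aliases coupledPairs,SyntheticTruth-method
setMethod("coupledPairs", "SyntheticTruth", function(x) x@coupledPairs)

#' @rdname tknet-accessors
#' @aliases dietEffectSign,SyntheticTruth-method
setMethod("dietEffectSign", "SyntheticTruth", function(x) x@dietEffectSign)

#' @rdname tknet-accessors
#' @aliases factorLoadings,SyntheticTruth-method
setMethod("factorLoadings", "SyntheticTruth", function(x) x@factorLoadings)

#' @rdname tknet-accessors
#' @aliases members,Subnetwork-method
setMethod("members", "Subnetwork", function(x) x@members)

#' @rdname layerNodes
#' @aliases layerNodes,TranskingdomNetwork-method
setMethod("layerNodes", "TranskingdomNetwork", function(x, layers) {
  x@nodes$node[x@nodes$layer %in% layers]
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  design: 2 diets x %d samples/group, 2 compartments\n",
              object@nPerGroup))
  cat(sprintf("  features: %d + %d microbes | %d genes | %d + %d metabolites | %d phenotypes\n",
              object@nMicrobesA, object@nMicrobesB, object@nGenes,
              object@nMetabSerum, object@nMetabLiver, object@nPhenotypes))
  cat(sprintf("  factors: %d, loadings A=%.2f B=%.2f host=%.2f\n",
              object@nFactors, object@loadingA, object@loadingB,
              object@loadingHost))
  cat(sprintf("  diet effect SD=%.2f, depth=%d, noise SD=%.2f, seed=%d\n",
              object@dietEffectSD, object@sequencingDepth, object@noiseSD,
              object@seed))
})

setMethod("show", "MultiOmicsDataset", function(object) {
  cat(sprintf("MultiOmicsDataset: %d layers, %d samples\n",
              length(object@layers), nrow(object@sampleData)))
  for (nm in names(object@layers))
    cat(sprintf("  %-12s %4d features (%s%s)\n", nm, nrow(object@layers[[nm]]),
                object@layerInfo$kind[object@layerInfo$layer == nm],
                ifelse(is.na(object@layerInfo$compartment[object@layerInfo$layer == nm]),
                       "", paste0(", ",
                       object@layerInfo$compartment[object@layerInfo$layer == nm]))))
  cat("  diet groups:", paste(names(table(object@sampleData$diet)),
                              table(object@sampleData$diet),
                              sep = "=", collapse = " "), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d coupled microbe-host pairs, %d features with planted loadings\n",
              nrow(object@coupledPairs), nrow(object@factorLoadings)))
})

setMethod("show", "TranskingdomNetwork", function(object) {
  cat(sprintf("TranskingdomNetwork: %d nodes, %d edges\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
  if (nrow(object@nodes)) {
    tab <- table(object@nodes$layer)
    cat("  nodes by layer:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  rep <- object@report
  if (length(rep))
    cat(sprintf("  candidates=%d retained=%d PUC=%s\n",
                rep$n_candidates, rep$n_retained,
                ifelse(is.na(rep$puc), "NA", sprintf("%.3f", rep$puc))))
})

setMethod("show", "TopologyReport", function(object) {
  cat("TopologyReport\n")
  rt <- object@retention$table
  if (!is.null(rt))
    for (i in seq_len(nrow(rt)))
      cat(sprintf("  retention %-6s %d/%d = %.2f\n", rt$compartment[i],
                  rt$n_retained[i], rt$n_input[i], rt$proportion[i]))
  if (!is.null(object@retention$chisq))
    cat(sprintf("  retention chi-square = %.3f, p = %.3g\n",
                object@retention$chisq$statistic, object@retention$chisq$p))
  if (nrow(object@edgeCounts))
    for (i in seq_len(nrow(object@edgeCounts)))
      cat(sprintf("  edges %-6s -> %-12s %d\n", object@edgeCounts$compartment[i],
                  object@edgeCounts$host_layer[i], object@edgeCounts$n_edges[i]))
  for (nm in names(object@closeness)) {
    cl <- object@closeness[[nm]]
    cat(sprintf("  avg shortest path -> %s: %s vs %s (Wilcoxon p = %.3g)\n", nm,
                formatC(cl$mean1, digits = 3, format = "f"),
                formatC(cl$mean2, digits = 3, format = "f"),
                cl$wilcoxon$p))
  }
})

setMethod("show", "Subnetwork", function(object) {
  cat(sprintf("Subnetwork %d (%s): %d nodes, %d edges, density %.3f, modularity %.3f\n",
              object@id, object@layer, length(object@members), object@nEdges,
              object@density, object@modularity))
})
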