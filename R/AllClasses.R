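#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Simulation configuration for paired-compartment multi-omics data
#'
#' Holds every knob of the synthetic generator: the 2 diet groups x 2
#' gut compartments design, feature counts per omic layer, the latent
#' factor structure that plants cross-kingdom coupling, and the RNG seed.
#'
#' @slot nPerGroup integer, samples per diet group (the full design has
#'   \code{2 * nPerGroup} animals, each contributing both compartments).
#' @slot nMicrobesA,nMicrobesB integer, genus counts for compartment A
#'   (ileum) and B (colon); the two compartments share a genus namespace.
#' @slot nGenes,nMetabSerum,nMetabLiver,nPhenotypes integer, host feature
#'   counts per layer.
#' @slot nFactors integer, number of latent factors.
#' @slot loadingA,loadingB numeric, |loading| of compartment A / B microbes
#'   on their factor; \code{loadingA > loadingB} plants the topological
#'   asymmetry the pipeline is meant to detect.
#' @slot loadingHost numeric, |loading| of host features on their factor.
#' @slot dietEffectSD numeric, scale (latent SD units) of diet-effect
#'   magnitudes.
#' @slot sequencingDepth integer, multinomial total count per microbial
#'   sample.
#' @slot noiseSD numeric, residual latent noise SD.
#' @slot seed integer RNG seed.
#' @seealso [simulationConfig()], [generateDataset()]
#' @export
setClass("SimulationConfig",
  representation(
    nPerGroup = "integer", nMicrobesA = "integer", nMicrobesB = "integer",
    nGenes = "integer", nMetabSerum = "integer", nMetabLiver = "integer",
    nPhenotypes = "integer", nFactors = "integer",
    loadingA = "numeric", loadingB = "numeric", loadingHost = "numeric",
    dietEffectSD = "numeric", sequencingDepth = "integer",
    noiseSD = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cnt <- c(
    nMicrobesA = object@nMicrobesA, nMicrobesB = object@nMicrobesB,
    nGenes = object@nGenes, nMetabSerum = object@nMetabSerum,
    nMetabLiver = object@nMetabLiver, nPhenotypes = object@nPhenotypes,
    nFactors = object@nFactors
  )
  if (any(cnt < 1L)) {
    msg <- c(msg, paste("all feature/factor counts must be >= 1; offending:",
                        paste(names(cnt)[cnt < 1L], collapse = ", ")))
  }
  if (object@nPerGroup < 4L) msg <- c(msg, "nPerGroup must be >= 4")
  if (object@loadingA < 0 || object@loadingB < 0 || object@loadingHost < 0) {
    msg <- c(msg, "loadings must be >= 0")
  }
  if (object@sequencingDepth < 100L) msg <- c(msg, "sequencingDepth must be >= 100")
  if (object@noiseSD <= 0) msg <- c(msg, "noiseSD must be > 0")
  if (object@dietEffectSD < 0) msg <- c(msg, "dietEffectSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Paired-compartment multi-omics dataset
#'
#' One feature-by-sample matrix per omic layer, sharing a single sample
#' set, plus layer annotation (kind, compartment) and sample metadata
#' (diet group). Microbial layers hold non-negative integer counts;
#' host layers are continuous.
#'
#' @slot layers named list of numeric matrices (features x samples),
#'   all with identical column names.
#' @slot layerInfo data.frame with columns \code{layer}, \code{kind}
#'   (microbe/gene/metabolite/phenotype) and \code{compartment}
#'   (ileum/colon or NA for host layers).
#' @slot sampleData data.frame with columns \code{sample_id} and
#'   \code{diet} (NC or HFD).
#' @seealso [generateDataset()], [layerNames()], [assayLayer()]
#' @export
setClass("MultiOmicsDataset",
  representation(layers = "list", layerInfo = "data.frame",
                 sampleData = "data.frame")
)

setValidity("MultiOmicsDataset", function(object) {
  msg <- character()
  if (!length(object@layers)) return("dataset has no layers")
  if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)))
    msg <- c(msg, "layers must be uniquely named")
  sids <- object@sampleData$sample_id
  for (nm in names(object@layers)) {
    m <- object@layers[[nm]]
    if (!is.matrix(m) || !is.numeric(m)) {
      msg <- c(msg, sprintf("layer '%s' is not a numeric matrix", nm))
      next
    }
    if (!identical(colnames(m), sids))
      msg <- c(msg, sprintf("layer '%s' columns do not match sampleData sample_id", nm))
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      msg <- c(msg, sprintf("layer '%s' needs unique feature rownames", nm))
  }
  if (!all(c("layer", "kind", "compartment") %in% names(object@layerInfo)))
    msg <- c(msg, "layerInfo needs columns layer, kind, compartment")
  else if (!setequal(object@layerInfo$layer, names(object@layers)))
    msg <- c(msg, "layerInfo layers do not match names(layers)")
  if (!all(c("sample_id", "diet") %in% names(object@sampleData)))
    msg <- c(msg, "sampleData needs columns sample_id, diet")
  else if (!all(object@sampleData$diet %in% c("NC", "HFD")))
    msg <- c(msg, "diet must be NC or HFD")
  mic <- object@layerInfo$layer[object@layerInfo$kind == "microbe"]
  for (nm in intersect(mic, names(object@layers))) {
    m <- object@layers[[nm]]
    if (is.matrix(m) && is.numeric(m) &&
        (any(m < 0) || any(m != round(m))))
      msg <- c(msg, sprintf("microbial layer '%s' must hold non-negative integer counts", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Planted ground truth of a synthetic dataset
#'
#' @slot coupledPairs data.frame with columns \code{microbe}, \code{host}
#'   (node ids, \code{layer:feature}) and \code{sign} (+1/-1), the expected
#'   correlation sign: the product of the pair's factor-loading signs.
#' @slot dietEffectSign named numeric (+1/-1/0) per node id.
#' @slot factorLoadings data.frame with columns \code{node}, \code{factor},
#'   \code{loading}.
#' @export
setClass("SyntheticTruth",
  representation(coupledPairs = "data.frame", dietEffectSign = "numeric",
                 factorLoadings = "data.frame")
)

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (!all(c("microbe", "host", "sign") %in% names(object@coupledPairs)))
    msg <- c(msg, "coupledPairs needs columns microbe, host, sign")
  else if (nrow(object@coupledPairs) &&
           !all(object@coupledPairs$sign %in% c(-1, 1)))
    msg <- c(msg, "coupled-pair signs must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' Transkingdom association network
#'
#' Undirected network over differential features of all layers, with
#' edges retained by the meta-analytic filter (per-diet-group correlation
#' sign consistency, Fisher-combined p under BH FDR control, optional
#' fold-change coherence).
#'
#' @slot graph igraph object (undirected, simple).
#' @slot nodes data.frame: \code{node}, \code{layer}, \code{kind},
#'   \code{compartment}, \code{lfc}, \code{q} (differential FDR).
#' @slot edges data.frame of retained edges with per-group correlations,
#'   Fisher-combined p, BH q, sign and coherence flag.
#' @slot report list: candidate/retained counts, PUC (proportion of
#'   unexpected correlations), input feature counts per layer, isolated
#'   (screened-in but edgeless) features, skipped constant pairs.
#' @seealso [buildNetwork()], [nodeTable()], [edgeTable()], [asIgraph()]
#' @export
setClass("TranskingdomNetwork",
  representation(graph = "ANY", nodes = "data.frame", edges = "data.frame",
                 report = "list")
)

setValidity("TranskingdomNetwork", function(object) {
  msg <- character()
  if (!igraph::is_igraph(object@graph)) msg <- c(msg, "graph must be an igraph")
  else {
    if (igraph::any_loop(object@graph)) msg <- c(msg, "network must not contain self-edges")
    if (igraph::vcount(object@graph) &&
        any(igraph::degree(object@graph) == 0))
      msg <- c(msg, "network must not contain isolated nodes")
  }
  if (length(msg)) msg else TRUE
})

#' Topology comparison report
#'
#' Per-compartment retention, cross-layer edge counts, degree/power-law
#' diagnostics, BIBC hub table and set-to-set shortest-path closeness
#' with Wilcoxon comparisons; the package's rendering of the two-
#' compartment verdict.
#'
#' @slot retention list: per-compartment counts/proportions and the
#'   chi-square comparison.
#' @slot edgeCounts data.frame: compartment x host layer edge counts.
#' @slot degree list: degree histogram, power-law MLE exponent, log-log R2.
#' @slot bibc list: per (compartment, host layer) BIBC score tables and
#'   top-fraction compartment shares.
#' @slot closeness list: per host layer, both compartments' path-length
#'   distributions, means, unreachable counts and the Wilcoxon test.
#' @export
setClass("TopologyReport",
  representation(retention = "list", edgeCounts = "data.frame",
                 degree = "list", bibc = "list", closeness = "list")
)

#' A dense subnetwork (community) of one omic layer
#'
#' @slot id integer rank (1 = densest).
#' @slot members character node ids.
#' @slot nEdges integer internal edge count.
#' @slot density numeric internal density 2e / (n (n - 1)).
#' @slot modularity numeric, this community's contribution to the
#'   layer-subgraph modularity.
#' @slot layer character, the layer tag all members carry.
#' @export
setClass("Subnetwork",
  representation(id = "integer", members = "character", nEdges = "integer",
                 density = "numeric", modularity = "numeric",
                 layer = "character")
)

setValidity("Subnetwork", function(object) {
  if (object@density < 0 || object@density > 1) "density must lie in [0, 1]" else TRUE
})
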