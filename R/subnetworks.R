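#' Detect high-density subnetworks within one omic layer
#'
#' Runs Louvain modularity optimization on the layer-induced subgraph
#' (e.g. the liver-gene co-association network), discards communities
#' below \code{minSize}, ranks the rest by internal density
#' \code{2e / (n (n - 1))} and returns the top \code{k}. Louvain is
#' order-sensitive, so the RNG seed is fixed explicitly; the same seed
#' yields the same membership.
#'
#' @param network \linkS4class{TranskingdomNetwork}.
#' @param layer layer tag whose induced subgraph is searched (default
#'   "genes").
#' @param k number of subnetworks to return (default 2).
#' @param minSize minimum community size kept (default 10).
#' @param seed RNG seed for the Louvain pass (default 1).
#' @return list of \linkS4class{Subnetwork}; fewer than \code{k} with a
#'   warning if not enough qualifying communities exist.
#' @export
detectDenseSubnetworks <- function(network, layer = "genes", k = 2,
                                   minSize = 10, seed = 1) {
  stopifnot(is(network, "TranskingdomNetwork"))
  nodes <- layerNodes(network, layer)
  if (length(nodes) < 2 * minSize)
    stop("layer-induced subgraph too small: ", length(nodes),
         " nodes, need >= ", 2 * minSize)
  sg <- igraph::induced_subgraph(asIgraph(network), nodes)
  set.seed(seed)
  comm <- igraph::cluster_louvain(sg)
  memb <- igraph::membership(comm)
  m <- igraph::ecount(sg)

  subs <- list()
  for (cid in unique(memb)) {
    mem <- names(memb)[memb == cid]
    if (length(mem) < minSize) next
    csub <- igraph::induced_subgraph(sg, mem)
    e <- igraph::ecount(csub)
    n <- length(mem)
    dens <- if (n > 1) 2 * e / (n * (n - 1)) else 0
    degSum <- sum(igraph::degree(sg, mem))
    modc <- if (m > 0) e / m - (degSum / (2 * m))^2 else 0
    subs[[length(subs) + 1L]] <- list(members = sort(mem), nEdges = e,
                                      density = dens, modularity = modc)
  }
  if (!length(subs)) {
    warning("no community of size >= ", minSize, " found")
    return(list())
  }
  ord <- order(vapply(subs, `[[`, numeric(1), "density"), decreasing = TRUE)
  subs <- subs[ord]
  if (length(subs) < k)
    warning("only ", length(subs), " qualifying subnetwork(s) found, asked for ", k)
  subs <- subs[seq_len(min(k, length(subs)))]
  lapply(seq_along(subs), function(i)
    new("Subnetwork", id = i, members = subs[[i]]$members,
        nEdges = as.integer(subs[[i]]$nEdges), density = subs[[i]]$density,
        modularity = subs[[i]]$modularity, layer = layer))
}

#' Closeness of a compartment's microbes to a subnetwork
#'
#' Shortest-path distribution from a compartment's microbial nodes to
#' the members of a dense subnetwork, measured on the FULL network (a
#' microbe may reach a gene module through a metabolite); delegates to
#' [setCloseness()].
#'
#' @param network \linkS4class{TranskingdomNetwork}.
#' @param compartmentSet character, the compartment's microbial node ids.
#' @param subnetwork a \linkS4class{Subnetwork} (or character member
#'   vector).
#' @return as [setCloseness()].
#' @export
subnetworkCloseness <- function(network, compartmentSet, subnetwork) {
  mem <- if (is(subnetwork, "Subnetwork")) members(subnetwork)
         else as.character(subnetwork)
  setCloseness(network, compartmentSet, mem)
}
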