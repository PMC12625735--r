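#' Fisher's method for combining independent p-values
#'
#' \code{X = -2 sum ln p_i} referred to a chi-square distribution with
#' \code{2k} degrees of freedom (upper tail). Used to combine the
#' per-diet-group correlation p-values of a candidate edge.
#'
#' @param p numeric vector of p-values in (0, 1]. Zeros are clamped to
#'   the smallest positive double with a warning; values above 1 are an
#'   error.
#' @return the combined p-value (single number).
#' @examples
#' fisherCombine(c(0.05, 0.05))
#' @export
fisherCombine <- function(p) {
  if (!length(p)) stop("need at least one p-value")
  if (any(is.na(p))) stop("p-values must not be missing")
  if (any(p > 1)) stop("p-values must be <= 1")
  if (any(p < 0)) stop("p-values must be >= 0")
  if (any(p == 0)) {
    warning("p-value(s) of 0 clamped to smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

# Spearman/Pearson correlations + t-approximation p-values between all
# rows of a matrix within one sample subset. Returns list(r, p, n).
.groupCor <- function(values, cols, method) {
  x <- values[, cols, drop = FALSE]
  n <- ncol(x)
  if (n < 4L) stop("need >= 4 samples per diet group, got ", n)
  if (method == "spearman")
    x <- t(apply(x, 1L, rank))  # average ranks on ties
  r <- suppressWarnings(stats::cor(t(x)))
  r[!is.finite(r)] <- NA  # constant feature in this group
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pv[!is.na(r) & abs(r) >= 1] <- 0
  list(r = r, p = pv, n = n)
}

#' Per-diet-group pairwise correlations over screened features
#'
#' For every unordered feature pair, Spearman (default) or Pearson
#' correlation and its t-approximation p-value are computed separately
#' within the NC and HFD samples. Pairs of microbes from different
#' compartments are excluded when \code{excludeCrossCompartment} is TRUE
#' (the compartments are analyzed as side-by-side networks against the
#' host layers, not against each other); all other within- and
#' cross-layer pairs are kept. Pairs where either feature is constant
#' within a group are skipped and logged.
#'
#' @param values features x samples matrix (rownames = node ids).
#' @param dietLabels factor/character, NC/HFD per sample.
#' @param nodeInfo data.frame with columns \code{node}, \code{kind},
#'   \code{compartment}, aligned with rownames of \code{values}.
#' @param method "spearman" (default) or "pearson".
#' @param excludeCrossCompartment drop microbe_A x microbe_B pairs
#'   (default TRUE).
#' @return data.frame of candidate edges: node_a, node_b, r_NC, r_HFD,
#'   p_NC, p_HFD, combined_p; attribute \code{skipped} holds the number
#'   of constant-feature pairs dropped.
#' @export
pairwiseCorrelations <- function(values, dietLabels, nodeInfo,
                                 method = c("spearman", "pearson"),
                                 excludeCrossCompartment = TRUE) {
  method <- match.arg(method)
  diet <- factor(dietLabels, levels = c("NC", "HFD"))
  if (any(is.na(diet))) stop("dietLabels must be NC or HFD")
  if (!identical(nodeInfo$node, rownames(values)))
    stop("nodeInfo$node must match rownames(values) in order")
  nf <- nrow(values)
  if (nf < 2L) stop("need at least two features")

  gNC <- .groupCor(values, diet == "NC", method)
  gHF <- .groupCor(values, diet == "HFD", method)

  idx <- which(upper.tri(matrix(0, nf, nf)), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  if (excludeCrossCompartment) {
    micro <- nodeInfo$kind == "microbe"
    cross <- micro[a] & micro[b] &
      !is.na(nodeInfo$compartment[a]) & !is.na(nodeInfo$compartment[b]) &
      nodeInfo$compartment[a] != nodeInfo$compartment[b]
    a <- a[!cross]; b <- b[!cross]
  }
  rNC <- gNC$r[cbind(a, b)]; rHF <- gHF$r[cbind(a, b)]
  pNC <- gNC$p[cbind(a, b)]; pHF <- gHF$p[cbind(a, b)]
  skip <- is.na(rNC) | is.na(rHF)
  out <- data.frame(
    node_a = nodeInfo$node[a][!skip], node_b = nodeInfo$node[b][!skip],
    r_NC = rNC[!skip], r_HFD = rHF[!skip],
    p_NC = pNC[!skip], p_HFD = pHF[!skip],
    stringsAsFactors = FALSE
  )
  pn <- pmax(out$p_NC, .Machine$double.xmin)
  ph <- pmax(out$p_HFD, .Machine$double.xmin)
  out$combined_p <- stats::pchisq(-2 * (log(pn) + log(ph)), df = 4,
                                  lower.tail = FALSE)
  attr(out, "skipped") <- sum(skip)
  out
}

#' Filter candidate edges into a transkingdom network
#'
#' Retains candidate edges that are (i) sign-consistent: the NC and HFD
#' correlations have the same nonzero sign; (ii) significant: BH q of the
#' Fisher-combined p (adjusted jointly across all candidates) is below
#' \code{fdr}; and (iii), when \code{requireCoherence}, coherent: the
#' correlation sign equals the product of the two nodes' fold-change
#' signs. PUC — the proportion of unexpected correlations — is the
#' fraction of edges passing (i)+(ii) that violate (iii); it is reported
#' whether or not coherence is enforced.
#'
#' @param candidates data.frame from [pairwiseCorrelations()].
#' @param nodeInfo data.frame: \code{node}, \code{layer}, \code{kind},
#'   \code{compartment}, \code{lfc}, \code{q} for every screened feature
#'   (network nodes get these as attributes; screened features without a
#'   retained edge are reported as isolated).
#' @param fdr edge FDR threshold (default 0.05).
#' @param requireCoherence drop incoherent edges (default TRUE).
#' @return a \linkS4class{TranskingdomNetwork}.
#' @export
filterEdges <- function(candidates, nodeInfo, fdr = 0.05,
                        requireCoherence = TRUE) {
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  need <- c("node", "layer", "kind", "compartment", "lfc", "q")
  if (!all(need %in% names(nodeInfo)))
    stop("nodeInfo needs columns ", paste(need, collapse = ", "))
  if (!nrow(candidates)) {
    warning("empty candidate list; returning empty network")
    return(.newNetwork(candidates[0, ], nodeInfo, n_candidates = 0L,
                       puc = NA_real_, skipped = 0L))
  }
  missingNodes <- setdiff(unique(c(candidates$node_a, candidates$node_b)),
                          nodeInfo$node)
  if (length(missingNodes))
    stop("candidates reference nodes absent from nodeInfo: ",
         paste(utils::head(missingNodes, 3), collapse = ", "))

  cand <- candidates
  cand$q <- stats::p.adjust(cand$combined_p, method = "BH")
  sNC <- sign(cand$r_NC); sHF <- sign(cand$r_HFD)
  consistent <- sNC == sHF & sNC != 0
  cand$sign <- ifelse(consistent, sNC, 0)
  lfcSign <- stats::setNames(sign(nodeInfo$lfc), nodeInfo$node)
  cand$coherent <- cand$sign ==
    lfcSign[cand$node_a] * lfcSign[cand$node_b] & cand$sign != 0
  sig <- consistent & !is.na(cand$q) & cand$q < fdr
  puc <- if (any(sig)) mean(!cand$coherent[sig]) else NA_real_
  keep <- if (requireCoherence) sig & cand$coherent else sig
  .newNetwork(cand[keep, , drop = FALSE], nodeInfo,
              n_candidates = nrow(candidates), puc = puc,
              skipped = attr(candidates, "skipped") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.newNetwork <- function(edges, nodeInfo, n_candidates, puc, skipped) {
  rownames(edges) <- NULL
  usedNodes <- unique(c(edges$node_a, edges$node_b))
  nodes <- nodeInfo[nodeInfo$node %in% usedNodes, , drop = FALSE]
  rownames(nodes) <- NULL
  g <- igraph::graph_from_data_frame(
    d = edges[, intersect(c("node_a", "node_b", "r_NC", "r_HFD", "combined_p",
                            "q", "sign", "coherent"), names(edges)),
              drop = FALSE],
    directed = FALSE, vertices = nodes
  )
  inputPerLayer <- table(nodeInfo$layer)
  retainedPerLayer <- table(factor(nodes$layer, levels = names(inputPerLayer)))
  new("TranskingdomNetwork", graph = g, nodes = nodes, edges = edges,
      report = list(
        n_candidates = n_candidates, n_retained = nrow(edges), puc = puc,
        skipped_pairs = as.integer(skipped),
        n_input = as.list(inputPerLayer),
        n_retained_nodes = as.list(retainedPerLayer),
        isolated = setdiff(nodeInfo$node, usedNodes)
      ))
}

#' Build a transkingdom network from a dataset and differential screens
#'
#' Orchestrates the construction: features passing their layer's
#' differential screen enter; microbial layers are CLR-normalized before
#' correlation; per-group correlations, Fisher meta-analysis and the
#' sign-consistency / FDR / coherence filter produce the network.
#'
#' @param dataset a \linkS4class{MultiOmicsDataset}.
#' @param diffResults named list (one element per layer of
#'   \code{dataset}) of data.frames from [twoGroupDifferential()].
#' @param fdr edge FDR (default 0.05).
#' @param method correlation method, "spearman" or "pearson".
#' @param requireCoherence enforce fold-change coherence (default TRUE).
#' @param excludeCrossCompartment drop ileum x colon microbe pairs
#'   (default TRUE).
#' @param pseudocount CLR pseudocount for microbial layers.
#' @return a \linkS4class{TranskingdomNetwork}; its
#'   [constructionReport()] carries candidate/retained counts and PUC.
#' @examples
#' sim <- generateDataset(simulationConfig(nPerGroup = 8, nMicrobesA = 10,
#'   nMicrobesB = 10, nGenes = 15, seed = 3))
#' dr <- screenLayers(sim$dataset)
#' net <- buildNetwork(sim$dataset, dr)
#' net
#' @export
buildNetwork <- function(dataset, diffResults, fdr = 0.05,
                         method = c("spearman", "pearson"),
                         requireCoherence = TRUE,
                         excludeCrossCompartment = TRUE, pseudocount = 0.5) {
  method <- match.arg(method)
  stopifnot(is(dataset, "MultiOmicsDataset"))
  lyr <- layerNames(dataset)
  if (length(lyr) < 2L) stop("need at least two layers")
  if (!all(lyr %in% names(diffResults)))
    stop("diffResults must cover every layer: missing ",
         paste(setdiff(lyr, names(diffResults)), collapse = ", "))
  info <- layerInfo(dataset)

  blocks <- list(); rows <- list()
  for (nm in lyr) {
    dr <- diffResults[[nm]]
    pass <- dr$feature[dr$pass]
    if (!length(pass)) next
    m <- assayLayer(dataset, nm)[pass, , drop = FALSE]
    kind <- info$kind[info$layer == nm]
    if (kind == "microbe") m <- clrTransform(m, pseudocount)
    rownames(m) <- nodeId(nm, rownames(m))
    blocks[[nm]] <- m
    drp <- dr[dr$pass, , drop = FALSE]
    rows[[nm]] <- data.frame(
      node = nodeId(nm, drp$feature), layer = nm, kind = kind,
      compartment = info$compartment[info$layer == nm],
      lfc = drp$lfc, q = drp$q, stringsAsFactors = FALSE
    )
  }
  if (length(blocks) < 2L)
    stop("fewer than two layers have features passing the differential screen")
  values <- do.call(rbind, blocks)
  nodeInfo <- do.call(rbind, rows)
  rownames(nodeInfo) <- NULL

  cand <- pairwiseCorrelations(values, dietLabels(dataset), nodeInfo,
                               method = method,
                               excludeCrossCompartment = excludeCrossCompartment)
  filterEdges(cand, nodeInfo, fdr = fdr, requireCoherence = requireCoherence)
}

#' Run the two-group differential screen on every layer
#'
#' Microbial layers are CLR-normalized first (their test then runs on
#' CLR values, whose fold change is a mean difference); host layers are
#' tested on their native scale.
#'
#' @inheritParams buildNetwork
#' @param method two-group test, "mw" or "welch".
#' @param fdr screen FDR per layer.
#' @return named list of data.frames (one per layer).
#' @export
screenLayers <- function(dataset, method = c("mw", "welch"), fdr = 0.05,
                         pseudocount = 0.5) {
  method <- match.arg(method)
  info <- layerInfo(dataset)
  diet <- dietLabels(dataset)
  out <- lapply(layerNames(dataset), function(nm) {
    m <- assayLayer(dataset, nm)
    if (info$kind[info$layer == nm] == "microbe")
      m <- clrTransform(m, pseudocount)
    twoGroupDifferential(m, diet, method = method, pseudocount = pseudocount,
                         fdr = fdr)
  })
  stats::setNames(out, layerNames(dataset))
}
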