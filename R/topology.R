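.asGraph <- function(network) {
  if (is(network, "TranskingdomNetwork")) asIgraph(network)
  else if (igraph::is_igraph(network)) network
  else stop("'network' must be a TranskingdomNetwork or an igraph")
}

.checkSets <- function(g, set1, set2) {
  vn <- igraph::V(g)$name
  if (!length(set1) || !length(set2)) stop("node sets must be nonempty")
  if (length(intersect(set1, set2))) stop("node sets must be disjoint")
  miss <- setdiff(c(set1, set2), vn)
  if (length(miss)) stop("nodes absent from network: ",
                         paste(utils::head(miss, 3), collapse = ", "))
}

#' Chi-square comparison of network retention between two compartments
#'
#' Tests whether the proportion of input (differential) features that
#' survive into the network with at least one edge differs between the
#' compartments: a 2x2 chi-square on retained/dropped x compartment,
#' without Yates continuity correction by default.
#'
#' @param nInA,nRetainedA input and retained feature counts, compartment A.
#' @param nInB,nRetainedB same for compartment B.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list: statistic, p, proportions, and the 2x2 table. With a
#'   zero margin the p-value is NA with a warning.
#' @export
retentionComparison <- function(nInA, nRetainedA, nInB, nRetainedB,
                                correct = FALSE) {
  if (nRetainedA > nInA || nRetainedB > nInB)
    stop("retained count cannot exceed input count")
  tab <- matrix(c(nRetainedA, nInA - nRetainedA,
                  nRetainedB, nInB - nRetainedB),
                nrow = 2, byrow = TRUE,
                dimnames = list(compartment = c("A", "B"),
                                status = c("retained", "dropped")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in the retention table; chi-square undefined")
    return(list(statistic = NA_real_, p = NA_real_,
                proportions = c(A = nRetainedA / max(nInA, 1),
                                B = nRetainedB / max(nInB, 1)),
                table = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       proportions = c(A = nRetainedA / nInA, B = nRetainedB / nInB),
       table = tab)
}

#' Count edges linking two disjoint node sets
#'
#' @param network \linkS4class{TranskingdomNetwork} or igraph.
#' @param set1,set2 disjoint character vectors of node ids.
#' @return integer: edges with exactly one endpoint in each set.
#' @export
bipartiteEdgeCount <- function(network, set1, set2) {
  g <- .asGraph(network)
  .checkSets(g, set1, set2)
  el <- igraph::as_edgelist(g, names = TRUE)
  sum((el[, 1] %in% set1 & el[, 2] %in% set2) |
      (el[, 1] %in% set2 & el[, 2] %in% set1))
}

#' Degree distribution and power-law diagnostics
#'
#' Discrete maximum-likelihood exponent
#' \code{alpha = 1 + n / sum(ln(k / (kmin - 0.5)))} over degrees
#' \code{k >= kmin}, plus a descriptive log-log OLS R-squared of the
#' degree histogram. The claim a scale-free fit supports here is
#' qualitative; no bootstrap goodness-of-fit is attempted.
#'
#' @param network \linkS4class{TranskingdomNetwork}, igraph, or a bare
#'   numeric vector of degrees.
#' @param kmin minimum degree entering the MLE (default 1).
#' @return list: \code{alpha}, \code{r_squared}, \code{histogram}
#'   (data.frame degree/count), \code{n} (degrees used).
#' @export
degreePowerlaw <- function(network, kmin = 1) {
  k <- if (is.numeric(network)) network else igraph::degree(.asGraph(network))
  k <- k[k >= kmin]
  if (length(k) < 10L) stop("need >= 10 nodes with degree >= kmin")
  if (length(unique(k)) < 2L)
    stop("all degrees equal; power-law exponent undefined")
  alpha <- 1 + length(k) / sum(log(k / (kmin - 0.5)))
  tab <- table(k)
  hist <- data.frame(degree = as.integer(names(tab)),
                     count = as.integer(tab))
  fit <- stats::lm(log(count) ~ log(degree), data = hist)
  r2 <- if (nrow(hist) >= 3L) summary(fit)$r.squared else NA_real_
  list(alpha = alpha, r_squared = r2, histogram = hist, n = length(k))
}

#' Bipartite betweenness centrality (BIBC)
#'
#' For every node v, the sum over pairs (s in set1, t in set2) of
#' \code{sigma_st(v) / sigma_st}, where \code{sigma_st} counts shortest
#' s-t paths and \code{sigma_st(v)} those passing through v as an
#' interior node (endpoints never score for their own pairs). Pairs with
#' no connecting path contribute 0. Identifies bottleneck mediators of
#' information flow between, e.g., a compartment's microbes and the
#' liver transcriptome. Unweighted edges; computed by Brandes-style
#' dependency accumulation with sources restricted to set1 and endpoint
#' credit restricted to set2.
#'
#' @param network \linkS4class{TranskingdomNetwork} or igraph.
#' @param set1,set2 disjoint nonempty character vectors of node ids.
#' @return named numeric vector of BIBC scores over all network nodes.
#' @examples
#' g <- igraph::make_graph(~ a - m - b)
#' bibcScores(g, "a", "b")  # m scores 1
#' @export
bibcScores <- function(network, set1, set2) {
  g <- .asGraph(network)
  .checkSets(g, set1, set2)
  vn <- igraph::V(g)$name
  nv <- length(vn)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  src <- match(set1, vn)
  isTarget <- vn %in% set2
  score <- numeric(nv)

  for (s in src) {
    # BFS with shortest-path counting
    dist <- rep.int(-1L, nv); sigma <- numeric(nv)
    pred <- vector("list", nv)
    dist[s] <- 0L; sigma[s] <- 1
    queue <- integer(nv); qh <- 1L; qt <- 1L; queue[1L] <- s
    order <- integer(nv); no <- 0L
    while (qh <= qt) {
      v <- queue[qh]; qh <- qh + 1L
      no <- no + 1L; order[no] <- v
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          qt <- qt + 1L; queue[qt] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    # dependency accumulation, reverse BFS order; only set2 sinks credit
    delta <- numeric(nv)
    for (i in rev(seq_len(no))) {
      w <- order[i]
      coeff <- ((if (isTarget[w] && w != s) 1 else 0) + delta[w]) / sigma[w]
      for (v in pred[[w]]) delta[v] <- delta[v] + sigma[v] * coeff
    }
    delta[s] <- 0
    score <- score + delta
  }
  stats::setNames(score, vn)
}

#' Membership shares of the top-scoring fraction
#'
#' Takes the top \code{ceiling(fraction * n)} nodes by score — ties
#' broken by stable feature-id (name) order — and returns each group's
#' share of that top set.
#'
#' @param scores named numeric vector (e.g. BIBC over microbial nodes).
#' @param groups named character/factor giving each scored node's group;
#'   names must cover \code{names(scores)}.
#' @param fraction top fraction to select (default 0.20).
#' @return list: \code{shares} (named numeric, sums to 1), \code{top}
#'   (character vector of selected nodes), \code{k}.
#' @export
topFractionMembership <- function(scores, groups, fraction = 0.20) {
  if (!length(scores)) stop("empty score table")
  if (is.null(names(scores))) stop("scores must be named")
  if (!all(names(scores) %in% names(groups)))
    stop("groups must cover every scored node")
  k <- ceiling(fraction * length(scores))
  ord <- order(-scores, names(scores))
  top <- names(scores)[ord[seq_len(k)]]
  grp <- factor(as.character(groups[names(scores)]))
  shares <- table(factor(as.character(groups[top]), levels = levels(grp))) / k
  list(shares = stats::setNames(as.numeric(shares), names(shares)),
       top = top, k = k)
}

#' Set-to-set shortest-path closeness
#'
#' Breadth-first shortest-path length for every (s, t) pair across the
#' two sets on the unweighted network; unreachable pairs are excluded
#' from the distribution and counted. The mean of the distribution is
#' the closeness metric between, e.g., a gut compartment and a host
#' omic layer.
#'
#' @param network \linkS4class{TranskingdomNetwork} or igraph.
#' @param set1,set2 disjoint nonempty character vectors of node ids.
#' @return list: \code{lengths} (numeric multiset), \code{mean} (NA when
#'   nothing is reachable), \code{n_unreachable}, \code{n_pairs}.
#' @export
setCloseness <- function(network, set1, set2) {
  g <- .asGraph(network)
  .checkSets(g, set1, set2)
  d <- igraph::distances(g, v = set1, to = set2, weights = NA)
  lens <- as.numeric(d[is.finite(d)])
  list(lengths = lens,
       mean = if (length(lens)) mean(lens) else NA_real_,
       n_unreachable = sum(!is.finite(d)),
       n_pairs = length(d))
}

#' Wilcoxon rank-sum comparison of two path-length distributions
#'
#' Two-sided Mann-Whitney/Wilcoxon test; exact enumeration when both
#' samples have at most \code{exactMax} values and no ties straddle the
#' groups, tie-corrected normal approximation otherwise.
#'
#' @param dist1,dist2 nonempty numeric vectors (e.g. \code{lengths} from
#'   [setCloseness()]).
#' @param exactMax exact-enumeration size cutoff per sample (default 8).
#' @param exact force exact (TRUE) or approximate (FALSE); NULL = auto.
#' @return list: \code{statistic} (Mann-Whitney U of dist1), \code{p},
#'   \code{exact}.
#' @export
compareCloseness <- function(dist1, dist2, exactMax = 8, exact = NULL) {
  if (!length(dist1) || !length(dist2)) stop("distributions must be nonempty")
  ties <- anyDuplicated(c(dist1, dist2)) > 0
  if (is.null(exact))
    exact <- length(dist1) <= exactMax && length(dist2) <= exactMax && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(dist1, dist2, exact = exact, correct = !exact)
  )
  list(statistic = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Full two-compartment topology comparison report
#'
#' Assembles, for a built network: per-compartment retention and its
#' chi-square test, bipartite edge counts to each host layer, degree /
#' power-law diagnostics, per-compartment BIBC against each host layer
#' with top-fraction compartment shares, and set-to-set closeness with
#' Wilcoxon comparisons. Deterministic given the network.
#'
#' @param network a \linkS4class{TranskingdomNetwork} built by
#'   [buildNetwork()] (its construction report supplies per-layer input
#'   counts).
#' @param microbeLayers length-2 character, the compartment layers in
#'   (A, B) order; default \code{c("microbes_A", "microbes_B")}.
#' @param hostLayers character, host layers to compare against; defaults
#'   to every non-microbe layer present in the network.
#' @param topFraction BIBC hub fraction (default 0.20).
#' @return a \linkS4class{TopologyReport}.
#' @export
compartmentReport <- function(network, microbeLayers = c("microbes_A",
                                                         "microbes_B"),
                              hostLayers = NULL, topFraction = 0.20) {
  stopifnot(is(network, "TranskingdomNetwork"))
  nodes <- nodeTable(network)
  if (!all(c("layer", "compartment") %in% names(nodes)) || !nrow(nodes))
    stop("network nodes must carry layer/compartment tags")
  if (length(microbeLayers) != 2L)
    stop("exactly two microbe layers required")
  if (is.null(hostLayers))
    hostLayers <- setdiff(unique(nodes$layer), microbeLayers)
  if (!length(hostLayers)) stop("no host layers present in the network")

  rep <- constructionReport(network)
  nIn <- function(l) as.integer(rep$n_input[[l]] %||% 0L)
  setA <- layerNodes(network, microbeLayers[1])
  setB <- layerNodes(network, microbeLayers[2])
  retTab <- data.frame(
    compartment = microbeLayers,
    n_input = c(nIn(microbeLayers[1]), nIn(microbeLayers[2])),
    n_retained = c(length(setA), length(setB)),
    stringsAsFactors = FALSE
  )
  retTab$proportion <- ifelse(retTab$n_input > 0,
                              retTab$n_retained / retTab$n_input, NA)
  chisq <- retentionComparison(retTab$n_input[1], retTab$n_retained[1],
                               retTab$n_input[2], retTab$n_retained[2])

  edgeCounts <- do.call(rbind, lapply(hostLayers, function(h) {
    hs <- layerNodes(network, h)
    data.frame(
      compartment = microbeLayers,
      host_layer = h,
      n_edges = c(
        if (length(setA) && length(hs)) bipartiteEdgeCount(network, setA, hs) else 0L,
        if (length(setB) && length(hs)) bipartiteEdgeCount(network, setB, hs) else 0L
      ),
      stringsAsFactors = FALSE
    )
  }))

  deg <- tryCatch(degreePowerlaw(network),
                  error = function(e) list(alpha = NA_real_,
                                           r_squared = NA_real_,
                                           histogram = NULL, n = NA_integer_,
                                           message = conditionMessage(e)))

  microbes <- c(setA, setB)
  compartmentOf <- stats::setNames(nodes$layer, nodes$node)
  bibcList <- list()
  for (h in hostLayers) {
    hs <- layerNodes(network, h)
    for (i in 1:2) {
      ms <- if (i == 1) setA else setB
      key <- paste(microbeLayers[i], h, sep = "->")
      if (!length(ms) || !length(hs)) { bibcList[[key]] <- NULL; next }
      sc <- bibcScores(network, ms, hs)
      scm <- sc[microbes]
      tf <- topFractionMembership(scm, compartmentOf[microbes],
                                  fraction = topFraction)
      bibcList[[key]] <- list(
        scores = data.frame(node = names(scm), bibc = as.numeric(scm),
                            compartment = as.character(compartmentOf[microbes]),
                            top = names(scm) %in% tf$top,
                            stringsAsFactors = FALSE),
        top_shares = tf$shares, k = tf$k
      )
    }
  }

  closeness <- list()
  for (h in hostLayers) {
    hs <- layerNodes(network, h)
    c1 <- if (length(setA) && length(hs)) setCloseness(network, setA, hs) else
      list(lengths = numeric(), mean = NA_real_, n_unreachable = 0L,
           n_pairs = 0L)
    c2 <- if (length(setB) && length(hs)) setCloseness(network, setB, hs) else
      list(lengths = numeric(), mean = NA_real_, n_unreachable = 0L,
           n_pairs = 0L)
    wt <- if (length(c1$lengths) && length(c2$lengths))
      compareCloseness(c1$lengths, c2$lengths)
    else list(statistic = NA_real_, p = NA_real_, exact = NA)
    closeness[[h]] <- list(
      lengths1 = c1$lengths, lengths2 = c2$lengths,
      mean1 = c1$mean, mean2 = c2$mean,
      n_unreachable1 = c1$n_unreachable, n_unreachable2 = c2$n_unreachable,
      n_pairs1 = c1$n_pairs, n_pairs2 = c2$n_pairs,
      wilcoxon = wt
    )
  }

  new("TopologyReport",
      retention = list(table = retTab, chisq = chisq),
      edgeCounts = edgeCounts, degree = deg, bibc = bibcList,
      closeness = closeness)
}

#' Flatten a topology report to plain lists (JSON-ready)
#'
#' @param report a \linkS4class{TopologyReport}.
#' @return nested list of plain vectors/data.frames, suitable for
#'   \code{jsonlite::toJSON}; round-trips through JSON.
#' @export
reportToList <- function(report) {
  stopifnot(is(report, "TopologyReport"))
  list(
    retention = list(
      table = report@retention$table,
      chisq = list(statistic = report@retention$chisq$statistic,
                   p = report@retention$chisq$p)
    ),
    edge_counts = report@edgeCounts,
    degree = list(alpha = report@degree$alpha,
                  r_squared = report@degree$r_squared,
                  histogram = report@degree$histogram),
    bibc = lapply(report@bibc, function(b)
      list(top_shares = as.list(b$top_shares), k = b$k, scores = b$scores)),
    closeness = lapply(report@closeness, function(cl)
      list(mean1 = cl$mean1, mean2 = cl$mean2,
           n_unreachable1 = cl$n_unreachable1,
           n_unreachable2 = cl$n_unreachable2,
           n_pairs1 = cl$n_pairs1, n_pairs2 = cl$n_pairs2,
           lengths1 = cl$lengths1, lengths2 = cl$lengths2,
           wilcoxon = list(statistic = cl$wilcoxon$statistic,
                           p = cl$wilcoxon$p)))
  )
}
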