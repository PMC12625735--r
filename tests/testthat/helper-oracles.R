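# Independent reference implementations used as test oracles.
# These deliberately use brute force / enumeration, not the package's
# code paths.

# BH step-up reference: sort, p * m / rank, cumulative minimum from the
# largest p downward.
bhReference <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exhaustive BIBC: enumerate every shortest path of every (s, t) pair
# with igraph::all_shortest_paths and count interior passages.
bibcBruteForce <- function(g, set1, set2) {
  vn <- igraph::V(g)$name
  score <- stats::setNames(numeric(length(vn)), vn)
  for (s in set1) {
    asp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = s, to = set2, weights = NA))
    paths <- asp$vpaths %||% asp$res
    ends <- vapply(paths, function(p) igraph::as_ids(p)[length(p)],
                   character(1))
    for (t in unique(ends)) {
      pt <- paths[ends == t]
      ns <- length(pt)
      for (p in pt) {
        ids <- igraph::as_ids(p)
        interior <- ids[-c(1, length(ids))]
        if (length(interior)) score[interior] <- score[interior] + 1 / ns
      }
    }
  }
  score
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-pair BFS from scratch over an adjacency list (no igraph).
bfsDistance <- function(adj, from, to) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[from] <- 0
  q <- from
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) if (!is.finite(dist[w])) {
      dist[w] <- dist[v] + 1
      q <- c(q, w)
    }
  }
  dist[to]
}

adjacencyList <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

# Random connected-ish test graph with named vertices.
randomGraph <- function(n, p = 0.15) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# Type-II sums-of-squares F tests for a 2x2 design via explicit
# reduced-model residual sums of squares.
anovaType2Reference <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  rss <- function(form) sum(stats::resid(stats::lm(form))^2)
  rssFull <- rss(y ~ a * b)
  rssAB <- rss(y ~ a + b)
  dfRes <- length(y) - 4L
  ssA <- rss(y ~ b) - rssAB
  ssB <- rss(y ~ a) - rssAB
  ssAB <- rssAB - rssFull
  ms <- rssFull / dfRes
  list(F_a = ssA / ms, F_b = ssB / ms, F_ab = ssAB / ms, df_res = dfRes)
}

# Small all-layers config so simulation-heavy tests stay fast.
tinyConfig <- function(seed = 1, ...) {
  simulationConfig(nPerGroup = 8, nMicrobesA = 14, nMicrobesB = 14,
                   nGenes = 24, nMetabSerum = 6, nMetabLiver = 6,
                   nPhenotypes = 3, sequencingDepth = 5000,
                   dietEffectSD = 3, seed = seed, ...)
}
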