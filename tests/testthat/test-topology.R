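test_that("retention chi-square matches hand computation and is symmetric", {
  r0 <- retentionComparison(100, 50, 100, 50)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  # (100, 90) vs (100, 10): all expected cells are 50, chi2 = 4 * 40^2 / 50
  r1 <- retentionComparison(100, 90, 100, 10)
  O <- c(90, 10, 10, 90); E <- rep(50, 4)
  expect_equal(r1$statistic, sum((O - E)^2 / E))
  r2 <- retentionComparison(100, 10, 100, 90)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p, r2$p)

  expect_error(retentionComparison(10, 11, 10, 5), "exceed")
  expect_warning(rz <- retentionComparison(10, 0, 10, 0), "zero margin")
  expect_true(is.na(rz$p))
})

test_that("bipartite edge counting matches a brute-force double loop", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("c", paste0("l", 1:5))
  expect_equal(bipartiteEdgeCount(star, "c", paste0("l", 1:5)), 5L)
  expect_equal(bipartiteEdgeCount(star, "l1", "l2"), 0L)
  expect_error(bipartiteEdgeCount(star, c("c", "l1"), c("l1", "l2")),
               "disjoint")

  set.seed(11)
  for (i in 1:10) {
    g <- randomGraph(sample(10:25, 1))
    vn <- igraph::V(g)$name
    s1 <- sample(vn, 4); s2 <- sample(setdiff(vn, s1), 5)
    el <- igraph::as_edgelist(g)
    brute <- 0L
    for (r in seq_len(nrow(el)))
      for (a in s1) for (b in s2)
        if ((el[r, 1] == a && el[r, 2] == b) ||
            (el[r, 1] == b && el[r, 2] == a)) brute <- brute + 1L
    expect_equal(bipartiteEdgeCount(g, s1, s2), brute)
  }
})

test_that("power-law diagnostics: recovery, star histogram, count-scale invariance", {
  set.seed(12)
  kk <- 10:100000
  k <- sample(kk, 5000, TRUE, prob = kk^-2.5)
  est <- degreePowerlaw(k, kmin = 10)
  expect_gt(est$alpha, 2.3)
  expect_lt(est$alpha, 2.7)

  star <- igraph::make_star(12, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:12)
  ds <- degreePowerlaw(star)
  expect_equal(nrow(ds$histogram), 2L)  # degree 1 (x11) and degree 11

  # doubling every degree's count leaves the MLE unchanged
  set.seed(13)
  k2 <- sample(1:50, 200, TRUE, prob = (1:50)^-2)
  expect_equal(degreePowerlaw(k2)$alpha, degreePowerlaw(c(k2, k2))$alpha)

  expect_error(degreePowerlaw(rep(3, 20)), "equal")
  expect_error(degreePowerlaw(1:5), ">= 10")
})

test_that("BIBC on hand-built geodesics: single path and split diamond", {
  g <- igraph::make_graph(~ a - m - b)
  sc <- bibcScores(g, "a", "b")
  expect_equal(sc[["m"]], 1)
  expect_equal(sc[["a"]], 0)
  expect_equal(sc[["b"]], 0)

  # two equal geodesics a-m1-g1 and a-m2-g1 split the pair's unit mass
  d <- igraph::graph_from_literal(a - m1, a - m2, m1 - g1, m2 - g1)
  sd <- bibcScores(d, "a", "g1")
  expect_equal(sd[["m1"]], 0.5)
  expect_equal(sd[["m2"]], 0.5)
  expect_error(bibcScores(g, character(0), "b"), "nonempty")
  expect_error(bibcScores(g, c("a", "m"), c("m", "b")), "disjoint")
})

test_that("BIBC equals exhaustive shortest-path enumeration on random graphs", {
  set.seed(14)
  for (i in 1:25) {
    g <- randomGraph(sample(8:30, 1), p = runif(1, 0.08, 0.3))
    vn <- igraph::V(g)$name
    s1 <- sample(vn, sample(2:4, 1))
    s2 <- sample(setdiff(vn, s1), sample(2:5, 1))
    mine <- bibcScores(g, s1, s2)
    brute <- bibcBruteForce(g, s1, s2)
    expect_equal(mine, brute[names(mine)], tolerance = 1e-9)
  }
})

test_that("total BIBC equals the summed interior length of reachable geodesic bundles", {
  set.seed(15)
  for (i in 1:10) {
    g <- randomGraph(sample(10:30, 1), p = 0.12)
    vn <- igraph::V(g)$name
    s1 <- sample(vn, 3); s2 <- sample(setdiff(vn, s1), 4)
    d <- igraph::distances(g, v = s1, to = s2, weights = NA)
    expected <- sum(d[is.finite(d)] - 1)
    expect_equal(sum(bibcScores(g, s1, s2)), expected, tolerance = 1e-9)
  }
})

test_that("top-fraction membership uses the ceiling rule and stable tie-break", {
  sc <- stats::setNames(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), paste0("n", 1:10))
  gr <- stats::setNames(rep(c("A", "B"), 5), paste0("n", 1:10))
  out <- topFractionMembership(sc, gr, fraction = 0.20)
  expect_equal(out$k, 2L)
  expect_equal(sort(out$top), c("n1", "n2"))
  expect_equal(out$shares[["A"]], 0.5)

  # all scores tied: selection by feature-id order, shares follow it
  scTie <- stats::setNames(rep(1, 10), sprintf("m%02d", 10:1))
  grTie <- stats::setNames(rep(c("A", "B"), each = 5),
                           sprintf("m%02d", 1:10))
  outTie <- topFractionMembership(scTie, grTie, fraction = 0.4)
  expect_equal(outTie$top, sprintf("m%02d", 1:4))  # stable id order
  expect_equal(outTie$shares[["A"]], 1)

  allA <- topFractionMembership(sc, stats::setNames(rep("A", 10),
                                                    names(sc)))
  expect_equal(allA$shares[["A"]], 1)
  expect_error(topFractionMembership(numeric(0), gr), "empty")
})

test_that("set closeness matches per-pair BFS and is symmetric in its sets", {
  p <- igraph::make_graph(~ a - m - g)
  cl <- setCloseness(p, "a", "g")
  expect_equal(cl$lengths, 2)
  expect_equal(cl$mean, 2)

  kb <- igraph::make_full_bipartite_graph(3, 4)
  igraph::V(kb)$name <- c(paste0("a", 1:3), paste0("b", 1:4))
  clk <- setCloseness(kb, paste0("a", 1:3), paste0("b", 1:4))
  expect_true(all(clk$lengths == 1))
  expect_equal(clk$mean, 1)

  set.seed(16)
  for (i in 1:10) {
    g <- randomGraph(sample(8:30, 1), p = 0.12)
    vn <- igraph::V(g)$name
    s1 <- sample(vn, 3); s2 <- sample(setdiff(vn, s1), 4)
    cl <- setCloseness(g, s1, s2)
    adj <- adjacencyList(g)
    brute <- numeric(0)
    unreach <- 0L
    for (a in s1) for (b in s2) {
      d <- bfsDistance(adj, match(a, vn), match(b, vn))
      if (is.finite(d)) brute <- c(brute, d) else unreach <- unreach + 1L
    }
    expect_equal(sort(cl$lengths), sort(brute))
    expect_equal(cl$n_unreachable, unreach)
    expect_equal(cl$n_pairs, 12L)
    cl2 <- setCloseness(g, s2, s1)
    expect_equal(cl$mean, cl2$mean)
    expect_equal(sort(cl$lengths), sort(cl2$lengths))
  }
})

test_that("removing an edge never shortens any shortest path", {
  set.seed(17)
  for (i in 1:10) {
    g <- randomGraph(15, p = 0.25)
    if (igraph::ecount(g) < 2) next
    d0 <- igraph::distances(g, weights = NA)
    g2 <- igraph::delete_edges(g, sample(igraph::ecount(g), 1))
    d1 <- igraph::distances(g2, weights = NA)
    expect_true(all(d1 >= d0 - 1e-12))
  }
})

test_that("Wilcoxon closeness comparison: exact enumeration and tie-corrected approximation", {
  # {1,2} vs {3,4}: 1 of C(4,2)=6 orderings is as extreme, two-sided 1/3
  out <- compareCloseness(c(1, 2), c(3, 4))
  expect_true(out$exact)
  expect_equal(out$p, 1 / 3, tolerance = 1e-12)
  # enumeration oracle: all ways to label 4 ranks
  perms <- combn(4, 2)
  u <- apply(perms, 2, function(ix) sum(rank(1:4)[ix]) - 3)
  pEnum <- mean(u <= min(u)) * 2
  expect_equal(out$p, pEnum, tolerance = 1e-12)

  same <- compareCloseness(c(5, 6, 7), c(5, 6, 7), exact = FALSE)
  expect_gt(same$p, 0.99)

  set.seed(18)
  for (i in 1:10) {
    a <- sample(seq(0.1, 100, by = 0.1), 8)
    b <- sample(seq(0.15, 100, by = 0.1), 8)
    pe <- compareCloseness(a, b, exact = TRUE)$p
    pa <- compareCloseness(a, b, exact = FALSE)$p
    expect_lt(abs(pe - pa), 0.02)
  }
  expect_error(compareCloseness(numeric(0), 1), "nonempty")
})

test_that("compartment report assembles every panel and survives a JSON round-trip", {
  sim <- generateDataset(simulationConfig(nPerGroup = 10, nMicrobesA = 20,
                                          nMicrobesB = 20, nGenes = 30,
                                          nMetabSerum = 8, nMetabLiver = 8,
                                          nPhenotypes = 3, seed = 41))
  dr <- screenLayers(sim$dataset)
  net <- buildNetwork(sim$dataset, dr)
  rep <- compartmentReport(net)

  rt <- rep@retention$table
  expect_true(all(rt$proportion >= 0 & rt$proportion <= 1, na.rm = TRUE))
  expect_true(all(rep@edgeCounts$n_edges >= 0))
  for (nm in names(rep@closeness)) {
    cl <- rep@closeness[[nm]]
    expect_equal(length(cl$lengths1) + cl$n_unreachable1, cl$n_pairs1)
    if (length(cl$lengths1)) expect_gte(cl$mean1, 1)
  }
  for (b in rep@bibc) expect_true(all(b$scores$bibc >= -1e-12))

  lst <- reportToList(rep)
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA,
                         null = "null")
  back <- jsonlite::fromJSON(js, simplifyVector = TRUE)
  expect_equal(back$retention$chisq$statistic,
               lst$retention$chisq$statistic, tolerance = 1e-9)
  expect_equal(unlist(back$closeness$genes$lengths1),
               lst$closeness$genes$lengths1, tolerance = 1e-9)
})
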