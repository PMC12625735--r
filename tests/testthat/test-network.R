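# nodeInfo helper for hand-built candidate tables
mkNodeInfo <- function(nodes, lfc = rep(1, length(nodes)),
                       kind = rep("gene", length(nodes)),
                       compartment = rep(NA_character_, length(nodes))) {
  data.frame(node = nodes, layer = kind, kind = kind,
             compartment = compartment, lfc = lfc,
             q = rep(0.01, length(nodes)), stringsAsFactors = FALSE)
}

test_that("Fisher combination matches closed-form chi-square tails", {
  expect_equal(fisherCombine(c(1, 1)), 1)
  # df = 4 survival function is (1 + x/2) exp(-x/2): independent route
  x <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(x, 11.98293, tolerance = 1e-5)
  expect_equal(fisherCombine(c(0.05, 0.05)), (1 + x / 2) * exp(-x / 2),
               tolerance = 1e-9)
  expect_equal(fisherCombine(c(0.05, 0.05)), 0.01747866, tolerance = 1e-6)
  # k = 1 identity
  for (p in c(0.001, 0.3, 0.999)) expect_equal(fisherCombine(p), p,
                                               tolerance = 1e-12)
  expect_error(fisherCombine(1.2), "<= 1")
  expect_warning(out <- fisherCombine(c(0, 0.5)), "clamped")
  expect_true(out >= 0)
})

test_that("Fisher combination is permutation-symmetric and monotone", {
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(2:5, 1))
    expect_equal(fisherCombine(p), fisherCombine(sample(p)))
    j <- sample(length(p), 1)
    p2 <- p; p2[j] <- p[j] * runif(1)
    expect_lte(fisherCombine(p2), fisherCombine(p) + 1e-15)
  }
})

test_that("pairwise correlations: perfect monotone pairs, candidate counts, group separation", {
  diet <- rep(c("NC", "HFD"), each = 6)
  vals <- rbind(f1 = c(1:6, 1:6),      # identity in both groups
                f2 = c(1:6, 1:6)^3,    # monotone transform of f1
                f3 = c(6:1, 1:6))      # anti-monotone in NC, monotone in HFD
  ni <- mkNodeInfo(rownames(vals))
  cand <- pairwiseCorrelations(vals, diet, ni)
  expect_equal(nrow(cand), choose(3, 2))
  r12 <- cand[cand$node_a == "f1" & cand$node_b == "f2", ]
  expect_equal(r12$r_NC, 1)
  expect_equal(r12$r_HFD, 1)
  r13 <- cand[cand$node_a == "f1" & cand$node_b == "f3", ]
  expect_equal(r13$r_NC, -1)
  expect_equal(r13$r_HFD, 1)  # sign-inconsistent; the filter must drop it
  net <- filterEdges(cand, ni, fdr = 0.5, requireCoherence = FALSE)
  expect_false(any(edgeTable(net)$node_a == "f1" &
                   edgeTable(net)$node_b == "f3"))
})

test_that("candidate enumeration covers C(n,2) pairs and honors the cross-compartment exclusion", {
  set.seed(2)
  vals <- matrix(rnorm(10 * 24), 10, 24,
                 dimnames = list(paste0("f", 1:10), NULL))
  diet <- rep(c("NC", "HFD"), each = 12)
  ni <- mkNodeInfo(rownames(vals))
  expect_equal(nrow(pairwiseCorrelations(vals, diet, ni)), 45L)

  ni2 <- mkNodeInfo(rownames(vals),
                    kind = rep(c("microbe", "microbe"), each = 5),
                    compartment = rep(c("ileum", "colon"), each = 5))
  cand2 <- pairwiseCorrelations(vals, diet, ni2)
  expect_equal(nrow(cand2), 45L - 25L)  # 5x5 cross-compartment pairs dropped
  cand3 <- pairwiseCorrelations(vals, diet, ni2,
                                excludeCrossCompartment = FALSE)
  expect_equal(nrow(cand3), 45L)
})

test_that("constant-in-group features are skipped and logged", {
  vals <- rbind(f1 = c(1, 1, 1, 1, 2, 5, 3, 8),
                f2 = c(1, 3, 2, 4, 2, 5, 3, 8),
                f3 = rnorm(8))
  diet <- rep(c("NC", "HFD"), each = 4)
  ni <- mkNodeInfo(rownames(vals))
  cand <- pairwiseCorrelations(vals, diet, ni)
  expect_equal(attr(cand, "skipped"), 2L)  # both pairs involving f1
  expect_false("f1" %in% c(cand$node_a, cand$node_b))
})

test_that("Spearman candidate statistics are invariant under strictly monotone transforms", {
  set.seed(3)
  vals <- matrix(rnorm(6 * 16), 6, 16, dimnames = list(paste0("f", 1:6),
                                                       NULL))
  diet <- rep(c("NC", "HFD"), each = 8)
  ni <- mkNodeInfo(rownames(vals))
  base <- pairwiseCorrelations(vals, diet, ni)
  transforms <- list(function(x) exp(x), function(x) x^3,
                     function(x) atan(x) * 5 + 2)
  for (f in transforms) {
    v2 <- vals
    j <- sample(6, 1)
    v2[j, ] <- f(v2[j, ])
    out <- pairwiseCorrelations(v2, diet, ni)
    expect_equal(out$r_NC, base$r_NC, tolerance = 1e-12)
    expect_equal(out$combined_p, base$combined_p, tolerance = 1e-12)
  }
})

test_that("edge filtering applies sign consistency, FDR and coherence; PUC is reported", {
  cand <- data.frame(
    node_a = c("a", "a", "b", "c"), node_b = c("b", "c", "c", "d"),
    r_NC = c(0.9, 0.8, -0.9, 0.9), r_HFD = c(0.8, -0.8, -0.8, 0.85),
    p_NC = c(0.001, 0.001, 0.001, 0.001),
    p_HFD = c(0.002, 0.002, 0.002, 0.002), stringsAsFactors = FALSE)
  cand$combined_p <- apply(cand[, c("p_NC", "p_HFD")], 1, fisherCombine)
  # lfc signs: a +, b +, c -, d + -> a-b expects +, b-c expects -, c-d expects -
  ni <- mkNodeInfo(c("a", "b", "c", "d"), lfc = c(1, 2, -1, 3))
  net <- filterEdges(cand, ni, fdr = 0.05, requireCoherence = TRUE)
  et <- edgeTable(net)
  # a-c is sign-inconsistent (dropped before PUC); c-d is significant but
  # incoherent (+ correlation, expected -): enters PUC, removed by coherence
  expect_setequal(paste(et$node_a, et$node_b), c("a b", "b c"))
  expect_equal(constructionReport(net)$puc, 1 / 3)
  net2 <- filterEdges(cand, ni, fdr = 0.05, requireCoherence = FALSE)
  expect_equal(nrow(edgeTable(net2)), 3L)

  # threshold semantics: q = 0.04 retained at fdr 0.05
  one <- cand[1, ]
  net3 <- filterEdges(one, ni, fdr = 0.05)
  expect_equal(nrow(edgeTable(net3)), 1L)

  # all-inconsistent input: empty network, PUC missing
  flip <- cand[2, , drop = FALSE]
  net4 <- filterEdges(flip, ni, fdr = 0.05)
  expect_equal(nrow(edgeTable(net4)), 0L)
  expect_true(is.na(constructionReport(net4)$puc))
  expect_warning(filterEdges(cand[0, ], ni), "empty")
})

test_that("edge retention is monotone in the FDR threshold", {
  set.seed(4)
  sim <- generateDataset(tinyConfig(seed = 31))
  dr <- screenLayers(sim$dataset)
  key <- function(net) paste(edgeTable(net)$node_a, edgeTable(net)$node_b)
  n01 <- buildNetwork(sim$dataset, dr, fdr = 0.01)
  n05 <- buildNetwork(sim$dataset, dr, fdr = 0.05)
  expect_true(all(key(n01) %in% key(n05)))
})

test_that("network construction is deterministic and tags nodes completely", {
  sim <- generateDataset(tinyConfig(seed = 32))
  dr <- screenLayers(sim$dataset)
  n1 <- buildNetwork(sim$dataset, dr)
  n2 <- buildNetwork(sim$dataset, dr)
  expect_identical(edgeTable(n1), edgeTable(n2))
  nt <- nodeTable(n1)
  expect_true(all(!is.na(nt$layer)))
  expect_true(all(!is.na(nt$lfc)))
  expect_true(all(igraph::degree(asIgraph(n1)) >= 1))
  # retained node sets and input counts are mutually consistent
  rep <- constructionReport(n1)
  expect_equal(sum(unlist(rep$n_retained_nodes)), nrow(nt))
})

test_that("truth-coupled strong-compartment pairs are recovered above the false-edge rate", {
  sim <- generateDataset(simulationConfig(seed = 33))
  dr <- screenLayers(sim$dataset)
  net <- buildNetwork(sim$dataset, dr)
  et <- edgeTable(net)
  ekey <- c(paste(et$node_a, et$node_b), paste(et$node_b, et$node_a))
  tp <- coupledPairs(sim$truth)
  tpA <- tp[grepl("^microbes_A", tp$microbe), ]
  nodes <- nodeTable(net)$node
  inNet <- tpA$microbe %in% nodes & tpA$host %in% nodes
  tpA <- tpA[inNet, ]
  recovered <- mean(paste(tpA$microbe, tpA$host) %in% ekey)
  # false-edge rate among never-coupled candidate pairs
  allPairs <- paste(et$node_a, et$node_b)
  coupledKey <- c(paste(tp$microbe, tp$host), paste(tp$host, tp$microbe))
  isMH <- (grepl("^microbes", et$node_a) & !grepl("^microbes", et$node_b)) |
          (grepl("^microbes", et$node_b) & !grepl("^microbes", et$node_a))
  falseEdges <- sum(isMH & !(allPairs %in% coupledKey))
  nCand <- constructionReport(net)$n_candidates
  expect_gt(recovered, falseEdges / nCand)
})
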